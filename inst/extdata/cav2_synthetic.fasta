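>cav2_synthetic synthetic caveolin-2-like reference (162 aa); NOT the UniProt P51636-1 sequence: constructed stand-in carrying the printed features (fragment 77-88 FEISKYVMYKFL, Trp at 70/113/133, three-segment hydropathic architecture)
GSEQTDKPSQNSHTEGKDSPTQESNKGSDTPQHSEGNKSDQTPESNGKSDHTQESPNGSK
DTQESLIFLWLIFLILFEISKYVMYKFLLIFSGTSGSEEKEDEEKELIFLLIWALIVLIF
LAILFLIVLLIFWEEKEDEELIFLAILFLIVLLIFLSEQKDN
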