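---
title: "Characterizing protein-membrane interactions with memphys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing protein-membrane interactions with memphys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memphys)
library(dplyr)
```

memphys implements the computational side of a classic biophysical
characterization of a peripheral membrane protein — the workflow used to ask
whether a protein such as caveolin-2 binds lipid bilayers, whether it
recognizes cholesterol, and what the interaction does to its structure and
stability. The package covers six layers of that workflow: sequence motif
detection, interfacial hydropathy, disorder-profile summaries, far-UV
circular dichroism (CD), steady-state fluorescence (anisotropy, FRET,
binding titrations), and differential scanning calorimetry (DSC). A seeded
synthetic-data module makes every layer testable without instrument data.

## Cholesterol-recognition motifs

Cholesterol recognition in membrane proteins is commonly screened with
gapped consensus motifs. Reading N→C:

* **CRAC**: (L/V) – X₁₋₅ – (Y/F) – X₁₋₅ – (K/R)
* **CARC**: (K/R) – X₁₋₅ – (Y/F) – X₁₋₅ – (L/V) — the mirror of CRAC
* **CBM** (caveolin-binding motif): Φxxxx Φxx Φ with Φ aromatic (F, W, Y),
  fixed length 9

`scan_motifs()` reports **every** distinct span that admits a valid anchor
parse. We deliberately avoid greedy suppression: overlapping CARC/CBM
arrangements are biologically meaningful (a cholesterol-binding element
sitting inside a protein-interaction motif changes how accessible each is),
and `overlap_report()` quantifies exactly those intersections. When a span
admits several parses, the attached representative minimizes the first gap,
then the second — an arbitrary but deterministic tie-break; the span set
itself is parse-independent.

Two interpretation choices were genuinely open. First, Φ is taken as
{F, W, Y}: tryptophan is aromatic, and excluding it from a motif defined
only as "aromatic" would be an undocumented restriction. Second, the CARC
centre position is restricted to Y/F, as the consensus is usually printed;
some literature variants admit W there, so `carc_center_w = TRUE` widens it.
`X` in a sequence may occupy gap positions but never anchors — an unknown
residue cannot positively support a motif call.

Coordinates are 1-based inclusive throughout, and every sequence carries a
`numbering_offset` so that published fragment numbering (e.g. a peptide
spanning residues 77–88) is preserved in all reports:

```{r motifs}
frag <- protein_table("cav2_frag", "FEISKYVMYKFL", numbering_offset = 77)
scan_motifs(frag)
overlap_report(scan_motifs(frag))
```

## Interfacial hydropathy

`hydropathy_profile()` slides a window (default 19 residues, the width
conventionally used for interfacial scans of membrane proteins) along the
sequence and sums per-residue water→POPC-interface transfer free energies
from the published Wimley–White interfacial scale, embedded as
`ww_interfacial`. Negative windowed ΔG means partitioning into the bilayer
interface is favorable. Protonation-variant residues are fixed at the
standard neutral-pH choices (Asp⁻, Glu⁻, His⁰, Lys⁺, Arg⁺). Terminal
residues without a complete window receive no value — padding would invent
data.

`call_segments()` reports maximal runs of favorable window centres
(`dg < 0` by default). Because different hydropathy servers draw segment
boundaries differently (centre coordinates vs full-window coverage) and the
exact rule behind published segment tables is rarely stated, both
conventions are available (`expand = FALSE`/`TRUE`) and every segment table
records which one produced it. Exact reproduction of any particular
server's printed boundaries is therefore a calibration exercise, not a
guarantee; the robust outputs are the segment count and the coverage of
regions of interest.

The package ships `inst/extdata/cav2_synthetic.fasta`, a **synthetic**
caveolin-2-like reference (162 aa). It is not the database sequence of
caveolin-2; it is a constructed stand-in that carries the documented
landmark features — the printed fragment F77…L88 with its CARC/CBM overlap,
tryptophans at 70/113/133, and a three-segment hydrophobic architecture in
the 70–155 region separated by polar linkers — so that sequence-level
examples and tests are self-contained:

```{r hydropathy}
fa <- read_fasta(system.file("extdata", "cav2_synthetic.fasta",
                             package = "memphys"))
prof <- hydropathy_profile(fa)
call_segments(prof)
```

Disorder prediction itself (IUPred-style energy models) is out of scope;
`read_disorder_profile()` ingests any predictor's per-residue 0–1 scores
and `fraction_disordered()` summarizes the thresholded fraction (default
threshold 0.5, the conventional order/disorder midpoint) and the maximal
disordered regions.

## Far-UV circular dichroism

`to_mean_residue_ellipticity()` applies the standard conversion
[θ] = θ(mdeg) / (10 · l · c · n). The two diagnostics implemented are:

* `helix_ratio()` — the θ₂₂₂/θ₂₀₈ ratio, read by linear interpolation on
  the grid (grids are ≤ 2 nm, so curvature between points is negligible).
  A ratio **strictly** greater than 1 classifies as `coiled_coil`, else
  `isolated_helices`; the ratio is only defined when both ellipticities are
  negative. The ratio is invariant to positive rescaling, so it does not
  matter whether raw or mean-residue ellipticity is supplied.
* `classify_shape()` — 'w'-shaped (two minima, near 208 and 222 nm,
  α-helical) vs 'v'-shaped (single minimum near 215–222 nm, β-rich);
  minima are detected after a 3-point moving average (configurable) to
  stop grid-level noise from splitting a trough.

`deconvolve_cd()` estimates secondary-structure fractions by non-negative
least squares against a reference basis, normalized to sum to 1, with the
residual norm reported. Server-grade reference sets (and their algorithms)
are not redistributable, so the built-in `cd_basis_default()` is a
documented synthetic basis — five smooth band-shape classes
(regular/distorted helix, right-twisted strand, turn, other) — and any
user basis on a common grid is accepted. The deconvolution is validated by
recovery on constructed mixtures (exact to 10⁻⁶ noiseless; mean absolute
fraction error < 0.05 at 2% noise across the simplex), which is the
appropriate desk-testable property; published percentage decompositions
from proprietary servers are context, not targets.

## Fluorescence

Steady-state anisotropy uses the polarizer formula
r = (I∥ − G·I⊥)/(I∥ + 2G·I⊥) with the grating factor G = I₉₀/₀ / I₉₀/₉₀
(`anisotropy()`, `g_factor()`). When the 90° pair is present it is used;
otherwise G defaults to 1. `polarized_from_anisotropy()` inverts the
formula exactly and is what the generator uses, so anisotropy round-trips
are exact by construction.

Binding titrations are fitted with the single-site hyperbola
y(x) = baseline ± P₁·x/(Kd + x) (`fit_hyperbolic()`), by bounded
Levenberg–Marquardt with data-driven initialization and three seeded
restarts on non-convergence. The baseline is a free parameter by default —
fixing it to the x = 0 observation (available via `fix_baseline = TRUE`)
would propagate a single point's noise into every parameter. Flat series
are flagged (`amplitude_zero`) rather than fitted: a Kd from a zero-amplitude
curve is meaningless. FRET efficiency is fractional donor quenching,
E = 1 − F_DA/F_D (`fret_efficiency()`); apparent enhancement on noisy data
is reported as 0 with a warning, not an error. `quenching_curve()` converts
a donor-fluorescence-vs-acceptor series to fractional quenching and fits it
through the origin, with `quenching_at()` evaluating the fitted percent
quenching at any acceptor concentration.

```{r fluorescence}
ti <- simulate_scenario("anisotropy_titration", seed = 1)
fit <- fit_hyperbolic(ti$data, kind = "decrease")
glance(fit)
```

## Differential scanning calorimetry

`subtract_baseline()` removes a linear chemical baseline anchored on
pre- and post-transition windows (buffer-scan subtraction is assumed done
by the instrument software), warning when a window appears to sit on the
transition. `analyze_thermogram()` extracts Tm (apex of the corrected
trace, refined by a parabola through the apex and its neighbours),
the calorimetric enthalpy ΔH_cal (trapezoidal integral), and optionally a
two-state fit of Cp(T) = ΔH²K / (R·T²(1+K)²), K = exp[(ΔH/R)(1/Tm − 1/T)],
yielding the van't Hoff enthalpy. ΔCp between states is fixed at 0 (there
is rarely information to constrain it in a single scan; an option could
relax this). For genuinely two-state data ΔH_vH/ΔH_cal ≈ 1, and the test
suite asserts this self-consistency to 2%.

## The synthetic-data module

`simulate_scenario()` is first-class, tested code, and its defaults *are*
the study conditions the rest of the package is validated against:

| scenario | key defaults |
|---|---|
| `fret_titration` | Kd 0.75 µM; 8 points over 0–3 µM; baseline 100, amplitude 50 (a.u., artifact choices); noiseless unless overridden |
| `anisotropy_titration` | 30% cholesterol: r 0.21 → 0.17, Kd 0.48 µM; 0%/5% cholesterol: flat r 0.12 |
| `dph_quenching` | saturating quenching 0.9, Kd 1 µM → fitted 60% quenching at 2 µM |
| `fret_saturation` | donor 100, efficiency 0.16 → F_DA 84 |
| `polarized_baseline` | target r realized exactly; G 1.1 (artifact choice) |
| `dsc_three_condition` | Tm 55/60/64 °C, ΔH 200/300/360 kJ/mol for buffer / +SUV / +SUV+cholesterol (magnitudes are artifact choices; the ordering is the modeled finding) |
| `motif_plant` | 160-mer, anchor-free background, one CARC planted at 81–88 |
| `cd_mixture` | 0.6/0.4 regular/distorted helix mixture on the default basis |
| `disorder_profile` | 162 residues, disordered fraction 0.46, N-terminal block, Beta-distributed scores peaking just above 0.5 |

The binding/anisotropy/quenching/efficiency defaults encode the reported
parameters of the caveolin-2–liposome system (half-maximal concentrations,
plateaus, efficiencies); magnitudes the literature leaves in arbitrary
units are round numbers, marked "artifact choice" in
`scenario_defaults()`. Noise is Gaussian on observables and absent on
sequences — the simplest model consistent with steady-state instrument
noise. Identical `(scenario, seed, overrides)` give byte-identical output.

What the generator deliberately does **not** emulate: instrument-specific
noise spectra, photobleaching, inner-filter effects, scattering from
vesicles, multi-site or cooperative binding, and multi-transition
thermograms. Passing the recovery tests therefore shows the estimators are
correct for the stated data-generating models at realistic noise, not that
real spectra are guaranteed to be this well-behaved.

## Problem sizes and numerical choices

The validation suite uses sizes chosen to exercise each method well past
its asymptotic regime while staying instant on a laptop: motif-scanner
oracle equivalence on random sequences up to 60 residues; 100-seed
titration ensembles at σ = 5% of amplitude (the median recovered Kd must
lie within 15% of truth across Kd ∈ [0.3, 1] µM); 50-seed CD mixture and
DSC noise ensembles at 2% noise; DSC grids of 301 points over 30–90 °C.
Degenerate inputs are first-class: flat titrations, collinear bases,
peakless thermograms, all-gap alignments and empty hit lists all have
defined, tested behavior.

Other numerical choices: the Kd initial guess is the interpolated
half-amplitude concentration; the smoothing before CD minima detection is
a 3-point moving average; hyperbolic fits bound P₁ ≥ 0 and Kd > 0; the
two-state DSC fit is initialized at the apex Tm and the calorimetric
integral.

## The pipeline

`run_pipeline()` ties the stages together over on-disk inputs (FASTA,
TSV spectra/titrations/thermograms), validates every path before running
anything, runs each enabled stage independently, and writes per-stage TSV
or JSON reports plus a status summary; it raises a single error naming all
failed stages at the end. Reports are deterministic functions of the
inputs. As an R-native toolkit the package exposes this as a function
rather than a shell executable; `scripts/acceptance.R` shows the same
workflow driven non-interactively.

## Known limitations

* The consensus scanner is pattern-matching, not structure: motif hits are
  candidates for cholesterol interaction, and hydropathy segments are
  propensities, not measured topology.
* The CD basis is synthetic; absolute fraction estimates depend entirely
  on the basis supplied and are not comparable to proprietary-server
  decompositions.
* The two-state DSC model assumes ΔCp = 0 and a single transition.
* The bundled reference FASTA is a labelled synthetic stand-in, suitable
  for demonstrating and testing the machinery, not for biological
  inference about caveolin-2 itself.
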