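---
title: "Comparing amyloid fibril polymorphs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing amyloid fibril polymorphs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilnmr)
```

# Scope

Amyloid-β fibrils adopt a cross-β fold with two β-strand segments (roughly
residues 10–22 and 30–38 on the Aβ(1–40) numbering) connected by a turn,
and a disordered N-terminus. Post-translationally modified variants — here
the N-truncated pyroglutamate form, pGlu3-Aβ(3–40), in which glutamate 3 is
cyclized to a lactam — raise the question of whether the modification
changes the mature fibril architecture. `fibrilnmr` implements the
quantitative chain used to answer that question at single-residue
resolution: secondary chemical-shift analysis, referencing-independent
cross-dataset correlation, DIPSHIFT order-parameter extraction, DARR
contact staging, ThT kinetics, and cross-β diffraction analysis, plus
seeded generators for every input type.

The package operates on plain-text tables (TSV/CSV with `# key: value`
comment headers). It does not process raw spectra: peak picking, resonance
assignment, 2D image azimuthal integration and EM morphometry are upstream
of its contracts.

# Secondary chemical shifts

For residue *i* and nucleus *n* (Cα or Cβ), the secondary shift is
Δδ = δ_obs + offset − δ_rc(type, n), with δ_rc from a bundled random-coil
table (standard Wishart/Sykes values, DSS referencing; the file carries a
provenance string and can be replaced by the user). The per-table
referencing `offset` (default 0 ppm) makes TMS/DSS conversion explicit:
fibril shift sets are often TMS-referenced while coil tables are
DSS-referenced, and a silent mismatch would bias every Δδ.

Classification uses the canonical sign rule — β-strand pulls Cα down and
Cβ up, helix the mirror — with a significance threshold of 0.7 ppm
(conventional secondary-shift cut; both nuclei must pass). Glycine has no
Cβ and is classified on the Cα sign alone, or coil below threshold.
Pyroglutamate (residue code `Z`) has no random-coil reference; its records
are skipped with a message rather than silently dropped.

For cross-dataset comparison the package uses ΔΔ = ΔCα − ΔCβ, which is
exactly invariant under any constant referencing shift of the carbon
scale (the constant cancels in the difference); Gly consequently never
enters, and `correlate_dd()` reports the Pearson coefficient with the
matched-residue count over the index intersection. Where structural
polymorphism doubles a resonance, analyses use polymorph rank 1 (the more
intense form) by default; rank selection is an argument, since which form
published tables report is rarely stated.

# DIPSHIFT order parameters

A separated-local-field (DIPSHIFT) experiment encodes the motionally
averaged ¹H-¹³C dipolar coupling in an intensity modulation over one MAS
rotor period τ_r. For a single spin pair at crystallite orientation
(β, γ), the instantaneous coupling under MAS is

ω(t) = π δ_eff [√2 sin 2β cos(ω_r t + γ) − sin²β cos(2 ω_r t + 2γ)],

the accumulated phase Φ(t₁) = ∫₀^{t₁} ω dt has a closed form, and the
observed curve is the powder average I(t₁) = ⟨cos Φ(t₁)⟩, normalized to
I(0) = 1. Two structural facts follow directly and serve as internal
checks: the rotor echo I(τ_r) = 1 (the full-period phase integral
vanishes) and time-reversal symmetry I(t₁) = I(τ_r − t₁).

Numerical choices:

- **Powder average.** The default scheme is a 378-orientation ZCW-style
  set: cos β stratified uniformly (equal-area sampling, which carries the
  sin β solid-angle weight implicitly) with the azimuth advancing by the
  Fibonacci ratio, built as two 189-point spirals mirrored in γ. The
  mirroring makes the set closed under γ-negation, so the time-reversal
  symmetry above holds to machine precision rather than to the spiral's
  integration error; agreement with a dense 14 400-orientation product
  grid is ~1 × 10⁻⁴ in intensity. An explicit (β × γ) grid scheme is
  provided as the systematic reference.
- **Phase linearity.** Φ is linear in δ_eff, so a unit-phase matrix per
  (t₁ grid, powder) is precomputed and reused across coupling values;
  fitting cost is a cosine evaluation per trial coupling.
- **Coupling fit.** Coarse scan of 200 steps on [0, δ_max] followed by
  local golden-section/parabolic refinement; ties break toward the smaller
  coupling because the objective flattens near zero.
- **Constant-time detail.** Experimentally the modulation is acquired
  constant-time; the overall amplitude factor is absorbed by normalization
  and only the curve shape determines the coupling. This is an
  approximation, stated rather than hidden.

The order parameter is S = δ_eff / (κ δ_rigid), with δ_rigid = 22.7 kHz
(1.10 Å C–H bond) and κ the homonuclear-decoupling scale factor, default
the theoretical Lee-Goldburg value 1/√3 ≈ 0.577. Whether a given
laboratory used the theoretical or a calibrated scale is often
unreported, so κ is an explicit argument; both conventions are supported.
Fitted S marginally above 1 (≤ 1.05) is clipped to 1 with a flag — fit
noise — while larger values are rejected as evidence of a wrong rigid
limit or scale. Site-wise comparison of two S sets flags
|ΔS| > u_a + u_b, with 0.05 assumed where a record carries no
uncertainty (a typical DIPSHIFT fit uncertainty; error bars on published
order-parameter figures rarely state their computation). CH₂/CH₃ sites
are analyzed with the same single-pair model; multi-spin lineshapes are
out of scope and such sites should be interpreted with care.

# ThT kinetics

Fibrillation monitored by thioflavin T fluorescence is fitted with the
4-parameter logistic F(t) = F₀ + A/(1 + e^{−(t−t₅₀)/τ}) and the lag
reported as the tangent-intercept value t_lag = t₅₀ − 2τ (for the
logistic, the tangent construction at the midpoint and this closed form
coincide). Start values come from the data; the optimizer is
Levenberg-Marquardt (`minpack.lm::nls.lm`), run unbounded because bound
projection can stall the sharp-transition corner (τ → 0) at the
constraint; the logistic's (F₀, A, τ) → (F₀ + A, −A, −τ) sign symmetry is
canonicalized afterwards so amplitude and transition time are positive.
Standard errors come from the Gauss-Newton curvature at the optimum, and
the lag error includes the t₅₀–τ covariance. A trace whose running-median
range is below 3× the point-noise estimate is rejected as "no
transition" rather than fitted (the raw range of pure noise already spans
~5σ, hence the smoothing). Multi-well files are fitted per well and
reported as mean ± sd.

# DARR contacts and stage call

With long mixing (≈500 ms), ¹³C-¹³C DARR cross peaks report carbon pairs
within roughly 6 Å. A peak supports atom pair (a, b) when both coordinates
match the assigned shifts within 0.3 ppm (per dimension, default) in
either orientation; symmetric partners are merged, diagonal peaks
(|ω₁ − ω₂| < tol) are ignored, and only residue pairs with sequence
separation ≥ 2 are reported, since intra-residue and sequential peaks are
trivially present. Peaks matching several pairs within tolerance support
all of them, marked ambiguous. No distance is computed from intensity:
DARR here is a qualitative ≤ ~6 Å detector, and "absent" means "no peak
within tolerance" — the tolerance is the caller's lever.

The stage call uses two diagnostic contacts: Phe19–Leu34 (the interstrand
contact of the U-shaped mature fold) and Glu22–Ile31 (characteristic of
oligomers/protofibrils, absent in mature fibrils). Presence of (22, 31)
calls *intermediate* regardless of the rest; (19, 34) without (22, 31)
calls *mature*; neither calls *indeterminate*. The returned rationale
names the contacts that drove the call.

# Cross-β diffraction

Reflections on a 1D radial profile are found after subtracting a straight
line fitted to the first and last 10% of the angular grid. Candidate
local maxima are filtered by topographic prominence (height above the
higher of the two valley minima toward higher ground) at a default 10% of
the maximum background-subtracted intensity — a height-only cut would
keep noise wiggles riding on a peak top. Centers are refined to sub-grid
precision by a quadratic fit to log-intensity over the half-maximum
window (exact for a Gaussian line and noise-averaging; a 3-point parabola
is the fallback for very narrow peaks), then converted by Bragg's law
d = λ/(2 sin θ) with λ = 1.5418 Å (Cu Kα) by default. The cross-β call
requires one reflection in the interstrand window 4.6–4.8 Å and one in
the intersheet window 9.5–11.5 Å; the intersheet ring moves with
side-chain packing, hence the wide window.

# Synthetic data: what it emulates, and what it does not

Every generator is seeded per call and restores the global RNG state, so
outputs are bit-reproducible and tests cannot couple through hidden
state. Noiseless generators equal their forward models exactly; this is
tested by identity, not approximately.

- Shift tables: random-coil values ± the template offsets (2.0 ppm for
  both nuclei by default, a typical β-strand secondary-shift magnitude)
  with additive Gaussian noise, default sd 0.3 ppm (a realistic
  solid-state measurement-plus-linewidth uncertainty). The fibril
  template labels residues 10–22 and 30–38 β and the rest coil.
- Dephasing curves: the forward simulation at S·κ·δ_rigid plus additive
  Gaussian noise (default study conditions: MAS 5 kHz, 16 t₁ points,
  noise sd 0.02).
- ThT traces: the logistic times (1 + ε), ε Gaussian with sd 0.02 —
  fluorescence noise scales with signal, hence multiplicative; the 2%
  default is a typical plate-reader level, chosen once (the instrument
  noise magnitude is not a published value).
- Peak lists: both symmetric cross peaks per declared contact plus both
  orientations of every intra-residue pair, with coordinate jitter.
- Diffraction: Gaussian reflections on a constant background.

Real data differ in ways the generators deliberately do not model: no
lineshapes or overlap beyond coordinate jitter, no baseline drift in ThT
traces, no Lorentzian tails or texture in diffraction, no spin dynamics
beyond the single-pair dipolar model. Passing round-trip tests therefore
demonstrates correctness of the inference chain, not robustness to every
instrumental artifact.

The two study peptides are constructible by name:
`abeta_sequence("wt")` and `abeta_sequence("pglu3")`, the latter spanning
residues 3–40 with residue 3 typed `Z` (pyroglutamate). Because `Z` has
no random-coil reference, `gen_shift_table()` by default rejects
templates containing it (naming the residue); `skip_missing = TRUE`
instead emits no rows for such residues, which mirrors practice — the
pyroglutamate itself is not plotted in secondary-shift analyses.

# Pipeline and reproducibility

`make_fixtures()` writes a complete synthetic two-sample bundle (shift
tables, eight dephasing curves per sample with Ile31 raised in the
variant, three-well ThT files with true lags 7 h and 43 h, mature-preset
peak lists, cross-β profiles) plus a flat-TOML config and a manifest.
`run_pipeline()` executes the sections in fixed order (shifts →
correlation → dipshift → contacts → xrd → kinetics), marks missing
inputs "input absent", reports per-section rejections without aborting,
echoes every default into the report header, and writes byte-reproducible
`report.tsv`/`summary.txt` (numbers at 3 significant figures with units
in the labels). The config reader implements a minimal flat-TOML dialect
(sections, `key = value`, strings/numbers/booleans) — human-editable and
diff-able.

Test problem sizes are chosen to exercise the estimators well inside a
laptop-scale budget: 100-seed recovery loops for the secondary-shift
classifier, 200 seeded coupling fits across S = 0.1…1.0, a
14 400-orientation brute-force powder oracle evaluated at three rotor
phases, and 100-replicate lag-bias checks.

# Known limitations

- Single-pair dipolar model only; no relaxation, no multi-spin effects.
- The DIPSHIFT fit returns a point estimate; uncertainties enter at the
  comparison step as stated defaults, not from the curve fit itself.
- Contact "absence" is tolerance-relative; crowded spectral regions can
  make any tolerance choice ambiguous, and ambiguity is flagged rather
  than resolved.
- The random-coil reference is one literature convention; secondary-shift
  magnitudes (not ΔΔ comparisons) change with the chosen table.
- No mechanistic aggregation model is fitted; the logistic is an
  empirical descriptor and its lag convention (t₅₀ − 2τ) is one of
  several in use — stated explicitly so results are auditable.
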