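# fibrilnmr

Quantitative comparison of amyloid fibril polymorphs at single-residue
resolution, built around the biophysical toolchain used to characterize
amyloid-β (Aβ) fibrils: is a chemically modified fibril (such as the
N-truncated, pyroglutamate-bearing pGlu3-Aβ(3–40)) structurally the same as
the mature wildtype Aβ(1–40) fibril?

The package is aimed at solid-state NMR and protein-aggregation labs that
have per-residue chemical-shift tables, DIPSHIFT dephasing curves, DARR
cross-peak lists, ThT plate-reader traces and radial X-ray profiles, and
want the downstream numbers — secondary-structure calls, order parameters,
lag times, d-spacings, contact-based maturity calls — computed reproducibly
from plain-text inputs. A seeded synthetic-data module generates every
input type with realistic statistical structure, so the entire pipeline is
testable without a spectrometer.

## What it computes

**Secondary chemical shifts.** For each residue, Δδ = δ_obs − δ_rc against
a bundled random-coil reference. ΔCα ≤ −0.7 ppm together with ΔCβ ≥ +0.7
ppm calls β-strand; the mirrored pattern calls helix. The
referencing-independent metric ΔΔ = ΔCα − ΔCβ (undefined for Gly, which has
no Cβ) is compared across datasets by Pearson correlation — a constant
referencing offset cancels exactly, which is what makes cross-laboratory
comparison safe.

**DIPSHIFT order parameters.** The ¹H-¹³C dipolar dephasing over one MAS
rotor period is simulated as I(t₁) = ⟨cos Φ(t₁)⟩ with the accumulated phase
Φ evaluated in closed form per crystallite orientation and averaged over a
ZCW-style powder set. The effective coupling δ_eff is fitted by coarse-grid
plus golden-section least squares, and converted to a molecular order
parameter S = δ_eff / (κ·δ_rigid) with κ the homonuclear-decoupling scale
(Lee-Goldburg 1/√3 by default) and δ_rigid = 22.7 kHz the rigid-limit
one-bond C–H coupling. S = 1 is rigid; S = 0 is isotropic motion.

**ThT fibrillation kinetics.** F(t) = F₀ + A / (1 + exp(−(t − t₅₀)/τ)) is
fitted by Levenberg-Marquardt; the lag time is the tangent-intercept value
t_lag = t₅₀ − 2τ, with propagated standard errors.

**DARR contact staging.** Cross peaks matching assigned shifts within
tolerance (0.3 ppm default) yield inter-residue contacts; the Phe19–Leu34
interstrand contact with Glu22–Ile31 absent calls a *mature* fibril, while
a Glu22–Ile31 contact calls an *intermediate* (oligomer/protofibril) stage.

**Cross-β diffraction.** Reflections on a 1D radial profile are detected by
prominence after linear background subtraction and converted via Bragg's
law d = λ/(2 sin θ); one reflection near 4.7 Å (interstrand) plus one near
10 Å (intersheet) is the cross-β signature.

## Worked example

```r
library(fibrilnmr)

# Fibrillation kinetics: synthetic trace with true lag 13 - 2*3 = 7 h
trace <- gen_tht_trace(kinetics_preset(t50_h = 13, tau_h = 3,
                                       noise_frac = 0.02, seed = 7))
lag_time(fit_tht(trace))
#> $lag_h        $se_h
#> 6.90          0.18

# DIPSHIFT: a rigid backbone site (S = 0.95), fitted back from a 2%-noise curve
curve <- gen_dipshift_curve(S = 0.95, noise_sd = 0.02, seed = 7, site = "I31.CA")
order_parameter(fit_coupling(curve, 25000))
#>     site         S delta_eff_hz delta_rigid_hz     kappa
#> 1 I31.CA 0.938        12298         22700          0.577

# Cross-beta spacings from the reflection angles (Cu K-alpha)
bragg_d(c(18.881, 8.585))
#> 4.70 10.30

# Secondary structure: the two beta-strands of the fibril fold are recovered
rc  <- random_coil_table()
tab <- gen_shift_table(abeta_fibril_template("wt"), rc, seed = 7)
cls <- classify_ss(secondary_shift(tab, rc, quiet = TRUE))
table(cls[as.character(10:22)])
#> beta: 13
```

The fitted lag (6.90 ± 0.18 h) recovers the generating 7 h within its
standard error; the order parameter 0.938 recovers 0.95 within the ±0.05
fit uncertainty typical at this noise level; 18.881° and 8.585° convert to
the canonical 4.70 Å / 10.30 Å amyloid spacings.

The full two-sample comparison runs from a config file:

```r
make_fixtures("bundle", seed = 1)          # synthetic pGlu3 + WT input set
run_pipeline("bundle/config.toml", "out")  # writes out/report.tsv, out/summary.txt
```

or from the shell via the thin wrapper `inst/cli/fibrilnmr`
(`fixtures`, `report`, `shifts`, `correlate`, `dipshift`, `kinetics`,
`contacts`, `xrd` subcommands).

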