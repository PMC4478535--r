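---
title: "Population-dynamics estimation of chromosome loss rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-dynamics estimation of chromosome loss rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qctf)
```

## The assay and the forward model

The quantitative chromosome transmission fidelity (qCTF) assay reads
chromosome instability as a rate: the probability `m` per cell division
that a progeny cell lacks a reporter mini-chromosome (MC). Because the MC
represses a GFP reporter, the MC− subpopulation is directly countable by
flow cytometry, and a culture measured at the start and end of a
nonselective growth phase yields two ratios `R0` and `Rn` of MC− to MC+
cells plus, via OD readings, the number of divisions
`n = log2(OD_end / OD_start × dilution)`.

The package's generative convention is: each division of an MC+ cell
produces two progeny, each of which independently lacks the MC with
probability `m`. Per MC+ generation the MC+ pool therefore multiplies by
`a = 2(1−m)` and sheds `2m N+` cells into the MC− pool, which itself
multiplies by `2^(1/β)` — MC− cells complete `1/β` generations per MC+
generation, where `β = T−/T+` is the ratio of doubling times. Summing the
geometric series gives the expected ratio implemented in `forward_ratio()`:

$$R_n = R_0\,\rho^n + \frac{2m}{a}\,\frac{\rho^n - 1}{\rho - 1},
\qquad \rho = \frac{2^{1/\beta}}{a}.$$

This convention is pinned by an algebraic identity: at `β = 1` it
reproduces exactly the closed-form inverse
`m = 1 − ((1+R0)/(1+Rn))^(1/n)` (`estimate_m_beta1()`), which is the
standard formula for equal fitness. `n` is real-valued throughout, since
it derives from OD ratios rather than counted divisions, and the
closed-form expression above continues analytically to fractional `n`.

Key assumptions: whole-MC loss is the only route into the GFP+ pool (point
mutations in the repressor are not modelled); generations are synchronous;
loss is memoryless with a constant rate; the reporter is detectable in the
same generation as the loss (a one-generation delay can be switched on in
the simulator, see below).

## Inverse estimators

Three estimators recover `m` from `(R0, Rn, n)`:

* **Exact, equal fitness** (`estimate_m_beta1()`): the closed form above.
  This is the default for screens, where MC loss is assumed fitness-neutral.
* **Linearised** (`estimate_m_linear()`):
  `m ≈ (Rn − R0)/(n(1+Rn))`, the first-order expansion valid while the
  cumulative loss `m·n` is small. Its relative deviation from the exact
  inverse stays below 5% whenever `m·n ≤ 0.05` and grows monotonically with
  `m·n` — at the assay's basal operating point (`m ~ 1e−3`, `n ~ 5–16`) the
  two agree to about 1%.
* **General, fitness-corrected** (`estimate_m_general()`): both published
  conventions reduce to one scalar equation in an auxiliary root `q`,

  $$q^n R_n = R_0 + (2^{1-\gamma} - q)\,\frac{1-q^n}{1-q},
  \qquad m = 1 - 2^{\gamma-1} q,$$

  with `γ = 1/β` in `self_consistent` mode (the exact inverse of the
  forward model above) and `γ = β` in `conventional` mode (the as-published form, which corresponds to MC− cells multiplying by `2^β` per MC+
  generation). The two conventions cannot be reconciled for `β ≠ 1` — they
  even move in opposite directions along a `β` grid — so the package
  exposes both rather than silently choosing, with `self_consistent` as
  the default because it round-trips the package's own forward model to
  machine precision. At `β = 1` both collapse to the closed form.

### Numerical choices

The `q`-equation's residual is monotone in `q` on the search range. The
solver brackets the root against the `m = 0` point `q0 = 2^(1−γ)`
(expanding upward when `Rn` falls below the drift-only prediction, which
yields a negative rate) and runs `uniroot` at tolerance 1e−15; a missing
sign change raises an error naming the bracket. The geometric factor
`(1−q^n)/(1−q)` switches to its removable limit `n` within 1e−9 of `q = 1`.
In `self_consistent` mode the root is polished by three Newton steps
against `forward_ratio()` itself, so round-trip errors sit near machine
epsilon. Negative estimates (possible whenever `Rn < R0` by counting
noise) are reported, never clamped: clamping would bias replicate means
upward in the screen layer.

## Stochastic simulator

`simulate_population()` advances the two subpopulations in synchronous MC+
generations of length `T+`. Stochastically, the number of MC-retaining
progeny per generation is `Binomial(2N+, 1−m)`; the complement joins the
MC− pool, which multiplies by `2^(T+/T−)` with expectation-preserving
stochastic rounding (non-integer factors arise whenever `T− ≠ T+`).
Counts above 1e7 switch to a Gaussian approximation of the binomial —
beyond that scale the relative error of the approximation is below 1e−3 of
the standard deviation, and exact draws would dominate the runtime of
genome-scale screens. A deterministic mode replaces draws by expectations
and matches `forward_ratio()` to floating tolerance; this identity is
tested, making the simulator and estimator mutually validating but
independently implemented (recursion versus closed form).

`sample_events()` mimics acquisition: GFP+ events are
`Binomial(n_events, N−/(N+ + N−))`, intensities are drawn from two
log-normal modes (medians 100 and 10,000 a.u., log10-sd 0.2 — the
~100-fold separation characteristic of the de-repressed reporter), and
acquisition order is shuffled. OD readings are total cells times a
calibration constant with multiplicative log-normal noise (default CV 2%),
since OD serves purely as a division counter. The one-cell-cycle lag
before a fresh MC− cell becomes fluorescent is available as `gfp_delay`
(default off); at `m ~ 1e−3` it shifts measured ratios by roughly one
generation's worth of loss, i.e. about `m` itself, and the default keeps
the simulator aligned with the estimators' convention.

## Growth curves

`fit_growth_rate()` log-transforms OD, drops readings below an OD floor
(default 0.01) so blank-level noise cannot dominate, fits a second-order
(local quadratic) smoother, evaluates it on a 10× dense grid, and takes
the maximum numerical first derivative (central differences, one-sided at
the ends) as the specific growth rate `k`; the doubling time is `ln 2/k`.

A local quadratic (loess, degree 2, span 0.25, at least 8 points per
neighbourhood) was chosen over a penalized spline deliberately: the
maximum slope of a log-OD curve sits at the start of the observation
window whenever the culture starts well below carrying capacity, and
natural-boundary smoothing splines flatten the fit exactly there, biasing
doubling times upward by about 1% at 2% measurement noise. Local
polynomials of even degree remain design-unbiased to second order at
boundaries. On a noiseless exponential the fit is exact to <0.1% at any
amplitude (the log transform also makes `k` invariant to OD rescaling and
time shifts); on a 24-h logistic curve sampled every 15 min the recovered
doubling time is within 2% of the exponential-phase value, with or without
2% multiplicative noise (median over repeated draws). Curves of 12 or
fewer points fall back to an interpolating spline. A maximum slope below
1e−8/min is reported as "no growth" rather than a fit.

`beta_from_fits()` forms `β = T−/T+`; `compare_doubling_times()` wraps the
two-sided Welch t-test with explicit degenerate paths (identical values:
p = 1; zero variance with different means: complete separation, p
reported as 0).

## Gating

`auto_threshold()` estimates a kernel density of log10 intensity and
places the gate at the density minimum between the bulk GFP− mode and the
second population. Because a 0.25% positive population produces a KDE peak
three orders of magnitude lower than the bulk, the second mode is required
to be *prominent*: the density between it and the main peak must dip below
half the candidate's own height, which rejects KDE ripples riding on one
mode. With no prominent second mode the threshold falls back to the
geometric midpoint of the 1st and 99.9th percentiles. Ties at the
threshold count as negative — deterministic and conservative for rare
positives. Gating is one-dimensional on GFP intensity only; debris or
doublet pre-gating on scatter channels is the caller's responsibility for
real cytometer data, and is unnecessary for simulated events. This is a
documented limitation, not an oversight: the package's gate reproduces the
counting step, not an acquisition-quality pipeline.

## Screen statistics

Per replicate, `estimate_strain_cin()` composes fractions → ratios →
generations → estimator. Replicates aggregate to mean ± SEM; negative
per-replicate estimates are retained. Strains are compared to the control
by fold change of means and, by default, the Mann–Whitney U test — exact
two-sided p for group sizes ≤ 12 without ties (for fully separated 8-vs-8
groups the exact floor is `2/C(16,8) ≈ 1.55e−4`, comfortably below the
0.01 threshold), the tie-corrected normal approximation otherwise; a Welch
t-test is selectable. Hits require fold change > 1.5 (or < 1/1.5) *and*
P < 0.01; both tails are always reported because suppressor discovery
lives in the low tail. No multiple-testing correction is applied by
default — the raw-p rule is the screen's operating convention, and with
the exact test on 8 replicates it is conservative — but Benjamini–Hochberg
is available via `screen_config(p_adjust = "BH")` for users who prefer
FDR control across thousands of strains.

Primary (single-replicate) screens rank strains by `m` and carry the
`top_k_high` largest and `top_k_low` smallest forward; ties break
lexicographically by strain id so the selection is deterministic and
invariant to row order. `enrichment_test()` provides the conditional
two-sided Fisher exact p with a Haldane-corrected sample odds ratio for
downstream 2×2 contingency questions. `run_screen()` assumes `β = 1`
throughout (the high-throughput simplification; a `beta` override exists
in the config), logs failed replicates with reasons, and never drops rows
silently.

## Synthetic screens: what they do and do not emulate

`generate_screen()` reproduces the screen's operating point: a basal GFP+
fraction of about 0.25% of 0.2–0.3 million events per sample, 24-hour
growth phases, 8 replicates for validation screens, single replicates for
the ~5,000-strain primary stage, and planted fold changes spanning
1.5–10× (elevated) and 0.5–0.67× (suppressed). The basal loss rate
defaults to 1e−3 per division — a convention consistent with the
mini-chromosome's literature loss rate of order 1e−4–1e−3 and with the
basal GFP+ fraction accumulating over a few generations — not a measured
constant. Strain-to-strain nuisance variation is log-normal jitter on `m`
(CV 10%, configurable to 0), so null calibration is tested under
overdispersion rather than in an unrealistically clean regime.

The generator deliberately omits: saturation and dilution cycles within a
phase (cultures grow exponentially for the whole phase; OD is a division
counter, so only the start/end ratio matters), plate-position and batch
effects, evaporation, cross-contamination, transformation failures, cell
death, and any mutational route to GFP+ other than whole-MC loss. Passing
tests therefore demonstrate the correctness of the estimation and calling
machinery under the model's own assumptions, not robustness to every
artefact of real plates.

## Problem sizes in the validation experiments

The packaged experiments use: a 300-point parameter grid for solver round
trips (`m` 1e−4–1e−2, `β` 0.8–1.25, `n` 2–20, `R0` 0–0.05); 200 simulated
cultures at `m = 1e−3`, 10 generations, 3e5 events for stochastic
recovery; 50 noisy growth curves; 3e5-event gating mixtures; a 96-strain
null screen and 200 two-strain power screens at 8 replicates; and one
4919-strain single-replicate primary screen with 105/101 tail selection.
These sizes make every experiment reproducible in about a minute each on a
single core while keeping Monte-Carlo error well below the decision
margins involved.

## Known limitations

* The `β ≠ 1` exponent ambiguity is exposed, not resolved; conclusions
  sensitive to `β` should be checked under both conventions.
* The estimators treat `n` as exact; OD noise propagates into `m` in
  proportion to `m/n` and is small at screen settings, but very short
  phases (`n < 2`) amplify it.
* Gating assumes two log-normal-ish modes on one channel; heavily skewed
  autofluorescence or compensation artefacts require external pre-gating.
* The simulator's synchronous generations ignore cell-cycle structure; at
  the rates and depths simulated here the approximation error is far below
  counting noise, but it would matter for `m` approaching 0.1.
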