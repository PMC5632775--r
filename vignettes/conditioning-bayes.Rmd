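---
title: "Default Bayesian hypothesis tests for differential conditioning data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Default Bayesian hypothesis tests for differential conditioning data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condlab)
```

## The design and its hypotheses

Differential conditioning experiments present a reinforced stimulus
(CS1/CS+) and an unreinforced one (CS2/CS−) and measure a conditioned
response (CR) to each — startle EMG, skin conductance, US expectancy.
The quantity under test is the within-participant difference score
d = CS1 − CS2. condlab frames the question as a comparison of two
models of the standardized population effect δ:

* **H0**: δ = 0 — no differential responding;
* **H1**: δ ~ Cauchy(0, r) — differential responding of a priori
  unknown size, with the scale r controlling how much prior mass sits
  on large effects.

The prior odds P(H1)/P(H0) default to 1. The Bayes factor BF10 — the
ratio of the marginal likelihood of the data under H1 to that under
H0 — multiplies the prior odds into posterior odds, and BF01 = 1/BF10
quantifies evidence *for* the null, something a p-value cannot do and
something that matters when, e.g., testing whether CRs have converged
by the end of extinction.

## The Bayes factor and how it is computed

The data enter through the observed t statistic. Under fixed δ, t
follows a noncentral Student-t distribution with ν degrees of freedom
and noncentrality δ√N, where the *effective sample size* N is n for
the paired design (ν = n − 1) and n₁n₂/(n₁ + n₂) for the independent
design (ν = n₁ + n₂ − 2, matching the pooled-variance frequentist
test so t, ν and N always refer to one and the same design). Then

$$\mathrm{BF}_{10} \;=\; \frac{\int f_\nu(t;\,\delta\sqrt{N})\,
\mathrm{Cauchy}(\delta;\,0,r)\,d\delta}{f_\nu(t;\,0)}.$$

Two numerically independent routes to this integral are implemented:

1. **Primary — δ-integral.** The substitution δ = r·tan(θ) maps the
   real line onto (−π/2, π/2) and turns the Cauchy density into a flat
   1/π weight, leaving a smooth bounded integrand that adaptive
   quadrature (relative tolerance 1e−8) handles without tail
   truncation. The achieved error bound is stored in the result
   (`quad_error`); failure to converge is an error, never a silent
   `NaN`.
2. **Cross-check — g-mixture.** A Cauchy is a normal on δ whose
   variance g is mixed over an inverse-gamma(1/2, r²/2) density.
   Conditional on g the marginal of t is available in closed form, so
   BF10 is also a one-dimensional integral over g. Substituting
   g = r²u makes the mixing density scale-free, keeping the quadrature
   well-conditioned for any prior width including r → 0.

Every `bf_ttest()` call evaluates both and errors if they disagree
beyond a relative 1e−6; the observed disagreement (typically ~1e−10)
is stored in `cross_rel_diff`. BF01 is computed as the exact
reciprocal, never re-integrated.

```{r}
bf_ttest(2.92, n1 = 40)
```

Limiting behaviour worth knowing: as r → 0 H1 collapses onto H0 and
BF10 → 1; BF10 is symmetric in t and strictly increasing in |t|; for
moderate data it decreases in r once r passes a small crest (below).

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `scale` (r) | Cauchy prior width on δ (unitless, δ is standardized) | 0.707 | the conventional default of the JZS t-test family; 1 and √2 are the usual alternatives |
| `prior_odds` | P(H1)/P(H0) before the data | 1 | equal prior plausibility, the standard reporting convention |
| `alpha` | significance level for p-value labels | .05 | field convention; pass e.g. .016 for Bonferroni-corrected batteries |
| `scales` | robustness grid | 0.1–2.0 by 0.05, plus 0.707/1/1.414 | spans "narrow" to "very wide" priors; the three conventional scales are always included and highlighted |

## Sensitivity analysis

Because different priors give different Bayes factors by construction,
`bf_sensitivity()` recomputes BF10 over the scale grid. Wider priors
put mass on large effects the data do not support, so for moderate
evidence BF10 falls as r grows; the report flags whether the
*direction* (which hypothesis is favoured) is stable over the grid,
and deliberately imposes no further numeric robustness verdict.

```{r}
curve <- bf_sensitivity(2.92, n1 = 40, scales = seq(0.3, 2, by = 0.05))
head(as.data.frame(curve), 4)
```

A detail visible at fine grid resolution: the curve is not monotone
from r = 0 — for the example above it crests near r ≈ 0.36 before its
monotone decline. Very narrow priors are themselves close to H0, which
caps BF10 near 1; the decline "after the scale passes ~0.3" is the
regime the robustness plot shows.

## Evidence categories and the report

`bf_category()` grades whichever of BF10/BF01 exceeds 1 on the
classical bands: anecdotal (1–3, "not worth more than a bare
mention"), substantial (3–10), strong (10–30), very strong (30–100),
decisive (> 100); boundaries are half-open (a BF of exactly 3 is still
anecdotal) and a BF of exactly 1 supports neither hypothesis. An
alternative vocabulary in circulation calls the 3–10 band "moderate";
the labels above are the ones this package prints, and users quoting a
BF of, say, 6.6 should be aware some authors would verbally upgrade
it.

`render_report()` is deterministic (byte-identical across runs and
locales; "." decimal separator enforced) and purely presentational:
t, d and BFs display at 2 decimals, p at 3 with a "< .001" floor,
while every stored number remains full precision and is exported
unrounded by `write_results()` (JSON at 17 significant digits for an
exact binary64 round-trip). Interpretation sentences are a pure
toggle, appended only on request, and state that they are generated
from the numerical values alone.

## The synthetic-data generator

`simulate_cs()` draws (CS1, CS2) pairs from a bivariate normal with
condition means μ₁/μ₂, common SD σ and within-subject correlation ρ —
exactly the noise model the paired t-statistic assumes, which is the
point: calibration claims (type-I error, evidence accumulation) are
made under the tests' own assumptions. The implied standardized paired
effect is δ = (μ₁ − μ₂)/(σ√(2(1 − ρ))). Defaults ρ = 0.5 and σ in
low single-digit CR units mirror the within-subject dependence typical
of averaged psychophysiological responses. What the generator does
*not* emulate — and what green tests therefore do not certify for real
data — are the skew of raw startle magnitudes, non-responders,
habituation drift, and trial-level autocorrelation; per-stimulus
averaging is assumed done upstream. `null_batch()` derives replicate
seeds from the base seed by a counter, so any replicate can be
regenerated singly; RNG kind is pinned (Mersenne-Twister/inversion)
and the caller's RNG state is restored.

```{r}
tbl <- simulate_cs(n = 40, mu1 = 5, mu2 = 4.4, sigma = 2, rho = 0.5, seed = 7)
glance(cs_analyze(tbl, sensitivity = FALSE))
```

## Numerical and design choices

* **Listwise deletion** for missing/non-finite values, with a message
  reporting the count: the paired design needs aligned CS1/CS2 scores,
  and silent imputation would be worse than transparent dropping.
* **Groups**: exactly two levels, ordered by first appearance — a
  stable sign convention for the group contrast; the independent test
  uses pooled variance (not Welch) so its ν matches the Bayesian
  effective-N algebra.
* **Degenerate inputs**: zero-variance difference scores raise an
  explicit error (the t statistic is undefined) rather than returning
  `Inf`/`NaN`.
* **Two-sided tests only**; directional priors and posterior
  distributions for δ are out of scope.
* **Problem sizes in the test suite**: calibration uses 5,000 null
  datasets of n = 30 (type-I error within 3 binomial SEs of .05),
  evidence-for-null checks 200 replicates of n = 500, oracle agreement
  1,000 random small tables — sizes at which the binomial/CLT bounds
  quoted in the tests are sharp while the whole suite stays
  interactive.

## Limitations

Only two stimuli and up to two groups (no ANOVA-style extensions);
normal-theory t statistics throughout (skewed raw responses should be
transformed or averaged first); the Cauchy is the only prior family,
so "informed" priors must be expressed through its scale; and Bayes
factors compare exactly the two hypotheses stated — they provide
relative, not absolute, evidence.
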