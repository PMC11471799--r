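---
title: "Modelling the sphingolipid rheostat: kinetics, control analysis and model comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the sphingolipid rheostat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sphingorheostat)
```

## The biological question

The sphingolipid rheostat — the interconversion chain ceramide ⇌
sphingosine ⇌ sphingosine-1-phosphate (S1P) — balances a pro-apoptotic
lipid (ceramide) against a pro-survival one (S1P). In the embryonic
zebrafish epidermis, loss of the protease inhibitor Hai1a raises
Matriptase and thereby sphingosine kinase (SphK) activity, which should
drain the ceramide side of the rheostat. Measured C16 ceramide is indeed
reduced in mutants at 2 days post fertilization (dpf), yet by 4 dpf
mutants show *more* ceramide than their wild-type siblings, along with
elevated sphinganine, the reporter of de novo synthesis. This package
asks, with a model: can the plain rheostat produce that reversal, and if
not, does a negative feedback from ceramide onto de novo synthesis
explain it?

## The models

Both models are pure mass action: interconversions are first order,
synthesis inputs are zero order, so the state equation is affine-linear,
$\dot x = A x + b$. This is a deliberate modelling commitment, not a
simplification of record: it makes steady states a linear solve, makes
trajectories available in closed form through the matrix exponential
$x(t) = x^* + e^{At}(x_0 - x^*)$, and keeps every downstream quantity
(control coefficients, likelihoods) analytically checkable.

**Core model** (three species, used for control analysis): ceramide
$x_1$, sphingosine $x_2$, S1P $x_3$, with reactions

* v1: boundary exchange, zero-order synthesis $k_0$ minus first-order
  reverse $k_{1r} x_1$. The synthesis lumps de novo production and
  sphingomyelin conversion into one boundary condition. Making v1 an
  exchange (rather than pure influx) is the only assignment under which
  the first three reactions are all reversible while keeping S1P
  degradation (v4, rate $k_4 x_3$) separate and irreversible.
* v2: $k_{2f} x_1 - k_{2r} x_2$; v3 (SphK): $k_3 x_2 - k_{3r} x_3$.

**Extended model** (four species, used for calibration): sphinganine
$x_{sa}$ enters via a zero-order de novo input $k_{00}$ and converts to
ceramide at $k_{01}$; downstream as in the core model. The extended model
deliberately has no separate ceramide boundary efflux: sphingomyelin
pools mirror ceramide in the measured data, so a distinct exchange would
be unidentifiable; sphingomyelin and very-long-chain ceramides are out of
scope.

**Condition dependence.** Genotype enters through a Boolean switch
$S_{on}$ (1 in wild type, 0 in the mutant — the switch marks the intact
inhibitor, not the lesion) acting on two apparent rates:
$$k_{3,app} = k_3\,(1 - S_{on}\,\alpha_{hai1a}), \qquad
  k_{00,app} = k_{00}\,(1 + S_{on}\,\alpha_{cer}).$$
$\alpha_{hai1a} \in [0.5, 1)$ encodes that wild-type SphK activity is at
least 50% below the mutant's. $\alpha_{cer} \in [-1, 0]$ is the negative
feedback: in wild type, where ceramide is plentiful, de novo synthesis is
throttled; in the mutant, where SphK has depleted ceramide below the
feedback threshold, synthesis runs free. We use the closed interval
$[-1, 0]$ although the inequality is sometimes written open, because the
boundary value $\alpha_{cer} = -1$ (synthesis fully off in wild type) is
exactly the setting of interest for the feedback scenario and estimated
feedback strengths run to that boundary. The threshold mechanism itself
is represented by the static per-condition switch, not by an explicit
ceramide-dependent switching function: with two time points and two
conditions the data cannot constrain a threshold's location or sharpness,
only the on/off contrast.

Time is measured in days with $t = 0$ at 2 dpf; all rate constants are
per day.

## Metabolic control analysis

Control coefficients are normalized steady-state sensitivities to
proportional scaling of whole reactions: a scaling $p_j$ multiplies all
rate constants of reaction $j$ (forward and reverse together — $k_0$ with
$k_{1r}$, $k_{2f}$ with $k_{2r}$, $k_3$ with $k_{3r}$, $k_4$ alone). This
is the standard convention under which the summation theorems
$\sum_j C^J_j = 1$ and $\sum_j C^{x_i}_j = 0$ hold exactly; both are
verified numerically on every call and property-tested over random
parameter draws. Implicit differentiation of the balance equations gives
$\partial x^*/\partial p_j = -A^{-1} N_{\cdot j} v_j^*$ with $N$ the
stoichiometry matrix and $v^*$ the net steady-state rates; the reference
flux is the effective downstream flux $J = v_4^* = k_4 x_3^*$, which all
net rates equal at steady state. An independent finite-difference
implementation (`control_coefficients_fd`) serves as oracle.

Scaled (logarithmic) coefficients are the primary output; unscaled
sensitivities are available behind a flag. A zero net rate at the
reference state makes the scaled elasticities undefined and is treated as
an error, not a limit.

The result that matters biologically: the concentration control
coefficient of ceramide with respect to the SphK reaction v3 is $\le 0$
for every positive parameter set, and strictly negative as soon as any
reverse or efflux rate is positive. Since the mutant is modelled solely
as an increase in $k_3$, the rheostat alone predicts ceramide depletion
in the mutant at steady state — the 4-dpf ceramide excess must come from
elsewhere. `k3_perturbation_report()` restates this as mutant/wild-type
steady-state ratios at a chosen fold change.

## Likelihood and calibration

Measurements $m_{j}(t_k)$ (pmol per mg protein) are modelled as
independent Gaussian readouts of scaled states,
$m = s_i\,x_i(t) + \varepsilon$, $\varepsilon \sim N(0, \sigma_i^2)$,
with one scaling factor $s_i$ and one noise parameter $\sigma_i$ per
species (scalings are needed because LC-MS readouts of different lipids
are not unit-convertible). The negative log-likelihood is the sum over
measurements of $\tfrac12\log(2\pi) + \log\sigma_i +
(s_i x_i(t) - m)^2 / (2\sigma_i^2)$.

**Initial conditions.** With data at only 2 and 4 dpf, the 2-dpf
measurements anchor the simulation: each observed species starts at its
2-dpf sample mean divided by its current scaling factor, so 2-dpf
predictions match the 2-dpf means exactly and the information in the data
is concentrated on the 2→4 dpf change. Latent species (S1P, which was not
quantified by mass spectrometry and is treated as unobserved by default)
start at a free parameter, `x0_s1p`, *shared between conditions*: the
conditions table carries only the genotype switch, so condition-specific
hidden initial pools are not part of the model. This is a substantive
choice — a per-condition latent initial would act as an unconstrained
per-condition input capable of mimicking almost any genotype contrast,
defeating the comparison the calibration is meant to make.

**Noise handling.** By default $\sigma_i$ is profiled out analytically:
the conditional maximiser is the root-mean-square residual
$\hat\sigma_i = \sqrt{\mathrm{mean}(r^2)}$ (`sigma_mle`), which is exact
for this likelihood and removes three parameters from the search. Joint
estimation is available (`sigma_mode = "estimate"`) and is tested to
agree with the profile at the optimum. A lower clamp
$\sigma_{min} = 10^{-8}$ avoids the degenerate spike on noise-free data.

**Optimisation.** Multi-start local optimisation: starts are drawn
log-uniformly within bounds (uniformly for the $\alpha$'s), each run uses
L-BFGS-B with finite-difference gradients on transformed parameters (all
positive parameters in log10, $\alpha$'s native), and the best endpoint
wins; ties cannot occur in practice but would resolve to the first start.
The full-size protocol uses 100 starts; the packaged experiments use 100
in the full-size analysis script and 25 elsewhere, sizes chosen so the
multi-start optimum is stable across seeds for this 12–13 parameter
problem. Rate bounds are $[10^{-3}, 10^3]$ day⁻¹; model-evaluation
failures inside the objective return a large penalty ($10^{10}$) by
default. The objective is compiled (RcppArmadillo) and propagates the
affine-linear system by matrix exponential, evaluating in ~50 µs; the
exported `negative_log_likelihood()` keeps a readable R implementation
that is pinned to the compiled one by tests.

**Model comparison.** The feedback variant frees $\alpha_{cer} \in
[-1, 0]$; the no-feedback variant fixes $\alpha_{cer} = 0$ and thus nests
inside it. `compare_variants()` fits both and shares optimisation basins
between them: the feedback fit is warm-started from the no-feedback
optimum, and the no-feedback fit is polished from the feedback optimum
projected onto $\alpha_{cer} = 0$. This makes the nesting inequality
(feedback NLL ≤ no-feedback NLL) hold up to optimiser tolerance rather
than up to multi-start luck. The verdict is not likelihood-based but
coverage-based, matching how the figures argue: a variant succeeds if its
4-dpf sphinganine and ceramide predictions lie inside the 95% confidence
intervals of the data in both conditions. Intervals are Student-t by
default (deterministic and exactly testable); a bootstrap-percentile
option exists because plotting libraries typically bootstrap their error
bars. 2-dpf cells are inside by construction and are flagged as such.

With two time points, individual rate constants are *not* identifiable
(only combinations such as $s_i k_{00,app}/k_{01}$ are), and the package
makes no claims about pointwise rate recovery; assessment is framed
entirely on fit quality, CI coverage, and the sign/boundary behaviour of
$\alpha_{cer}$.

## The synthetic-data generator

No raw lipidomics tables are redistributable, so the generator emulates
the study design from known ground truth: two conditions (wild type,
mutant), times {2, 4} dpf, four biological replicates, observables
{sphinganine, ceramide, sphingosine}, additive Gaussian noise per
species, values truncated at zero (with the count of truncation events
recorded; at the preset noise levels truncation is negligible by
construction).

The documented preset (`paper_like_truth`) uses $k_{00} = 2$,
$k_{01} = 0.6$, $k_{2f} = 1$, $k_{2r} = 0.5$, $k_3 = 2$, $k_{3r} = 0.1$,
$k_4 = 1$ day⁻¹, $\alpha_{hai1a} = 0.5$, and $\alpha_{cer} = -1$
(feedback) or $0$ (no feedback); 2-dpf states (sa, cer, sph, s1p) of
$(0.4, 1.0, 0.4, 0.2)$ in wild type and $(0.3, 0.7, 0.3, 0.4)$ in the
mutant (mutant ceramide below wild type, S1P above — the 2-dpf
phenotype); scalings $(20, 300, 25)$ placing ceramide in the hundreds of
pmol/mg and the sphingoid bases in the units-to-tens range typical of
LC-MS lipidomics; and noise $(0.8, 25, 1.2)$ pmol/mg, roughly 4–10%
coefficients of variation. The preset was constructed to satisfy, in its
noise-free trajectories, the qualitative data pattern: mutant ceramide
below wild type at 2 dpf and above at 4 dpf with mutant sphinganine
elevated (feedback variant), no crossing without feedback, all species
positive, and every measured cell at least ~3 noise standard deviations
above zero so the Gaussian noise model is effectively untruncated. These
constraints are asserted programmatically when the preset is built, and
the noise levels are the regime in which four replicates give confidence
intervals tight enough for the coverage-based model discrimination to
work — the regime a well-powered quadruplicate design operates in.

What the generator does *not* emulate: LC-MS acquisition, internal
standards, protein normalisation, technical-replicate hierarchy,
biological replicate correlations, or non-Gaussian heavy tails. Passing
tests therefore show that the inference machinery recovers structure
under its own assumptions at realistic magnitudes — not that those
assumptions hold for any particular real dataset.

## Numerical choices

* ODE engine: `deSolve::lsoda` (stiff-capable), defaults rtol $10^{-8}$ /
  atol $10^{-10}$, configurable; oracle comparisons that assert $10^{-8}$
  absolute agreement request rtol $10^{-10}$ / atol $10^{-12}$.
* The analytic engine uses `Matrix::expm`; the compiled objective uses
  `arma::expmat`. Solver-level negative undershoots are clipped at zero
  only within $10^{-8}$.
* Steady states by LU solve of $A x = -b$, rejected if the residual
  exceeds $10^{-10}$ (relative); a singular balance matrix (no outflow)
  is an error, not a limit.
* Finite-difference control coefficients use central differences on log
  coordinates, default relative step $10^{-4}$.
* Optimiser: maxit 200, factr $10^7$ per start; parameter transforms as
  above.
* Serialization: TSVs with 17 significant digits, sorted identifiers,
  Unix newlines; JSON reports with full-precision numbers and no
  timestamps — repeated runs are byte-identical, and the provenance block
  (package version, seed, start count, modes) suffices to re-run a
  comparison exactly.

## Problem sizes used in the packaged experiments

The test suite and the acceptance script run the control-analysis
properties on 100 random parameter draws, the simulation oracles on 50
draws, and the model-discrimination experiment on 20 synthetic datasets
with 25 starts per variant per dataset; `analysis/04_fit_variants.R`
runs the single-dataset comparison at the full 100 starts. These sizes
were chosen as the smallest at which the corresponding statistics are
stable across seeds.

## Known limitations

* No spatial or compartmental resolution (plasma-membrane versus
  intracellular pools), no sphingomyelin or C24/C26 ceramide dynamics,
  no stochastic kinetics.
* The feedback is a static genotype-linked switch; dynamic
  threshold-crossing within a condition is outside the model class.
* MCA applies to the core model only; the extended model is compared via
  calibration, not control coefficients.
* Parameter uncertainty is not quantified (no profile likelihoods or
  posterior sampling); the comparison rests on CI coverage of
  predictions, not on information criteria.
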