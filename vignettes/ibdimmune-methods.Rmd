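---
title: "Methods: a cytokine-network model of gut immune regulation in IBD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a cytokine-network model of gut immune regulation in IBD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdimmune)
```

## The model

Chronic intestinal inflammation in Crohn's-type IBD is treated here as a
shift of the gut mucosal immune network from one equilibrium to another.
The network couples fifteen tissue concentrations (all in g/cm^3^, rates in
week^-1^): two activated macrophage pools ($M_1$, $M_2$), the four helper
and regulatory T-cell lineages (Th1 $T_1$, Th2 $T_2$, Th17 $T_{17}$, Treg
$T_r$, each proxied in data by its master transcription factor T-bet,
GATA-3, ROR$\gamma$t, Foxp3), and nine cytokines (IFN-$\gamma$, IL-2, IL-4,
IL-6, IL-10, IL-12, IL-21, TNF-$\alpha$, TGF-$\beta$).

Cytokines are produced linearly by their source cells and decay first
order, e.g.

$$\frac{dI_\gamma}{dt} = \nu_{\gamma M} M_1 + \nu_{\gamma 1} T_1 - \delta_\gamma I_\gamma.$$

Two cytokine equations carry extra structure: IL-10 production by Treg is
amplified by IL-2 receptor occupancy through the bracket
$[1 + n_{2r}\, I_2/(\zeta_2 + I_2)]$, and IL-12 production is suppressed by
IL-10 through $1/(1 + I_{10}/\zeta_{10})$.

Cell dynamics combine saturating activation
($\mathrm{sat}(x;\zeta)=x/(\zeta+x)$, see `saturate()`) with hyperbolic
inhibition ($1/(1+x/c)$, see `inhibit()`). Undifferentiated macrophages
(fixed pool $M_0$) are activated to $M_1$ by TNF-$\alpha$ and to $M_2$ by
IL-10; $M_1 \leftrightarrow M_2$ transitions are driven by TGF-$\beta$ and
IFN-$\gamma$ and conserve $M_1+M_2$. Th1 is driven by IL-12
(IL-10-suppressed) plus IL-2 self-amplification and inhibited by Th2 and
Treg; Th2 by IL-4, inhibited by Th1 and Treg; Th17 by IL-21 and IL-6 gated
by TGF-$\beta$ and resisted by IFN-$\gamma$ and IL-4, inhibited by Treg;
Treg by TGF-$\beta$ and IL-10 gated by IL-2, damped by TNF-$\alpha$
($1/(1+I_\alpha/\zeta_\alpha)$), and inhibited by Th17. The full
right-hand side is `model_rhs()`; the state ordering is fixed by
`state_names()` (the source equations never fix one).

**The IL-10 bracket.** The printed form of the Treg IL-10 term has
$I_\gamma$ in the numerator over $\zeta_2 + I_2$; the surrounding
derivation defines the factor as IL-2 receptor occupancy, and only the
$I_2$ reading is dimensionally paired with $\zeta_2$ and reproduces the
published healthy IL-10 concentration. We implement $I_2$ and keep the
printed variant behind `eq8_numerator = "Igamma"` for auditability.

## Parameters and dialects

All rate constants and the inhibition constants $\gamma$ are taken
verbatim from the published value tables (`default_parameters("printed")`;
the packaged YAML config reproduces them). Half-saturation constants
$\zeta$ equal the healthy steady-state concentrations by construction.

The printed tables, however, are not mutually consistent: evaluated at the
published healthy state, the IFN-$\gamma$, IL-2, IL-6 and IL-12 balances
fail by factors of 2.7 to 37, the $M_2$ balance by 45%, IL-4 by 12% and
TGF-$\beta$ by 6%, while IL-10, IL-21, TNF-$\alpha$ and all four T-cell
balances close to within ~2% (`audit_printed_parameters()` documents every
equation). A runnable equilibrium model must resolve this explicitly, so
the package ships two dialects:

* `"printed"` — tables verbatim; not an equilibrium; used for audits and
  for single-balance arithmetic.
* `"self_consistent"` (default) — the calibration re-executed so the
  published healthy state is an *exact* fixed point: the estimated rates
  are kept at full precision instead of printed rounding, the macrophage
  basal rates are re-derived from the anchored macrophage densities
  ($f_1 = 1.6$, $f_2 = 17.47$), and each cytokine equation's production
  rates are rescaled by one common per-equation factor (preserving
  within-equation ratios) so its balance closes exactly.

Two equivalent constructions exist — rescale production rates onto the
published concentrations, or keep printed rates and rescale the
concentrations together with their $\zeta$'s — and they generate
identical cell dynamics (the cytokine rescaling is a per-species change of
units). We ship the former because it leaves the published steady state
and half-saturation table untouched. Supporting this reading, the IL-2
balance at the published state implies a production rate of
$8.05\times10^{-4}$, exactly the printed IL-21 production value one row
away, suggesting a table transposition rather than a modelling difference.

## Calibration

`calibrate_healthy()` reproduces the estimation chain. With
$\zeta = $ steady state, every saturation factor is exactly $1/2$ at
equilibrium and the system closes sequentially:

1. macrophage densities (anchored, with $f_1, f_2$ re-derived — the
   default, required to reproduce the published signalling maxima — or
   solved from the printed $f$'s via `macrophages = "balance"`);
2. $\nu_{6M} = \delta_6 I_6 / M_1$ from the anchored IL-6 concentration;
3. $\lambda_T$ — the common mRNA-to-density factor for the master
   regulators — pinned by the IL-10 balance, the only equation linking a
   known production rate to a T-cell density whose cytokine is anchored:
   $\lambda_T = (\delta_{10} I_{10} - \nu_{10M} M_2) /
   (\nu_{10r}(1 + n_{2r}/2)\,\overline{\mathrm{Foxp3}})$;
4. $\nu_{\alpha 1}$ from the TNF-$\alpha$ balance;
5. the four signalling maxima from the T-cell balances, now linear:
   e.g. $0.4\,(\sigma_{12} M/4 + \sigma_2 T_1/2) = \mu_1 T_1$ gives
   $\sigma_{12} = 10.93$; likewise $\sigma_4 = 1.94$,
   $\sigma_{21} = \sigma_6 = 156$, $\sigma_\beta = \sigma_{10} = 14.0$
   (all within 0.25% of the published estimates).

Anchoring follows the measurement convention: tissue cytokine
concentrations are proportional to mucosal mRNA means with one factor
$\lambda_c$ fixed by setting healthy IL-6 to $8.00\times10^{-6}$ g/cm^3^
(`anchor_cytokines()`). The tests verify the calibration against an
independent linear solve of the four reduced T-cell equations and check
dimensional homogeneity under joint rescaling of densities and anchors.

## Synthetic cohorts

The study's per-patient mucosal panels (IL-6, IL-10, TNF-$\alpha$, T-bet,
GATA-3, ROR$\gamma$t, Foxp3) are not deposited; only per-type group-mean
fold changes and the cohort split 7/18/17/16 survive. `generate_cohort()`
emulates exactly that structure:

* baseline healthy means (IL-6 800, IL-10 154, TNF-$\alpha$ 975, T-bet
  458, GATA-3 134, ROR$\gamma$t 3370, Foxp3 606 counts) chosen once so the
  anchoring reproduces the published healthy concentrations exactly
  ($\lambda_c = 10^{-8}$, $\lambda_T = 10^{-4}$);
* 20 healthy controls by default — the study never states its control
  count; 20 is typical for biopsy control panels;
* multiplicative log-normal noise, default CV 15% (expression panels are
  right-skewed and strictly positive), parameterised mean-correctly so
  the group mean is exact for every noise level;
* `enforce_types` redraws any record whose T-bet/GATA-3 signs contradict
  its own type. This guarantees label consistency but truncates those two
  marginals: at CV 20% the GATA-3 mean of Th1-high/Th2-low patients is
  biased by about $-3$ percentage points of fold change. The group-mean
  recovery test therefore runs with enforcement off; sign consistency is
  tested separately under the default. At the default CV 15% the bias is
  under 2 points.

What passing these tests shows — and does not show — about real data: the
generator reproduces the *group-mean* structure and positivity of
expression panels, not NanoString count technicalities (background,
positive-control normalisation), inter-gene correlation within a patient,
or heavy-tailed outliers. Classification and fitting results on synthetic
cohorts demonstrate pipeline correctness, not clinical performance.

## Stratification and the inverse problem

`classify_patient()` applies the strict sign rule on (T-bet, GATA-3)
versus the healthy means; a patient exactly at a healthy mean is
unclassifiable by that rule and raises an error rather than being silently
assigned (how the study would have typed such a patient is unstated).

`fit_type_parameters()` solves the inverse problem the per-type
deregulation table answers: find fractional changes of
$\nu_{\gamma 1}, \nu_{\alpha 1}, \nu_{\beta r}, \nu_{10r}, \sigma_{12},
\sigma_4, \sigma_{21}(=\sigma_6), \sigma_\beta(=\sigma_{10})$ whose
predicted equilibrium fold changes match the seven observed targets.
Design choices, each genuinely open:

* **Objective** — least squares on fractional changes with weights
  $1/(1+|t|)$: the evidence is stated entirely in fold-change language,
  and master-regulator folds equal T-cell density folds because
  $\lambda_T$ cancels.
* **Tied Treg production** — the published table carries identical
  $\nu_{\beta r}$ and $\nu_{10r}$ values in every type; tying them
  (default) leaves 7 free changes for 7 targets, which is locally
  identifiable. Untied (8 free) the problem is generically
  underdetermined by one dimension.
* **Optimizer** — bounded Levenberg–Marquardt with a finite-difference
  Jacobian over the equilibrium forward map, restarted from seeded points
  (first restart at zero). We first tried a derivative-free simplex
  search; over this violently nonlinear forward map it stalls at losses
  around $10^{-3}$, while Levenberg–Marquardt reaches $10^{-25}$ and
  recovers known deregulations exactly, so the least-squares structure is
  worth exploiting. Box bounds $[-0.999, 5]$.
* **Validity domain** — targets are restricted to $(-1, 10)$; outside the
  physiological fold-change regime the forward map runs into extreme
  states where many parameter combinations produce identical saturated
  observables.

Fitting the observed per-type fold changes reproduces the published
deregulation table's sign pattern in all four types and near-exact
magnitudes for three of them; the Th1-high/Th2-high type matches its
targets equally well (loss $\sim 10^{-21}$) at a larger
$\nu_{\gamma 1}/\sigma_{21}$ — with seven constraints the solution the
published fit selected there is not unique, as its own authors' framing
(a simulation-guided fit) suggests.

## Steady states and blockade

Two numerical points matter everywhere:

* **Scaled Newton** — the state spans eleven orders of magnitude
  (TGF-$\beta$ at $10^{-12}$, Th17 at $0.3$), so the raw Jacobian has
  condition number $\sim 10^{20}$; `find_steady_state()` solves the
  Newton step in variables scaled by the healthy state and accepts steps
  only while the residual decreases and the state stays non-negative
  (tolerance $10^{-10}$ on loss-normalised residuals).
* **Integrate first** — the system is multistable under strong
  deregulations. Newton (or parameter continuation) launched from the
  healthy state can converge to dynamically unreachable roots: for the
  Th1-high/Th2-low deregulation it lands on a state with a 118-fold Th1
  excess, while the trajectory actually reached from health settles at
  +38%. Steady states are therefore always located by integrating
  (`deSolve::lsoda`, rtol $10^{-8}$, atol $10^{-12}$, 100 weeks with a
  500-week fallback) and only then polishing; a polish that moves more
  than 20% from the integration endpoint is rejected.

`simulate_blockade()` models complete anti-TNF therapy as the source
text states it: TNF-$\alpha$ clamped to zero, its equation removed, the
macrophage activation term gone and the Treg damping lifted. An
equivalent implementation (TNF-$\alpha$ production rates sent to zero) is
kept as an internal cross-check; the two agree to $<0.1$%. A `dose`
parameter (fraction of TNF-$\alpha$ production remaining) exposes partial
blockade but defaults to the complete case.

**Baseline convention.** Published blockade percentages include a "105%
decrease", impossible relative to pre-treatment. Changes divided by the
*healthy* level can exceed 100% and indeed reproduce the published
numbers within the stated 20-point band (Th1-high/Th2-low: Th1 −77 vs 93,
Th17 −27 vs 40; Th1-high/Th2-high: Th1 −120 vs 105, Treg +108 vs 108;
the two Th1-low types: Th1 −34/−22 vs 35/34, Th17 −18/−17 vs 19/21, Treg
+19/+6 vs ~0). Both conventions are always computed and reported; the
healthy-baseline one is treated as primary. One qualitative departure:
in the Th1-high/Th2-high type our model sends Th17 *up* after blockade
(+69% of healthy) where the published narrative reports all types' Th17
falling; the published Th1/Treg responses for that type reproduce
regardless.

## Sensitivity analysis

`run_sensitivity()` draws 5000 Latin hypercube samples of the nine
activation rates ($\sigma_{M\alpha}, \sigma_{M10}, \sigma_{12}, \sigma_2,
\sigma_4, \sigma_{21}, \sigma_6, \sigma_\beta, \sigma_{10}$) uniformly
within ±20% of calibrated healthy values, integrates each from the healthy
equilibrium for 100 weeks (final-time outputs, as stated in the source;
a steady-state output option exists) and computes PRCCs: rank-transform
all columns, regress parameter and output ranks on the other parameters'
ranks, correlate the residuals. p-values use the standard t approximation
with $n - 2 - (k-1)$ degrees of freedom; significance flags use
$|\mathrm{PRCC}| > 0.5$ and $p < 0.01$. Draws that fail to integrate are
dropped listwise; more than 1% failures aborts (at ±20% we observe none).

Our run reproduces the headline mechanism — Th1 is controlled negatively
by the Treg activation rates $\sigma_\beta, \sigma_{10}$ and positively
by $\sigma_{12}$ — and matches the published sign pattern for the Th1
output except $\sigma_{M10}$. It does **not** reproduce the published
Th2 column, where Th2 co-moves with the Th1 drivers (published
$\sigma_{12}$–$T_2$ PRCC $+0.84$; ours $-0.88$). We probed this
extensively: printed dialect, self-consistent dialect, transient initial
conditions (zero and near-zero T-cell pools), and one-dimensional sweeps
all give a Th2 that falls when Th1 rises. Mechanistically, the two
channels by which Th1 feeds back on Treg — TNF-$\alpha$ damping
(negative) and IL-2-gated activation (positive) — cancel almost exactly
at the calibrated point, leaving the direct Th1→Th2 inhibition to
dominate; the published Th2 column would require the IL-2 channel to be
absent or saturated. Our coefficient magnitudes are also systematically
larger (e.g. $\sigma_{10}$–$T_1$ of $-0.92$ vs published $-0.69$), as
expected for a noise-free deterministic model with only nine varied
inputs. The acceptance checks report these discrepancies rather than
masking them; the corresponding acceptance test is expected to fail and
says so in its output.

## Problem sizes and determinism

Default sizes are the study's own: 5000 LHS draws, 100-week horizons,
cohort 58 patients + 20 controls. The test suite uses a 1000-draw
sensitivity variant (tolerance widened from ±0.15 to ±0.2) and 2-restart
fits; the analysis scripts under `analysis/` run the full sizes. Every
stochastic element (cohort draws, LHS, fit restarts) is governed by an
explicit integer seed, and pipeline manifests record seeds and output
checksums so any table can be regenerated exactly.

## Known limitations

* No spatial structure and no IL-5/IL-13/IL-17/IL-22 species.
* Equilibrium-only comparisons: no treatment time courses or
  pharmacokinetics of anti-TNF antibodies.
* Per-type (not per-patient) inverse fitting, mirroring the published
  group-mean analysis.
* The self-consistent dialect is one principled resolution of the
  published tables' internal inconsistencies; the source study's own
  resolution is unknowable from the printed record.
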