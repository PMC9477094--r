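---
title: "The pgxcea decision-analytic model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pgxcea decision-analytic model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxcea)
```

## The decision problem

Seven high-risk drugs — clopidogrel, capecitabine, systemic fluorouracil,
azathioprine, mercaptopurine, tioguanine and irinotecan — interact with
variant phenotypes of four pharmacogenes (*CYP2C19*, *DPYD*, *TPMT*,
*UGT1A1*) in ways that can be fatal: a poor metabolizer dosed by protocol
can die of myelosuppression, fluoropyrimidine toxicity, or (for
clopidogrel) a cardiovascular event that an adjusted dose or an
alternative drug would have avoided. The Dutch Pharmacogenetics Working
Group (DPWG) grades these drug-gene interactions (DGIs) as "essential":
a single-gene test is advised before the first prescription.

`pgxcea` asks the population-level question: if every patient initiating
one of these drugs in a year were genotyped once and prescribed according
to the guideline, how many gene-drug-related deaths would be avoided, and
at what cost?

## The cohort model

For each drug with yearly initiator count $N$, phenotype strata with
population frequencies $P_{ph}$ and one-year absolute risks of
gene-drug-related death $AR^{SoC}_{ph}$ (standard of care) and
$AR^{PGx}_{ph}$ (genotype-guided care), the expected deaths prevented
per year are

$$
N_{GDRDP} \;=\; \sum_{drug} N \sum_{ph} P_{ph}\,
\bigl(AR^{SoC}_{ph} - AR^{PGx}_{ph}\bigr),
$$

and the incremental one-year cost, from a healthcare perspective, is

$$
Cost \;=\; \sum_{drug} \Bigl[ N \cdot c_{test}
 + N_{act} \cdot c_{HCP}
 + N\,\bigl(c^{PGx}_{drug} - c^{SoC}_{drug}\bigr) \Bigr],
$$

where $N_{act} = N \sum_{ph\,:\,actionable} P_{ph}$ is the expected number
of initiators whose result changes the prescription. The cost per death
prevented is the ratio of the two; when the cost is negative while deaths
are prevented the intervention *dominates* standard of care.

Three structural assumptions are enforced as validated invariants rather
than conventions:

* a **non-actionable** stratum (no dose or drug change recommended) has
  identical risks in both arms — a test that does not change the
  prescription cannot change the outcome;
* on an actionable stratum $AR^{PGx} \le AR^{SoC}$ — guideline-guided
  adjustment never harms, within this model;
* stratum frequencies sum to 1 within 0.005, the slack implied by
  three-decimal published frequencies.

Derived quantities are algebraically linked and tested as identities:
the number needed to genotype is
$NNG = 1 / \sum_{ph} P_{ph}(AR^{SoC}_{ph}-AR^{PGx}_{ph})$, so
$NNG \times N_{GDRDP} = N$; the relative risk reduction is
$N_{GDRDP}$ over SoC deaths; portfolio totals are sums (or ratios of
sums) of per-scenario values with no independent computation path.

## Tunable parameters

| parameter | unit | default | meaning |
|---|---|---|---|
| `adoption` | fraction | 1.0 | initiators actually tested |
| `adherence` | fraction | 1.0 | actionable recommendations followed |
| `pharmacist_minutes` | min | 18 | recording/discussing one actionable result |
| `physician_minutes` | min | 6 | physician share of that discussion |
| `hcp_cost_per_actionable` | EUR | derived | minute-weighted salary cost, or set directly |

The base case fixes adoption and adherence at 100%, reflecting a fully
implemented national programme; both enter multiplicatively on the
achieved risk reduction and on the actionable count, so sensitivity
analyses can relax them without touching the risk inputs.

## The bundled Dutch portfolio and its reconstruction

The package ships the seven-DGI Dutch portfolio (148,128 initiators/year)
under `inst/extdata/`, with a per-field provenance ledger
(`fixture_provenance()`). Published inputs — initiator counts, phenotype
frequencies, per-stratum absolute risk reductions, unit costs, certainty
scores — are stored as printed. Two groups of values are *derived*,
because the underlying numbers are not public:

* **Per-stratum absolute risks.** Publications report the risk
  *reduction* per stratum and the expected deaths under standard of care
  per drug, not the per-stratum risk pair. We reconstruct a per-drug
  baseline risk $r_0$ (shared by non-actionable strata and by the tested
  arm of actionable strata), set $AR^{SoC} = r_0 + ARR$ on actionable
  strata, and solve $r_0$ so that $N \sum P_{ph} AR^{SoC}_{ph}$ equals
  the published deaths-with-SoC anchor. For azathioprine this gives
  $r_0 = 15.8/6979 - 0.0003229 \approx 0.00194$.
* **Clopidogrel risk reductions.** The published per-stratum ARR column
  (0.30%, 0.05%) is internally inconsistent with the published NNG of 287
  and the 410.8 deaths prevented it implies (it would give an NNG of
  about 1,327). The fixture follows the NNG chain — the one consistent
  with the headline mortality results — by scaling both printed ARRs by a
  common factor of about 4.62 so that $\sum P \cdot ARR = 1/287$.
* **HCP interpretation cost.** The per-actionable cost of 16.39 EUR is
  the published HCP total divided by the published actionable count; the
  salary tables behind it are not public.

Two published classifications disagree about UGT1A1: the pair table flags
*1/*28 actionable but gives it no recommendation and counts it as zero
actionable patients, and flags PM non-actionable while giving it a dose
reduction and counting its patients. A stratum here is **actionable iff
the recommendation changes dose or drug**, which follows the counts used
in the published actionable and HCP-cost arithmetic.

Because some published per-DGI euro aggregates were computed from
unrounded inputs, recomputation from printed inputs lands within about
1% of the printed per-DGI cost totals and within about 1.5% of the
printed per-DGI cost-effectiveness ratios (e.g. azathioprine 379,196
vs 374,411 EUR per death prevented), while all portfolio-level headline
numbers agree to their printed precision. The test suite freezes the
recomputed values and checks the distance to the printed ones, rather
than silently adopting either.

## The synthetic generator and the microsimulation oracle

`generate_portfolio()` draws structurally valid random portfolios:
stratum frequencies from a symmetric Dirichlet (default concentration
0.6, chosen so that rare phenotypes of order $10^{-3}$ — the published
range is 0.001–0.925 — appear regularly), baseline one-year death risks
uniform on $[0, 0.05]$ and risk reductions on $[0, 0.02]$, bracketing the
fixture's range (baseline risks $1.6\times10^{-3}$–$2.9\times10^{-2}$,
ARRs up to $1.4\times10^{-2}$), and at least one actionable stratum per
scenario, as in every published "essential" DGI. The generator emulates
the *statistical structure* of the problem — categorical phenotypes,
per-stratum Bernoulli death risks, arm-dependent risk only on actionable
strata — and deliberately not its clinical texture: no covariates,
comedication, indication mixtures or time-varying risk. Passing the
property suite therefore demonstrates algebraic and statistical
correctness of the engine, not the external validity of any particular
risk estimate.

`microsimulate()` is the independent oracle: each simulated patient draws
a phenotype, then a *single* uniform number decides death in both arms
against the per-stratum risks (common random numbers). Since
$AR^{PGx} \le AR^{SoC}$, every PGx-arm death is also a SoC-arm death, so
simulated deaths prevented are non-negative in every replicate and the
Monte-Carlo variance reduces to that of the per-patient prevention
indicator — the sharpest oracle available at desk scale. The validation
suite checks 3-standard-error agreement with the analytic engine at
$10^6$ patients per fixture scenario, $\sqrt{n}$ error scaling over ten
seeds, and analytic-inside-99.7%-interval coverage over a 50-scenario
generated suite at $10^5$ patients each; the structural identities run
over a 1,000-scenario suite. These sizes keep the whole validation run in
well under a minute while leaving Monte-Carlo bands far narrower than any
tolerance being asserted.

```{r oracle}
aza <- dutch_essential_portfolio()$scenarios[[1]]
deaths_prevented(aza)
microsimulate(aza, n_patients = 1e5, seed = 1)[c("deaths_prevented", "se")]
```

## Sensitivity machinery

The published analysis reports point estimates only; the sensitivity
layer is this package's own convention, flagged as such. `one_way()`
evaluates the full portfolio on a grid of one input; `threshold_search()`
bisects a monotone bracket to the value where the pooled cost per death
prevented (or the total cost) crosses a target, stopping at a bracket
width of 1 EUR or $10^{-6}$ relative, whichever is reached first;
`psa()` re-evaluates the full model per draw — no approximation — with
beta distributions for probabilities and gamma for costs, the standard
health-economics choices for quantities bounded to $[0,1]$ and
$[0,\infty)$. Probability draws that would violate
$AR^{PGx} \le AR^{SoC}$ (or any other invariant) are redrawn, up to 100
attempts, rather than truncated, avoiding silent bias at the boundary;
frequencies are renormalised jointly to the simplex.

## Numerical choices

* Internal computation is never rounded. Display rounding (deaths to one
  decimal — whole deaths on the TOTAL row, as in the published table —
  euros and counts to integers, percentages to one decimal) rounds ties
  away from zero, matching the published tables rather than banker's
  rounding.
* Undefined ratios (NNG, CEA, RRR with zero denominators) raise typed
  conditions (`pgxcea_undefined_nng` etc.), never silent `Inf`/`NaN`;
  `cohort_result()` alone stores `NA` for an undefined NNG so that
  portfolios containing a null-benefit scenario still aggregate.
* Risk-ordering comparisons allow $10^{-12}$ absolute slack so that
  round-tripped inputs do not fail validation on representation error.
* The JSON result bundle writes doubles at 17 significant digits, so
  re-reading reproduces every unrounded value bit-exactly.
* All stochastic operations take an explicit integer seed and are
  bit-reproducible given it.

## Known limitations

* One-year horizon, no discounting, and mortality only: no QALYs or
  life-years, no non-fatal adverse reactions, no loss-of-efficacy
  pathway. Cost-effectiveness per death prevented is therefore not
  directly comparable to per-QALY thresholds.
* Phenotype frequencies come from a Dutch (predominantly Caucasian)
  sample; actionable-phenotype frequencies differ materially in other
  ancestries, so the bundled numbers do not transport.
* The reconstructed absolute risks are anchored to published aggregates;
  they are internally consistent with the published mortality arithmetic
  but are not independently sourced per-stratum risks.
* Homogeneous cohorts: every initiator of a drug shares one indication,
  dose protocol and baseline risk.
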