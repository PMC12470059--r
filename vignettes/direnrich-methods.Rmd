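---
title: "Methods: direction-aware enrichment of DE signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: direction-aware enrichment of DE signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(direnrich)
```

## The problem

Bulk transcriptomic contrasts (for example a diseased-vs-control cortical
RNA-seq comparison) produce one summary row per gene: a log2 fold change and
a BH-adjusted p-value. Downstream questions are often *direction-aware*: a
down-regulated miRNA is expected to *de-repress* its direct mRNA targets, so
the biologically predicted test is whether the miRNA's validated targets are
over-represented among *up*-regulated genes — not among all changed genes.
`direnrich` implements that workflow end to end: ranking, a compact
direction-preserving core signature, set-level over-representation with
effect sizes and uncertainty, and composition-confounding sensitivity
checks, with a synthetic-data generator that makes the whole chain testable
without any external downloads.

## Model and statistics

**Composite score.** Genes are prioritized by
$S = |\mathrm{log_2FC}| \times (-\log_{10} p_{\mathrm{adj}})$, base-10
logarithm. $S$ combines effect size and statistical confidence in one
ranking heuristic; it carries no standalone inferential meaning.
Significance is evaluated separately by the strict rule
$p_{\mathrm{adj}} < \alpha$ (default $\alpha = 0.05$). Reported adjusted
p-values of zero are floored at $10^{-300}$ before the log so that $S$
stays finite; the floor is a documented constant, far below any printable
p-value. Ranking ties are resolved deterministically: smaller
$p_{\mathrm{adj}}$, then larger $|\mathrm{log_2FC}|$, then alphabetical
symbol; records without a usable $p_{\mathrm{adj}}$ (`UNTESTED`) always
sort last, alphabetically. A gene with $\mathrm{log_2FC} = 0$ has no
direction and is never called UP or DOWN, however small its p-value.

**Core signature.** Among significant genes only, the top `size` (default
80) by $S$ are retained in rank order, preserving their UP/DOWN calls. No
threshold on $S$ itself is applied, so the core is "the best `size`
significant genes", not "genes with $S$ above a cutoff". If fewer than
`size` genes are significant the core is simply all of them, with a
warning.

**Universe.** The background $M$ is every gene with a non-missing adjusted
p-value; $K_{up}$ and $K_{down}$ are the significant genes per direction.
Target sets are always restricted to this background before testing,
because genes never assayed cannot count for or against enrichment.

**Over-representation test.** For a target set of size $n$ (after
restriction) with overlap $a$ against a direction partition of size $K$,
the 2×2 table is $(a,\; b = n - a,\; c = K - a,\; d = M - n - K + a)$. The
one-sided p-value is the exact hypergeometric upper tail
$P(X \ge a)$, computed by direct summation of the log-gamma pmf over the
support with a log-sum-exp — no normal or chi-square approximation. The
effect size is the cross-product odds ratio $ad/bc$; when any cell is zero
the Haldane–Anscombe correction (add 0.5 to all four cells) is applied and
flagged — and only then, because published raw-cell values are otherwise
reproduced exactly. The CI is Woolf's logit interval
$\exp(\ln \mathrm{OR} \pm z\sqrt{1/a + 1/b + 1/c + 1/d})$ with
$z = \Phi^{-1}(0.975) \approx 1.959964$ at the default 95% level, computed
on the same (possibly corrected) cells as the point estimate.

**Multiplicity.** BH step-up adjustment is applied *within* each
pre-specified test family (for example the three miRNA target tiers:
functional-only, CLIP-supported, validated-any) and never pooled across
families. `bh_adjust()` is the textbook step-up, cross-checked in the test
suite against `stats::p.adjust`. One known discrepancy in published
three-row tables of this kind: the middle-ranked q sometimes equals its raw
p rather than the step-up value; `direnrich` always reports standard BH.

**ORA filters.** For exploratory ORA over large collections, term-size
bounds (5–500 after background restriction) and a minimum overlap of 2 are
applied; filtered sets are reported with a `filter_status` but not tested,
and do not count toward the BH family size. For small pre-specified
families the filter is disabled (`size_filter = FALSE`) so that even an
$n = 8$ curated set is tested — matching how such confirmatory families
are analyzed in practice.

**Background calibration.** When a published table prints $(n, a, K,
\mathrm{OR})$ but not the background size, `calibrate_background()` inverts
the cross-product: $d = \mathrm{round}(\mathrm{OR}\cdot b c / a)$,
$M = a + b + c + d$. The inversion is exact up to the rounding of $d$; the
residual between implied and reported OR is returned so the user can judge
the calibration. A single calibrated $M$ that reproduces *several*
independently printed ORs is strong evidence the reconstruction is right.

## Sensitivity analysis

Bulk-tissue direction calls conflate cell-intrinsic regulation with
composition shifts. Two re-tests probe this:

* **Marker exclusion** removes the union of cell-type marker panels from
  background and partitions, then re-runs the identical tests.
* **Stratification** splits the universe into marker-defined strata. The
  default map assigns the neuron panel to a `neuron` stratum and the union
  of astrocyte/microglia/oligodendrocyte/endothelial panels to `glia`;
  genes in both panels, or in neither, are unassigned and excluded from
  every stratum. This is an explicit modeling choice — expression-weighted
  stratum scores would be an alternative — and a user-supplied map
  overrides it.

Verdicts compare each variant against the primary run. The rule is
deterministic: if a needed statistic is missing the test is `untestable`;
if the log-OR sign flips, the verdict is `reversed` when the variant CI
excludes 1 and `attenuated` otherwise; if the signs agree, the verdict is
`attenuated` when the variant *point estimate* falls outside the primary CI
on the side toward OR = 1, else `consistent`. The point-estimate-vs-CI form
was chosen over a CI-overlap test because overlap verdicts flip on CI width
alone: a variant estimate of 1.3 against a primary 2.0 [1.5, 2.6] is a
meaningful attenuation even though wide intervals overlap. No formal
heterogeneity test is attempted; the published analyses this mirrors report
only qualitative persistence.

## The synthetic-data generator

`simulate_de_table()` draws, per gene, a true state (null/up/down) with
probabilities $(1 - \pi_{up} - \pi_{down},\ \pi_{up},\ \pi_{down})$, a true
effect $0 / \mu_{up} / -\mu_{down}$, an observed
$\mathrm{log_2FC} = \text{effect} + N(0, \sigma_e)$, a two-sided p from
$z = \mathrm{log_2FC}/se$, and BH-adjusted p-values over all $M$ genes.

Defaults are fixed once, as a stated world: $M = 20{,}000$ genes,
$\pi_{up} = 0.15$, $\mu_{up} = \mu_{down} = 1.5$, $\sigma_e = se = 0.3$ —
under which roughly 3,000 genes are called Up at $\alpha = 0.05$, the scale
of a strongly perturbed cortical contrast. $\pi_{down} = 0.125$ was chosen
so the expected Up/Down call ratio matches the mild up-regulation excess
(ratio ≈ 1.19) typical of such contrasts. A single shared $se$ keeps the
power function interpretable; per-gene standard errors are a realistic
refinement the generator deliberately omits. Marker panels default to five
disjoint 50-gene panels (curated CNS panels are typically tens of genes);
`panel_up_rate` optionally biases panels into Up-called genes to emulate
composition confounding.

**Planted enrichment.** `plant_target_set()` samples target membership
independently per gene with probability $p_1$ for Up-*called* genes and
$p_0$ otherwise, where $(p_0, p_1)$ solve
$\frac{p_1(1-p_0)}{p_0(1-p_1)} = \omega$ and
$K p_1 + (M-K) p_0 = n_{\mathrm{target}}$ ($p_0$ by bisection to half a
gene of the requested expected size). Planting against *observed* calls —
not true states — makes $\ln\omega$ exactly the estimand of the downstream
odds ratio, so parameter-recovery tests need no attenuation bookkeeping.
Had we planted against true states, measurement error in the calls would
bias the estimated OR toward 1 by a factor depending on power and FDR.

What a green test establishes: the inferential chain (universe →
contingency → Fisher/OR/CI/BH) is calibrated and recovers a known planted
association at realistic scale. What it does not establish: robustness to
features of real data the generator omits — correlated genes, per-gene
variance heterogeneity, fold-change-dependent significance, annotation
errors, or biased target-set curation.

## Numerical choices

* Hypergeometric tail by log-gamma summation with log-sum-exp: exact to
  machine precision for every table tested (the suite checks equality to
  `1e-12` against enumeration for all tables with $M \le 60$, and pmf
  normalization up to $M = 10{,}000$).
* p-values are clamped to `(0, 1]`; $a = 0$ short-circuits to exactly 1.
* `round()` on the calibrated $d$ (not floor/ceiling), so calibration error
  is at most half a count.
* All randomness flows through explicit seeds (`withr::with_seed`), RNG is
  R's default Mersenne-Twister; identical `(config, seed)` re-runs are
  bit-identical, which the suite asserts.
* Machine outputs (TSV/JSON) keep full double precision; display rounding
  (OR and CI to 2 decimals, p/q to 3 significant figures) happens only in
  `render_report()`.

## Known limitations

* The Woolf CI is a large-sample interval; for tiny cells (the $n = 8$,
  $a = 4$ regime) it is wide and only approximately calibrated, which is
  exactly why the one-sided exact p is the primary inference.
* `harmonize()` performs no symbol lookup of its own: without a supplied
  alias table it only case/whitespace-normalizes. True HGNC harmonization
  requires a curated map.
* The sensitivity verdicts are heuristics for reporting, not tests of
  effect heterogeneity.
* The pipeline consumes DE *summary* tables; it neither re-fits
  differential expression nor models counts.
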