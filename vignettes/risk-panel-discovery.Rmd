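---
title: "Exhaustive risk-panel discovery: model, assumptions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exhaustive risk-panel discovery: model, assumptions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskpanel)
```

## The problem and the model

Melanomas treated with BRAF/MEK inhibitors commonly relapse; biopsies taken
before treatment (PRE) and after progression (PROG) differ in their
transcriptional programs. Given a candidate gene list nominated upstream
(for instance from a proteomic comparison of drug-sensitive and
drug-resistant cell lines), the task is to find the gene subset whose joint
expression best predicts the resistant state, and to quantify how well that
panel transfers to independent cohorts.

`riskpanel` implements this as a fully enumerated model-selection problem.
For each non-empty subset $G$ of the candidate universe, a two-class
Fisher discriminant is fitted with equal priors:

$$\beta_G \propto (S_G + \lambda I)^{-1}(\mu_{PROG} - \mu_{PRE}),$$

where $S_G$ is the pooled within-class covariance of the subset's expression
and $\lambda$ a small ridge (below). Each sample receives the linear risk
score $\sum_{i \in G} x_i \beta_i$ — a pure dot product with no intercept,
so the score is defined even when cohorts are on different scales; the
decision offset lives entirely in the cutpoint. Subsets are ranked by the
Mann–Whitney AUC of the score (ties between a PRE and a PROG sample count
one half), and the subset with the highest AUC wins. The per-sample score
of the winning panel is the *risk score* used everywhere downstream.

Assumptions worth stating explicitly:

- **Two classes, linear boundary.** The discriminant is linear in the
  (normalized, log-like) expression values; no interactions, no nonlinear
  terms.
- **Resubstitution scoring.** Subsets are ranked by apparent AUC on the
  discovery cohort itself, which makes the winner's AUC an optimistically
  biased estimate (see *Selection bias* below). Cross-validated subset
  ranking is deliberately not the default: the package mirrors the
  single-cohort-discovery / independent-validation workflow.
- **Samples are treated as exchangeable within stage.** Patient pairing is
  carried in the metadata and used for fold-change stratification, but the
  discriminant itself fits no patient-level random effects.

## Tunable parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `shrinkage` (`fit_panel_lda`) | `1e-6·tr(S)/p`, escalated ×10 up to `0.1·tr(S)/p` | fraction of average eigenvalue | 18 genes against ~30 samples makes near-singular pooled covariances routine during the search; the escalation ladder stabilises them without materially biasing well-conditioned fits. Subsets that stay singular at the cap are recorded as skipped, never silently scored. |
| `min_size`, `max_size` | 1, \|universe\| | genes | The full enumeration is $2^p-1$ subsets; bounds exist for sensitivity analyses. |
| `cutpoint_criterion` | Youden's $J = se + sp - 1$ | — | The upstream literature computes "optimal cutpoints" without naming a criterion; Youden is the standard default and the criterion is pluggable (any `f(sens, spec)`). Ties break toward higher specificity, then the lower cutpoint, for determinism. |
| DEG `alpha` | 0.1 | p-value | A deliberately permissive screen: the DEG list feeds enrichment, where the hypergeometric test, not the screen, carries the inferential weight. |
| pathway `alpha` | 0.05 | p-value | Threshold on the unadjusted Spearman p of pathway activity vs risk score; a BH-adjusted variant is available (`adjust = TRUE`). |
| `threshold` (`correlation_network`) | 0.3 | \|Spearman rho\| | Conventional moderate-correlation cut for co-expression edges; strict inequality. |
| `k` (pathway PCA clusters) | 3 | clusters | Resistant-cohort pathway maps typically resolve into a PROG-enriched, a PRE-enriched and an intermediate cluster; `k` is overridable and gene-module clustering uses silhouette-selected `k` instead. |

## The synthetic cohort generator

`cohort_spec()` defines a multivariate normal law on the normalized
log-expression scale: genes belong to correlation blocks (within-block
correlation per block), PROG samples are shifted by per-gene standardized
effects, and per-gene baselines emulate abundance differences. The shipped
`template_cohort_spec()` mirrors the study design the package is built
around: 17 PRE and 13 PROG samples over an 18-gene proteomics-derived
panel, three modules — two up-regulated (led by HMOX1/ICAM1/ENG/GRN and
MMP2/TP53) and one down-regulated, anti-correlated module (SPARC/VIM) —
with effect sizes of mixed sign in the 0.2–1.1 SD range chosen to
reproduce the per-gene odds-ratio magnitudes (roughly 1.1–2.7 per SD, and
below 1 for the down module) that such cohorts report, and full PRE/PROG
patient pairing.

One parameterisation note: the spec expresses between-module correlation as
a **single scalar with per-module signs** (+1 up, −1 down, 0 for
independent background genes), i.e.
$\mathrm{cor}(g_i, g_j) = s_{b(i)} s_{b(j)} \rho_{between}$ across modules.
A single unsigned scalar cannot simultaneously make the two up-modules
positively correlated with each other and both anti-correlated with the
down-module; the signed form is the smallest parameterisation that can.
Covariance validity is checked at spec construction (per-block
equicorrelation bounds plus a full eigenvalue check), so an invalid design
fails before any simulation.

`simulate_multi_cohort()` draws independent cohorts from the same law and
applies per-dataset affine distortions (`scale·x + location`) emulating
platform and normalization differences; `merge_common_genes()` removes
exactly this class of distortion, which is what the z-score merge is for.

What the generator does **not** emulate: count noise and library-size
effects (no negative-binomial layer), probe-level artefacts,
heavy-tailed or bimodal expression, dropout or any single-cell structure,
and patient-level random effects beyond shared ids. Passing tests therefore
demonstrate the correctness and calibration of the *procedure* under a
clean Gaussian design — not that any particular panel will validate on real
cohorts.

## Numerical choices

- **Odds ratios.** Stage is regressed on expression with a logistic model
  (PROG = 1) and OR = exp(β̂) per SD, expression standardized per gene
  within dataset. Reporting "odds ratios from linear regression" is a
  category error the package does not reproduce: ORs are only defined under
  a logit link. Perfect separation is flagged (`separation = TRUE`, OR 0 or
  ∞) rather than raised, and separated fits carry no Wald p-value.
- **AUC confidence intervals** use the DeLong placement variance with an
  *untruncated* normal interval; near-perfect classifiers can report an
  upper bound above 1, matching the reporting convention of cohort studies
  (`clip = TRUE` gives a presentation-clipped copy).
- **Fold change is a difference, not a ratio.** LDA scores can be negative,
  so a ratio is ill-defined; the patient-level "fold change" is
  mean(PROG scores) − mean(PRE scores), biopsies averaged within stage
  first. Strata: Down if FC < 0, Slightly up if 0 ≤ FC < z, Up if FC ≥ z,
  z = 0.25·max(FC). The two boundary cases (FC = 0, FC = z), which strict
  inequalities leave unassigned, are closed upward (Slightly up and Up
  respectively). When no FC is positive, z is degenerate and the cohort is
  all-Down with a flag. z is computed within each dataset, because max(FC)
  is scale-dependent and cohort scales differ before merging.
- **Z-score merge.** Per gene and dataset, both stages pooled (within-stage
  standardization would erase the effect of interest), sample SD (n−1),
  computed after intersecting gene universes (per-gene results are
  identical either way). Zero-variance genes are dropped with a named
  warning, not NaN-propagated.
- **Ties and determinism.** Equal-AUC subsets resolve to the smaller panel,
  then the ascending bitmask; PCA component signs are fixed so each
  component's largest-magnitude loading is positive; cutpoint ties prefer
  higher specificity, then the lower cutpoint; the classification rule is a
  strict ">". Every table a pipeline run writes is a pure function of
  config + seed.
- **Degenerate inputs.** Zero-variance genes: Kruskal–Wallis p := 1,
  Spearman rho undefined and flagged, PCA with scaling errors naming the
  gene. Missing values are a hard load-time error — silent NaN handling
  would quietly change every downstream statistic.
- **Orientation.** β is oriented so PROG scores higher on average.
  Swapping the class labels therefore negates β exactly: the score always
  measures risk of whichever state is labelled PROG.

## Open design choices, and why they were decided this way

- **"Permutations/combinations" = all non-empty subsets.** The count
  $2^{18}-1 = 262{,}143$ identifies the enumeration unambiguously; gene
  order is irrelevant to a discriminant.
- **Selection on the discovery cohort only**, validation afterwards —
  rather than selecting on pooled discovery + validation data — keeps the
  validation estimate interpretable.
- **The winning panel is an output, not a constant.** Nothing in the
  package hard-codes a particular 13-gene solution; the search result
  depends on the cohort given to it.
- **Hypergeometric over-representation** stands in for interaction-guided
  active-subnetwork enrichment. The subnetwork step is an external
  algorithm with its own machinery; ORA consumes the same DEG list and
  feeds the identical downstream scoring, which is what this package owns.
  Users can supply any GMT collection.
- **Pathway activity = mean member-gene z-score** ("agglomerate z-score"),
  with a pluggable aggregator (e.g. median). The per-sample pathway score
  is what gets correlated with the risk score; both the full selected set
  and a top-K view are available to the caller.
- **Module count selection** for gene correlation modules uses maximum mean
  silhouette over $k \in [2, \min(8, n-1)]$ (complete linkage on
  $1-\rho$); the upstream choice of cluster-validity machinery is not
  specified in the literature the workflow follows, and silhouette is the
  transparent default.

## Selection bias, demonstrated

The best-of-262,143 apparent AUC is a maximum over a huge family of
correlated estimates. The acceptance tests quantify this on null cohorts
(18 independent genes, zero effects, 17 + 13 samples): the mean single-gene
AUC sits at 0.5, while the searched panel's apparent AUC approaches 1 —
and collapses back to chance on an independent cohort drawn from the same
null law. This is the package's standing argument for never reporting the
discovery AUC without independent validation.

## Problem sizes used by the tests

The suite exercises full 18-gene searches (262,143 subsets per fit; a few
seconds each on one CPU thanks to the compiled inner loop), 25-replicate
recovery studies at 60 + 60 samples with five planted effects, 20-seed null
calibrations, and 1,000-vector dual-route AUC identities. These sizes were
chosen as the smallest designs at which the relevant asymptotics (CI
coverage, null calibration, recovery rates) are stable.

## Known limitations

- The exhaustive search is limited to 25 candidate genes (memory and time
  grow as $2^p$); it is a candidate-list distiller, not a genome-wide
  feature selector.
- Apparent metrics are resubstitution estimates by design; the package
  reports them alongside validation, it does not correct them.
- The Gaussian generator cannot certify behaviour on count data, and the
  z-score merge removes only affine batch structure — nonlinear platform
  effects need dedicated batch correction upstream.
- Probe-to-gene collapsing, GEO retrieval and normalization of raw data are
  out of scope: inputs are normalized gene-by-sample matrices.
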