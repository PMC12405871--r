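---
title: "Digenic models for seed dormancy, germination, and pericarp flavonoids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digenic models for seed dormancy, germination, and pericarp flavonoids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digenic)
```

## The system and the questions

Rice carries two major pericarp pigmentation loci: *Rc/rc* (red pigments,
proanthocyanidins, chromosome 7) and *Pb/pb* (purple pigments,
anthocyanins, chromosome 4). Both loci are pleiotropic: beyond pigment
chemistry they affect seed primary dormancy, germination velocity after
dormancy release, and imbibition (water-uptake) speed. With both allelic
variants assembled into one genetic background — four homozygous isogenic
lines (ILs) covering the 2×2 classes, plus an F2 from selfing the double
heterozygote — the phenotypic variance of each trait can be partitioned
into additive, dominance, and epistatic components of the two loci.

This package implements that analysis end to end: germination statistics
from raw counts, orthogonal-contrast design matrices, OLS fitting with
forward selection and a sequential R² partition, per-timepoint effect
trajectories along the imbibition curve with three-phase segmentation, and
synthetic-data generators emulating each experimental design.

## Germination statistics

A germination test scores each sample of *N* seeds on counting days
*d* (daily at 2–7 days of imbibition for the ILs; days 3, 5, 7 for the
F2), recording the incremental count *n_d* of seeds newly germinated. Two
statistics summarise a sample:

* **GP**, the cumulative germination percentage by day *i*:
  $GP_i = 100\sum_{d \le i} n_d / N$.
* **GI**, the germination index: $GI = 100 \sum_d n_d (T+1-d) / (N\,T)$
  with horizon $T = 7$. Earlier germination earns a larger weight
  $T+1-d$; this single rule reproduces both published weight vectors
  (6..1 for days 2..7 and 5, 3, 1 for days 3, 5, 7) without special cases.
  Low GI for dormant genotypes reflects both fewer and later germinations.

Counts are stored incrementally; cumulative input is differenced at
ingestion with a monotonicity check. The wet-lab scoring criterion
(radicle > 3 mm) is upstream of the software: counts are taken as given.

```{r}
r <- germination_record("example", NULL, n_total = 60,
                        schedule = 2:7, counts = c(30, 15, 0, 0, 0, 0))
c(GP7 = cumulative_gp(r, 7), GI = germination_index(r))
```

## Contrast coding and the three model kinds

Genotypes are stored as functional-allele dosages (0/1/2). The models use
the classical orthogonal contrasts: additive $x \in \{-1, 0, +1\}$,
dominance $z \in \{-0.5, +0.5\}$ (heterozygote positive), and products of
parent codes for every epistatic or interaction column. Under balanced
replication (or exact 1:2:1 segregation) these columns are mutually
orthogonal, so each coefficient estimates its genetic effect regardless of
which other terms are in the model.

Three model kinds cover the designs (`model_spec()`):

| kind | terms | used for |
|------|-------|----------|
| `hom` | a1, a2, i_a1a2 | IL germination; per-timepoint water content |
| `f2`  | a1, d1, a2, d2, four epistatic products | F2 GP/GI |
| `gxt` | a1, a2, i_a1a2, tau, I_a1tau, I_a2tau | flavonoids at 5 vs 40 DPA |

The development-time covariate is coded 0 (5 DPA) / 1 (40 DPA) *as
published*, although this makes the genotype-by-time product columns
non-orthogonal to the main effects (`check_orthogonality()` makes this
visible). We deliberately do not centre it: the variance partition below
is defined so that the resulting order dependence is resolved by the
selection path itself.

## Fitting, selection, and the variance partition

`fit_digenic()` composes design construction, forward selection, OLS on
the retained terms, and the per-term partition. Forward selection starts
from the intercept-only model and repeatedly admits the candidate with the
largest sum-of-squares increment whose partial F-test has p < 0.05 (the
published procedure states only "stepwise selection at 5%"; we use pure
forward entry, no removal step — the simpler rule, uniformly applied and
configurable via `alpha`). Ties break by candidate order in the model
specification, so the procedure is deterministic.

Each retained term's **R² increment** is the drop in residual SS at the
step where it entered, divided by the total SS about the mean. Increments
sum to the final model R². On orthogonal designs they are
permutation-invariant and equal SS(term)/SS(total); on non-orthogonal
designs (0/1 time coding, unbalanced F2) they are order-dependent, and
entry order — the order the stepwise procedure itself chose — is the
documented convention. This convention reproduces the published partition
pattern in which the genotype-by-time interaction dominates the
anthocyanin variance.

Numerical edge rules:

* A candidate that drives the residual SS to numerical zero
  (RSS ≤ 1e−10 × SST) enters with p = 0 even with no residual df left.
* A *saturated noise-free* fit — e.g. the three-term homozygous model on
  exactly four class means — leaves no residual df at any step, so partial
  F tests cannot admit anything; such fits use `select = FALSE` (plain
  least squares), which is also how the published class-mean effects are
  reproduced.
* Zero-variance or duplicated predictor columns are dropped with a warning
  before fitting; a genuinely rank-deficient design is an error naming the
  collinear columns.
* p-values are partial t/F with residual df from the current model; no
  multiple-testing correction is applied (none was in the source analysis).

```{r}
il <- data.frame(rc_dosage = c(0, 2, 0, 2), pb_dosage = c(0, 0, 2, 2),
                 y = unname(il_gp7_reference()))
fit_digenic(il, model_spec("hom"), select = FALSE)
```

## Replicate reconstruction from published summaries

Raw flavonoid replicates are not available; the published table gives
per-cell means and standard errors of 3 replicates.
`reconstruct_replicates(m, se, n)` returns the symmetric pattern
$m + se\sqrt{n}\,e$ (centred unit-variance ramp $e$), whose sample mean
and SE equal the inputs *exactly*. Because every model predictor is
constant within a genotype-by-time cell, all between/within sums of
squares — hence every coefficient, F statistic, and R² — computed from the
reconstruction equal the values the raw data would give. (This is exact,
not approximate; the test suite verifies it by simulation to 1e−10.)
Non-detectable cells enter as exact zeros with zero SE — the only
treatment under which the genotype-by-time model is estimable over all 8
cells.

One caveat: reconstruction inherits the *printed rounding* of means and
SEs. For the anthocyanin panel this retains two small extra terms (a1 and
I_a1tau, ~3–4% shares each) beyond the four the source reports as
significant; the dominant genotype-by-time share (63%) and its first-entry
position are unaffected.

```{r}
fit_digenic(flavonoid_records("CA"), model_spec("gxt"))$estimates[,
  c("term", "coefficient", "r2_increment", "entry_order")]
```

## Imbibition time courses and phase segmentation

`fit_per_timepoint()` fits the homozygous model independently at every
measurement time (all three genetic terms always estimated; significance
carried as raw p < 0.05 flags — deliberately uncorrected across the ~20
time points, matching the per-timepoint reporting convention; treat the
flags as descriptive, not inferential). On the balanced design the
background µ(t) is the unweighted mean of the four class means,
independent of the genetic effects, and traces the classical triphasic
water-uptake curve.

`segment_phases()` replaces the visual phase identification of the source
with a transparent criterion: a continuous three-segment piecewise-linear
least-squares fit, breakpoints searched exhaustively over all admissible
pairs of observed time points (≥ 2 observations per segment), minimum SSE
wins, ties to the earliest pair. A trajectory that a single straight line
fits exactly has no identifiable phases and raises an error; a fit whose
middle segment is not the flattest is flagged `valid_plateau = FALSE`.

Because breakpoints are searched on the observed grid, they can only be
estimated at observed times. The published sampling grid (every 4 h from
12–60 h, offset by 2) contains no point at the nominal 30/50 h phase
boundaries, so on that grid the best attainable estimate is the
neighbouring grid point; recovery studies in the test suite therefore use
a breakpoint-aligned grid variant when exactness is asserted.

## The synthetic-data generators

The generators state one fixed world, used by all tests:

* **F2 genotypes**: independent 1:2:1 at each locus (unlinked loci,
  selfing of a double heterozygote); n = 259 phenotyped plants.
* **Phenotypes**: the additive-dominance-epistasis model as a generative
  process, with the published F2 GP effect set (−15.0, −3.9, −8.2, −6.2
  about 78.6) and residual SD 14.1 — derived so the expected model R² is
  ~0.45 as reported (genetic variance 159.5 under exact segregation
  frequencies).
* **Germination counts**: per seed, Bernoulli germination with the
  genotype's p_g (the published GP7 targets 0.82/0.50/0.69/0.16), then a
  germination day from a discretized logistic law truncated to the
  horizon — a two-parameter, heavy-enough-tailed timing law chosen because
  the source specifies daily counts but no process model. Seeds are scored
  at the first counting day on or after germination, so the three-day F2
  schedule bins exactly as a real inspection schedule would. E[GP7] = p_g
  by construction. Mean days 3/4/3.5/5 (later for more dormant classes)
  and scale 0.8 are plausible non-published values.
* **Flavonoid panels**: Gaussian replicates around the published cell
  means with SD = SE·√3; non-detects as flagged exact zeros; a
  configurable detection floor.
* **Imbibition**: triphasic base curve with breakpoints 30/50 h and
  slopes 0.012/0.001/0.004 per h (phase magnitudes chosen to reach a
  realistic ~0.36 water-content at the end of phase I; not published
  numerically), genotype offsets ramping in from onset times 28 h (Rc) and
  6 h (Pb) — mirroring the reported significance onsets — and measurement
  noise SD 0.005.

What a green test does **not** establish: the generators draw Gaussian,
homoscedastic noise and independent seeds; real germination counts are
overdispersed across dishes, real imbibition errors are serially
correlated within a sample, and real flavonoid measurements are
log-normal-ish with detection censoring rather than exact zeros. Recovery
and coverage results should be read as verifying the *estimator
machinery*, not as evidence about robustness to those features.

## Design choices that were genuinely open

* **Selection rule**: pure forward entry at α = 0.05 (no removal), partial
  F entry test; the source's wording does not distinguish forward from
  bidirectional stepwise. Uniformly applied.
* **Sequential vs partial R²**: sequential in entry order, for the reasons
  above; for the unbalanced F2 the printed increments are consistent with
  either reading.
* **Time covariate kept 0/1**, not centred: verbatim published coding; the
  partition convention absorbs the consequence.
* **Coverage property**: interval coverage is evaluated on the full-model
  fit rather than post-selection (post-selection intervals are not
  nominal-level; embedding that bias into an acceptance property would
  test the wrong thing).
* **Exact-fit entry rule** (RSS → 0 ⇒ enter): required so that noise-free
  constructions behave sensibly under selection.

## Limitations

* Two loci, two time levels, no linkage, no mixed models or REML; the F2
  analysis treats plant means as independent observations.
* Phase segmentation assumes exactly three linear phases; curves with
  smooth transitions get grid-resolution breakpoint estimates, and the
  plateau validity check is a heuristic.
* Reconstruction from printed summaries is exact for sums of squares but
  inherits printed rounding; retained-term sets near the α boundary can
  differ from the raw-data analysis.
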