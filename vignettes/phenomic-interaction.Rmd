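---
title: "Quantifying drug-gene interaction from phenomic growth curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying drug-gene interaction from phenomic growth curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenogi)
```

## The model

`phenogi` analyzes quantitative high-throughput cell array phenotyping
(Q-HTCP) screens: a mutant library (gene knockouts plus hypomorphic
knockdowns) is arrayed on agar with a drug dose series — here 0, 2.5, 5,
7.5 and 15 µg/mL — in two metabolic contexts, a fermentable "glycolytic"
medium and a non-fermentable "respiratory" medium, and imaged every ~2 h.
Each culture's image-intensity time series is fit to the logistic model

$$G(t) = \frac{K}{1 + e^{-r (t - l)}},$$

yielding the cell proliferation parameters (CPPs): carrying capacity $K$
(intensity units), maximum specific rate $r$ (1/h), and $l$, the time at
which $G(l) = K/2$ (hours; written $L$ when used as a phenotype). The area
under the fitted curve (AUC) over the observation window is computed from
the closed-form antiderivative.

Drug–gene interaction for a mutant strain is the departure of its dose
response from the expectation formed by (i) its own untreated phenotype and
(ii) the reference strain's dose response. With $D_i$ the dose, $R_i$ the
mean reference CPP at $D_i$ (from 768 replicate reference cultures per
medium), and $Y_i$ the mutant CPP:

* $K_i = Y_i - R_i$, the departure at dose $i$;
* $K_0$, the departure at dose 0, is the *shift* — the drug-independent
  effect of the gene perturbation;
* $L_i = K_i - K_0$ isolates the drug-specific interaction;
* ordinary least squares of $L_i = A + B D_i$ over all doses (dose 0
  included, intercept estimated) summarizes the dose trend, and
  $\mathrm{INT} = A + B D_{\max}$ evaluates it at the maximum dose;
* $z = (\mathrm{INT} - \overline{\mathrm{REF_{INT}}}) /
  \mathrm{SD}(\mathrm{REF_{INT}})$ standardizes against the null
  distribution obtained by scoring each reference dose-series by the same
  procedure.

Deletion *enhancers* (the drug hurts the mutant more than the reference)
satisfy $z_L \ge 2$ or $z_K \le -2$; deletion *suppressors* the mirror
image. Comparing calls between media classifies Warburg dependence:
non-specific (NS) when a call holds in both media, respiratory-specific (R)
or glycolysis-specific (G) otherwise.

Missing data follow the screen's conventions: a culture with no growth
curve at a treated dose contributes $Y_i = 0$ for $K$, $r$ and AUC, while
$L$ (a time, unobservable for a dead culture) is imputed with $Y_i\max$ —
the largest $L$ among cultures at that dose whose $K$ is within 2 SD of the
reference mean; observed $L$ above $Y_i\max$ is capped at it (outlier
capping applies to $L$ only, mirroring the imputation's scope). A strain
with no growth curve at dose 0 has no defined interaction: it receives no
z-score, and display exports mark it with the sentinel value 0.0001 and an
empty shift cell.

## Downstream analyses

**Profile clustering (REMc).** Genes with $|z_L| > 2$ in at least one
medium enter a 4-feature profile matrix ($z_L$, $z_K$ per medium; shifts
are carried for display but never clustered). Diagonal-covariance Gaussian
mixtures are fit by EM for $k = 1..k_{\max}$ with random restarts; $k$ is
chosen by BIC and each cluster with at least `min_size` members is
re-clustered recursively until a round yields $k = 1$ everywhere or the
depth limit is reached. Clusters are named by pedigree ("1-0-0" is the
first cluster of round 1, "2-0.0-3" its fourth child, "3-0.0.3-1" the
second child of that). Within clusters, rows are ordered by average-linkage
hierarchical clustering on Euclidean distance for heatmap display.

**GO enrichment and term averaging.** Cluster membership is tested per GO
term by the one-sided hypergeometric upper tail against the universe of all
scored genes, with Bonferroni adjustment. Complementarily, the GO term
average (GTA) summarizes each term directly: the mean of member genes' $L$
interaction z-scores (GTA value), their sample SD (gtaSD, $n-1$
denominator — the convention that reproduces the published worked
examples), and the GTA score $|\mathrm{GTA}| - \mathrm{gtaSD}$. A term is
reported when $|\mathrm{GTA}| > 2$ *and* the score exceeds 2: a strong
average interaction not explained by within-term spread.

**Human predictions.** In cell-line panels, each gene's standardized
expression is regressed on standardized drug sensitivity (the coefficient
equals the Pearson correlation; two-sided $t$ test, $n-2$ df, nominal
$p < 0.05$ without multiplicity correction — deliberately liberal, as the
yeast evidence provides the prior). Genes under-expressed in sensitive
lines (UES) are matched through a yeast–human homology table (one-to-one /
one-to-many / many-to-many) to yeast deletion enhancers, and OES genes to
suppressors; direction mismatches are never emitted. Predictions supported
by two independent panels and called in both media form the priority set.

## The synthetic-data generator

Real screens of this design require robotics and curated databases; the
generator emulates the statistical structure of every input so the whole
pipeline is testable from a single seed:

* logistic growth with additive Gaussian intensity noise truncated at 0
  (the simplest model consistent with replicate error bars), culture-level
  jitter of $l$ and $K$, and a linear reference dose response on $l$
  (slower) and $K$ (lower) — a monotone form standing in for the empirical
  dose effect;
* strain-specific baseline shifts at dose 0, and planted linear
  dose-by-gene interaction slopes for configurable fractions of enhancers
  and suppressors, each active in both media or in only one (cycled
  deterministically so every Warburg class is represented);
* petite-like strains producing flat baseline traces in respiratory medium
  only;
* 768 reference cultures per medium, split evenly across doses; cultures
  sharing a replicate index across doses form the reference series that
  define the null interaction distribution;
* GO terms of size 2–50 over the strain universe with planted terms whose
  members share an interaction sign; a homology table giving planted yeast
  genes dedicated human partners; and two independent cell-line panels with
  expression–sensitivity correlations of magnitude `r_planted` for planted
  UES/OES genes.

Planted effect sizes are parameterised in hours of $L$ displacement at the
maximum dose (default 3 ± 0.5 h). Under the default intensity noise
(SD 2 on curves with $K$ 150–200) the reference interaction SD for $L$ is
roughly 0.2–0.3 h, so defaults correspond to effects of about 10–15
reference SDs — comfortably above the 4-SD regime where sign recovery is
expected to be near-perfect. What the generator does *not* emulate: plate
spatial effects, neighbor artifacts, non-logistic growth shapes, batch
structure across plates, and correlated measurement error — so passing
tests demonstrate correctness of the statistical machinery under the
model's assumptions, not robustness to every artifact of real screens.

## Numerical choices

* **Growth fits** use Levenberg–Marquardt with bounds $K \in (0, 2\max y]$,
  $r \in (0, 10]$, $l \in [0, 2\,\mathrm{horizon}]$ and log-odds-regression
  starting values; a flat trace, solver failure, a fitted $K$ below 5% of
  the reference median at dose 0, or a fitted half-time outside the
  observed window (the $L$ CPP is then unidentifiable) is reported as
  `no_growth` with $K = r = 0$.
* **EM clustering** uses diagonal covariances, 10 restarts (means seeded
  from random rows), relative tolerance $10^{-6}$, at most 500 iterations,
  an absolute variance floor of $10^{-6}$ plus a relative floor of
  $10^{-3}$ of each feature's variance, and discards restarts in which a
  component captures fewer than two rows — both guards against the
  classical likelihood singularities of mixture fitting. BIC replaces the
  original screen's cross-validated selection as a deterministic,
  reproducible surrogate; cluster counts are therefore a re-specification,
  not a replication, of any particular historical run.
* **Determinism.** Every stage derives a child seed from the master seed
  (`child_seed(seed, k)`, a fixed affine map mod $2^{31}-1$), so adding or
  re-running one stage never perturbs another.
* **Sample SDs** ($n-1$) are used throughout; for GTA this is forced by
  the published worked examples (sd of $\{-13.9, -10.5\}$ must print 2.4,
  not the population value 1.7).

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)           # 96 strains, 768 references/medium
run <- run_pipeline(cfg)
print(run)
head(run$scores[order(-abs(run$scores$z_L)),
                c("strain_id", "medium", "z_L", "z_K", "call")])
run$gta[run$gta$significant, c("term_id", "medium", "gta_value", "gta_sd")]
run$predictions[run$predictions$priority, ]
write_run(run, "phenogi_out")
```

The default test-suite and example problem sizes (96–150 strains, 40–60
reference cultures in unit tests, the full 768 in the end-to-end run) were
chosen so each stage's statistical behaviour is measurable while a complete
run stays interactive on a laptop.

## Known limitations

* The per-strain replicate structure of real screens is not published in
  detail; the generator defaults to one culture per (strain, medium, dose)
  and exposes `replicates` as a knob.
* Whether $Y_i\max$ capping should also apply to $K$ and $r$ is ambiguous
  in the source procedure; it is implemented for $L$ only (switchable via
  `cap_outliers`).
* The cell-line association model is a re-specification (standardized OLS,
  coefficient = Pearson r) of an analysis originally delegated to external
  pharmacogenomics software; tissue-stratified and pooled modes are both
  provided, without covariate adjustment.
* Genome-wide biological inventories (cluster counts, enriched-term counts,
  specific gene lists) depend on the real library and database versions and
  are out of scope; the package reproduces the *procedures* and the printed
  worked examples.
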