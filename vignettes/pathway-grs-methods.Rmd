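---
title: "Pathway-based genetic risk scores for blood lipids: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-based genetic risk scores for blood lipids: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`pathgrs` implements a complete small-panel genetic-epidemiology workflow
for two dyslipidemia phenotypes — fasting triglycerides (TG) and
HDL-cholesterol (HDL-C), both in mg/dL — built around pathway-based
genetic risk scores (GRS). The packaged panel comprises 19 variants in
lipid-metabolism genes organised into three pathways: reverse cholesterol
transport (RCT), cellular lipid uptake (CLU) and lipoprotein formation
(LPF). Because individual-level cohort data of this kind are not publicly
distributable, the package ships a synthetic cohort generator that
realises exactly the statistical model the analysis fits; every stage of
the pipeline is exercised and tested against it.

# The analysis model

## Per-SNP association

Genotypes are dosage-coded 0/1/2 as copies of a designated counted
allele. For each SNP the package fits an ordinary least-squares general
linear model

$$ y_i = \mu + \beta g_i + \gamma^\top c_i + \varepsilon_i $$

where $y$ is the phenotype on its analysis scale, $g$ the dosage, and $c$
the covariates (age and sex in the base model; BMI and/or ancestry PCs in
extended models). Normality of each phenotype is assessed by Shapiro–Wilk
at $\alpha = 0.05$; a rejected phenotype is natural-log transformed and
all reported means are back-transformed (geometric means). In the
synthetic cohort TG is log-normal by construction and HDL-C normal, so
the transform decision is deterministic in practice.

Two parallel fits are produced deliberately:

* the **additive (dosage) fit** supplies the per-allele effect $\beta$,
  its Wald p-value, a normal-approximation 95% CI, and the partial
  $R^2$;
* a **genotype-as-category fit** (0/1/2 as a factor) supplies
  least-squares means per genotype class at covariate means, with
  Tukey–Kramer-adjusted pairwise comparisons (via `emmeans`).

The categorical fit exists because risk alleles are defined through
adjusted class means, while score weights require a single per-allele
slope; reconciling the two conventions inside one object avoids any
ambiguity about which fit feeds which downstream step. Tukey–Kramer is
applied only within one model's genotype contrasts — its standard scope —
and no across-SNP multiplicity correction is made, matching the
small-panel reporting style this workflow mirrors.

**Partial $R^2$** of any term is defined as the increment in model $R^2$
over the same-sample model without the term, which equals the term's
Type-III sum of squares divided by the corrected total SS. The test suite
holds the implementation to the nested-model definition at an absolute
tolerance of 1e-10 on every fitted model.

**Risk alleles are phenotype-specific.** For TG the risk allele is the
one whose higher dosage class has the higher adjusted mean (the counted
allele iff $\hat\beta > 0$); for HDL-C it is the allele associated with
the *lower* adjusted mean ($\hat\beta < 0$). The same SNP can therefore
carry different risk alleles for the two phenotypes. An exactly zero
estimate is flagged ambiguous and the minor allele is assigned with a
warning — a tie-break that can only trigger on degenerate inputs.

## Quality control and linkage disequilibrium

* **MAF / call rate**: computed from non-missing codes; the folded MAF is
  $\min(\hat p, 1-\hat p)$.
* **Hardy–Weinberg equilibrium**: 1-df Pearson $\chi^2$ of observed
  genotype counts against $p^2, 2pq, q^2$ at the estimated allele
  frequency, no continuity correction. SNPs with $p < 0.05$ are excluded;
  the workflow this package encodes states exclusion but no $\alpha$, so
  0.05 — its global significance convention — is the default and is
  configurable. Monomorphic SNPs are not testable and are excluded with
  their own reason.
* **LD**: the genotypes are unphased, so two estimators are computed per
  pair: the composite $r^2$ (squared Pearson correlation of dosages) and
  $|D'| = |D|/D_{max}$ from two-locus haplotype frequencies estimated by
  EM (tolerance 1e-8, at most 1000 iterations; only the double
  heterozygote is ambiguous and its cis/trans split is re-estimated each
  iteration). This internal computation is a deliberate substitution for
  a reference-panel web service: it estimates LD in the analysis sample
  itself and requires no network. Pairs are assessed within a gene or
  chromosome, mirroring the original analysis convention.
* **Tag-SNP pruning**: connected components of the graph of pairs with
  $D' \ge 0.8$ (threshold configurable; reported pruned groups had
  $D' = 1.0$ but no cutoff was stated) collapse to the member with the
  greatest phenotype variance explained, i.e. the largest partial $R^2$
  from the age+sex per-SNP model. Ties break to the larger MAF, then
  lexicographic SNP id. Pruning is idempotent by construction.
* **The ABCA1 pair** (rs4149310, rs9282541) is *not* a pruning outcome:
  both variants stay in the panel and are partitioned between phenotypes
  (rs4149310 contributes to TG scores, rs9282541 to HDL-C scores),
  encoded as a `pheno_specific` column in the panel and an exemption in
  the pruning graph. Their $D' = 1$ coexists with a small $r^2$, which no
  reasonable $r^2$ threshold would prune.

## Score construction

For a definition with members $j = 1..m$, each member's risk-allele
count is the dosage itself when the counted allele is the risk allele and
$2 - g$ otherwise. Scores are

$$ \mathrm{GRS}_i = \sum_j w_j \, \tilde g_{ij} $$

with $w_j \equiv 1$ for the additive score (range $[0, 2m]$; the
14-member total score attains 28 for an individual homozygous for every
risk allele) and $w_j = $ the in-sample per-risk-allele effect estimate
for the weighted score. Weights are kept *signed*: with risk-oriented
dosages they are positive for TG and typically negative for HDL-C, so
weighted HDL-C scores sum to negative values — matching the raw-signed-sum
convention implied by a negative mean weighted HDL-C score in the source
workflow. In-sample weights are a known overfitting risk; external
weights were not an option because published effect sizes for this
population are largely unavailable, and the limitation is stated rather
than hidden.

Scopes are the three pathways, their union (`TOTAL`), and `TOP_HITS`
(SNPs individually associated below a threshold). The top-hits default is
the *loose* $p < 0.10$ rule: the reported TG top-hits list is larger than
the individually significant set at 0.05, implying the loose rule was
used; both sets remain constructible.

Individuals missing any member genotype are excluded from that score
(complete-case; expected-dosage imputation exists but is off by default).
**Risk groups** split at the median of the analysed scores; high risk is
*strictly greater* than the median, ties go low — consistent with a
"more than $m$ alleles" description of the high-risk group. The partition
is invariant under adding any constant to all scores.

## GRS-phenotype models and reporting

The GRS model is the same OLS GLM with the score in place of the dosage.
Reported per fit: model F-test p and $R^2$, the score term's Wald p,
$\beta$ per unit score with 95% CI, and the score's partial $R^2$.
"Percent variability explained" is $100 \times R^2$; the GRS percent is
*suppressed* ("NC", not calculated) whenever the score term fails
$p < 0.05$, reproducing the reporting convention of the tabulated
results this layout mirrors — the raw partial $R^2$ is always retained in
the object for programmatic use.

Risk-group differences use Student's t-test on the analysis scale, with
group means ± SE back-transformed for log phenotypes (delta-method SE).
Sex-stratified runs drop sex from the covariates and refit within each
stratum (minimum 30 individuals, else skipped with a warning); no formal
gene–sex interaction is fit, as the motivating cohort was underpowered
for one. TG concentrations can additionally be classified into four
guideline bands with half-open boundaries: Optimal (< 90), Early
metabolic risk (90 ≤ TG < 130), Borderline metabolic risk
(130 ≤ TG < 150), Clinical hypertriglyceridemia (≥ 150 mg/dL).

## Ancestry adjustment

Admixture is adjusted with principal components of
ancestry-informative-marker (AIMs) genotypes: dosages are mean-imputed,
centered by $2\hat p$ and scaled by $\sqrt{2\hat p(1-\hat p)}$
(frequency-scaled, Patterson-style, chosen over raw covariance because it
weights drift information evenly across allele frequencies), then
decomposed by SVD. Two components are the default, matching the source
workflow's choice; the factor-analysis "sufficiency" judgement is
replaced by an explicit `n_components` parameter. Component signs follow
a fixed convention (largest-magnitude loading positive) so results are
reproducible across marker orderings.

# The synthetic cohort generator

The generator is first-class, tested code. Its defaults *are* the study
conditions the package emulates:

| Parameter | Default | Basis |
|---|---|---|
| n | 580 | cohort size |
| counted-allele frequencies | panel `maf_cohort` column | published cohort MAFs |
| sex | Bernoulli, 315/580 female | cohort composition |
| age | Normal(18.9, 0.9) truncated to [18, 25] years | cohort mean; family chosen, not published |
| BMI | Normal(23.6, 4.0) truncated positive, kg/m² | cohort mean; family chosen |
| TG | log-normal, residual SD 0.42 on the log scale | SD implied by the cohort mean ± SE (approximation, not a published value) |
| HDL-C | normal, residual SD 10 mg/dL | same reasoning |
| missingness | 1% completely at random | plausible assay-level missingness |

Intercepts (3.88 log-mg/dL for TG, 62.5 mg/dL for HDL-C) are solved so
the marginal means land near the cohort means (≈ 108.5 and 49.6 mg/dL)
after accounting for the mean genetic and covariate contributions.
Default SNP effects concentrate TG signal in CETP/MLXIPL/LIPC/PPARG
variants (0.03–0.07 per allele on the log scale) and HDL-C signal in
ABCA1-rs9282541 (−4 mg/dL per allele, the dominant key SNP) with smaller
CETP/LIPC/LPL contributions — magnitudes chosen once as plausible
common-variant lipid effects that reproduce the qualitative association
pattern (a dominant HDL-C key SNP whose removal abolishes the
association; TG signal spread over several pathways), not published
estimates.

Three LD blocks emulate the reported haplotype structure, each with one
absent recombinant class so every within-block pair has $|D'| = 1$: the
ANGPTL4 trio, the CD36 pair, and the ABCA1 pair (risk alleles placed on
*opposite* haplotypes so $D' = 1$ coexists with small $r^2$, ≈ 0.07 at
the panel frequencies — the qualitative phenomenon, not the exact
reference-panel value of 0.041, which is unattainable at these marginal
frequencies). Block marginals match the panel's cohort frequencies.

Genotypes at independent SNPs are two Bernoulli draws (Hardy–Weinberg by
construction); HWE failure in real data is an assay phenomenon the
generator does not emulate — the packaged panel instead *flags* the
reported HWE-failing CD36 variant, and the QC stage is tested on
constructed heterozygote-deficit genotypes. AIMs follow a two-way
admixture model: individual admixture proportions $q_i \sim$ Beta(3, 2)
and per-AIM frequencies interpolate between two well-separated ancestral
frequency sets (design constants drawn once from a fixed stream,
0.75–0.95 vs 0.05–0.25). An optional confounded mode makes panel allele
frequencies ancestry-dependent (±`freq_delta`/2 between ancestral
populations) and shifts phenotype means linearly in $q$, creating genuine
population-stratification confounding for type-I-error experiments.

One master seed drives everything through a fixed stream-splitting rule
(genotypes seed+1, AIMs +2, phenotypes +3, admixture +4, missingness +5),
so all outputs are byte-identical given the seed. Phenotypes are
generated from the complete genotype matrix before missingness is
applied.

**What passing tests do and do not show.** The generator has no real
human LD map beyond the three constructed blocks, no genotyping-batch or
informative-missingness structure, exactly two ancestral populations, no
relatedness, and no diet/activity covariates. Tests against it verify the
estimators and the pipeline logic under the assumed model — they do not
validate the biological claims of any particular cohort.

# Verification design

The test suite checks, among other properties:

* HWE $\chi^2$ against an independently computed expected-count
  chi-square for *every* genotype-count triple with $n \le 30$
  (exhaustive), and hand-derived values such as $\chi^2 = 100$ for
  (50, 0, 50);
* EM-based $D'$/$r^2$ against the closed form on simulated haplotypes
  (AB/Ab/aB/ab at 0.45/0.05/0.05/0.45 gives $D' = 0.8$, $r^2 = 0.64$;
  n = 5000);
* partial $R^2$ ≡ nested-model $\Delta R^2$ at 1e-10 on every fit;
* null calibration of the GRS term: rejection rate 0.05 ± 0.02 over
  1000 null simulations at n = 580;
* parameter recovery: configured per-SNP effects and the unit slope of a
  truth-weighted score recovered within 2 SEs in ≥ 93% of 200 replicates
  at n = 580;
* confounding control: under the confounded generator
  (`freq_delta = 0.15`, log-TG shift 0.4 per unit admixture — strengths
  chosen when the experiment was designed so that stratification visibly
  inflates the unadjusted test while remaining within what two PCs of 64
  AIMs can absorb), the unadjusted GRS type-I error is inflated and two
  AIMs PCs restore it to 0.05 ± 0.02 over 800 replicates;
* exact invariance of p-values, partial $R^2$, risk-allele identity and
  the risk-group partition under allele recoding ($g \to 2-g$);
* byte-identical rerun determinism, file round-trips, and the panel
  bookkeeping that reduces 19 packaged variants to 14 members per
  phenotype under the reported exclusions.

Monte-Carlo suite sizes (200–1000 replicates; cohorts of 250–580; 400
SNPs for the p-value uniformity check) were chosen to keep Monte-Carlo
error well inside each asserted band while the whole suite runs in about
a minute.

# Known limitations and deliberate non-goals

* Weighted-score weights are estimated in-sample; no cross-validation is
  performed, so weighted-score $R^2$ values are optimistic.
* LD estimation assumes biallelic, autosomal variants; no imputation,
  multi-allelic handling, or X-chromosome dosage.
* The "NC" suppression rule is a reporting convention, not an inference
  procedure; raw quantities remain available.
* The VCF reader covers biallelic records with a GT field only; the CSV
  dialect is the canonical interchange format for panels of this size.
* The pipeline's functions (and `run_pipeline()`) are the interface;
  simulation, QC, association, scoring and reporting are all driven from
  R rather than a shell entry point, which suits an analysis package of
  this scope.
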