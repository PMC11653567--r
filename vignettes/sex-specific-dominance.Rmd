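---
title: "Inferring sex-specific dominance of gene expression from reciprocal crosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring sex-specific dominance of gene expression from reciprocal crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssdominance)
```

## The question and the design

When two homozygous lines are crossed, the expression of a transcript in
the F1 heterozygote can sit anywhere between (or beyond) the two parental
levels. If heterozygote expression deviates from the parental average in
a sex-dependent way — the allele conferring higher expression acting
dominant in one sex and recessive in the other — regulatory variation can
experience net balancing selection under sexually antagonistic selection.
This package infers such sex-specific dominance from bulk RNA-seq counts
of a standard reciprocal-cross design: per cross, two parental homozygous
lines and their two reciprocal F1s (each line used as dam and as sire),
both sexes, with replicated samples — 4 genotypes x 2 sexes x r
replicates.

The estimand is the dominance coefficient of the high-expression allele,
defined on the natural scale relative to the arithmetic midparent. For
sex $s$, with normalized parental means $AA_s \le BB_s$ (the line with
the higher pooled-sex expression is always relabeled "BB") and the
heterozygote mean $H_s$ pooled over the two reciprocal directions,

$$\delta_s = \ln \frac{H_s}{(AA_s + BB_s)/2}.$$

$\delta_s = 0$ means additivity, $\delta_s > 0$ dominance of the
high-expression allele, $\delta_s < 0$ recessivity. A transcript shows
*sex-specific dominance* (SSD) when the sex-by-dominance interaction in
the count model is significant, and a *dominance reversal* when,
additionally, $\hat\delta_f$ and $\hat\delta_m$ have opposite signs.

## The count model

Counts for one transcript are modeled as negative binomial with a log
link,

$$\log \mu_{i} = o_i + \beta_0 + \beta_s x_i^{sex} + \beta_a a_i +
\beta_h h_i + \beta_p p_i + \beta_{sa} x_i^{sex} a_i +
\beta_{sh} x_i^{sex} h_i + \beta_{sp} x_i^{sex} p_i,$$

where $o_i$ is the log median-of-ratios size factor, $x^{sex} = \pm 1$
(female $+1$), $a \in \{-1, 0, +1\}$ codes the additive genotype
(low-line homozygote, heterozygote, high-line homozygote), $h$ indicates
heterozygosity, and $p = \pm 1$ distinguishes the two reciprocal
heterozygote directions (positive when the dam is the high line; 0 for
homozygotes), so that parent-of-origin effects are identified purely by
the reciprocal F1 contrast. With a complete design the eight columns are
saturated for the eight (genotype, sex) cells. Headline calls are 1-df
likelihood-ratio tests (LRTs): dropping $\beta_{sh}$ for the
sex-by-dominance test, dropping $h$ within one sex's samples for per-sex
nonadditivity, and dropping $p$ within a sex for per-sex parent-of-origin
effects. Wald statistics are available for inspection but are not used
for calls; LRTs behave better at three replicates per cell.

The per-gene dispersion $\phi$ (variance $\mu + \phi\mu^2$) is estimated
once per gene by maximizing the Cox–Reid adjusted profile likelihood
under the saturated design, and is then held fixed across every nested
fit of that gene. Estimating $\phi$ under the richest model and sharing
it across contrasts is standard practice for count GLMs; re-estimating
under reduced models would distort LRT p-values. No empirical-Bayes
shrinkage across genes is applied: with $\ge 3$ replicates in each of 8
cells the per-gene estimate has 16 residual degrees of freedom, and
keeping the estimator self-contained makes its behavior fully testable.
The known cost is a mildly liberal LRT at 3 replicates (type-I error
about 0.06 at nominal 0.05, and empirical FDR of roughly 0.10–0.12 in
the SSD calls at q ≤ 0.05 — about twice the nominal level); the
validation suite measures both.

Note that $\delta$ is deliberately computed from normalized observed
group means (the definition above), while significance comes from the
GLM. The GLM's own dominance coefficient `beta_h` — a deviation from the
*geometric* midparent — is reported alongside for transparency. The two
scales agree at small parental differences but diverge for large ones;
filtering step 2 (below) removes the genes for which the divergence
would differ by sex.

## Workflow

Per cross (all inference is per cross, and autosomal and X-linked
transcripts are analyzed separately):

1. **Y removal and low-count filter.** Y-linked transcripts are removed.
   A transcript is removed when its mean raw count per sample is below 3
   within *every* sex; requiring failure in all sexes (rather than any)
   retains sex-limited transcripts, which can exceed 5 log2 units of sex
   bias and would otherwise be lost. The alternative scope is available
   as `low_count_scope = "any_sex"`.
2. **Normalization and QC.** Median-of-ratios size factors; a shifted-log
   transform `log2(count/sf + 1)` for sample-level diagnostics only.
   Mis-sexed samples (e.g. a mislabeled pool) are flagged as
   within-sex outliers: each sample is assigned to the nearer sex
   centroid in the top-2 PC space (leave-one-out); disagreements with the
   annotation are flagged and excluded. A centroid rule replaces visual
   inspection so the procedure is reproducible.
3. **Two-step focal filter** (parental samples only): step 1 keeps
   transcripts with a significant parental-line difference (only these
   are informative about dominance); step 2 removes transcripts with a
   significant sex-by-line interaction, i.e. sexually discordant
   parental effects. Both use 1-df LRTs with q-values at 0.05; step 2 is
   assessed among step-1 survivors.
4. **Dominance stage.** Orientation (high line becomes "BB";
   deterministic lexicographic tie-break), $\delta_f, \delta_m$ from
   normalized group means, the LRT battery above, and q-values computed
   separately per cross and chromosome class. For X-linked genes males
   are hemizygous — male "heterozygotes" express the maternal allele —
   so dominance and its sex interaction are assessed in females only,
   and male X data serve only the dam-clustering diagnostic.
5. **Classification.** Per sex: dominant / recessive / additive by the
   sign of $\delta$ and the per-sex q-value; SSD by the interaction
   q-value; reversal by opposite $\delta$ signs within SSD. Each focal
   transcript is also labeled by whether heterozygotes show greater or
   lesser absolute log2 sex bias than the midparent.
6. **Post-hoc statistics.** Major-axis (type II) regression of
   $\delta_f$ on $\delta_m$ (both estimates carry error, so a symmetric
   regression is appropriate), with the Jolicoeur rotation CI; a 1-df
   equal-proportions chi-square (no continuity correction) for the
   greater/lesser split among SSD transcripts; a directional
   two-sample Kolmogorov–Smirnov test of whether SSD transcripts have
   stochastically larger |log2 sex bias| than non-SSD focal transcripts,
   with the one-sided asymptotic p-value $\exp(-2 D^{+2} mn/(m+n))$; and
   Fisher's exact test associating sex-bias direction with SSD.
7. **GO over-representation** of the SSD set against the cross's focal
   set (not the whole transcriptome) as universe: classic per-term
   hypergeometric upper-tail test, terms with fewer than 5 universe
   genes skipped, optional ancestor propagation when ontology edges are
   supplied. Graph-decorrelation algorithms are out of scope; with the
   focal set as universe the classic test answers the headline question.

Multiple testing uses Storey q-values with fixed $\lambda = 0.5$:
$\hat\pi_0 = \min(1, \#\{p > 0.5\} / (0.5\,m))$ followed by the step-up
rule; with $\hat\pi_0 = 1$ this is exactly Benjamini–Hochberg. A fixed
$\lambda$ keeps the procedure deterministic; at the m of a typical cross
the difference from the smoother variant is negligible. The cutoff is
0.05 throughout.

## The synthetic-data generator

Real data for this design exist but validation requires known truth, so
the generator emulates the study conditions: three crosses of 2,000
transcripts, 4 genotypes x 2 sexes x 3 replicates each (72 samples);
about half of transcripts sex-biased, with |log2 fold change| uniform on
(0.5, 10) — the upper bound calibrated so that PC1 of the transformed
counts separates the sexes and carries upward of 85% of the variance, the
regime reported for abdominal tissue of this kind; about half of
transcripts with a parental-line difference per cross (between-line fold
change 1.2–4x), of which 30% have sex-discordant additive effects (the
step-2 target); dominance coefficients Normal(0, 0.3) truncated at
|1.2|, shared between the sexes except in the SSD fraction (8% of
line-different genes), where the sexes are separated by a gap of 0.5–1.5;
rare parent-of-origin effects (2%); X-hemizygous males; male-only Y
expression; log-normal library sizes (sd 0.3 in log space); and
dispersions log-normal with median 0.02 — deliberately low, because each
sample pools six isogenic individuals. Sex effects, baselines, chromosome
classes and dispersions are gene-level properties shared across crosses;
line effects, dominance and parent-of-origin effects are drawn
independently per cross, so the three crosses expose largely distinct
variants.

What the generator does *not* emulate: GC or length biases, batch
effects, correlated expression modules, cis/trans architecture, allelic
read-level signal, and partial (within-sample) sex contamination —
mislabeled samples are swapped whole, since a pooled sample is the unit
an analyst can flag. Passing tests on this generator therefore validate
the statistical machinery under the design's stochastic model, not
robustness to those artifacts.

Two generator-related caveats are worth stating. First, with strong
line effects in half the transcriptome, heterozygote samples genuinely
exceed the geometric-mean pseudo-reference (the arithmetic midparent is
at least the geometric mean of the parents), so median-of-ratios size
factors can absorb a small genotype-correlated component; with the
default effect scales the residual bias on $\hat\delta$ is below 0.01,
and the sex-by-dominance test is unaffected because the bias cancels
between the sexes. Second, the sex-by-dominance LRT with plug-in
per-gene dispersion at 3 replicates is mildly liberal (about 0.06 size
at nominal 0.05); the empirical FDR among SSD calls at q ≤ 0.05 is
correspondingly near 0.1 rather than 0.05. Both are measured by the
validation suite at fixed problem sizes (2,000 null genes for the size
check; the default three-cross design for end-to-end recovery).

## Numerical choices and degenerate inputs

* IRLS runs to a relative deviance change below 1e-10 (at most 100
  iterations); dispersion estimates are floored at 1e-8 and capped at 10.
* A nested fit whose likelihood exceeds the full fit's (a convergence
  failure) triggers a refit of the full model from the reduced solution;
  a persistent violation flags the gene, which is excluded from calls.
* All-zero genes return the dispersion floor with a flag; zero midparent
  or heterozygote means yield NA dominance coefficients (these cannot
  occur for focal transcripts, which must pass the low-count filter and
  show parental differential expression).
* Exact orientation ties are broken toward the lexicographically larger
  line label and logged.
* The chi-square test is uncorrected by design: with counts in the
  hundreds a continuity correction only distorts the statistic.
* Empty margins in the 2x2 exact test return p = 1 with a message.

## Reproducibility

Everything downstream of the generator is deterministic: rerunning
`run_pipeline()` on the same inputs reproduces every number bit for bit,
and `write_results()` serializes doubles at 17 significant digits so a
write/read round trip is lossless. The generator itself is seeded. The
`scripts/acceptance.R` script regenerates the synthetic study from a
seed, reruns the pipeline, and reports the headline quantities; the
testthat suite asserts the corresponding bands at fixed problem sizes
(200–2,000 genes per check) chosen to keep the full validation run in a
few minutes on one CPU.

## Known limitations

* No empirical-Bayes dispersion moderation; with fewer than 3 replicates
  per cell the per-gene LRTs would become unreliable.
* The LRT's mild liberality at low replication is inherited by the SSD
  q-values (empirical FDR of roughly 0.10–0.12 at q ≤ 0.05 under the
  default conditions); users wanting strict FDR 0.05 should use
  q ≤ 0.02–0.025 or add replicates.
* Per-sex dominance calls use within-sex LRTs; a joint-model Wald
  alternative would differ slightly in borderline cases.
* The step-1/step-2 filters use q ≤ 0.05 on the respective tested sets;
  raw-p filtering would enlarge the focal set at the cost of more
  uninformative genes.
* GO analysis assumes the supplied map is complete for the universe;
  unannotated genes simply never appear in any term.
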