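---
title: "Quantifying retrotransposon activity against biological age: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retrotransposon activity against biological age: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rteage)
library(dplyr)
```

## The problem

Retrotransposons (RTEs) — LINEs, SINEs and LTR elements — are mobile
elements silenced by DNA methylation and heterochromatin. Their reactivation
has been tied to inflammation, senescence and genome instability, all
hallmarks of aging. Testing that link in large human cohorts is hard
because the biggest non-cancerous blood cohorts are microarray-based, and
array probes were never designed for repetitive sequence. `rteage`
implements a probe-reuse strategy: find the array probes that happen to sit
in noncoding repeat sequence, assign each to a repeat, and average them into
per-sample RTE class and family scores. The scores are then related not to
chronological age but to *biological age*, read out through gene-expression
signatures (type-I interferon response, inflammatory cytokines and
chemokines, inflammaging, SASP, cellular senescence).

This vignette documents the models, the tunable parameters, the synthetic
data the package validates itself on, and the numerical choices made where
the design was genuinely open.

## Probe assignment

Coordinates are 0-based half-open everywhere inside the package;
RepeatMasker `.out` (1-based inclusive) and GTF are shifted on read, BED
passes through. Context classification is a strict precedence: a probe
overlapping any exon by ≥ 1 bp is `exonic`, otherwise inside any gene body
`intronic`, otherwise `intergenic`. Only intergenic and intronic probes
enter repeat assignment, since exonic probes measure the host transcript.
Strand is stored but ignored for overlap — expression probes interrogate
transcripts regardless of the annotated strand, and the analysis has no
strand-resolved step.

Each qualifying probe is assigned to **one** repeat: maximum overlap, ties
broken by leftmost repeat start and then lexicographic repeat name. Single
assignment (rather than multi-assignment) means a probe spanning two nested
repeats never counts twice in a class score. Any overlap ≥ 1 bp qualifies;
no minimum-overlap tuning parameter is exposed because none is needed for
the downstream statistics. The indexed implementation (GenomicRanges) is
checked exactly against an O(n·m) brute-force oracle in the test suite.

## Score aggregation

The RTE score of group *g* (class or family) in sample *s* is the
unweighted mean of the values of the probes assigned to *g*. Class scores
pool probes across the class's families, so families contributing more
probes weigh more — a deliberate choice, documented and tested, matching
how the probe populations actually sample the genome. The same estimator
serves log-intensity expression and methylation beta values (a mean of
betas stays in [0, 1]). Duplicate feature rows (several probes reporting
one gene symbol) are collapsed to their per-sample mean before any scoring.

For read-level data, each read is counted once toward its best-overlapping
repeat (same tie-break as probes) and counts are normalized to reads per
million. RPM with a `column_total` denominator makes every sample column
sum to exactly 10^6; a supplied-totals mode supports denominators computed
on a wider feature universe.

## Signature scoring

Scoring is rank-based and single-sample. Genes are ranked 1..n ascending
within each sample (average ranks on ties). With *m* of a signature's genes
present, the mean rank lies between (m+1)/2 (signature at the bottom) and
(2n−m+1)/2 (signature at the top); the score maps that interval onto
[0, 1]. Scoring is unidirectional — the six biological-age signatures are
plain gene lists with no down-set — and uncentred, so larger is always
"more signature-like". Scores depend only on within-sample ranks, hence are
invariant to any strictly monotone transform of a sample's values; this is
the property that lets one compare scores across normalization schemes.
Genes missing from the matrix are dropped from the signature and reported
(never silently): cohorts on older array versions routinely lack a handful
of signature genes, and the missing-gene report is the audit trail.
Symbols are matched case-insensitively after whitespace stripping; no alias
resolution is attempted.

## Gene-set variation scoring

The per-sample enrichment score is computed in three steps. (1) For gene
*g* with values x and standard deviation sd_g, a Gaussian-kernel CDF
estimate `h(g,s) = mean_k Φ((x_gs − x_gk)/(sd_g/4))`; zero-variance genes
get h ≡ 0.5. The bandwidth sd/4 is the standard choice for continuous
microarray-scale data; a count-kernel mode is out of scope. (2) Within each
sample, genes are ordered by decreasing h; position r carries weight
|G/2 − r|, emphasising both extremes of the ranking. (3) Walking down the
ordering, the running sum gains w/Σ_set(w) at members and loses 1/(G−m) at
non-members; the enrichment score is the maximum positive deviation plus
the minimum negative deviation of the walk (the difference-of-extremes
statistic, chosen over max-absolute-deviation and fixed). Ties in h are
broken by row order, making the walk deterministic.

High/low differential calls use a two-sided Welch t-test on the enrichment
scores with the deliberately permissive thresholds |logFC| > 0.1 and
p < 0.05 (which test to use on enrichment scores is an open design point;
Welch was chosen over a moderated t to keep the package self-contained, and
no multiple-testing correction is applied by default, matching the raw-star
annotation convention — a Benjamini–Hochberg option exists on the
correlation table). MSigDB-style curation is reproduced by
`filter_gene_set_names()`: names ending `_UP`/`_DN` and three fixed
near-duplicate acute-inflammation GO sets are dropped.

## Cohort statistics

Quartile stratification uses linear-interpolation quantiles (type 7):
`low` is value ≤ Q1, `high` is value > Q3, `medium` the rest, so boundary
ties resolve deterministically (low side inclusive, high side exclusive).
Median splits send values > median to `high`, the rest — including the
median element at odd n — to `low`. The quartile estimator itself was
unspecified in the analyses this package systematizes; type 7 is R's
default and the convention is fixed for reproducibility.

Pearson correlations use pairwise deletion of missing values, with the
two-sided p from the t distribution on n−2 df. Rank-sum contrasts use the
normal approximation with tie **and continuity** corrections: at the group
sizes the single-cell contrasts produce (around 10 per group), the
uncorrected approximation is anti-conservative (rejection rate 0.051
versus the exact test's 0.043 at nominal 0.05), while the corrected one
matches the exact test; identical groups still give p = 1 exactly because
the z statistic is 0.

## The synthetic cohorts

The generators exist to validate the pipeline end to end, with structure
chosen to emulate the statistical shape of blood aging cohorts — not their
biology. The central construct is a latent biological-age factor **B** per
sample, standard normal and *independent of chronological age*. Defaults:

| parameter | default | meaning |
|---|---|---|
| `n_samples` | 600 | cohort size (real cohorts: 139–1202) |
| `age_range` | 15–101 | uniform ages, the span of the modelled cohorts |
| `beta_bar` | LINE/LTR +0.5, SINE −0.5 (PBMC mode), Satellite 0 | probe-level coupling to B |
| `sig_coupling` | 1 | signature-gene coupling to B |
| `noise_sd` | 1 | residual SD (log-intensity scale) |
| `beta_age_expr` | 0 | no chronological-age signal in expression |
| `beta_age_meth` | −0.002/yr | methylation slope; ≈ 0.17 beta over the age span |
| `meth_noise_sd` | 0.05 | probe-level beta noise |
| `probes_per_family` | 8 | ≥ 3 per family required |

Signature genes follow `sig_coupling·B + ε`; RTE probes follow
`beta_bar[class]·B + ε`. Because B ⟂ age, RTE scores show no age
correlation while correlating with signature scores through B — the
headline dissociation. In `monocyte` mode SINE couples positively,
mirroring the cohort-type dependence of the SINE sign. The expected
attenuated correlation `r = β·σ_B / sqrt(β²σ_B² + σ_ε²/n_probes)` is
verified against the observed correlation within Fisher-z bounds in the
tests.

Methylation betas are `clip(b0 + slope·age + ε, 0, 1)` with probe baselines
b0 ~ U(0.70, 0.85); at the default slope and noise, clipping touches well
under 1% of values (clipping, not a logistic link, keeps the planted slope
exactly linear where it matters). The matched expression matrix couples
LINE/LTR probe expression to the *age-independent residual* of methylation
(inverted), so expression-stratified groups recover hypomethylation without
inducing an artificial age–expression correlation; SINE and Satellite
expression is decoupled, reproducing the observed SINE exception.

The single-cell generator draws negative-binomial counts (dispersion 10)
for 300 genes and the three RTE classes over a compact panel of five PBMC
lineages (plasma cells, B, T, NK, CD14 monocytes) across 21 samples —
the panel is deliberately smaller than a fully annotated atlas; it is the
minimal set on which per-cell-type contrasts are meaningful. Signature
genes scale linearly as (1 + 0.4·B) with an equal-size decoy block scaling
as (1 − 0.4·B): the linear balanced form keeps the expected library size
independent of B. An earlier multiplicative exp(±cB) form was rejected
because its cosh(cB) library-size inflation in extreme-B samples coupled
the RPM denominator to the grouping and produced systematic spurious
contrasts. RTE baselines (5/8/4 counts per cell for LINE/SINE/LTR) keep
RTE reads a small fraction of each library, as in real data. The planted
effect multiplies the plasma-cell LINE mean by 3 in samples with
above-median B only.

What the generators do **not** emulate: batch and dye effects, probe
sequence biases, cell-type composition drift with age, twin/longitudinal
structure, doublets, and ambient RNA. Passing recovery tests therefore
demonstrates that the pipeline's statistics detect the structure they claim
to detect — not that real cohorts are free of these confounders.

## Validation design

Every operation with a closed form or a cheap oracle is tested against it:
brute-force interval assignment, literal-loop enrichment scoring, rank-sum
enumeration over all C(6,3) label assignments, and the n(n+1)/2 rank-sum
identity. Calibration tests check that the Pearson test and Welch t reject
at 5% ± 1.5% under seeded null simulations (2000 replicates). Recovery
tests check planted structure at the study-condition defaults: the n = 600
cohorts for expression and methylation, 50 seeded replicates of a 1.5-sd
gene-set shift on a 1000-gene background, and 25 seeded replicates of the
single-cell effect. The 1000-gene background matters: on a much smaller
transcriptome (150 genes), shifting one 25-gene set displaces every other
gene's kernel-CDF ranks enough to drag unshifted decoy sets into spurious
"down" calls — a rank-composition artifact of a toy-sized gene universe,
not of the scorer.

```{r recovery, eval = FALSE}
# the headline dissociation, at the default study conditions
cfg <- synthetic_config(seed = 1)
ex  <- simulate_expression_cohort(cfg)
asg <- assign_probes_to_repeats(
  classify_probe_context(ex$annotation$probes, ex$annotation$genes),
  ex$annotation$repeats)
cls <- aggregate_rte_scores(ex$expr, asg, "class")
sig <- score_signatures(ex$expr, ex$signatures)
wide <- ex$metadata |>
  inner_join(pivot_scores(cls), by = "sample_id") |>
  inner_join(pivot_scores(sig), by = "sample_id")
correlate_pairs(wide |> select(-sample_id))
```

## Degenerate inputs and edge rules

- Empty gene model ⇒ every probe `intergenic`; empty repeat list ⇒ zero
  assignments (neither is an error).
- Probes without coordinates get context `unknown` and are always excluded.
- A signature sharing no gene with the matrix, or covering every ranked
  gene, is an error naming the signature (the normalization degenerates).
- Constant vectors are errors for correlation and the splits; all-tied
  rank-sum comparisons return p = 1.
- Zero library totals: an error naming the sample (bulk RPM); the
  (cell type, sample) is dropped with a warning (single-cell, where sparse
  combinations are routine).
- Unannotated cells are dropped and counted; cell types lacking two samples
  per group are skipped with a warning.

## Known limitations

The probe-reuse strategy measures a class through a few dozen probes, so
subfamily resolution is out of reach and family scores lean on few probes.
No liftover, probe re-alignment, raw-intensity normalization or batch
correction is provided — inputs are assumed normalized. The rank-sum and
Welch tests treat samples as exchangeable; twin or longitudinal designs are
analysed cross-sectionally. The exact probe counts of specific array
manifests (e.g. how many RTE-covering probes a given manifest yields)
depend on the manifest and RepeatMasker release and are not reproduced
here.
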