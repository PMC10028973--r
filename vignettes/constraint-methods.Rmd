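---
title: "Base-level constraint calling and its disease correlates: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Base-level constraint calling and its disease correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(constraintkit)
```

## The problem

Comparative genomics produces per-base conservation scores: for each
position of a reference genome, a test of whether that base has evolved
more slowly than the neutral expectation across a species alignment. In
the phyloP convention these scores are signed $-\log_{10}$ p-values —
positive for conservation, negative for acceleration. A base under
purifying selection ("constrained") is a base whose score clears a
significance threshold, and the set of constrained bases turns out to be a
powerful annotation for human genetics: common variants avoid it, CNVs
that overlap it are enriched in cases, somatic recurrence inside it flags
candidate non-coding drivers, and clusters of constrained bases outside
every known annotation point at unannotated functional elements.

`constraintkit` implements that whole chain as a tested pipeline:

1. **`call_constrained_bases`** — genome-wide FDR thresholding of a score
   track;
2. **variant annotation** — constraint and coding context per variant,
   allele-frequency-spectrum summaries, depletion and enrichment tests;
3. **gene metrics** — `fracCdsCons` and part-wise analogs, binomial excess
   z, covariate-adjusted residual constraint, alignment-column entropy,
   deciles, density-based outlier genes;
4. **CNV burden** — constrained bases impacted per call and per person,
   case-control tests;
5. **NCCM scan** — somatic non-coding constraint mutations aggregated over
   gene loci;
6. **UNICORN detection** — unannotated intergenic constraint regions,
   matched backgrounds, fine-mapping PIP comparisons;

plus a **synthetic-genome simulator** that generates all inputs with known
ground truth.

## Coordinates and containers

All internal coordinates are 0-based half-open; GFF3 and VCF are converted
at the I/O boundary and BED is native. One convention everywhere removes a
whole class of off-by-one errors. Two containers carry the pipeline:

- `ScoreTrack` — per-base numeric scores per contig, `NA` marking bases
  with no score. The **universe** is the set of scored bases; it is the
  denominator of every genome-fraction statistic.
- `ConstrainedSet` — sorted, disjoint, non-adjacent intervals per contig,
  normalized at construction (overlaps and adjacencies merged), with
  $O(\log n)$ count, membership and nearest-base queries built on
  cumulative interval lengths. Distance between bases is the absolute
  position difference, so adjacent bases are at distance 1.

## Calling constrained bases

For each scored base the conservation-side p-value is $p = 10^{-s}$ when
$s > 0$ and $p = 1$ otherwise; acceleration is never called. The
Benjamini–Hochberg procedure is applied across the whole universe at level
$q$ (default 0.05), and the score threshold $t^\*$ is the smallest score
among rejected bases, so the constrained set is exactly
$\{s \ge t^\*\}$ with an inclusive boundary. A fixed-threshold mode
(`fixed_threshold = 2.27`, say) bypasses BH for reproducing published
cutoffs, and `matched_fraction_threshold` finds the threshold putting a
second score (a phastCons-like posterior, for instance) on the same
genome-fraction footing, taking the achievable fraction closest to the
target from below when ties make the target unattainable exactly.

Whether the FDR sweep should run genome-wide or per chromosome is not
settled usage; we compute it genome-wide (a single sweep over the whole
universe), which is also what makes the threshold a single number.

Clustering of constrained bases is summarized by the median
nearest-neighbor distance. The null places the same number of bases
uniformly over the universe; it is deliberately validated against a
brute-force placement oracle in the tests rather than against any external
published value, because published spacing nulls rarely document their
randomization. The empirical p-value uses the +1 correction and so never
returns 0.

## The simulator: what it emulates, and what it does not

`simulate_genome` builds the study conditions the rest of the package is
tested under:

- **Scores.** Neutral bases draw $s = \pm\log_{10} U$, $U \sim
  \mathrm{Uniform}(0,1)$ with a random sign — i.e. exactly the null the BH
  procedure assumes, which is what makes FDR control itself testable.
  Constrained bases draw $s = -\log_{10} p$ with $p \sim
  \mathrm{Beta}(0.05, 10)$, a small-p law giving strong but imperfect
  separation.
- **Constrained elements.** A target budget of `round(f_c * universe)`
  bases (default $f_c = 0.035$, matching the few-percent constrained
  fraction reported for mammalian genomes) is placed as contiguous
  elements — geometric lengths of mean 25 bp — into CDS, promoters,
  enhancers, unannotated intergenic islands and background, with the final
  background element trimmed so the realized fraction hits the budget
  exactly. Islands (the planted UNICORN truth) keep at least 1 kb from any
  gene span, promoter or enhancer.
- **Annotation.** Gene models with 3–7 exons, strand-aware UTRs and a CDS
  of length divisible by 3, spread over the first ~70% of each contig;
  ~70% of genes get a linked enhancer, one in five of which also links to
  the neighboring gene (enhancer bases count fully for every linked
  gene). Promoters default to [TSS−2000, TSS+200) oriented by strand — a
  common convention, kept configurable because published analyses differ.
- **Germline variants.** Positions uniform over the universe; allele
  counts from the neutral spectrum $P(AC = k) \propto 1/k$ on
  $1..AN$. At constrained bases a draw with $AC > 1$ is accepted with
  probability $s_{dep}^{\log_{10} AC}$ and redrawn otherwise, so
  $s_{dep} < 1$ (default 0.3) depletes constraint among common variants
  — the direction, not the magnitude, is the modeled claim.
- **CNV cohorts.** Control calls uniform; case placements accepted with
  probability proportional to $1 + e_{cnv} f$ where $f$ is the
  constrained fraction of the call ($e_{cnv} = 0$ makes arms
  exchangeable). Call lengths are log-uniform between 300 bp and 10 kb:
  SV size spectra are heavy on small events, and short calls are also
  where a fraction-proportional tilt has variance to act on — with
  uniform multi-kb lengths the planted enrichment is averaged away and
  the case/control contrast is not reliably detectable at the default
  cohort size (500 per arm, Poisson mean 5 calls per person).
- **Somatic cohorts.** Poisson background at $\mu_b = 10^{-6}$ per scored
  base per patient (40 patients); within each planted driver's locus
  (introns, UTRs and ±100 kb of the span, CDS removed) the rate at
  constrained bases is multiplied by $m_d = 50$. Ages come from a
  pediatric/adult mixture; identical mutations within one patient are
  de-duplicated, across patients they count separately.
- **Alignment columns.** With probability $\theta$ a column is
  monomorphic; otherwise residues are i.i.d. uniform over the 20 amino
  acids.

Every simulator is a pure function of (config, seed), and the ground truth
(constrained intervals, island intervals, driver ids, per-gene CDS
fractions) is serialized alongside the outputs so tests never re-derive
it.

What the simulator does **not** emulate: real chromosome lengths, linkage
disequilibrium, mutation signatures, diploid genotypes, GC-correlated
alignability, or the correlation structure of real conservation scores.
Passing tests therefore demonstrate the correctness and calibration of the
statistics under a known generative model — not that real genomes satisfy
that model.

## Variant annotation

Region class is resolved by the fixed priority CDS > UTR5 > UTR3 >
promoter > enhancer > intron > intergenic, so every variant gets exactly
one label. Coding context is computed in transcript orientation from the
standard genetic code: codon position (1–3), synonymous vs non-synonymous
for the specific alternate allele, and a can-mutate-to-stop flag (true iff
some single-nucleotide substitution at that position yields TAA/TAG/TGA).
Base-composition flags are read on the plus strand of the reference: a
C-or-G reference base, and a CpG flag meaning C followed by G or G
preceded by C. Allele-frequency bins default to six labels from
singletons to common (AF ≥ 0.005), with the common bin taking precedence
over the allele-count bins so the scheme partitions any cohort regardless
of AN; the interior bin edges are configurable since published six-bin
summaries rarely print theirs.

The depletion test is an exact binomial test of the observed constrained
fraction against the genome-wide expectation, reported with the fold
change (fold < 1 = depletion). Feature enrichment is an unregularized
logistic model of the constrained flag on binary indicators; with a single
predictor the odds ratio equals the 2×2 contingency odds ratio, and
complete separation is reported as a flagged infinite OR rather than an
error.

## Gene metrics

`fracCdsCons` is defined literally: constrained bases in the gene's CDS
union divided by CDS length, with promoter and linked-enhancer analogs.
The excess-constraint z is the binomial normal approximation
$z = (k - Lr)/\sqrt{Lr(1-r)}$ against the genome-wide CDS constrained
rate $r$; when $r$ is computed from the same gene universe the raw
excesses sum to zero. The residual score is the standardized residual of
an OLS fit of `fracCdsCons` on twelve numeric covariates (log CDS length,
gene-body GC, codon-position GC ×3, stop-reachable fraction,
synonymous-substitution fraction, log exon count, log mean exon length,
log distance to contig end, promoter GC, log UTR length). The overall GC
covariate is computed on the gene body rather than the CDS deliberately:
CDS GC is exactly the mean of the three codon-position GC terms and would
make the design singular. The covariate list is a documented
reconstruction — published gene-level constraint models describe their
covariates only as codon, consequence and positional features — and is
fully configurable.

Alignment-column conservation is $1 - \overline{H}_{norm}$ with
$H_{norm} = -\sum_a f_a \ln f_a / \ln 20$ per column, gaps excluded, no
small-sample bias correction (the plug-in bias at 200 species is ~0.016
and is accounted for in the tests rather than corrected in the
estimator).

Deciles rank non-missing scores ascending, assign
$\lfloor 10 (rank-1)/n \rfloor$, let tied scores share their midrank's
decile, and label missing scores 99. Outlier genes are DBSCAN noise
points plus members of clusters smaller than 1% of genes, on the
standardized metric matrix with missingness encoded as indicator columns;
DBSCAN is implemented in-package (classic distance-matrix formulation)
with `eps`, `minpts` and the size threshold exposed.

## CNV burden

Per call, the constrained-base count is an interval query; per sample the
three conventional measures are the number of calls, total bases and
total constrained bases (overall and per class). Overlapping calls within
one sample count bases multiply by default — burden is per-call additive
— with a `merge_overlaps` flag for the once-per-base alternative, since
published burden analyses are silent on this. The case-control test is a
two-sided rank-sum — exact for ≤30 samples without ties, tie-corrected
normal otherwise — alongside a logistic model of the label on the
standardized measure. Frequency strata mirror the conventional cutoffs:
singleton (AC = 1) and common (AF ≥ 0.005).

## NCCM scan

A somatic mutation is an NCCM iff its score is ≥ 1.2 (inclusive) and it
falls outside every CDS interval; "non-coding" deliberately leaves UTRs
and introns eligible because they are part of the published locus
definition, with a switch to exclude UTRs as well. The locus is the union
of introns, UTRs and ±100 kb flanks minus CDS, and the rate denominator
is that de-duplicated union length per 100 kb — not span + 200 kb — to
avoid double-counting intron/flank overlap. Mutations in overlapping loci
count for every gene (a nearest-TSS assignment is available). Candidate
flags are inclusive: rate ≥ 2 per 100 kb, count ≥ 5. Age stratification
operationalizes "primarily adult/pediatric" as ≥ 2/3 of distinct
NCCM-bearing patients in one group (inclusive boundary, so 2 of 3
patients suffices), with the cohort subgroup tally reported per locus.

## UNICORNs

Constrained bases outside the annotation catalog are merged across gaps
of ≤ 10 bases; any catalog bases a merge sweeps in are subtracted back
out, so regions can never overlap the catalog. Regions shorter than 20
bases or with fewer than 10 constrained bases are dropped. All four
parameters (merge gap, minimum length, minimum constrained count, and the
1 kb gene-body buffer used when building catalogs) are mandatory
configuration with these documented defaults, because published region
definitions of this kind do not print theirs. Matched backgrounds are
sampled per region — same contig first, any contig after `max_tries`
rejections (with a warning) — each interval length-equal and free of
catalog and constrained bases, so the length multiset matches exactly.
The PIP comparison is a one-sided permutation test of the mean PIP inside
regions versus the matched background (labels shuffled over the two sets,
+1 correction), with Bonferroni across traits for the per-trait
breakdown; permutation is primary, and a linear model on the set
indicator is the optional mirror of regression-based published analyses.

## Numerical choices and degenerate inputs

- BH is `p.adjust(method = "BH")`; rank-sum `wilcox.test`; exact binomial
  `binom.test`; correlations `cor(method = "spearman")` with midranks.
- An empty rejection set returns threshold `+Inf` and an empty set; a
  constant track under matched-fraction thresholding returns an empty set
  with a warning (achievable fractions are only {0, 1}).
- A perfect residual fit returns all-zero residual scores (the
  standardized residual is otherwise 0/0); rank-deficient designs drop
  collinear columns with a warning; fewer genes than covariates is an
  error.
- Constant burden in both arms gives p = 1 with a warning; empty strata
  and empty PIP sets give NA with a warning.
- Variants whose stated reference allele disagrees with the reference
  sequence are flagged and warned about, not dropped.

## Problem sizes used in the tests

The test suite and the acceptance script run entirely on simulated data:
1 Mb genomes for FDR calibration (50 replicates), driver recovery and the
acceptance pipeline; 100–500 kb genomes for module-level checks; 200 null
replicates at 30 samples per arm for burden-test calibration; 500-SNP
cohorts for PIP power. These sizes were chosen so each statistical check
has the replication its error bound needs while the whole suite stays
desk-scale.

## Known limitations

- The FDR guarantee is for the one-sided conservation test under a
  uniform neutral p-value; real phyloP nulls are discrete and
  correlated along the genome, so realized FDR on real tracks can differ.
- Gene metrics assume one transcript per gene; isoform-aware CDS handling
  is out of scope.
- The consequence annotation covers SNVs only (no splice, frameshift or
  indel logic) — it is a constraint-analysis companion, not a VEP
  replacement.
- Heritability partitioning, fine-mapping itself, and ortholog inference
  are consumed as inputs where relevant, never computed.
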