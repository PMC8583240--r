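---
title: "Methods: novel lncRNA discovery and characterization with lncforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: novel lncRNA discovery and characterization with lncforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures behind `lncforge`, the
reasoning for the design choices that were genuinely open, and what the
package's planted-truth tests do and do not demonstrate about real data.

## Coordinates and transcript models

All intervals are held internally as 0-based half-open pairs; GTF I/O
converts to and from the 1-based closed GTF convention on the boundary.
This makes interval arithmetic (lengths, adjacency, containment) free of
`±1` bookkeeping while keeping the standard dialect on disk. Exons within a
transcript must be sorted and strictly disjoint; overlapping exons are
rejected rather than merged, because assemblers emit disjoint exons and an
overlap indicates corrupt input that silent merging would hide.

The *intron chain* of a transcript is the ordered list of gaps between its
consecutive exons. Intron-chain identity — same chromosome, same strand,
identical intron coordinates, terminal exon ends free — is the structural
notion of "same transcript" used throughout: for the `=` class code, for
cross-platform validation, and for database re-annotation. For two
single-exon transcripts the condition is vacuous, so the package defines
their match as same-strand overlap of the single exons; this is documented
rather than hidden because single-exon candidates are removed by the
novelty filter anyway.

## Class codes

gffcompare-style class codes describe a candidate's structural relation to
the reference annotation. The code letters are standard usage, but their
exact semantics vary between tools, so the package fixes them
deterministically, with precedence `'=' > 'y' > 'x' > 'i' > 'o*' > 'u'`:

* `=` — some reference transcript has an identical intron chain (same
  strand);
* `y` — a whole reference transcript span lies inside one intron of the
  candidate;
* `x` — the candidate shares at least one exonic base with a reference
  exon on the opposite strand and none on the same strand;
* `i` — the candidate lies entirely within one intron of a reference
  transcript, with no reference-exon overlap;
* `u` — no overlap with any reference exon, intron or span on either
  strand;
* `o*` — every remaining overlap pattern (the full gffcompare alphabet
  `c, k, m, n, j, e, o, s, p, r` is deliberately collapsed into this
  catch-all; those distinctions play no role in lncRNA discovery).

Two semantics were open and are exposed as configuration:

* `i` ignores strand by default (`same_strand_intronic = FALSE`): intronic
  lncRNAs are not conventionally strand-restricted relative to their host.
* `x` requires *exclusive* antisense exonic overlap by default
  (`antisense_exclusive = TRUE`): a candidate that overlaps exons on both
  strands is structurally ambiguous and lands in `o*`.

Candidates with strand `.` skip the strand-dependent codes (`=`, `x`) and
carry a warning flag in their evidence string. Ties for the best reference
match break by largest shared exonic base count, then lexicographically, so
classification is deterministic and independent of input order. The test
suite checks the whole classifier against an independently written
quadratic-time oracle on randomized catalogs.

## The novelty filter

A candidate becomes a putative novel lncRNA only if it passes all of:

1. **Prevalence** — count > 0 in at least `ceiling(0.5 × n_samples)`
   samples. The bound is inclusive ("at least half"), so 5 of 10 samples
   suffices.
2. **Length** — spliced length (sum of exon lengths) > 200 nt. Genomic
   span would count introns and is not what an RNA's length means;
   spliced length is the deliberate reading of the 200-nt lncRNA
   convention.
3. **Multi-exonic** — at least two exons. Single-exon models are the main
   false-positive mode of assembly from short reads.
4. **Class code** in `{u, i, x, y}`.
5. **Noncoding** — coding probability below the cutoff (below).
6. **Chromosome** — one of chr1–chr22 or chrX (both `chrN` and bare `N`
   spellings accepted).

Criteria are evaluated per candidate with per-criterion booleans recorded,
so the filter is auditable and trivially order-independent. A candidate
without a sequence fails the coding criterion with a logged reason instead
of crashing the run.

Cross-platform validation intersects survivors from two platforms by
intron-chain identity and keeps the platform-A model as the
representative. Database re-annotation marks a validated transcript as
previously annotated when a database transcript matches by intron chain
*or* by same-strand exonic overlap of at least 50% of the shorter
transcript (`db_match_mode = "chain_or_overlap"`). The overlap arm exists
because public lncRNA catalogs frequently store the same locus with
different exon boundaries; requiring exact chains would overcount novelty.
`chain_only` mode is available for strict matching.

## Coding potential

The scorer follows the CPAT design: four sequence features combined by
logistic regression.

* **ORF length** — the longest ATG-initiated ORF over the three forward
  frames, ending at the first in-frame stop (included) or the last
  complete codon. Ties break toward the smallest start offset.
* **ORF coverage** — ORF length over transcript length.
* **Fickett TESTCODE** — for each base, a codon-position asymmetry
  parameter `max(count₁,count₂,count₃) / (min + 1)` and a content
  fraction, both mapped through the published probability lookup tables
  and combined with the published weights. `N` bases are excluded from
  content fractions.
* **Hexamer log-odds** — mean `log(f_coding(h)/f_noncoding(h))` over the
  in-frame hexamers of the longest ORF (whole sequence, frame 0, when no
  ORF exists). Coding frequencies are trained on in-frame hexamers of ORFs,
  noncoding frequencies on any-frame hexamers; a shared pseudocount
  (default 1) keeps log-odds finite, and a hexamer absent from both
  corpora scores exactly 0. Hexamers containing `N` are skipped.

A terminal poly(A) run is removed before feature computation, so scores are
invariant to polyadenylation artifacts of any length.

The logistic combiner is fitted by maximum likelihood (IRLS via
`stats::glm`); perfect separation — common on clean synthetic corpora —
falls back to a ridge-stabilized fit (`glmnet`, `alpha = 0`,
`lambda = 1e-3`) with a warning. The decision cutoff defaults to 0.364,
the published human default of this model family; it is configuration,
not a fitted quantity. Model weights are never shipped as opaque
constants: the pipeline trains on the package's labeled synthetic corpora
at run time (deriving the corpus seed from the run seed), and any user
FASTA corpora can be substituted. Scoring uses the spliced transcript
sequence, not the genomic span — the molecule being translated is the
spliced RNA.

## Conservation

Per-base conservation scores (phastCons-like, each base in `[0, 1]`) enter
as a bedGraph track. For each exon the package reports the mean score over
the bases the track covers; uncovered bases are excluded from numerator
and denominator (matching mean-over-overlaps semantics of interval
intersection tools), and a fully uncovered exon is `NA`. The alternative
reading — uncovered means unconserved — is available as
`uncovered_as_zero = TRUE`. Summaries pool *exons*, not transcripts,
because conservation profiles of lncRNAs are heterogeneous across exons;
per-class output gives count, mean, median and deciles, suitable for
density plots. No statistical test is attached: the profile contrast is
descriptive.

## Differential expression

The shipped engine is a paired t-test on per-subject `log2(TPM + 1)`
differences (post − pre), two-sided, with BH adjustment
(`stats::p.adjust`). TPM is computed as
`(count/length) / Σ(count/length) × 10⁶` per sample. Fold change is
reported in the signed convention: with
`r = (mean post + 0.01)/(mean pre + 0.01)`, `FC = r` when `r ≥ 1` and
`−1/r` otherwise, so a 30% drop prints as ≈ −1.4 rather than 0.71. The
pseudocounts (0.01 in the ratio, 1 in the log transform) guard division
and the log at zero TPM and are configurable.

Features whose paired differences have zero variance are flagged: all-zero
differences give p = 1 (no evidence), constant nonzero differences give
p = NA and are excluded from the BH denominator (a t-test is undefined
there, and keeping them would distort the FDR).

The high-confidence selection rule is strict: padj < 0.001 **and**
|FC| > 1.2 **and**, for annotated features only, detection at ≥ 0.5 TPM in
at least 90% of both the pre and post groups. Novel transcripts are exempt
from the detection criterion by default (`exempt_novel = TRUE`) — they are
expected to sit near the detection floor, and the criterion is phrased for
annotated genes — with an override for users who want it applied
uniformly. Thresholds are strict inequalities, so padj = 0.001 or
|FC| = 1.2 exactly are excluded.

The engine sits behind a plain data-frame interface (`de_select` needs
only `padj`, `fold_change` and the detection fractions), so per-feature
results fitted elsewhere — e.g. a DESeq2 negative-binomial fit — can be
substituted without touching the selection rule. Dispersion modeling,
size-factor normalization and outlier replacement are deliberately out of
scope.

## Co-expression network

The network is unsigned: `a_ij = |pearson(x_i, x_j)|^β` with unit
diagonal. The soft threshold β is either fixed (default 6) or chosen as
the smallest candidate power whose connectivity distribution is
approximately scale-free: R² ≥ 0.8 with negative slope for the linear fit
of `log10 p(k)` on `log10 k` over 10 equal-width connectivity bins, **and**
mean connectivity ≥ 1. The mean-connectivity floor matters: an
uncorrelated expression matrix raised to a high power produces a
near-empty network whose heavy-tailed trace of residual correlations fits
a power law spuriously; requiring non-degenerate connectivity makes pure
noise fall through to the conventional fallback power 6 instead.

Topological overlap is the standard form
`TOM_ij = (Σ_{u≠i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)` with
unit diagonal, checked in the tests against a direct triple-loop oracle.
Modules come from average-linkage hierarchical clustering of `1 − TOM`
with a *static* cut at height 0.99 and a minimum module size of 30 genes
(the pipeline's small-fixture default is 10). The dynamic tree-cut
heuristic used by WGCNA adapts better to real expression data but is
considerably more complex and not needed to recover planted structure; the
static cut is a documented divergence, and both the height and the minimum
size are configuration.

Terminology is kept strict where the field sometimes conflates it: the
*module eigengene* is the first principal component of the per-gene
standardized member matrix (unit variance, oriented to correlate
positively with mean member expression, so sign is reproducible); *kME*
(module membership) is the Pearson correlation between a gene's profile
and a module eigengene. Hubs are genes with kME in their own module
strictly above 0.7, optionally restricted to differential-expression
survivors — the default mirrors building the network on all expressed
genes first and filtering modules to DE genes for reporting. A signed
adjacency variant (`(1 + cor)/2)^β`) exists as configuration but is an
untested surface.

## cis-eQTL overlap

eSNP positions from a minimal association TSV
(`snp_id, chrom, pos, egene_id, pvalue`) are filtered at association
p < 1 × 10⁻⁸ on load (the threshold is configurable; 10⁻⁷ is a defensible
alternative reading for locus-level reporting, and both appear in
published GTEx-based analyses). Exon containment ignores strand — a SNP
has no strand — and counts boundary bases. lncRNA–eGene correlation is a
plain Pearson correlation across samples with a t-distribution p-value,
plus a flag for whether the pair shares a co-expression module. The
package intentionally does not parse GTEx's native formats: exporting to
the minimal TSV is one join, and it keeps external downloads out of the
test loop.

## The synthetic-fixture module

Every pipeline input can be generated with planted ground truth:

* **Reference annotations** — disjoint multi-exon genes with generous
  introns (1.5–6 kb) and intergenic gaps (4–12 kb), both strands, mRNA and
  lncRNA biotypes.
* **Candidates** — constructed geometrically so their true class code is
  known: `=` copies a reference intron chain with jittered terminal ends;
  `u` occupies intergenic gaps (≥ 500 nt margins); `i` sits at a
  randomized offset inside a reference intron; `x` straddles a reference
  exon from the opposite strand; `y` places one exon on each side of a
  small reference gene. Placements are randomized within their
  constraints so independently generated candidates do not collide on
  intron chains.
* **Sequences** — coding sequences embed a long codon-biased ORF;
  noncoding sequences are exact dinucleotide-preserving (Altschul–Erikson)
  shuffles of coding ones, so mono- and dinucleotide composition — and
  hence GC content — match the coding corpus exactly while codon structure
  is destroyed.
* **Conservation tracks** — per-base Beta draws per class (defaults:
  Beta(8, 2) for coding exons, Beta(2, 8) for noncoding), run-length
  encoded to bedGraph.
* **Expression** — log-normal baselines (log2 mean 4, sd 1.5); planted DE
  features multiply the post-condition mean by their effect; module genes
  follow `loading · latent + √(1 − loading²) · noise` with the latent
  factor optionally correlated to the pre/post trait; Poisson counts at
  2 × 10⁶ expected depth. The generator also returns the
  pre-normalization log-expression matrix, which is the natural input for
  network analysis: per-sample TPM renormalization induces compositional
  correlation between unrelated genes, which is a real phenomenon but not
  part of the planted truth.
* **SNP tables** — significant eSNPs planted inside target exons,
  significant decoys outside every exon, and optional above-threshold rows
  that loaders must drop.

Each generator draws from its own RNG stream derived from the master seed
and a stable label, so adding one generator to a fixture never perturbs
the others, and every generator is bit-reproducible given its seed.
Counts are Poisson rather than negative-binomial by default — the shipped
DE engine is TPM-based, so overdispersion realism is opt-in rather than
baked in.

**What passing these tests shows, and what it does not.** The fixtures
verify the machinery: exact interval arithmetic, correct precedence and
bookkeeping, calibrated nulls, recovery of structure that is genuinely
present. They do not emulate misassembly, fragmented transcripts,
intron-retention artifacts, batch effects, overdispersed counts or
correlated noise, so planted-truth recovery rates here are upper bounds on
real-data performance, not estimates of it.

## Problem sizes and numerical choices

The tests and the acceptance script run at desk scale, chosen to finish in
minutes while leaving comfortable statistical margins: reference catalogs
of 20–140 genes on 2–4 Mb chromosomes; the 38-candidate class-code
partition (19/13/5/1) with 150- and 60-candidate platform sets; corpora of
300–500 sequences of 0.4–1.2 kb; expression matrices of 500 features × 40
subject pairs (the null calibration uses 60–200 replicates); module
fixtures of 30–60 genes with 20–81 pairs; conservation tracks over ~1,000
exons; SNP fixtures of 25–100 rows. Tolerances: BH against its oracle at
10⁻¹², TOM against its oracle at 10⁻¹², TPM column sums at 10⁻⁶ relative,
exact equality for planted counts. Logistic fits run IRLS to
convergence (`maxit = 100`); eigengenes come from exact SVD; all
hierarchical clustering is exact average linkage.

## Known limitations

* Class-code semantics are this package's fixed definitions of the
  standard letters; other tools' assignments can differ at boundary cases
  (e.g. non-exclusive antisense overlap).
* The Fickett lookup tables are transcribed from the published statistic;
  scores are validated by property (determinism, hand-computed lookups,
  coding/noncoding discrimination on planted corpora), not against an
  external tool's output.
* The paired t-test on log TPM is a deliberate simplification of count
  modeling; for low-count features a negative-binomial engine fed through
  the pluggable interface is the better choice.
* The static tree cut can split a module that dynamic cutting would keep
  whole on real data.
* GTF round-tripping preserves attribute text per transcript (taken from
  its first exon record), not per exon.
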