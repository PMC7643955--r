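---
title: "Methods: DMR calling, differential expression and methylome-transcriptome integration in methexpr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DMR calling, differential expression and methylome-transcriptome integration in methexpr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`methexpr` re-implements, as a tested and reusable pipeline, an integrative
single-cell analysis of DNA methylation and gene expression across human
oocyte maturation stages (germinal vesicle GV, metaphase I, metaphase II).
The scientific setting: CpG methylation is roughly constant across
maturation while genome-wide non-CpG (CHG/CHH) methylation roughly doubles
in the mature MII stage, and the question is whether that non-CpG gain is
regulatory — sitting in differentially methylated regions (DMRs) that
overlap transposable elements and transcription-factor binding motifs and
tracking expression changes of nearby genes.

Because the underlying study deposits no raw-data accession, every stage of
the pipeline is exercised on synthetic data with planted ground truth. The
generator is first-class, tested code: the recovery, error-rate and
integration guarantees quoted below are all computed by the test suite and
the acceptance script, on the synthetic conditions described here, and by
nothing else.

# The DMR caller

Per-cell bisulfite calls (chromosome, 0-based position, strand, context,
methylated count, total count) are handled per context — CpG, CHG, CHH —
throughout, and both strands are enumerated and counted independently,
including CpG sites. Collapsing CpG strand pairs would borrow strength at
symmetric sites but would treat contexts asymmetrically and complicate the
sparse single-cell bookkeeping; uniformity won.

Single-cell coverage is far too sparse for per-site or per-cell tests, so
cells of a stage are pooled by summing counts per site (the expression side
of the study merges samples per stage for the same reason). The genome is
tiled with 3 kb windows advancing in 600 bp steps; when the last regular
window ends before the chromosome does, one terminal window `[L - 3000, L)`
is appended (a chromosome shorter than the window gets the single truncated
window `[0, L)`), so every base is covered.

Each window with pooled coverage of at least `min_cov = 10` in *both*
groups enters the testing universe; the 2x2 table of pooled
(methylated, unmethylated) counts is tested with a two-sided Fisher exact
test using the **doubling rule** — `p = min(1, 2 min(lower tail, upper
tail))` of the conditional hypergeometric — rather than the
minimum-likelihood rule of `stats::fisher.test`, because the doubled tail
is symmetric, cheap to vectorise, and exactly reproducible from `phyper`;
the test suite checks it against full enumeration of the hypergeometric
support. Benjamini-Hochberg adjustment runs across testable windows only.
Windows with `q <= 0.05` and an absolute methylation difference
`|delta| >= 0.1` are kept; overlapping significant windows of the same
direction merge into a DMR (per context). The source study defers its exact
window test, coverage filter and cutoffs to an earlier publication, so
these four values are declared, configurable defaults of this package —
substitutes, not reconstructions.

Two conventions matter downstream. Coordinates are 0-based half-open
everywhere internally (GTF is converted at the I/O boundary), and abutting
half-open intervals do **not** merge — `[0, 10)` and `[10, 20)` share no
base. A DMR's direction is labelled relative to the later maturation stage
(hyper = more methylated in MII for the MII/MI contrast); its q-value is
the minimum q among constituent windows and its levels are recomputed from
pooled counts over the merged interval, so a reported DMR's `delta` is
usually smaller than the peak window's (boundary windows dilute it).

Bisulfite conversion efficiency is estimated from unmethylated lambda
spike-ins as `1 - sum(meth) / sum(total)`; libraries at or below 98% are
flagged by `conversion_qc()`.

# Genomic classification

Promoters span −2000/+500 bp around the TSS, strand-aware; in half-open
coordinates a minus-strand TSS *t* gives `[t - 499, t + 2001)`. A region is
**distal** when it overlaps no promoter, exon or UTR of any gene — taken
literally, so introns qualify as distal. This surprises intuition, which is
why `classify_feature()` is exposed separately with the priority rule
promoter > 5'UTR > 3'UTR > exon > intron > distal (any-overlap per tier)
for feature breakdowns. Gene body means the full transcript span; no
promoter subtraction is applied. Regulatory-domain assignment of distal
regions to genes is the transparent desk-scale rule — nearest TSS to the
region midpoint within 100 kb, ties to the lexicographically lower gene id
— replacing the database-backed basal-plus-extension service used in the
original analysis. Where a DMR overlaps several genes, per-gene sets and
gene-DMR pairs are both reported rather than guessing which the original
"60%" statistic counted.

# Expression and differential expression

TPM and FPKM are computed from counts and union-of-exon lengths
(`TPM = 1e6 * rate / sum(rate)`; `FPKM = 1e9 * count / (length * N)`), with
merged-stage FPKM summing counts across a stage's cells first — identical,
by construction, to FPKM of the summed library. Expressed means merged
FPKM >= 1 (the boundary value is included); a stage-specific gene passes
the threshold in exactly one stage.

The DE test is a self-contained negative-binomial Wald test, not a wrapper:
library-size factors normalised to geometric mean 1, a single
method-of-moments dispersion shared across genes (the smallest model that
exercises the test), group means with a pseudo-mean of 0.5 added before the
log-ratio so log2FC is always finite, delta-method standard errors under
`Var = mu + alpha mu^2`, and a t reference with `n_A + n_B - 2` degrees of
freedom — a plain normal reference is visibly anti-conservative at
single-cell group sizes with a plug-in dispersion. A DEG has adjusted
p <= 0.05 and fold change >= 2 (`|log2FC| >= 1`). The pseudo-mean biases
log2FC towards zero for near-silent genes (about −0.4 log2 units at a group
mean of 1), which is why parameter-recovery tests condition on adequate
expression. DESeq2 serves as an independent cross-check in one test, never
as the implementation. The per-cell PCA ranks genes by mean expression,
keeps the top 1000, and runs centred, unscaled PCA on log2(x + 1).

# Integration

Motif scanning is a log-odds PWM scan in bits against a uniform background,
both strands, N scoring −Inf; the default hit threshold is 0.8 x the PWM's
maximum attainable score — deterministic and PWM-relative, since the
original study does not state the threshold its motif tool used. A
transcription factor is *triangulated* when it is expressed (FPKM >= 1 in
MI or MII), appears in the user-supplied list of DNMT3B binding partners,
and has at least one motif hit inside a DMR; the three flags are
conjunctive, and a TF without a PWM is excluded (flag NA) rather than
silently failed. Whether the original 62/151 target tallies used ChIP
clusters or motif hits is not fully specified; only the motif mode is
implemented here (ChIP peak sets are external data out of desk scale), and
the tally counts target genes whose gene-body DMR contains a hit, split by
DMR direction. Set enrichment is the one-sided hypergeometric
over-representation test with BH across sets, replacing database-backed
enrichment services with user-supplied gene sets.

# The synthetic generator

The generator's defaults are the study conditions, chosen once:

| parameter | default | why |
|---|---|---|
| genome | 2 x 200 kb | smallest genome giving ~650 testable windows per context per chromosome |
| genes | 80, spans 1-2.5 kb, 1-3 exons | enough genes for BH to be meaningful at desk scale |
| cells per stage | 5 | the study's WGBS arm had ~10 cells/stage, mRNA ~7; 5 keeps the suite fast while staying in the single-cell regime |
| CpG mean | 0.50 | stage-invariant, mid-range oocyte CpG methylation |
| non-CpG mean | 0.025 -> 0.05 | the mature level doubles the immature one, the study's central global trend |
| coverage | Poisson(1)/cytosine/cell | sparse single-cell regime; recovery guarantees are stated at coverage 2 |
| planted DMRs | 15 x 3 kb, effect +0.3, hyper in MII, 90% inside repeats | width equals the caller's window so one window fully contains each and sensitivity is interpretable; pairwise separation > window + 2 steps so each is recovered as its own merged region |
| repeat track | 45% of genome (40% LINE1 family) | human-like repeat load |
| planted DEGs | 30, log2FC in [1, 3], MII only | GV and MI share means *by construction*, mirroring the absence of DEGs between the immature stages |
| DMR-DEG links | 60% of genes whose body overlaps a planted DMR get a positive log2FC | emulates the positive gene-body methylation/expression association |
| NB dispersion | 0.1, shared | smallest model that exercises the DE test |
| conversion failure | 0.005 | all simulated libraries pass the > 98% QC gate |
| cell-to-cell methylation jitter | 0 (logit-scale sd, exposed as `cell_meth_sd`) | the study reports no per-stage cell variance, so it is a free parameter, not an asserted value |

Contexts are assigned from the simulated sequence with Bismark semantics
(CpG: C followed by G; CHG: C-H-G; CHH otherwise; both strands
independently). Per cytosine and cell, coverage is Poisson and the
methylated count Binomial in the site mean; a planted DMR raises the MII
mean of its own context only, clamped at 1 with a warning. Each planted DMR
carries exactly one context label, and every DMR-DEG link's region overlaps
its gene's body — both are asserted by tests. A consensus motif can be
embedded into a fraction of planted DMRs (before context assignment, so
the sequence stays self-consistent) for end-to-end TF-triangulation
fixtures.

What the generator does **not** emulate, so passing tests do not speak to
it: real gene density (the synthetic genome is ~300x denser in genes than
human, so genic-feature fractions of DMRs — distal%, promoter% — are not
comparable to real annotations, and the distal-DMR branch of the analysis
can be empty on defaults); stage-specific expressed-gene counts;
sequence-composition biases (the genome is i.i.d. uniform ACGT);
imprinting or allelic structure; read-level artefacts (no FASTQ, no
alignment). External-data fractions from the original study (distal DMRs in
DNase sites, DMRs at transposable elements at genome scale) require its
supplementary DMR lists plus public tracks and are out of desk scale; the
overlap machinery itself is validated per-base on synthetic tracks.

# Validation and problem sizes

The test suite (about one minute on one CPU) checks, among other things:
exact window p-values against full hypergeometric enumeration; interval
merging and overlap fractions against per-base oracles; the PWM scanner
against exhaustive per-offset scoring; enrichment p-values against direct
tail summation; TPM column conservation and merged-FPKM associativity;
BH's FDR control on uniform p-values (1000 replicates of 100 tests);
caller invariance to cell and chromosome order; and determinism of every
generator output under a fixed seed. On the default study conditions it
verifies >= 90% recovery of planted non-CpG DMRs at coverage 2 with
nominal false discovery on the GV-vs-MI null, >= 90% DE power at planted
|log2FC| = 3 with 8 cells per group with controlled type-I error on null
simulations, an (essentially) empty GV-vs-MI DEG contrast, and end-to-end
recovery of a planted TF whose motif was embedded in 80% of the planted
DMRs. `scripts/acceptance.R` recomputes these quantities from scratch at a
caller-supplied seed.

Numbered drivers under `analysis/` (simulate, call-dmrs, expression,
classify, integrate, plus `00_run_all.R` with a checksummed manifest) run
the same functions as a narrative workflow; identical seed and
configuration reproduce identical output checksums.

# Known limitations

The window test treats pooled counts as independent Bernoulli draws; within
a cell, neighbouring sites share molecules, so p-values at very high
per-cell coverage are optimistic — at single-cell coverage the effect is
negligible. The common-dispersion DE model ignores gene-wise dispersion
variation, and the pseudo-mean biases fold changes of near-silent genes
towards zero. No smoothing/HMM DMR model, no per-site differential calls,
no imputation of uncovered sites, and no isoform-level quantification are
provided — all deliberately out of scope.
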