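---
title: "Methods: small RNA analysis with mirnaflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA analysis with mirnaflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirnaflow)
```

# Scope and model

mirnaflow implements a desk-scale small RNA sequencing analysis for microRNA
(miRNA) expression across tissue libraries: read cleaning with exact
per-category accounting, exact-match genome mapping, rule-based known-miRNA
quantification, hairpin-based novel miRNA prediction, differential expression
by an exact conditional Poisson test, seed/energy target prediction,
hypergeometric term enrichment, and a combined miRNA-gene regulatory network
with degree-based hub calling. A synthetic-data generator produces every
input with known ground truth, so each stage is testable end to end.

The intended user is a computational biologist who wants the classical
single-replicate small RNA workflow (one pooled library per tissue) as
auditable, reproducible code rather than a chain of external tools.

# Read cleaning and accounting

Reads are assigned to exactly one category by the first failing test, in a
fixed cascade order matching the standard published accounting layout:

1. *3' adapter null* — no adapter found. The matcher accepts the leftmost
   occurrence of an adapter prefix of at least 6 nt with at most one
   mismatch; the published analyses name this filter without specifying a
   matcher, so the matcher here is a documented package choice.
2. *Insert null* — the trimmed insert is empty.
3. *5' adapter contaminant* — the insert contains the 5' adapter (same
   matching rule).
4. *Smaller than 18 nt* — insert shorter than `min_len` (default 18).
5. *polyA* — at least 70% adenine after trimming. "polyA" is not defined
   operationally in the published protocols; 70% is the package's fixed
   definition.

Because each read lands in exactly one category, the identity
`clean = high_quality - sum(removed)` holds exactly, and
`validate_accounting()` flags any published column whose printed numbers do
not close (one widely circulated sheep intestinal accounting table repeats a
removal tally in its cecum column; the validator flags it rather than
accepting it). Percentages are reported at two decimals with R's
round-half-even, matching the published formatting.

The raw-to-high-quality step (image-level base calling) is accepted as
given: the FASTQ input is treated as the high-quality read set, because that
step is not reproducible from sequence data.

# Genome mapping

`map_reads()` maps by exact substring search on both strands. The published
pipeline used a mismatch-tolerant external aligner, but downstream miRNA
quantification requires perfect precursor matches anyway, so exact matching
is used throughout; multi-mappers are recorded at all loci and counted once
in the mapped-read total.

# Known miRNA quantification

A read counts toward a mature miRNA iff (a) it occurs in the precursor with
zero mismatches and (b) its precursor interval overlaps the mature interval
by at least 16 identical bases. Offsets ("dislocation") are allowed — the
16-base identical overlap is the only constraint. miRNAs with fewer than 10
reads in a library are zeroed in that library; the floor is applied per
library. A read satisfying the rule for k matures contributes 1/k to each by
default (conserving totals); a count-to-each mode is available.

# Folding and novel miRNA prediction

`fold_rna()` minimises a deliberately simple, fully documented energy model:
each admissible pair contributes a fixed energy (GC -3.0, AU -2.0, GU -1.0
kcal/mol) and each hairpin (terminal) loop adds +0.5 kcal/mol as an entropic
penalty; hairpin loops span at least 3 nt and pseudoknots are excluded. The
model is additive, so an exact Nussinov-style dynamic programme finds the
optimum; the test suite checks it against exhaustive structure enumeration
on short sequences. An external thermodynamic folding engine could be
substituted, but all shipped results use the built-in model so they are
bit-reproducible. The MFE acceptance threshold is -18 kcal/mol: the
published criterion prints the bound without a sign, and a positive bound is
vacuous for folding energies, so the negative reading is implemented
(configurable).

Novel prediction clusters unassigned mapped reads (gap at most 10 nt),
excises each cluster with 20 nt flanks (precursors capped at 300 nt,
candidate matures 18-26 nt — these mirror typical hairpin-prediction tool
defaults, which are not printed anywhere, and are documented package
defaults), folds the excised region, and accepts a candidate when the MFE
meets the threshold and the candidate mature (most abundant read) has at
least 16 bases paired in a single stem orientation — all its paired bases
'(' or all ')' — so it cannot straddle a terminal loop. Because a hairpin's
reverse complement is also a hairpin, mirror candidates from antisense
mappings at the same locus are collapsed, keeping the best-supported one.
Accepted candidates whose mature matches a supplied cross-species reference
(16 identical bases, no mismatch) are labelled `conserved`, the rest
`novel`.

Cross-study comparison of novel matures (`compare_novel_sets()`) reports a
pair when some ungapped alignment window covers at least 18 bases with at
most one mismatch. The published protocol additionally quotes a BLAST
e-value cutoff; an e-value has no meaning without a database-size context at
this scale, so the coverage/mismatch rule is the operative filter here.

# Differential expression

Counts are normalised as TPM with the library's total clean reads as the
denominator, exactly as the standard formula states (not the mapped-miRNA
total; switchable). Fold-change is `log2((tpm_a + c)/(tpm_b + c))` with a
pseudocount `c = 0.01` TPM to handle zeros (the published formula is silent
on zeros).

The test is the Audic-Claverie exact conditional Poisson test. Given count
`x` in a library of `N1` reads, the probability of count `y` in a library of
`N2` reads is

$$p(y\mid x) = \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}}$$

computed in log space via `lgamma` (direct factorials overflow). The printed
final factor sometimes appears without its minus sign; only the negative
exponent normalises (`sum_y p(y|x) = 1`), which the tests verify, so the
negative exponent is implemented. Both tails include the observed count
(`C = P(Y <= y)`, `D = P(Y >= y)`); the two-sided p doubles the smaller tail
and caps at 1. One-sided modes are available: the published analysis does
not state its tail convention, and the choice is logged in each run's
parameter log. With the inclusive-tails convention the two-sided p is not
exactly exchange-symmetric in (x, N1) vs (y, N2); the discrepancy is bounded
by twice the observed point mass and is negligible at the count scales the
test is applied to, and the exact tail duality
`P(Y <= y | x; N1, N2) = P(X >= x+1 | y; N2, N1)` is tested at 1e-12.

Bonferroni correction multiplies by the number of miRNAs tested in the given
pairwise comparison (rows with any count in the pair, after the 10-read
floor), matching per-comparison correction; significance requires a fold
change of at least 2 and corrected p below 0.01. Every report partitions its
significant calls into up- and down-regulated sets that sum exactly to the
total, and the up/down partition is carried in `summary()`.

# Target prediction

Two routes are intersected. The seed route reports canonical site types:
7mer-m8 (transcript pairs miRNA positions 2-8), 7mer-A1 (positions 2-7 plus
an adenine opposite position 1) and 8mer (both). A trained context-score
percentile cannot be reproduced without the published training data, so the
site-type classification stands in for it — this substitution is the largest
deliberate departure from the published tool chain. A permissive mode
(any 7 contiguous complementary bases in positions 1-8) is available.

The energy route scores duplexes with the same pair constants as the folding
model over ungapped alignments with at most one single-base bulge; only
stacked runs of at least two consecutive pairs contribute (an isolated pair
does not stack), plus one +0.5 kcal/mol initiation penalty. G:U wobbles are
disallowed in the seed match but allowed, at their reduced constant, in the
duplex body. Sites at or below -20 kcal/mol pass. Duplex windows are
anchored at seed sites: because the final candidate set is the intersection
of the two routes, any candidate must carry a seed site, so anchoring does
not change the intersection while keeping the scan linear. Whole transcripts
are scanned (the published prediction ran against full RNA sequences, not
annotated 3' UTRs).

# Enrichment

`hypergeom_upper()` evaluates the exact upper tail in log space, and
`enrich()` tests every term with at least 2 background genes and at least
one candidate, adjusting within each namespace by Benjamini-Hochberg
(the published analysis used an external web tool whose internal
multiple-testing procedure is unstated; Bonferroni is switchable).
Significance is FDR < 0.1. The background defaults to the supplied expressed
gene list (FPKM > 1) when given — the published methods state both "all
genes" and "FPKM > 1", and the expressed-background reading is the default,
with both supported. Singleton terms produce degenerate tests and are
skipped.

# Regulatory network

Interaction edges require a combined score of at least 0.4 and both
endpoints among the candidate target genes; only genes with at least one
surviving interaction edge are kept, together with the miRNAs predicted to
regulate them, and both edge types merge into one graph. Hub genes are the
`ceiling(0.05 * gene nodes)` genes of highest degree — with 92 gene nodes
that is 5 — counting both edge types (an interaction-only degree mode is
available); ties break lexicographically for determinism, as neither the
ceiling nor the tie rule is printed anywhere. Hub miRNAs are exactly the
regulators of hub genes. Export writes an edge list, a node-attribute table
and GraphML; the TSV pair round-trips the graph exactly.

# The synthetic-data generator

The generator emulates the statistical structure of a three-tissue pooled
small RNA study:

- *Reads*: mature sequences (20-24 nt, mode 22) with the 3' adapter
  appended, at Poisson counts with mean `mean_count` per expressed miRNA; a
  fraction `de_fraction` of miRNAs is planted at `de_fold`-fold higher
  expression in one designated library. Counts are Poisson rather than
  negative binomial because the differential test assumes Poisson sampling;
  an overdispersion knob exists and defaults off.
- *Contamination*: the five accounting categories at configurable rates
  (defaults mirror the published per-category proportions, except polyA,
  which is raised from ~5e-6 to 1e-4 so the category is populated at
  desk-scale depth). Categories are mutually exclusive — one defect per
  read — so the generator ledger and the filter tallies must agree
  read-for-read, and every emitted read is verified to classify into its
  intended category (junction windows between insert and adapter could
  otherwise fake an earlier adapter hit).
- *Genome*: known precursors are planted verbatim as mature + loop + reverse
  complement, novel loci as perfect inverted repeats (22 bp stem, 6-8 nt
  loop) with reads emitted from both arms so a read cluster spans the
  hairpin within the default cluster gap. All planted sequences are drawn
  adapter-safe by rejection sampling.
- *Annotation tables*: planted enriched terms cover 80% of the designated
  candidate genes against a sparse background; interaction tables plant hub
  genes of top degree among the candidates; FPKM backgrounds mark all genes
  expressed.

What the generator does **not** emulate: sequencing errors, realistic
quality strings, isomiR heterogeneity, multi-locus miRNA families,
cross-mapping between paralogues, or real genome composition. Passing tests
therefore demonstrate the correctness of the rules and statistics on clean
inputs, not robustness to noisy real libraries.

Sequencing depth per published library is not available beyond totals;
defaults (3 libraries, 20 miRNAs, 20,000 reads/library, mean count 200) are
chosen for desk-scale runtime and statistical power, not fidelity to the
original depth. The test and acceptance runs use 5,000-8,000 reads per
library and 12-50 miRNAs; parameter-recovery checks run 20 independent
seeds at mean count 200 and fold 4.

# Numerical and reproducibility choices

All probability computations run in log space. Upper tails are summed
directly from the observed count with an adaptive cutoff rather than as
`1 - lower` (avoiding cancellation). Every stochastic step derives its seed
from the configuration seed via `withr::with_seed`, so a pipeline run is a
pure function of (inputs, configuration, seed) — reruns are byte-identical,
which the tests assert. The run log records every parameter and the MD5 of
the serialized configuration.

# Known limitations

- Single library per condition: no replicate-aware inference (negative
  binomial GLMs are out of scope by design; the exact conditional test is
  the published method).
- The folding energy model is a teaching-grade approximation; absolute MFE
  values are not comparable to full nearest-neighbour thermodynamics, only
  the acceptance behaviour around the configured threshold is meaningful.
- Genomic-context filtering of novel-miRNA inputs (antisense exon/intron
  partitioning) is reduced to "not assigned to any annotation class".
- Term sets are taken as given; no ontology-graph propagation.
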