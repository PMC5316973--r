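---
title: "Methods: TSS annotation from differential RNA-seq and downstream analyses"
author: "archTSS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TSS annotation from differential RNA-seq and downstream analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archTSS)
```

# The problem

Differential RNA-seq (dRNA-seq) maps transcription start sites (TSSs) by
comparing two libraries built from the same RNA: one treated with a
terminator 5'-phosphate-dependent exonuclease (TEX+), which degrades
processed 5'-monophosphorylated ends and so enriches intact
tri-phosphorylated transcript 5' ends, and an untreated control (TEX-)
that retains intact, processed and degraded 5' ends alike. A genuine TSS
appears as a sharp pile-up of read 5' ends in the TEX+ library that is
also present (though diluted) in the TEX- library; processed ends appear
in TEX- only. In small archaeal genomes this single experiment delimits
the primary transcriptome: promoter elements (the TATA box, the
transcription-factor-B recognition element BRE, the promoter-proximal
element PPE, and the weak initiator), 5' UTRs and the leaderless-mRNA
subpopulation, Shine-Dalgarno ribosome-binding sites, non-coding RNA
candidates, and — with a second genome — conservation of the upstream
regulatory landscape.

`archTSS` implements this analysis end-to-end and ships a planted-truth
simulator so that every stage can be verified against known ground truth
without external sequencing data.

# Coordinate conventions

Genomic coordinates are 1-based and inclusive everywhere inside the
package; BED/bedGraph boundaries are converted at the file boundary only.
Positions relative to a TSS (or to the first base of a start codon) skip
zero: +1 is the reference base itself and -1 the base immediately 5' of
it, matching the usual description of the initiation dinucleotide as the
-1/+1 pair. On the reverse strand, "upstream" means larger coordinates
and all extracted windows are reverse-complemented so that upstream is
always leftward in the returned sequence.

# TSS calling

The calling procedure is a pipeline of five small rules:

1. **Cross-library confirmation** (`detectCandidates`): every position
   with at least one TEX+ 5'-end read is a potential TSS; it is kept only
   if the TEX- library has a 5' end within ±5 nt on the same strand.
   The window is the `cross_library_window` parameter. No TEX+/TEX-
   enrichment-ratio filter is applied by default: presence in both
   libraries, not a ratio, is the criterion.
2. **Clustering** (`clusterCandidates`): retained candidates within
   150 nt of each other chain into clusters (single linkage), so a
   cluster is a maximal run of candidates with no gap above
   `cluster_gap`.
3. **Iterative subdivision** (`subdivideCluster`): a cluster whose
   count-weighted positional standard deviation is below 15 nt is
   treated as one TSS signal; otherwise it is split at the single largest
   inter-member gap (ties: leftmost) and both halves are subdivided
   recursively. Every split strictly reduces the member count, so the
   recursion terminates. Wherever an SD is invoked we use the
   *population* SD of member positions weighted by read counts
   (denominator = total reads); the rule's source never defines its SD,
   so this parameter-free choice is documented here and used
   consistently.
4. **Selection and merging** (`selectTss`, `mergeAdjacentTss`):
   sub-clusters with fewer than 3 total reads are discarded; otherwise
   the member with the most reads becomes the TSS (tie: the 5'-most
   position on the strand). Adjacent selected TSSs from one original
   cluster whose pairwise weighted SD falls below 15 nt are merged by
   dropping the lower-read TSS (tie: the downstream one). Both
   tie-breaks make the output independent of input order.
5. **Classification** (`classifyTss`): for each ORF, TSSs on its strand
   whose distance to the start codon lies in [-300, +50] compete — the
   max-read TSS is primary (P), the rest secondary (S). TSSs not claimed
   as P/S that fall inside an annotated ORF are internal (I, same
   strand) or antisense (A, opposite strand); everything else is
   intergenic (N). Finally, S and I TSSs with fewer than 50% of the
   reads of the relevant primary TSS (the primary of the same ORF, or of
   the ORF containing the internal TSS) are dropped. A TSS eligible for
   several ORFs is assigned to the ORF whose start codon is nearest
   downstream on its strand.

The figure-legend window (-300..+50) rather than the narrower prose
window (-300..0) is the default; both bounds are parameters
(`upstream_window`, `downstream_window`). All five thresholds live in
`callingParams()` and every one is overridable.

# 5' UTRs and leaderless mRNAs

The 5' UTR length of a primary TSS is the distance from the TSS to the
first base of the start codon (strand-aware; `computeUtr`). TSSs
downstream of the start codon — allowed by the +50 classification bound —
get no UTR record, since a negative UTR is undefined; they remain in the
TSS table. A transcript is classified leaderless (lmRNA) when its UTR is
at most 5 nt (`classifyLeader`): the consensus archaeal ribosome-binding
site needs about 6 nt of leader, so the threshold is *inclusive* at
5 nt — a 5-nt leader still cannot hold the motif, and UTR-length
histograms in this regime show a distinct 0–5 nt mode; it is a
parameter. Distribution summaries use 1-nt histogram bins
and the lower-median convention for even counts. COG summaries count
multi-letter assignments once under the first letter (documented,
parameterizable); genes without a COG letter are "unassigned".

# Promoter and RBS motifs

Motif discovery is a single-motif ZOOPS (zero-or-one occurrence per
sequence) expectation-maximization over windows extracted at -50..+10
around each TSS, with a 0-order background estimated from the windows,
pseudocount 0.25 per matrix cell, seeded restarts, and a phase-shift
refinement that re-seeds from the current occurrence register shifted by
up to two columns and keeps strictly better solutions. The EM objective
(log-likelihood up to the constant background term) is non-decreasing
across iterations and is exposed as `logLik_trace`. Results are
deterministic given the seed. This recovers motif *localization and
consensus*; motif significance statistics are out of scope.

Because the BRE directly abuts the TATA box, the A-rich BRE and the
T/A-rich TATA form one ~12-nt composite signal, and a 6-wide ZOOPS
model's optimum is a hybrid register straddling the two (we verified
numerically that the hybrid's likelihood exceeds the pure-TATA
register's). The discovery width for promoter characterization is
therefore 11 — wide enough to pin the composite, with the TATA box as
its final hexamer — after which `realignMotifWindow` re-extracts fixed
flanks (7 nt upstream, 21 nt downstream) around each occurrence for logo
rendering and flank inspection. The initiator (GAGAT at +2..+6) is
handled by degenerate scanning (`scanIupac`), not by EM: it is weak and
fixed-position. Shine-Dalgarno scanning (`scanRbs`) slides the IUPAC
pattern GGDGRD over -20..+10 around each start codon; the reported
offset is the 5'-most match start, which in G-rich SD contexts can
precede the planted/canonical start by a few nt because shifted
degenerate matches are genuine matches.

# Expression and fold-change screening

Per-gene signal is the strand-matched sum of coverage over the CDS;
rRNA/tRNA genes are excluded from both counting and the normalization
denominator. Counts are scaled to reads-per-million of the library's
non-structural total. The fold-change screen computes
(normalized_a + 1)/(normalized_b + 1) and passes genes at ratio ≥ 2 or
≤ 1/2; the pseudocount (default 1 on the normalized scale) stabilizes
ratios at low expression and makes the screen antisymmetric under
condition swap. Per-million scaling makes every ratio subject to a
library-composition factor (if many genes go up, everything else
appears to go down slightly); the screen operates on normalized ratios
and its output says so. Negative-binomial differential testing is out of
scope; the leadered-vs-leaderless expression comparison uses the
Kruskal-Wallis rank test from base R. Signal over overlapping
same-strand genes is counted for both genes, with a warning — interval
sums stay auditable, at the price of double counting.

# ncRNA candidates

Antisense and intergenic TSSs whose promoter carries a TATA occurrence
overlapping -30..-20 become ncRNA candidates; BRE/PPE flags are
informational. No 3'-end rule is available at desk scale, so the extent
is estimated as the maximal downstream run where ssRNA coverage stays at
or above 10% of the TSS-proximal maximum (the peak within the first
20 nt) — a documented stand-in, parameterized by `min_frac`. GC content
is computed over the estimated extent with N excluded from numerator and
denominator. Expression grouping is inclusive at 2-fold: candidates up
in all changed comparisons form group I, down in all form group II,
discordant or unchanged candidates stay ungrouped.

# Comparative upstream-region analysis

Orthologs are paired by reciprocal best hits from precomputed all-vs-all
protein hit tables filtered at E ≤ 1e-10 and query coverage ≥ 0.8
(coverage is defined on the query; the alternative is a parameter). Best
hit = lowest E-value, ties broken by bit score then subject id, and the
result is a one-to-one matching. Region conservation aligns, per pair,
the strand-oriented promoter (-40..-21 relative to the primary TSS),
upstream (-100..-41), 5' UTR (+1..start codon - 1) and ORF sequences
with an in-package Needleman-Wunsch (match 1, mismatch -1, linear gap
-2 — a deliberately plain scheme, since nothing in this analysis depends
on affine gaps) whose traceback
prefers diagonal over up over left, and reports percent identity as
matches over alignment columns, averaged per pair (pooled-column
averaging is the documented alternative). Leaderless genes have no UTR
region and are skipped with a count. Note one systematic effect: global
alignment inflates identity more for short, highly diverged sequences
(many short UTRs) than for fixed 20-nt promoters, which compresses — but
does not invert — planted identity differences.

# The synthetic-data generator

`simulateGenome` plants, per operon-first gene: a TSS at the configured
UTR distance; a TATA hexamer sampled from a TTWTAW-biased weight matrix
with its center uniformly in -30..-20; an A-biased BRE hexamer
immediately 5' of it; an invariant "A" at -10; a pyrimidine at -1 and a
purine at +1 each at rate 0.93; GAGAT at +2..+6 in 30% of sufficiently
long leaders; and a Shine-Dalgarno instance (sampled from GGDGRD)
starting 9 nt upstream of the start codon in leadered genes with ≥9-nt
UTRs. Leaderless genes (probability `leaderless_fraction`) get UTRs of
0–5 nt, 70% exactly 0; leadered UTR lengths are 6 + a geometric variable
whose median matches `utr_length_median`. Antisense and intergenic TSSs
receive the same promoter treatment, plus transcript bodies re-sampled
at 48% GC. TEX+ profiles put 90% of each TSS's Poisson-distributed reads
at the exact position and 10% at ±1 nt; TEX- profiles split reads
50/35/15 between the TSS, processed positions uniformly 20–30 nt
downstream, and uniform background, plus a per-base degradation
background (TEX+ gets a tenth of that rate — the enrichment magnitude is
not prescribed anywhere, so it is a parameter, not a claim). Coverage
profiles under-cover the first ~25 nt of each transcript by 80%,
emulating the loss of proximal 5' termini in strand-specific libraries.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: read-level errors and mappability, sequence
composition beyond a 0-order background plus planted elements,
transcription-unit 3' ends, condition-dependent TSS switching, operon
read-through, and rRNA/tRNA abundance beyond flagged annotation entries.
Recovery rates measured here are upper bounds for real libraries.

`simulateGenomePair` derives a second genome by substituting bases at
per-region rates (defaults: ORF 0.25, promoter 0.37, UTR 0.42,
upstream/background 0.5) so that per-region conservation estimates can
be checked against planted divergence, including the qualitative
ordering ORF > promoter > UTR.

# Problem sizes and numerical choices

The test-suite and the acceptance script run at desk scale: 200 planted
TSSs (mean depth 20, degradation 0.01/base) for recovery; 500 promoter
windows for TATA localization; 500 genes for leaderless-fraction
recovery; 1,000 random ≤20-candidate strands, 500 random ≤8-nt sequence
pairs and 1,000 random string/pattern cases for oracle equivalence; and
100 seeded genome pairs for conservation ordering, with 100 ortholog
pairs per run for the short-region (promoter/UTR) estimates and 20 for
the ORF estimate — ORF identities are long-alignment means with several-
fold smaller per-pair variance, so unequal subsampling equalizes the
precision of the three estimates. Tolerances follow the quantity: exact
equality for fixture arithmetic, binomial 95% intervals for planted-rate
recovery, and ±2 nt for TSS positions (the cross-library tolerance is
±5 nt; the caller is expected to do better than the confirmation
window). Degenerate inputs are handled explicitly: empty profiles yield
background-only candidates, empty clusters cannot arise (every candidate
is in exactly one cluster), zero-read selections are dropped before
merging, and empty UTR or record sets error or return empty summaries as
documented per function.

# Known limitations

* The iterative-subdivision realization (largest-gap bisection) is the
  simplest SD-decreasing split; other SD-decreasing splits are possible
  and would occasionally partition wide clusters differently.
* The ncRNA 3'-extent rule is an invented stand-in (see above); GC
  content and expression response inherit its uncertainty.
* The fold-change screen is a normalized-ratio screen, not a
  dispersion-aware test.
* EM motif discovery finds one motif per run; overlapping composite
  signals must be handled by width choice, as done for BRE–TATA.
* Leaderless classification depends on TSS positional accuracy;
  off-by-one TSS calls can move a 5-nt UTR across the threshold.

# Session info

```{r}
sessionInfo()
```
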