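---
title: "Paired-motif discovery and H-H/TnG topology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired-motif discovery and H-H/TnG topology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foxpair)
```

This vignette documents the models and procedures behind `foxpair`, the
assumptions they make, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the design
choices made where the design was genuinely open.

## The biological problem

FoxP3 binds DNA both as a head-to-head (H-H) dimer on inverted-repeat
forkhead motifs — two half-sites facing each other across a short spacer,
optimally 4 nt — and as a multimer on TnG-repeat microsatellites (tandem
TnG units with n = 2–5, appearing as CAn arrays when read on the other
strand). The pipeline quantifies (i) which half-site sequences support
paired binding, from degenerate-oligo pull-down sequencing; (ii) which
pair orientations are preferred; (iii) where oriented pairs occur in
genomic interval sets relative to a background; and (iv) how H-H sites
relate spatially and orientationally to TnG repeats and to
differentially expressed genes.

## Library designs and read extraction

Two 80-bp oligo designs share the scaffold
`NBS1 (27 nt) – site1 (7 nt) – TCGA – site2 (7 nt) – NBS2 (35 nt)`:
the *random-rcFKHM* design fixes site 2 to GTAAACA (the reverse
complement of the canonical forkhead motif TGTTTAC), so an FKHM in site 1
recreates an IR-FKHM; the *random–random* design leaves both sites
degenerate. The packaged default flank sequences are synthetic
stand-ins — the experimental flanks are deposit-specific — constructed to
contain no TCGA occurrence and no forkhead-like (TGTTT/TGTTG, or reverse
complement) or GCAT cores, so they cannot seed spurious matches in
shifted windows. Users reproducing a specific experiment should pass
their own flanks to `pd_template()`.

Extraction anchors on the final 10 nt of NBS1 and the first 10 nt of NBS2
at the expected spacing, with no mismatches allowed (full-length merged
reads and exact structure matching are assumed; anchored search also
tolerates adapter remnants upstream). Reads are rejected when the fixed
spacer or a fixed site 2 mismatches, when a variable position is N, or
when any variable-position Phred score falls below 20. The quality floor
is applied per base, the stricter reading of a threshold "in the variable
regions"; reads without quality strings (FASTA input) skip the filter
with a warning. Replicates are concatenated before tabulation, so counts
add across replicates by construction.

## 2N motif discovery

Per-sequence counts over the full 4^7 = 16,384 row space are aggregated
into degenerate "2N motifs": each 7-mer contributes to the C(7,2) = 21
patterns obtained by wildcarding two positions, and each motif's count is
the sum of its 16 instantiations. Two exact invariants follow and are
tested: total motif count equals 21× total sequence count, and a motif's
count equals the sum over its instantiation rows. Ranking uses the
pull-down/input aggregate ratio with a pseudocount of 1 raw count on the
input aggregate (none is inherent to the method; 1 keeps input-sparse
motifs finite without materially moving well-sampled ratios). Ties are
broken lexicographically for determinism. No minimum-count floor is
applied before ranking.

Group classification uses only the concrete positions of a pattern:
group 1 requires a literal TGTTT or TGTTG substring; group 2 requires a
fully concrete GCAT core whose flanks, where concrete, lie in {C, T}
(N flanks and the pattern boundary are indeterminate and acceptable; a
core spanning an N is not completed by the wildcard). This matches how
groups are assigned to visible cores, and makes classification a pure
function of the pattern string.

The downstream "top 10 motifs" are an input: by default the 10
top-ranked motifs of this stage, overridable with a user list when the
experimentally curated set is available.

## Pair orientation with register shifts

With 10 motifs, all ordered pairs in four orientations give 400 patterns
(100 combinations × H-H, H-T, T-H, T-T), rendered as 18-mers with the
fixed TCGA spacer: H-H is `A·gap·revcomp(B)`, H-T `A·gap·B`, T-H
`revcomp(A)·gap·revcomp(B)`, T-T `revcomp(A)·gap·B`. Because the binding
register in the random–random library is not fixed, each read is tested
through five windows at offsets −2…+2 around the spacer, reconstructed
from the template flanks. A read counts at most once per pattern
regardless of how many offsets match (any-shift semantics), and may
support several distinct patterns. Reads are deduplicated to unique
sequences and counted with multiplicities by default
(`unique_mode = TRUE` counts each unique sequence once; which of the two
the original tabulation used is ambiguous, so both are provided).

Shifted windows overlay fixed template bases, which biases raw counts;
counts are therefore divided by an analytic baseline: per offset, the
match probability is the product over window positions of 1/0 for fixed
bases inside/outside the pattern's base set and |set|/4 for uniform
variable bases, and the baseline is the *sum* over the five offsets —
the expected number of matching offsets rather than P(at least one
match). The two differ only by co-match terms, which are negligible for
these patterns (at most one register can align the fixed spacer), and
the sum is exactly computable without enumerating 4^14 sequences; the
Monte-Carlo agreement is verified in the tests. Patterns with baseline 0
(incompatible with the fixed spacer at every offset) are flagged
non-normalizable and excluded with a warning. Display matrices are
scaled 0–100 jointly across the four orientations so heatmaps share one
scale; orientation totals are sums of unscaled normalized values.

## Genome scanning and enrichment

Genomic scanning renders pair patterns with an N-wildcard gap of the
requested size rather than the literal TCGA spacer: in the genome the
spacer is unconstrained, and a tandem TnG array can then legitimately
register as multiple H-T group1–group1 pairs with a 4-nt gap. Scanning
is positive-strand only; within one pattern, matches are greedy
non-overlapping (the search resumes past each match, preventing inflated
counts from sliding matches in repeats), while overlaps between
different patterns are allowed to avoid search-order bias. Matches
straddling an interval edge are not found, since scanning is
per-interval sequence. Greedy selection over equal-length windows picks
a maximum-cardinality non-overlapping set, so counts are invariant under
strand reversal — the tested transposition symmetry of the H-H/T-T
matrices and the H-T/T-H exchange.

Enrichment of foreground over background interval sets uses occurrence
rates per Mb of total set length and a one-sided exact binomial test:
conditioning on the total occurrence count n = count_fg + count_bg, each
occurrence falls in the foreground with null probability
p0 = len_fg/(len_fg + len_bg), and the p-value is P(X ≥ count_fg). This
conditional parameterization is one reading of an "exact binomial test"
on normalized counts; the alternative (treating count_fg against an
independent n) is noted but not used, and the chosen form is
oracle-tested against direct pmf summation. Raw p < 0.05 is the default
threshold with no multiplicity correction, matching the original
procedure; a Benjamini-Hochberg option is provided. Fold changes apply a
0.5-count continuity correction to the background only when its count is
0, leaving typical values untouched. Occurrences are counted
per-occurrence (not per-peak presence); merged H-H sites are available
for per-locus statements.

## TnG repeats and H-H topology

TnG detection is unit-grammar based: maximal tandem arrays of T{2,5}G
(strand +) or CA{2,5} (strand −, the reverse-complement reading), with
mixed unit lengths allowed within an array, a minimum of 3 units and
12 bp (configurable floors; the grammar needs a detectability cutoff and
three units is the shortest convincing tandem array), followed by
low-complexity exclusions: pure dinucleotide repeats of ≥6 TG/AC/TA/TC/
AG/CG units and ≥12-bp homopolymers are removed. The grammar itself
cannot produce these degenerate cases, but the filter also covers
imported hit sets (a BED import path lets users supply an external
scanner's output instead). Repeat length is the merged-array length.

Topology relates merged H-H sites and repeats by signed border-to-border
distance: 0 for overlap *or* abutment (the 0-nt-gap category includes
immediately adjacent sites; under half-open coordinates abutting
intervals share no base, so abutment is assigned 0 by decision),
positive when the repeat lies downstream of the H-H, negative upstream.
A TnG (+) repeat upstream, or a CAn (−) repeat downstream, reads
"aligned" — its reading direction continues the proximal H-H half-site —
otherwise "divergent"; for distance-0 pairs the side is taken from
interval midpoints. Equidistant repeats tie-break to the smaller start.
Occupancy is the coverage AUC in a 200-bp window around the repeat
center; stratification compares repeats at 0-nt gap against repeats
>1 kb from any H-H site (intermediate distances are excluded from both
classes, following the two-class design), within short (≤20 bp) and long
(≥40 bp) length classes. AUC is log2-transformed as log2(AUC + 1), since
synthetic nulls can produce exactly zero coverage. Binder-free control
regions are ATAC peaks ≥10 kb from every ChIP peak with window-AUC below
the minimum observed across ChIP peaks.

## Gene association

Distances are measured from the gene body (the annotation interval),
expanded symmetrically — not from the TSS. Density is overlapping
feature bp per Mb of window length (occurrence counts would conflate
feature number and size), averaged within significant
(adjusted p < 0.05) and non-significant groups over windows of 1 kb to
1 Mb. The nearby-feature fraction uses a 2-kb expansion with strict
half-open overlap, binned by adjusted p (default edges 0, 1e-10, 1e-5,
0.05, 1 — the exact published bins are unstated, so the edges are
configurable) and split by fold-change direction; empty bins are
reported as missing rather than 0.

## The synthetic-data generator

`sim_pdseq_reads()` emulates a single-round pull-down: an input pool
with uniform variable positions, and a pull-down drawn from that pool
with replacement with probability proportional to
`noise_floor + sum of matched pattern weights` (fixed-register site-1 or
site-2 weights, or any-shift pair-pattern weights). Qualities are
constant Q30 by default. `sim_genome()` builds an i.i.d. background
contig (uniform base composition by default, configurable GC),
non-overlapping 600-bp ChIP and ATAC peaks on a slot grid, planted
oriented pair sites inside peaks, planted TnG arrays either abutting a
planted H-H site in the aligned configuration or >1 kb from every H-H,
piecewise-triangular coverage bumps (over ChIP peaks, plus
repeat-centered bumps whose height is boosted for H-H-adjacent repeats),
and a DE gene table in which the probability of placing a gene next to a
planted feature increases with −log10(adjusted p). Guard bases are
written at the background-facing ends of planted arrays so that the
maximal detected array coincides exactly with the planted interval,
making recall-1.0 assertions exact. Placement collisions are retried and
error out after a bounded number of attempts. Identical seed and
configuration give byte-identical output.

Default study conditions: a 300-kb contig, 30 ChIP and 90 ATAC peaks,
24 H-H pairs of the canonical inverted repeat at a 4-nt gap planted in
ChIP peaks, 24 TnG arrays ((TTTG)×5 = 20 bp and (TTTG)×12 = 48 bp, half
zero-gap-linked and half far), and 80 genes. These sizes keep the full
test suite and the acceptance script within minutes on one CPU while
leaving every recovery margin wide; the PD-seq recovery tests use 1e5
reads per library and a 4× planted weight over 20 seeds, and the
random–random orientation analysis uses 3e5 reads — the smallest depth
at which the baseline-normalized orientation totals are no longer
dominated by Poisson noise on rare small-baseline patterns (a single
chance read on a pattern with baseline ~1e-6 contributes ~1e6 to a
total at lower depths).

What the generator does *not* emulate: sequencing error and quality
degradation profiles, PCR duplicates and fragmentation, paired-end
merging artifacts, genomic base composition structure (CpG islands,
repeat families), chromatin-driven peak shapes, or multi-round
selection. Passing recovery tests therefore demonstrates correctness of
the analysis machinery on data matching its assumptions, not robustness
to the full noise structure of real libraries.

## Numerical and degenerate-input conventions

Coordinates are 0-based half-open throughout (BED convention; all
external interval files are BED). Lowercase (soft-masked) sequence is
uppercased on ingestion; characters outside the IUPAC alphabet are
errors. Degenerate matching is subset matching: a subject position
matches when its base set is contained in the pattern's, so an N in a
*subject* only matches an N in the pattern — genome Ns never match
concrete patterns. Ranking ties break lexicographically; equidistant
nearest features break to the smaller start; empty inputs yield empty,
correctly typed results (with warnings where silence would be
surprising). The per-sequence fold-enrichment pseudocount (0.5 RPM on
the input) and the 2N ranking pseudocount (1 raw count) are stated
defaults, not fitted values.

## Known limitations

The baseline correction assumes uniform variable positions in the input
library; a composition-biased input would need an empirical baseline.
The binomial enrichment treats occurrences as independent, which
repetitive sequence violates (mitigated, but not removed, by
non-overlapping within-pattern counting). TnG detection by unit grammar
is not a PWM scan: hits agree with a position-weight-matrix scanner on
clean tandem arrays but diverge on degenerate edges, and the 12-bp/
3-unit floor is a choice, not an inference. The H-H/repeat "aligned"
call uses interval midpoints to decide sides at distance 0, which is
arbitrary for repeats that fully contain an H-H site.
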