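---
title: "Methods: paralog discovery from long-read amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paralog discovery from long-read amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`paraseek` recovers the members of a tandemly duplicated gene family from
multiplexed Nanopore amplicon reads. This vignette documents the model behind
each stage, the tunable parameters and their defaults, the numerical choices
that make results reproducible, and what the simulator-based tests do and do
not establish.

## The inference problem

A single primer pair anchored in conserved UTRs amplifies every paralog of a
gene family at once. After sequencing, each read carries one (sometimes
several, for concatemers) amplicon drawn from one paralog, corrupted by
Nanopore noise: substitutions and, characteristically, small indels
concentrated in homopolymer runs. The task is to decide how many distinct
paralogs are present, reconstruct each one's sequence, and annotate it — with
paralogs as close as ~1% and as far as ~15% apart, and per-read error of the
same order as the paralog divergence. The central tension is the clustering
granularity: too coarse lumps paralogs (underclustering), too fine splits one
paralog's reads (overclustering). The pipeline treats the clustering identity
threshold as a per-sample free parameter and selects it by explicit criteria,
with an independent consensus-level guard against overclustering.

## Amplicon extraction and filtering

Primer sites are located by substitution-only matching with a per-primer
budget (default 3 mismatches on ~22 bp primers); IUPAC codes in the primer
match their degenerate sets, read bases are literal. Both strands are
scanned, every forward match is paired with every downstream reverse match,
and the amplicon span includes both primer sites. Per read, the smallest
amplicon strictly longer than `min_amplicon` (default 1,000 bp) is extracted:
in a concatemeric or chimeric read the spans that cross junctions are longer
than the true amplicon, so the smallest qualifying span is the conservative
choice.

Substitution-only matching deliberately rejects primer sites carrying an
indel. At ~4% read error this discards roughly a third to a half of reads —
acceptable at amplicon coverage, and it enriches for accurate reads.
`primer_indels = TRUE` switches to edit-distance site matching when coverage
is scarce.

Filtering keeps amplicons of 1,200–2,400 bp (inclusive window, the expected
amplicon size range) with mean quality strictly above Q14. Mean quality is
defined on the error-probability scale, `-10·log10(mean_i 10^(-Q_i/10))`, so
a few very low-quality bases dominate the mean, which is the intended
behaviour of a read-accuracy filter. The optional read-level prefilter
(Q > 7) reproduces basecaller pass filtering for inputs that skipped it.

Boundary conventions are deliberate and tested: the 1,000 bp extraction
floor and both quality floors are strict (`>`), the size window is inclusive
at both ends.

## Identity, clustering, and threshold selection

Sequence identity between two amplicons is the number of matched columns of
a global alignment under unit edit costs, divided by the length of the
shorter sequence and capped at 1. Among minimum-edit alignments the one with
the most matches defines the match count, which makes the metric
well-defined rather than traceback-dependent. This is the definition behind
cd-hit's threshold; it is computed exactly by dynamic programming instead of
a word-filter heuristic, so clustering results are a pure function of the
input.

Greedy clustering considers amplicons longest-first (ties keep input order);
each joins the first cluster whose representative (the seed, i.e. its
longest member) it matches at identity ≥ c, else it seeds a new cluster.
Membership is tested against the representative only — the cd-hit scheme.
A cluster is *supported* when it contains strictly more than `support`
(default 10%) of the sample's filtered amplicons; with a minimum of ~100
amplicons per sample this bounds spurious clusters from nonspecific or
chimeric reads, which arrive at a few percent each.

The threshold grid is 0.84–0.91 in steps of 0.01. At each grid value the
sample is clustered and the threshold chosen by three ordered criteria:

1. the largest number of supported clusters,
2. among ties, the largest number of amplicons inside supported clusters,
3. among remaining ties, the largest c.

Consensuses are then built for the chosen threshold's supported clusters; if
any two exceed 99.45% identity the threshold is deemed overclustered and
discarded, and selection is reapplied over thresholds whose supported-cluster
count is strictly smaller than the discarded one's, repeating until clean.
Where several rounds occur, the comparison is against the most recently
discarded threshold. If restriction empties the candidate set the scan falls
back to any never-flagged grid values (with a warning); if every value was
flagged it stops with an explicit error rather than reporting a threshold it
could not validate.

### Banded acceleration

Inside the greedy loop, identity against a threshold c is computed with a
banded alignment. If identity ≥ c then the optimal alignment has at most
`2·m·(1−c) + |len(a)−len(b)|` edits (m = shorter length), and any alignment
with e edits never strays more than e cells from the diagonal; a band of
that width therefore returns the exact identity whenever the answer is
≥ c, and overflowing the band proves the answer is < c. The user-facing
`pairwise_identity()` always runs the full, unbanded computation, and the
test suite asserts banded/full agreement on randomized pairs.

## Consensus polishing

Each supported cluster's consensus starts from the longest member as a
template: all members (capped at `max_members = 100`, longest-first, to
bound runtime on very deep clusters) are globally aligned to the template
and voted per column. The majority base wins; gap-majority columns are
deleted; insertions present in more than half of the members are added
(majority insertion string, lexicographically smallest on ties); voting ties
retain the template base. A second round realigns members to the round-one
consensus and re-votes, which resolves most template-biased columns. The
procedure is deterministic given the member order and idempotent on its own
output. The neural polisher used in comparable Nanopore pipelines is
replaced by this transparent majority rule; adequacy is enforced by a tested
guarantee — on simulated clusters with ≥ 30 members at ≤ 5% per-base error
the consensus reaches ≥ 99.8% identity to the true paralog — rather than by
claims about the error model.

Nonspecific clusters (mispriming products) are detected by identity to a
reference gene set: a consensus is *specific* at ≥ 80% identity (inclusive)
to any reference. The published analyses performed this curation manually;
0.80 is this package's operationalization and is a config knob
(`nonspecific_min_identity`), set low enough that any true family member at
≤ 15% divergence passes easily while random or off-target products (≤ ~60%
under this metric) fail clearly.

## Annotation, frame repair, hallmarks

A reference gene model (genomic sequence + CDS exons, 0-based half-open
internally; GFF3 conversion happens only at I/O) is projected onto each
specific consensus through a global alignment. An exon counts as mapped when
at least half of its reference bases align; a consensus mapping fewer than
`min(4, n_exons)` exons is rejected, fewer than all exons sets a `partial`
flag. Projected exon boundaries that break the canonical GT..AG intron motif
are snapped to the nearest canonical dinucleotide within ±6 bp — large
enough to absorb small alignment ambiguities at splice sites, small enough
not to jump to a spurious motif. An alignment identity below 0.5 rejects the
reference as too distant (for same-length DNA this effectively triggers only
on genuinely unrelated or compositionally extreme sequences, since the
matches/shorter-length metric is generous on random pairs).

Homopolymer frameshift repair runs only when the concatenated CDS length is
not a multiple of 3 or the translation contains an internal stop. Candidate
sites are homopolymer runs of ≥ 3 bases in the *reference* CDS whose
consensus run length differs; the repair resets the consensus run to the
reference length. The smallest set of such run edits (subsets tried in
increasing size, up to 4 simultaneous edits) that restores the frame and
removes the premature stop is applied and recorded base-by-base; if none
succeeds the gene is left unrepaired and flagged rather than force-edited.
In-frame genes are never touched: a run-length difference that preserves the
frame is treated as a genuine biological difference. Repairs are restricted
to CDS intervals — intronic indels are irrelevant to the protein and are
left as observed.

Hallmark validation checks the structural evidence of a functional gene:
ATG at the gene start, a stop codon at the gene end, GT..AG at every intron,
the family's conserved cysteines (default 4) and proline at
reference-aligned protein positions (supplied as a `conserved_profile()`,
positional rather than motif-searched, because the family defines them
positionally against known reference proteins), and the protein length.

Paralog assignment is best-identity against named reference paralogs with
two guards: a floor (default 0.97) below which the gene is `unassigned`, and
a margin (default 0.005) under which the call is `ambiguous` rather than
arbitrarily resolved. The margin default is half the smallest paralog
divergence the pipeline is expected to resolve (~1%).

## The simulator: what it emulates, what it does not

`simulate_paralog_family()` draws an ancestral gene — six CDS exons by
default (~645 bp coding for a 214-residue protein plus stop), GT..AG
introns, total start-to-stop length 1,500 bp, 130 bp UTR spacers and 22 bp
primer sites, for a ~1.8 kb amplicon — and derives each paralog by placing
substitutions to a target pairwise divergence (default 5%). CDS
substitutions are restricted to synonymous third-codon positions and never
touch the start/stop codons, the conserved-residue codons, splice
dinucleotides, or primer sites, so hallmark checks remain meaningful at any
feasible divergence; a divergence that cannot be placed without violating
these constraints raises an error. One paralog can optionally lose 130 bp
of intron 2, mirroring a known paralog-diagnostic deletion.

`simulate_reads()` emits full amplicons with random flanking margins,
i.i.d. per-base substitution/insertion/deletion noise (defaults 2%/1%/1%)
with indel rates multiplied (default 3×) inside homopolymer runs ≥ 4 bp
(homopolymer insertions duplicate the run base), per-base qualities from a
normal model (mean 18, sd 4; error-derived bases drawn 8 Phred lower, so
quality tracks accuracy the way basecaller qualities loosely do), random
read orientation, and configurable fractions of nonspecific (5%) and
chimeric (2%) amplicons. All randomness flows from the single config seed;
reads use a derived sub-stream, and the global RNG state is saved and
restored around every simulation call.

These defaults are the regime the pipeline is designed for: ~100 reads per
paralog at ~96% read accuracy. The noise model is deliberately simple — it
has no sequence-context error profile beyond the homopolymer boost, no
quality drift along the read, no strand bias, and chimeras are clean
two-segment joins. Passing tests therefore demonstrate the pipeline's
*algorithmic* correctness (clustering, threshold selection, consensus,
repair, assignment under controlled noise), not that real flow-cell data
will behave identically; on real data the extraction yield, the supported
fraction, and the consensus accuracy floor are the quantities to re-examine.

## Numerical and degenerate-input conventions

- All internal coordinates are 0-based half-open; GFF3 (1-based inclusive)
  is converted only at the I/O boundary. FASTQ qualities are Phred+33.
- Deterministic tie-breaks everywhere: equal-length amplicons keep input
  order at sort time; equal-length smallest amplicons prefer the `+`
  orientation, then the leftmost start; alignment traceback prefers
  diagonal, then gap-in-consensus, then gap-in-reference; consensus voting
  ties keep the template base.
- `select_threshold()` is a pure function of the per-threshold table;
  permuting its input does not change the answer.
- Degenerate inputs are contracts, not crashes: empty FASTQ gives an empty
  tibble; a sample with zero filtered amplicons yields a report with no
  genes and an explicit warning; `detect_overclustering()` of fewer than
  two consensuses is empty; `supported_count(total = 0)` is 0; empty
  reference sets are errors.
- Sequences are limited to 8,191 bases in the alignment kernel (the packed
  integer radix), far above the amplicon regime.

## Problem sizes in the shipped tests

The unit tests run reduced instances (tens of reads, 40–80 bp fuzzing
sequences, ~1,000 oracle-equivalence cases); the acceptance suite and
`scripts/acceptance.R` run the full study operating point — families of 1–4
paralogs at 5% divergence with 100 reads per paralog (~1,800 bp amplicons),
plus the identical-paralog collapse case. These sizes were chosen to make
each guarantee measurable at the study's own scale while keeping a complete
run in the minutes range on one core.

## Known limitations

- Allelic variation within a paralog collapses into one consensus; the
  pipeline reports genes, not haplotypes.
- A paralog attracting fewer than the support fraction of amplicons
  (strong PCR bias, > ~10 paralogs) is invisible by construction.
- Paralogs closer than the overclustering limit (99.45%) are merged by the
  guard even when genuinely distinct.
- The 0.80 specificity floor, the 3-mismatch primer budget, and whether
  amplicons include primer sites are operational conventions; the upstream
  analyses they mirror made these calls manually or left them unstated.
- Identity under the matches/shorter-length metric is generous on sequences
  of very different lengths; length filtering upstream keeps the metric in
  its intended regime.
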