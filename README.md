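# paraseek

Recovering the full-length sequences — and the copy number — of recently
duplicated genes is awkward with short reads and expensive with genomes.
`paraseek` implements a long-read alternative: amplify the whole gene family
with one primer pair anchored in conserved UTRs, sequence the multiplexed
amplicons on a Nanopore device, and let a clustering pipeline separate the
paralogs computationally. It is aimed at researchers studying copy-number
and sequence variation in tandem gene duplicates (the motivating system is
the *epdl2* family of mormyrid electric fish, duplicated into 2–5 copies at
roughly 85–99% pairwise identity) but applies to any amplicon target in the
1.2–2.4 kb range.

## The method

For each demultiplexed sample the pipeline:

1. **Extracts amplicons in silico.** Every primer-delimited region on either
   strand is located with IUPAC-degenerate, substitution-only matching
   (budget of 3 mismatches per primer site); per read, the *smallest*
   amplicon strictly longer than 1,000 bp is kept — the guard against
   concatemeric and chimera-spanning spans.
2. **Filters** amplicons to 1,200–2,400 bp and mean quality Q > 14, where
   mean quality is defined on the error-probability scale,
   `-10·log10(mean(10^(-Q_i/10)))` (an optional read-level Q > 7 prefilter
   mirrors basecaller pass filtering).
3. **Clusters** the amplicons greedily at an identity threshold `c`:
   sequences are considered longest-first and each joins the first cluster
   whose representative it matches at identity ≥ c, where identity is the
   matched-column count of a global minimum-edit alignment divided by the
   shorter sequence length (the cd-hit definition, computed exactly). A
   cluster is **supported** when it holds strictly more than 10% of the
   sample's amplicons.
4. **Selects c automatically** over the grid 0.84–0.91 (step 0.01) by a
   three-tier rule: most supported clusters; then most amplicons classified
   into supported clusters; then the largest `c`. If two cluster consensuses
   exceed 99.45% identity (overclustering — one gene split in two), that `c`
   is discarded and selection is repeated over thresholds with strictly
   fewer supported clusters.
5. **Polishes a consensus** per supported cluster by star alignment against
   the longest member plus per-column majority vote, iterated twice, and
   screens out nonspecific clusters (< 80% identity to any reference gene).
6. **Annotates** each specific consensus by projecting a reference gene
   model through a global alignment (splice boundaries snapped to GT..AG
   within ±6 bp), repairs homopolymer-indel frameshifts inside CDS exons by
   restoring reference run lengths, translates, validates gene hallmarks
   (ATG start, terminal stop, canonical splice sites, the family's four
   conserved cysteines and conserved proline), and assigns each gene to a
   named paralog by best identity with a 0.5% margin rule.

A seeded simulator (`sim_config()`, `simulate_paralog_family()`,
`simulate_reads()`) generates ground-truthed paralog families and
Nanopore-like reads — substitution/indel noise with boosted homopolymer
indels, nonspecific and chimeric amplicons — so the whole pipeline is
testable end to end without any external data.

## Worked example

Simulate a three-paralog family at 5% divergence with 100 reads per paralog,
then run the full pipeline:

```r
library(paraseek)

cfg <- sim_config(seed = 7, n_paralogs = 3)
truth <- simulate_paralog_family(cfg)
sim <- simulate_reads(truth)

report <- run_sample(
  sim$reads, truth$primers,
  references = truth$ancestor,          # specificity screen
  ref_model = truth$gene_models[[1]],  # annotation transfer
  named_refs = truth$paralog_seqs,     # paralog assignment
  profile = truth$profile              # conserved-residue checks
)
report
#> <paraseek_report> sample sim
#>   reads in: 321; amplicons extracted: 169; after size/quality filter: 169
#>   chosen c = 0.91 (3 supported clusters)
#>   genes: 3
#> <paraseek_gene> sim.cluster3: span 1498 bp, 6 CDS exons, protein 214 aa; paralog: paralog_3
#> <paraseek_gene> sim.cluster4: span 1500 bp, 6 CDS exons, protein 214 aa; paralog: paralog_1
#> <paraseek_gene> sim.cluster5: span 1500 bp, 6 CDS exons, protein 214 aa; paralog: paralog_2
```

All three paralogs come back as separate supported clusters at the selected
threshold, each annotated with the expected six CDS exons and a 214-residue
protein, and each assigned to the correct source paralog. (Roughly half of
the raw reads survive extraction: with ~4% read error, a 22 bp primer site
often carries an indel, which substitution-only site matching rejects —
`paraseek_config(primer_indels = TRUE)` relaxes this.) `tidy(report)` gives
the per-gene table, `glance(report)` the per-sample counts, and
`autoplot(report$scan)` the threshold-scan diagnostics:

```r
tidy(report)[, 1:5]
#>   gene_id      length_start_stop paralog_label n_cds in_frame
#> 1 sim.cluster3              1498 paralog_3         6 TRUE
#> 2 sim.cluster4              1500 paralog_1         6 TRUE
#> 3 sim.cluster5              1500 paralog_2         6 TRUE
```

Checking the consensuses against the simulator's truth:

```r
sapply(report$genes, function(g)
  pairwise_identity(g$bases, truth$paralog_seqs[[g$paralog_label]]))
#> sim.cluster3 sim.cluster4 sim.cluster5
#>            1            1            1
```

A thin CLI wrapping the same functions is installed at
`system.file("cli", "paraseek", package = "paraseek")` with subcommands
`simulate`, `extract` and `run`.

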