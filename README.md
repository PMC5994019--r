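# holosort

Pre-assembly sorting of holobiont meta-transcriptomic reads by k-mer
coverage, with chimera screening of assembled contigs and a fully
truth-labelled synthetic-data generator.

## The problem

Holobiont samples — a host organism sequenced together with its symbionts
(coral + dinoflagellates, sponge + bacteria, radiolarian + microalgae) —
yield one mixed RNA-seq read pool. Assembling that pool directly produces
chimeric contigs that erroneously join host and symbiont fragments and
leaves every contig's organism of origin ambiguous. holosort is for
researchers who want to disentangle the partners *before* assembly, using
whatever reference material exists for each partner (raw reads, ESTs, or
assembled transcripts, even from related species), then assemble and
annotate each partner's read set independently.

## The method

Each partner's reference library (*bank*) is reduced to its **solid
k-mers** — the k-mers whose occurrence count in the bank reaches a solidity
threshold τ (default: 2 for raw-read banks, 1 for assembled banks) — and
indexed in an exact or fingerprint-verified membership structure (the
fingerprint variant bounds false positives by ~2·2⁻ᶠ and never misses an
indexed k-mer). For a read of length *l*, a position is *covered* when some
indexed k-mer's window contains it; the read is **similar** to the bank
when at least *l* × *s*/100 positions are covered (default *s* = 50,
default *k* = 25, k-mers canonical). Every read then lands in exactly one
of four categories:

| similar to host | similar to symbiont | category |
|---|---|---|
| yes | no | `host` |
| no | yes | `symbiont` |
| yes | yes | `shared` |
| no | no | `unassigned` |

An optional iterative-enrichment loop appends exclusively-assigned reads to
their partner's bank and re-classifies, recruiting reads that bridge
indexed and unindexed regions of incomplete references. Companion tools
flag host–symbiont **chimeras** among assembled contigs — from 12-column
translated-search hit tables (split-origin best-hit rule) or alignment-free
via per-position k-mer origin profiles — and compute per-category assembly
metrics (N50, GC). See the methods vignette
(`vignettes/holosort-methods.Rmd`) for the full model, parameter rationale
and limitations.

## Worked example

A complete synthetic study: simulate a two-partner holobiont (divergence
0.15, 10% conserved transcripts, error-free 100-bp reads), index both
banks, partition the reads, and score against the generator's truth
labels.

```r
library(holosort)

cfg <- simulation_config(seed = 42, divergence = 0.15, error_rate = 0)
sim <- simulate_holobiont(cfg)

spec <- kmer_spec(k = 25)
host_idx <- index_bank(sim$host_bank, spec, bank_type = "assembled", source_label = "host")
sym_idx  <- index_bank(sim$symbiont_bank, spec, bank_type = "assembled", source_label = "symbiont")
host_idx
#> <bank_index> 'host': 29292 distinct solid k-mers (k=25/canonical, solidity >= 1, exact mode)

part <- partition_reads(sim$reads, host_idx, sym_idx, s_percent = 50)
part
#> <read_partition> 2922 reads (k = 25, s = 50%, span coverage)
#>    category n_reads percent n_too_short
#>        host    1333   45.62           0
#>    symbiont    1251   42.81           0
#>      shared     338   11.57           0
#>  unassigned       0    0.00           0

evaluate_partition(part$assignments, sim$reads)
#> <partition_evaluation> 2922 reads, accuracy 0.9966
#>  truth_origin host symbiont shared unassigned
#>     conserved    0        0    328          0
#>          host 1333        0      4          0
#>      symbiont    0     1251      6          0
```

Reading the output: every conserved-origin read is correctly `shared` (it
genuinely belongs to both libraries); partner-origin reads are recovered
essentially perfectly, the handful of `shared` calls being homolog reads
that retain a long error-free stretch matching the other partner — the
rule working as specified. `tidy()`/`glance()` extract these tables as
tibbles, `autoplot(part)` draws the category bars, and
`partition_reads(..., outdir = ...)` writes the four category
FASTA/FASTQ files for independent assembly.

A command-line front-end wrapping the same functions ships in
`inst/scripts/holosort.R` (subcommands `simulate`, `index`, `classify`,
`chimera`, `metrics`; every run writes a reproducibility manifest).

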