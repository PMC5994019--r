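---
title: "Sorting holobiont reads by k-mer coverage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sorting holobiont reads by k-mer coverage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holosort)
```

## The problem

A holobiont sample — a coral and its dinoflagellate symbionts, a sponge and
its bacteria, a radiolarian colony and its microalgae — is sequenced as one
mixed RNA pool. Assembling that pool directly mixes transcripts of organisms
separated by hundreds of millions of years of evolution, produces chimeric
contigs joining host and symbiont fragments, and makes any downstream
"who does what" question ambiguous. holosort sorts the reads *before*
assembly: every read is compared against a reference library (bank) for each
partner and routed to one of four categories — **host**, **symbiont**,
**shared** (similar to both banks), or **unassigned** (similar to neither) —
so that each subset can be assembled and annotated independently.

## The similarity measure

Each bank is reduced to its **solid k-mers**: the k-mers whose occurrence
count in the bank reaches a solidity threshold $\tau$. For a read of length
$l$, every window of length $k$ is queried against the bank index, and a
position $p$ of the read counts as *covered* when at least one matching
window contains it (overlapping or non-overlapping matches each cover their
full $k$-base footprint). The read is **similar** to the bank when

$$\#\{\text{covered positions}\} \;\ge\; l \times s/100,$$

with the boundary inclusive ("at least"). The measure is deliberately
asymmetric: it depends on where matching k-mers fall on the *query* read,
never on their layout in the bank, so a short conserved insert inside an
otherwise foreign read contributes only its own footprint.

Two readings of "coverage" circulate for this family of methods: the number
of covered positions, and the number of matching window *starts*. Both are
implemented (`coverage_mode = "span"` / `"start"`). Span with denominator
$l$ is the default because it is the only combination under which the
criterion $l \times s$ is attainable for every $s \le 100$ (a read has only
$l - k + 1$ window starts, so start-counting against $l$ saturates below 1).
The window-count denominator $l - k + 1$ is available as an option for users
who want start-mode fractions on a $[0,1]$ scale.

Classification is then a two-bit decision: similar to host only → `host`;
symbiont only → `symbiont`; both → `shared`; neither → `unassigned`. The
four categories are pairwise disjoint and exhaustive by construction, and
reads shorter than $k$ — which cannot contain a single window — are routed
to `unassigned` and tallied separately (`n_too_short`) rather than dropped,
so category counts always sum to the input total.

## The index

The membership structure mirrors a quasi-dictionary: a compact hash-based
index with per-element fingerprints. Two modes:

* **exact** (default): membership is answered against the stored solid set;
  no false positives, no false negatives.
* **fingerprint**: each indexed k-mer deposits an $f$-bit fingerprint
  (second, independent hash) in a slot chosen by a first hash modulo the
  number of indexed k-mers $N$. Indexed k-mers are always found; a foreign
  k-mer is falsely admitted only when its fingerprint collides with one
  resident in its slot. With load factor 1 the expected number of resident
  fingerprints per slot is 1, so the false-positive rate is $\approx 2^{-f}$
  and empirically bounded by $2 \cdot 2^{-f}$ (the factor-two headroom
  absorbs slot-occupancy fluctuations; the bound is verified on $10^5$
  foreign queries in the test suite). Widths below 4 bits are rejected —
  the contract would be vacuous.

No true minimal perfect hash is constructed; the slot/fingerprint table
honours the same membership contract at desk scale, which is the point of
the structure here. Both hashes are polynomial hashes over the 2-bit base
encoding, computed in exact double-precision integer arithmetic modulo
$2^{31}$-scale primes, so indexes are reproducible across platforms.

K-mer counting is an in-process exact counter (the data sizes this package
targets do not need an external disk-based counter), and by default k-mers
are **canonical** — folded onto the lexicographic minimum of the k-mer and
its reverse complement — because RNA-seq libraries are commonly unstranded;
`canonical = FALSE` restores stranded behaviour.

## Parameters and defaults

| parameter | default | meaning and rationale |
|---|---|---|
| `k` | 25 bases | word length; small enough that 50-bp reads still carry 26 windows, long enough that a match is near read-specific |
| `solidity_threshold` | 2 (read banks), 1 (assembled banks) | raw short-read banks with real coverage have mostly-singleton error k-mers; every k-mer of an assembled transcript/EST is presumed real |
| `s_percent` | 50 | fraction of read positions that must be covered; lowering it (e.g. to 40) recalls more reads at the cost of specificity |
| `fingerprint_bits` | 12 | false-positive rate ≈ $2^{-12} \approx 2.4\times10^{-4}$ per foreign query |
| `coverage_mode` | `"span"` | see above |
| `denominator` | `"read_length"` | see above |
| `pair_policy` | `"independent"` | counts are per read; `union`/`intersection` reconciliation available for paired libraries |

## Paired reads

Mates are classified independently by default. `reconcile_pairs()` offers
two joint policies: **union** propagates any partner assignment across the
pair (a host mate plus a symbiont mate — or any shared mate — makes the pair
shared; a partner label plus an unassigned mate adopts the label), and
**intersection** keeps a label only when both mates agree, demoting
disagreements to unassigned.

## Iterative enrichment

When a bank is incomplete, reads from its missing sequence fall into
`unassigned`. Enrichment appends the reads assigned *exclusively* to a
partner to that partner's bank, rebuilds both indexes with the same per-bank
solidity thresholds, and re-classifies the whole read set; reads straddling
the boundary between indexed and unindexed sequence seed the recovery of
their neighbours, and each round advances roughly
`read_length × (1 − s/100)` bases into unindexed territory. Shared reads are
added to neither bank — the conservative choice, preventing a conserved read
from dragging one partner's sequence into the other's library and feeding
back. Since indexes only gain k-mers across rounds, per-read coverage
fractions never decrease, so the unassigned count is provably
non-increasing; the loop stops at `max_rounds` or when a round recruits
fewer than `min_new_reads` reads.

A subtlety worth stating: enrichment can only help when the recruited reads
*carry* k-mers absent from the bank. If incompleteness means whole
transcripts are missing (`make_banks(mode = "subset")`, the missing-lineage
scenario), reads of missing transcripts share nothing with the index,
round-1 recruits add no new k-mers, and the fixed point is reached
immediately — which is the honest behaviour, not a defect. Enrichment pays
off when references are *partial* (truncated transcripts, EST fragments:
`make_banks(mode = "truncate")`), and that is the fixture the enrichment
validations use.

## Chimera screening

Contigs assembled from a mixed pool can erroneously join host and symbiont
fragments. Given translated-search hits of the contigs against the two
partner references (standard 12-column tabular alignments, e-value-filtered
at $10^{-3}$ by default), `detect_chimeras()` applies a split-origin rule:
per contig, take the highest-bitscore host interval and the
highest-bitscore symbiont interval among hits spanning at least
`min_hit_span` (50) bases; the contig is a **chimera** when both exist and
their overlap does not exceed `max_overlap_fraction` (0.2) of the shorter
interval. Ties on bitscore break deterministically (lower e-value, then
leftmost, then shortest), making the verdict invariant to hit order and
duplicated rows. The thresholds are exposed; this is the package's own
formalisation of split-origin screening, with no claim of fidelity to any
particular external script.

`kmer_origin_profile()` is the alignment-free companion: every contig
position is labelled `host` / `symbiont` / `both` / `neither` by span
coverage against the two indexes, and the switch points between host and
symbiont segments localise a fusion breakpoint. On divergent partners the
last fully-host window ends exactly at the breakpoint, so the switch point
lands within $k$ bases of the truth (typically within 1–2 bases; windows
straddling the joint belong to neither index and form a short `neither`
gap).

## Assembly metrics

`contig_metrics()` recomputes the per-category assembly statistics worth
reporting without an aligner: contig count, length extremes and mean, N50,
and GC. The N50 convention — the largest contig length $L$ present such
that contigs of length $\ge L$ hold at least half of all assembled bases —
is stated explicitly because tools differ on ties and parity; fidelity to
any specific assembly-evaluation tool is not claimed. GC is computed over
unambiguous A/C/G/T bases only. Remapping rates, ORF counts and functional
annotations require an aligner, an ORF caller and annotation databases;
those columns are deliberately absent rather than zero-filled.

## The synthetic generator

All validation runs on generated data with exact truth labels. The
generator emulates the structural features the classifier's contract
depends on:

* two partner transcript sets with a **conserved** fraction (identical
  copies — the origin of shared reads), a **homolog** fraction (diverged by
  independent per-base substitutions at the `divergence` rate), and
  partner-**unique** transcripts;
* reads of fixed length with uniform starts, a uniform per-base
  substitution `error_rate`, and reverse-complement emission with
  probability 0.5;
* incomplete banks, by whole-transcript subsampling or per-transcript
  truncation (see above);
* fusion contigs with recorded breakpoints, drawn uniformly from the middle
  60% of the contig, plus equal numbers of pure negatives.

Defaults (30 + 30 transcripts of 500–1500 bp, divergence 0.15, conserved
fraction 0.1, homolog fraction 0.3, 100-bp reads at 5× coverage, error rate
0.005) give a few thousand reads — large enough for stable percentages,
small enough that the whole suite runs in minutes; these are the problem
sizes the validations and the acceptance script use. The substitution-only
model (no indels) keeps true coverage exactly computable; uniform base
composition, absence of quality-score structure, of expression-level skew,
and of rRNA are acknowledged simplifications. Passing tests therefore
demonstrate the *method's* contracts (partition identity, monotonicity in
$s$, recovery at stated divergence, completeness sensitivity, FP bounds),
not performance on any real library: real banks differ in redundancy, GC,
contamination, and the divergence between real partners is not uniform
along transcripts.

At the default study conditions (divergence 0.15, $k = 25$, $s = 50$,
error-free reads, complete banks), reads from partner-unique transcripts
are recovered essentially perfectly and conserved-origin reads are labelled
shared; reads from *homologs* at that divergence occasionally retain an
error-free stretch matching the other partner long enough to cross the
threshold, and are then — correctly, per the rule — called shared. This is
why recovery statements are phrased over partner-unique and conserved
reads; homolog-origin reads are tracked as their own truth class.

## Determinism and numerical choices

Every generator accepts a seed and restores the caller's RNG state;
identical configuration gives byte-identical FASTA/FASTQ output. The
classifier is seed-free and deterministic: identical inputs and parameters
give byte-identical category files and reports. Degenerate inputs follow
the principle "empty in, empty out, no errors": empty banks build empty
exact indexes, empty read sets give all-zero reports, contigs shorter than
$k$ give all-`neither` profiles. Mismatched k-mer specifications between
the two indexes — or between an index dump and the expected $k$ — are
configuration errors, never silently reconciled.

## Known limitations

* Exactly two reference banks; the four-category model is hard-coded.
  Multi-partner holobionts must currently be handled pairwise.
* The in-process counter holds the solid set in memory; banks beyond
  desk scale (hundreds of Mbp) belong to dedicated external counters.
* Substitution-only simulation; indel robustness is untested.
* The fingerprint index is a slot/fingerprint table, not a true minimal
  perfect hash; its memory profile is not representative of one even
  though its membership contract is.
* Quality strings are carried through unchanged but never used; no
  quality-aware trimming or filtering is performed (that is upstream
  territory).
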