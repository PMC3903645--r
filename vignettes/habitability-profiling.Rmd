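---
title: "Profiling microbial habitability from environment-labelled 16S rRNA references"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling microbial habitability from environment-labelled 16S rRNA references}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhindex)
```

## The problem

Which environments can a given prokaryotic group inhabit? 16S rRNA surveys
of environmental samples answer the converse question ("who lives here?");
turning them around requires a reference in which every 16S rRNA sequence
carries the label of the environment it was sampled from. `mhindex`
implements both halves of that inversion:

1. **Reference condensation** — raw environment-tagged amplicon or
   metagenomic reads are filtered and collapsed into a compact set of
   *representative* sequences per environmental category.
2. **Habitability profiling** — a query 16S rRNA sequence is searched
   against the labelled reference and summarized as **Microbial
   Habitability Indices (MHIs)**: per-environment percentages at a ladder
   of identity thresholds.

## The MHI statistic

Let $N_c(e)$ be the number of significant hits labelled with environment
$e$ whose alignment identity is at least $c$, let $R(e)$ be the number of
reference sequences labelled $e$, and $R_\mathrm{total}$ the total
reference size. Then

$$
\mathrm{MHI}_c(e) \;=\; 100 \cdot
\frac{N_c(e)\,\log\!\big(R_\mathrm{total}/R(e)\big)}
     {\sum_{e'} N_c(e')\,\log\!\big(R_\mathrm{total}/R(e')\big)} .
$$

The logarithmic factor is an inverse-document-frequency style weight:
environments that contribute many sequences to the reference are expected
to appear among the hits by chance, so their counts are down-weighted.
Each threshold column is normalized to 100% by construction, which the
test suite asserts to $10^{-6}$. The implementation uses the natural
logarithm; because the weight enters numerator and denominator linearly,
any other base gives identical percentages (also a tested property).

The default thresholds $c \in \{0.97, 0.95, 0.90, 0.85, 0.80\}$
approximate species, genus, family, order and class resolution of 16S
identity. A threshold with no qualifying hit produces no column.
Environments below 1% are grouped under `other`. Two degenerate cases are
handled explicitly rather than silently: a single environment spanning the
whole store has weight $\log 1 = 0$, and an all-zero-weight column returns
a flagged empty result with a warning instead of dividing by zero.

Multiple queries can be profiled *collectively*. The primary mode sums the
per-environment hit counts across queries before one MHI computation;
because the statistic is scale-invariant in the counts (tested), profiling
the same query twice changes nothing. A secondary mode that averages the
per-query percentages is exposed behind `mode = "mean"` — the two coincide
for symmetric inputs but weight unequal queries differently; summing
counts is the default because it treats the queries as one pooled hit
list, the natural reading for multiple rRNA copies of one genome.

## Search and ranking

Queries are aligned to the reference by affine-gap local alignment
(match +2, mismatch −3, gap open 5, gap extend 2 — the common nucleotide
BLAST scoring) on both strands, with candidate subjects preselected by a
shared canonical 12-mer seed. Significance is a Karlin–Altschul e-value
$E = K\,m\,n\,e^{-\lambda S}$ with documented approximate constants
($\lambda = 0.625$, $K = 0.41$); hits above the cutoff (default
$10^{-10}$) are discarded and at most 10,000 hits are kept. The seed
prefilter cannot change results whenever a true hit shares at least one
seed; the suite verifies equality with an exhaustive all-pairs search on a
50-entry store.

Ranking is *not* by identity or e-value but by the ratio

$$ \text{sort key} \;=\; \frac{\text{matched bases}}
   {\text{full hit length} + \text{gaps opened in the hit}} , $$

which pushes short partial hits below full-length ones; this is why
queries are expected to be longer than the reference sequences and a
warning is emitted below 500 bp. Two readings of this ratio were possible
("aligned nucleotides" could mean matched bases or all aligned query
bases; "length of the hit sequence" could mean its full length or only
the aligned span). We use matched bases over full hit length plus hit
gaps: it is the only combination under which a partial hit can never
outrank a full-length hit of equal quality. Identity for thresholding is
the separate conventional quantity matches / alignment columns.

## Reference condensation

Per environment, QC-passed reads go through four stages:

* **Near-duplicate removal (99%)** — greedy, longest-first clustering with
  5′-anchored overlap identity (the shorter read as a near-prefix of the
  longer), the convention for removing artificial duplicates from
  pyrosequencing amplicon data. Representatives are the longest members.
* **rRNA screening** — a read is kept if the fraction of its distinct
  canonical 15-mers shared with a user-supplied screening FASTA reaches
  0.2. At that default, a true 16S fragment 10% diverged from the nearest
  screening sequence still passes ($0.9^{15} \approx 0.21$ expected),
  while unrelated sequence scores near zero.
* **Chimera removal** — see below.
* **Species-level clustering (97%)** — greedy, longest-first centroid
  clustering; identity is matches / alignment columns of the best local
  alignment, and the alignment must cover ≥ 90% of the shorter sequence
  so that a tiny overlap can never join two clusters. 97% is the accepted
  species boundary for prokaryotic 16S rRNA; clustering within (not
  across) environments preserves the per-environment counts $R(e)$ that
  the MHI weighting needs.

Greedy order is always longest-first with ties broken by id, so outputs
are deterministic.

### The two-parent chimera test

For each breakpoint on a 10-bp grid (excluding 50 bp at each end), the
read's left segment is matched against its best ungapped-aligning
candidate parent and the right segment against the best *different*
candidate; uncovered positions count as mismatches and a candidate must
cover ≥ 90% of a segment to be eligible. The read is called chimeric when
the best two-parent model beats the best single parent by a margin
(default 0.02) *and* each parent explains its own segment at ≥ 0.9
identity. The second condition matters: without it, a distant relative at
~86% identity can prop up one short segment of what is otherwise a
single-parent alignment and produce false positives.

Inside `build_reference` the screen is sequential in longest-first order:
a representative is tested only against representatives already accepted
as non-chimeric. This prevents two chimeras with the same parent pair
from vouching for each other (each would otherwise be the other's perfect
"single parent") and means a chimera can never act as anyone's parent.
Candidate parents are *all* accepted representatives rather than only
multi-member clusters: at the corpus sizes this package targets, an
abundance gate can leave a parent template without any eligible candidate,
while the per-segment identity floor plus the improvement margin already
prevent genuine reads from being assembled into a two-parent model.

Known limitation: when two templates are *locally* very similar
(≥ ~93–94% over the segment a chimera inherits from its minority parent),
the two-parent improvement falls below the margin and the chimera is
missed. This is inherent to breakpoint-model chimera detection at a fixed
margin, not specific to this implementation; at the default simulation
conditions it affects roughly one read in a few hundred.

## Read quality control

Stages run in a fixed order — 3′ quality trimming (Phred < 20 suffix),
3′ adapter removal (semi-global, ≥ 3 bp overlap, ≤ 10% mismatches),
discarding reads with any ambiguous base, truncation at the first
homopolymer run ≥ 5 bp — and after *every trimming stage* reads shorter
than 200 bp are removed and attributed to that stage, so the report's
per-stage counts partition the input exactly (asserted on every run).
Quality trimming is 3′-only because pyrosequencing-style error
accumulates at the 3′ end; "removing" ambiguous reads (rather than
trimming them) and truncating at (rather than excising) homopolymer runs
are the two interpretations that keep every output read a prefix of its
input read, which the suite checks as an invariant. Each filter is
idempotent.

## What the synthetic generator emulates — and what it does not

`sim_params()` defines the package's reference study conditions: two
environments × five templates, 1000-bp templates at ~15% pairwise
divergence (comfortably beyond the species radius, so template recovery
is unambiguous), 200 reads of 250–400 bp at 1% divergence from their
template, with 15% planted duplicates, 5% chimeras, 5% short inserts and
5% ambiguous reads, a 12-bp adapter and a sub-Phred-20 3′ tail on every
read. These sizes keep the full pipeline-recovery check and the 100-query
habitat-recovery check inside a few minutes on one core.

Three deliberate idealizations make the ground truth *exactly*
recoverable, and they are what passing tests do and do not show:

* **Reads are 5′-anchored template prefixes**, as in primer-anchored
  amplicon sequencing. This is what makes prefix-based duplicate removal
  meaningful and guarantees that same-template reads overlap fully for
  the 97% clustering.
* **Read mutations sit on per-read strided position lattices** (stride
  = 1/divergence, distinct offsets per read) instead of iid positions.
  Two same-template reads then diverge by almost exactly 2%, which lies
  deterministically *between* the 99% duplicate threshold and the 97%
  species threshold. With iid placement at these read lengths, pairwise
  divergence straddles both thresholds with non-negligible probability
  and exact per-stage count recovery would be a matter of luck rather
  than a property.
* **No sequence ever contains a homopolymer run ≥ 5 bp** (templates have
  no adjacent repeats; substitutions avoid both neighbours; chimera
  junctions cannot bridge runs). The homopolymer filter therefore fires
  only in its own unit tests, keeping the per-stage accounting of the
  pipeline test clean.

Real amplicon data have none of these properties: positions mutate
independently, reads start at several primer sites, quality decays
noisily, and indels occur (the generator is substitution-only by
default). Pipeline-recovery tests therefore demonstrate correctness of
the *bookkeeping and thresholds*, not field-realistic accuracy. The
screening reference emitted with a simulated corpus is the template set
itself; screen *discrimination* (rejecting non-rRNA sequence) is
exercised separately in unit tests.

Queries are drawn with iid mutations (their mismatch counts are
binomial, as recovery statistics assume). Habitat-recovery checks profile
queries at 1.5% divergence — within the ≤ 2% "same species" regime but
off the boundary itself, since at exactly 2% the per-hit identity
distribution is centred on the 97% cutoff and the measurement becomes a
coin-flip on the boundary rather than a habitat-recovery test. Against a
template-derived reference, recovery is ≥ 95% by a wide margin; against
the pipeline-condensed store (whose representatives carry their own ~1%
read divergence) the same queries sit at the species boundary and recover
~80–85%, a number `scripts/acceptance.R` reports separately.

## Numerical and interface choices

* Thresholds are inclusive (identity ≥ c counts), matching the
  97%-species convention of counting boundary ties.
* All randomness in the generator flows from one integer seed; reruns
  are byte-identical, and the command-line tools embed a provenance
  header (package version and parameters, deliberately no timestamps) so
  identical invocations produce identical files.
* The reference FASTA header grammar is `>{env}.{ordinal}` with the
  *final* dot as separator, so category labels may contain spaces or
  dots (`human gut.12`).
* FASTQ is fixed at Phred+33; records with other encodings or missing
  quality strings are rejected rather than guessed at.
* Text statistics print two decimals in descending MHI order, one line
  per threshold (`(97%, 36 hits) freshwater: 88.15%; marine: 11.85%`);
  JSON carries full precision.

## Worked example

```{r example, eval = FALSE}
p <- sim_params(seed = 1)
corpus <- simulate_corpus(p)
qc <- lapply(sim_reads_by_env(corpus), function(r) {
  run_qc(r, qc_params(adapters = p$adapter))$records
})
store <- build_reference(qc, corpus$screen_ref)
store
q <- generate_query(corpus$templates, "soil", divergence = 0.01,
                    length = 600, seed = 99)
profile_query(q, store)
```

The same flow is available from the shell through `exec/mhindex`
(`simulate`, `build-ref`, `query` subcommands); see the README for the
commands and their output.
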