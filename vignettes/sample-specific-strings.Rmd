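---
title: "Detecting sample-specific strings with sfstools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sample-specific strings with sfstools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Given two sequenced samples -- a *target* read set $T$ and a *reference*
set $R$ (reads, assembled genomes, or a mix) -- every genomic difference
between the underlying genomes leaves a trace: some substring of a target
read spans the difference and therefore occurs nowhere in the references.
Enumerating *all* such substrings is hopeless (their number is quadratic in
the length of $T$), so sfstools computes the **substring-free** subset: the
strings present in $T$, absent from $R$, none of which contains a shorter
string with the same property.  These minimal witnesses, one per viable
start position, are the *sample-specific strings* (SFS).  Because membership
is decided by exact string matching against the reference reads themselves,
the approach needs no read mapping, no reference genome and no fixed k-mer
size; with accurate long reads (HiFi-scale, ~0.1% error) it recovers
sequence evidence for nearly all variants segregating between two samples,
including structural variants whose breakpoints defeat coordinate-based
comparison.

## The index

Membership queries are served by an FMD-index: a single FM-index built over
the reference strings *and their reverse complements*, each terminated by a
sentinel that sorts below every base.  A string $Q$ is represented by a
bi-interval $[i, j, l]$: the suffix-array interval of $Q$, the interval of
its reverse complement, and their common width $l$, which equals the number
of occurrences of $Q$ in the indexed text ($l = 0$ means $Q$ is absent from
both strands).  Two constant-time operations extend a bi-interval by one
character: *backward* extension ($Q \to \sigma Q$) and *forward* extension
($Q \to Q\sigma$), the latter implemented as a backward extension of the
complement on the paired interval with the two interval roles swapped.

Construction is deliberately plain: an SA-IS suffix array over the
concatenated collection, the BWT read off it, and checkpointed rank tables
(one checkpoint per 64 positions).  Correctness, not compression, is the
contract here; the backend is replaceable.

The package also offers a **single-strand** mode in which reverse
complements are *not* indexed.  Forward extension then needs a second
direction, so the index keeps a second BWT over the reversed strings and the
paired interval tracks $\mathrm{reverse}(Q)$ instead of the reverse
complement.  This mode exists because the edit-distance bound below is a
statement about a plain string pair; with reverse complements indexed,
palindromic chance matches would obscure it.  It is an extension beyond the
original formulation, clearly flagged as such.

### Handling of non-ACGT input

Exact matching over ambiguous bases is undefined, so every input sequence is
uppercased and split at maximal runs of non-A/C/G/T characters (including
`N`) into clean fragments, both when indexing and when searching.  A string
spanning a removed run can therefore never be reported; a record left with
no A/C/G/T content is skipped with a warning.  How the original
implementation treats such bases is not documented; splitting is this
package's own, conservative choice.

## The Ping-Pong search

For one target $t$, the search keeps two cursors $b$ (begin) and $e$ (end)
and a bi-interval, alternating two steps:

1. **Backward:** starting from the current interval, prepend $t[b-1]$,
   $t[b-2]$, ... until the interval empties.  If instead the search reaches
   the start of $t$ with a non-empty interval, the remaining prefix occurs
   in the references and nothing further can be specific: the search stops.
   (In particular, if all of $t$ occurs in the index the output is empty.)
2. **Forward:** the mismatch position $b$ starts a specific string.
   Reinitialize the interval to the single character $t[b]$ and append
   $t[b+1], t[b+2], \dots$ until the interval empties at position $e$; emit
   $t[b..e]$, the shortest substring of $t$ starting at $b$ that is absent
   from the references.

In **exact** mode the interval saved just before the failing forward
extension (the interval of $t[b..e-1]$, which does occur) seeds the next
backward step, so consecutive solutions may overlap on $t$ and every start
position that admits a specific string produces one.  No two emissions share
a start position, the distinct emissions are substring-free, and on random
instances the output provably matches a brute-force solver.  The worst case
is quadratic: heavily overlapping solutions can each have linear length.

In **relaxed** mode the saved interval is discarded and the search restarts
from one position left of the last emission's start, with the interval
reinitialized to that single character.  Emissions then occupy pairwise
disjoint intervals, at most two extension queries are spent per symbol of
$t$ (linear time), and -- because disjoint emissions each consume at least
one edit -- the number of emissions for a pair $(t, r)$ is bounded by their
Levenshtein distance.  The relaxed output is a subset of the exact solution;
whether it is always minimal against the full candidate set is not obvious
from the construction, so the tests assert membership and disjointness only.

One degenerate case needs a rule the pseudocode leaves open: if the single
character $t[b]$ is itself absent from the index, the length-1 string *is*
the specific string at $b$; it is emitted directly and the search resumes
one position to the left with a fresh initialization (both modes).

Also note a deliberate reading of the restart rule in relaxed mode: a
literal substitution into the pseudocode would both reinitialize *at* and
re-extend *with* the same character, consuming it twice; the implementation
restarts so that the next backward extension prepends the character two left
of the emission start, which is the documented intent.

### Counting and canonicalization

Targets are processed independently (the per-target solutions union to the
collection-level solution), so the search parallelizes trivially; the
package exposes this as a `chunks` argument whose value provably cannot
change the output.  Every emission event increments the count of its
sequence -- the same string seen at two positions, or from two reads, counts
twice.  Counts are keyed by the lexicographic minimum of a sequence and its
reverse complement: reads are strand-agnostic and, against a both-strands
index, a string is specific exactly when its reverse complement is, so the
two spellings describe the same event.  (Whether the original
implementation collapses strands when counting is unstated; this is the
package's convention, applied consistently.)  The abundance filter `tau`
then removes strings seen fewer than `tau` times, the standard guard
against sequencing-error artifacts.  Output ordering is deterministic:
descending count, then lexicographic.

## The brute-force oracle

`oracle_sfs()` re-solves the problem by enumeration: hash every substring of
the references (both strands if applicable, capped at the target length,
since no specific string can be longer than its target), collect the
substrings of $t$ absent from that set, and keep a string iff both of its
one-shorter substrings are present (or it has length 1).  A second,
independently coded construction -- per start position, binary-search the
shortest absent prefix with fixed-string matching, then discard dominated
intervals -- must agree with it, and the index-based search must agree with
both.  The oracle enforces a size guard (~2000 total characters) and is
test-only by design.

## The trio simulator

The simulator builds the smallest world in which precision and recall of de
novo SV detection are decidable *without alignment*:

* a uniform random ancestral genome (default test scale: 50 kb);
* a pool of inherited variants (SNPs and 1-50 bp indels, 20 by default)
  assigned to parents with random zygosity;
* each child haplotype copies one parental haplotype verbatim
  (`recombination = FALSE`, the default) -- crossovers are available behind
  a flag but create junctions novel to the parental *reads*, which would
  contaminate a precision defined as "fraction of child-specific strings
  covering a de novo variant";
* de novo SVs (20 by default, 50-500 bp, insertions/deletions/inversions in
  as-equal-as-possible numbers) injected into child haplotypes only.

All variants are placed without overlap on ancestral coordinates, so every
haplotype is one pass of edits over the same genome, and liftover between
haplotype and ancestral coordinates is exact outside variant intervals.
Reads are drawn per haplotype with uniform starts and truncated-normal
lengths (10 kb +- 2 kb, min 1 kb, scaled down proportionally for haplotypes
shorter than five mean read lengths) until the target coverage is met;
coordinates are recorded before optional error injection (substitutions,
insertions, deletions 6:2:2 -- the mix is not documented for real
instruments, matters little at the 0.1% HiFi-like total rate, and is
configurable).

Two choices compensate for desk scale and deserve emphasis:

* **Boundary-clipped read sampling.** Read starts are drawn from
  $[-(L-1), H-1]$ and clipped to the haplotype, so coverage is uniform up to
  the sequence ends.  Sampling starts only inside $[0, H-L]$ -- harmless on
  a 200 Mb chromosome -- leaves the first and last read-length of a 50 kb
  haplotype contained in almost no read, which both hides variants placed
  there (recall loss) and makes ordinary inherited sequence near the edges
  look child-specific (precision loss).  Clipping removes the artifact
  rather than papering over it in the metric.
* **Variant placement margin.** Variants additionally keep a margin
  (default 10% of the genome length) from each end, for the same reason.

What a green simulation test does *not* establish: behaviour on repetitive
genomes (the ancestral sequence is i.i.d. uniform, so 17-mers are
essentially unique), realistic SV size spectra, quality-score-aware errors,
or recall in the presence of variants that genuinely create no novel
sequence -- the random world essentially never produces those, which is why
recall here sits at 100% rather than the published ~98.7% of a
chromosome-scale run.

## Evaluation

`evaluate_simulation()` lifts each retained emission from read to haplotype
coordinates (exact for error-free reads; for error-injected reads the
pre-error interval is used, a documented approximation) and intersects it
with the truth placements, breakpoints inclusive: an emission $[h_s, h_e)$
covers a variant at $[v_s, v_e)$ iff $h_s \le v_e$ and $h_e \ge v_s$.  For
a deletion, $v_s = v_e$ is the junction point.  Precision is the fraction
of retained emission *occurrences* covering at least one de novo variant
(a per-distinct-sequence figure is reported alongside); recall is the
fraction of de novo variants covered at least once.  With error-free reads,
no recombination and `tau = 5`, every retained child-specific string traces
back to a de novo variant -- the simulation analogue of the published
100.0% error-free precision -- and all 20 default variants are recovered.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open everywhere outside the search core; the
  algorithm's inclusive ends are converted at the boundary.
* Sentinels separate indexed fragments and never match query symbols, so
  matches cannot span two reads.
* Extending an empty bi-interval yields an empty bi-interval; widths are
  monotone non-increasing under extension on either side.
* Empty collections, empty queries and non-ACGT queries are errors, not
  silent empties; an index file with a wrong magic, version or truncated
  payload is rejected explicitly.
* All simulator randomness flows from explicit seeds through named
  substreams (genome, variants, reads), and every seeded function restores
  the caller's RNG state.

## Known limitations

* The exact search is quadratic in the worst case by design; no attempt is
  made to detect adversarial inputs.
* The index is plain (uncompressed BWT, int32 positions): collections are
  limited to ~2 Gb of indexed text and desk-scale memory.
* Specific strings spanning removed non-ACGT runs are unreportable.
* The relaxed mode's output is not guaranteed minimal against the full
  candidate set (only specific and disjoint); treat its counts accordingly.
* Error-injected reads shift coordinates slightly; evaluation against
  errorful reads is approximate by the length of the injected indels.
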