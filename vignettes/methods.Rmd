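---
title: "Pin-anchored read mapping: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pin-anchored read mapping: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of what it computes and why its
defaults are what they are. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## The index

The reference plus strand is scanned for k-mers (words); each word is
encoded base-4 with the 5'-most base most significant and hashed by the
MurmurHash3 64-bit finalizer (`fmix64`), reduced modulo a prime table size
H. We fix murmur64 to the finalizer rather than the full streamed hash
because a word's encoding is already a single 64-bit value and the
finalizer gives a one-line, bit-exact contract; the test suite checks it
against an independent implementation written in 16-bit limb arithmetic.

Each of the H rows is five bytes — a tally byte and a 32-bit value — so a
human-scale index stays close to 25 GB while desk-scale indexes are a few
megabytes. The tally's high bit means "slot present". Concrete codes:
`0xFF` pin, `0xFE` singleton, `0x81`–`0xFC` multi-list head with a 7-bit
forward skip of 1–124 rows, `0xFD` head whose skip overflows into the
value field as an absolute row pointer; interior list rows (present bit
clear) use `0x01`–`0x7D` as skips, `0x7E` for the list end and `0x7F` for
pointer overflow; `0x00` is empty. Interior rows are allocated from the
nearest empty rows scanning forward from the head, wrapping at H. Exact
values for the reserved codes are this package's choice; only the
present-bit convention and the 7-bit skip budget are structural.

Three classifications matter to search. A *pin* occurs exactly once in the
reference counting both strands, so a pin found in a read implies a single
candidate placement. A *singleton* occurs once on the plus strand but its
reverse complement also occurs, implying at least two candidates. Slots
with more than t occurrences on either strand are *excluded*: abundant
words are almost always repetitive and would multiply candidate alignments
for little sensitivity gain, and counting the minus strand prevents
over-confident placements of words that are rare on the plus strand but
common on the minus. Exclusion leaves no trace in the table — an excluded
slot's row is reusable for list storage — so decoding reports it as
absent; the distinction exists only at build time.

Hash collisions merge position lists silently. Verification is delegated
to alignment: a collided candidate is abandoned after a handful of
mismatching flank columns, which costs less than storing disambiguation
bytes for every slot.

### Table size

`choose_table_size()` returns the smallest prime at least 1.6× the
reference length, floored at 65,537. The ratio mirrors the recommended
human-genome setting (a 5·10⁹-row table for a ~3.1 Gb genome). At desk
scale the floor dominates, and collision rates are then appreciable: with
a 10 kb genome, about 20,000 strand-words hash into 65,537 rows, so only
roughly three quarters of slots are collision-free pins even though almost
every 24-mer is unique as a string. Properties that assert the
*near-unique regime* (for instance "at least 99% of slots are pins on
i.i.d. genomes") therefore build their indexes with an explicit H of a few
hundred times the genome length; this is a statement about hash-collision
rates, not about the genome.

## The search

For a read of length L there are n = L − k + 1 words. They are visited in
the order `(stride · j) mod n`, with the stride the smallest prime at
least k + 5 (29 for k = 24, L = 150); if that prime divides n the next
prime is taken so the schedule stays a permutation for every read length.
Neighbouring words share k − 1 bases, so a failed word predicts failure of
its neighbours; striding ahead finds informative words sooner.

Pass 1 (braces) walks the two mates' pins alternately — next pin in R1,
then next pin in R2 — and screens each pair on coordinates alone: same
reference sequence, opposite query strands consistent with FR orientation,
implied fragment length in (0, `max_frag`]. Only survivors are aligned. A
*good brace* — both mates align with score at least |Q| − `good_margin` —
terminates the search immediately: the chance that a different placement
beats two agreeing pins is negligible, and this is what makes typical
pairs cost one row fetch per scheduled word. For single-end reads a brace
is two non-overlapping pins within the read on the same strand whose
implied placements agree within `diag_tol`.

Pass 2 seeds from remaining slots with abundance ≤ 2; pass 3 from the rest
up to t. Two deliberate interpretations:

* Pins that pass 1 never aligned (for example when the mate has no pins at
  all, so no brace candidate ever formed) are included in pass 2.
  Excluding them would leave a read's unique locus untried whenever its
  mate is uninformative, which cannot be the intent of prioritising
  low-abundance seeds; attempted locations are cached, so nothing is ever
  aligned twice.
* Early termination applies after all positions of the current slot have
  been attempted, not after the first high-scoring alignment. The
  positions of one slot are exactly the copies of one repeated word; if a
  read lies in an exact two-copy repeat, both copies must surface so the
  tie forces S = T and MAPQ 0. Terminating inside the position list would
  hide the ambiguity and report unwarranted confidence.

Alignment attempts record failed locations, and both accepted and failed
locations are deduplicated within `diag_tol` (16 bases, matching the band
width) so a location is extended at most once per read.

### Alignment and scoring

Seeds extend gaplessly in both directions under an x-drop rule: stop a
direction when the running score falls more than x below its maximum. The
seed block itself is counted as k matches without verification — collided
seeds are caught by their flanks. If the extension covers the whole query
it is promoted directly to an alignment (rescored column by column, which
also corrects the rare collided-but-flank-compatible case); otherwise the
top HSPs (up to `max_gapped` = 4) are extended by banded affine
semi-global DP: the entire query must be aligned, the reference window is
free at both ends, and cells are restricted to a band around the HSP
diagonal. With the band spanning the whole matrix this reduces to textbook
semi-global DP, which is how it is tested.

Scoring defaults are match +1, mismatch −2, gap open −4, gap extend −1
(a gap of length g costs 4 + g), x-drop 16, band 16, HSP acceptance at
half the query length. Only match = +1 is structural — the MAPQ formula
needs T/|Q| to range over [0, 1]; the rest are declared BLAST-like values,
exposed in `scoring_scheme()` and as CLI flags. MAPQ is rounded half up
and clamped to the SAM range [0, 254]. `veryfast` is an accuracy/speed
preset: abundance cap 3 (canonically at index build; enforced at search
time against a default index, with a warning), x-drop 8, no third pass, at
most 2 gapped extensions per read. Only the abundance cap is structural to
the preset; the rest are this package's reading of "tweaks to heuristic
parameters".

### Pairing and MAPQ

After the passes, the FR-consistent alignment pair maximising T₁ + T₂
within `max_frag` is chosen (proper pair); otherwise each mate keeps its
best alignment and the pair is flagged discordant. S is the best score at
a different locus; absent that, S = T/2 — a prior reflecting that early
termination deliberately avoids looking for second-best alignments, so "no
second alignment seen" is much weaker evidence than "none exists". If
pairing chooses a non-top alignment for a mate, S is clamped to T, again
surfacing ambiguity as MAPQ 0. There is no mate-rescue alignment pass:
a mate that cannot be placed from its own seeds is reported unmapped
rather than forced into the expected window.

## The benchmark

The simulator draws ten read pairs per locus, each pair placed uniformly
among fragments in which R1 or R2 contains the locus; anchoring all ten on
one position is what lets systematic errors (most reads of a locus agreeing
on the same wrong placement) be told apart from scattered ones. Reference
loci are uniform random positions; variant loci are variant positions in
the haplotype that carries them, so every variant-genome read overlaps at
least one variant. Fragment lengths follow Normal(350, 35) truncated to
[L, 1000]. Which physical end is read 1 is a per-pair coin flip.

The diploid genome applies phased variants to their haplotype and assigns
unphased ones by seeded coin flip; monotone coordinate maps through indels
take each haplotype position back to the reference, with inserted bases
collapsing to the insertion point. Substitution errors are injected with
probability 10^(−q/10) per base; indel errors are not injected (they are
rare on the platform being modelled, and the variant genome already
carries indels). Quality strings come from a donor FASTQ when provided;
the built-in synthetic profile holds mean Q38 for cycles 1–100 decaying
linearly to Q25 at cycle 150, Gaussian jitter (sd 3) clamped to [2, 41] —
a stand-in with position-dependent decay but none of a real run's cycle
artefacts or tile effects.

Scoring: a read is *confident* iff MAPQ ≥ 10; *correct* iff on the right
sequence and strand within 10 bases of truth (the tolerance absorbs
indel-induced start shifts; it is configurable). The per-locus metrics use
different denominators by design: S_l divides loci whose ≥3 confident
reads have a correct majority by *all* loci (a locus drowned in
low-confidence reads is a sensitivity failure), while E_l divides
same-wrong-majority loci by loci *with* ≥3 confident reads (a systematic
error can only be charged where there was confident evidence). "Majority"
is strictly more than half; wrong placements are clustered with the same
10-base tolerance before the majority test, so a locus systematically
mapped to one wrong repeat copy is counted once. With zero confident reads
E_r is 0; with zero qualifying loci E_l is 0.

Pairwise method comparison follows the benchmark's notation: MI is the
mean of (S_X − S_Y) − (E_X − E_Y) over the four genome×granularity
combinations, IM counts strictly-better metrics of eight, TI sums MI over
opponents; `X >>(MI) Y` when all eight are better, `<<` when all worse,
otherwise `>IMxy` or `<IMyx` by the majority direction (ties render with
`>`). Calibration tables report q_measured = −10·log₁₀(n_err/n) per
reported MAPQ with at least 50 reads, `Inf` when no errors were observed.

## Mappability

Error-free pairs are simulated at 10× read depth (fragment 350, L = 150)
and mapped; a base is mappable iff covered by at least one read — either
mate, each with its own MAPQ — with MAPQ ≥ Q. Unmappable regions are
maximal unmappable runs of length ≥ L in which every length-L window has
fewer than 10 uncalled bases; a region failing the window rule anywhere is
rejected whole, so N-runs do not masquerade as interesting unmappable
sequence. Q defaults to 3 (P_error ≥ 0.5, unusable downstream). Placement
is deterministic tiling at spacing 2L/depth by default — reproducible and
gap-free — with seeded random placement available; the scan returns its
raw placements so several thresholds can be evaluated from one mapping
run. Consensus across configurations is base-level interval intersection.

A planted exact duplication of length D leaves an unmappable core of about
D − 2(L − 1) bases per copy: reads overlapping a boundary are unique and
confident, so only bases reachable solely by fully-interior reads go
unmappable. Duplications shorter than ~2L therefore produce no reportable
region — a property of the definition, not a detection failure.

## Synthetic fixtures

`make_genome()` plants features in an i.i.d. random backbone at recorded
coordinates: exact repeats (expected slot status `multi` at the copy
number), inverted repeats (`singleton` — the reverse complement occurs on
the plus strand), N-runs (not indexed), and words repeated past t
(`excluded`). `make_variants()` draws clustered positions (Poisson cluster
centres, geometric within-cluster spacing, mean cluster size 4 at ~30 bp
spacing) because real variants cluster and multi-variant reads are the
challenging case; plain geometric spacing is available for comparison with
Poisson-style simulators. SNP:indel ratio defaults to 9:1, indels 1–6 bp.

What the fixtures do not emulate: repeat families with internal divergence
(Alu/LINE-like), GC or coverage bias, real base-call error correlation
beyond position-dependent quality decay, and chromosome-scale structure.
Passing tests on these fixtures therefore demonstrates the algorithmic
contracts — census-exact indexing, oracle-equal alignment, tie handling,
metric definitions — not performance on real genomes.

## Numerical and engineering choices

* Coordinates are 0-based half-open internally; 1-based conversion happens
  once, at SAM serialisation. Coordinates cross the R/C++ boundary as
  doubles (exact far beyond any 32-bit reference).
* `encode_word()` at the R level is limited to words of ≤ 26 nt so the
  encoding stays exact in a double; the compiled index path carries full
  64-bit values for the whole supported k range of 8–31.
* Phred+33 is the only quality encoding; lowercase reference bases are
  uppercased and any IUPAC wildcard becomes N; words containing N are
  neither indexed nor queried, and N never matches in alignment.
* MAPQ rounds half up (the formula's natural reading); ties for the best
  alignment keep the first in scan order and force S = T.
* The on-disk index container is little-endian with magic `PMAPIDX1`,
  format version, parameters, catalogue, packed genome and exactly 5·H row
  bytes; decode validates pointers, detects chain cycles and interior rows
  claiming head status.
* All randomness flows through explicit seeds (`with_seed` restores the
  caller's RNG state); the mapper itself is deterministic, so identical
  inputs give byte-identical SAM.

## Problem sizes used by the tests

The suite runs on genomes from 200 bases (exhaustive census comparisons)
through 3–30 kb (adversarial index fixtures, mappability scans) to 1 Mb
(end-to-end mapping and the benchmark pipeline with 200 loci × 10 pairs);
alignment oracles use 50 random instances of up to 200 nt against full
unbanded DP. These sizes were chosen so that brute-force oracles remain
exact and the whole suite completes in a couple of minutes while still
crossing every code path, including 7-bit-skip overflows in index lists
(forced by a crafted genome whose filler words occupy all 126 rows after a
repeated word's slot).

## Known limitations

* References must stay below 2³² bases (32-bit coordinates in rows); the
  five-pointer-byte extension for larger references is not implemented.
* No mate rescue, no split/chimeric alignments, no secondary or
  supplementary SAM records, no BAM/CRAM output.
* Search passes run per read after the joint brace pass; base qualities do
  not influence alignment scores.
* The per-thread buffer of the original design is modelled as a per-query
  cache contract (each head row fetched once in pass 1, lists chased
  lazily and cached); actual multi-threading is out of scope beyond
  read-chunk parallelism being embarrassingly parallel.
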