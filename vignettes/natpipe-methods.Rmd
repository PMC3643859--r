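---
title: "natpipe: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{natpipe: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`natpipe` implements a desk-scale, fully testable pipeline for natural
antisense transcript (NAT) analysis in plant transcriptomes: predicting
sense/antisense pairs from a transcript set, classifying them as *cis*
(convergent, divergent, enclosed) or *trans* from gene coordinates,
profiling NAT-derived small RNAs (strand bias, enrichment of small RNA
loci in the overlap region), calling nat-siRNA cleavage targets from
degradome (PARE) 5' tags with a position-specific mismatch rule, and
screening NAT transcripts for pre-miRNA-like stem-loops. A seeded
synthetic-data generator with a ground-truth manifest makes every stage
verifiable without external downloads.

# NAT prediction

## Model

Two transcripts form a NAT pair when one carries a near-perfect reverse
complement of a stretch of the other. We detect this with ungapped
seed-and-extend local alignment of each sequence against the reverse
complement of the other: exact 11-mer seeds, X-drop extension (drop 20)
under +1/−2 scoring. NAT overlaps are near-identity complementary
blocks, so an ungapped model suffices and keeps the significance
calculation closed-form.

Significance uses the gapless Karlin–Altschul form

$$E = K \, m \, n \, e^{-\lambda S},$$

with $m, n$ the transcript lengths and $S$ the block score. For +1/−2
scoring at uniform base composition, $\lambda$ solves
$0.25 e^{\lambda} + 0.75 e^{-2\lambda} = 1$, giving
$\lambda = \ln\!\big((3+\sqrt{21})/2\big) \approx 1.3328$; $K = 0.621$.
A pair is called when the best block has $E \le 10^{-9}$, length
$\ge 31$ nt and identity $\ge 0.95$. The length floor matches the
smallest overlap reported in the soybean NAT literature this pipeline
is modelled on (31 bp); all thresholds are `alignment_params()` knobs.

Seeding is lossless for threshold-passing blocks: a block of length
$L \ge 31$ at $\ge 95\%$ identity has at most $\lfloor L/20 \rfloor$
mismatches, so by pigeonhole it contains an exact run of
$\ge 19L/(L+20) \ge 11$ nt.

One best block is kept per pair (highest score, ties to the leftmost
start on the first transcript); multiple discrete complementary regions
between the same two transcripts are collapsed to the best.

## cis/trans classification

A pair is *cis* iff the two genes sit on the same chromosome, their
genomic spans overlap by at least 1 bp, and their annotated strands are
opposite; anything else — including same-strand genomic overlap, which
is sequence-level complementarity via an inverted repeat rather than
transcription from opposite strands of one locus — is *trans*. Cis
geometry is typed from gene spans alone: *enclosed* when one span
contains the other, otherwise *convergent* when the plus-strand gene
starts first (the shared region covers both 3' ends) and *divergent*
when the minus-strand gene starts first (both 5' ends). Spliced 3'/5'
ends are not recoverable from span data, so span order plus strand is
the whole decision; equal starts or equal ends imply containment, so
the three classes are exhaustive and mutually exclusive — a property
the test suite checks against an independent decision table on 10,000
random geometries.

# Small RNA profiling

Reads are screened against optional exclusion sets (structural ncRNAs,
transposable elements): a read is removed iff its sequence or reverse
complement occurs exactly inside any exclusion sequence. Mapping is
exact, full-length and sense-only; the antisense partner is its own
transcript. Multi-mapping reads count at every placement for per-pair
statistics and once for library-level unique tallies.

Per pair, strand bias is the ratio of read abundances between the two
transcripts: `One` when only one transcript produced reads, `Equal`
when the ratio lies in $[0.5, 2]$ (boundaries inclusive), `Bias`
otherwise. Both abundance-weighted and unique-sequence ratios are
available; the abundance weighting is the default.

Enrichment of small RNA production in the double-stranded overlap
region uses locus densities. With $N_o$ unique small RNA loci (distinct
sequence/transcript/position placements) in the overlap of summed
length $L_o$ (both transcripts, i.e. twice the block length), and $N_t$
loci over the whole pair of summed length $L_t$:

$$D_o = N_o / L_o, \quad D_t = N_t / L_t, \quad
  \text{score} = D_o / D_t,$$

with a 1-df chi-squared goodness-of-fit test of $(N_o, N_t - N_o)$
against the uniform expectation $(N_t L_o/L_t, N_t(1 - L_o/L_t))$.
Densities are emitted per kilobase in output tables. A hit is "in the
overlap" iff its start position lies in the overlap interval — an
unambiguous rule for boundary-straddling reads. Across pairs, $D_o$ is
compared with $D_t$ by a paired t-test (both densities are measured on
the same pair).

Two calibration facts matter for interpreting the score:

* Under a per-base sampling rate $f$-fold higher inside the overlap,
  the expected pooled score is $f / (1 + (f-1) L_o/L_t)$, not $f$: the
  denominator density $D_t$ includes the overlap itself. The
  "recovers $f$ within 15%" acceptance property is therefore stated in
  the small-overlap regime ($L_o/L_t \approx 0.025$: 31–60 nt overlaps
  on ~2 kb transcripts), where the attenuation is inside the band.
* Two geometries concentrate reads in the overlap for reasons
  unrelated to $f$, and are excluded from the calibration worlds (but
  not from the end-to-end world): the antisense gene of an *enclosed*
  pair is wall-to-wall overlap, so every read it produces is an
  overlap read; and members of a trans family carry identical overlap
  blocks, so overlap reads multi-map across sibling pairs while
  non-overlap reads stay private.

# Degradome target calling

Degradome 5' tags are mapped exactly onto NAT transcripts. Around each
tag the "long degradome" window — the tag footprint ±20 nt, clipped at
transcript ends — is extracted, and every NAT-derived small RNA is slid
along it allowing up to three substitutions and no indels. Mismatch
positions are reported in siRNA coordinates with position 1 at the
siRNA 5' end, which pairs the 3'-most base of the site (the standard
convention for plant small RNA target rules; the tag 5' end is *not*
required to sit opposite positions 10/11, since the procedure searches
the whole window). A candidate is accepted iff

* at most one mismatch in positions 1–9,
* no mismatch at positions 10–11 (the cleavage-defining duplex core),
* at most two mismatches after position 11.

G:U wobble counts as a full mismatch by default; `gu_half = TRUE`
downgrades it to half weight for exploratory use. Calls are
deduplicated on (siRNA, transcript, site) with degradome support
summed, and origin-coded: `a` when the target forms a NAT pair with a
transcript the siRNA derives from, `s` when the siRNA derives from the
target itself, `o` otherwise; siRNAs carried by more than five
transcripts are flagged `multiple`. Because the degradome is mapped
onto NAT transcripts only, `o` targets are NAT members whose own pair
is unrelated to the siRNA.

# Hairpin screening

Around each screened small RNA locus, a precursor window of ±200 nt is
cut from the transcript and folded. The built-in folding engine is a
Nussinov-style base-pair maximisation dynamic program over
$\{AU, UA, GC, CG, GU, UG\}$ with minimum hairpin loop 3 and a
deterministic traceback (the 5'-most base is paired whenever an optimal
structure allows it, with its 5'-most optimal partner). It is not a
thermodynamic model — the choice buys zero external dependencies and an
exact brute-force oracle for testing — and a thermodynamic folder can
be plugged in through the `engine` argument of `fold()`.

The miRNA-feature check is an explicit, configurable stand-in for a
MirCheck-style screen. It first extracts the *duplex run*: the longest
stretch of miRNA bases pairing one opposite arm where consecutive pairs
are separated by at most `max_bulge_mir` (default 2) unpaired bases on
either strand. Maximisation tracebacks occasionally divert a single
mature base into a tiny loop-internal pair; the run decomposition
ignores such strays instead of failing the candidate, which a literal
"all partners contiguous" rule would do. Pass requires: few stray pairs
off the duplex side; at most `max_unpaired_mir` (4) miRNA bases outside
the run; bulges within the run ≤ 2 nt; the miRNA not extending more
than `max_loop_tail` (2) bases past its innermost pair toward the
terminal loop (the implied miRNA* would overlap the loop); and at least
`min_stem_pairs` (15) base pairs in the stem enclosing the loop.
Relaxing any threshold can only turn failures into passes (tested).

# The synthetic world

The generator states one idealised world and the tests live in it:

* cis pairs are laid out on a shared genomic segment with the requested
  orientation geometry, so overlap complementarity is exact by
  construction; trans families copy the reverse complement of a
  partner block into 1–3 paralogs at distant loci; background genes are
  i.i.d. sequence at 35% GC.
* overlap lengths are log-uniform on [31, 500] nt (right-skewed, like
  the published distributions; a qualitative emulation, not a fit);
  gene lengths uniform on [1000, 3000] nt.
* small RNA lengths have modes at 21/22/24 nt; abundances are geometric
  (long-tailed, producing the familiar unique-vs-total gap); reads are
  exact transcript substrings with the overlap sampled at rate $f$
  (default 5) and a per-pair One/Equal/Bias allocation.
* degradome scenarios plant a guide siRNA (cut from a non-overlap
  region of a NAT transcript, so nearby sampled reads cannot shadow
  it), write its reverse complement with template mismatches into a
  target, and emit a tag whose 5' end sits opposite siRNA position 10.
  Thirty templates satisfy the positional rule and thirty violate it;
  site placement keeps a 30 nt margin from other planted features so
  each window contains exactly one explicable site.
* hairpin precursors are inverted repeats (arm 220 nt, loop 8–15 nt)
  with the mature sequence as the loop-adjacent end of the 5' arm. The
  long arm makes the ±200 nt screening window fall inside the planted
  stem, so recovery tests the screen rather than the luck of the
  surrounding fold; the ≥20 bp duplex floor is comfortably met.

Everything derives from R's RNG under a single seed (stage seeds are
`seed + k`, $k \le 3$), and the manifest is re-verified against the
emitted sequences on every write.

What a green run does *not* establish: performance on spliced
transcripts whose genomic span differs from the spliced sequence, on
sequencing errors or mismatched mappings (the world is error-free and
mapping is exact by design), on gapped antisense alignments, or on
thermodynamic folding.

# Numerical and procedural choices

* Coordinates are 0-based half-open internally, 1-based inclusive in
  every emitted table; `N` never matches anywhere.
* The pair caller is order-invariant (canonical id ordering within a
  pair, deterministic sorts) and the whole pipeline is
  timestamp-free, so identical inputs give byte-identical outputs.
* Degradome scanning and seed extension run in small C++ kernels; the
  R-level `scan_candidate_sites()` is the reference implementation and
  the suite asserts equivalence on random cases.
* Hairpin screening is capped at the most abundant
  `hairpin_max_loci` loci (default 300) because folding is cubic in
  the window length; the cap is deterministic (count, then transcript,
  then position).
* Degenerate inputs: the paired t-test returns $t=0, p=1$ when all
  density differences are zero; pairs with no mapped reads are skipped
  by the enrichment and strand-bias tables; windows shorter than 40 nt
  are not folded.

# Known limitations

* Trans families plant a single shared block; real paralog families
  have divergent copies with partial-identity blocks.
* The enrichment score is attenuated for large $L_o/L_t$ (see above);
  users comparing overlap classes with very different geometry should
  compare chi-squared results, not raw scores.
* Strand-bias categories are assigned from whichever weighting is
  requested; libraries with extreme abundance skew can flip categories
  between `total` and `unique` weighting, which is why both are
  emitted.
* The built-in folder maximises pair count, which over-pairs long
  random sequences relative to thermodynamic structure; verdicts on
  windows that are not dominated by a real stem should be treated as a
  screen, not a structure prediction.
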