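---
title: "Methods: staggered-cleavage-aware junction analysis"
author: "junctionr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staggered-cleavage-aware junction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(junctionr)
```

## The measurement problem

Cas9 programmed with two sgRNAs cuts a locus twice; cellular ligation of the
four double-strand-break ends produces DNA-fragment deletions, inversions and
duplications. Short PCR amplicons (< 290 bp) across each predicted ligation
junction report how the ends were joined: precisely, with small deletions,
with insertions, with both, or — rarely — with resections that remove more
than ~100 nt. These categories are informative because they separate repair
pathways: canonical NHEJ yields precise joins and 1-bp deletions,
microhomology-mediated end joining (MMEJ/TMEJ, Polθ-dependent) yields 2–100-bp
deletions whose size is set by the distance of embedded microhomologies from
the cut, and fill-in of staggered-cut 5′ overhangs (Polλ-associated) yields
1–3-bp templated insertions.

Generic amplicon aligners are a poor fit for two reasons. First, they spread
indels across the read, whereas Cas9 repair products carry them at the
junction. Second — the package's namesake problem — Cas9 cleavage is not
always blunt at the −3|−4 protospacer position: it can leave 1–3-nt 5′
overhangs spanning positions −4 to −6 upstream of the PAM. A junction read
produced from such ends can legitimately contain sequence attributable to
*both* reference arms (a retained overhang or microhomology copy), which a
conventional aligner must misreport as mismatch, insertion, or a misplaced
gap.

## The three-part decomposition

Reads are aligned to a *junctional reference*: upstream arm $U$ and
downstream arm $D$, each trimmed to a window (default 150 nt per arm, so the
reference covers any amplicon read), joined at the blunt cut positions. Each
read $r$ of length $n$ is decomposed as a left part $r[0,i)$, a middle part
$r[i,j)$, and a right part $r[j,n)$, scored as

$$S(i,j) \;=\; S_{\mathrm{fit}}(r[0,i),\,U)\;+\;S_{\mathrm{fit}}(r[j,n),\,D)\;+\;c_{\mathrm{ins}}\,\max(0,\,j-i),$$

where $S_{\mathrm{fit}}$ is an affine-gap alignment that is global in the
read part and free at both arm ends. The free junction-proximal arm ends are
not penalized, and their unaligned lengths are reported as `del_up` and
`del_down` — deletions are expected at the junction, so they are measured,
not scored. The middle part is the unmapped insertion at the cleavage site
(internal arm gaps remain ordinary alignment gaps, so insertions are only
called at the junction). Crucially, $j < i$ is allowed up to `max_overlap`
bases: the two parts may overlap in the read, and overlap bases are scored in
*both* arms. A single retained copy of junction-flanking homology — the
fill-in product of a staggered cut, or the retained copy of an MMEJ
microhomology — then counts for both arms, which is exactly the staggered-cut
geometry a blunt-cut aligner cannot express.

Both optimization levels (the split indices and the per-part alignments) are
solved exactly: one dynamic-programming pass per arm computes
$S_{\mathrm{fit}}$ for every read prefix/suffix with the optimal arm
endpoint (ties resolved toward the junction) and the path origin, and an
$O(n^2)$ combination finds the optimal $(i,j)$. The implementation is in
C++ (Rcpp); `brute_force_align()` re-derives the optimum independently from
enumerated splits scored with `Biostrings::pairwiseAlignment()` and agrees
with the production aligner on every tested instance — the test suite treats
oracle equivalence, not any particular parameter set, as the aligner's
contract.

### Scoring parameters

All parameters live in `scoring_scheme()` and are deliberately exposed,
since no published constants exist for this exact formulation:

* `match = +1`, `mismatch = −2` (N never matches, conservatively);
* `gap_open = −4`, `gap_extend = −1` (a length-$k$ arm gap costs $4+k$);
* `insertion_base_penalty = −1` per middle base — milder per base than any
  gap, so junction insertions are reported as unmapped middle sequence
  rather than as arm gaps. A consequence worth knowing: a substitution
  error on the junction-adjacent base scores one point better as a 1-bp
  deletion plus 1-bp insertion than as a mismatch, so at a 1 % error rate
  of order 2 % of reads shift into the indel class; this stays within
  binomial counting noise at library scale and vanishes at error rate 0.
* `max_overlap = 3` — the staggered-overhang window is 1–3 nt, and keeping
  the maximum overlap gain (3 matches) below the minimum gap penalty (5)
  means overlap can never be used to buy a gap elsewhere, which keeps
  deletion sizes exact;
* `min_anchor = 15` nt per retained part; `min_score_frac = 0.6` of the
  perfect-match score as the mapped threshold, which cleanly rejects
  unrelated sequence.

### Tie-breaking

Equal-score decompositions are resolved deterministically: smallest middle
insertion, then smallest `del_up + del_down`, then largest overlap, then
leftmost split. The first two prefer the parsimonious reading (precise
ligation over gratuitous indels); the leftmost rule left-aligns ambiguous
junction placements, matching the convention used by the simulator's truth
records.

## Outcome classification

`classify_outcomes()` maps each mapped alignment to the four outcome groups
— precise, deletion, insertion, indel — which are kept mutually exclusive
(reads with both a deletion and an insertion are indels only; whether such
reads should also enter deletion-size histograms is ambiguous in the
field's practice, and exclusivity is the reproducible choice). Overlap bases
are counted as deleted sequence (the read retains one copy of something
present in both arms, so the physical junction lost those bases) and
attributed to the downstream arm, consistent with left-aligned retention;
`del_total = del_up + del_down + overlap_len` is then the physical deletion
size. Sizes are binned 1 / 2–20 / 21–100 / >100 bp, the last labeled a large
resection; the 100-nt boundary (configurable) mirrors the analysis
convention that small deletions — the MMEJ regime — are those under 100 bp.
Deleted positions are reported PAM-relative per arm (each arm carries its
own guide frame), so staggered-end loss shows up as mass at −4/−5/−6.

A 1–3-bp insertion is *templated* when it equals the predicted overhang of
either junction-side guide — the bases at PAM-relative −4 to −(3+k) —
compared in both reading orders and on both strands, because the
orientation of the duplicated bases at inversion and duplication junctions
is not defined a priori. The overhang itself is returned 5′→3′ on the
protospacer strand.

## Large resections from two-segment mappings

For LAM-HTGTS-style data, `map_read_segments()` reuses the split aligner
with both "arms" set to the user-supplied locus window (forward, and
reverse-complemented for the prey), yielding a bait segment and a prey
segment per read. `classify_resection()` applies the orientation rules:
prey strictly downstream of bait on the forward strand is a deletion-type
resection; prey on the reverse strand is inversion-type. `resected_nt` sums
the bait shortfall before the bait cut and the prey excess beyond the prey
cut; this sum is invariant under junction-homology slides (a slide moves
one base between the two terms), so it is exactly recoverable even though
the junction placement itself can be ambiguous. Overlap is disabled for
this mode — it is a staggered-cut concept, meaningless for genome-window
segment mapping. The minimum prey length is the shared `min_anchor`
(15 nt).

## Microhomology statistics

For a deletion-sized region of $n$ bp around the cut, the microhomology
length $M$ is the longest common substring of the two flanks (contiguous —
matching the coin-run analogy underlying the theory, not a subsequence).
The Arratia–Waterman bounds give

$$P(M \le L) \;\le\; \frac{1+p}{1-p}\Bigl(1-\tfrac{2}{n}\log_{1/p}n\Bigr)^{-2} p^{\,2\log_{1/p}n - L - 1},
\qquad P(M \le L) \;\ge\; 1-p^{\,L-2\log_{1/p}n+1},$$

with $p = 1/4$ for uniform DNA and logarithms computed as
$\ln n/\ln(1/p)$ in double precision. The raw formulas leave $[0,1]$ at
small $n$ (and for extreme $p$, where the exponent goes negative and the
upper bound diverges), so both are clamped to $[0,1]$.
`mmej_probability_lower_bound(n, L = 2)` $= 1 - \mathrm{upper}(n, L{-}1)$
is the conservative probability that at least 2 bp of microhomology flanks
the cut; it reaches 99.7 % at $n = 100$, the quantitative basis for
treating sub-100-bp deletions as the MMEJ regime.

Two conventions coexist deliberately. When *measuring* $M$ in real sequence,
`microhomology_query()` splits the region $n/2$ per flank (remainder
upstream), since the region straddles the cut. When *validating the
asymptotics* (`simulate_M_ratio()`, and the empirical bound-sandwich test),
flanks of length $n$ each are drawn, because that is the regime in which
the theorem is stated and in which $M/\log_{1/p}(n) \to 2$ with limit
constant exactly 2 — the bounds above likewise take $n$ as the per-sequence
length (that is how the 99.7 % figure arises). With $n/2$ flanks the same
ratio converges to 2 like $2 - 2\log_4(2)/\log_4 n$, i.e. visibly below 2
at any simulable $n$; `flank_len` is an explicit argument so either
convention can be requested. The longest-common-substring search itself is
exact: a $k$-mer set-intersection test inside a bracketed binary search on
$k$, validated against a quadratic dynamic program over an exhaustive
reduced-alphabet set.

## The simulator as ground truth

`simulate_library()` is first-class, tested code: it draws an outcome class
per read from a configured mixture, applies it at the junction, windows to
amplicon size (reads never exceed 290 nt), and applies substitution errors.
Defaults describe a busy editing library: 35 % precise, 15 % 1-bp
staggered-end deletions, 27 % MMEJ deletions (microhomology 2–4 bp, offsets
0–12 nt per side), 12 % templated fill-in insertions (k = 1–3), 6 % random
insertions, 5 % large resections (101–160 nt), 0.1 % per-base error,
240-nt amplicon windows, 5 000 reads. The synthetic locus places the two
guides PAM-out — upstream guide on the forward strand, downstream guide on
the reverse strand — so both junction arms present −4/−5/−6 adjacent to the
junction, the common dual-sgRNA deletion design.

Substitution-only errors keep truth assignment unambiguous (Illumina error
is substitution-dominated); indel errors are out of scope. MMEJ deletion
reads are emitted with the upstream microhomology copy retained
(left-aligned, matching the aligner's tie rule) and size
`up_offset + mh + down_offset`. The truth table's templated flag is
evaluated with the same predicate the classifier uses, so a random
insertion that happens to equal a predicted overhang is labeled as what any
observer of the read must call it.

What passing round-trip tests show — and what they do not: at error rate 0
the full pipeline recovers every read's category, deletion size and
templated flag exactly, and at 1 % error the mixture is recovered within
binomial noise; this validates the algorithmic chain, not the biology. The
simulator does not model PCR amplification bias (negligible for same-size
amplicons), chimeric reads, quality-dependent errors, or indel sequencing
errors, so real-library performance on those axes is untested here.

## Numerical and design choices worth recording

* Coordinates are 0-based half-open throughout; cuts are inter-base
  integers; the junction coordinate equals `nchar(upstream_arm)`.
* The duplication junction is built head-to-tail (sequence ending at the
  downstream cut joined to sequence starting at the upstream cut), the
  standard tandem-duplication geometry; other head arrangements were not
  observed in the schematics this follows.
* `align_both_strands()` prefers the forward strand on exact score ties.
* Problem sizes in the tests were chosen to characterize the estimators
  well while keeping the default suite fast: 500 oracle-equivalence reads,
  5 000-read round-trip libraries, 500 Monte-Carlo replicates per $n$ up to
  $n = 2^{16}$ for the asymptotic ratio, and $10^4$ replicates per $n$ for
  the bound sandwich.
* Known limitations: no genome-scale indexing (references are supplied
  windows); adapter handling is fixed-prefix trimming; paired-end merging
  is naive best-ungapped-overlap; PAMs other than NGG are rejected.
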