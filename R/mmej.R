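#' Longest common substring of two cleavage-site flanks
#'
#' The microhomology length M of a deletion-sized region is the length of
#' the longest common (contiguous) substring of the sequences flanking the
#' cleavage site.  Computed exactly by doubling-plus-binary search over the
#' k-mer length, testing at each k whether the flanks share any k-mer.
#'
#' @param left_flank,right_flank Non-empty flank sequences.
#' @return Integer M >= 0.
#' @export
#' @examples
#' longest_flanking_match("ACGT", "CGTA") # "CGT" -> 3
longest_flanking_match <- function(left_flank, right_flank) {
  if (nchar(left_flank) == 0 || nchar(right_flank) == 0) {
    stop("empty window", call. = FALSE)
  }
  na <- nchar(left_flank); nb <- nchar(right_flank)
  hi_max <- min(na, nb)
  has_common <- function(k) {
    if (k == 0L) return(TRUE)
    if (k > hi_max) return(FALSE)
    ka <- unique(substring(left_flank, 1:(na - k + 1L), k:na))
    any(substring(right_flank, 1:(nb - k + 1L), k:nb) %in% ka)
  }
  # bracket [lo, hi] around M, starting from the typical scale of the longest
  # shared k-mer for uniform DNA (log4 of the pair count); the probe is only
  # a starting point — the expansion below is exact for any input
  probe <- max(1L, min(hi_max, as.integer(floor(log(as.double(na) * nb) / log(4)))))
  if (has_common(probe)) {
    lo <- probe
    step <- 2L
    while (lo + step <= hi_max && has_common(lo + step)) {
      lo <- lo + step
      step <- step * 2L
    }
    hi <- min(lo + step - 1L, hi_max)
  } else {
    hi <- probe - 1L
    step <- 2L
    lo <- hi - step
    while (lo >= 1L && !has_common(lo)) {
      hi <- lo - 1L
      step <- step * 2L
      lo <- hi - step
    }
    if (lo < 0L) lo <- 0L
  }
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (has_common(mid)) lo <- mid else hi <- mid - 1L
  }
  as.integer(lo)
}

#' Microhomology of a deletion-sized window around a cut site
#'
#' Splits a region of length `n` centered on the cleavage coordinate into
#' two flanks (`ceiling(n/2)` upstream, `floor(n/2)` downstream) and returns
#' the microhomology query: the flanks, and M from
#' [longest_flanking_match()].
#'
#' @param sequence Sequence containing the cut.
#' @param cut 0-based inter-base cleavage coordinate within `sequence`.
#' @param n Region length (nt, >= 2); truncated at the sequence ends.
#' @return A list with `left_flank`, `right_flank`, `n`, and `M`.
#' @export
microhomology_query <- function(sequence, cut, n) {
  stopifnot(n >= 2, cut >= 1, cut <= nchar(sequence) - 1)
  up <- ceiling(n / 2); dn <- floor(n / 2)
  left <- substr(sequence, max(1L, cut - up + 1L), cut)
  right <- substr(sequence, cut + 1L, min(nchar(sequence), cut + dn))
  list(left_flank = left, right_flank = right, n = n,
       M = longest_flanking_match(left, right))
}

log_basep <- function(n, p) log(n) / log(1 / p)

#' Arratia-Waterman bounds on P(M <= L)
#'
#' Closed-form bounds on the probability that the longest common substring
#' M of two random sequences of length n (per-position match probability p,
#' 1/4 for uniform DNA) does not exceed a threshold L:
#' upper bound `(1+p)/(1-p) * (1 - (2/n) log_{1/p} n)^-2 * p^(2 log_{1/p} n - L - 1)`
#' and lower bound `1 - p^(L - 2 log_{1/p} n + 1)`.  The raw formulas leave
#' the unit interval at small n and are clamped to [0, 1].
#'
#' @param n Region (sequence) length, >= 2.
#' @param L Microhomology threshold, >= 1.
#' @param p Per-position base-match probability (0 < p < 1).
#' @return Probability in [0, 1]; vectorized over `n`.
#' @export
p_upper_bound_M_le_L <- function(n, L, p = 0.25) {
  check_bound_args(n, L, p)
  lg <- log_basep(n, p)
  if (any((2 / n) * lg >= 1)) stop("bound undefined for n", call. = FALSE)
  raw <- (1 + p) / (1 - p) * (1 - (2 / n) * lg)^(-2) * p^(2 * lg - L - 1)
  pmin(1, pmax(0, raw))
}

#' @rdname p_upper_bound_M_le_L
#' @export
p_lower_bound_M_le_L <- function(n, L, p = 0.25) {
  check_bound_args(n, L, p)
  lg <- log_basep(n, p)
  raw <- 1 - p^(L - 2 * lg + 1)
  pmin(1, pmax(0, raw))
}

check_bound_args <- function(n, L, p) {
  if (any(n < 2)) stop("bound undefined for n", call. = FALSE)
  stopifnot(all(L >= 1), p > 0, p < 1)
}

#' Conservative lower bound on the MMEJ probability P(M >= L)
#'
#' One minus the Arratia-Waterman upper bound for P(M <= L - 1): a
#' conservative estimate of the probability that a deletion-sized region of
#' n bp around the cleavage site contains at least L bp of flanking
#' microhomology.  With the defaults (L = 2, p = 1/4) this reaches 99.7% at
#' n = 100 — at deletion sizes up to 100 bp an MMEJ-competent microhomology
#' is almost always available.
#'
#' @inheritParams p_upper_bound_M_le_L
#' @return Probability in [0, 1]; vectorized over `n`.
#' @export
mmej_probability_lower_bound <- function(n, L = 2, p = 0.25) {
  pmin(1, pmax(0, 1 - p_upper_bound_M_le_L(n, L - 1, p)))
}

#' MMEJ probability lower-bound curve over deletion sizes
#'
#' @param n_values Deletion sizes (nt).
#' @inheritParams p_upper_bound_M_le_L
#' @return A tibble (class `mmej_curve`) with columns `n` and
#'   `p_mmej` (lower-bound probability of M >= L); see
#'   [autoplot.mmej_curve()].
#' @export
mmej_curve <- function(n_values, L = 2, p = 0.25) {
  out <- tibble(n = as.numeric(n_values),
                p_mmej = mmej_probability_lower_bound(n_values, L, p))
  class(out) <- c("mmej_curve", class(out))
  out
}

#' Monte-Carlo estimate of the asymptotic microhomology ratio
#'
#' Draws pairs of independent random sequences and estimates the mean of
#' `M / log_{1/p}(n)`, which converges to 2 almost surely as n grows
#' (Erdos-Renyi-type law for the longest common substring).  The default
#' flank length is `n` per sequence, the convention under which the limit
#' constant is exactly 2 and under which the closed-form bounds are stated;
#' `flank_len` can be set to `n %/% 2` to mirror the deletion-window split
#' used on real sequence.
#'
#' @param n Region length entering the normalization `log_{1/p}(n)`.
#' @param reps Number of Monte-Carlo replicates (>= 100).
#' @param seed RNG seed.
#' @param p Per-position match probability; `1/p` must be a whole number
#'   (alphabet size), p = 1/4 for uniform DNA.
#' @param flank_len Length of each simulated flank (default `n`).
#' @return A one-row tibble: `n`, `reps`, `mean_ratio`, `se_ratio`,
#'   `mean_M`.
#' @export
simulate_M_ratio <- function(n, reps, seed, p = 0.25, flank_len = n) {
  stopifnot(reps >= 100, n >= 2, flank_len >= 1)
  a <- round(1 / p)
  if (abs(1 / a - p) > 1e-9) {
    stop("p must be the reciprocal of a whole alphabet size", call. = FALSE)
  }
  set.seed(seed)
  alphabet <- c("A", "C", "G", "T", LETTERS)[seq_len(a)]
  draw <- function() paste(sample(alphabet, flank_len, replace = TRUE), collapse = "")
  M <- vapply(seq_len(reps), function(i) {
    if (a == 1L) return(flank_len) # degenerate p = 1: everything matches
    longest_flanking_match(draw(), draw())
  }, numeric(1))
  ratio <- M / log_basep(n, p)
  tibble(n = n, reps = reps, mean_ratio = mean(ratio),
         se_ratio = sd(ratio) / sqrt(reps), mean_M = mean(M))
}

# M samples for empirical P(M <= L); used to validate the bound sandwich
simulate_M_distribution <- function(n, reps, seed, p = 0.25, flank_len = n) {
  set.seed(seed)
  a <- round(1 / p)
  alphabet <- c("A", "C", "G", "T", LETTERS)[seq_len(a)]
  vapply(seq_len(reps), function(i) {
    if (a == 1L) return(as.integer(flank_len))
    longest_flanking_match(
      paste(sample(alphabet, flank_len, replace = TRUE), collapse = ""),
      paste(sample(alphabet, flank_len, replace = TRUE), collapse = ""))
  }, integer(1))
}
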