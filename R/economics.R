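# Production planning: stochastic overproduction vs deterministic stopping.
#
# Producing a descendant with the suitable genotype is a Bernoulli trial with
# the Mendelian probability p delivered by the crossing engine (1/4 for a
# single-locus heterozygote sibling cross, 1/16 for the two-locus analogue).
# A genetics-assay workflow must pre-commit to n descendants chosen so that
# P(X >= k) clears a confidence level (complementary cumulative binomial); a
# scoring-at-nascence workflow stops at the k-th success, whose expected
# trial count is the negative-binomial mean k/p.

.check_prob <- function(p, allow_zero = FALSE) {
  p <- as.numeric(as_rational(p))
  if (length(p) != 1L || is.na(p) || p > 1 || p < 0 || (!allow_zero && p == 0)) {
    stop("p must be a single probability in ", if (allow_zero) "[0, 1]" else "(0, 1]",
         call. = FALSE)
  }
  p
}

#' Complementary cumulative binomial probability
#'
#' `P(X >= k)` for `X ~ Binomial(n, p)`, computed by finite summation of the
#' `k` complementary binomial terms. This is the probability that a batch of
#' `n` descendants contains at least `k` suitable individuals.
#'
#' @param n batch size (non-negative integer).
#' @param p per-descendant success probability; numeric or fraction string
#'   such as `"1/16"`.
#' @param k required number of suitable individuals (non-negative integer).
#' @return Probability in `[0, 1]`.
#' @examples
#' binomial_tail(11, 1/4, 1) # just above 0.95
#' @export
binomial_tail <- function(n, p, k) {
  if (length(n) != 1L || is.na(n) || n < 0 || n != round(n)) stop("n must be a non-negative integer")
  if (length(k) != 1L || is.na(k) || k < 0 || k != round(k)) stop("k must be a non-negative integer")
  p <- .check_prob(p, allow_zero = TRUE)
  if (k == 0) return(1)
  if (k > n) return(0)
  1 - sum(stats::dbinom(0:(k - 1), n, p))
}

#' Minimum batch size for a stochastic workflow
#'
#' Smallest `n` such that `binomial_tail(n, p, k) >= confidence`: the number
#' of descendants that must be produced up front so that, with the stated
#' confidence, at least `k` of them carry the suitable genotype. At the
#' default 95% confidence this gives 11 descendants for p = 1/4 and 47 for
#' p = 1/16.
#'
#' @param p per-descendant success probability (numeric or fraction string).
#' @param k required suitable individuals.
#' @param confidence required probability of having `k` successes, in (0, 1).
#' @return Integer batch size.
#' @examples
#' min_required(1/4)    # 11
#' min_required("1/16") # 47
#' @export
min_required <- function(p, k = 1, confidence = 0.95) {
  p <- .check_prob(p)
  if (length(k) != 1L || k < 1 || k != round(k)) stop("k must be a positive integer")
  if (length(confidence) != 1L || confidence <= 0 || confidence >= 1) {
    stop("confidence must lie in (0, 1)")
  }
  n <- as.integer(k)
  while (binomial_tail(n, p, k) < confidence) n <- n + 1L
  n
}

#' Expected stopping time of the deterministic workflow
#'
#' When every descendant is genotyped at nascence, production stops at the
#' k-th suitable individual. The number of trials to the k-th success is
#' negative-binomial with mean `k/p`: on average 4 descendants at p = 1/4,
#' 16 at p = 1/16.
#'
#' @param p per-descendant success probability (numeric or fraction string).
#' @param k required suitable individuals.
#' @return Expected number of descendants produced, `k/p`.
#' @export
expected_deterministic <- function(p, k = 1) {
  p <- .check_prob(p)
  if (length(k) != 1L || k < 1 || k != round(k)) stop("k must be a positive integer")
  k / p
}

#' Stopping-time probability mass function
#'
#' `P(k-th success occurs at trial n) = C(n-1, k-1) p^k (1-p)^(n-k)`,
#' the trial-count parameterization of the negative binomial; zero for
#' `n < k`.
#'
#' @param p per-descendant success probability.
#' @param k required successes.
#' @param n trial index (vectorized).
#' @return Probability vector, same length as `n`.
#' @export
stopping_time_pmf <- function(p, k, n) {
  p <- .check_prob(p)
  if (length(k) != 1L || k < 1 || k != round(k)) stop("k must be a positive integer")
  out <- numeric(length(n))
  ok <- !is.na(n) & n >= k & n == round(n)
  out[ok] <- stats::dnbinom(n[ok] - k, size = k, prob = p)
  out
}

#' Compare stochastic and deterministic production workflows
#'
#' Assembles the planner's two numbers for one cross: the pre-committed
#' batch size `n_stochastic = min_required(p, k, confidence)` and the
#' deterministic expectation `k/p`, together with the waste reduction
#' `1 - (k/p) / n_stochastic`. For p = 1/16 at 95% confidence this is
#' 1 - 16/47, about two-thirds.
#'
#' @inheritParams min_required
#' @return An object of class `"workflow_comparison"` with fields
#'   `p`, `k`, `confidence`, `n_stochastic`, `achieved_confidence`,
#'   `expected_deterministic`, `reduction_fraction`.
#' @examples
#' compare_workflows("1/16")
#' @export
compare_workflows <- function(p, k = 1, confidence = 0.95) {
  pn <- .check_prob(p)
  n <- min_required(pn, k, confidence)
  e <- expected_deterministic(pn, k)
  structure(
    list(p = pn, k = k, confidence = confidence,
         n_stochastic = n,
         achieved_confidence = binomial_tail(n, pn, k),
         expected_deterministic = e,
         reduction_fraction = 1 - e / n),
    class = "workflow_comparison"
  )
}

#' @export
print.workflow_comparison <- function(x, ...) {
  cat("Workflow comparison (p = ", format(x$p), ", k = ", x$k,
      ", confidence = ", format(x$confidence), ")\n", sep = "")
  cat(sprintf("  stochastic batch size     : %d (achieves %.4f)\n",
              x$n_stochastic, x$achieved_confidence))
  cat(sprintf("  deterministic expectation : %.4g\n", x$expected_deterministic))
  cat(sprintf("  progeny reduction         : %.1f%%\n", 100 * x$reduction_fraction))
  invisible(x)
}

#' Waste scaling with the number of distinct transgenes
#'
#' With `m` unlinked transgenes handled simultaneously, the suitable-
#' genotype probability compounds to `per_locus_p^i` for `i` transgenes.
#' This returns the stochastic/deterministic comparison for each
#' `i = 1..m`; the absolute saving `n_stochastic - k/p_i` grows roughly
#' geometrically, i.e. the number of wasted animals avoided increases
#' exponentially with the number of transgenes.
#'
#' @param m number of distinct transgenes.
#' @param per_locus_p suitable probability contributed by each transgene.
#' @param k required suitable individuals.
#' @param confidence stochastic-workflow confidence level.
#' @return A data frame of class `"workflow_scaling"` with one row per `i`:
#'   `n_transgenes`, `p`, `n_stochastic`, `expected_deterministic`,
#'   `saving`, `reduction_fraction`.
#' @examples
#' scaling_with_transgenes(2) # savings 7 and 31 at p = 1/4 per locus
#' @export
scaling_with_transgenes <- function(m, per_locus_p = 1/4, k = 1, confidence = 0.95) {
  if (length(m) != 1L || m < 1 || m != round(m)) stop("m must be a positive integer")
  pl <- .check_prob(per_locus_p)
  rows <- lapply(seq_len(m), function(i) {
    cmp <- compare_workflows(pl^i, k, confidence)
    data.frame(
      n_transgenes = i, p = cmp$p, n_stochastic = cmp$n_stochastic,
      expected_deterministic = cmp$expected_deterministic,
      saving = cmp$n_stochastic - cmp$expected_deterministic,
      reduction_fraction = cmp$reduction_fraction
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("workflow_scaling", "data.frame")
  out
}
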