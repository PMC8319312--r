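# Seeded synthetic data: multinomial progeny samples, vial-level scoring
# tables and Monte-Carlo workflow simulation. These emulate the statistical
# structure of real scoring tables — several mating vials per cross, each
# scored exhaustively for marker phenotypes — with counts drawn from the
# exact Mendelian phenotype distribution of the cross.

# run code under a seed without clobbering the caller's RNG state
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  expr
}

# derive a per-vial substream seed: adding vials never perturbs earlier ones
.vial_seed <- function(seed, i) (seed + 1000003 * i) %% 2147483647

# accept a genotype_dist, a named rational or a named numeric vector
.as_pheno_probs <- function(dist) {
  if (inherits(dist, "genotype_dist")) dist <- phenotype_distribution(dist)
  if (inherits(dist, "rational")) {
    if (!isTRUE(sum(dist) == rational(1))) stop("distribution does not sum to 1")
    p <- as.numeric(dist)
  } else {
    p <- dist
    if (is.null(names(p)) || abs(sum(p) - 1) > 1e-9) {
      stop("distribution must be named and sum to 1")
    }
  }
  names(p) <- vapply(names(p), function(s) phenotype_string(parse_phenotype(s)), "")
  p
}

#' Multinomial progeny sample
#'
#' Draws the phenotype counts of `n` progeny from an exact phenotype
#' distribution. Reproducible under a fixed seed; the caller's RNG state is
#' left untouched.
#'
#' @param dist phenotype distribution: a `genotype_dist`, a named
#'   [rational()] vector (as returned by [phenotype_distribution()]) or a
#'   named numeric vector summing to 1.
#' @param n number of progeny (>= 0).
#' @param seed integer seed.
#' @return Named integer vector of counts, one per phenotype class, summing
#'   to `n`.
#' @export
sample_progeny <- function(dist, n, seed) {
  if (length(n) != 1L || n < 0 || n != round(n)) stop("n must be a non-negative integer")
  p <- .as_pheno_probs(dist)
  if (n == 0) {
    return(structure(integer(length(p)), names = names(p)))
  }
  counts <- .with_seed(seed, stats::rmultinom(1, n, p))[, 1]
  structure(as.integer(counts), names = names(p))
}

#' Simulate a vial-level scoring table
#'
#' Emulates the layout of real mating-procedure scoring tables: several
#' female–male pair vials per cross, each vial's progeny scored exhaustively
#' for marker phenotype. Each vial is one independent multinomial draw from
#' the exact phenotype distribution; per-vial seeds are derived from the
#' top-level seed so that adding vials never perturbs earlier ones.
#'
#' @param dist phenotype distribution (see [sample_progeny()]).
#' @param n_vials number of vials (default 6, up to six pairs per cross).
#' @param progeny_per_vial single count or one count per vial (default 100).
#' @param seed integer seed.
#' @param cross_id free-text cross identifier.
#' @param generation generation label, e.g. `"F9"`.
#' @return A data frame of class `"scoring_table"` with columns `vial_id`,
#'   `cross_id`, `generation`, `phenotype`, `count`; every supported
#'   phenotype class appears for every vial (zeros included).
#' @examples
#' loci <- locus_set(transgene_locus("ACOS", c("mCe", "mVe")))
#' het <- genotype(loci, "ACOS:mCe/mVe")
#' tab <- simulate_vials(cross(het, het), seed = 1, generation = "F7")
#' head(tab)
#' @export
simulate_vials <- function(dist, n_vials = 6, progeny_per_vial = 100, seed,
                           cross_id = "cross", generation = "F") {
  if (length(n_vials) != 1L || n_vials < 1 || n_vials != round(n_vials)) {
    stop("n_vials must be a positive integer")
  }
  if (length(progeny_per_vial) == 1L) {
    progeny_per_vial <- rep(progeny_per_vial, n_vials)
  }
  if (length(progeny_per_vial) != n_vials) {
    stop("progeny_per_vial must have length 1 or n_vials")
  }
  if (any(progeny_per_vial < 0)) stop("progeny counts must be non-negative")
  p <- .as_pheno_probs(dist)
  rows <- lapply(seq_len(n_vials), function(i) {
    counts <- sample_progeny(p, progeny_per_vial[[i]], .vial_seed(seed, i))
    data.frame(
      vial_id = sprintf("V%d", i),
      cross_id = cross_id,
      generation = generation,
      phenotype = names(counts),
      count = as.integer(counts),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("scoring_table", "data.frame")
  out
}

#' Monte-Carlo simulation of the two production workflows
#'
#' The *stochastic* strategy produces a fixed batch of `n` descendants per
#' replicate (defaulting to the planner's [min_required()]) and records how
#' many are suitable; the *deterministic* strategy genotypes at nascence and
#' stops at the `k`-th suitable descendant, recording the trial count.
#'
#' @param strategy `"deterministic"` or `"stochastic"`.
#' @param p per-descendant success probability (numeric or fraction string).
#' @param k required suitable individuals.
#' @param reps number of replicates.
#' @param seed integer seed.
#' @param n batch size for the stochastic strategy; default
#'   `min_required(p, k, confidence)`.
#' @param confidence used only to derive the default `n`.
#' @return A data frame of class `"workflow_sim"` with columns `produced`,
#'   `successes`, `success` (at least `k` suitable), plus attributes
#'   `strategy`, `p`, `k`, `n`.
#' @examples
#' sim <- simulate_workflow("deterministic", "1/16", reps = 1000, seed = 1)
#' mean(sim$produced) # near 16
#' @export
simulate_workflow <- function(strategy = c("deterministic", "stochastic"),
                              p, k = 1, reps, seed, n = NULL, confidence = 0.95) {
  strategy <- match.arg(strategy)
  pn <- .check_prob(p)
  if (length(reps) != 1L || reps < 1 || reps != round(reps)) stop("reps must be a positive integer")
  if (length(k) != 1L || k < 1 || k != round(k)) stop("k must be a positive integer")
  if (strategy == "stochastic") {
    if (is.null(n)) n <- min_required(pn, k, confidence)
    successes <- .with_seed(seed, stats::rbinom(reps, n, pn))
    out <- data.frame(produced = rep(n, reps), successes = successes,
                      success = successes >= k)
  } else {
    produced <- .with_seed(seed, k + stats::rnbinom(reps, size = k, prob = pn))
    out <- data.frame(produced = produced, successes = rep(k, reps),
                      success = rep(TRUE, reps))
    n <- NA_integer_
  }
  structure(out, strategy = strategy, p = pn, k = k, n = n,
            class = c("workflow_sim", "data.frame"))
}

#' @export
summary.workflow_sim <- function(object, ...) {
  cat("Monte-Carlo workflow simulation (", attr(object, "strategy"),
      ", p = ", format(attr(object, "p")), ", k = ", attr(object, "k"),
      ", reps = ", nrow(object), ")\n", sep = "")
  cat(sprintf("  mean produced     : %.4f\n", mean(object$produced)))
  cat(sprintf("  success fraction  : %.4f\n", mean(object$success)))
  invisible(object)
}
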