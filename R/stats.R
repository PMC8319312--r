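# Statistical verification of scoring tables: per-vial phenotype ratios and
# one-sample two-tailed t-tests against theoretical Mendelian ratios. Vials
# are the replication unit; their phenotype proportions are treated as plain
# arithmetic means (no transform), matching how marker-ratio tables are
# conventionally checked.

#' Per-vial phenotype ratios
#'
#' Fraction of each vial's progeny showing a phenotype, in vial order.
#' Phenotypes absent from a vial count as zero; a vial with zero total
#' progeny cannot yield a ratio and is an error.
#'
#' @param table a `scoring_table` (see [simulate_vials()] or
#'   [read_scoring_table()]).
#' @param phenotype phenotype string (any marker order; canonicalized).
#' @return Named numeric vector of per-vial ratios.
#' @export
vial_ratios <- function(table, phenotype) {
  stopifnot(is.data.frame(table))
  ph <- phenotype_string(parse_phenotype(phenotype))
  vials <- unique(table$vial_id)
  vapply(vials, function(v) {
    sub <- table[table$vial_id == v, ]
    total <- sum(sub$count)
    if (total == 0) stop("vial '", v, "' has zero scored progeny", call. = FALSE)
    sum(sub$count[sub$phenotype == ph]) / total
  }, 0)
}

#' One-sample two-tailed t-test against a Mendelian ratio
#'
#' Tests whether the arithmetic mean of per-vial phenotype ratios differs
#' from the theoretical Mendelian ratio:
#' `t = (mean - theoretical) / (s / sqrt(n))` with `n - 1` degrees of
#' freedom, two-tailed. Degenerate zero-variance samples are handled by
#' contract: if every ratio equals the theoretical value, `t = 0` and
#' `p = 1`; if the ratios agree with each other but not with the
#' theoretical value, the difference is reported as significant (`p = 0`)
#' and flagged.
#'
#' @param ratios numeric vector of per-vial ratios (at least 2).
#' @param theoretical theoretical ratio; numeric or fraction string such as
#'   `"9/16"`.
#' @param alpha significance level (default 0.05).
#' @param phenotype optional phenotype label carried into the result.
#' @return An object of class `"mendelian_ttest"` with fields `phenotype`,
#'   `theoretical`, `vial_ratios`, `mean_ratio`, `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `significant`, `degenerate`.
#' @examples
#' mendelian_ttest(c(0.24, 0.26, 0.25, 0.25), "1/4")
#' @export
mendelian_ttest <- function(ratios, theoretical, alpha = 0.05, phenotype = NA_character_) {
  if (length(ratios) < 2L) stop("need at least two vial ratios")
  theo_r <- as_rational(theoretical)
  theo <- as.numeric(theo_r)
  n <- length(ratios)
  m <- mean(ratios)
  s <- stats::sd(ratios)
  degenerate <- FALSE
  if (s == 0) {
    if (isTRUE(all.equal(m, theo))) {
      t_stat <- 0
      p <- 1
    } else {
      t_stat <- sign(m - theo) * Inf
      p <- 0
      degenerate <- TRUE
    }
  } else {
    t_stat <- (m - theo) / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  structure(
    list(phenotype = phenotype, theoretical = theo_r, vial_ratios = ratios,
         mean_ratio = m, t_statistic = t_stat, degrees_of_freedom = n - 1L,
         p_value = p, alpha = alpha, significant = p < alpha,
         degenerate = degenerate),
    class = "mendelian_ttest"
  )
}

#' @export
print.mendelian_ttest <- function(x, ...) {
  cat("One-sample two-tailed t-test vs Mendelian ratio ", format(x$theoretical),
      if (!is.na(x$phenotype)) paste0(" (", x$phenotype, ")"), "\n", sep = "")
  cat(sprintf("  mean of %d vial ratios: %.4f\n",
              x$degrees_of_freedom + 1L, x$mean_ratio))
  cat(sprintf("  t = %.4f, df = %d, p = %.4g %s%s\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value,
              if (x$significant) sprintf("(significant at alpha = %g)", x$alpha) else "(n.s.)",
              if (x$degenerate) " [degenerate variance]" else ""))
  invisible(x)
}

#' Test every phenotype of a scoring table against its Mendelian ratio
#'
#' Convenience wrapper running [mendelian_ttest()] for each phenotype class,
#' with theoretical ratios taken either from an exact distribution (a
#' `genotype_dist` or a [phenotype_distribution()]) or given explicitly.
#' No multiple-testing correction is applied by default, matching the
#' per-phenotype reporting convention of marker-ratio tables; an optional
#' Bonferroni flag is provided as an extension.
#'
#' @param table a `scoring_table`.
#' @param expected theoretical ratios: a `genotype_dist`, a named
#'   [rational()] vector, or a named vector/list of fractions such as
#'   `c("mO+mCe" = "9/16")`.
#' @param alpha significance level.
#' @param bonferroni divide `alpha` by the number of phenotypes tested?
#' @return A data frame with one row per phenotype: `phenotype`,
#'   `theoretical`, `mean_ratio`, `t_statistic`, `degrees_of_freedom`,
#'   `p_value`, `significant`, `degenerate`.
#' @export
mendelian_tests <- function(table, expected, alpha = 0.05, bonferroni = FALSE) {
  if (inherits(expected, "genotype_dist")) expected <- phenotype_distribution(expected)
  if (inherits(expected, "rational")) {
    theo <- as.numeric(expected)
    theo_str <- format(expected)
    names(theo) <- names(theo_str) <- names(expected)
  } else {
    expected <- unlist(expected)
    theo <- vapply(expected, function(x) as.numeric(as_rational(x)), 0)
    theo_str <- vapply(expected, function(x) format(as_rational(x)), "")
    names(theo) <- names(theo_str) <- names(expected)
  }
  phenos <- vapply(names(theo), function(s) phenotype_string(parse_phenotype(s)), "")
  a <- if (bonferroni) alpha / length(phenos) else alpha
  rows <- lapply(seq_along(phenos), function(i) {
    r <- vial_ratios(table, phenos[[i]])
    tt <- mendelian_ttest(r, theo[[i]], alpha = a, phenotype = phenos[[i]])
    data.frame(
      phenotype = phenos[[i]],
      theoretical = theo_str[[i]],
      mean_ratio = tt$mean_ratio,
      t_statistic = tt$t_statistic,
      degrees_of_freedom = tt$degrees_of_freedom,
      p_value = tt$p_value,
      significant = tt$significant,
      degenerate = tt$degenerate,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
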