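# Gamete formation, Cre-mediated marker resolution and exact crossing.
#
# All distributions here are exact rationals. Loci assort independently
# (unlinked; free recombination), each parental allele is transmitted with
# probability 1/2, and when Cre is active every transmitted dual-cassette
# allele is resolved to one of its two single-marker states.

#' Cre-mediated resolution of one allele
#'
#' A dual-marker cassette carries both markers inside interweaved but
#' incompatible Lox site pairs; Cre recombination excises one marker, leaving
#' a single-marker allele. With resolution efficiency `e`, a dual allele
#' becomes each single-marker allele with probability `e/2` (the two Lox
#' pairs are assumed equally reactive) and stays dual with probability
#' `1 - e`. Single-marker and wild-type alleles are unaffected.
#'
#' @param allele allele string (`"+"`, `"D"` or a marker name).
#' @param locus the owning `transgene_locus`.
#' @param efficiency resolution probability in `[0, 1]`; numeric or fraction
#'   string. Default 1 (complete resolution).
#' @return A list with components `allele` (character vector of outcome
#'   alleles) and `p` (exact [rational()] probabilities summing to 1).
#' @examples
#' agoc <- transgene_locus("AGOC", c("mO", "mC"))
#' cre_resolve("D", agoc)           # mO and mC, 1/2 each
#' cre_resolve("D", agoc, "9/10")   # partial resolution
#' @export
cre_resolve <- function(allele, locus, efficiency = 1) {
  stopifnot(inherits(locus, "transgene_locus"))
  .check_allele(allele, locus)
  eff <- as_rational(efficiency)
  if (length(eff) != 1L || eff < rational(0) || eff > rational(1)) {
    stop("efficiency must be a single probability in [0, 1]")
  }
  if (allele != "D") {
    return(list(allele = allele, p = rational(1)))
  }
  half <- eff / 2
  out_a <- c(locus$markers, "D")
  out_p <- rat_c(half, half, rational(1) - eff)
  keep <- as.numeric(out_p) > 0
  list(allele = out_a[keep], p = out_p[keep])
}

# distribution of the allele an individual transmits at one locus
.transmitted_allele <- function(g, id, cre_active, efficiency) {
  a <- g$alleles[[id]]
  acc_a <- character(0)
  acc_p <- list()
  for (parent_allele in a) {
    res <- if (cre_active) {
      cre_resolve(parent_allele, g$loci[[id]], efficiency)
    } else {
      list(allele = parent_allele, p = rational(1))
    }
    for (i in seq_along(res$allele)) {
      p <- rational(1, 2) * res$p[i]
      j <- match(res$allele[[i]], acc_a)
      if (is.na(j)) {
        acc_a <- c(acc_a, res$allele[[i]])
        acc_p[[length(acc_p) + 1L]] <- p
      } else {
        acc_p[[j]] <- acc_p[[j]] + p
      }
    }
  }
  list(allele = acc_a, p = do.call(rat_c, acc_p))
}

#' Gamete distribution of a genotype
#'
#' Enumerates the haplotypes a genotype transmits, with exact probabilities:
#' per locus each allele is passed with probability 1/2, loci assort
#' independently, and with `cre_active = TRUE` (the individual carries a
#' Cre-expressing helper) every transmitted dual allele is resolved via
#' [cre_resolve()] (germline action).
#'
#' @param g a `genotype`.
#' @param cre_active apply Cre resolution to transmitted alleles?
#' @param efficiency Cre resolution efficiency (see [cre_resolve()]).
#' @return A list of class `"gamete_dist"` with `haplotypes` (list of named
#'   allele vectors, one entry per locus) and `p` (exact rationals summing
#'   to 1, named by haplotype string).
#' @export
gametes <- function(g, cre_active = FALSE, efficiency = 1) {
  stopifnot(inherits(g, "genotype"))
  ids <- names(g$loci)
  per_locus <- lapply(ids, function(id) .transmitted_allele(g, id, cre_active, efficiency))
  haps <- list(structure(character(0), names = character(0)))
  probs <- list(rational(1))
  for (l in seq_along(ids)) {
    dist <- per_locus[[l]]
    new_haps <- list()
    new_probs <- list()
    for (h in seq_along(haps)) {
      for (i in seq_along(dist$allele)) {
        hap <- c(haps[[h]], structure(dist$allele[[i]], names = ids[[l]]))
        new_haps[[length(new_haps) + 1L]] <- hap
        new_probs[[length(new_probs) + 1L]] <- probs[[h]] * dist$p[i]
      }
    }
    haps <- new_haps
    probs <- new_probs
  }
  p <- do.call(rat_c, probs)
  names(p) <- vapply(haps, function(h) paste(names(h), h, sep = ":", collapse = ";"), "")
  structure(list(loci = g$loci, haplotypes = haps, p = p), class = "gamete_dist")
}

#' @export
print.gamete_dist <- function(x, ...) {
  cat("<gamete distribution, ", length(x$haplotypes), " haplotypes>\n", sep = "")
  print(data.frame(haplotype = names(x$p), p = format(x$p),
                   row.names = NULL, stringsAsFactors = FALSE))
  invisible(x)
}

# internal constructor for genotype-class distributions
.gd_new <- function(loci, reps, p) {
  stopifnot(length(reps) == length(p))
  if (length(p) && !isTRUE(sum(p) == rational(1))) {
    stop("internal error: genotype distribution does not sum to 1")
  }
  structure(list(loci = loci, classes = reps, p = p), class = "genotype_dist")
}

#' Single-genotype distribution
#'
#' Wraps one genotype as a degenerate `genotype_dist` (probability 1), the
#' form expected by the scheme propagation machinery.
#'
#' @param g a `genotype`.
#' @return A `genotype_dist`.
#' @export
as_genotype_dist <- function(g) {
  if (inherits(g, "genotype_dist")) return(g)
  stopifnot(inherits(g, "genotype"))
  key <- genotype_class(g)
  p <- rational(1)
  names(p) <- key
  .gd_new(g$loci, structure(list(g), names = key), p)
}

#' Cross two parents exactly
#'
#' Forms the exact offspring distribution as the product of the two parents'
#' gamete distributions, collapsed to unordered genotype classes. The result
#' is symmetric in parent order and its probabilities sum to exactly 1.
#' With `cre_active = TRUE` both parents' transmitted dual alleles are
#' Cre-resolved (helper present in this cross).
#'
#' @param parent_a,parent_b `genotype` objects sharing one locus set.
#' @param cre_active apply Cre resolution to transmitted gametes?
#' @param efficiency Cre resolution efficiency.
#' @return A `genotype_dist`: exact rational probabilities over unordered
#'   genotype classes.
#' @examples
#' loci <- locus_set(transgene_locus("AGOC", c("mO", "mC")))
#' hemi <- genotype(loci, "AGOC:mO/+")
#' cross(hemi, hemi) # 1/4 mO/mO, 1/2 mO/+, 1/4 +/+
#' @export
cross <- function(parent_a, parent_b, cre_active = FALSE, efficiency = 1) {
  stopifnot(inherits(parent_a, "genotype"), inherits(parent_b, "genotype"))
  if (!identical(names(parent_a$loci), names(parent_b$loci))) {
    stop("configuration error: parents have different locus sets")
  }
  ga <- gametes(parent_a, cre_active, efficiency)
  gb <- gametes(parent_b, cre_active, efficiency)
  ids <- names(parent_a$loci)
  keys <- character(0)
  reps <- list()
  probs <- list()
  for (i in seq_along(ga$haplotypes)) {
    for (j in seq_along(gb$haplotypes)) {
      alleles <- lapply(ids, function(id) c(ga$haplotypes[[i]][[id]], gb$haplotypes[[j]][[id]]))
      names(alleles) <- ids
      g <- genotype(parent_a$loci, alleles)
      key <- genotype_class(g)
      p <- ga$p[i] * gb$p[j]
      k <- match(key, keys)
      if (is.na(k)) {
        keys <- c(keys, key)
        reps[[length(reps) + 1L]] <- g
        probs[[length(probs) + 1L]] <- p
      } else {
        probs[[k]] <- probs[[k]] + p
      }
    }
  }
  p <- do.call(rat_c, probs)
  names(p) <- keys
  names(reps) <- keys
  .gd_new(parent_a$loci, reps, p)
}

#' Number of genotype classes in a distribution
#'
#' Counts the unordered genotype classes carrying positive probability. A
#' two-locus sibling cross of double hemizygotes yields the familiar nine
#' classes.
#'
#' @param dist a `genotype_dist`.
#' @return Integer count.
#' @export
count_genotype_classes <- function(dist) {
  stopifnot(inherits(dist, "genotype_dist"))
  sum(as.numeric(dist$p) > 0)
}

#' @export
as.data.frame.genotype_dist <- function(x, ...) {
  data.frame(
    class = names(x$p),
    phenotype = vapply(x$classes, phenotype_of, ""),
    probability = format(x$p),
    decimal = round(as.numeric(x$p), 6),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' @export
print.genotype_dist <- function(x, ...) {
  cat("<genotype distribution, ", length(x$p), " classes>\n", sep = "")
  df <- as.data.frame(x)
  print(df[order(-df$decimal, df$class), ], row.names = FALSE)
  invisible(x)
}
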