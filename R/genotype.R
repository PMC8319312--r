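# Genotypes over a set of unlinked transgene loci.

#' Construct a genotype
#'
#' A genotype assigns to every locus of a locus set an ordered
#' (maternal, paternal) pair of alleles. Alleles are encoded as `"+"`
#' (wild type), `"D"` (unresolved dual-marker cassette) or a marker name
#' (resolved single-marker cassette). Loci omitted from `alleles` default to
#' wild type on both chromosomes. The maternal/paternal order is retained
#' internally but all reporting collapses to unordered genotype classes.
#'
#' @param loci a [locus_set()].
#' @param alleles named list, one entry per locus id, each a character vector
#'   of length 2 `(maternal, paternal)`; or a single genotype string (see
#'   [parse_genotype()]).
#' @param sex optional `"female"` or `"male"`; annotation only, no genetic
#'   effect (all loci are treated as autosomal).
#' @return An object of class `"genotype"`.
#' @examples
#' loci <- locus_set(
#'   transgene_locus("AGOC", c("mO", "mC")),
#'   transgene_locus("ACOS", c("mCe", "mVe"))
#' )
#' genotype(loci, list(AGOC = c("mO", "mC"), ACOS = c("mCe", "mVe")))
#' genotype(loci, "AGOC:mO/mO") # ACOS defaults to +/+
#' @export
genotype <- function(loci, alleles = list(), sex = NULL) {
  if (is.character(alleles)) return(parse_genotype(loci, alleles, sex = sex))
  if (!is.null(sex) && !sex %in% c("female", "male")) {
    stop("sex must be NULL, 'female' or 'male'")
  }
  extra <- setdiff(names(alleles), names(loci))
  if (length(extra)) stop("alleles given for unknown loci: ", paste(extra, collapse = ", "))
  full <- lapply(names(loci), function(id) {
    a <- alleles[[id]]
    if (is.null(a)) a <- c("+", "+")
    if (length(a) != 2L) stop("locus ", id, ": need exactly two alleles")
    .check_allele(a[[1]], loci[[id]])
    .check_allele(a[[2]], loci[[id]])
    a
  })
  names(full) <- names(loci)
  structure(list(loci = loci, alleles = full, sex = sex), class = "genotype")
}

#' All-wild-type genotype
#'
#' @param loci a [locus_set()].
#' @param sex optional sex label.
#' @return A `genotype` with `+/+` at every locus.
#' @export
wildtype_genotype <- function(loci, sex = NULL) genotype(loci, list(), sex = sex)

#' Parse a genotype-class string
#'
#' Reads strings such as `"AGOC:mO/mC;ACOS:mCe/mVe"`. Wild-type alleles are
#' written `"+"`, unresolved dual cassettes `"D"`. Loci absent from the
#' string default to `+/+`.
#'
#' @param loci a [locus_set()].
#' @param text genotype string.
#' @param sex optional sex label.
#' @return A `genotype`.
#' @export
parse_genotype <- function(loci, text, sex = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  alleles <- list()
  if (nzchar(text)) {
    for (part in strsplit(text, ";", fixed = TRUE)[[1]]) {
      kv <- strsplit(trimws(part), ":", fixed = TRUE)[[1]]
      if (length(kv) != 2L) stop("malformed genotype segment '", part, "'")
      id <- trimws(kv[[1]])
      if (!id %in% names(loci)) stop("unknown locus '", id, "' in genotype string")
      pair <- strsplit(trimws(kv[[2]]), "/", fixed = TRUE)[[1]]
      if (length(pair) != 2L) stop("locus ", id, ": allele pair must be written a/b")
      alleles[[id]] <- trimws(pair)
    }
  }
  genotype(loci, alleles, sex = sex)
}

#' Canonical genotype-class string
#'
#' Serializes the unordered genotype class: per locus the two alleles are
#' sorted canonically (resolved markers in canonical order, then `"D"`, then
#' `"+"`), loci appear in locus-set order. Two genotypes that differ only by
#' maternal/paternal swaps share the same class string.
#'
#' @param g a `genotype`.
#' @return Length-one character string, e.g. `"AGOC:mO/mC;ACOS:mCe/mVe"`.
#' @export
genotype_class <- function(g) {
  stopifnot(inherits(g, "genotype"))
  parts <- vapply(names(g$loci), function(id) {
    a <- g$alleles[[id]]
    a <- a[order(.allele_rank(a))]
    paste0(id, ":", a[[1]], "/", a[[2]])
  }, "")
  paste(parts, collapse = ";")
}

#' @export
print.genotype <- function(x, ...) {
  cat("<genotype ", genotype_class(x),
      if (!is.null(x$sex)) paste0(" (", x$sex, ")"), ">\n", sep = "")
  invisible(x)
}

#' Visible phenotype of a genotype
#'
#' The phenotype is the union of transformation markers made visible by any
#' allele at any locus: a single-marker allele shows its marker, an
#' unresolved dual cassette shows both markers of its locus pair, wild-type
#' alleles show nothing. Invariant under maternal/paternal swaps.
#'
#' @param g a `genotype`.
#' @return Canonical phenotype string (see [phenotype_string()]).
#' @examples
#' loci <- locus_set(transgene_locus("AGOC", c("mO", "mC")))
#' phenotype_of(genotype(loci, "AGOC:mO/mC")) # "mO+mC"
#' phenotype_of(wildtype_genotype(loci))      # "wt"
#' @export
phenotype_of <- function(g) {
  stopifnot(inherits(g, "genotype"))
  m <- unlist(lapply(names(g$loci), function(id) {
    c(.allele_markers(g$alleles[[id]][[1]], g$loci[[id]]),
      .allele_markers(g$alleles[[id]][[2]], g$loci[[id]]))
  }))
  phenotype_string(if (is.null(m)) character(0) else m)
}

#' Zygosity of a genotype at one locus
#'
#' Classifies the allele pair at `locus`: `wildtype` (no transgene-bearing
#' allele), `hemizygous` (exactly one), `homozygous` (two transgene-bearing
#' alleles with identical visible marker sets), or `heterozygous` (two
#' transgene-bearing alleles with different visible marker sets — the key
#' selectable intermediate, revealed by showing both cassette markers).
#'
#' @param g a `genotype`.
#' @param locus locus id (or `transgene_locus`).
#' @return One of `"wildtype"`, `"hemizygous"`, `"heterozygous"`,
#'   `"homozygous"`.
#' @export
classify_zygosity <- function(g, locus) {
  stopifnot(inherits(g, "genotype"))
  id <- if (inherits(locus, "transgene_locus")) locus$id else locus
  if (!id %in% names(g$loci)) stop("locus ", id, " not present in genotype")
  a <- g$alleles[[id]]
  bearing <- a != "+"
  if (!any(bearing)) return("wildtype")
  if (sum(bearing) == 1L) return("hemizygous")
  m1 <- .allele_markers(a[[1]], g$loci[[id]])
  m2 <- .allele_markers(a[[2]], g$loci[[id]])
  if (setequal(m1, m2)) "homozygous" else "heterozygous"
}

#' Enumerate all unordered genotype classes over a locus set
#'
#' All unordered allele-pair combinations per locus, combined over loci.
#' Used as the default candidate set for [infer_parent_from_testcross()].
#'
#' @param loci a [locus_set()].
#' @param include_dual include unresolved dual-cassette alleles (`"D"`)?
#' @return Named list of `genotype` objects, named by class string.
#' @export
all_genotype_classes <- function(loci, include_dual = TRUE) {
  per_locus <- lapply(loci, function(lc) {
    alleles <- c(lc$markers, if (include_dual && length(lc$markers) == 2L) "D", "+")
    pairs <- list()
    for (i in seq_along(alleles)) {
      for (j in i:length(alleles)) {
        pairs[[length(pairs) + 1L]] <- c(alleles[[i]], alleles[[j]])
      }
    }
    pairs
  })
  grid <- expand.grid(lapply(per_locus, seq_along), KEEP.OUT.ATTRS = FALSE)
  out <- list()
  for (r in seq_len(nrow(grid))) {
    alleles <- lapply(seq_along(loci), function(l) per_locus[[l]][[grid[r, l]]])
    names(alleles) <- names(loci)
    g <- genotype(loci, alleles)
    out[[genotype_class(g)]] <- g
  }
  out
}
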