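# Canonical transformation markers and transgene loci.
#
# Four eye-specific fluorescent transformation markers are supported: mOrange
# (mO) and mCherry (mC) form one cassette pair, mCerulean (mCe) and mVenus
# (mVe) the other. Under suitable filter sets all four are distinguishable,
# which is what makes two-transgene phenotype scoring unambiguous.

LOX_MARKERS <- c("mO", "mC", "mCe", "mVe")

#' Canonical transformation markers
#'
#' Returns the four recognised marker names in their fixed canonical order
#' (`mO < mC < mCe < mVe`). All phenotype strings and genotype-class strings
#' use this order.
#'
#' @return Character vector of the four marker names.
#' @export
canonical_markers <- function() LOX_MARKERS

#' Marker metadata
#'
#' Fluorophore and detection filter label for each canonical marker. The
#' filter labels are free-text descriptions of the filter set used to score
#' the marker; they carry no computational meaning.
#'
#' @return A data frame with columns `name`, `fluorophore`, `filter_label`.
#' @export
marker_info <- function() {
  data.frame(
    name = LOX_MARKERS,
    fluorophore = c("mOrange", "mCherry", "mCerulean", "mVenus"),
    filter_label = c("FS orange", "FS red", "FS cyan", "FS yellow"),
    stringsAsFactors = FALSE
  )
}

.check_markers <- function(markers, what = "marker") {
  bad <- setdiff(markers, LOX_MARKERS)
  if (length(bad)) {
    stop("unknown ", what, ": ", paste(bad, collapse = ", "),
         " (known: ", paste(LOX_MARKERS, collapse = ", "), ")", call. = FALSE)
  }
  invisible(markers)
}

# sort markers into canonical order, dropping duplicates
.canon_markers <- function(markers) {
  LOX_MARKERS[sort(unique(match(markers, LOX_MARKERS)))]
}

#' Define a transgene locus
#'
#' A locus is a chromosomal insertion site of a transgene cassette. A
#' dual-marker cassette carries two markers embedded in interweaved but
#' mutually incompatible Lox site pairs, so Cre exposure resolves it to a
#' single-marker allele. Helper (Cre-expressing) transgenes carry a single
#' marker.
#'
#' @param id locus identifier, e.g. `"AGOC"`, `"ACOS"`, `"FIRE"`.
#' @param markers character vector of one (helper) or two (dual cassette)
#'   distinct canonical marker names; for a dual cassette these are the two
#'   markers of the cassette.
#' @param chromosome optional free-text chromosome label.
#' @return An object of class `"transgene_locus"`.
#' @examples
#' transgene_locus("AGOC", c("mO", "mC"))
#' transgene_locus("FIRE", "mC", chromosome = "ChLGX")
#' @export
transgene_locus <- function(id, markers, chromosome = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  .check_markers(markers)
  if (!length(markers) %in% 1:2) stop("a locus carries one or two markers")
  if (anyDuplicated(markers)) stop("locus markers must be distinct")
  structure(
    list(id = id, markers = .canon_markers(markers), chromosome = chromosome),
    class = "transgene_locus"
  )
}

#' @export
print.transgene_locus <- function(x, ...) {
  cat("<locus ", x$id, ": ", paste(x$markers, collapse = "/"),
      if (!is.na(x$chromosome)) paste0(" on ", x$chromosome), ">\n", sep = "")
  invisible(x)
}

#' Assemble a locus set
#'
#' Collects loci into the named, ordered list used by [genotype()] and
#' [mating_scheme()]. Locus order is declaration order and fixes the order
#' of genotype-class strings.
#'
#' @param ... `transgene_locus` objects.
#' @return Named list of loci.
#' @export
locus_set <- function(...) {
  loci <- list(...)
  if (length(loci) == 1L && is.list(loci[[1]]) && !inherits(loci[[1]], "transgene_locus")) {
    loci <- loci[[1]]
  }
  ok <- vapply(loci, inherits, TRUE, "transgene_locus")
  if (!all(ok)) stop("all elements must be transgene_locus objects")
  ids <- vapply(loci, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate locus ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  names(loci) <- ids
  loci
}

# --- alleles ----------------------------------------------------------------
# An allele at a locus is encoded as a string: "+" (wild type, no transgene),
# "D" (unresolved dual-marker cassette), or a marker name (Cre-resolved
# single-marker cassette). "D" is only valid at two-marker loci.

.check_allele <- function(allele, locus) {
  ok <- allele == "+" ||
    (allele == "D" && length(locus$markers) == 2L) ||
    allele %in% locus$markers
  if (!ok) {
    stop("invalid allele '", allele, "' at locus ", locus$id,
         " (expected '+', 'D' or one of ", paste(locus$markers, collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(allele)
}

# markers made visible by one allele
.allele_markers <- function(allele, locus) {
  if (allele == "+") return(character(0))
  if (allele == "D") return(locus$markers)
  allele
}

# canonical sort rank for an allele string: resolved markers first (canonical
# marker order), then dual, then wild type
.allele_rank <- function(allele) {
  r <- match(allele, LOX_MARKERS)
  r[allele == "D"] <- 5L
  r[allele == "+"] <- 6L
  r
}

#' Serialize a marker set as a canonical phenotype string
#'
#' Markers are joined in canonical order with `"+"`; the empty set is the
#' wild-type phenotype `"wt"`.
#'
#' @param markers character vector of marker names (possibly empty).
#' @return Length-one character string.
#' @examples
#' phenotype_string(c("mCe", "mO")) # "mO+mCe"
#' phenotype_string(character(0))   # "wt"
#' @export
phenotype_string <- function(markers) {
  .check_markers(markers)
  m <- .canon_markers(markers)
  if (!length(m)) "wt" else paste(m, collapse = "+")
}

#' Parse a phenotype string into a marker set
#'
#' Inverse of [phenotype_string()]; accepts markers in any order and
#' canonicalizes (`"mCe+mO"` parses to the same set as `"mO+mCe"`).
#'
#' @param text phenotype string, e.g. `"mO+mCe"` or `"wt"`.
#' @return Character vector of markers in canonical order (empty for `"wt"`).
#' @export
parse_phenotype <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (text == "wt" || text == "") return(character(0))
  m <- strsplit(text, "+", fixed = TRUE)[[1]]
  .check_markers(m, what = "marker in phenotype")
  .canon_markers(m)
}
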