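# Table and config I/O. Scoring tables travel as plain TSV; schemes are
# declared in YAML. Exactness lives in the data structures; files carry
# fractions as strings and decimals only for human inspection.

.SCORING_COLS <- c("vial_id", "cross_id", "generation", "phenotype", "count")

#' Read a vial-level scoring table
#'
#' Reads a TSV with header `vial_id, cross_id, generation, phenotype,
#' count`, validates it and canonicalizes phenotype strings (`"mCe+mO"`
#' becomes `"mO+mCe"`). Unknown marker tokens, negative counts and
#' duplicate (vial, phenotype) rows are errors.
#'
#' @param path file path.
#' @return A data frame of class `"scoring_table"`.
#' @export
read_scoring_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(sort(names(tab)), sort(.SCORING_COLS))) {
    stop("scoring table must have columns: ", paste(.SCORING_COLS, collapse = ", "))
  }
  tab <- tab[, .SCORING_COLS]
  if (!is.numeric(tab$count) || any(is.na(tab$count)) || any(tab$count != round(tab$count))) {
    stop("counts must be integers")
  }
  if (any(tab$count < 0)) stop("negative count in scoring table")
  tab$phenotype <- vapply(tab$phenotype, function(s) phenotype_string(parse_phenotype(s)), "")
  key <- paste(tab$vial_id, tab$cross_id, tab$generation, tab$phenotype)
  if (anyDuplicated(key)) {
    stop("duplicate (vial, phenotype) row: ", key[duplicated(key)][[1]])
  }
  tab$count <- as.integer(tab$count)
  class(tab) <- c("scoring_table", "data.frame")
  tab
}

#' Write a scoring table as TSV
#'
#' @param table a `scoring_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scoring_table <- function(table, path) {
  stopifnot(is.data.frame(table), all(.SCORING_COLS %in% names(table)))
  utils::write.table(table[, .SCORING_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pivot a scoring table to wide layout
#'
#' One row per vial, one column per phenotype class plus a `total` column —
#' the layout used for human inspection of mating-procedure results.
#'
#' @param table a `scoring_table`.
#' @return A wide data frame.
#' @export
pivot_scoring_table <- function(table) {
  stopifnot(is.data.frame(table))
  vials <- unique(table$vial_id)
  phens <- unique(table$phenotype)
  out <- data.frame(vial_id = vials, stringsAsFactors = FALSE)
  for (ph in phens) {
    out[[ph]] <- vapply(vials, function(v) {
      sum(table$count[table$vial_id == v & table$phenotype == ph])
    }, 0L)
  }
  out$total <- vapply(vials, function(v) sum(table$count[table$vial_id == v]), 0L)
  out
}

#' Write a scheme-run report as TSV
#'
#' @param run a `scheme_run` (see [run_scheme()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_generation_report <- function(run, path) {
  utils::write.table(report_table(run), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a mating scheme from a YAML config
#'
#' The config declares the loci (id, markers, optional chromosome) and the
#' steps. Each step names the progeny generation it produces, two parents —
#' either `genotype: "AGOC:mO/+;ACOS:+/+"` or
#' `from: <label>` with optional `require:`/`forbid:` marker lists and
#' `sex:` — and an optional `cre: true` flag marking helper presence.
#' The three built-in schemes under `inst/extdata/schemes/` are examples of
#' the format.
#'
#' @param path YAML file path.
#' @return A [mating_scheme()].
#' @export
read_scheme_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$name) || is.null(cfg$loci) || is.null(cfg$steps)) {
    stop("scheme config needs 'name', 'loci' and 'steps'")
  }
  loci <- locus_set(lapply(cfg$loci, function(l) {
    transgene_locus(l$id, unlist(l$markers),
                    chromosome = if (is.null(l$chromosome)) NA_character_ else l$chromosome)
  }))
  parse_parent <- function(ps, where) {
    if (!is.null(ps$genotype)) {
      fixed_parent(ps$genotype)
    } else if (!is.null(ps$from)) {
      from_generation(ps$from,
                      require = if (is.null(ps$require)) character(0) else unlist(ps$require),
                      forbid = if (is.null(ps$forbid)) character(0) else unlist(ps$forbid),
                      sex = ps$sex)
    } else {
      stop("step ", where, ": parent needs either 'genotype' or 'from'")
    }
  }
  steps <- lapply(cfg$steps, function(s) {
    scheme_step(s$label,
                parse_parent(s$parent_a, s$label),
                parse_parent(s$parent_b, s$label),
                cre_active = isTRUE(s$cre))
  })
  mating_scheme(cfg$name, loci, steps)
}

#' Built-in mating schemes
#'
#' Three ready-made schemes covering the standard use cases:
#' \describe{
#'   \item{`agoc_single`}{Creation of a single homozygous line from a
#'     dual-cassette founder: founder x Cre helper, Cre-resolved gametes
#'     outcrossed to wild type, the two single-marker hemizygote classes
#'     intercrossed (suitable heterozygotes arise at 25%), then a
#'     heterozygote sibling cross whose single-marker progeny phenotypes
#'     reveal homozygotes. A reconstruction of the canonical
#'     single-transgene procedure.}
#'   \item{`agoc_acos_double`}{Creation of a double homozygous line from
#'     two single homozygous lines with color-complementary cassettes:
#'     two parallel homozygote x homozygote crosses give 100% double
#'     hemizygotes, these are intercrossed to obtain four-marker double
#'     heterozygotes, and the final sibling cross yields each
#'     double-homozygous marker combination at 1/16.}
#'   \item{`resegregation`}{Splitting a double-transgenic line back into
#'     singles via wild-type outcrosses, then rebuilding double homozygotes
#'     with the alternative marker pairing.}
#' }
#'
#' @param name one of `"agoc_single"`, `"agoc_acos_double"`,
#'   `"resegregation"`.
#' @return A [mating_scheme()].
#' @examples
#' run_scheme(builtin_scheme("agoc_acos_double"))
#' @export
builtin_scheme <- function(name = c("agoc_single", "agoc_acos_double", "resegregation")) {
  name <- match.arg(name)
  path <- system.file("extdata", "schemes", paste0(name, ".yaml"),
                      package = "loxcross", mustWork = TRUE)
  read_scheme_config(path)
}
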