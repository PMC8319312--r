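# Declarative multi-generation mating schemes.
#
# A scheme names its loci and an ordered list of crossing steps. Each step
# produces one progeny generation; parents are either explicit genotypes
# (founders, wild types) or phenotype-selected individuals drawn from an
# earlier generation. Selection acts on what a screen can see — marker
# presence/absence — never on the underlying genotype, which is the whole
# premise of non-invasive scoring.

#' Phenotype-based selection rule
#'
#' Selects individuals whose visible marker set contains every marker in
#' `require` and none in `forbid`. An optional sex label restricts which
#' individuals are drawn but has no genetic effect (sex is assigned 1:1
#' independently of genotype).
#'
#' @param require markers that must be visible.
#' @param forbid markers that must be absent.
#' @param sex optional `"female"` or `"male"`.
#' @return An object of class `"selection_rule"`.
#' @export
selection_rule <- function(require = character(0), forbid = character(0), sex = NULL) {
  .check_markers(require)
  .check_markers(forbid)
  if (length(intersect(require, forbid))) {
    stop("required and forbidden marker sets must be disjoint")
  }
  if (!is.null(sex) && !sex %in% c("female", "male")) stop("invalid sex label")
  structure(
    list(require = .canon_markers(require), forbid = .canon_markers(forbid), sex = sex),
    class = "selection_rule"
  )
}

#' @export
print.selection_rule <- function(x, ...) {
  cat("<select",
      if (length(x$require)) paste0(" +[", paste(x$require, collapse = ","), "]"),
      if (length(x$forbid)) paste0(" -[", paste(x$forbid, collapse = ","), "]"),
      if (!is.null(x$sex)) paste0(" ", x$sex),
      ">\n", sep = "")
  invisible(x)
}

.rule_matches <- function(markers, rule) {
  all(rule$require %in% markers) && !any(rule$forbid %in% markers)
}

#' Parent drawn from an earlier generation
#'
#' @param from generation label of an earlier step.
#' @param require,forbid,sex forwarded to [selection_rule()].
#' @return A parent specification for [scheme_step()].
#' @export
from_generation <- function(from, require = character(0), forbid = character(0), sex = NULL) {
  stopifnot(is.character(from), length(from) == 1L)
  structure(list(from = from, rule = selection_rule(require, forbid, sex)),
            class = "parent_spec")
}

#' Explicit parent genotype
#'
#' @param g a `genotype`, or a genotype string resolved against the scheme's
#'   loci when the scheme is built.
#' @return A parent specification for [scheme_step()].
#' @export
fixed_parent <- function(g) {
  stopifnot(inherits(g, "genotype") || (is.character(g) && length(g) == 1L))
  structure(list(genotype = g), class = "parent_spec")
}

#' One crossing step of a mating scheme
#'
#' @param label generation label of the progeny this step produces
#'   (e.g. `"F9"`); must be unique within the scheme.
#' @param parent_a,parent_b parent specifications ([from_generation()] or
#'   [fixed_parent()]).
#' @param cre_active is a Cre helper present in this cross (transmitted dual
#'   alleles get resolved)?
#' @return An object of class `"scheme_step"`.
#' @export
scheme_step <- function(label, parent_a, parent_b, cre_active = FALSE) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label),
            inherits(parent_a, "parent_spec"), inherits(parent_b, "parent_spec"),
            is.logical(cre_active), length(cre_active) == 1L)
  structure(list(label = label, parent_a = parent_a, parent_b = parent_b,
                 cre_active = cre_active), class = "scheme_step")
}

#' Assemble a mating scheme
#'
#' Validates that generation labels are unique, every `from` reference
#' points to an earlier step, and explicit parent genotype strings parse
#' against the scheme's loci.
#'
#' @param name scheme name.
#' @param loci a [locus_set()].
#' @param steps list of [scheme_step()] objects, in chronological order.
#' @return An object of class `"mating_scheme"`.
#' @export
mating_scheme <- function(name, loci, steps) {
  stopifnot(is.character(name), length(name) == 1L, length(steps) >= 1L)
  ok <- vapply(steps, inherits, TRUE, "scheme_step")
  if (!all(ok)) stop("steps must be scheme_step objects")
  labels <- vapply(steps, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicate generation labels")
  seen <- character(0)
  for (k in seq_along(steps)) {
    for (side in c("parent_a", "parent_b")) {
      ps <- steps[[k]][[side]]
      if (!is.null(ps$from)) {
        if (!ps$from %in% seen) {
          stop("step ", labels[[k]], ": ", side, " references generation '",
               ps$from, "' which does not precede it")
        }
      } else if (is.character(ps$genotype)) {
        steps[[k]][[side]]$genotype <- parse_genotype(loci, ps$genotype)
      }
    }
    seen <- c(seen, labels[[k]])
  }
  structure(list(name = name, loci = loci, steps = steps), class = "mating_scheme")
}

#' @export
print.mating_scheme <- function(x, ...) {
  cat("<mating scheme '", x$name, "': ", length(x$loci), " loci, ",
      length(x$steps), " steps>\n", sep = "")
  for (s in x$steps) {
    fmt <- function(ps) {
      if (!is.null(ps$from)) {
        r <- ps$rule
        paste0(ps$from,
               if (length(r$require)) paste0(" +[", paste(r$require, collapse = ","), "]"),
               if (length(r$forbid)) paste0(" -[", paste(r$forbid, collapse = ","), "]"))
      } else {
        genotype_class(ps$genotype)
      }
    }
    cat("  ", s$label, ": ", fmt(s$parent_a), " x ", fmt(s$parent_b),
        if (s$cre_active) "  [Cre]", "\n", sep = "")
  }
  invisible(x)
}

# --- distribution-level operations ------------------------------------------

#' Phenotype distribution of a genotype distribution
#'
#' Pushes a genotype-class distribution forward through [phenotype_of()]:
#' classes sharing a visible marker set pool their probability. Exact; sums
#' to 1.
#'
#' @param dist a `genotype_dist`.
#' @return Named [rational()] vector, names are canonical phenotype strings,
#'   ordered by decreasing probability.
#' @export
phenotype_distribution <- function(dist) {
  stopifnot(inherits(dist, "genotype_dist"))
  phen <- vapply(dist$classes, phenotype_of, "")
  keys <- character(0)
  probs <- list()
  for (i in seq_along(phen)) {
    k <- match(phen[[i]], keys)
    if (is.na(k)) {
      keys <- c(keys, phen[[i]])
      probs[[length(probs) + 1L]] <- dist$p[i]
    } else {
      probs[[k]] <- probs[[k]] + dist$p[i]
    }
  }
  p <- do.call(rat_c, probs)
  names(p) <- keys
  ord <- order(-as.numeric(p), keys)
  p[ord]
}

#' Which genotype classes lie behind each phenotype
#'
#' Maps every phenotype in the support of a distribution to the set of
#' genotype classes (positive probability) that display it. A phenotype is
#' *deterministic* when that set is a singleton — scoring it identifies the
#' genotype outright. This is the identifiability analysis behind
#' marker-based zygosity reading: after Cre resolution, losing one marker of
#' a pair is what reveals homozygosity.
#'
#' @param dist a `genotype_dist`.
#' @return An object of class `"scoring_map"`: a named list
#'   (phenotype -> character vector of class strings) with a named logical
#'   attribute `"deterministic"`.
#' @export
scoring_map <- function(dist) {
  stopifnot(inherits(dist, "genotype_dist"))
  phen <- vapply(dist$classes, phenotype_of, "")
  out <- lapply(split(names(dist$p), phen), sort)
  det <- vapply(out, function(v) length(v) == 1L, TRUE)
  structure(out, deterministic = det, class = "scoring_map")
}

#' @export
print.scoring_map <- function(x, ...) {
  det <- attr(x, "deterministic")
  for (ph in names(x)) {
    cat(format(ph, width = 14), if (det[[ph]]) "-> " else "~> ",
        paste(x[[ph]], collapse = " | "),
        if (!det[[ph]]) "   [ambiguous]", "\n", sep = "")
  }
  invisible(x)
}

#' Condition a genotype distribution on a phenotype selection
#'
#' Restricts to genotype classes whose phenotype satisfies the rule and
#' renormalizes exactly. Selecting on an impossible phenotype is an error
#' (an empty vial cannot parent the next generation).
#'
#' @param dist a `genotype_dist`.
#' @param rule a [selection_rule()].
#' @param context optional label used in the empty-selection error message.
#' @return A `genotype_dist`.
#' @export
apply_selection <- function(dist, rule, context = NULL) {
  stopifnot(inherits(dist, "genotype_dist"), inherits(rule, "selection_rule"))
  phen <- vapply(dist$classes, phenotype_of, "")
  keep <- vapply(phen, function(ph) .rule_matches(parse_phenotype(ph), rule), TRUE)
  keep <- keep & as.numeric(dist$p) > 0
  if (!any(keep)) {
    stop("empty selection", if (!is.null(context)) paste0(" at step '", context, "'"),
         ": no genotype class matches ", paste(format(rule$require), collapse = ","),
         call. = FALSE)
  }
  keys <- names(dist$p)[which(keep)]
  p <- dist$p[which(keep)] / sum(dist$p[which(keep)])
  names(p) <- keys
  .gd_new(dist$loci, dist$classes[which(keep)], p)
}

# exact offspring distribution when each parent is itself a distribution
.cross_pool <- function(da, db, cre_active = FALSE, efficiency = 1) {
  keys <- character(0)
  reps <- list()
  probs <- list()
  for (i in seq_along(da$p)) {
    for (j in seq_along(db$p)) {
      w <- da$p[i] * db$p[j]
      off <- cross(da$classes[[i]], db$classes[[j]], cre_active, efficiency)
      for (k in seq_along(off$p)) {
        key <- names(off$p)[[k]]
        p <- w * off$p[k]
        m <- match(key, keys)
        if (is.na(m)) {
          keys <- c(keys, key)
          reps[[length(reps) + 1L]] <- off$classes[[k]]
          probs[[length(probs) + 1L]] <- p
        } else {
          probs[[m]] <- probs[[m]] + p
        }
      }
    }
  }
  p <- do.call(rat_c, probs)
  names(p) <- keys
  names(reps) <- keys
  .gd_new(da$loci, reps, p)
}

#' Propagate a mating scheme generation by generation
#'
#' Runs every step of the scheme with exact arithmetic: parent pools are
#' conditioned on their selection rules, the cross is formed (with Cre
#' resolution where the step declares a helper), and each progeny
#' generation is reported with its genotype distribution, phenotype
#' distribution and scoring map. Steps whose selection rule matches an
#' ambiguous phenotype still run, but the report flags the selection as
#' non-deterministic.
#'
#' @param scheme a [mating_scheme()].
#' @param efficiency Cre resolution efficiency used wherever a step is
#'   `cre_active`.
#' @return An object of class `"scheme_run"`: a list of per-generation
#'   reports, each with elements `label`, `genotype_dist`, `phenotype_dist`,
#'   `scoring`, `selection_ambiguous` (named flags for the two parents).
#' @examples
#' run <- run_scheme(builtin_scheme("agoc_acos_double"))
#' run[["F10"]]$phenotype_dist
#' @export
run_scheme <- function(scheme, efficiency = 1) {
  stopifnot(inherits(scheme, "mating_scheme"))
  pools <- list()
  reports <- list()
  for (s in scheme$steps) {
    resolve <- function(ps, side) {
      if (!is.null(ps$from)) {
        pool <- pools[[ps$from]]
        if (is.null(pool)) stop("step ", s$label, ": dangling generation reference '", ps$from, "'")
        sel <- apply_selection(pool, ps$rule, context = s$label)
        list(dist = sel, ambiguous = length(sel$p) > 1L)
      } else {
        list(dist = as_genotype_dist(ps$genotype), ambiguous = FALSE)
      }
    }
    pa <- resolve(s$parent_a, "parent_a")
    pb <- resolve(s$parent_b, "parent_b")
    off <- .cross_pool(pa$dist, pb$dist, s$cre_active, efficiency)
    pools[[s$label]] <- off
    reports[[s$label]] <- list(
      label = s$label,
      genotype_dist = off,
      phenotype_dist = phenotype_distribution(off),
      scoring = scoring_map(off),
      selection_ambiguous = c(parent_a = pa$ambiguous, parent_b = pb$ambiguous)
    )
  }
  structure(reports, scheme = scheme, class = "scheme_run")
}

#' @export
print.scheme_run <- function(x, ...) {
  scheme <- attr(x, "scheme")
  cat("Scheme '", scheme$name, "' — theoretical progeny ratios\n", sep = "")
  for (rep in x) {
    cat("\n", rep$label, ":\n", sep = "")
    pd <- rep$phenotype_dist
    det <- attr(rep$scoring, "deterministic")
    for (i in seq_along(pd)) {
      ph <- names(pd)[[i]]
      cat(sprintf("  %-12s %8s  (%6.2f%%)%s\n", ph, format(pd[i]),
                  100 * as.numeric(pd[i]),
                  if (!det[[ph]]) "  [ambiguous genotype]" else ""))
    }
    if (any(rep$selection_ambiguous)) {
      cat("  note: non-deterministic parent selection\n")
    }
  }
  invisible(x)
}

#' Tabulate a scheme run
#'
#' Flattens a [run_scheme()] result into one row per generation and
#' phenotype, with exact and decimal ratios, the genotype classes behind
#' each phenotype and whether scoring that phenotype is deterministic.
#'
#' @param run a `scheme_run`.
#' @return A data frame with columns `generation`, `phenotype`, `ratio`,
#'   `ratio_decimal`, `genotype_classes`, `deterministic`.
#' @export
report_table <- function(run) {
  stopifnot(inherits(run, "scheme_run"))
  rows <- lapply(run, function(rep) {
    pd <- rep$phenotype_dist
    det <- attr(rep$scoring, "deterministic")
    data.frame(
      generation = rep$label,
      phenotype = names(pd),
      ratio = format(pd),
      ratio_decimal = round(as.numeric(pd), 6),
      genotype_classes = vapply(names(pd), function(ph) paste(rep$scoring[[ph]], collapse = "|"), ""),
      deterministic = vapply(names(pd), function(ph) det[[ph]], TRUE),
      row.names = NULL,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# --- testcrosses ------------------------------------------------------------

#' Expected testcross phenotype distribution
#'
#' Phenotype distribution of the progeny when `g` is mated to wild type.
#' Because wild type contributes only `"+"` alleles, the progeny marker
#' distribution reads out the gametes of `g` directly, which is what makes
#' the testcross a genotype verifier.
#'
#' @param g a `genotype`.
#' @return Named [rational()] phenotype distribution.
#' @export
testcross_expectation <- function(g) {
  stopifnot(inherits(g, "genotype"))
  phenotype_distribution(cross(g, wildtype_genotype(g$loci)))
}

#' Infer a parental genotype from observed testcross phenotypes
#'
#' Given the set of phenotype classes observed among testcross progeny,
#' returns the candidate genotype classes whose expected testcross support
#' (the phenotypes with positive probability) equals the observed set.
#'
#' @param observed character vector of observed phenotype strings (any
#'   marker order; canonicalized).
#' @param candidates named list of candidate `genotype` objects, e.g.
#'   [all_genotype_classes()] or the `classes` of a `genotype_dist`.
#' @return Named list of compatible genotypes (names are class strings).
#' @export
infer_parent_from_testcross <- function(observed, candidates) {
  stopifnot(length(observed) >= 1L)
  obs <- sort(unique(vapply(observed, function(s) phenotype_string(parse_phenotype(s)), "")))
  if (inherits(candidates, "genotype_dist")) candidates <- candidates$classes
  hits <- Filter(function(g) {
    supp <- sort(names(testcross_expectation(g)))
    identical(supp, obs)
  }, candidates)
  if (!length(hits)) {
    stop("inconsistent scoring: no candidate genotype has testcross support {",
         paste(obs, collapse = ", "), "}", call. = FALSE)
  }
  hits
}

#' Check a scheme for marker collisions
#'
#' Two loci whose marker sets intersect cannot be scored side by side: the
#' shared marker's presence would be ambiguous. This is why a Cre helper
#' line is recolored before being combined with a cassette that already
#' uses its marker.
#'
#' @param scheme a `mating_scheme` (or a [locus_set()]).
#' @return A data frame with columns `locus_a`, `locus_b`, `shared_markers`;
#'   zero rows when the scheme is collision-free.
#' @export
check_marker_collisions <- function(scheme) {
  loci <- if (inherits(scheme, "mating_scheme")) scheme$loci else scheme
  ids <- names(loci)
  rows <- list()
  if (length(ids) >= 2L) {
    for (i in seq_len(length(ids) - 1L)) {
      for (j in (i + 1L):length(ids)) {
        shared <- intersect(loci[[i]]$markers, loci[[j]]$markers)
        if (length(shared)) {
          rows[[length(rows) + 1L]] <- data.frame(
            locus_a = ids[[i]], locus_b = ids[[j]],
            shared_markers = paste(shared, collapse = "+"),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(rows)) {
    data.frame(locus_a = character(0), locus_b = character(0),
               shared_markers = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
}
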