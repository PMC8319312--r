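# Exact reduced-fraction arithmetic. All genotype/phenotype probabilities in
# the crossing engine are propagated as rationals so Mendelian ratios such as
# 9/16 come out exact, not as 0.5625000000000001. Numerators and denominators
# are carried in doubles (exact integers up to 2^53); operations abort on
# overflow rather than silently losing exactness.

.gcd2 <- function(a, b) {
  while (b != 0) {
    t <- a %% b
    a <- b
    b <- t
  }
  a
}

.rat_check <- function(n, d) {
  if (any(abs(n) >= 2^53) || any(d >= 2^53)) {
    stop("rational overflow: value no longer exactly representable", call. = FALSE)
  }
}

#' Exact rational numbers
#'
#' Construct a vector of exact fractions `num/den`, stored in reduced form
#' with positive denominators. These underlie every probability returned by
#' [cross()], [gametes()], [phenotype_distribution()] and friends, so that
#' Mendelian ratios are exact and distributions sum to exactly one.
#'
#' Arithmetic (`+`, `-`, `*`, `/`), comparisons and `sum()` are supported and
#' stay exact; `as.numeric()` converts to double for presentation or
#' statistics.
#'
#' @param num integer-valued numerators.
#' @param den integer-valued denominators (recycled; must be non-zero).
#' @return An object of class `"rational"`.
#' @examples
#' rational(9, 16) + rational(7, 16)
#' sum(rational(1, 4) * rational(1, 4), rational(3, 16))
#' @export
rational <- function(num, den = 1) {
  if (length(den) == 1L && length(num) > 1L) den <- rep(den, length(num))
  if (length(num) == 1L && length(den) > 1L) num <- rep(num, length(den))
  if (length(num) != length(den)) stop("num and den lengths differ")
  if (any(den == 0)) stop("zero denominator")
  if (any(num != round(num)) || any(den != round(den))) {
    stop("num and den must be integer-valued")
  }
  s <- sign(den)
  num <- num * s
  den <- den * s
  g <- mapply(.gcd2, abs(num), den)
  g[g == 0] <- 1
  n <- num / g
  d <- den / g
  .rat_check(n, d)
  structure(list(n = n, d = d, nm = NULL), class = "rational")
}

#' Coerce to an exact rational
#'
#' Accepts `rational` objects (returned unchanged), fraction strings such as
#' `"9/16"`, integer-valued numerics, and general doubles (converted by
#' continued-fraction expansion, erroring if no exact small-denominator
#' representation exists within tolerance).
#'
#' @param x object to coerce.
#' @param max_den largest denominator admitted when approximating a double.
#' @return A `rational` vector.
#' @export
as_rational <- function(x, max_den = 1e9) {
  if (inherits(x, "rational")) return(x)
  if (is.character(x)) {
    parts <- strsplit(x, "/", fixed = TRUE)
    num <- suppressWarnings(vapply(parts, function(p) as.numeric(p[[1]]), 0))
    den <- suppressWarnings(vapply(parts, function(p) if (length(p) > 1L) as.numeric(p[[2]]) else 1, 0))
    if (any(is.na(num)) || any(is.na(den))) stop("cannot parse fraction string")
    return(rational(num, den))
  }
  if (!is.numeric(x)) stop("cannot coerce to rational")
  n <- d <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[[i]]
    if (xi == round(xi)) {
      n[i] <- xi
      d[i] <- 1
    } else {
      cf <- .double_to_frac(xi, max_den)
      n[i] <- cf[[1]]
      d[i] <- cf[[2]]
    }
  }
  rational(n, d)
}

# continued-fraction expansion of a double; errors if the convergent with
# denominator <= max_den is not within 1e-12 relative error
.double_to_frac <- function(x, max_den) {
  h0 <- 0; h1 <- 1; k0 <- 1; k1 <- 0
  r <- x
  for (it in 1:64) {
    a <- floor(r)
    h <- a * h1 + h0
    k <- a * k1 + k0
    if (k > max_den) break
    h0 <- h1; h1 <- h; k0 <- k1; k1 <- k
    if (abs(h1 / k1 - x) <= 1e-12 * max(1, abs(x))) {
      return(c(h1, k1))
    }
    frac <- r - a
    if (frac == 0) break
    r <- 1 / frac
  }
  if (abs(h1 / k1 - x) <= 1e-12 * max(1, abs(x))) return(c(h1, k1))
  stop("no exact rational representation for ", x)
}

#' @export
length.rational <- function(x) length(x$n)

#' @export
names.rational <- function(x) x$nm

#' @export
`names<-.rational` <- function(x, value) {
  if (!is.null(value) && length(value) != length(x$n)) stop("names length mismatch")
  x$nm <- value
  x
}

#' @export
`[.rational` <- function(x, i) {
  if (is.character(i)) {
    if (is.null(x$nm)) stop("rational vector has no names")
    i <- match(i, x$nm)
  }
  structure(list(n = x$n[i], d = x$d[i], nm = x$nm[i]), class = "rational")
}

# concatenate rationals (internal; c() would not dispatch reliably)
rat_c <- function(...) {
  xs <- lapply(list(...), as_rational)
  n <- unlist(lapply(xs, function(x) x$n))
  d <- unlist(lapply(xs, function(x) x$d))
  nm <- unlist(lapply(xs, function(x) if (is.null(x$nm)) rep(NA_character_, length(x$n)) else x$nm))
  out <- rational(n, d)
  if (!all(is.na(nm))) names(out) <- nm
  out
}

#' @export
Ops.rational <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "-") return(rational(-e1$n, e1$d))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not defined for rationals")
  }
  e1 <- as_rational(e1)
  e2 <- as_rational(e2)
  l1 <- length(e1$n); l2 <- length(e2$n)
  if (l1 != l2) {
    if (l1 == 1L) { e1$n <- rep(e1$n, l2); e1$d <- rep(e1$d, l2) }
    else if (l2 == 1L) { e2$n <- rep(e2$n, l1); e2$d <- rep(e2$d, l1) }
    else stop("length mismatch in rational arithmetic")
  }
  switch(.Generic,
    "+" = rational(e1$n * e2$d + e2$n * e1$d, e1$d * e2$d),
    "-" = rational(e1$n * e2$d - e2$n * e1$d, e1$d * e2$d),
    "*" = rational(e1$n * e2$n, e1$d * e2$d),
    "/" = {
      if (any(e2$n == 0)) stop("division by zero")
      rational(e1$n * e2$d, e1$d * e2$n)
    },
    "==" = e1$n * e2$d == e2$n * e1$d,
    "!=" = e1$n * e2$d != e2$n * e1$d,
    "<" = e1$n * e2$d < e2$n * e1$d,
    "<=" = e1$n * e2$d <= e2$n * e1$d,
    ">" = e1$n * e2$d > e2$n * e1$d,
    ">=" = e1$n * e2$d >= e2$n * e1$d,
    stop(.Generic, " not defined for rationals")
  )
}

#' @export
Summary.rational <- function(..., na.rm = FALSE) {
  x <- rat_c(...)
  switch(.Generic,
    sum = {
      n <- 0; d <- 1
      for (i in seq_along(x$n)) {
        n <- n * x$d[i] + x$n[i] * d
        d <- d * x$d[i]
        g <- .gcd2(abs(n), d)
        if (g > 1) { n <- n / g; d <- d / g }
        .rat_check(n, d)
      }
      rational(n, d)
    },
    max = x[which.max(x$n / x$d)],
    min = x[which.min(x$n / x$d)],
    stop(.Generic, " not defined for rationals")
  )
}

#' @export
as.double.rational <- function(x, ...) {
  out <- x$n / x$d
  names(out) <- x$nm
  out
}

#' @export
format.rational <- function(x, ...) {
  out <- ifelse(x$d == 1, format(x$n, scientific = FALSE, trim = TRUE),
                paste0(format(x$n, scientific = FALSE, trim = TRUE), "/",
                       format(x$d, scientific = FALSE, trim = TRUE)))
  names(out) <- x$nm
  out
}

#' @export
print.rational <- function(x, ...) {
  print(format(x), quote = FALSE)
  invisible(x)
}

#' @export
as.character.rational <- function(x, ...) format(x)
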