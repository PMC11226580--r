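#' Exact rational numbers
#'
#' A small vectorized rational-number class used for all stoichiometric
#' bookkeeping in the package. Numerators and denominators are stored as
#' integer-valued doubles, which is exact for the magnitudes arising from
#' metabolic ledgers (well below 2^53). Every value is kept in lowest terms
#' with a positive denominator, so equality is plain component equality and
#' ledgers built from rational multiplicities are reproduced bit-exactly.
#'
#' @param num numeric vector of integer values (numerators), or a character
#'   vector of the form \code{"3"} or \code{"-1/8"}.
#' @param den numeric vector of integer values (denominators), recycled.
#' @return an object of class \code{"rat"}.
#' @examples
#' rat(1, 8) + rat(7, 8)  # == 1
#' rat("2/3") * 3
#' @export
rat <- function(num, den = 1) {
  if (is.character(num)) {
    stopifnot(missing(den) || all(den == 1))
    parts <- strsplit(num, "/", fixed = TRUE)
    n <- vapply(parts, function(p) as.numeric(p[[1L]]), numeric(1))
    d <- vapply(parts, function(p) if (length(p) > 1L) as.numeric(p[[2L]]) else 1, numeric(1))
    return(rat(n, d))
  }
  if (inherits(num, "rat")) return(num)
  num <- as.numeric(num)
  den <- as.numeric(den)
  if (any(is.na(num)) || any(is.na(den))) stop("rational components must be finite")
  if (any(num != round(num)) || any(den != round(den)))
    stop("rational components must be integer-valued; got a non-integer")
  if (any(den == 0)) stop("zero denominator")
  k <- max(length(num), length(den))
  num <- rep_len(num, k)
  den <- rep_len(den, k)
  .rat_new(num, den)
}

.rat_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b != 0)) {
    t <- b
    b <- ifelse(b == 0, 0, a %% b)
    a <- t
  }
  a
}

.rat_new <- function(num, den) {
  s <- ifelse(den < 0, -1, 1)
  num <- num * s
  den <- den * s
  g <- .rat_gcd(num, den)
  g[g == 0] <- 1
  structure(list(num = num / g, den = den / g), class = "rat")
}

#' @export
length.rat <- function(x) length(x$num)

#' @export
format.rat <- function(x, ...) {
  ifelse(x$den == 1, format(x$num, scientific = FALSE, trim = TRUE),
         paste0(format(x$num, scientific = FALSE, trim = TRUE), "/",
                format(x$den, scientific = FALSE, trim = TRUE)))
}

#' @export
print.rat <- function(x, ...) {
  cat("<rational> ", paste(format(x), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
as.double.rat <- function(x, ...) x$num / x$den

#' @export
as.character.rat <- function(x, ...) format(x)

#' @export
`[.rat` <- function(x, i) .rat_new(x$num[i], x$den[i])

#' @export
`[<-.rat` <- function(x, i, value) {
  value <- rat(value)
  x$num[i] <- value$num
  x$den[i] <- value$den
  .rat_new(x$num, x$den)
}

#' @export
c.rat <- function(...) {
  parts <- lapply(list(...), rat)
  .rat_new(unlist(lapply(parts, `[[`, "num")),
           unlist(lapply(parts, `[[`, "den")))
}

#' @export
Ops.rat <- function(e1, e2) {
  if (nargs() == 1L) {
    e1 <- rat(e1)
    return(switch(.Generic,
      "-" = .rat_new(-e1$num, e1$den),
      "+" = e1,
      stop("unary ", .Generic, " not defined for rationals")))
  }
  e1 <- rat(e1); e2 <- rat(e2)
  switch(.Generic,
    "+" = .rat_new(e1$num * e2$den + e2$num * e1$den, e1$den * e2$den),
    "-" = .rat_new(e1$num * e2$den - e2$num * e1$den, e1$den * e2$den),
    "*" = .rat_new(e1$num * e2$num, e1$den * e2$den),
    "/" = {
      if (any(e2$num == 0)) stop("division by zero rational")
      .rat_new(e1$num * e2$den, e1$den * e2$num)
    },
    "==" = e1$num == e2$num & e1$den == e2$den,
    "!=" = !(e1$num == e2$num & e1$den == e2$den),
    "<"  = e1$num * e2$den <  e2$num * e1$den,
    "<=" = e1$num * e2$den <= e2$num * e1$den,
    ">"  = e1$num * e2$den >  e2$num * e1$den,
    ">=" = e1$num * e2$den >= e2$num * e1$den,
    stop(.Generic, " not defined for rationals"))
}

#' @export
sum.rat <- function(..., na.rm = FALSE) {
  x <- c.rat(...)
  acc <- rat(0)
  for (i in seq_len(length(x))) acc <- acc + x[i]
  acc
}

rat_is_zero <- function(x) x$num == 0
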