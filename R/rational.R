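# Exact rational arithmetic for Mendelian probabilities.
#
# Segregation probabilities in a three-locus diploid model are dyadic
# rationals with tiny denominators (products of powers of 2 and viability
# denominators), so numerators/denominators are stored as doubles holding
# exact integers. All distributions in the model layer flow through these
# helpers so that printed ratios such as 1:3, 9:7 or 2:1 are reproduced
# bit-exactly; floating point appears only in the statistics layer.

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) {
    t <- a %% b
    a <- b
    b <- t
  }
  a
}

#' Construct an exact rational number
#'
#' @param num integer numerator.
#' @param den integer denominator (> 0 after sign normalisation).
#' @return An object of class `rat`: a length-2 numeric `c(num, den)` in
#'   lowest terms with a positive denominator.
#' @keywords internal
rat <- function(num, den = 1) {
  if (den == 0) stop("rational with zero denominator")
  if (den < 0) {
    num <- -num
    den <- -den
  }
  g <- .gcd2(num, den)
  if (g > 0) {
    num <- num / g
    den <- den / g
  }
  structure(c(num, den), class = "rat")
}

rat_num <- function(r) unclass(r)[1]
rat_den <- function(r) unclass(r)[2]

rat_add <- function(a, b) rat(rat_num(a) * rat_den(b) + rat_num(b) * rat_den(a),
                             rat_den(a) * rat_den(b))
rat_sub <- function(a, b) rat_add(a, rat(-rat_num(b), rat_den(b)))
rat_mul <- function(a, b) rat(rat_num(a) * rat_num(b), rat_den(a) * rat_den(b))
rat_div <- function(a, b) {
  if (rat_num(b) == 0) stop("rational division by zero")
  rat(rat_num(a) * rat_den(b), rat_den(a) * rat_num(b))
}
rat_eq <- function(a, b) rat_num(a) == rat_num(b) && rat_den(a) == rat_den(b)

#' @export
as.double.rat <- function(x, ...) rat_num(x) / rat_den(x)

# Numeric value of a rational (explicit accessor; used internally instead
# of as.numeric so dispatch never matters).
rat_value <- function(x) rat_num(x) / rat_den(x)

#' @export
format.rat <- function(x, ...) {
  if (rat_den(x) == 1) as.character(rat_num(x)) else
    paste0(rat_num(x), "/", rat_den(x))
}

#' @export
print.rat <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# Convert a numeric to an exact rational by continued fractions.  Survival
# probabilities supplied as doubles (e.g. 0.5, 0.25) are rationalised so the
# viability-selection step stays exact.
as_rational <- function(x, max_den = 1e6) {
  if (inherits(x, "rat")) return(x)
  if (length(x) == 2 && is.numeric(x) && all(x == round(x))) {
    return(rat(x[1], x[2]))
  }
  stopifnot(is.numeric(x), length(x) == 1, is.finite(x))
  if (x == round(x)) return(rat(x))
  sign <- if (x < 0) -1 else 1
  x0 <- abs(x)
  h1 <- 1; h0 <- 0; k1 <- 0; k0 <- 1
  b <- x0
  repeat {
    a <- floor(b)
    h2 <- a * h1 + h0; k2 <- a * k1 + k0
    if (k2 > max_den) break
    h0 <- h1; h1 <- h2; k0 <- k1; k1 <- k2
    if (abs(h1 / k1 - x0) < .Machine$double.eps * 4) break
    frac <- b - a
    if (frac < .Machine$double.eps) break
    b <- 1 / frac
  }
  rat(sign * h1, k1)
}
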