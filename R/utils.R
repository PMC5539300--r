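#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-row sample variances of a matrix
#' @noRd
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

#' Inverse of the trigamma function
#'
#' Solves `trigamma(x) = y` for `x > 0` by a Newton iteration on the scale of
#' `1/trigamma`, which is nearly linear in `x` and therefore converges from a
#' crude start. Used when fitting the prior degrees of freedom of the
#' moderated-t variance model.
#'
#' @param y positive numeric vector.
#' @return numeric vector `x` with `trigamma(x) = y`.
#' @noRd
trigamma_inverse <- function(y) {
  out <- rep(NA_real_, length(y))
  if (!length(y)) return(out)
  bad <- !is.finite(y) | y <= 0
  out[bad] <- NaN
  hi <- !bad & y > 1e7
  out[hi] <- 1 / sqrt(y[hi])
  lo <- !bad & y < 1e-6
  out[lo] <- 1 / y[lo]
  todo <- which(is.na(out))
  if (!length(todo)) return(out)
  yy <- y[todo]
  x <- 0.5 + 1 / yy
  for (i in seq_len(50L)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / yy) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  out[todo] <- x
  out
}

#' Pearson chi-square statistic for a 2x2 table, no continuity correction
#'
#' Closed form n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)).
#' @param tab 2x2 numeric matrix of counts.
#' @return list with `statistic`, `df`, `p.value`.
#' @noRd
chisq_2x2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2L), all(tab >= 0))
  a <- tab[1L, 1L]; b <- tab[1L, 2L]; cc <- tab[2L, 1L]; d <- tab[2L, 2L]
  n <- a + b + cc + d
  den <- (a + b) * (cc + d) * (a + cc) * (b + d)
  if (den == 0) {
    stop("chi-square undefined: a margin of the 2x2 table is zero; ",
         "use the Fisher exact p-value instead")
  }
  stat <- n * (a * d - b * cc)^2 / den
  list(statistic = stat, df = 1L,
       p.value = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

# Format numerics so that read-back with as.numeric() is exact (17 significant
# digits round-trips IEEE doubles); whole numbers are written without a
# decimal point so integer matrices round-trip byte-identically.
format_num <- function(x) {
  out <- character(length(x))
  whole <- is.finite(x) & x == round(x) & abs(x) < 2^53
  out[whole] <- sprintf("%.0f", x[whole])
  out[!whole] <- formatC(x[!whole], digits = 17, format = "g")
  out
}
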