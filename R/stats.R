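# log(sum(exp(lx))) without leaving log space; -Inf-safe
logsumexp <- function(lx) {
  lx <- lx[is.finite(lx) | lx == -Inf]
  if (length(lx) == 0L || all(lx == -Inf)) return(-Inf)
  m <- max(lx)
  m + log(sum(exp(lx - m)))
}

#' Construct a 2x2 contingency table for a category comparison
#'
#' Holds the four counts used throughout the ATC and gene-set comparisons:
#' members of set A and set B inside a category, and the members of each
#' set outside it.
#'
#' @param n_in_a,n_in_b counts of set-A / set-B members in the category.
#' @param n_out_a,n_out_b counts of set-A / set-B members not in the category.
#' @return An object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(n_in_a, n_in_b, n_out_a, n_out_b) {
  counts <- c(n_in_a = n_in_a, n_in_b = n_in_b,
              n_out_a = n_out_a, n_out_b = n_out_b)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("contingency counts must be non-negative integers")
  structure(as.list(counts), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$n_in_a, x$n_in_b, x$n_out_a, x$n_out_b), 2, byrow = TRUE,
              dimnames = list(c("in", "out"), c("A", "B")))
  print(m)
  invisible(x)
}

#' Two-sided Fisher exact test
#'
#' Exact two-sided p-value for a 2x2 table under the hypergeometric null,
#' using the minimum-likelihood (small-p-values) two-sided definition: the
#' p-value is the sum of point probabilities, over all tables with the same
#' margins, that do not exceed the observed table's point probability. All
#' sums run in log space with log-gamma binomial coefficients so that
#' p-values far below double underflow of individual factors (down to
#' ~1e-300) remain accurate.
#'
#' @param table a [contingency_2x2()], or anything coercible via four counts.
#' @return p-value in (0, 1]. Attribute `underflow` is set when the true
#'   value underflows double precision (the smallest positive double is
#'   returned instead of 0).
#' @export
fisher_exact_two_sided <- function(table) {
  if (!inherits(table, "contingency_2x2"))
    stop("expected a contingency_2x2 object")
  a <- table$n_in_a; b <- table$n_in_b
  c_ <- table$n_out_a; d <- table$n_out_b
  mA <- a + c_      # size of set A
  mB <- b + d       # size of set B
  k  <- a + b       # category total
  if (mA == 0L || mB == 0L || k == 0L || (c_ + d) == 0L) {
    warning("degenerate table (empty row or column); p = 1")
    return(1)
  }
  support <- max(0L, k - mB):min(k, mA)
  lp <- lchoose(mA, support) + lchoose(mB, k - support) - lchoose(mA + mB, k)
  lp_obs <- lp[support == a]
  # relative tolerance guards against log-gamma rounding at equal-probability
  # tables (same convention as the classical implementation)
  keep <- lp <= lp_obs + log1p(1e-7)
  lp_sum <- logsumexp(lp[keep])
  p <- exp(min(lp_sum, 0))
  if (p == 0) {
    p <- .Machine$double.xmin
    attr(p, "underflow") <- TRUE
  }
  p
}

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' Probability of observing `k` or more successes when drawing `draws`
#' items without replacement from a population of size `population`
#' containing `successes` marked items. Exact tail sum in log space.
#'
#' @param population population size N.
#' @param successes number of marked items K in the population.
#' @param draws sample size n.
#' @param observed observed overlap k.
#' @return tail probability in (0, 1].
#' @export
hypergeom_sf <- function(population, successes, draws, observed) {
  N <- population; K <- successes; n <- draws; k <- observed
  vals <- c(N, K, n, k)
  if (any(is.na(vals)) || any(vals != floor(vals)))
    stop("hypergeometric query requires integer arguments")
  if (K < 0 || K > N || n < 0 || n > N)
    stop("require 0 <= successes <= population and 0 <= draws <= population")
  lo <- max(0, n + K - N)
  hi <- min(n, K)
  if (k < lo || k > hi)
    stop("observed overlap outside the feasible range [", lo, ", ", hi, "]")
  if (k == lo) return(1)
  support <- k:hi
  lp <- lchoose(K, support) + lchoose(N - K, n - support) - lchoose(N, n)
  p <- exp(min(logsumexp(lp), 0))
  if (p == 0) {
    p <- .Machine$double.xmin
    attr(p, "underflow") <- TRUE
  }
  p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]),
#' returned in the input order and clipped at 1.
#'
#' @param pvalues numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
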