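#' Pearson chi-square test of homogeneity / independence
#'
#' Self-contained Pearson chi-square on a contingency table of counts:
#' expected counts from the product of marginals over the grand total,
#' statistic \eqn{\chi^2 = \sum (O - E)^2 / E}, df = (r-1)(c-1), p-value
#' from the upper tail of the chi-square distribution. No continuity
#' correction is applied (switchable), so 2x2 tables match the classic
#' uncorrected Pearson statistic.
#'
#' @param table numeric matrix of non-negative counts, at least 2x2.
#' @param correct apply the Yates continuity correction on 2x2 tables.
#' @return a one-row tibble of class `lamin_stat` with columns
#'   `method`, `statistic`, `df`, `p_value`.
#' @examples
#' chi_square(matrix(c(20, 10, 10, 20), 2, 2))
#' @export
chi_square <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("need at least 2 rows and 2 columns", call. = FALSE)
  if (any(table < 0) || any(!is.finite(table)))
    stop("counts must be finite and non-negative", call. = FALSE)
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0))
    stop("zero marginal in row ", which(rs == 0)[1], call. = FALSE)
  if (any(cs == 0))
    stop("zero marginal in column ", which(cs == 0)[1], call. = FALSE)
  n <- sum(table)
  expected <- outer(rs, cs) / n
  dev <- abs(table - expected)
  if (correct && nrow(table) == 2L && ncol(table) == 2L)
    dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  new_lamin_stat("chi-square", stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Self-contained two-sided two-sample KS test. The statistic is the
#' exact supremum of the difference of the two empirical CDFs, evaluated
#' at the pooled unique sample values (right-continuous convention, so
#' ties are handled consistently). The p-value is asymptotic, from the
#' Kolmogorov distribution at \eqn{\sqrt{nm/(n+m)}\, D}; it is mildly
#' conservative for small samples.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @return a one-row tibble of class `lamin_stat` with columns
#'   `method`, `statistic` (D), `df` (NA), `p_value`.
#' @examples
#' ks_two_sample(rnorm(30), rnorm(30, 1))
#' @export
ks_two_sample <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 finite values", call. = FALSE)
  pts <- sort(unique(c(x, y)))
  # right-continuous ECDFs evaluated at the pooled unique values
  fx <- findInterval(pts, sort(x)) / length(x)
  fy <- findInterval(pts, sort(y)) / length(y)
  d <- max(abs(fx - fy))
  ne <- length(x) * length(y) / (length(x) + length(y))
  new_lamin_stat("two-sample KS", d, df = NA_integer_,
                 p_value = kolmogorov_sf(sqrt(ne) * d))
}

# Survival function of the Kolmogorov distribution,
# Q(lambda) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2).
kolmogorov_sf <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- seq_len(101)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

new_lamin_stat <- function(method, statistic, df, p_value) {
  out <- tibble::tibble(
    method = method,
    statistic = as.numeric(statistic),
    df = df,
    p_value = as.numeric(p_value)
  )
  class(out) <- c("lamin_stat", class(out))
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a test result
#' @param x a `lamin_stat` object.
#' @param ... unused.
#' @return a tibble with one row per test.
#' @method tidy lamin_stat
#' @export
tidy.lamin_stat <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a test result
#' @inheritParams tidy.lamin_stat
#' @return a one-row tibble.
#' @method glance lamin_stat
#' @export
glance.lamin_stat <- function(x, ...) tidy.lamin_stat(x)
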