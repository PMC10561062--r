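# Biweight midcorrelation: the robust correlation used for all cross-tissue
# and profile-similarity statistics in this package.

# Tukey-biweight transform of one vector. Returns the normalized transformed
# vector, or NULL when the biweight is degenerate (zero MAD, or all weights
# vanish) and a product-moment fallback is required.
# The MAD here is the raw median absolute deviation, without the 1.4826
# normal-consistency constant; the constant would rescale u uniformly and is
# a pure convention, but callers (and any external oracle) must share it.
.biweight_transform <- function(x) {
  med <- stats::median(x)
  mad0 <- stats::median(abs(x - med))
  if (mad0 == 0) {
    return(NULL)
  }
  u <- (x - med) / (9 * mad0)
  a <- (1 - u^2)^2 * (abs(u) < 1)
  xt <- (x - med) * a
  nrm <- sqrt(sum(xt^2))
  if (nrm == 0) {
    return(NULL)
  }
  xt / nrm
}

# Mean-centred, unit-norm vector for the product-moment fallback;
# NULL if the vector has zero variance.
.pearson_transform <- function(x) {
  v <- x - mean(x)
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) {
    return(NULL)
  }
  v / nrm
}

#' Biweight midcorrelation of two vectors
#'
#' Robust correlation built from medians and median absolute deviations
#' (MADs) with Tukey biweights down-weighting observations far from the
#' median: with `u_i = (x_i - med(x)) / (9 MAD(x))`, weights
#' `a_i = (1 - u_i^2)^2` for `|u_i| < 1` (zero otherwise), and transformed
#' values `x~_i = (x_i - med(x)) a_i`, the statistic is
#' `sum(x~ y~) / (||x~|| ||y~||)`. The MAD is the raw median absolute
#' deviation (no 1.4826 consistency constant).
#'
#' When either vector is degenerate for the biweight (zero MAD, or every
#' weight vanishing), the function falls back to the product-moment
#' (Pearson) correlation and flags it; if the fallback is also degenerate
#' (zero variance) the correlation is undefined and an error is thrown.
#'
#' @param x,y Numeric vectors of equal length (at least 3), all finite.
#' @return A list with elements `r` (correlation in `[-1, 1]`) and `method`
#'   (`"bicor"` or `"pearson_fallback"`).
#' @examples
#' bicor(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))
#' @export
bicor <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) {
    stop("bicor: x and y must be numeric vectors")
  }
  if (length(x) != length(y)) {
    stop("bicor: x and y must have equal length (", length(x), " vs ",
         length(y), ")")
  }
  if (length(x) < 3) {
    stop("bicor: need at least 3 observations, got ", length(x))
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("bicor: non-finite values in input")
  }
  tx <- .biweight_transform(x)
  ty <- .biweight_transform(y)
  if (is.null(tx) || is.null(ty)) {
    px <- .pearson_transform(x)
    py <- .pearson_transform(y)
    if (is.null(px) || is.null(py)) {
      stop("bicor: input degenerate for both biweight and product-moment ",
           "correlation (zero variance)")
    }
    r <- sum(px * py)
    return(list(r = max(-1, min(1, r)), method = "pearson_fallback"))
  }
  r <- sum(tx * ty)
  list(r = max(-1, min(1, r)), method = "bicor")
}

#' Biweight midcorrelation between the rows of two matrices
#'
#' Computes [bicor()] between every row of `X` and every row of `Y`
#' (columns are matched observations, e.g. individuals). Rows that are
#' degenerate for the biweight transform are handled with the same
#' product-moment fallback as [bicor()]: a pair involving at least one
#' degenerate row gets the plain Pearson correlation of the two raw rows.
#'
#' @param X,Y Numeric matrices with identical column counts (and matching
#'   column order); rows are variables.
#' @return A list with `r` (matrix `nrow(X)` by `nrow(Y)`) and `method`
#'   (character matrix, `"bicor"` or `"pearson_fallback"`).
#' @export
bicor_matrix <- function(X, Y) {
  if (!is.matrix(X) || !is.matrix(Y)) {
    stop("bicor_matrix: X and Y must be matrices")
  }
  if (ncol(X) != ncol(Y)) {
    stop("bicor_matrix: column counts differ (", ncol(X), " vs ", ncol(Y), ")")
  }
  if (ncol(X) < 3) {
    stop("bicor_matrix: need at least 3 matched observations, got ", ncol(X))
  }
  if (!all(is.finite(X)) || !all(is.finite(Y))) {
    stop("bicor_matrix: non-finite values in input")
  }
  tX <- .transform_rows(X)
  tY <- .transform_rows(Y)
  R <- tX$B %*% t(tY$B)
  method <- matrix("bicor", nrow(X), ncol = nrow(Y),
                   dimnames = list(rownames(X), rownames(Y)))
  if (any(tX$fallback) || any(tY$fallback)) {
    mask <- outer(tX$fallback, tY$fallback, `|`)
    Rp <- tX$Z %*% t(tY$Z)
    R[mask] <- Rp[mask]
    method[mask] <- "pearson_fallback"
  }
  R[R > 1] <- 1
  R[R < -1] <- -1
  dimnames(R) <- list(rownames(X), rownames(Y))
  list(r = R, method = method)
}

# Row-wise transforms: biweight where possible, with a parallel
# pearson-normalized copy for fallback pairs.
.transform_rows <- function(M) {
  n_row <- nrow(M)
  B <- matrix(0, n_row, ncol(M))
  Z <- matrix(0, n_row, ncol(M))
  fallback <- logical(n_row)
  for (i in seq_len(n_row)) {
    xi <- M[i, ]
    ti <- .biweight_transform(xi)
    pi <- .pearson_transform(xi)
    if (is.null(pi)) {
      stop("bicor_matrix: row ", if (!is.null(rownames(M))) rownames(M)[i] else i,
           " has zero variance; correlation undefined")
    }
    Z[i, ] <- pi
    if (is.null(ti)) {
      fallback[i] <- TRUE
      B[i, ] <- pi
    } else {
      B[i, ] <- ti
    }
  }
  list(B = B, Z = Z, fallback = fallback)
}

#' Two-sided p-value for a correlation coefficient
#'
#' Student-t transform of a correlation: `t = r sqrt((n - 2) / (1 - r^2))`
#' referred to the t distribution on `n - 2` degrees of freedom. For
#' `r = +/-1` the p-value is exactly 0. Vectorized over `r`.
#'
#' @param r Correlation(s) in `[-1, 1]`.
#' @param n Number of paired observations (scalar or vector, each >= 3).
#' @return Two-sided p-value(s) in `[0, 1]`.
#' @export
correlation_pvalue <- function(r, n) {
  if (any(!is.finite(r)) || any(abs(r) > 1 + 1e-12)) {
    stop("correlation_pvalue: r must be finite and within [-1, 1]")
  }
  if (any(n < 3)) {
    stop("correlation_pvalue: n must be at least 3")
  }
  r <- pmax(-1, pmin(1, r))
  p <- numeric(length(r))
  exact <- abs(r) >= 1
  p[exact] <- 0
  if (any(!exact)) {
    rr <- r[!exact]
    nn <- if (length(n) == 1) rep(n, sum(!exact)) else n[!exact]
    tt <- rr * sqrt((nn - 2) / (1 - rr^2))
    p[!exact] <- 2 * stats::pt(abs(tt), df = nn - 2, lower.tail = FALSE)
  }
  pmin(1, p)
}
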