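#' @include AllClasses.R
NULL

#' Quantile (equal-count) discretization of a numeric sample
#'
#' Assigns each of the N observations to one of K bins such that bin
#' occupancies are as equal as possible: the observation of 0-based rank r
#' (ranked by value, ties broken by original sample position) receives the
#' 0-based label \code{floor(r * K / N)}. When \code{N %% K == 0} every bin
#' holds exactly N/K samples, so the marginal label distribution is
#' perfectly uniform and the plug-in marginal entropy equals log2(K)
#' exactly; otherwise bin occupancies differ by at most one. The labelling
#' is monotone (a strictly larger value never gets a smaller label) and
#' invariant under any strictly increasing transform of the values, since
#' only ranks enter.
#'
#' Bins are always built from the observed sample itself, never from a
#' known generating distribution — simulated data are treated exactly like
#' empirical data would be.
#'
#' @param x numeric vector of N finite values (impute missing values
#'   first, see [loadAndImpute()]).
#' @param K integer number of bins, \code{2 <= K <= N}.
#' @return Integer vector of length N with labels in \code{0:(K-1)}.
#' @examples
#' quantileBin(10:1, 2)           # five 1s then five 0s
#' table(quantileBin(rnorm(100), 10))  # ten samples per bin
#' @export
quantileBin <- function(x, K) {
  if (!is.numeric(x) || length(x) < 1L) {
    stop("x must be a non-empty numeric vector")
  }
  if (any(!is.finite(x))) {
    stop("non-finite values: impute or remove them before binning")
  }
  K <- as.integer(K)
  if (is.na(K) || K < 2L) {
    stop("K must be an integer >= 2")
  }
  N <- length(x)
  if (K > N) {
    stop("more bins than samples (K > N)")
  }
  ord <- order(x)                   # stable: ties keep original order
  labels <- integer(N)
  labels[ord] <- as.integer(floor((seq_len(N) - 1) * as.numeric(K) / N))
  labels
}

#' Discretize a set of columns into a common number of bins
#'
#' Applies [quantileBin()] independently to each column with the same K —
#' a shared bin count is required because K enters both the O-information
#' estimate and its bias term, and comparing systems binned to different K
#' is not meaningful. Columns that are already discrete, in the sense of
#' having at most K distinct values, are by default passed through with
#' their distinct values remapped (in increasing order) to
#' \code{0:(d-1)}, keeping their natural categories instead of forcing d
#' categories into K quantile bins; such a column's cardinality is d, not
#' K. Set \code{passThrough = FALSE} to quantile-bin every column
#' unconditionally (the behaviour the triplet simulators rely on).
#'
#' @param x numeric matrix or data.frame of N rows (samples) and at least
#'   one column (variable); all columns the same length.
#' @param K integer common bin count, \code{2 <= K <= N}.
#' @param passThrough logical; keep columns with <= K distinct values as
#'   remapped categories (default TRUE).
#' @return A [BinnedMatrix-class].
#' @examples
#' set.seed(1)
#' m <- binMatrix(data.frame(a = rnorm(50), b = runif(50)), K = 5)
#' cardinalities(m)
#' @export
binMatrix <- function(x, K, passThrough = TRUE) {
  if (is.data.frame(x)) {
    if (!all(vapply(x, is.numeric, logical(1)))) {
      stop("all columns must be numeric")
    }
    x <- as.matrix(x)
  }
  if (!is.matrix(x)) {
    stop("x must be a matrix or data.frame of numeric columns")
  }
  K <- as.integer(K)
  n <- ncol(x)
  labels <- matrix(0L, nrow(x), n)
  colnames(labels) <- if (is.null(colnames(x))) {
    paste0("V", seq_len(n))
  } else {
    colnames(x)
  }
  card <- integer(n)
  for (j in seq_len(n)) {
    v <- x[, j]
    if (any(!is.finite(v))) {
      stop(sprintf("column %s has non-finite values: impute first",
                   colnames(labels)[j]))
    }
    u <- sort(unique(v))
    if (passThrough && length(u) <= K) {
      labels[, j] <- match(v, u) - 1L
      card[j] <- length(u)
    } else {
      labels[, j] <- quantileBin(v, K)
      card[j] <- K
    }
  }
  BinnedMatrix(labels, card)
}
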