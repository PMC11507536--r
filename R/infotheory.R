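#' @include AllClasses.R
NULL

# log(2) constant used for the Miller-Maddow nat -> bit conversion
.LN2 <- log(2)

#' Joint occurrence counts over a subset of variables
#'
#' Tallies how often each joint bin-label combination of the selected
#' columns occurs in the data. The resulting [CountTable-class] underlies
#' every entropy estimate: marginal entropies use single-column subsets,
#' the leave-one-out joint entropies use (n-1)-column subsets, and the
#' full joint entropy uses all columns. Only combinations that actually
#' occur are stored, so [observedSupport()] of the result is the empirical
#' support estimate used by the bias correction.
#'
#' @param x a [BinnedMatrix-class].
#' @param subset integer vector of column indices (non-empty, valid).
#' @return A [CountTable-class].
#' @examples
#' m <- BinnedMatrix(cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L)))
#' countJoint(m, 1:2)    # four combinations, one count each
#' @export
countJoint <- function(x, subset) {
  stopifnot(is(x, "BinnedMatrix"))
  subset <- as.integer(subset)
  if (length(subset) < 1L) {
    stop("subset must be non-empty")
  }
  if (any(subset < 1L) || any(subset > ncol(x@labels))) {
    stop("subset contains invalid column indices")
  }
  lab <- x@labels
  card <- as.numeric(x@cardinalities)
  if (prod(card[subset]) < 2^53) {
    codes <- as.numeric(lab[, subset[1L]])
    mult <- card[subset[1L]]
    for (j in subset[-1L]) {
      codes <- codes + mult * as.numeric(lab[, j])
      mult <- mult * card[j]
    }
  } else {
    codes <- do.call(paste, c(lapply(subset, function(j) lab[, j]),
                              sep = "\r"))
  }
  counts <- tabulate(match(codes, unique(codes)))
  new("CountTable", counts = as.integer(counts),
      N = nrow(lab), subset = subset)
}

#' Plug-in (naive) entropy of a count table
#'
#' The maximum-likelihood entropy estimate
#' \deqn{\hat H = -\sum_i (c_i/N) \log_2 (c_i/N)}
#' over the observed joint combinations. Combinations that never occur
#' contribute exactly zero and are never stored. The plug-in estimate is
#' downward biased at finite N (by Jensen's inequality): rare
#' combinations are under- or unobserved, making the empirical
#' distribution look more concentrated than the truth.
#'
#' @param x a [CountTable-class].
#' @return An [EntropyEstimate-class] with \code{estimator = "plugin"} and
#'   a zero bias term.
#' @examples
#' m <- BinnedMatrix(matrix(rep(0:7, each = 2), ncol = 1), 8L)
#' entropyValue(pluginEntropy(countJoint(m, 1)))  # 3 bits, uniform on 8
#' @export
pluginEntropy <- function(x) {
  stopifnot(is(x, "CountTable"))
  p <- x@counts / x@N
  h <- -sum(p * log2(p))
  new("EntropyEstimate", value = max(h, 0), estimator = "plugin",
      biasTerm = 0, supportUsed = 1L)
}

#' Miller-Maddow corrected entropy of a count table
#'
#' Adds the second-order Taylor bias term
#' \deqn{\delta_H = (K - 1) / (2 N \ln 2)}
#' to the plug-in estimate, where K is the support: the number of
#' combinations the variables \emph{can} jointly take. For empirical data
#' the support is typically unknown and is estimated by
#' [observedSupport()]; pass a larger value when the true support is
#' known. The term vanishes as N grows at fixed support. The derivation
#' assumes the asymptotic sampling regime (every combination observed many
#' times); the function does not enforce it — the correction is useful,
#' with caveats, well outside it — but warns when \code{N < support}.
#'
#' @param x a [CountTable-class].
#' @param support integer; the support count to plug in. Defaults to the
#'   observed support. Must be at least [observedSupport()] — a support
#'   smaller than what was actually seen is inconsistent.
#' @return An [EntropyEstimate-class] with
#'   \code{estimator = "miller_maddow"}.
#' @examples
#' m <- BinnedMatrix(matrix(quantileBin(rnorm(1000), 10), ncol = 1), 10L)
#' mmEntropy(countJoint(m, 1))   # bias term 9 / (2000 ln 2)
#' @export
mmEntropy <- function(x, support = observedSupport(x)) {
  stopifnot(is(x, "CountTable"))
  support <- as.integer(support)
  if (is.na(support) || support < 1L) {
    stop("support must be a positive integer")
  }
  if (support < observedSupport(x)) {
    stop("inconsistent support: fewer than the observed combinations")
  }
  if (x@N < support) {
    warning(sprintf(
      "N = %d < support = %d: outside the asymptotic sampling regime the Miller-Maddow term is derived in",
      x@N, support))
  }
  plug <- pluginEntropy(x)
  bias <- (support - 1) / (2 * x@N * .LN2)
  new("EntropyEstimate", value = plug@value + bias,
      estimator = "miller_maddow", biasTerm = bias,
      supportUsed = support)
}
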