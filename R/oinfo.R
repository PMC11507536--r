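#' @include infotheory.R
NULL

# One pass over the system: plug-in entropies and observed supports of the
# marginals, the leave-one-out joints and the full joint.
.oinfoTerms <- function(x) {
  n <- ncol(x@labels)
  full <- countJoint(x, seq_len(n))
  hMarg <- numeric(n)
  hMinus <- numeric(n)
  suppMinus <- integer(n)
  for (j in seq_len(n)) {
    hMarg[j] <- pluginEntropy(countJoint(x, j))@value
    tabMinus <- countJoint(x, setdiff(seq_len(n), j))
    hMinus[j] <- pluginEntropy(tabMinus)@value
    suppMinus[j] <- observedSupport(tabMinus)
  }
  list(hFull = pluginEntropy(full)@value, hMarg = hMarg, hMinus = hMinus,
       suppFull = observedSupport(full), suppMinus = suppMinus)
}

#' Naive (plug-in) O-information of a discretized system
#'
#' The O-information of an n-variable system is the signed balance of
#' redundancy (+) and synergy (-):
#' \deqn{\Omega = (n-2) H(X^n) + \sum_j [ H(X_j) - H(X^n_{-j}) ],}
#' where \eqn{H(X^n)} is the joint entropy of all variables,
#' \eqn{H(X_j)} a marginal entropy and \eqn{H(X^n_{-j})} the joint entropy
#' with variable j left out. The naive estimator plugs empirical
#' frequencies into every term. It is symmetric under variable reordering
#' and bounded by \eqn{\pm (n-2)\log_2 K_{max}}, but inherits the
#' finite-sample bias of its entropy terms: undersampled joints pull
#' estimates towards synergy, which is why bias assessment matters before
#' interpreting negative values.
#'
#' @param x a [BinnedMatrix-class] with at least 3 columns (the
#'   O-information of a pair is identically zero and not meaningful here).
#' @return Numeric scalar, bits.
#' @examples
#' # exhaustive XOR: the maximally synergistic 2-bin triplet, Omega = -1
#' x12 <- as.matrix(expand.grid(0:1, 0:1))
#' oinfoNaive(BinnedMatrix(cbind(x12, (x12[, 1] + x12[, 2]) %% 2)))
#' @export
oinfoNaive <- function(x) {
  stopifnot(is(x, "BinnedMatrix"))
  n <- ncol(x@labels)
  if (n < 3L) {
    stop("O-information needs at least 3 variables")
  }
  t <- .oinfoTerms(x)
  (n - 2) * t$hFull + sum(t$hMarg - t$hMinus)
}

#' Miller-Maddow bias term for the O-information
#'
#' The additive bias approximation obtained by propagating the
#' Miller-Maddow entropy bias through every term of the O-information:
#' \deqn{\delta_{MM} = \frac{1}{2 N \ln 2}\Big[\sum_j (K_j - K_{(-j)})
#'   + (n-2) K_{(n)} - n + 2\Big],}
#' where \eqn{K_j} are the variable cardinalities, \eqn{K_{(-j)}} the
#' supports of the leave-one-out joints and \eqn{K_{(n)}} the support of
#' the full joint. The expected naive estimate is
#' \eqn{E[\hat\Omega] \approx \Omega - \delta_{MM}}, so the corrected
#' estimator is \eqn{\hat\Omega + \delta_{MM}}. The term can take either
#' sign: for a full-support independent triplet with common K it
#' simplifies to \eqn{(K-1)^3 / (2N\ln 2) > 0}, for a full-support
#' synergistic triplet to \eqn{(-2K^2+3K-1)/(2N\ln 2) < 0}, and for a
#' redundant triplet to \eqn{(K-1)/(2N\ln 2)}.
#'
#' @param cardinalities integer vector, per-variable bin counts Kj.
#' @param supportsMinusJ integer vector of leave-one-out supports K(-j),
#'   same length and order as \code{cardinalities}.
#' @param supportN integer, full joint support K(n).
#' @param N integer, sample count (>= 1).
#' @return Numeric scalar, bits.
#' @examples
#' deltaMM(rep(10, 3), rep(100, 3), 1000, 1000)  # (K-1)^3 / (2N ln 2)
#' @export
deltaMM <- function(cardinalities, supportsMinusJ, supportN, N) {
  n <- length(cardinalities)
  if (length(supportsMinusJ) != n) {
    stop("supportsMinusJ must match cardinalities in length")
  }
  if (N < 1) {
    stop("N must be >= 1")
  }
  if (supportN < 1 || any(supportsMinusJ < 1) || any(cardinalities < 1)) {
    stop("all supports and cardinalities must be >= 1")
  }
  (sum(cardinalities - supportsMinusJ) + (n - 2) * supportN - n + 2) /
    (2 * N * .LN2)
}

#' Bias-corrected O-information estimate
#'
#' Computes the naive O-information and adds the Miller-Maddow bias term
#' [deltaMM()], with the supports K(n) and K(-j) taken according to
#' \code{supportMode}:
#' \describe{
#'   \item{observed}{count the distinct joint bin combinations actually
#'     seen in the data (the default, and all that is available for
#'     empirical data).}
#'   \item{theoretical}{use the products of the cardinalities — the
#'     support of a full-support (e.g. independent) system.}
#'   \item{known}{user-supplied supports, for simulated systems whose true
#'     supports are known (a synergistic triplet has K(n) = K^2, not
#'     K^3).}
#' }
#' Observed supports underestimate true supports exactly in the
#' undersampled regimes where the bias is largest, which is why the
#' corrected estimator only partially removes the bias there.
#'
#' @param x a [BinnedMatrix-class], at least 3 columns.
#' @param supportMode \code{"observed"} (default), \code{"theoretical"}
#'   or \code{"known"}.
#' @param knownSupports for \code{supportMode = "known"}: a list with
#'   elements \code{supportN} (scalar) and \code{supportsMinusJ} (length-n
#'   vector).
#' @return An [OInfoResult-class].
#' @examples
#' set.seed(7)
#' x <- simulateTriplet("independent", N = 1000, K = 10, seed = 7)
#' oinfoCorrected(x)
#' @export
oinfoCorrected <- function(x,
                           supportMode = c("observed", "theoretical",
                                           "known"),
                           knownSupports = NULL) {
  stopifnot(is(x, "BinnedMatrix"))
  supportMode <- match.arg(supportMode)
  n <- ncol(x@labels)
  if (n < 3L) {
    stop("O-information needs at least 3 variables")
  }
  N <- nrow(x@labels)
  card <- x@cardinalities
  t <- .oinfoTerms(x)
  naive <- (n - 2) * t$hFull + sum(t$hMarg - t$hMinus)

  if (supportMode == "observed") {
    suppN <- t$suppFull
    suppMinus <- t$suppMinus
  } else if (supportMode == "theoretical") {
    prodAll <- prod(as.numeric(card))
    if (prodAll > .Machine$integer.max) {
      stop("theoretical supports exceed integer range")
    }
    suppN <- as.integer(prodAll)
    suppMinus <- vapply(seq_len(n), function(j) {
      as.integer(prod(as.numeric(card[-j])))
    }, integer(1))
  } else {
    if (is.null(knownSupports) ||
        is.null(knownSupports$supportN) ||
        is.null(knownSupports$supportsMinusJ)) {
      stop("supportMode = 'known' requires knownSupports with supportN and supportsMinusJ")
    }
    suppN <- as.integer(knownSupports$supportN)
    suppMinus <- as.integer(knownSupports$supportsMinusJ)
    if (length(suppMinus) != n) {
      stop("knownSupports$supportsMinusJ must have one entry per variable")
    }
  }

  dmm <- deltaMM(card, suppMinus, suppN, N)
  new("OInfoResult", omegaNaive = naive, deltaMM = dmm,
      omegaCorrected = naive + dmm, n = as.integer(n), N = as.integer(N),
      cardinalities = card, supportN = suppN,
      supportsMinusJ = suppMinus, supportMode = supportMode)
}

#' Theoretical O-information bounds
#'
#' For an n-variable system whose largest cardinality is Kmax, the
#' O-information is bounded by
#' \deqn{(2-n)\log_2 K_{max} \le \Omega \le (n-2)\log_2 K_{max}.}
#' The upper bound is attained exactly by a fully redundant system (every
#' variable determines every other), the lower bound by a maximally
#' synergistic one (n-1 independent uniform variables plus their mod-K
#' sum). The bounds hold for the empirical distribution too, so they also
#' bound the naive estimate.
#'
#' @param n integer, number of variables (>= 3).
#' @param Kmax integer, largest cardinality (>= 2).
#' @return Named numeric vector \code{c(lower, upper)}, bits;
#'   \code{lower == -upper}.
#' @examples
#' theoreticalBounds(3, 50)   # about -5.64 / +5.64 bits
#' @export
theoreticalBounds <- function(n, Kmax) {
  if (n < 3L) {
    stop("n must be >= 3")
  }
  if (Kmax < 2L) {
    stop("Kmax must be >= 2")
  }
  upper <- (n - 2) * log2(Kmax)
  c(lower = -upper, upper = upper)
}
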