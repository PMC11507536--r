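#' @include AllGenerics.R
NULL

#' BinnedMatrix: discretized samples of an n-variable system
#'
#' An N x n integer matrix of 0-based bin labels together with the
#' per-column cardinalities (K1, ..., Kn). This is the sole input of the
#' O-information estimators: every entropy term is computed from joint
#' occurrence counts of its label columns. Column j must only use labels
#' in \{0, ..., Kj - 1\}.
#'
#' @slot labels integer matrix, N rows (samples) x n columns (variables),
#'   entries in \code{0:(Kj-1)} per column. Column names identify variables.
#' @slot cardinalities integer vector of length n; Kj, the number of bins
#'   (possible labels) of variable j.
#'
#' @seealso [binMatrix()], [quantileBin()], [oinfoNaive()], [oinfoCorrected()]
#' @export
setClass("BinnedMatrix",
  representation(labels = "matrix", cardinalities = "integer"),
  validity = function(object) {
    lab <- object@labels
    card <- object@cardinalities
    if (!is.numeric(lab)) {
      return("labels must be an integer matrix")
    }
    if (nrow(lab) < 1L || ncol(lab) < 1L) {
      return("labels must have at least one row and one column")
    }
    if (length(card) != ncol(lab)) {
      return("one cardinality per column is required")
    }
    if (any(card < 1L)) {
      return("cardinalities must be >= 1")
    }
    for (j in seq_len(ncol(lab))) {
      v <- lab[, j]
      if (anyNA(v) || any(v != floor(v))) {
        return(sprintf("column %d contains non-integer or missing labels", j))
      }
      if (any(v < 0L) || any(v >= card[j])) {
        return(sprintf("column %d has labels outside [0, K-1]", j))
      }
    }
    TRUE
  }
)

#' Construct a BinnedMatrix
#'
#' @param labels integer matrix of 0-based bin labels (N samples x n
#'   variables). Column names are kept as variable identifiers; unnamed
#'   columns are named \code{V1, ..., Vn}.
#' @param cardinalities integer vector of per-column bin counts Kj. By
#'   default the smallest consistent value, \code{max(label) + 1}, per
#'   column. Supply explicitly when a nominal K exceeds the labels
#'   actually observed.
#' @return A [BinnedMatrix-class] object.
#' @examples
#' m <- BinnedMatrix(cbind(a = c(0L, 1L, 0L), b = c(1L, 1L, 0L)))
#' cardinalities(m)
#' @export
BinnedMatrix <- function(labels, cardinalities = NULL) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (is.null(colnames(labels))) {
    colnames(labels) <- paste0("V", seq_len(ncol(labels)))
  }
  if (is.null(cardinalities)) {
    cardinalities <- apply(labels, 2L, function(v) max(v) + 1L)
  }
  new("BinnedMatrix", labels = labels,
      cardinalities = as.integer(cardinalities))
}

#' @rdname accessors
#' @export
setMethod("binLabels", "BinnedMatrix", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("cardinalities", "BinnedMatrix", function(x) {
  stats::setNames(x@cardinalities, colnames(x@labels))
})

#' @rdname accessors
#' @export
setMethod("nSamples", "BinnedMatrix", function(x) nrow(x@labels))

#' @rdname accessors
#' @export
setMethod("nVariables", "BinnedMatrix", function(x) ncol(x@labels))

setMethod("show", "BinnedMatrix", function(object) {
  cat(sprintf("BinnedMatrix: %d samples x %d variables\n",
              nrow(object@labels), ncol(object@labels)))
  cat("cardinalities:",
      paste(sprintf("%s=%d", colnames(object@labels), object@cardinalities),
            collapse = ", "), "\n")
})

#' CountTable: joint occurrence counts over a column subset
#'
#' Exact counts of the joint bin-label combinations observed over a subset
#' of the columns of a [BinnedMatrix-class]. Only combinations that occur
#' are stored (every count is >= 1); counts sum to the sample size N. The
#' number of stored combinations is the observed support, the quantity the
#' bias correction plugs in for K(n) and K(-j) when the true supports are
#' unknown.
#'
#' @slot counts integer vector of positive counts, one per observed joint
#'   combination, in first-appearance order.
#' @slot N integer; total sample count (sum of counts).
#' @slot subset integer; the column indices the counts were taken over.
#'
#' @seealso [countJoint()], [pluginEntropy()], [mmEntropy()]
#' @export
setClass("CountTable",
  representation(counts = "integer", N = "integer", subset = "integer"),
  validity = function(object) {
    if (length(object@counts) < 1L) {
      return("a CountTable must hold at least one combination")
    }
    if (any(object@counts < 1L)) {
      return("zero or negative counts must never be stored")
    }
    if (sum(object@counts) != object@N) {
      return("counts must sum to N")
    }
    if (length(object@subset) < 1L) {
      return("subset must be non-empty")
    }
    TRUE
  }
)

#' @rdname accessors
#' @export
setMethod("observedSupport", "CountTable", function(x) length(x@counts))

#' @rdname accessors
#' @export
setMethod("nSamples", "CountTable", function(x) x@N)

setMethod("show", "CountTable", function(object) {
  cat(sprintf("CountTable over columns {%s}: %d observed combinations, N = %d\n",
              paste(object@subset, collapse = ","),
              length(object@counts), object@N))
})

#' EntropyEstimate: a plug-in or Miller-Maddow entropy value
#'
#' An entropy estimate in bits, tagged by the estimator that produced it.
#' For the Miller-Maddow estimator, \code{biasTerm} holds the additive
#' correction (support - 1) / (2 N ln 2) and \code{supportUsed} the support
#' count that was plugged in; for the plug-in estimator the term is 0.
#'
#' @slot value numeric; the entropy estimate in bits.
#' @slot estimator character; \code{"plugin"} or \code{"miller_maddow"}.
#' @slot biasTerm numeric; additive bias-correction term in bits (>= 0).
#' @slot supportUsed integer; support count used in the bias term (1 for
#'   plug-in, where no support enters).
#'
#' @seealso [pluginEntropy()], [mmEntropy()]
#' @export
setClass("EntropyEstimate",
  representation(value = "numeric", estimator = "character",
                 biasTerm = "numeric", supportUsed = "integer"),
  validity = function(object) {
    if (!object@estimator %in% c("plugin", "miller_maddow")) {
      return("estimator must be 'plugin' or 'miller_maddow'")
    }
    if (object@value < -1e-12) {
      return("entropy must be non-negative")
    }
    if (object@biasTerm < 0) {
      return("the Miller-Maddow bias term is non-negative")
    }
    if (object@estimator == "plugin" && object@biasTerm != 0) {
      return("plug-in estimates carry a zero bias term")
    }
    TRUE
  }
)

#' @rdname accessors
#' @export
setMethod("entropyValue", "EntropyEstimate", function(x) x@value)

#' @rdname accessors
#' @export
setMethod("biasTerm", "EntropyEstimate", function(x) x@biasTerm)

setMethod("show", "EntropyEstimate", function(object) {
  cat(sprintf("EntropyEstimate [%s]: %.6f bits", object@estimator,
              object@value))
  if (object@estimator == "miller_maddow") {
    cat(sprintf(" (bias term %.6f, support %d)", object@biasTerm,
                object@supportUsed))
  }
  cat("\n")
})

#' OInfoResult: naive and bias-corrected O-information of one system
#'
#' The result of estimating the O-information of an n-variable system:
#' the naive plug-in estimate, the Miller-Maddow bias term delta_MM, the
#' corrected estimate (naive + delta_MM), and the support counts K(n) and
#' K(-j) that entered the bias term, together with how they were obtained
#' (\code{"observed"}: counted from the data; \code{"theoretical"}:
#' products of cardinalities; \code{"known"}: user-supplied).
#'
#' @slot omegaNaive numeric; plug-in O-information in bits.
#' @slot deltaMM numeric; Miller-Maddow bias term in bits (either sign).
#' @slot omegaCorrected numeric; \code{omegaNaive + deltaMM}.
#' @slot n integer; number of variables.
#' @slot N integer; number of samples.
#' @slot cardinalities integer; per-variable bin counts Kj.
#' @slot supportN integer; support of the full joint system, K(n).
#' @slot supportsMinusJ integer; leave-one-out supports K(-j), length n.
#' @slot supportMode character; \code{"observed"}, \code{"theoretical"}
#'   or \code{"known"}.
#'
#' @seealso [oinfoCorrected()], [deltaMM()], [theoreticalBounds()]
#' @export
setClass("OInfoResult",
  representation(omegaNaive = "numeric", deltaMM = "numeric",
                 omegaCorrected = "numeric", n = "integer", N = "integer",
                 cardinalities = "integer", supportN = "integer",
                 supportsMinusJ = "integer", supportMode = "character"),
  validity = function(object) {
    if (abs(object@omegaCorrected - object@omegaNaive - object@deltaMM) >
        1e-12) {
      return("omegaCorrected must equal omegaNaive + deltaMM")
    }
    if (length(object@supportsMinusJ) != object@n) {
      return("one K(-j) support per variable is required")
    }
    if (!object@supportMode %in% c("observed", "theoretical", "known")) {
      return("supportMode must be observed, theoretical or known")
    }
    kmax <- max(object@cardinalities)
    bound <- (object@n - 2) * log2(kmax)
    if (object@omegaNaive > bound + 1e-9 ||
        object@omegaNaive < -bound - 1e-9) {
      return("omegaNaive violates the (2-n)log2(Kmax) bounds")
    }
    TRUE
  }
)

#' @rdname accessors
#' @export
setMethod("omegaNaive", "OInfoResult", function(x) x@omegaNaive)

#' @rdname accessors
#' @export
setMethod("omegaCorrected", "OInfoResult", function(x) x@omegaCorrected)

#' @rdname accessors
#' @export
setMethod("biasTerm", "OInfoResult", function(x) x@deltaMM)

#' @rdname accessors
#' @export
setMethod("nSamples", "OInfoResult", function(x) x@N)

#' @rdname accessors
#' @export
setMethod("nVariables", "OInfoResult", function(x) x@n)

#' @rdname accessors
#' @export
setMethod("cardinalities", "OInfoResult", function(x) x@cardinalities)

setMethod("show", "OInfoResult", function(object) {
  cat(sprintf("OInfoResult (n = %d, N = %d, supports: %s)\n",
              object@n, object@N, object@supportMode))
  cat(sprintf("  naive Omega:     %+.6f bits\n", object@omegaNaive))
  cat(sprintf("  delta_MM:        %+.6f bits\n", object@deltaMM))
  cat(sprintf("  corrected Omega: %+.6f bits\n", object@omegaCorrected))
  cat(sprintf("  K(n) = %d; K(-j) = %s\n", object@supportN,
              paste(object@supportsMinusJ, collapse = ", ")))
})
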