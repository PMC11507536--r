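#' @include simulate.R
NULL

#' Load a rectangular table and median-impute missing values
#'
#' Reads a CSV/TSV file (header row, one row per sample), keeps the
#' numeric columns, and replaces every missing entry with the median of
#' its column. Non-numeric columns are dropped with a warning; a column
#' with no observed values at all cannot be imputed and is an error, as
#' is a table with fewer than three usable columns (no triplet can be
#' formed). The median of an even-sized column is the mean of the two
#' central values.
#'
#' @param path path to a delimited text file; tab-separated for
#'   \code{.tsv}/\code{.txt}, comma-separated otherwise.
#' @param missingTokens character values treated as missing (default
#'   \code{""}, \code{"NA"}, \code{"NaN"}).
#' @return A data.frame of numeric, fully imputed columns.
#' @seealso [scanTriplets()]
#' @export
loadAndImpute <- function(path, missingTokens = c("", "NA", "NaN")) {
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = missingTokens,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  numeric_cols <- list()
  dropped <- character(0)
  for (nm in names(raw)) {
    v <- raw[[nm]]
    if (is.numeric(v)) {
      numeric_cols[[nm]] <- as.numeric(v)
    } else if (is.logical(v) && all(is.na(v))) {
      numeric_cols[[nm]] <- as.numeric(v)   # all-missing, caught below
    } else {
      conv <- suppressWarnings(as.numeric(v))
      if (any(is.na(conv) & !is.na(v))) {
        dropped <- c(dropped, nm)
      } else {
        numeric_cols[[nm]] <- conv
      }
    }
  }
  if (length(dropped) > 0L) {
    warning("dropping non-numeric column(s): ",
            paste(dropped, collapse = ", "))
  }
  for (nm in names(numeric_cols)) {
    v <- numeric_cols[[nm]]
    if (all(is.na(v))) {
      stop("column ", nm, " has no observed values to impute from")
    }
    v[is.na(v)] <- stats::median(v, na.rm = TRUE)
    numeric_cols[[nm]] <- v
  }
  if (length(numeric_cols) < 3L) {
    stop("fewer than 3 usable numeric columns; no triplets can be scanned")
  }
  as.data.frame(numeric_cols, check.names = FALSE)
}

#' Scan all variable triplets of a table for synergy and redundancy
#'
#' Discretizes every column of a table into a common number of equal-count
#' bins (see [binMatrix()]; already-discrete columns keep their
#' categories) and computes the naive and bias-corrected O-information of
#' every one of the C(M, 3) variable triplets. Records are ranked
#' ascending by estimate, so rank 1 is the most synergistic triplet; ties
#' are broken lexicographically by variable names for deterministic
#' output. Per-column and per-pair entropies are computed once and reused
#' across triplets.
#'
#' Interpret ranks against a matched [nullBenchmark()]: at small N/K the
#' naive estimator pushes even independent triplets far below zero, so a
#' strongly negative estimate alone is not evidence of synergy.
#'
#' @param x data.frame or numeric matrix of M >= 3 columns (impute
#'   missing values first, see [loadAndImpute()]), or a
#'   [BinnedMatrix-class] that is already discretized.
#' @param K common bin count (default 10).
#' @param supportMode \code{"observed"} (default) or
#'   \code{"theoretical"}; per-triplet true supports are not available
#'   when scanning empirical data.
#' @return data.frame with one row per triplet: \code{var1, var2, var3,
#'   omega_naive, omega_corrected, rank_naive, rank_corrected}, ordered
#'   by \code{rank_naive}.
#' @examples
#' set.seed(2)
#' tab <- data.frame(a = runif(200), b = runif(200), c = runif(200),
#'                   d = runif(200))
#' scanTriplets(tab, K = 4)
#' @export
scanTriplets <- function(x, K = 10L,
                         supportMode = c("observed", "theoretical")) {
  supportMode <- match.arg(supportMode)
  if (is(x, "BinnedMatrix")) {
    bm <- x
  } else {
    bm <- binMatrix(x, K)
  }
  M <- ncol(bm@labels)
  if (M < 3L) {
    stop("at least 3 variables are required")
  }
  N <- nrow(bm@labels)
  card <- bm@cardinalities
  vnames <- colnames(bm@labels)

  hMarg <- vapply(seq_len(M), function(j) {
    pluginEntropy(countJoint(bm, j))@value
  }, numeric(1))

  # pair entropies and observed supports, reused across triplets
  hPair <- matrix(NA_real_, M, M)
  sPair <- matrix(NA_integer_, M, M)
  for (i in seq_len(M - 1L)) {
    for (j in (i + 1L):M) {
      tab <- countJoint(bm, c(i, j))
      hPair[i, j] <- hPair[j, i] <- pluginEntropy(tab)@value
      sPair[i, j] <- sPair[j, i] <- observedSupport(tab)
    }
  }

  triples <- utils::combn(M, 3L)
  nT <- ncol(triples)
  omegaN <- numeric(nT)
  omegaC <- numeric(nT)
  for (t in seq_len(nT)) {
    i <- triples[1L, t]; j <- triples[2L, t]; k <- triples[3L, t]
    full <- countJoint(bm, c(i, j, k))
    hFull <- pluginEntropy(full)@value
    omegaN[t] <- hFull + hMarg[i] + hMarg[j] + hMarg[k] -
      hPair[j, k] - hPair[i, k] - hPair[i, j]
    if (supportMode == "observed") {
      suppN <- observedSupport(full)
      suppMinus <- c(sPair[j, k], sPair[i, k], sPair[i, j])
    } else {
      cc <- as.numeric(card[c(i, j, k)])
      suppN <- as.integer(prod(cc))
      suppMinus <- as.integer(prod(cc) / cc)
    }
    omegaC[t] <- omegaN[t] +
      deltaMM(card[c(i, j, k)], suppMinus, suppN, N)
  }

  rec <- data.frame(var1 = vnames[triples[1L, ]],
                    var2 = vnames[triples[2L, ]],
                    var3 = vnames[triples[3L, ]],
                    omega_naive = omegaN, omega_corrected = omegaC,
                    stringsAsFactors = FALSE)
  ordN <- order(rec$omega_naive, rec$var1, rec$var2, rec$var3)
  rec$rank_naive[ordN] <- seq_len(nT)
  ordC <- order(rec$omega_corrected, rec$var1, rec$var2, rec$var3)
  rec$rank_corrected[ordC] <- seq_len(nT)
  rec <- rec[order(rec$rank_naive), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Independent-triplet null benchmark for a scan
#'
#' Simulates fully independent uniform triplets at the same sample size N
#' and bin count K as a scanned dataset and summarizes their naive and
#' bias-corrected O-information. Because the naive estimator of an
#' independent triplet is itself strongly negative when N is small
#' relative to K^3, this simulated null — not zero — is the reference
#' against which scanned triplets should be judged synergistic.
#'
#' @param N,K sample and bin counts matching the scanned data.
#' @param trials number of simulated triplets (default 30).
#' @param supportMode passed to [oinfoCorrected()].
#' @param seed integer master seed.
#' @return A list with elements \code{N, K, trials, meanNaive,
#'   meanCorrected, naiveSamples, correctedSamples} (estimates in bits).
#' @examples
#' nb <- nullBenchmark(N = 500, K = 5, trials = 10, seed = 1)
#' nb$meanNaive
#' @export
nullBenchmark <- function(N, K, trials = 30L,
                          supportMode = c("observed", "theoretical",
                                          "known"),
                          seed = 1L) {
  supportMode <- match.arg(supportMode)
  trials <- as.integer(trials)
  if (trials < 1L) {
    stop("trials must be >= 1")
  }
  known <- if (supportMode == "known") {
    list(supportN = K^3, supportsMinusJ = rep(K^2, 3L))
  } else {
    NULL
  }
  sysIdx <- match("independent", .SYSTEMS)
  naive <- numeric(trials)
  corrected <- numeric(trials)
  for (t in seq_len(trials)) {
    s <- .deriveSeed(seed, sysIdx, N, K, t)
    x <- simulateTriplet("independent", N, K, s)
    r <- oinfoCorrected(x, supportMode = supportMode,
                        knownSupports = known)
    naive[t] <- r@omegaNaive
    corrected[t] <- r@omegaCorrected
  }
  list(N = as.integer(N), K = as.integer(K), trials = trials,
       meanNaive = mean(naive), meanCorrected = mean(corrected),
       naiveSamples = naive, correctedSamples = corrected)
}

#' Overlap of top-ranked triplets between two rankings
#'
#' Counts how many triplets appear in the top \code{topM} of both
#' rankings — typically the naive ranking of a scan versus its
#' bias-corrected ranking, to see how much the correction reshuffles the
#' most synergistic triplets. Both record sets must cover the same
#' triplet universe (same variables).
#'
#' @param before,after data.frames as returned by [scanTriplets()].
#' @param topM size of the head of each ranking to compare.
#' @param rankBefore,rankAfter which ranking to use on each side:
#'   \code{"naive"} or \code{"corrected"}. Defaults compare the naive
#'   ranking of \code{before} with the corrected ranking of \code{after}.
#' @return Integer overlap count in \code{0:topM}.
#' @examples
#' set.seed(3)
#' tab <- data.frame(matrix(runif(200 * 5), 200))
#' sc <- scanTriplets(tab, K = 4)
#' rankOverlap(sc, sc, topM = 3)                       # naive vs corrected
#' rankOverlap(sc, sc, topM = 3, rankAfter = "naive")  # identity: 3
#' @export
rankOverlap <- function(before, after, topM,
                        rankBefore = c("naive", "corrected"),
                        rankAfter = c("corrected", "naive")) {
  rankBefore <- match.arg(rankBefore)
  rankAfter <- match.arg(rankAfter)
  keyB <- paste(before$var1, before$var2, before$var3, sep = "\r")
  keyA <- paste(after$var1, after$var2, after$var3, sep = "\r")
  if (!setequal(keyB, keyA)) {
    stop("before and after must cover the same triplets")
  }
  colB <- paste0("rank_", rankBefore)
  colA <- paste0("rank_", rankAfter)
  topB <- keyB[before[[colB]] <= topM]
  topA <- keyA[after[[colA]] <= topM]
  length(intersect(topB, topA))
}
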