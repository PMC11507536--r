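#' @include oinfo.R
NULL

.SYSTEMS <- c("redundant", "independent", "synergistic")

# Deterministic per-trial seed: mix integers into [1, 2^31 - 2] with a
# multiplicative hash mod the Mersenne prime 2^31 - 1 (exact in doubles).
.deriveSeed <- function(...) {
  parts <- c(...)
  h <- 17
  for (k in parts) {
    h <- (h * 31 + (as.numeric(k) %% 2147483647)) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

# Run expr with a private RNG stream; the caller's RNG state is untouched.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# True O-information of each canonical triplet system, bits.
.trueOmega <- function(system, K) {
  switch(system,
         redundant = log2(K),
         independent = 0,
         synergistic = -log2(K),
         stop("unknown system: ", system))
}

#' Simulate one canonical triplet system
#'
#' Generates one sample of a triplet with known true O-information, using
#' the same equal-count discretization an analyst would apply to
#' empirical data (bins are built from the observed draws, not from the
#' known generating distribution):
#' \describe{
#'   \item{redundant}{one continuous uniform sample of size N,
#'     quantile-binned into K bins, copied to all three columns
#'     (X1 = X2 = X3). True Omega = +log2(K), the maximum for a triplet.}
#'   \item{independent}{three independent continuous uniform samples,
#'     each quantile-binned. True Omega = 0.}
#'   \item{synergistic}{two independent uniform samples quantile-binned;
#'     the third column is the modular sum of the \emph{bin labels},
#'     X3 = (b1 + b2) mod K. True Omega = -log2(K), the minimum; at K = 2
#'     this is the XOR gate.}
#' }
#' The three systems need very different sample sizes to resolve their
#' joint distribution: N >= K (redundant), N >= K^3 (independent),
#' N >= K^2 (synergistic full joint). Output is deterministic given
#' \code{(system, N, K, seed)} and leaves the caller's RNG state alone.
#'
#' @param system \code{"redundant"}, \code{"independent"} or
#'   \code{"synergistic"}.
#' @param N integer sample count, \code{N >= K}.
#' @param K integer bin count, \code{K >= 2}.
#' @param seed integer seed for this draw.
#' @return A [BinnedMatrix-class] with columns X1, X2, X3 and common
#'   cardinality K.
#' @examples
#' x <- simulateTriplet("synergistic", N = 100, K = 2, seed = 1)
#' all(binLabels(x)[, 3] == (binLabels(x)[, 1] + binLabels(x)[, 2]) %% 2)
#' @export
simulateTriplet <- function(system = .SYSTEMS, N, K, seed) {
  system <- match.arg(system)
  N <- as.integer(N)
  K <- as.integer(K)
  if (K < 2L) {
    stop("K must be >= 2")
  }
  if (N < K) {
    stop("N must be at least K (equal-count binning needs N >= K)")
  }
  labels <- .withSeed(seed, {
    switch(system,
      redundant = {
        b <- quantileBin(stats::runif(N), K)
        cbind(X1 = b, X2 = b, X3 = b)
      },
      independent = {
        cbind(X1 = quantileBin(stats::runif(N), K),
              X2 = quantileBin(stats::runif(N), K),
              X3 = quantileBin(stats::runif(N), K))
      },
      synergistic = {
        b1 <- quantileBin(stats::runif(N), K)
        b2 <- quantileBin(stats::runif(N), K)
        cbind(X1 = b1, X2 = b2, X3 = (b1 + b2) %% K)
      })
  })
  BinnedMatrix(labels, rep(K, 3L))
}

#' Simulate one (system, N, K) cell of the bias study
#'
#' Repeats [simulateTriplet()] + [oinfoCorrected()] over independent
#' trials and summarizes the naive and corrected estimates against the
#' known true O-information of the system:
#' \itemize{
#'   \item \code{delta} — bias of the naive mean, true Omega minus the
#'     mean naive estimate; positive means biased towards synergy.
#'   \item \code{delta_bc} — the same for the corrected mean.
#'   \item \code{epsilon} — \code{|delta_bc| - |delta|}; negative means
#'     the correction reduced the absolute bias.
#' }
#' Per-trial seeds are derived deterministically from
#' \code{(baseSeed, system, N, K, trial)}, so any cell can be re-run in
#' isolation and grids are reproducible cell by cell.
#'
#' @param system one of \code{"redundant"}, \code{"independent"},
#'   \code{"synergistic"}.
#' @param N,K sample and bin counts, \code{N >= K >= 2}.
#' @param trials number of independent repetitions (>= 1; the study
#'   convention is 30).
#' @param supportMode passed to [oinfoCorrected()].
#' @param baseSeed integer master seed.
#' @return A one-row data.frame with columns \code{system, N, K, trials,
#'   mean_naive, sd_naive, mean_corrected, true_omega, delta, delta_bc,
#'   epsilon} (all estimates in bits; \code{sd_naive} is the sample SD
#'   over trials).
#' @examples
#' runCell("independent", N = 500, K = 5, trials = 5, baseSeed = 1)
#' @export
runCell <- function(system, N, K, trials = 30L,
                    supportMode = c("observed", "theoretical", "known"),
                    baseSeed = 1L) {
  system <- match.arg(system, .SYSTEMS)
  supportMode <- match.arg(supportMode)
  trials <- as.integer(trials)
  if (trials < 1L) {
    stop("trials must be >= 1")
  }
  known <- NULL
  if (supportMode == "known") {
    # true supports of the canonical systems at common cardinality K
    known <- switch(system,
      redundant = list(supportN = K, supportsMinusJ = rep(K, 3L)),
      independent = list(supportN = K^3, supportsMinusJ = rep(K^2, 3L)),
      synergistic = list(supportN = K^2, supportsMinusJ = rep(K^2, 3L)))
  }
  sysIdx <- match(system, .SYSTEMS)
  naive <- numeric(trials)
  corrected <- numeric(trials)
  for (t in seq_len(trials)) {
    seed <- .deriveSeed(baseSeed, sysIdx, N, K, t)
    x <- simulateTriplet(system, N, K, seed)
    r <- oinfoCorrected(x, supportMode = supportMode,
                        knownSupports = known)
    naive[t] <- r@omegaNaive
    corrected[t] <- r@omegaCorrected
  }
  trueOmega <- .trueOmega(system, K)
  meanNaive <- mean(naive)
  meanCorr <- mean(corrected)
  delta <- trueOmega - meanNaive
  deltaBC <- trueOmega - meanCorr
  data.frame(system = system, N = as.integer(N), K = as.integer(K),
             trials = trials, mean_naive = meanNaive,
             sd_naive = if (trials > 1L) stats::sd(naive) else 0,
             mean_corrected = meanCorr, true_omega = trueOmega,
             delta = delta, delta_bc = deltaBC,
             epsilon = abs(deltaBC) - abs(delta),
             stringsAsFactors = FALSE)
}

#' Run a (system, N, K) grid of bias-study cells
#'
#' Full factorial sweep of [runCell()] over systems, sample sizes and bin
#' counts. Cells with N < K cannot be binned and are skipped (with a
#' message). The defaults span the full bias landscape — K = 2..50 step
#' 1, N = 500..20000 step 500, 30 trials — but most analyses (and the
#' package's own tests) use reduced grids.
#'
#' @param systems character vector of system tags (default all three).
#' @param Nvalues,Kvalues integer vectors of sample sizes and bin counts.
#' @param trials trials per cell (default 30).
#' @param supportMode passed to [runCell()].
#' @param baseSeed integer master seed; the same seed reproduces the grid
#'   bit for bit.
#' @param verbose print a progress line per system.
#' @return A long-format data.frame, one row per (system, N, K) cell, with
#'   the [runCell()] columns.
#' @examples
#' g <- runGrid(Nvalues = c(500, 1000), Kvalues = c(2, 5),
#'              trials = 3, baseSeed = 1)
#' subset(g, system == "independent")
#' @export
runGrid <- function(systems = .SYSTEMS,
                    Nvalues = seq(500L, 20000L, by = 500L),
                    Kvalues = 2:50, trials = 30L,
                    supportMode = c("observed", "theoretical", "known"),
                    baseSeed = 1L, verbose = FALSE) {
  systems <- match.arg(systems, .SYSTEMS, several.ok = TRUE)
  supportMode <- match.arg(supportMode)
  cells <- list()
  i <- 0L
  for (sys in systems) {
    if (verbose) {
      message("system: ", sys)
    }
    for (K in sort(as.integer(Kvalues))) {
      for (N in sort(as.integer(Nvalues))) {
        if (N < K) {
          message(sprintf("skipping cell %s N=%d K=%d: N < K", sys, N, K))
          next
        }
        i <- i + 1L
        cells[[i]] <- runCell(sys, N, K, trials = trials,
                              supportMode = supportMode,
                              baseSeed = baseSeed)
      }
    }
  }
  do.call(rbind, cells)
}

#' Minimum sample sizes to observe all joint combinations
#'
#' For each bin count K, the theoretical minimum sample sizes needed to
#' observe every marginal bin (N = K), every pair combination (N = K^2)
#' and every triplet combination (N = K^3). These are the boundary lines
#' that organize the bias landscape: a redundant triplet resolves at
#' N = K, a synergistic one at N = K^2, an independent one only at
#' N = K^3.
#'
#' @param Kvalues integer vector of bin counts.
#' @return data.frame with columns \code{K, N_marginal, N_pair,
#'   N_triplet}.
#' @examples
#' boundaryLines(c(2, 10, 50))
#' @export
boundaryLines <- function(Kvalues) {
  K <- as.integer(Kvalues)
  data.frame(K = K, N_marginal = as.numeric(K), N_pair = as.numeric(K)^2,
             N_triplet = as.numeric(K)^3)
}
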