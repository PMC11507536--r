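---
title: "Estimating O-information and correcting its finite-sample bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating O-information and correcting its finite-sample bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OinfoBias)
```

## The quantity

The O-information of a system of $n$ discrete variables
$X^n = (X_1, \dots, X_n)$ is a signed balance between redundancy and
synergy, built from Shannon entropies:

$$\Omega(X^n) = (n-2)\,H(X^n) + \sum_{j=1}^n \big[H(X_j) - H(X^n_{-j})\big],$$

where $H(X^n)$ is the joint entropy of all variables, $H(X_j)$ a
marginal entropy, and $H(X^n_{-j})$ the joint entropy with variable $j$
removed. All entropies in this package are in bits. $\Omega > 0$ means
the system is redundancy-dominated (information is shared: the extreme
case is $X_1 = X_2 = X_3$, which attains $+\log_2 K$ for $K$-bin
variables); $\Omega < 0$ means synergy dominates (information lives only
in the joint state: the extreme case is $X_3 = (X_1 + X_2) \bmod K$,
the XOR gate at $K = 2$, which attains $-\log_2 K$). For mutually
independent variables $\Omega = 0$. The measure is symmetric in its
variables and bounded by $\pm (n-2)\log_2 K_{\max}$
(`theoreticalBounds()`).

The package centres on triplets ($n = 3$) — the smallest systems with a
nontrivial O-information — but the estimator and its bias term are
implemented for general $n$.

## Discretization

Continuous variables are discretized by equal-count (quantile) binning
(`quantileBin()`, `binMatrix()`): the sample of rank $r$ (0-based,
ties broken by original sample position) receives label
$\lfloor rK/N \rfloor$. When $K$ divides $N$ every bin holds exactly
$N/K$ samples, so the marginal distribution is exactly uniform and the
plug-in marginal entropy is exactly $\log_2 K$ — the marginal entropy
terms then contribute no bias at all, which is one reason equal-count
binning is preferable here to equal-width binning (which can leave bins
empty and makes $K$ ambiguous). All variables must share the same $K$,
because $K$ enters both the estimate and its bias term.

Bins are always constructed from the observed sample, never from a known
generating distribution — including inside the simulators — so that
simulated and empirical data pass through the identical pipeline. Two
consequences matter. First, labels depend only on ranks, so any strictly
increasing transform of a variable leaves all results unchanged. Second,
the bias correction below is derived under the assumption that bins are
fixed beforehand and samples fall into them multinomially; observed-
sample binning slightly violates that (marginal counts are exactly, not
only on average, uniform), which costs the correction some accuracy but
is the only option on real data.

Columns that are already discrete — operationally, columns with at most
$K$ distinct values — are by default passed through with their
categories remapped to $0, \dots, d-1$ rather than collapsed into $K$
quantile bins, and keep cardinality $d$. This is a package choice for
mixed tables (the estimator only needs each column's cardinality, which
may then differ from $K$); forcing $d < K$ categories through quantile
binning would manufacture spurious ties. `passThrough = FALSE` disables
it.

## The plug-in estimator and its bias

`oinfoNaive()` plugs empirical frequencies into every entropy term.
Plug-in entropies are biased downward at finite $N$ (Jensen's
inequality): unseen or under-seen joint combinations make the empirical
distribution look too concentrated. The bias of the O-information is the
*balance* of those entropy biases, because joint and leave-one-out terms
enter with opposite signs. Three canonical triplets with known
$\Omega$ (`simulateTriplet()`) map the landscape:

* **redundant** ($X_1 = X_2 = X_3$, $\Omega = +\log_2 K$): all terms
  share one distribution; biases cancel except through $H(X^n)$, and
  quantile binning makes even that exact once $N \ge K$. Bias and trial
  variance are essentially zero.
* **independent** ($\Omega = 0$): needs $N \gtrsim K^3$ samples to
  populate the joint support. For $K^2 \lesssim N \lesssim K^3$ the
  full joint entropy is severely underestimated while pair entropies are
  not, pushing the estimate strongly *negative* — independent triplets
  masquerade as synergistic. This is the regime that motivates the
  package.
* **synergistic** ($X_3 = (X_1+X_2) \bmod K$, $\Omega = -\log_2 K$):
  the full joint support is only $K^2$, and the bias runs the other way
  (towards redundancy) for $N \gtrsim K^2$.

`boundaryLines()` returns the $N = K, K^2, K^3$ lines that organize
these regimes.

## The Miller–Maddow correction

The second-order Taylor expansion of the plug-in entropy around the true
cell probabilities gives the classic additive bias term
$(K - 1)/(2N\ln 2)$ bits for a variable with support $K$
(`mmEntropy()`). Propagating that term through every entropy in the
O-information yields the bias approximation

$$\delta_{MM} = \frac{1}{2N\ln 2}\Big[\sum_j \big(K_j - K_{(-j)}\big)
  + (n-2)\,K_{(n)} - n + 2\Big],$$

where $K_{(n)}$ and $K_{(-j)}$ are the supports (possible joint bin
combinations) of the full system and of the system without variable $j$.
Since the expected naive estimate is approximately
$\Omega - \delta_{MM}$, the corrected estimator is
$\hat\Omega_{BC} = \hat\Omega + \delta_{MM}$ (`oinfoCorrected()`,
`deltaMM()`). The printed grouping of the bias formula is read as
$[\sum_j (K_j - K_{(-j)})] + (n-2)K_{(n)} - n + 2$, the only reading
consistent with its own derivation and with the closed forms below.

For triplets with common $K$ and full supports the term has closed
forms used throughout the tests: $(K-1)^3/(2N\ln 2)$ (independent,
positive), $(-2K^2+3K-1)/(2N\ln 2)$ (synergistic, a negative concave
parabola in $K$), and $(K-1)/(2N\ln 2)$ (redundant).

### Support modes

The supports are rarely known. `supportMode` selects:

* `"observed"` (default): count the distinct joint combinations seen in
  the data. This is all empirical data offers. It *underestimates* true
  supports precisely in the undersampled regimes where the bias is
  largest, which is why the correction is partial there.
* `"theoretical"`: products of cardinalities — correct for a
  full-support (e.g. independent) system.
* `"known"`: user-supplied, for simulated systems (a synergistic triplet
  has $K_{(n)} = K^2$, not $K^3$).

The Miller–Maddow derivation assumes the asymptotic sampling regime
(every combination observed many times). The package deliberately does
not enforce it — the interesting regimes are outside it — but
`mmEntropy()` warns when $N$ is below the support, which can only
happen with theoretical or known supports (observed supports never
exceed $N$).

## The simulation study

`runCell()` repeats simulate-and-estimate over independent trials for
one (system, $N$, $K$) cell and reports the mean and sample SD of the
naive estimate, the corrected mean, and three derived quantities: the
naive bias $\delta = \Omega - \bar{\hat\Omega}$, the corrected bias
$\delta_{BC'} = \Omega - \bar{\hat\Omega}_{BC'}$, and
$\varepsilon' = |\delta_{BC'}| - |\delta|$ (negative when the
correction helped). `runGrid()` sweeps a full factorial grid; its
defaults span the whole bias landscape ($K = 2..50$ step 1,
$N = 500..20000$ step 500, 30 trials, observed supports). The package's own tests and acceptance
checks use a reduced grid — $K \in \{2, 10, 30, 50\}$,
$N \in \{500, 5000, 20000\}$, 30 trials — which covers every regime
boundary at a few seconds of runtime; problem sizes were chosen so the
whole suite re-runs comfortably on one CPU.

Numerical and design choices, made once:

* Trial seeds derive from a deterministic integer hash of
  (baseSeed, system, $N$, $K$, trial), so any cell reproduces in
  isolation and grids are bit-identical across runs with one seed. The
  simulators save and restore the caller's RNG state.
* Cell SDs use the sample convention (denominator trials $- 1$).
* Cells with $N < K$ are infeasible for equal-count binning and are
  skipped with a message rather than run.
* Entropy sums are accumulated in double precision; deterministic
  identities are tested at $10^{-12}$–$10^{-9}$ bits. Zero-count
  combinations are never stored, so $0\log 0$ never arises.

What the generators do *not* emulate: non-uniform marginals, mixed
synergy/redundancy, dependence structures between triplets of a larger
table, or missingness. Passing the simulation checks therefore
demonstrates correct estimation under the three canonical systems, not
estimator performance on arbitrary real data.

## Scanning a table

`scanTriplets()` generalizes the empirical workflow: discretize every
column of an $N \times M$ table to a common $K$ (default 10), compute
naive and corrected O-information for all $\binom{M}{3}$ triplets, and
rank them ascending (rank 1 = most synergistic), ties broken
lexicographically by variable names so output is deterministic.
`loadAndImpute()` reads CSV/TSV, drops non-numeric columns with a
warning, and imputes missing entries with the column median (mean of
the two central values for even counts). Per-column and per-pair count
tables are computed once and shared across the $O(M^3)$ triplets.

Because the naive estimator drags even independent triplets far below
zero at small $N/K$, ranks should be read against
`nullBenchmark()`: simulated independent triplets at the scanned
table's own $N$ and $K$. At the empirical-application scale
($N = 1684$, $K = 10$) the null means are about $-0.38$ naive and
$-0.14$ corrected bits (recomputed by `scripts/acceptance.R` and the
test suite) — a scanned triplet is only notably synergistic if it falls
clearly below that reference, not merely below zero.

Semantic curation of composite variables (ratios, sums, means of other
columns — which are synergistic by construction and rarely interesting)
cannot be automated from values alone; the CLI accepts an exclude list
instead.

## Known limitations

* The correction is second-order: it overestimates the bias of
  independent triplets when $N \lesssim K^2$ (where entropy-term biases
  partially cancel) and slightly overcorrects redundant triplets near
  $N = K$, overshooting $+\log_2 K$. A third-order term would be the
  natural refinement and is out of scope.
* Observed supports are themselves downward-biased estimates; better
  support estimators would directly improve the correction.
* Jackknife, Grassberger and Bayesian entropy corrections, permutation
  nulls, and continuous (Gaussian) O-information estimators are out of
  scope.
* Experiments target $n = 3$; the formulas accept larger $n$ but the
  simulators and reference numbers do not cover it.
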