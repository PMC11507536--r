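# OinfoBias

Estimation of the **O-information** of systems of discrete (or
quantile-discretized) variables, with a quantitative treatment of the
finite-sample bias of the naive plug-in estimator and an additive
**Miller–Maddow-derived bias correction**.

## The problem

The O-information of an n-variable system X^n = (X1, …, Xn),

    Ω(X^n) = (n−2)·H(X^n) + Σ_j [ H(Xj) − H(X^n_−j) ],

balances redundancy (Ω > 0, information shared across variables) against
synergy (Ω < 0, information present only in the joint state, as in the
XOR gate). It is increasingly used to mine tabular biomedical and omics
data for higher-order interactions between variable triplets. But every
entropy term is estimated by plugging in empirical frequencies, and
plug-in entropies are biased downward at finite sample size. For a
triplet of K-bin variables the joint support is K³: whenever the sample
size N is below roughly K³, the joint entropy is underestimated much
more than the pair entropies, and *fully independent triplets score as
strongly synergistic*. At N = 10,000 and K = 50 an independent triplet
averages about −3.2 bits — closer to the theoretical minimum
−log2(50) ≈ −5.64 than to its true value 0.

This package is for anyone ranking triplets by O-information who needs
to know how much of a negative score is bias. It provides:

* deterministic equal-count (quantile) binning (`quantileBin`,
  `binMatrix`),
* plug-in and Miller–Maddow entropy estimation over column subsets
  (`pluginEntropy`, `mmEntropy`, `countJoint`),
* the naive estimator, its bias term
  δ_MM = [Σ_j (Kj − K(−j)) + (n−2)·K(n) − n + 2] / (2N ln 2),
  and the corrected estimator Ω̂ + δ_MM (`oinfoNaive`, `deltaMM`,
  `oinfoCorrected`), with supports counted from the data, taken as
  cardinality products, or supplied,
* simulators for fully redundant, independent and synergistic triplets
  with known true Ω, and a grid driver mapping bias over (N, K)
  (`simulateTriplet`, `runCell`, `runGrid`, `boundaryLines`),
* a scan mode ranking all variable triplets of a table, with an
  independent-triplet null benchmark at matched N and K
  (`loadAndImpute`, `scanTriplets`, `nullBenchmark`, `rankOverlap`),
  plus a thin CLI (`inst/scripts/oinfo-bias.R`).

## Worked example

```r
library(OinfoBias)

# An independent uniform triplet at the scale of a typical cohort table:
# N = 1684 samples, K = 10 equal-count bins. True Omega = 0.
x <- simulateTriplet("independent", N = 1684, K = 10, seed = 42)
oinfoCorrected(x)
#> OInfoResult (n = 3, N = 1684, supports: observed)
#>   naive Omega:     -0.358409 bits
#>   delta_MM:        +0.243733 bits
#>   corrected Omega: -0.114676 bits
#>   K(n) = 840; K(-j) = 100, 100, 100
```

The naive estimate of this *independent* triplet is −0.36 bits — it
looks synergistic purely through undersampling (only 840 of the 1000
possible joint bin combinations are ever observed). The correction
recovers about two thirds of the bias. Averaged over 30 such triplets:

```r
nb <- nullBenchmark(N = 1684, K = 10, trials = 30, seed = 1)
sprintf("null: naive %.3f corrected %.3f", nb$meanNaive, nb$meanCorrected)
#> "null: naive -0.378 corrected -0.143"
```

These null means — not zero — are the reference against which a scanned
triplet at this N and K should be called synergistic. A scan of a table
ranks all C(M,3) triplets by both estimators:

```r
sc <- scanTriplets(my_table, K = 10)        # var1..3, omega_naive,
head(sc)                                    # omega_corrected, ranks
rankOverlap(sc, sc, topM = 50)              # naive vs corrected top-50
```

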