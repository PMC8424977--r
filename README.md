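# marrqc

Rank-based reproducibility assessment for mass spectrometry metabolomics.

Untargeted MS metabolomics experiments report thousands of metabolite
features, many of which are artefacts (background ions, adducts, poorly
integrated peaks). Before downstream analysis one wants to know which
features are *reproducible* — concordant across replicate experiments —
and to select them with explicit error control rather than an arbitrary
variability cutoff. `marrqc` is for analysts running technical or
biological replicates (QC pipelines, platform comparisons, preprocessing
benchmarks) who need a nonparametric, data-driven answer.

## The statistic

For a replicate pair, each of the $M$ features is ranked within each
replicate (rank 1 = largest abundance) and summarized by its maximum rank
statistic $\mathrm{Max}_m = \max(R_{m,1}, R_{m,2})$. The proportion
$\pi_1$ of reproducible features is estimated by fitting the ideal-split
limiting survival function to the empirical survival function of
$\mathrm{Max}_m/M$, minimizing over candidate split points $l \le \lambda M$:

$$\mathrm{MSE}_M(l/M) = (M-l)^{-1}\sum_{x=l}^{M}
\bigl[\hat S_M(x/M) - (1-l/M)\,S_{l/M}(x/M)\bigr]^2,\qquad
\hat\pi_1 = \hat k/M .$$

Features are then declared reproducible below the largest threshold
$\hat N$ whose estimated marginal FDR,
$\widehat{\mathrm{mFDR}}(l) = (l-\hat k)^2 / \{Q(l)(M-\hat k)\}$, stays at
or below the nominal level $\alpha$. With $I$ replicates the procedure
runs over all $\binom{I}{2}$ pairs (hierarchical designs are handled by
pooling lower layers), and the resulting $M \times J$ call matrix is
filtered on both margins with strict thresholds $c_s$ (features) and
$c_m$ (sample pairs). An RSD baseline
($100 \cdot \mathrm{sd}/|\mathrm{mean}|$, 25 % cutoff) is included for
comparison, and three simulation generators with known truth support
operating-characteristic studies (empirical FDR, power $= 1-\mathrm{NDR}$,
bias of $\hat\pi_1$).

## Worked example

One simulated replicate pair at realistic scale ($M = 2860$, true
$\pi_1 = 0.75$, replicate correlation 0.99):

```r
library(marrqc)
sim <- simulate_bivariate_normal(2860, pi1 = 0.75, mu_r = 4.01,
                                 rho_r = 0.99, seed = 42)
res <- marr_pair(sim$t1, sim$t2, alpha = 0.05, tie_seed = 42)
res
#> MaRR replicate-pair result
#>   M = 2860 metabolites, alpha = 0.05, lambda = 0.9
#>   pi1_hat = 0.7486 (k_hat = 2141), threshold N_hat = 2425
#>   declared reproducible: 2250 (78.7%)
score_calls(res$calls, sim$reproducible, res$pi1_hat, sim$pi1)
#> calls: tp 2145 fp 105 fn 0 tn 610 | FDR 0.0467 power 1.0000 bias -0.0014
```

The estimated reproducible proportion (0.7486) recovers the planted 0.75;
every truly reproducible feature is found (power 1), and the realized
false discovery fraction among the 2250 calls (0.0467) sits below the
nominal $\alpha = 0.05$.

The full file-to-file pipeline on a synthetic 3-operator x 3-spike-in x
3-replicate fixture:

```r
d <- tempfile()
paths <- generate_fixture(d, n_features = 200, pi1 = 0.75, seed = 1)
out <- run_pipeline(paths$abundance, paths$metadata, file.path(d, "out"),
                    alpha = 0.05, c_s = 0.5, c_m = 0.5, seed = 42)
out$layers$replicate$summary
#>   threshold pct_reproducible_pairs pct_reproducible_metabolites
#> 1       0.7                 100.00                           75
#> 2       0.8                  11.11                           75
#> 3       0.9                   0.00                           75
```

Reading: every one of the 27 technical-replicate pairs has more than 70 %
of features called reproducible, and 75 % of features are reproducible in
more than 70/80/90 % of pairs — matching the planted 75 % reproducible
fraction. The output directory also contains the call matrix, per-margin
flag files, percent-scale histogram data, the reproducible-feature subset
matrix, and a log with provenance headers (package version, config hash,
master seed) on every file.

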