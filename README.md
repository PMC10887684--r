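# wextropy

Nonparametric estimation of **weighted extropy** for positive lifetime
data, with bandwidth selection theory, a reproducible Monte Carlo
bias/RMSE engine, and a reliability-ranking workflow for competing
systems.

Weighted extropy

$$J^w(X) = -\tfrac12 \int_0^\infty x\, f_X^2(x)\,dx$$

is the shift-dependent variant of extropy $J(X) = -\tfrac12\int f_X^2$:
the weight $x$ makes uncertainty carried by large lifetimes count for
more, which matters in survival and reliability settings where *when* a
failure happens is part of the information. $J^w$ is always nonpositive
and — because the weight cancels the Jacobian of a scale change — depends
on the *shape* of the lifetime distribution only. In reliability terms, a
system whose estimated $J^w$ is most negative carries the highest
uncertainty and is ranked least reliable.

The package provides three nonparametric estimators, all with
Sheather–Jones plug-in bandwidths by default:

| function | estimator |
|---|---|
| `we_lkde()` | log-kernel estimator $-\tfrac12\int x \hat f_{log}^2$, kernels placed in log space; preferred for skewed / heavy-tailed data |
| `we_kde()` | plain kernel estimator $-\tfrac12\int x \hat f_X^2$ |
| `we_empirical()` | spacings form $-\tfrac14\sum_i (X_{i+1:n}^2 - X_{i:n}^2)\hat f_X^2(X_{i:n})$ over the order statistics |

plus `we_parametric()` (maximum-likelihood plug-in, exponential or
lognormal), true values via `true_weighted_extropy()` /
`true_extropy()`, the L-KDE's asymptotic bias/variance/AMISE theory
(`we_lkde_bias_theory()`, `we_lkde_var_theory()`, `we_lkde_amise()`,
`amise_optimal_bandwidth()`), density estimators (`kde_fit()`,
`lkde_fit()`), and a Monte Carlo engine (`run_bias_rmse_table()`,
`run_moment_table()`, `sample_distribution()`).

## Worked example

Estimate the weighted extropy of a bundled synthetic lifetime sample
(drawn from an exponential model with rate 0.640, mimicking a life test
of electrical appliances):

```r
library(wextropy)
f <- system.file("extdata", "synthetic_appliance_cycles.txt",
                 package = "wextropy")
estimate_command(f, method = "lkde")
#> weighted extropy estimate
#>   file:   .../synthetic_appliance_cycles.txt
#>   method: lkde
#>   n:      60
#>   h:      0.6577916
#>   value:  -0.09531421
estimate_command(f, method = "parametric", family = "exponential")
#>   value:  -0.125
```

The parametric value is exactly $-0.125$ for *any* exponential fit
(scale invariance), so it anchors the nonparametric estimates. A small
simulation study comparing estimators on identical samples:

```r
run_bias_rmse_table(dist_spec("exponential"), c("lkde", "empirical"),
                    n_values = c(50, 200), reps = 200, seed = 42)
#>   distribution estimator   n       H abs_bias     rmse reps seed
#> 1  exponential      lkde  50 -0.1178 0.007156 0.017637  200   42
#> 2  exponential empirical  50 -0.1619 0.036892 0.044589  200   42
#> 3  exponential      lkde 200 -0.1190 0.006007 0.009511  200   42
#> 4  exponential empirical 200 -0.1348 0.009783 0.012342  200   42
```

`H` is the mean estimate across replicates (true value $-0.125$);
`abs_bias` and `rmse` quantify accuracy, and both shrink with sample
size. The L-KDE is the most accurate here, as expected on positive
skewed data.

Ranking competing systems (most negative = least reliable):

```r
paths <- system.file("extdata",
                     paste0("synthetic_system", 1:3, ".txt"),
                     package = "wextropy")
compare_command(paths, method = "lkde")
#> system comparison by weighted extropy (lkde)
#>                 system  n         h      value
#>  synthetic_system3.txt 12 0.2505985 -0.2986073
#>  synthetic_system2.txt 12 0.3449876 -0.2154747
#>  synthetic_system1.txt 12 0.4811398 -0.1346192
#> ranking (least reliable first): synthetic_system3.txt < ...
```

A thin command-line wrapper over these functions ships at
`inst/cli/wextropy.R` (`estimate`, `compare`, `simulate` subcommands).

## Documentation

The methods vignette (`vignettes/weighted-extropy.Rmd`) describes the
measure, the estimators and their numerical details, the simulation
design, and known limitations.
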