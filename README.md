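# l0adridge

Feature selection and prediction for high-dimensional generalized linear
models under an **L0 penalty** — the penalty that charges each nonzero
coefficient directly.  The package is aimed at biomarker discovery in
omics-scale regression problems (counts, binary or probability-valued
outcomes, continuous responses) where the number of features P vastly
exceeds the number of samples N and the goal is a *small, exact* set of
selected features rather than the long, shrunken lists that L1-type
penalties produce.

## The method

For a canonical-link GLM with cumulant function B, mean
μ = G(θ) = B′(θ), variance V(μ) = B″(θ) and linear predictor θ = Xβ,
the selection criterion is

    min over β of  Σᵢ [B(θᵢ) − Yᵢθᵢ]  +  (λ/2) |β|₀ ,

with |β|₀ the number of nonzero coefficients.  Exact L0 optimization is
combinatorial, so the package approximates it by **adaptive ridge**: writing
|β|₀ = Σⱼ βⱼ²/βⱼ² and freezing the denominator at the previous estimate
η = β_old makes each pass a convex ridge solve in which feature j carries
the penalty λ/(2ηⱼ²).  Small coefficients are penalized ever harder and
collapse to exact zero (zeros are absorbing; anything below ε = 1e−6 is
hard-thresholded), large ones escape shrinkage.  Each pass is one Newton
step against the working response Z = VXβ_old + (Y − μ):

    β_new = (D XᵗVX + λI)⁻¹ D XᵗZ ,          D = diag(η²),

and when N < P the identity
(DXᵗVX + λI_P)⁻¹DXᵗ = DXᵗ(VXDXᵗ + λI_N)⁻¹ replaces the P×P inverse by an
N×N one, so fits with P = 10⁴ features take well under a second.
λ is tuned by AIC (λ = 2), BIC (λ = log N) or k-fold cross-validation over
a log-spaced grid.  Linear, logistic and Poisson families are provided;
the logistic family accepts probability-valued responses in [0, 1].

See the methods vignette (`vignettes/l0-adaptive-ridge-methods.Rmd`) for
the full account: assumptions, numerical choices, tuning protocols, the
simulation harness and known limitations.

## A worked example

Poisson counts from 200 samples and 1000 features, only three features
and the intercept truly active:

```r
library(l0adridge)
set.seed(1)
x <- matrix(rnorm(200 * 1000), 200, 1000)
y <- rpois(200, exp(1 + 0.5 * x[, 1] + 0.5 * x[, 5] + 0.4 * x[, 10]))
fit <- l0adridge_bic(x, y, "poisson")   # lambda = log(200)
fit
#> L0 adaptive-ridge poisson fit (N = 200)
#>   lambda = 5.29832, selected 4 of 1001 coefficients
#>   11 iterations, converged; -loglik = -618.0886, objective = -607.4920
#>   support: (Intercept), V1, V5, V10
round(coef(fit)[fit$support], 4)
#> (Intercept)          V1          V5         V10
#>      1.0619      0.4398      0.4906      0.3713
```

The fit recovers exactly the four true coefficients — no false
discoveries among the 997 noise features — with estimates close to the
generating values (1, 0.5, 0.5, 0.4).  The `objective` field is the
penalized criterion −L + (λ/2)|β|₀ at the solution.

The replicated benchmark harness reports support-recovery quality over
many draws of such a design (PTM = fraction of replications recovering
the support exactly, ANSF = average selected-support size, FDR = average
false-discovery proportion):

```r
run_benchmark("poisson", n = 100, p = 100, n_reps = 20,
              tuning = "bic", seed = 1)
#> Replication summary over 20 replications
#>   rMSE 1.8969 (+-0.1983)   |bias| 0.2350 (+-0.1044)
#>   ANSF 4.000 (+-0.000)   PTM 100.0%   FDR 0.00%
```

(The rMSE here is on the count scale, whose Poisson noise floor is
√E[μ] ≈ 1.9 — a correctly selected 4-feature model sits at that floor.)

A thin command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "l0adridge.R", package = "l0adridge"))')" \
  fit --features X.csv --response y.csv --family poisson --criterion bic --out run
# writes run_coef.csv, run_summary.json, run.log
```

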