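# DMShrink

Bayesian Dirichlet-Multinomial regression with global-local shrinkage priors,
for finding sparse associations between sample-level covariates and taxa in
compositional count data (microbiome OTU/genus tables and similar).

## The problem and the model

A microbiome study yields a samples × taxa table of counts `y[i, j]` together
with covariates `X[i, l]` (clinical, environmental, sociodemographic). Counts
are compositional (only relative abundances are meaningful) and over-dispersed
relative to a multinomial. DMShrink models the counts as multinomial with a
Dirichlet-distributed probability vector, marginalized to the
Dirichlet-Multinomial (D-M) likelihood with shape vector `a[i, ]` per sample,

    y[i, ] ~ DirichletMultinomial(a[i, ]),    a[i, j] = g(eta[i, j]) > 0,
    eta[i, j] = beta0[j] + sum_l X[i, l] * beta[l, j],

where `g` is a configurable link (logit on the shape by default; `exp` and a
fixed-concentration `softmax` construction are alternatives). The p × J
coefficient matrix carries a global-local shrinkage prior

    beta[l, j] ~ N(0, lambda[l, j]^2 * tau[j]^2)

with three selectable hyperprior families: **horseshoe**
(`lambda ~ C+(0, tau)`, `tau ~ C+(0, 1)`, per-taxon `tau[j]`), **horseshoe+**
(an extra half-Cauchy layer on the local scale), and the classical
**Bayesian lasso** (`beta ~ N(0, lambda^2)`,
`lambda^2 ~ Exp(rate = tau^2/2)`, `tau^2 ~ InvGamma(xi/2, xi d^2/2)`, one
global rate `tau`). Posterior
sampling is by a built-in No-U-Turn Hamiltonian Monte Carlo sampler with
non-centered parameterizations for the heavy-tailed scale hierarchies.
Associations are selected either by 95% posterior credible intervals excluding
zero or by 2-means clustering of the posterior coefficient magnitudes, and
model fit is assessed by dissimilarity-based posterior predictive checks
(Bray-Curtis by default). A synthetic compositional data generator and a
replicated simulation harness reproduce the evaluation scheme the method was
studied under.

## Worked example

Simulate a small study with two truly associated (covariate, taxon) pairs,
fit the horseshoe model, and select associations:

```r
library(DMShrink)

cfg <- simConfig(n = 30, p = 3, q = 6, p0 = 1, q0 = 2,
                 signalLow = 2, signalHigh = 3,
                 depthSet = c(500, 1000), seed = 11)
sim <- simulateDMData(cfg)
sim
#> DMSimulation: n=30, p=3, q=6 (active 1x2), rho=0.40, psi=0.70
#>   non-zero coefficients: 2 of 18
#>   seed: 11

fit <- dmFit(sim, prior = horseshoePrior(), link = generatorLink(cfg),
             chains = 2, iter = 1000, warmup = 500, seed = 21)
fit
#> DMFit: horseshoe prior, softmax link
#>   3 covariates x 6 taxa (30 samples); 2 chains x 1000 iter (500 warmup)
#>   1000 retained draws; 0 divergent transition(s)
#>   |posterior mean beta| range: 0.0157 - 3.48

sel <- selectCredible(fit, level = 0.95)
sel
#> DMSelection (cri)
#>   level: 0.95
#>   selected: 2 of 18 associations

which(selected(sel)) == which(sim@activeMask)
#> [1] TRUE TRUE
```

The fitted object reports the prior, link, sampler schedule and divergent
transition count; `selectCredible()` returns the selected mask together with
the interval bounds and posterior means (`as.data.frame(sel)` tabulates
them). Here the two truly non-zero coefficients — and nothing else — are
selected. `generatorLink(cfg)` fits with the same fixed-concentration softmax
shape construction the generator uses, so estimates sit on the generating
scale; with real data you would normally keep the default logit link or pass
`dmLink("exp")`.

Convergence diagnostics and a posterior predictive check:

```r
head(dmDiagnostics(fit), 3)
#>   parameter     rhat ess_bulk ess_tail
#> 1  beta0[1] 1.004635 214.5140 368.4915
#> 2  beta0[2] 1.004302 211.6978 356.0177
#> 3  beta0[3] 1.004482 215.0963 293.1855

set.seed(1)
reps <- posteriorReplicates(fit, sim@design, sampleDepths(sim), nRep = 100)
ppcCompare(sim@experiment, reps)
#> DMPPC: bray_curtis with 100 replicates
#>   d(obs, rep): mean 0.5098; d(rep, rep): mean 0.5243
#>   overlap statistic P(dRep > dObs): 0.615
```

An overlap statistic near 0.5 says the observed table is exchangeable with
the model's posterior predictive replicates; values near 0 or 1 flag misfit.

A shell interface with `simulate`, `fit`, `select`, `ppc` and `evaluate`
subcommands (each writing a reproducibility manifest) ships in
`inst/scripts/dmshrink.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/dmshrink.R", package = "DMShrink"))')" \
    simulate --preset scheme1b --seed 1 --out sim_out
```

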