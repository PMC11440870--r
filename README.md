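# mrfmix

Hierarchical Bayesian restoration of low-count emission images (planar
gamma-camera / radionuclide data) with Markov random field priors.

Counts follow a Poisson likelihood `E[Y] = AX`, where `X` is the unknown
nonnegative activity image and `A` is a point-spread-function system
matrix.  The package samples the posterior of `X` under:

* a **homogeneous first-order MRF prior** with an absolute-value
  (Laplace, edge-preserving) or quadratic (Gaussian, smoothing)
  potential and a scale `tau` under the `1/tau` hyperprior, or
* a **locally adaptive mixture prior**: a latent binary label per pixel
  selects between a Laplace term (scale `tau_l`, high-contrast
  neighbourhoods) and a Gaussian term (scale `tau_g`, smooth
  neighbourhoods), with Gaussian hyperpriors on the scales (means 100
  and 10, sd 1), Bernoulli(`rho`) labels, and a Beta(0.5, 0.5)
  hyperprior on `rho`.

Inference is Metropolis-within-Gibbs with random-walk pixel sweeps,
proposal scales adapted toward the 0.234 acceptance optimum during
burn-in, exact Gibbs draws for the labels and for `rho` (conjugate
Beta), and Metropolis updates for the scales.  The hot loops are
compiled (Rcpp) and use R's RNG, so chains are bit-reproducible from a
seed.  See the `methods` vignette for the full model and the frozen
design choices.

## Worked example

The package generates its own ground truth: a 29 × 58 hard-edge phantom
(hot value 1099 on background 0), a smoothed variant (base 400/75,
Gaussian kernel sd 1.5), and a mouse-like phantom for classification
experiments.

```r
library(mrfmix)

truth <- reference_phantom(1)
sim <- simulate_observation(truth, kernel_sd = 1, seed = 101)

chain <- run_homogeneous(sim$y, sim$A, 29, 58, potential = "laplace",
                         config = mcmc_config(iterations = 5000,
                                              burn_in = 100, seed = 7))
chain
#> <mrf_chain> laplace model, 29 x 58 grid
#>   iterations: 5000  burn-in: 100
#>   mean pixel acceptance (post burn-in): 0.251
#>   posterior mean tau: 130.36

s <- posterior_summary(chain)      # mean + 95% credible intervals
mse(s$mean, truth)
#> [1] 2610.912
mse(as_image(sim$y, 29, 58), truth)   # raw observation, for comparison
#> [1] 21670.22
```

The mixture prior reduces the error further and returns a per-pixel
label map:

```r
mix <- run_mixture(sim$y, sim$A, 29, 58,
                   config = mcmc_config(iterations = 5000, burn_in = 100,
                                        store_theta = TRUE, seed = 7))
glance(mix)
#> # A tibble: 1 x 7
#>   model   iterations burn_in accept_pixel tau_l tau_g   rho
#>   <chr>        <int>   <int>        <dbl> <dbl> <dbl> <dbl>
#> 1 mixture       5000     100        0.203  112. 0.385 0.320

mse(posterior_mean_image(mix), truth)
#> [1] 2237.941

classify_theta(mix)    # binary high-contrast map (524 pixels flagged)
```

Evaluation helpers include masked MSE over eight fixed regions of
interest (`make_roi_masks()`), MSE sensitivity sweeps over the prior
scale (`tau_sweep()`, with `autoplot()`), row/column profiles with
credible bands (`extract_profile()`, `plot_profile()`), and a k-means
intensity baseline for the label map (`kmeans_baseline()`).

## Command line

`inst/exec/mrfmix` wraps `cli_main()` with subcommands `simulate`,
`fit`, `sweep`, `evaluate`, and `classify`.  Every run writes
`run_log.txt` with the package version, configuration echo, and seed.

```sh
mrfmix simulate --phantom paper1 --seed 1 --out sim/
mrfmix fit --observed sim/observed.csv --model mixture --out chain/
mrfmix evaluate --chain chain/ --truth sim/truth.csv --out eval/
```

Chain archives are plain-text directories (`config.yaml`, `traces.csv`,
`x_mean.csv`, and `theta_freq.csv` for mixture chains); any archive is
regenerable from its embedded config and seed.  Matrices are exchanged
as CSV (canonical), 16-bit TIFF, or plain PGM; sparse system matrices as
`i j value` text triplets.

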