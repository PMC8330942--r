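# tfmodules

Bayesian inference of combinatorial transcription factor (TF) modules from
multi-TF ChIP-seq read counts, and prediction of active regulatory
elements from the inferred module posteriors.

## The problem

Transcription factors act in modules: a master factor recruits mediators,
and the combination — not any single factor — activates an enhancer or
promoter. Inferring modules by intersecting per-TF peak calls
systematically loses mediators, whose binding is weak and whose peaks are
not called. `tfmodules` works on the read counts directly. Given ChIP-seq
profiles of T TFs and a matched input control, counted over fixed 500-bp
bins across K candidate regions, it infers for every region a posterior
distribution over TF modules and, from those posteriors, predicts which
regions are active.

## The model

Observed counts decompose per region k and TF t as

    Y[k,t] = b(c_k,t) X[k,t] + (1 - b(c_k,t)) I[k,t] + N[k,t]

where `c_k` indexes a row of the binary module catalog **B** (row 0 is
background), bound counts follow a discrete Power-Law(X_min = 10, γ_t),
background counts a Gamma(mean α_t, shape β_t) fitted to the input
profile, and N is a Gaussian residual with an inverse-Gamma prior on its
variance. Counts below X_min are background with probability one. In
promoter mode a TSS-distance factor (exponential decay λ_t for bound,
uniform Δd/d_p = 500/20000 for background) multiplies the likelihood; in
enhancer mode it is dropped.

A Gibbs sampler alternates (i) weight-based *read tossing* — each TF's
reads are re-assigned to its bound and background regions by a multinomial
draw proportional to residual x emission x distance weights, with every
bound region floored at X_min reads — (ii) a conjugate inverse-Gamma draw
of the residual variance, and (iii) a per-region categorical draw of the
module index over all catalog rows. Post-burn-in sampling frequencies form
the posterior matrix **Ĉ**; its per-region modes (frequency ≥ τ = 0.1) are
the region's modules and its column sums the genome-wide module
abundances. An elastic-net logistic classifier (penalty
λ_p[(1−α)/2·Σβ² + α·Σ|β|]) maps rows of **Ĉ** to activity labels derived
from CAGE-style TPM measurements, and hypergeometric / linear-model
utilities quantify enrichment of predictions in marker peaks, chromatin
loops and time-course expression clusters.

See the methods vignette (`vignettes/tf-module-inference.Rmd`) for the
fitting procedures, design decisions and simulator details.

## Worked example

Simulate the 4-TF benchmark scenario with known ground truth, fit the
emission models from the data, sample modules and score the recovery of
per-TF binding events:

```r
library(tfmodules)

spec <- simulationSpec(case = 1, nRegions = 5000, seed = 1)
sim  <- simulateCounts(spec)

models  <- fitTFModels(sim$counts)
catalog <- enumerateModules(tfNames(sim$counts))
post    <- runGibbs(sim$counts, models, catalog,
                    samplerConfig(burnIn = 100, nSamples = 200, seed = 2))
post
#> ModulePosterior: 5000 regions x 16 modules (incl. background)
#>   top modules by abundance:
#>     background                     0.294
#>     TF1+TF2+TF3+TF4                0.107
#>     TF1+TF3+TF4                    0.061
#>     TF1+TF2+TF4                    0.056
#>     TF3+TF4                        0.051

sets  <- assignModules(post, tau = 0.1)
score <- scoreBindingRecovery(sim$truth, sets, catalog,
                              boundCounts = sim$boundCounts)
#> overall  precision 0.977  recall 0.960  F 0.969
#> weak     precision 0.993  recall 0.959  F 0.976  (3392 regions)
```

The posterior recovers the simulated background fraction (0.294 vs the
generating 0.29) and identifies per-TF binding events with F-measure 0.97;
on the hard subset of regions carrying at least one *weak* binding event
(true bound count in [10, 30], i.e. hugging the X_min floor) the F-measure
stays above 0.95, which is the point of modeling the background with an
input-fitted Gamma instead of thresholding peaks.

Fitted parameters for this run (true exponents 1.6/1.8/2.0/2.5, the weak
TF4 truncated near the floor; true background mean ~3):

```r
models
#> TFModelSet (enhancer mode):
#>   tf    gamma xmin alphaMean betaShape lambda totalReads
#>  TF1 1.550124   10  4.318695  4.264697     NA    2456490
#>  TF2 1.730079   10  4.169230  3.303531     NA     779821
#>  TF3 1.902913   10  4.467203  3.546505     NA     213414
#>  TF4 2.973140   10  4.138993  2.507049     NA      48466
```

A command-line wrapper with `simulate`, `fit`, `search`, `sample`,
`classify`, `enrich` and `run-all` subcommands lives in
`inst/scripts/tfmodules-cli.R`, and `runPipeline()` orchestrates the same
stages from a key=value configuration file, writing TSV artifacts and a
JSON run manifest.

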