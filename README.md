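# sloppySpikes

Sloppiness analysis of pairwise maximum-entropy models of cortical
neuronal ensembles, for systems neuroscientists studying how collective
spiking statistics, cortical state, sensory responses and functional
network structure hang together.

## What it computes

Spiking activity of an ensemble of N single units is binarized in 10-ms
bins (σᵢ = ±1) and modelled, epoch by epoch (100 s), with the pairwise
maximum-entropy (Ising) distribution

    P(σ) = exp(−E(σ)) / Z,    E(σ) = −Σᵢ hᵢσᵢ − ½ Σᵢⱼ Jᵢⱼσᵢσⱼ,

fitted by gradient descent on the moment discrepancies (learning rate
0.1, tolerance 0.005). Model sloppiness is quantified by the Fisher
information matrix — for this family, the covariance of the observable
vector x = [σ₁…σ_N, σ₁σ₂, …] under the model — whose leading
eigenvectors are the stiff parameter combinations. On top of this core
the package provides:

* goodness-of-fit: Jensen–Shannon divergence vs an independent model and
  the Kullback–Leibler ratio R = (D₁ − D₂)/D₁;
* parameter-trajectory projections onto FIM eigenvectors and the
  projection-variance-by-rank profile, with stationary surrogates
  (repeated refits of one model) as the estimation-error control;
* per-parameter sensitivities s (contribution to the leading
  eigenvector, plus an eigenvalue-weighted variant), aggregated over
  ensembles to all Npop units and pairs, median-split into stiff and
  sloppy classes;
* cortical state via silence density (fraction of empty 20-ms bins),
  its co-variation with pattern statistics, and state–observable
  correlations rcs;
* stimulus responses via the modulation index
  MI = |r_stim − r_spon|/(r_stim + r_spon) and its relation to
  sensitivity and state;
* functional-network topology: a Bonferroni-thresholded significant-
  correlation graph, betweenness centrality, neuron-to-population
  coupling, and ROC/AUC class separation with permutation tests;
* a synthetic spike-data generator (correlated high-rate core, drifting
  low-rate periphery, slow state fluctuations, click-evoked
  periphery-dominated responses) with full ground truth.

## Worked example

```r
library(sloppySpikes)

cfg <- runConfig(Q = 6, generator = generatorConfig(
  nSingle = 40, nMulti = 10, duration = 1200))
res <- runPipeline(cfg, seed = 1)

mean(res$gof$kl_ratio, na.rm = TRUE)
#> [1] 0.4336668
res$stateDivergence$rc          # pattern-divergence vs state-change corr.
#> [1] 0.8158579
res$miSensitivity$rc            # responsiveness vs sensitivity
#> [1] -0.8919259
res$classComparison$auc
#>   quantity       AUC           p n_sloppy n_stiff
#> 1     rate 1.0000000 0.000999001       19      18
#> 2       BC 0.5000000 1.000000000       19      18
#> 3 coupling 0.9707602 0.000999001       19      18
```

Reading: the pairwise model removes ~43% of the independent model's
divergence from the data; epochs whose silence density differs more have
more dissimilar pattern statistics (r = 0.82); the most stimulus-
responsive units carry the least-sensitive (sloppy) parameters
(r = −0.89); and firing rate separates stiff from sloppy units
essentially perfectly (AUC = 1), as does population coupling, while this
small run's correlation graph is too dense for centrality to
discriminate (AUC = 0.5). `writeArtifacts(res, dir)` exports the CSV/JSON
artifact set, and `runStage()` drives the simulate → analyse → report
stages against a run directory.

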