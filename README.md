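# camsecr

Bayesian spatially explicit capture-recapture (SECR) for camera-trap
surveys of individually identifiable animals, with the surrounding survey
workflow: photo deduplication, capture-array construction, design
validation, habitat-masked state spaces, convergence and adequacy
diagnostics, buffer-sensitivity scans, and relative-abundance indices for
the unmarked prey community. Everything is testable end to end against
bundled synthetic-data generators that reproduce a canonical 13-station,
63-night montane leopard survey design.

## Who it is for

Field ecologists and quantitative conservation biologists estimating the
density of leopards, tigers, jaguars or any species recognisable from
natural markings, from single-session paired-camera surveys — especially
where density per unit habitat (not just abundance) is the management
quantity, e.g. when trophy-hunting quotas or population comparisons are
at stake.

## The model

Each of M = n + augmentation individuals (observed plus all-zero
pseudo-individuals) carries an inclusion flag `z ~ Bernoulli(psi)` and a
latent activity centre `s` uniform over a habitat-masked mesh of the
buffered trap rectangle. Detection is a half-normal encounter rate with a
trap-specific behavioural response (model Mb),

    lambda(d, C) = lambda0 * exp(-d^2 / (2 sigma^2)) * exp(b1 * C),

with Bernoulli captures per trap-night, `p = 1 - exp(-lambda)`; `C`
flags a prior capture of that animal in that trap. Density is
`D = 100 * Ns / A` animals per 100 km², with `Ns` the realised number of
included individuals and `A` the suitable area. A compiled
Metropolis-within-Gibbs sampler (conjugate psi, exact-Gibbs z, mesh-walk
centre moves, adaptive random-walk detection parameters) returns the
joint posterior; `summarize_posterior()` reports means, SDs, 95% HPD
intervals and Geweke z scores in the conventional order D, lambda0,
sigma, b1, psi, Ns.

## Worked example

Simulate the canonical survey bundle, fit at the reduced test profile
(25,000 iterations, 2 km mesh, ~3 s), and inspect the posterior:

```r
library(camsecr)
bundle <- canonical_fixture(seed = 1403, spacing_km = 2)
fit <- secr_mcmc(bundle$sim$arr, bundle$statespace,
                 config = mcmc_config(iterations = 25000, burn_in = 5000,
                                      seed = 1))
summarize_posterior(fit)
#>   parameter    mean     sd hpd_lower hpd_upper geweke_z
#> 1         D  10.379  3.037     5.104    16.493   -0.202
#> 2   lambda0   0.023  0.007     0.010     0.036    1.000
#> 3     sigma   2.012  0.293     1.499     2.588   -0.496
#> 4        b1   1.329  0.312     0.722     1.959   -0.788
#> 5       psi   0.566  0.166     0.276     0.902   -0.175
#> 6        Ns 219.624 64.273   108.000   349.000   -0.202
```

The generating truth was D = 10.73 per 100 km², lambda0 = 0.029,
sigma = 1.69 km, b1 = 1.10: the density row says this survey's data
support 10.4 animals per 100 km² with a 95% HPD of roughly 5-16, all
Geweke |z| < 1.6 (chains long enough), and a positive behavioural
response (animals re-encounter favoured trails). Model adequacy and prey
abundance:

```r
bayesian_pvalue(fit)
#> Bayesian p-value = 0.499 (freeman_tukey, 2000 draws)

rai_table(bundle$prey_photos, camera_days = trap_nights(bundle$traps))
#>         species n_events capture_frequency rai detected
#> 1      bushbuck       13              1.59   1     TRUE
#> 2        baboon       10              1.22   0     TRUE
#> 3     porcupine        8              0.98   5     TRUE
#> 4          kudu        7              0.85  27     TRUE
#> 5 common_duiker        3              0.37  17     TRUE
```

A p-value near 0.5 indicates an adequate model; capture frequency is
independent photos per 100 camera days and `rai` is whole days of effort
until the species' first photograph (0 = day one).

A command-line wrapper ships in `inst/scripts/camsecr` with subcommands
`simulate`, `fit`, `summarize`, `diagnose`, `buffer-scan`, `rai` and
`design-check`.

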