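# Small shared fit used by several blocks (reduced design for speed).
local_small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- simulation_truth(D = 25, lambda0 = 0.1, sigma = 1.5, b1 = 0.8,
                                n_stations = 9, n_occasions = 20,
                                buffer_km = 8, spacing_km = 2)
      traps <- grid_traps(3, 3, spacing = 2, K = 20)
      ss <- build_statespace(traps, buffer_km = 8, spacing_km = 2)
      pop <- simulate_population(ss, truth, seed = 61)
      sim <- simulate_capture_histories(pop, traps, truth, ss, seed = 62)
      cfg <- mcmc_config(iterations = 6000, burn_in = 1000,
                         augmentation = 150, seed = 63)
      cache <<- list(fit = secr_mcmc(sim$arr, ss, config = cfg),
                     sim = sim, ss = ss, truth = truth, cfg = cfg,
                     traps = traps)
    }
    cache
  }
})

test_that("hpd returns the shortest interval at the requested mass", {
  expect_error(hpd(rnorm(500), prob = 1.2), "prob")
  const <- rep(3.5, 1000)
  expect_equal(unname(hpd(const)), c(3.5, 3.5))

  set.seed(5)
  u <- runif(40000)
  h <- hpd(u, 0.95)
  expect_equal(h[["upper"]] - h[["lower"]], 0.95, tolerance = 0.02)

  x <- rnorm(40000)
  h2 <- hpd(x, 0.95)
  q <- quantile(x, c(0.025, 0.975))
  expect_equal(h2[["lower"]], unname(q[1]), tolerance = 0.08)
  expect_equal(h2[["upper"]], unname(q[2]), tolerance = 0.08)

  expect_warning(hpd(rnorm(100), 0.95), "short")
})

test_that("density derivation scales population size by suitable area", {
  fake <- structure(list(draws = data.frame(Ns = rep(100, 5)),
                         suitable_area = 1000), class = "camsecr_fit")
  expect_equal(derive_density(fake), rep(10, 5))
  fake$draws <- data.frame(Ns = c(100, 110))
  expect_equal(mean(derive_density(fake)), 10.5)
  fake$suitable_area <- 0
  expect_error(derive_density(fake), "positive")
})

test_that("sampler chains respect the hard latent-state bounds", {
  ctx <- local_small_fit()
  fit <- ctx$fit
  expect_true(all(fit$draws$Ns >= fit$n_obs))   # observed stay included
  expect_true(all(fit$draws$Ns <= fit$M))
  expect_true(all(fit$draws$D > 0))
  expect_equal(fit$draws$D,
               fit$draws$Ns / fit$suitable_area * 100)  # identity per draw
  # augmentation identity: E[Ns] = E[psi] * M for a well-mixed chain
  expect_equal(mean(fit$draws$Ns), mean(fit$draws$psi) * fit$M,
               tolerance = 3 * mcse(fit$draws$Ns) / mean(fit$draws$Ns) + 0.02)
})

test_that("a seeded run is exactly reproducible and step 0 freezes a chain", {
  ctx <- local_small_fit()
  fit2 <- secr_mcmc(ctx$sim$arr, ctx$ss, config = ctx$cfg)
  expect_identical(ctx$fit$draws, fit2$draws)

  cfg0 <- mcmc_config(iterations = 500, burn_in = 100, augmentation = 30,
                      seed = 64, step_lambda0 = 0)
  fit0 <- secr_mcmc(ctx$sim$arr, ctx$ss, config = cfg0)
  expect_equal(length(unique(fit0$draws$lambda0)), 1)  # frozen at init
  expect_gt(length(unique(fit0$draws$sigma)), 1)
})

test_that("posterior summaries recover known moments and report order", {
  n <- 5000
  set.seed(8)
  mu <- 3; sig <- 0.7
  fake <- structure(list(
    draws = data.frame(lambda0 = rnorm(n, mu, sig),
                       sigma = rnorm(n, 1, 0.1), b1 = rnorm(n),
                       psi = runif(n), Ns = rep(50, n),
                       D = rep(5, n)),
    suitable_area = 1000), class = "camsecr_fit")
  s <- suppressWarnings(summarize_posterior(fake))
  expect_equal(s$parameter, c("D", "lambda0", "sigma", "b1", "psi", "Ns"))
  row <- s[s$parameter == "lambda0", ]
  expect_equal(row$mean, mu, tolerance = 3 * sig / sqrt(n))
  expect_equal(row$sd, sig, tolerance = 0.05)
  # degenerate chain: zero SD, zero-width HPD
  rowNs <- s[s$parameter == "Ns", ]
  expect_equal(rowNs$sd, 0)
  expect_equal(rowNs$hpd_lower, rowNs$hpd_upper)
})

test_that("buffer scan emits one row per cell with shared per-buffer seeds", {
  ctx <- local_small_fit()
  cfg <- mcmc_config(iterations = 1500, burn_in = 500, augmentation = 50,
                     seed = 7)
  one <- buffer_sensitivity(ctx$sim$arr, buffers = 6, spacing_km = 2,
                            config = cfg)
  expect_equal(nrow(one), 1)
  expect_false(one$masked)

  msk <- mask_circles(cbind(20, 20), 3)
  two <- buffer_sensitivity(ctx$sim$arr, buffers = c(6, 8), spacing_km = 2,
                            mask = msk, config = cfg)
  expect_equal(nrow(two), 4)
  expect_equal(two$masked, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(two$seed[1], two$seed[2])      # common random numbers per buffer
  expect_true(all(diff(two$buffer_km) >= 0))
  expect_true(all(two$sd_D > 0))
})
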