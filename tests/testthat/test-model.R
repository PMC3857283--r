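test_that("half-normal encounter function behaves as specified", {
  p <- secr_params(lambda0 = 0.029, sigma = 1.69, b1 = 1.10, psi = 0.54)
  expect_equal(encounter_rate(p, 0, 0), 0.029)
  expect_equal(encounter_rate(p, 1e6, 0), 0)
  expect_error(encounter_rate(p, -1), "non-negative")

  p0 <- secr_params(0.5, 1, b1 = 0)
  expect_equal(encounter_rate(p0, 1.3, 0), encounter_rate(p0, 1.3, 1))
  expect_equal(encounter_probability(p0, 1.3, 0),
               encounter_probability(p0, 1.3, 1))

  # pre-encounter probability at the canonical baseline rate
  expect_equal(signif(encounter_probability(p, 0, 0), 3), 0.0286)
  # post-encounter probability at d = 0: direct evaluation
  expect_equal(encounter_probability(p, 0, 1),
               1 - exp(-0.029 * exp(1.10)), tolerance = 1e-12)
  expect_equal(round(encounter_probability(p, 0, 1), 4), 0.0834)

  # vanishing baseline rate drives p to zero
  tiny <- secr_params(1e-12, 1.69)
  expect_lt(encounter_probability(tiny, 0, 0), 1e-11)
})

test_that("encounter probability is monotone in d, lambda0 and b1", {
  d <- seq(0, 10, by = 0.5)
  p <- secr_params(0.1, 1.5, b1 = 0.7)
  pr <- encounter_probability(p, d, 0)
  expect_true(all(diff(pr) <= 0))
  expect_true(all(pr >= 0 & pr < 1))
  for (l0 in c(0.01, 0.05, 0.2)) {
    p_lo <- secr_params(l0, 1.5, 0.7)
    p_hi <- secr_params(l0 * 2, 1.5, 0.7)
    expect_true(all(encounter_probability(p_hi, d, 0) >=
                      encounter_probability(p_lo, d, 0)))
    expect_true(all(encounter_probability(p_lo, d, 1) >=
                      encounter_probability(p_lo, d, 0)))
  }
})

test_that("sigma <-> decay-coefficient conversions invert under both conventions", {
  for (conv in c("half-normal", "reciprocal")) {
    s <- c(0.5, 1.69, 3)
    expect_equal(b_to_sigma(sigma_to_b(s, conv), conv), s)
  }
  expect_equal(sigma_to_b(2), 1 / 8)        # lambda0 * exp(-d^2/(2 s^2))
  expect_equal(sigma_to_b(2, "reciprocal"), 0.5)
})

test_that("complete-data likelihood matches the elementwise oracle", {
  tr <- toy_traps(J = 2, K = 3)
  ss <- build_statespace(tr, buffer_km = 2, spacing_km = 1)
  p <- secr_params(0.3, 1.2, b1 = 0.5, psi = 0.6)

  # single capture: log p at the centre-trap distance
  y <- array(0L, c(1, 2, 3)); y[1, 1, 1] <- 1L
  arr <- array_from_y(y, tr)
  g <- which(ss$points$x == 0 & ss$points$y == 0)
  lat <- list(z = 1L, centres = g)
  C <- prior_capture_indicator(arr)
  ll <- complete_data_loglik(p, lat, arr, C, ss)
  expect_equal(ll, loglik_oracle(p, lat, arr, C, ss), tolerance = 1e-10)

  # random tiny instances, including augmented all-zero individuals
  set.seed(77)
  for (rep in 1:10) {
    y <- array(rbinom(2 * 2 * 3, 1, 0.4), c(2, 2, 3))
    if (any(apply(y, 1, sum) == 0)) next
    arr <- array_from_y(y, tr)
    C <- prior_capture_indicator(arr)
    M <- 4
    lat <- list(z = c(1L, 1L, rbinom(2, 1, 0.5)),
                centres = sample(which(ss$suitable), M, replace = TRUE))
    expect_equal(complete_data_loglik(p, lat, arr, C, ss),
                 loglik_oracle(p, lat, arr, C, ss), tolerance = 1e-10)
  }

  # relabelling individuals and traps leaves the likelihood unchanged
  y <- array(rbinom(2 * 2 * 3, 1, 0.5), c(2, 2, 3))
  y[1, 1, 1] <- 1L; y[2, 2, 2] <- 1L
  arr <- array_from_y(y, tr, ids = c("AF1", "AF2"))
  arr_rev <- array_from_y(y[2:1, c(2, 1), , drop = FALSE],
                          trap_stations(c("T2", "T1"),
                                        tr$stations$x[c(2, 1)],
                                        tr$stations$y[c(2, 1)],
                                        3,
                                        active = tr$active[c(2, 1), ]),
                          ids = c("AF1", "AF2"))
  lat2 <- list(z = c(1L, 1L), centres = c(5L, 9L))
  # relabelled array: swap centre assignment to follow the id sort
  expect_equal(
    complete_data_loglik(p, lat2, arr, prior_capture_indicator(arr), ss),
    complete_data_loglik(p, list(z = c(1L, 1L), centres = c(9L, 5L)),
                         arr_rev, prior_capture_indicator(arr_rev), ss),
    tolerance = 1e-10)

  # observed individual excluded from the population is signalled
  expect_warning(
    llz <- complete_data_loglik(p, list(z = c(0L, 1L), centres = c(5L, 9L)),
                                arr, prior_capture_indicator(arr), ss),
    "z = 0")
  expect_identical(llz, -Inf)
})

test_that("exact marginal likelihood agrees with nested-loop enumeration", {
  tr <- toy_traps(J = 1, K = 2)
  ss <- build_statespace(tr, buffer_km = 1, spacing_km = 1)  # 3x3 mesh
  ss$suitable[5:9] <- FALSE  # G = 4
  p <- secr_params(0.4, 1, b1 = 0.3, psi = 0.5)

  y <- array(0L, c(1, 1, 2)); y[1, 1, 1] <- 1L
  arr <- array_from_y(y, tr)
  C <- prior_capture_indicator(arr)
  M <- 2
  # independent oracle: loop over every z vector and centre tuple
  suit <- which(ss$suitable)
  G <- length(suit)
  total <- -Inf
  for (z1 in 0:1) for (z2 in 0:1) {
    lw <- (z1 + z2) * log(p$psi) + (2 - z1 - z2) * log(1 - p$psi)
    for (g1 in suit) for (g2 in suit) {
      # the enumeration legitimately visits z = 0 for the observed
      # individual; the likelihood is zero there and warns
      ll <- suppressWarnings(
        complete_data_loglik(p, list(z = c(z1, z2), centres = c(g1, g2)),
                             arr, C, ss))
      contrib <- lw + ll - 2 * log(G)
      if (is.finite(contrib)) {
        m <- max(total, contrib)
        total <- m + log(exp(total - m) + exp(contrib - m))
      }
    }
  }
  expect_equal(marginal_loglik_bruteforce(p, arr, ss, M = 2), total,
               tolerance = 1e-10)
  expect_error(marginal_loglik_bruteforce(p, arr, ss, M = 40), "too large")
})

test_that("single-point marginal reduces to its closed form and psi -> 1 limit", {
  tr <- toy_traps(J = 1, K = 3)
  ss <- build_statespace(tr, buffer_km = 1, spacing_km = 1)
  ss$suitable[-5] <- FALSE  # exactly the central point (the trap site)
  y <- array(0L, c(1, 1, 3)); y[1, 1, 2] <- 1L
  arr <- array_from_y(y, tr)
  C <- prior_capture_indicator(arr)

  p <- secr_params(0.4, 1, b1 = 0.3, psi = 0.7)
  lat <- list(z = 1L, centres = which(ss$suitable))
  Ly <- exp(complete_data_loglik(p, lat, arr, C, ss))
  # M = 1, one mesh point: psi * L(y | centre) (+ (1-psi) * 0, y nonzero)
  expect_equal(marginal_loglik_bruteforce(p, arr, ss, M = 1),
               log(p$psi * Ly), tolerance = 1e-10)

  # psi -> 1: marginal approaches the forced complete-data value
  p_hi <- secr_params(0.4, 1, b1 = 0.3, psi = 1 - 1e-12)
  expect_equal(marginal_loglik_bruteforce(p_hi, arr, ss, M = 1),
               complete_data_loglik(p_hi, lat, arr, C, ss),
               tolerance = 1e-8)
  # and increases monotonically toward it in psi
  psis <- c(0.2, 0.5, 0.8, 0.99)
  vals <- vapply(psis, function(ps) {
    marginal_loglik_bruteforce(secr_params(0.4, 1, 0.3, ps), arr, ss, 1)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})
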