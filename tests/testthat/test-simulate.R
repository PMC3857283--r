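test_that("generated trap arrays satisfy the survey-design constraints", {
  tr <- make_trap_array(seed = 5)
  expect_equal(nrow(tr$stations), 13)
  rep <- validate_design(tr, 1.7, 3.5)
  expect_true(rep$pass)
  expect_true(all(rep$nn_distances >= 1.7 & rep$nn_distances <= 3.5))

  tr2 <- make_trap_array(n_stations = 2, seed = 5)
  expect_equal(nrow(tr2$stations), 2)
  d <- dist(tr2$stations[, c("x", "y")])[1]
  expect_true(d >= 1.7 && d <= 3.5)

  again <- make_trap_array(seed = 5)
  expect_identical(tr$stations, again$stations)  # reproducible
})

test_that("population simulation follows the Poisson-density model", {
  tr <- grid_traps(2, 2, spacing = 2, K = 5)
  ss <- build_statespace(tr, buffer_km = 5, spacing_km = 1)
  truth <- simulation_truth(D = 10.73, spacing_km = 1, buffer_km = 5)
  expected <- 10.73 / 100 * suitable_area(ss)

  set.seed(9)
  Ns <- replicate(300, simulate_population(ss, truth)$N)
  expect_equal(mean(Ns), expected, tolerance = 3 * sqrt(expected / 300) /
                 expected)

  expect_equal(simulate_population(ss, simulation_truth(D = 0), seed = 1)$N, 0)

  fixed <- simulate_population(ss, simulation_truth(fixed_N = 42), seed = 1)
  expect_equal(fixed$N, 42)

  ssm <- apply_habitat_mask(ss, mask_circles(cbind(0, 0), 2))
  pop <- simulate_population(ssm, simulation_truth(D = 400), seed = 2)
  expect_true(all(pop$x^2 + pop$y^2 > 4))  # no centres in masked habitat
})

test_that("capture histories saturate, and are Binomial when b1 = 0", {
  tr <- toy_traps(J = 1, K = 20)
  ss <- build_statespace(tr, buffer_km = 2, spacing_km = 1)
  truth_hot <- simulation_truth(lambda0 = 50, sigma = 1, b1 = 0,
                                fixed_N = 1)
  pop <- list(N = 1, centres = which(ss$points$x == 0 & ss$points$y == 0),
              x = 0, y = 0)
  sim <- simulate_capture_histories(pop, tr, truth_hot, ss, seed = 3)
  expect_equal(sum(sim$arr$y), 20)  # p ~ 1: captured every occasion

  # b1 = 0: per-trap counts are Binomial(K, p(d))
  truth0 <- simulation_truth(lambda0 = 0.15, sigma = 2, b1 = 0, fixed_N = 1)
  d <- 1.5
  p_theory <- encounter_probability(secr_params(0.15, 2), d, 0)
  set.seed(21)
  counts <- replicate(150, {
    popd <- list(N = 1, centres = 1L, x = d, y = 0)
    tryCatch(sum(simulate_capture_histories(popd, tr, truth0, ss)$arr$y),
             error = function(e) 0)  # surveys with zero captures
  })
  expect_equal(mean(counts), 20 * p_theory,
               tolerance = 3 * sqrt(20 * p_theory * (1 - p_theory) / 150) /
                 (20 * p_theory))

  # behavioural response raises post-capture rates: more total captures
  truth_b <- simulation_truth(lambda0 = 0.15, sigma = 2, b1 = 1.5,
                              fixed_N = 1)
  set.seed(22)
  counts_b <- replicate(150, {
    popd <- list(N = 1, centres = 1L, x = d, y = 0)
    tryCatch(sum(simulate_capture_histories(popd, tr, truth_b, ss)$arr$y),
             error = function(e) 0)
  })
  expect_gt(mean(counts_b), mean(counts))
})

test_that("photo streams respect rates and bursts collapse under filtering", {
  tr <- grid_traps(2, 2, spacing = 2, K = 50)
  empty <- simulate_photo_stream(c(ghost = 0), tr, seed = 4)
  expect_equal(nrow(empty), 0)

  set.seed(5)
  r <- 3  # events per 100 camera days; 4 stations x 50 days = 200 days
  n <- replicate(200, nrow(simulate_photo_stream(c(kudu = r), tr)))
  lambda <- r / 100 * 4 * 50
  expect_equal(mean(n), lambda, tolerance = 3 * sqrt(lambda / 200) / lambda)

  burst <- simulate_photo_stream(c(kudu = 4), tr, clustering = 3, seed = 6)
  ev <- independent_events(burst)
  base <- simulate_photo_stream(c(kudu = 4), tr, clustering = 0, seed = 6)
  expect_equal(nrow(ev), nrow(base))  # each burst collapses to one event
})

test_that("the canonical bundle matches the printed survey accounting", {
  bundle <- canonical_fixture(seed = 2001, spacing_km = 2)
  expect_equal(trap_nights(bundle$traps), 819L)
  expect_equal(nrow(bundle$table1), 14)
  expect_equal(sum(bundle$table1$age_class == "adult"), 10)
  expect_equal(sum(bundle$table1$total_captures), 69)  # 55 adult + 14 juvenile

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture(bundle, d1)
  write_fixture(canonical_fixture(seed = 2001, spacing_km = 2), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # the written bundle re-reads into a working pipeline
  tr <- read_deployment(file.path(d1, "deployment.csv"))
  ev <- read_captures(file.path(d1, "captures.csv"), tr)
  arr <- build_capture_array(ev, tr)
  expect_gt(dim(arr$y)[1], 0)
  ss <- read_statespace(file.path(d1, "statespace.csv"))
  expect_equal(suitable_area(ss), suitable_area(bundle$statespace))
})

test_that("deployment files round-trip including partial activity", {
  act <- matrix(1L, 3, 6); act[2, 4:6] <- 0L
  tr <- trap_stations(c("A", "B", "C"), c(0, 2, 4), c(0, 1, 0), 6,
                      active = act)
  f <- withr::local_tempfile(fileext = ".csv")
  write_deployment(tr, f)
  tr2 <- read_deployment(f)
  expect_equal(tr2$stations, tr$stations)
  expect_equal(unname(tr2$active), unname(tr$active))
  expect_equal(trap_nights(tr2), sum(act))
})
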