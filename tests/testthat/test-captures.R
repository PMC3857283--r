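test_that("capture files parse in both dialects and flag bad input", {
  tr <- toy_traps()
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("LOC_ID,ANIMAL_ID,SO", "T1,AF1,1", "T2,AF1,3", "T1,AM1,2"), f)
  ev <- read_captures(f, tr)
  expect_s3_class(ev, "camsecr_events")
  expect_equal(nrow(ev), 3)

  writeLines(c("LOC_ID,ANIMAL_ID,SO", "T9,AF1,1"), f)
  expect_error(read_captures(f, tr), "T9")

  writeLines(c("LOC_ID,ANIMAL_ID,SO", "T1,AF1,1", "T1,,2"), f)
  expect_error(read_captures(f), "line\\(s\\): 3")

  writeLines(c("station,datetime,species,individual,flank",
               "T1,2008-03-01 20:00,leopard,AF1,left",
               "T1,2008-03-01 20:01,leopard,AF1,right"), f)
  ph <- read_captures(f, tr)
  expect_s3_class(ph, "camsecr_photos")
  expect_equal(nrow(ph), 2)

  writeLines(c("foo,bar", "1,2"), f)
  expect_error(read_captures(f), "format error")
})

test_that("flank photos collapse to station-day events and dedupe is idempotent", {
  ph <- photo_records(
    station_id = c("T1", "T1", "T1", "T2"),
    timestamp = as.POSIXct(c("2008-03-01 20:00", "2008-03-01 20:00",
                             "2008-03-03 21:00", "2008-03-05 02:00"),
                           tz = "UTC"),
    species = "leopard", individual_id = "AF1",
    flank = c("left", "right", "left", "right"))
  ev <- dedupe_photos(ph, start_date = as.Date("2008-03-01"))
  expect_equal(nrow(ev), 3)  # same-minute flanks merge; days 1, 3, 5 distinct
  expect_equal(ev$occasion, c(1L, 3L, 5L))
  ev2 <- capture_events(ev)
  expect_identical(ev, ev2)  # deduplication is idempotent

  expect_error(dedupe_photos(photo_records("T1", Sys.time(), "leopard",
                                           NA, "left")),
               "individual_id")
})

test_that("count-matched photo expansion recounts to the printed summary", {
  tr <- make_trap_array(seed = 42)
  tab <- leopard_individuals()
  exp1 <- expand_capture_summary(tab, tr, seed = 99)
  ev <- dedupe_photos(exp1$photos, start_date = tr$start_date)
  counts <- table(ev$individual_id)
  expect_equal(as.integer(counts[tab$individual_id]), tab$total_captures)
  locs <- tapply(ev$station_id, ev$individual_id,
                 function(s) length(unique(s)))
  expect_equal(as.integer(locs[tab$individual_id]),
               tab$n_capture_locations)
})

test_that("capture array respects the adults-only rule and event totals", {
  tr <- make_trap_array(seed = 42)
  ev <- expand_capture_summary(leopard_individuals(), tr, seed = 7)$events
  arr_all <- build_capture_array(ev, tr, adults_only = FALSE)
  arr_ad <- build_capture_array(ev, tr, adults_only = TRUE)
  expect_equal(dim(arr_all$y)[1], 14)
  expect_equal(dim(arr_ad$y)[1], 10)
  expect_true(all(arr_ad$individuals$age_class == "adult"))
  # ids sorted, and summing the array reproduces per-individual event counts
  expect_equal(rownames(arr_all$y), sort(unique(ev$individual_id)))
  expect_equal(unname(apply(arr_all$y, 1, sum)),
               as.integer(table(ev$individual_id)[rownames(arr_all$y)]))

  expect_error(build_capture_array(ev[0, ], tr), "no individuals")
})

test_that("events at inactive traps are rejected with a listing", {
  act <- matrix(1L, 2, 4)
  act[2, 3] <- 0L
  tr <- trap_stations(c("T1", "T2"), c(0, 2), c(0, 0), 4, active = act)
  ev <- capture_events(data.frame(individual_id = "AF1",
                                  station_id = "T2", occasion = 3))
  expect_error(build_capture_array(ev, tr), "inactive.*AF1@T2/occ3")
})

test_that("prior-capture indicator matches the cumulative-max oracle", {
  tr <- toy_traps(J = 1, K = 5)
  y <- array(0L, c(1, 1, 5))
  y[1, 1, 2] <- 1L
  arr <- array_from_y(y, tr)
  C <- prior_capture_indicator(arr)
  expect_equal(C[1, 1, ], c(0L, 0L, 1L, 1L, 1L))

  # all-zero history cannot arise via build_capture_array; test via random y
  set.seed(204)
  for (rep in 1:20) {
    n <- sample(1:3, 1); J <- sample(1:3, 1); K <- sample(2:5, 1)
    trr <- toy_traps(J = J, K = K)
    y <- array(rbinom(n * J * K, 1, 0.3), c(n, J, K))
    if (any(apply(y, 1, sum) == 0)) next
    arr <- array_from_y(y, trr)
    C <- prior_capture_indicator(arr)
    oracle <- array(0L, dim(y))
    for (i in 1:n) for (j in 1:J) for (k in 2:K) {
      oracle[i, j, k] <- max(arr$y[i, j, 1:(k - 1)])
    }
    expect_equal(unname(C), oracle)
    expect_true(all(C[, , 1] == 0L))
    expect_true(all(apply(C, c(1, 2), function(v) all(diff(v) >= 0))))
  }
})

test_that("trap nights sum active station-occasions and are additive", {
  expect_equal(trap_nights(trap_stations("A", 0, 0, 1)), 1L)
  act <- matrix(1L, 2, 10)
  act[2, 1:5] <- 0L
  tr <- trap_stations(c("A", "B"), c(0, 2), c(0, 0), 10, active = act)
  expect_equal(trap_nights(tr), sum(act))  # brute-force sum
  tr_a <- trap_stations("A", 0, 0, 10, active = act[1, , drop = FALSE])
  tr_b <- trap_stations("B", 2, 0, 10, active = act[2, , drop = FALSE])
  expect_equal(trap_nights(tr), trap_nights(tr_a) + trap_nights(tr_b))
})

test_that("design validation flags spacing, coverage and degenerate layouts", {
  close2 <- trap_stations(c("A", "B"), c(0, 1), c(0, 0), 5)
  rep1 <- validate_design(close2, min_spacing_km = 1.7)
  expect_false(rep1$pass)
  expect_true(all(rep1$spacing_violations$too_close))

  # regular 2 km grid: brute-force pairwise distances all within bounds
  g <- grid_traps(3, 3, spacing = 2)
  rep2 <- validate_design(g, 1.7, 3.5)
  D <- as.matrix(dist(g$stations[, c("x", "y")])); diag(D) <- Inf
  expect_equal(unname(rep2$nn_distances), unname(apply(D, 1, min)))
  expect_equal(nrow(rep2$spacing_violations), 0)

  # dense cluster: coverage passes, spacing fails
  cl <- trap_stations(sprintf("C%d", 1:5), runif(5, 0, 1), runif(5, 0, 1), 5)
  rep3 <- validate_design(cl, 1.7, 3.5)
  expect_true(rep3$coverage_ok)
  expect_gt(nrow(rep3$spacing_violations), 0)

  dup <- trap_stations(c("A", "B", "C"), c(0, 0, 2), c(0, 0, 0), 5)
  rep4 <- validate_design(dup)
  expect_true(all(c("A", "B") %in% rep4$degenerate))
  expect_false(rep4$pass)
})

test_that("individual ids parse to age and sex classes", {
  p <- parse_individual_id(c("AF1", "AM12", "JF2", "JM1"))
  expect_equal(p$age_class, c("adult", "adult", "juvenile", "juvenile"))
  expect_equal(p$sex, c("female", "male", "female", "male"))
  expect_warning(parse_individual_id("XX9"), "unparseable")
})
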