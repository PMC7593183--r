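test_that("the von Mises sampler hits its limits and is reproducible", {
  set.seed(71)
  x <- rvonmises(500, pi, 1e6)
  expect_true(all(abs(x - pi) < 0.01))
  u <- rvonmises(10000, 0, 0)
  expect_lt(mean_resultant_length(u), 0.03)
  set.seed(5); a <- rvonmises(100, 1, 2)
  set.seed(5); b <- rvonmises(100, 1, 2)
  expect_identical(a, b)
  expect_equal(rvonmises(0, 1, 2), numeric(0))
})

test_that("mixture specs validate weights and sample reproducibly", {
  expect_error(vm_mixture(c(0.5, 0.6), c(0, 1), c(1, 1)), "sum to 1")
  expect_error(vm_mixture(c(1.2, -0.2), c(0, 1), c(1, 1)), "sum to 1")
  spec <- vm_mixture(c(0.5, 0.5), c(0, pi), c(4, 4))
  s1 <- sample_vonmises_mixture(spec, 200, seed = 9)
  s2 <- sample_vonmises_mixture(spec, 200, seed = 9)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 < 2 * pi))
})

test_that("the overlap oracle integrates min(f, g) to high accuracy", {
  m1 <- vm_mixture(1, 0, 100)
  m2 <- vm_mixture(1, pi, 100)
  expect_equal(true_overlap(m1, m1), 1, tolerance = 1e-6)
  expect_lt(true_overlap(m1, m2), 0.001)
  set.seed(72)
  for (rep in 1:4) {
    a <- vm_mixture(1, runif(1, 0, 2 * pi), runif(1, 0.5, 5))
    b <- vm_mixture(c(0.4, 0.6), runif(2, 0, 2 * pi), runif(2, 0.5, 5))
    expect_equal(true_overlap(a, b), true_overlap(b, a),
                 tolerance = 1e-12)
    # doubled resolution agrees: discretization error is negligible
    expect_equal(true_overlap(a, b),
                 true_overlap(a, b, n_grid = 262144L), tolerance = 1e-6)
  }
})

test_that("a zero-rate design yields no detections", {
  des <- default_study_design()
  des$rates[] <- 0
  st <- generate_study(des, seed = 3)
  expect_null(st$detections)
  expect_equal(st$truth$n_primary_events, 0L)
})

test_that("burst bookkeeping is exact and the filter removes burst images", {
  st <- generate_study(seed = 8)
  expect_equal(nrow(st$detections),
               st$truth$n_primary_events + st$truth$n_burst_images)
  ct <- filter_independent(st$detections, config = st$design$season)
  # all burst images sit < 30 min after their primary, so contacts can
  # never exceed the primary event count
  expect_lte(nrow(ct), st$truth$n_primary_events)
  # and bursts cost at most a handful of primaries (a burst image can
  # shadow a primary only if the primary follows within the interval)
  expect_gte(nrow(ct), st$truth$n_primary_events * 0.9)
})

test_that("synthetic studies round-trip through the table readers", {
  st <- generate_study(seed = 12)
  dir <- tempfile()
  write_study(st, dir)
  ev <- read_detection_table(file.path(dir, "detections.csv"))
  expect_equal(nrow(ev), nrow(st$detections))
  expect_equal(ev$timestamp, st$detections$timestamp)
  expect_equal(ev$species, st$detections$species)
  dep <- read_deployment_table(file.path(dir, "deployments.csv"))
  expect_equal(dep$site_id, st$deployments$site_id)
  expect_equal(dep$start_date, st$deployments$start_date)
  caps <- read_capture_table(file.path(dir, "captures.csv"))
  expect_equal(nrow(caps), nrow(st$captures))

  # a written contact table round-trips losslessly
  ct <- filter_independent(st$detections, config = st$design$season)
  cpath <- file.path(dir, "contacts.csv")
  write_contact_table(ct, cpath)
  back <- read.csv(cpath)
  back$timestamp <- as.POSIXct(back$timestamp, tz = "UTC")
  expect_equal(back$timestamp, ct$timestamp)
  expect_equal(back$season, ct$season)
  expect_equal(back$site_id, ct$site_id)
})

test_that("default study reproduces the guild's detection-share ordering", {
  ok <- 0L
  for (seed in 1:10) {
    st <- generate_study(seed = seed)
    ct <- filter_independent(st$detections, config = st$design$season)
    sh <- contact_shares(ct)$by_species
    if (identical(sh$species,
                  c("red_fox", "stone_marten", "badger", "genet",
                    "wildcat"))) {
      ok <- ok + 1L
    }
  }
  expect_gte(ok, 9L)
})

test_that("estimated overlap tracks the truth record end to end", {
  st <- generate_study(seed = 21)
  ct <- filter_independent(st$detections, config = st$design$season)
  tr <- st$truth$overlaps
  ok <- TRUE
  for (row in c(1, 8)) {
    l1 <- tr$label1[row]; l2 <- tr$label2[row]; ssn <- tr$season1[row]
    a1 <- to_radians(ct$timestamp[ct$species == l1 & ct$season == ssn])
    a2 <- to_radians(ct$timestamp[ct$species == l2 & ct$season == ssn])
    est <- estimate_overlap(a1, a2)
    expect_lt(abs(est$value - tr$overlap[row]), 0.15)
  }
})
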