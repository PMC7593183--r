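test_that("RAI is contacts per 100 trap-days with aggregate consistency", {
  ct <- make_contact_table(data.frame(
    species = c("red_fox", "genet", "red_fox"),
    season = c("spring_summer", "spring_summer", "autumn_winter"),
    n = c(30, 17, 17)))
  eff <- c(S01 = 300)
  expect_equal(compute_rai(ct, eff, "red_fox")$rai, 100 * 47 / 300)
  expect_equal(compute_rai(ct, eff, "badger")$rai, 0)
  expect_equal(compute_rai(ct, eff, "red_fox",
                           period = "spring_summer")$rai, 10)
  # 47 contacts over 328 nights
  expect_equal(compute_rai(ct, c(S01 = 328), "red_fox")$rai,
               100 * 47 / 328, tolerance = 1e-12)
  # doubling contacts and nights together leaves RAI unchanged
  ct2 <- make_contact_table(data.frame(
    species = c("red_fox", "genet", "red_fox"),
    season = c("spring_summer", "spring_summer", "autumn_winter"),
    n = 2 * c(30, 17, 17)))
  expect_equal(compute_rai(ct2, 2 * eff, "red_fox")$rai,
               compute_rai(ct, eff, "red_fox")$rai)
  # guild aggregate equals the sum over species
  all_r <- compute_rai(ct, eff, "all_mesocarnivores")$rai
  per_sp <- vapply(c("red_fox", "stone_marten", "badger", "genet",
                     "wildcat"),
                   function(sp) compute_rai(ct, eff, sp)$rai, numeric(1))
  expect_equal(all_r, sum(per_sp))
  expect_error(compute_rai(ct, c(S02 = 100)), "S01")
})

test_that("small-mammal abundance counts distinct tags per campaign", {
  caps <- data.frame(plot_id = "P1", campaign = "autumn_winter",
                     tag = c("A", "A", "B", "C"))
  expect_equal(small_mammal_abundance(caps)$individuals, 3)
  expect_equal(small_mammal_abundance(caps[0, ], plots = "P1",
                                      campaigns = "x")$individuals, 0)
  both <- rbind(caps, data.frame(plot_id = "P1",
                                 campaign = "spring_summer", tag = "A"))
  ab <- small_mammal_abundance(both)
  expect_equal(ab$individuals[ab$campaign == "spring_summer"], 1)
  expect_equal(ab$individuals[ab$campaign == "autumn_winter"], 3)
})

test_that("site-plot linkage uses a strict 3-km radius and plot means", {
  sites <- data.frame(site_id = c("A", "B"), x = c(0, 10000), y = 0)
  plots <- data.frame(plot_id = c("P1", "P2", "P3"),
                      x = c(2500, 2900, 3000), y = 0)
  ab <- data.frame(plot_id = rep(c("P1", "P2", "P3"), 2),
                   campaign = rep(c("spring_summer", "autumn_winter"),
                                  each = 3),
                   individuals = c(10, 20, 99, 1, 3, 99))
  lk <- link_sites_to_plots(sites, plots, ab)
  expect_equal(lk$n_plots, c(2L, 0L))               # P3 at exactly 3 km: out
  expect_true(lk$linked[1] && !lk$linked[2])
  expect_equal(lk$abundance_spring_summer[1], 15)   # mean(10, 20)
  expect_equal(lk$abundance_autumn_winter[1], 2)

  # the default study design links 13 of its 18 sites
  des <- default_study_design()
  ab5 <- data.frame(plot_id = rep(des$plots$plot_id, 2),
                    campaign = rep(c("spring_summer", "autumn_winter"),
                                   each = 5),
                    individuals = 1)
  lk5 <- link_sites_to_plots(des$sites[, c("site_id", "x", "y")],
                             des$plots[, c("plot_id", "x", "y")], ab5)
  expect_equal(sum(lk5$linked), 13L)
  expect_equal(sum(!lk5$linked), 5L)
})

test_that("Moran's I equals the brute-force double sum and known signs", {
  set.seed(51)
  for (rep in 1:5) {
    coords <- matrix(runif(10, 0, 100), ncol = 2)
    values <- rnorm(5)
    m <- morans_i(values, data.frame(x = coords[, 1], y = coords[, 2]),
                  n_perm = 19, seed = 1)
    expect_equal(m$I, moran_brute(values, coords), tolerance = 1e-12)
  }

  coords <- data.frame(x = c(0, 0, 10, 10), y = c(0, 1, 0, 1))
  clustered <- morans_i(c(1, 1, -1, -1), coords, n_perm = 999, seed = 2)
  expect_gt(clustered$I, 0)
  alternating <- morans_i(c(1, -1, 1, -1), coords, n_perm = 999, seed = 2)
  expect_lt(alternating$I, 0)
  # permutation null centres on E[I] = -1/(N-1)
  expect_equal(mean(clustered$perm_values), clustered$expected,
               tolerance = 0.1)
  expect_error(morans_i(c(1, 1, 1), coords[1:3, ]), "all-equal")
  expect_error(morans_i(c(1, 2, 3),
                        data.frame(x = c(0, 0, 5), y = c(0, 0, 5))),
               "coincident")
})

test_that("Moran's I agrees with an independent implementation", {
  skip_if_not_installed("ape")
  # ape::Moran.I row-standardizes the weight matrix; on a regular
  # polygon every row sum is equal, so the standardization cancels and
  # the two conventions must agree
  ang <- 2 * pi * (0:5) / 6
  coords <- data.frame(x = 10 * cos(ang), y = 10 * sin(ang))
  set.seed(52)
  values <- rnorm(6)
  w <- 1 / as.matrix(dist(coords))
  diag(w) <- 0
  ref <- ape::Moran.I(values, w, scaled = FALSE)
  m <- morans_i(values, coords, n_perm = 9, seed = 1)
  expect_equal(m$I, ref$observed, tolerance = 1e-10)
  expect_equal(m$expected, ref$expected, tolerance = 1e-12)
})

test_that("camera-model permutation test matches exhaustive enumeration", {
  # identical groups: every permutation ties the observed zero difference
  t0 <- camera_model_diff_test(c(5, 5, 5, 5), c("A", "A", "B", "B"),
                               n_perm = 99, seed = 1)
  expect_equal(t0$observed, 0)
  expect_equal(t0$p, 1)

  te <- camera_model_diff_test(c(10, 10, 0, 0), c("A", "A", "B", "B"),
                               exhaustive = TRUE)
  expect_equal(te$p, 2 / 6)
  expect_equal(te$n_perm, 6L)

  # sampled version converges to the exhaustive p
  ts <- camera_model_diff_test(c(10, 10, 0, 0), c("A", "A", "B", "B"),
                               n_perm = 4999, seed = 3)
  expect_equal(ts$p, 2 / 6, tolerance = 0.05)
  # determinism under seed
  ts2 <- camera_model_diff_test(c(10, 10, 0, 0), c("A", "A", "B", "B"),
                                n_perm = 4999, seed = 3)
  expect_identical(ts$p, ts2$p)
  expect_error(camera_model_diff_test(1:4, rep("A", 4)), "two model")
})

test_that("permutation p-values are calibrated under a true null", {
  set.seed(53)
  hits <- 0L
  n_rep <- 200L
  for (rep in seq_len(n_rep)) {
    rai <- rnorm(12)
    labels <- rep(c("A", "B"), 6)
    p <- camera_model_diff_test(rai, labels, n_perm = 199)$p
    if (p <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.01)
  expect_lte(hits / n_rep, 0.10)
})
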