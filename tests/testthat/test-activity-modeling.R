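test_that("z-scaling centres and scales with the sample SD", {
  expect_equal(zscale(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(61)
  x <- rnorm(40, 7, 3)
  z <- zscale(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1)
  expect_error(zscale(rep(2, 10), "prey"), "prey")
})

test_that("AICc matches its closed form and limits", {
  expect_equal(aicc(-10, 3, 26), 27 + 2 / 22 * 1)   # 27.0909...
  expect_equal(aicc(-10, 3, 26), -2 * -10 + 2 * 3 + 2 * 3 * 4 / 22)
  expect_equal(aicc(-10, 3, 1e9), 26, tolerance = 1e-6)   # AIC limit
  expect_equal(aicc(0, 0, 10), 0)
  expect_error(aicc(-10, 9, 10), "exceed")
})

test_that("the mixed model collapses to OLS when site variance is zero", {
  # a zero-variance generating process can still yield a positive ML
  # variance estimate by chance; this draw lands on the boundary
  d <- simulate_model_dataset(beta_small_mammals = 0.7, sd_site = 0,
                              seed = 3)
  fit <- fit_lmm(d, c("small_mammals", "season", "rai_other"))
  ols <- stats::lm(rai ~ small_mammals + season + rai_other, data = d)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)),
               tolerance = 1e-6)
  expect_true(fit$boundary)
  expect_equal(fit$k, 6)   # intercept + 3 slopes + 2 variances
})

test_that("the mixed model recovers a known standardized effect", {
  ok <- 0L
  for (seed in 1:20) {
    d <- simulate_model_dataset(beta_small_mammals = 0.5, seed = seed)
    fit <- fit_lmm(d, "small_mammals")
    co <- fit$coefficients[fit$coefficients$term == "small_mammals", ]
    if (abs(co$estimate - 0.5) <= 2 * co$se) ok <- ok + 1L
  }
  expect_gte(ok, 16L)   # ~95% nominal, 20 draws
})

test_that("all-subsets selection produces 8 models with unit total weight", {
  d <- simulate_model_dataset(seed = 63)
  sel <- all_subsets_importance(d)
  expect_length(sel$fits, 8L)
  expect_equal(sum(sel$model_table$weight), 1, tolerance = 1e-12)
  expect_equal(sort(sel$model_table$delta)[1], 0)
  expect_true(all(sel$importance$w_plus >= 0 & sel$importance$w_plus <= 1))
  # two-model closed form: delta = {0, 2} gives w+ = 1/(1 + exp(-1))
  w <- exp(-c(0, 2) / 2)
  expect_equal((w / sum(w))[1], 1 / (1 + exp(-1)))
})

test_that("Akaike weights ignore constant shifts in AICc", {
  a <- c(100, 102, 105)
  w1 <- exp(-(a - min(a)) / 2)
  a2 <- a + 57
  w2 <- exp(-(a2 - min(a2)) / 2)
  expect_equal(w1 / sum(w1), w2 / sum(w2))
})

test_that("the best model containing a variable respects AICc and tie rules", {
  mk <- function(fixed, aicc, k) {
    structure(list(fixed = fixed, aicc = aicc, k = k), class = "lmm_fit")
  }
  fits <- list(mk("x", 30, 4), mk(c("x", "y"), 28, 5), mk("x", 31, 4))
  expect_equal(best_model_including(fits, "x")$aicc, 28)
  fits_tie <- list(mk("x", 28, 5), mk("x", 28, 4))
  expect_equal(best_model_including(fits_tie, "x")$k, 4)
  expect_error(best_model_including(fits, "z"), "no fitted model")
})

test_that("model dataset assembly: rows, covariates, focal exclusion", {
  st <- generate_study(seed = 7)
  ct <- filter_independent(st$detections, config = st$design$season)
  md <- build_model_dataset(ct, st$deployments, st$truth$links,
                            focal = "red_fox",
                            config = st$design$season)
  expect_equal(nrow(md), 26L)   # 13 linked sites x 2 seasons
  expect_equal(levels(md$season), c("autumn_winter", "spring_summer"))
  expect_lt(abs(mean(md$small_mammals)), 1e-12)
  expect_equal(sd(md$small_mammals), 1)
  expect_equal(sd(md$rai_other), 1)

  # rai_other is the seasonal aggregate RAI of the four non-focal species
  eff_ss <- effort_nights(st$deployments, season = "spring_summer",
                          config = st$design$season)
  site <- md$site_id[1]
  others <- setdiff(c("red_fox", "stone_marten", "badger", "genet",
                      "wildcat"), "red_fox")
  expected <- sum(vapply(others, function(sp) {
    r <- compute_rai(ct[ct$site_id %in% md$site_id, ],
                     eff_ss[names(eff_ss) %in% md$site_id], sp,
                     period = "spring_summer")
    r$rai[r$site_id == site]
  }, numeric(1)))
  got <- md$rai_other_raw[md$site_id == site &
                          md$season == "spring_summer"]
  expect_equal(got, expected)
})

test_that("residual diagnostics flag shape departures and degeneracy", {
  set.seed(64)
  fake_fit <- function(r, fv) {
    structure(list(model = structure(list(r = r, fv = fv),
                                     class = "fake")), class = "lmm_fit")
  }
  # stub resid/fitted via a minimal S3 class
  assign("residuals.fake", function(object, ...) object$r,
         envir = globalenv())
  assign("fitted.fake", function(object, ...) object$fv,
         envir = globalenv())
  on.exit({
    rm("residuals.fake", envir = globalenv())
    rm("fitted.fake", envir = globalenv())
  })
  d1 <- residual_diagnostics(fake_fit(rnorm(1000), rnorm(1000)))
  expect_lt(abs(d1$skewness), 0.2)
  d2 <- residual_diagnostics(fake_fit(stats::rt(1000, df = 3),
                                      rnorm(1000)))
  expect_gt(d2$excess_kurtosis, 1)
  d3 <- residual_diagnostics(fake_fit(rep(0, 30), rnorm(30)))
  expect_true(d3$degenerate)
})
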