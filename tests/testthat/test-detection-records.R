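test_that("detection tables read back row-for-row with schema checks", {
  df <- data.frame(site = c("S01", "S01", "S02"),
                   species = c("red_fox", "genet", "badger"),
                   timestamp = c("2018-08-01 10:00:00",
                                 "2018-08-01T11:30:00",
                                 "2018-12-01 23:59:59"),
                   camera_model = "cuddeback")
  ev <- read_detection_table(write_detection_csv(df))
  expect_equal(nrow(ev), 3L)
  expect_s3_class(ev$timestamp, "POSIXct")
  expect_equal(ev$species, c("red_fox", "genet", "badger"))

  df$species[2] <- "lynx"
  expect_warning(ev2 <- read_detection_table(write_detection_csv(df)),
                 "lynx")
  expect_equal(ev2$species[2], "other")

  df$species[2] <- "genet"
  df$timestamp[3] <- "2018-13-01 25:00"
  expect_error(read_detection_table(write_detection_csv(df)), "row\\(s\\) 3")

  expect_error(read_detection_table(
    write_detection_csv(df[, c("site", "species", "timestamp")])),
    "camera_model")
})

test_that("independence filter is greedy on the last retained detection", {
  ev <- make_events(paste("2018-08-01", c("00:00:00", "00:10:00",
                                          "00:29:00", "00:31:00")))
  ct <- filter_independent(ev)
  expect_equal(format(ct$timestamp, "%H:%M:%S"), c("00:00:00", "00:31:00"))

  # per-species grouping: interleaved species both keep their first event
  two_sp <- rbind(make_events("2018-08-01 00:00:00", species = "red_fox"),
                  make_events("2018-08-01 00:05:00", species = "genet"))
  expect_equal(nrow(filter_independent(two_sp)), 2L)

  # per-site grouping
  two_site <- rbind(make_events("2018-08-01 00:00:00", site = "S01"),
                    make_events("2018-08-01 00:05:00", site = "S02"))
  expect_equal(nrow(filter_independent(two_site)), 2L)

  expect_equal(nrow(filter_independent(ev[0, ])), 0L)
})

test_that("filtering is idempotent, order-invariant, and monotone in the interval", {
  set.seed(11)
  for (rep in 1:5) {
    ev <- make_events(utc("2018-08-01 00:00:00") +
                        sort(sample.int(86400 * 3, 60)),
                      species = sample(c("red_fox", "genet"), 60,
                                       replace = TRUE),
                      site = sample(c("S01", "S02"), 60, replace = TRUE))
    ct <- filter_independent(ev)
    # idempotence
    expect_equal(nrow(filter_independent(ct[, names(ev)])), nrow(ct))
    # reordering the input does not change the contacts
    shuf <- ev[sample.int(nrow(ev)), ]
    ct2 <- filter_independent(shuf)
    expect_equal(ct2$timestamp, ct$timestamp)
    # longer interval never yields more contacts
    counts <- vapply(c(5, 15, 30, 60, 120),
                     function(m) nrow(filter_independent(ev, m)),
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("season labels follow the equinox boundaries and partition the year", {
  expect_equal(assign_season(as.Date("2018-07-15")), "spring_summer")
  expect_equal(assign_season(as.Date("2018-12-25")), "autumn_winter")
  # equinox days join spring-summer (the configured ranges leave no gap)
  expect_equal(assign_season(as.Date("2018-09-23")), "spring_summer")
  expect_equal(assign_season(as.Date("2018-09-24")), "autumn_winter")
  expect_equal(assign_season(as.Date("2019-03-19")), "autumn_winter")
  expect_equal(assign_season(as.Date("2019-03-20")), "spring_summer")
  expect_error(assign_season(as.Date("2020-01-01")), "study window")

  days <- seq(as.Date("2018-07-01"), as.Date("2019-06-30"), by = "day")
  lab <- assign_season(days)
  expect_true(all(lab %in% c("spring_summer", "autumn_winter")))
})

test_that("trap nights count elapsed midnights and split cleanly by season", {
  dep <- data.frame(site_id = "S01", start_date = as.Date("2018-07-01"),
                    end_date = as.Date("2018-07-11"))
  expect_equal(unname(effort_nights(dep)["S01"]), 10)

  dep2 <- data.frame(site_id = "S01", start_date = as.Date("2018-09-20"),
                     end_date = as.Date("2018-09-28"))
  expect_equal(unname(effort_nights(dep2, season = "spring_summer")), 4)
  expect_equal(unname(effort_nights(dep2, season = "autumn_winter")), 4)

  # seasonal efforts sum to annual effort for every site of the default
  # study design
  des <- default_study_design()
  dep3 <- data.frame(site_id = des$sites$site_id,
                     start_date = des$sites$start_date,
                     end_date = des$sites$end_date)
  tot <- effort_nights(dep3, config = des$season)
  ss <- effort_nights(dep3, season = "spring_summer", config = des$season)
  aw <- effort_nights(dep3, season = "autumn_winter", config = des$season)
  expect_equal(as.numeric(ss + aw), as.numeric(tot))
  expect_equal(sum(tot), 5909)
})
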