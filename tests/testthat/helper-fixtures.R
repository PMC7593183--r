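# shared fixture builders (all data generated in code)

utc <- function(x) as.POSIXct(x, tz = "UTC")

make_events <- function(times, site = "S01", species = "red_fox",
                        model = "cuddeback") {
  data.frame(site_id = site, species = species, timestamp = utc(times),
             camera_model = model, stringsAsFactors = FALSE)
}

# contact table with given per-(species, season) counts; timestamps are
# synthetic but season-consistent
make_contact_table <- function(counts) {
  # counts: data.frame(species, season, n)
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    n <- counts$n[i]
    if (n == 0) return(NULL)
    base <- if (counts$season[i] == "spring_summer") {
      utc("2018-08-01 00:00:00")
    } else {
      utc("2018-11-01 00:00:00")
    }
    data.frame(site_id = "S01", species = counts$species[i],
               timestamp = base + seq_len(n) * 3600,
               camera_model = "cuddeback", season = counts$season[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("contact_table", class(out))
  out
}

write_detection_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# brute-force Moran's I oracle: literal double sum
moran_brute <- function(values, coords) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  W <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      w <- 1 / d
      num <- num + w * z[i] * z[j]
      W <- W + w
    }
  }
  (n / W) * num / sum(z^2)
}
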