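#' Season configuration for a two-season study calendar
#'
#' The study year is split at the astronomical equinoxes into spring-summer
#' and autumn-winter. Autumn-winter runs from \code{aw_start} to
#' \code{aw_end} inclusive; every other in-window date is spring-summer, so
#' the two labels partition the calendar with no gap (the equinox days
#' themselves fall in spring-summer).
#'
#' @param aw_start first date of autumn-winter (default 2018-09-24).
#' @param aw_end last date of autumn-winter (default 2019-03-19).
#' @param window_start,window_end study window bounds; dates outside raise
#'   an error in \code{\link{assign_season}}.
#' @return an object of class \code{season_config}.
#' @export
season_config <- function(aw_start = "2018-09-24", aw_end = "2019-03-19",
                          window_start = "2018-07-01",
                          window_end = "2019-07-31") {
  cfg <- list(aw_start = as.Date(aw_start), aw_end = as.Date(aw_end),
              window_start = as.Date(window_start),
              window_end = as.Date(window_end))
  stopifnot(cfg$aw_end >= cfg$aw_start,
            cfg$window_start <= cfg$aw_start,
            cfg$window_end >= cfg$aw_end)
  class(cfg) <- "season_config"
  cfg
}

#' Assign the seasonal label of a calendar date
#'
#' @param d a \code{Date} vector (or coercible).
#' @param config a \code{\link{season_config}}.
#' @return character vector, \code{"spring_summer"} or
#'   \code{"autumn_winter"}.
#' @examples
#' assign_season(as.Date("2018-07-15"))  # spring_summer
#' assign_season(as.Date("2018-12-25"))  # autumn_winter
#' @export
assign_season <- function(d, config = season_config()) {
  d <- as.Date(d)
  if (anyNA(d)) stop("unparseable date passed to assign_season()")
  bad <- d < config$window_start | d > config$window_end
  if (any(bad)) {
    stop(sprintf("date(s) outside the study window %s..%s: %s",
                 config$window_start, config$window_end,
                 paste(unique(d[bad]), collapse = ", ")))
  }
  ifelse(d >= config$aw_start & d <= config$aw_end,
         "autumn_winter", "spring_summer")
}

#' Read a camera-trap detection table
#'
#' Expects delimiter-separated text with a header row and columns
#' \code{site}, \code{species}, \code{timestamp} (ISO-8601, UTC) and
#' \code{camera_model}. Species outside the controlled vocabulary are
#' mapped to \code{"other"} with a warning.
#'
#' @param path path to the file.
#' @param sep field separator (default comma).
#' @return data frame with columns \code{site_id}, \code{species},
#'   \code{timestamp} (POSIXct, UTC), \code{camera_model}.
#' @export
read_detection_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  required <- c("site", "species", "timestamp", "camera_model")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("detection table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  ts <- parse_utc_timestamp(raw$timestamp)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))
    stop(sprintf("unparseable timestamp in row(s) %s (e.g. '%s')",
                 paste(utils::head(bad, 5L), collapse = ", "),
                 raw$timestamp[bad[1L]]))
  }
  species <- raw$species
  unknown <- !(species %in% SPECIES_VOCABULARY)
  if (any(unknown)) {
    warning(sprintf("%d detection(s) with species outside the vocabulary (%s) mapped to 'other'",
                    sum(unknown),
                    paste(unique(species[unknown]), collapse = ", ")))
    species[unknown] <- "other"
  }
  data.frame(site_id = as.character(raw$site), species = species,
             timestamp = ts, camera_model = as.character(raw$camera_model),
             stringsAsFactors = FALSE)
}

# ISO-8601, second resolution, always interpreted as UTC ("T" or space).
parse_utc_timestamp <- function(x) {
  x <- sub("T", " ", as.character(x), fixed = TRUE)
  as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
}

#' Filter raw detections down to independent contacts
#'
#' Greedy sequential filter applied within each (site, species) group:
#' the first event is retained and each later event is retained iff it
#' falls at least \code{interval_minutes} after the last \emph{retained}
#' event of that group. Ties at the identical second keep the first row in
#' stable input order. The result is independent of input row order.
#'
#' @param events data frame as returned by
#'   \code{\link{read_detection_table}}.
#' @param interval_minutes independence interval (default 30).
#' @param config season configuration used to label each contact.
#' @return a contact table: \code{site_id}, \code{species},
#'   \code{timestamp}, \code{camera_model}, \code{season}.
#' @export
filter_independent <- function(events, interval_minutes = 30,
                               config = season_config()) {
  stopifnot(interval_minutes > 0)
  if (is.null(events) || nrow(events) == 0L) {
    out <- data.frame(site_id = character(), species = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      camera_model = character(), season = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("contact_table", class(out))
    return(out)
  }
  ord <- order(events$site_id, events$species, events$timestamp)
  ev <- events[ord, , drop = FALSE]
  grp <- paste(ev$site_id, ev$species, sep = "\r")
  keep <- logical(nrow(ev))
  gap <- interval_minutes * 60
  for (g in split(seq_len(nrow(ev)), grp)) {
    last <- -Inf
    tt <- as.numeric(ev$timestamp[g])
    for (j in seq_along(g)) {
      if (tt[j] - last >= gap || !is.finite(last)) {
        keep[g[j]] <- TRUE
        last <- tt[j]
      }
    }
  }
  out <- ev[keep, , drop = FALSE]
  out$season <- assign_season(as.Date(out$timestamp, tz = "UTC"), config)
  rownames(out) <- NULL
  class(out) <- c("contact_table", class(out))
  out
}

#' Read a deployment table
#'
#' Columns: \code{site}, \code{camera_model}, \code{start_date},
#' \code{end_date}, \code{x}, \code{y} (planar coordinates in metres).
#'
#' @param path path to the file.
#' @param sep field separator.
#' @return data frame with one row per deployment interval.
#' @export
read_deployment_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  required <- c("site", "camera_model", "start_date", "end_date", "x", "y")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("deployment table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  out <- data.frame(site_id = as.character(raw$site),
                    camera_model = as.character(raw$camera_model),
                    start_date = as.Date(raw$start_date),
                    end_date = as.Date(raw$end_date),
                    x = as.numeric(raw$x), y = as.numeric(raw$y),
                    stringsAsFactors = FALSE)
  if (any(out$end_date < out$start_date)) {
    stop("deployment interval with end_date before start_date")
  }
  out
}

#' Sampling effort in trap nights per site
#'
#' A trap night is one elapsed midnight-to-midnight day inside an active
#' deployment interval, labelled by the date on which the night starts;
#' per interval, nights = end - start in days. With a \code{season}, only
#' nights whose starting date carries that label are counted, so seasonal
#' efforts always add up to the annual effort.
#'
#' @param deployments data frame with \code{site_id}, \code{start_date},
#'   \code{end_date}.
#' @param season optional \code{"spring_summer"} or \code{"autumn_winter"}.
#' @param config season configuration.
#' @return named numeric vector, nights per site (0 for a site with no
#'   deployment overlap).
#' @export
effort_nights <- function(deployments, season = NULL,
                          config = season_config()) {
  if (is.null(deployments) || nrow(deployments) == 0L) {
    return(setNames(numeric(0), character(0)))
  }
  stopifnot(all(deployments$end_date >= deployments$start_date))
  if (!is.null(season)) {
    season <- match.arg(season, SEASON_LEVELS)
  }
  per_interval <- function(start, end) {
    if (end == start) return(0)
    nights <- seq(start, end - 1, by = "day")   # night start dates
    if (is.null(season)) return(length(nights))
    sum(assign_season(nights, config) == season)
  }
  n <- mapply(per_interval, deployments$start_date, deployments$end_date)
  tapply(n, deployments$site_id, sum)[unique(deployments$site_id)]
}

#' Read a small-mammal capture table
#'
#' Columns: \code{plot}, \code{campaign} (a season label), \code{tag}.
#'
#' @param path path to the file.
#' @param sep field separator.
#' @return data frame \code{plot_id}, \code{campaign}, \code{tag}.
#' @export
read_capture_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  required <- c("plot", "campaign", "tag")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("capture table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  data.frame(plot_id = as.character(raw$plot),
             campaign = as.character(raw$campaign),
             tag = as.character(raw$tag), stringsAsFactors = FALSE)
}

#' Write a contact table to delimiter-separated text
#'
#' @param contacts a contact table from \code{\link{filter_independent}}.
#' @param path output path.
#' @export
write_contact_table <- function(contacts, path) {
  out <- as.data.frame(contacts)
  out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
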