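#' Relative Activity Index per site
#'
#' RAI = 100 * independent contacts / trap nights, per site, for a
#' species or an aggregate of species, over the whole year or one season.
#'
#' @param contacts a contact table (see \code{\link{filter_independent}}).
#' @param effort named vector of trap nights per site for the requested
#'   period (see \code{\link{effort_nights}}).
#' @param species a species name, a character vector of species to
#'   aggregate, or \code{"all_mesocarnivores"} for the five-species
#'   guild.
#' @param period \code{"year"}, \code{"spring_summer"} or
#'   \code{"autumn_winter"}; seasonal periods keep only matching
#'   contacts. The supplied \code{effort} must be for the same period.
#' @return data frame with \code{site_id}, \code{label}, \code{period},
#'   \code{contacts}, \code{nights}, \code{rai}; one row per site with
#'   effort, including zero-contact sites.
#' @export
compute_rai <- function(contacts, effort, species = "all_mesocarnivores",
                        period = "year") {
  period <- match.arg(period, c("year", SEASON_LEVELS))
  if (identical(species, "all_mesocarnivores")) {
    sel <- MESOCARNIVORES
    label <- "all_mesocarnivores"
  } else {
    sel <- species
    label <- paste(species, collapse = "+")
  }
  cc <- contacts[contacts$species %in% sel, , drop = FALSE]
  if (period != "year") cc <- cc[cc$season == period, , drop = FALSE]
  orphan <- setdiff(unique(cc$site_id),
                    names(effort)[!is.na(effort) & effort > 0])
  if (length(orphan)) {
    stop("site(s) with contacts but no positive effort for period '",
         period, "': ", paste(orphan, collapse = ", "))
  }
  counts <- table(factor(cc$site_id, levels = names(effort)))
  data.frame(site_id = names(effort), label = label, period = period,
             contacts = as.integer(counts),
             nights = as.numeric(effort),
             rai = 100 * as.integer(counts) / as.numeric(effort),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Small-mammal relative abundance per plot and campaign
#'
#' Relative abundance is the number of distinct marked individuals
#' captured in a campaign (recaptures within a campaign count once; the
#' same tag in different campaigns counts in each).
#'
#' @param captures data frame with \code{plot_id}, \code{campaign},
#'   \code{tag}.
#' @param plots optional character vector of plot ids to report (plots
#'   with no captures get 0 in every listed campaign).
#' @param campaigns optional campaign labels to report.
#' @return data frame \code{plot_id}, \code{campaign},
#'   \code{individuals}.
#' @export
small_mammal_abundance <- function(captures, plots = NULL,
                                   campaigns = NULL) {
  if (is.null(plots)) plots <- unique(captures$plot_id)
  if (is.null(campaigns)) campaigns <- unique(captures$campaign)
  if (nrow(captures) && any(!nzchar(captures$tag))) {
    stop("empty individual tag in capture table")
  }
  grid <- expand.grid(plot_id = plots, campaign = campaigns,
                      stringsAsFactors = FALSE)
  grid$individuals <- mapply(function(p, cm) {
    length(unique(captures$tag[captures$plot_id == p &
                               captures$campaign == cm]))
  }, grid$plot_id, grid$campaign)
  grid[order(grid$plot_id, grid$campaign), , drop = FALSE]
}

#' Link camera sites to small-mammal plots within a radius
#'
#' A site is linked to every plot strictly closer than \code{radius_m}
#' (Euclidean distance on planar metric coordinates); its prey-abundance
#' covariate per season is the arithmetic mean over linked plots. Sites
#' with no plot in range are flagged and excluded from modelling.
#'
#' @param site_coords data frame \code{site_id}, \code{x}, \code{y}
#'   (per-site mean camera position, metres).
#' @param plot_coords data frame \code{plot_id}, \code{x}, \code{y}.
#' @param abundance data frame from
#'   \code{\link{small_mammal_abundance}} with campaigns labelled by
#'   season.
#' @param radius_m linkage radius in metres (default 3000).
#' @return data frame with one row per site: \code{site_id},
#'   \code{n_plots}, \code{plots} (comma-separated), \code{linked}, and
#'   one \code{abundance_<season>} column per season present.
#' @export
link_sites_to_plots <- function(site_coords, plot_coords, abundance,
                                radius_m = 3000) {
  seasons <- unique(abundance$campaign)
  out <- lapply(seq_len(nrow(site_coords)), function(i) {
    d <- sqrt((plot_coords$x - site_coords$x[i])^2 +
              (plot_coords$y - site_coords$y[i])^2)
    near <- plot_coords$plot_id[d < radius_m]
    row <- data.frame(site_id = site_coords$site_id[i],
                      n_plots = length(near),
                      plots = paste(near, collapse = ","),
                      linked = length(near) > 0,
                      stringsAsFactors = FALSE)
    for (s in seasons) {
      ab <- abundance$individuals[abundance$plot_id %in% near &
                                  abundance$campaign == s]
      row[[paste0("abundance_", s)]] <- if (length(ab)) mean(ab) else NA_real_
    }
    row
  })
  do.call(rbind, out)
}

#' Moran's I spatial autocorrelation with a permutation test
#'
#' Inverse-distance weights \code{w_ij = 1/d_ij} (not row-standardized):
#' \deqn{I = \frac{N}{W}\frac{\sum_i\sum_j w_{ij} z_i z_j}{\sum_i z_i^2}}
#' with centred values \code{z}. Significance is assessed by a two-sided
#' permutation test on \code{|I - E[I]|} with \code{E[I] = -1/(N-1)},
#' including the observed arrangement (+1 smoothing).
#'
#' @param values one number per site.
#' @param coords data frame or matrix with columns \code{x}, \code{y}.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return an object of class \code{spatial_autocorr}: \code{I},
#'   \code{expected}, \code{p_perm}, \code{n_perm}, \code{seed},
#'   \code{weights} description.
#' @export
morans_i <- function(values, coords, n_perm = 999, seed = NULL) {
  coords <- as.matrix(as.data.frame(coords)[, c("x", "y")])
  n <- length(values)
  stopifnot(n >= 3, nrow(coords) == n)
  if (var(values) == 0) stop("Moran's I undefined for all-equal values")
  dmat <- as.matrix(dist(coords))
  if (any(dmat[upper.tri(dmat)] == 0)) {
    stop("coincident site coordinates give infinite inverse-distance weights")
  }
  w <- 1 / dmat
  diag(w) <- 0
  W <- sum(w)
  stat <- function(v) {
    z <- v - mean(v)
    (n / W) * as.numeric(t(z) %*% w %*% z) / sum(z^2)
  }
  I <- stat(values)
  e_i <- -1 / (n - 1)
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(k) stat(sample(values)),
                 numeric(1))
  p <- (1 + sum(abs(perm - e_i) >= abs(I - e_i))) / (n_perm + 1)
  out <- list(I = I, expected = e_i, p_perm = p, n_perm = n_perm,
              seed = seed, perm_values = perm,
              weights = "inverse distance, not row-standardized")
  class(out) <- "spatial_autocorr"
  out
}

#' @exportS3Method base::print
print.spatial_autocorr <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f), permutation p = %.4f (%d permutations)\n",
              x$I, x$expected, x$p_perm, x$n_perm))
  invisible(x)
}

#' Permutation test for a camera-model effect on detection rates
#'
#' Observed statistic: absolute difference of mean year-round RAI between
#' the two camera models. The null distribution permutes model labels
#' among sites, preserving group sizes; p is the fraction of null
#' differences at least as large in absolute value as the observed one
#' (no +1 smoothing — the count is divided by the number of
#' permutations).
#'
#' @param rai year-round RAI, one value per site.
#' @param model camera model label per site (exactly two levels).
#' @param n_perm permutations (default 999); ignored when
#'   \code{exhaustive}.
#' @param seed integer seed.
#' @param exhaustive enumerate all distinct label assignments instead of
#'   sampling (feasible for small site counts).
#' @return an object of class \code{perm_test}: \code{observed},
#'   \code{p}, \code{n_perm}, \code{seed}, \code{exhaustive}.
#' @export
camera_model_diff_test <- function(rai, model, n_perm = 999, seed = NULL,
                                   exhaustive = FALSE) {
  model <- as.character(model)
  lev <- unique(model)
  if (length(lev) != 2L) {
    stop("camera_model_diff_test needs exactly two model labels, got: ",
         paste(lev, collapse = ", "))
  }
  diff_for <- function(is_a) abs(mean(rai[is_a]) - mean(rai[!is_a]))
  observed <- diff_for(model == lev[1])
  n_a <- sum(model == lev[1])
  if (exhaustive) {
    picks <- combn(length(rai), n_a)
    null_d <- apply(picks, 2, function(ix) {
      diff_for(seq_along(rai) %in% ix)
    })
    n_perm <- ncol(picks)
  } else {
    if (!is.null(seed)) set.seed(seed)
    null_d <- vapply(seq_len(n_perm), function(k) {
      diff_for(seq_along(rai) %in% sample(length(rai), n_a))
    }, numeric(1))
  }
  out <- list(observed = observed, p = sum(null_d >= observed) / n_perm,
              n_perm = n_perm, seed = seed, exhaustive = exhaustive,
              null_values = null_d)
  class(out) <- "perm_test"
  out
}

#' @exportS3Method base::print
print.perm_test <- function(x, ...) {
  cat(sprintf("|mean RAI difference| = %.3f, permutation p = %.4f (%d %s permutations)\n",
              x$observed, x$p, x$n_perm,
              if (x$exhaustive) "exhaustive" else "sampled"))
  invisible(x)
}
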