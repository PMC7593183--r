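#' Pipeline configuration
#'
#' Bundles every tunable of the analysis chain; the defaults are the
#' study settings (30-min independence interval, 144-point grid, 1,000
#' bootstrap and null replicates, 999 permutations, 95% CIs, Dhat1 below
#' 50 observations with adjustments 0.8/1.0, 3-km linkage radius, 0.50
#' importance threshold).
#'
#' @param interval_minutes independence interval.
#' @param season season configuration (\code{\link{season_config}}).
#' @param grid_size density evaluation grid.
#' @param B_bootstrap smooth-bootstrap replicates.
#' @param B_null randomization-test replicates.
#' @param n_perm permutations for Moran's I and the camera-model test.
#' @param ci_level confidence level.
#' @param small_threshold Dhat1/Dhat4 sample-size cut-off.
#' @param adjust_small,adjust_large bandwidth adjustments.
#' @param radius_m site-plot linkage radius (metres).
#' @param importance_threshold cumulative-weight cut-off.
#' @param n_min minimum per-sample size for a density fit.
#' @param seed master seed; stage seeds are derived from it.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(interval_minutes = 30,
                            season = season_config(), grid_size = 144,
                            B_bootstrap = 1000, B_null = 1000,
                            n_perm = 999, ci_level = 0.95,
                            small_threshold = 50, adjust_small = 0.8,
                            adjust_large = 1.0, radius_m = 3000,
                            importance_threshold = 0.50, n_min = 10,
                            seed = 1) {
  cfg <- list(interval_minutes = interval_minutes, season = season,
              grid_size = grid_size, B_bootstrap = B_bootstrap,
              B_null = B_null, n_perm = n_perm, ci_level = ci_level,
              small_threshold = small_threshold,
              adjust_small = adjust_small, adjust_large = adjust_large,
              radius_m = radius_m,
              importance_threshold = importance_threshold,
              n_min = n_min, seed = seed)
  class(cfg) <- "pipeline_config"
  cfg
}

# one overlap comparison: point estimate + CI + randomization p
compare_pair <- function(s1, s2, config, seed) {
  ci <- smooth_bootstrap_ci(s1, s2, B = config$B_bootstrap,
                            level = config$ci_level, seed = seed,
                            small_threshold = config$small_threshold,
                            adjust_small = config$adjust_small,
                            adjust_large = config$adjust_large,
                            grid_size = config$grid_size)
  ts <- null_overlap_test(s1, s2, B = config$B_null, seed = seed + 1,
                          small_threshold = config$small_threshold,
                          adjust_small = config$adjust_small,
                          adjust_large = config$adjust_large,
                          grid_size = config$grid_size)
  data.frame(estimator = ci$estimate$estimator,
             overlap = ci$estimate$value, ci_low = ci$low,
             ci_high = ci$high, p = ts$p, n1 = ci$estimate$n1,
             n2 = ci$estimate$n2, B = config$B_bootstrap,
             seed = seed, note = "", stringsAsFactors = FALSE)
}

skipped_row <- function(note, n1, n2) {
  data.frame(estimator = NA_character_, overlap = NA_real_,
             ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
             n1 = n1, n2 = n2, B = NA_integer_, seed = NA_real_,
             note = note, stringsAsFactors = FALSE)
}

#' Pairwise activity-overlap report
#'
#' Runs every overlap comparison of the study design on a contact table:
#' the 10 mesocarnivore pairs within each season, the 5 species vs
#' small-mammal comparisons within each season, and the 6 within-species
#' between-season comparisons. Pairs whose smaller sample is below
#' \code{config$n_min} are kept as rows flagged
#' \code{"insufficient sample"}. Deterministic under the master seed.
#'
#' @param contacts a contact table with a \code{season} column.
#' @param config a \code{\link{pipeline_config}}.
#' @return data frame, one row per comparison, with columns
#'   \code{label1}, \code{season1}, \code{label2}, \code{season2},
#'   \code{estimator}, \code{overlap}, \code{ci_low}, \code{ci_high},
#'   \code{p}, \code{n1}, \code{n2}, \code{B}, \code{seed}, \code{note}.
#' @export
run_overlap_report <- function(contacts, config = pipeline_config()) {
  angles_of <- function(label, season) {
    sel <- contacts$species == label & contacts$season == season
    to_radians(contacts$timestamp[sel])
  }
  tasks <- list()
  for (ssn in SEASON_LEVELS) {
    for (pair in combn(MESOCARNIVORES, 2, simplify = FALSE)) {
      tasks[[length(tasks) + 1L]] <-
        list(l1 = pair[1], s1 = ssn, l2 = pair[2], s2 = ssn)
    }
    for (sp in MESOCARNIVORES) {
      tasks[[length(tasks) + 1L]] <-
        list(l1 = sp, s1 = ssn, l2 = "small_mammal", s2 = ssn)
    }
  }
  for (sp in c(MESOCARNIVORES, "small_mammal")) {
    tasks[[length(tasks) + 1L]] <-
      list(l1 = sp, s1 = "spring_summer", l2 = sp, s2 = "autumn_winter")
  }
  rows <- lapply(seq_along(tasks), function(i) {
    tk <- tasks[[i]]
    a1 <- angles_of(tk$l1, tk$s1)
    a2 <- angles_of(tk$l2, tk$s2)
    head <- data.frame(label1 = tk$l1, season1 = tk$s1, label2 = tk$l2,
                       season2 = tk$s2, stringsAsFactors = FALSE)
    body <- if (min(length(a1), length(a2)) < config$n_min) {
      skipped_row("insufficient sample", length(a1), length(a2))
    } else {
      compare_pair(a1, a2, config,
                   seed = fan_out_seed(config$seed, 10 + 2L * i))
    }
    cbind(head, body)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-species prey-abundance model report
#'
#' For each mesocarnivore: the 8-model all-subsets AICc table, the
#' cumulative-weight importance table with the influential flag, and the
#' coefficient table of the most parsimonious model containing each
#' variable (season reference level: autumn-winter).
#'
#' @param contacts contact table.
#' @param deployments deployment table.
#' @param links site-plot link table
#'   (\code{\link{link_sites_to_plots}}).
#' @param config a \code{\link{pipeline_config}}.
#' @param species focal species to model (default: the five
#'   mesocarnivores).
#' @return named list per species with \code{model_table},
#'   \code{importance} and \code{best_models} (per-variable coefficient
#'   tables).
#' @export
run_model_report <- function(contacts, deployments, links,
                             config = pipeline_config(),
                             species = MESOCARNIVORES) {
  out <- list()
  for (sp in species) {
    data <- build_model_dataset(contacts, deployments, links, focal = sp,
                                config = config$season)
    sel <- all_subsets_importance(data,
                                  threshold = config$importance_threshold)
    best <- lapply(setNames(CANDIDATE_VARIABLES, CANDIDATE_VARIABLES),
                   function(v) {
      fit <- best_model_including(sel$fits, v)
      list(fixed = fit$fixed, coefficients = fit$coefficients,
           aicc = fit$aicc, boundary = fit$boundary)
    })
    out[[sp]] <- list(model_table = sel$model_table,
                      importance = sel$importance, best_models = best,
                      n = nrow(data))
  }
  out
}

#' Detection-share summary of a contact table
#'
#' Per-species contact counts and their percentage shares of the guild's
#' total, plus seasonal shares; the arithmetic behind the headline
#' detection-share figures of a camera-trap study.
#'
#' @param contacts a contact table.
#' @param species the species set to summarize over (default: the five
#'   mesocarnivores).
#' @return list with \code{by_species} (species, contacts, share_pct),
#'   \code{by_season} (season, contacts, share_pct) and \code{total}.
#' @export
contact_shares <- function(contacts, species = MESOCARNIVORES) {
  cc <- contacts[contacts$species %in% species, , drop = FALSE]
  total <- nrow(cc)
  by_sp <- as.data.frame(table(factor(cc$species, levels = species)),
                         stringsAsFactors = FALSE)
  names(by_sp) <- c("species", "contacts")
  by_sp$share_pct <- 100 * by_sp$contacts / total
  by_sp <- by_sp[order(-by_sp$contacts), , drop = FALSE]
  by_ssn <- as.data.frame(table(factor(cc$season,
                                       levels = rev(SEASON_LEVELS))),
                          stringsAsFactors = FALSE)
  names(by_ssn) <- c("season", "contacts")
  by_ssn$share_pct <- 100 * by_ssn$contacts / total
  list(by_species = by_sp, by_season = by_ssn, total = total)
}
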