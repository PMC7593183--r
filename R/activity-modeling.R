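#' Standardize a numeric vector (z-score)
#'
#' Centres on the mean and divides by the sample standard deviation
#' (n - 1 denominator). Continuous covariates measured in different
#' units are scaled once on the full modelling dataset before any model
#' subsetting.
#'
#' @param x numeric vector of length >= 2.
#' @param name variable name used in error messages.
#' @return the scaled vector.
#' @export
zscale <- function(x, name = deparse(substitute(x))) {
  if (length(x) < 2L) stop("zscale needs at least 2 values: ", name)
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    stop("zero variance, cannot scale variable: ", name)
  }
  (x - mean(x)) / s
}

#' Build the seasonal-RAI modelling dataset for one focal species
#'
#' One row per linked site x season. The response is the focal species'
#' seasonal RAI; covariates are the mean small-mammal abundance of the
#' linked plots for that season, the season factor (autumn-winter
#' reference), and the aggregate seasonal RAI of the other four
#' mesocarnivores (a camera-position control). Continuous covariates are
#' z-scaled over the whole dataset.
#'
#' @param contacts contact table.
#' @param deployments deployment table (for seasonal effort).
#' @param links output of \code{\link{link_sites_to_plots}}.
#' @param focal focal mesocarnivore species.
#' @param config season configuration.
#' @return data frame with \code{site_id}, \code{season}, \code{rai}
#'   (response), \code{small_mammals}, \code{rai_other} (both scaled),
#'   plus unscaled \code{small_mammals_raw}, \code{rai_other_raw}.
#' @export
build_model_dataset <- function(contacts, deployments, links,
                                focal = "red_fox",
                                config = season_config()) {
  stopifnot(focal %in% MESOCARNIVORES)
  linked <- links[links$linked, , drop = FALSE]
  if (!nrow(linked)) stop("no camera sites linked to a small-mammal plot")
  others <- setdiff(MESOCARNIVORES, focal)
  contacts <- contacts[contacts$site_id %in% linked$site_id, , drop = FALSE]
  rows <- list()
  for (season in SEASON_LEVELS) {
    eff <- effort_nights(deployments, season = season, config = config)
    eff <- eff[names(eff) %in% linked$site_id]
    focal_rai <- compute_rai(contacts, eff, species = focal,
                             period = season)
    other_rai <- compute_rai(contacts, eff, species = others,
                             period = season)
    ab_col <- paste0("abundance_", season)
    if (!ab_col %in% names(linked)) {
      stop("links table has no abundance column for season ", season)
    }
    ab <- linked[[ab_col]][match(focal_rai$site_id, linked$site_id)]
    rows[[season]] <- data.frame(site_id = focal_rai$site_id,
                                 season = season, rai = focal_rai$rai,
                                 small_mammals_raw = ab,
                                 rai_other_raw = other_rai$rai,
                                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$season <- factor(out$season, levels = SEASON_LEVELS)
  out$small_mammals <- zscale(out$small_mammals_raw, "small_mammals")
  out$rai_other <- zscale(out$rai_other_raw, "rai_other")
  attr(out, "focal") <- focal
  out
}

#' Fit a random-intercept linear mixed model by maximum likelihood
#'
#' Response \code{rai}, fixed effects from \code{fixed} (any subset of
#' \code{small_mammals}, \code{season}, \code{rai_other}), and a random
#' intercept per camera site. ML (not REML) estimation, so AICc values
#' are comparable across models with different fixed effects. A
#' site-variance estimate on the zero boundary is allowed and flagged.
#'
#' @param data a modelling dataset (see
#'   \code{\link{build_model_dataset}}), or any data frame with columns
#'   \code{rai}, \code{site_id} and the requested covariates.
#' @param fixed character vector of fixed-effect names (may be empty for
#'   the intercept-only model).
#' @return an object of class \code{lmm_fit}: \code{fixed},
#'   \code{coefficients} (estimate, se), \code{var_site},
#'   \code{var_resid}, \code{logLik}, \code{k}, \code{n}, \code{aicc},
#'   \code{boundary}, \code{model} (the lme4 fit).
#' @export
fit_lmm <- function(data, fixed = character()) {
  if (length(unique(data$site_id)) < 2L) {
    stop("random-intercept model needs >= 2 sites")
  }
  rhs <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  form <- stats::as.formula(paste("rai ~", rhs, "+ (1 | site_id)"))
  fit <- withCallingHandlers(
    lme4::lmer(form, data = data, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    message = function(m) invokeRestart("muffleMessage")
  )
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_site <- vc$vcov[vc$grp == "site_id"]
  var_resid <- vc$vcov[vc$grp == "Residual"]
  ll <- as.numeric(logLik(fit))
  k <- length(beta) + 2L   # fixed effects (incl. intercept) + 2 variances
  n <- nrow(data)
  out <- list(fixed = fixed,
              coefficients = data.frame(term = names(beta),
                                        estimate = unname(beta),
                                        se = unname(se),
                                        stringsAsFactors = FALSE),
              var_site = var_site, var_resid = var_resid,
              logLik = ll, k = k, n = n, aicc = aicc(ll, k, n),
              boundary = lme4::isSingular(fit, tol = 1e-5), model = fit)
  class(out) <- "lmm_fit"
  out
}

#' @exportS3Method base::print
print.lmm_fit <- function(x, ...) {
  cat(sprintf("LMM (ML): rai ~ %s + (1 | site_id)\n",
              if (length(x$fixed)) paste(x$fixed, collapse = " + ") else "1"))
  print(x$coefficients, row.names = FALSE)
  cat(sprintf("site var = %.4f%s, residual var = %.4f, logLik = %.3f, k = %d, AICc = %.3f\n",
              x$var_site, if (x$boundary) " (boundary)" else "",
              x$var_resid, x$logLik, x$k, x$aicc))
  invisible(x)
}

#' Small-sample corrected Akaike Information Criterion
#'
#' \deqn{AICc = -2\ell + 2k + \frac{2k(k+1)}{n-k-1}}
#'
#' @param loglik maximized log-likelihood.
#' @param k parameter count (fixed effects including intercept plus the
#'   two variance components for the mixed models fitted here).
#' @param n number of observations.
#' @return the AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) {
    stop(sprintf("AICc undefined: n = %d must exceed k + 1 = %d", n, k + 1))
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

CANDIDATE_VARIABLES <- c("small_mammals", "season", "rai_other")

#' All-subsets AICc model set and cumulative-weight variable importance
#'
#' Fits all 2^3 = 8 combinations of the candidate fixed effects
#' (small-mammal abundance, season, other-species RAI), each with an
#' intercept and the site random intercept, ranks them by AICc, and
#' computes per-variable cumulative Akaike weights
#' \code{w+ = sum of model weights over models containing the variable}.
#' Variables with \code{w+ >= threshold} are flagged influential.
#'
#' @param data a modelling dataset.
#' @param candidates candidate variable names.
#' @param threshold cumulative-weight cut-off (default 0.50).
#' @return list with \code{fits} (8 \code{lmm_fit}s), \code{model_table}
#'   (subset, k, logLik, AICc, delta, weight) and \code{importance}
#'   (variable, w_plus, influential).
#' @export
all_subsets_importance <- function(data, candidates = CANDIDATE_VARIABLES,
                                   threshold = 0.50) {
  subsets <- lapply(0:(2^length(candidates) - 1), function(mask) {
    candidates[bitwAnd(mask, 2^(seq_along(candidates) - 1)) > 0]
  })
  fits <- vector("list", length(subsets))
  failed <- character(0)
  for (i in seq_along(subsets)) {
    fits[[i]] <- tryCatch(fit_lmm(data, subsets[[i]]), error = function(e) {
      failed <<- c(failed,
                   sprintf("{%s}: %s", paste(subsets[[i]], collapse = ","),
                           conditionMessage(e)))
      NULL
    })
  }
  if (length(failed)) {
    stop("model fit failed for subset(s):\n", paste(failed, collapse = "\n"))
  }
  aiccs <- vapply(fits, `[[`, numeric(1), "aicc")
  delta <- aiccs - min(aiccs)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  model_table <- data.frame(
    subset = vapply(subsets, function(s) {
      if (length(s)) paste(s, collapse = "+") else "(intercept)"
    }, character(1)),
    k = vapply(fits, `[[`, numeric(1), "k"),
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    AICc = aiccs, delta = delta, weight = w,
    stringsAsFactors = FALSE)
  model_table <- model_table[order(model_table$AICc), , drop = FALSE]
  w_plus <- vapply(candidates, function(v) {
    sum(w[vapply(subsets, function(s) v %in% s, logical(1))])
  }, numeric(1))
  importance <- data.frame(variable = candidates, w_plus = unname(w_plus),
                           influential = unname(w_plus) >= threshold,
                           stringsAsFactors = FALSE)
  list(fits = fits, subsets = subsets, model_table = model_table,
       importance = importance, threshold = threshold)
}

#' Most parsimonious model containing a given variable
#'
#' Among the fitted subsets that include \code{variable}, returns the one
#' with the lowest AICc; ties are broken by fewer parameters, then by
#' subset order.
#'
#' @param fits list of \code{lmm_fit} objects (e.g. from
#'   \code{\link{all_subsets_importance}}).
#' @param variable variable name.
#' @return the selected \code{lmm_fit}.
#' @export
best_model_including <- function(fits, variable) {
  has <- vapply(fits, function(f) variable %in% f$fixed, logical(1))
  if (!any(has)) stop("variable '", variable, "' appears in no fitted model")
  cand <- fits[has]
  aiccs <- vapply(cand, `[[`, numeric(1), "aicc")
  ks <- vapply(cand, `[[`, numeric(1), "k")
  cand[[order(aiccs, ks)[1]]]
}

#' Residual diagnostics for the saturated model
#'
#' Advisory summary of the conditional residuals: skewness, excess
#' kurtosis, Shapiro-Wilk statistic and p, and the ratio of residual
#' variances between the lower and upper halves of the fitted-value
#' range (a homoscedasticity indicator). Near-zero residual variance is
#' flagged degenerate.
#'
#' @param fit an \code{lmm_fit}.
#' @return list of diagnostics.
#' @export
residual_diagnostics <- function(fit) {
  r <- resid(fit$model)
  fv <- fitted(fit$model)
  n <- length(r)
  degenerate <- sd(r) < 1e-8 * max(1, sd(fv))
  if (degenerate) {
    return(list(skewness = 0, excess_kurtosis = 0, shapiro_w = NA_real_,
                shapiro_p = NA_real_, variance_ratio = NA_real_,
                degenerate = TRUE, n = n))
  }
  z <- (r - mean(r)) / sqrt(mean((r - mean(r))^2))
  sw <- if (n >= 3 && n <= 5000) shapiro.test(r) else NULL
  lower <- fv <= stats::median(fv)
  vr <- var(r[!lower]) / var(r[lower])
  list(skewness = mean(z^3), excess_kurtosis = mean(z^4) - 3,
       shapiro_w = if (is.null(sw)) NA_real_ else unname(sw$statistic),
       shapiro_p = if (is.null(sw)) NA_real_ else sw$p.value,
       variance_ratio = vr, degenerate = FALSE, n = n)
}
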