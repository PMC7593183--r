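#' Convert a clock time to an angle on the diel circle
#'
#' Maps a UTC time of day to radians with 2*pi radians = 24 h, so midnight
#' is 0 and noon is pi.
#'
#' @param t a POSIXct vector, or a character vector \code{"HH:MM:SS"}, or
#'   a numeric vector of seconds since midnight.
#' @return numeric vector of angles in \code{[0, 2*pi)}.
#' @export
to_radians <- function(t) {
  if (inherits(t, "POSIXct")) {
    secs <- as.numeric(t) %% 86400
  } else if (is.character(t)) {
    parts <- strsplit(t, ":", fixed = TRUE)
    secs <- vapply(parts, function(p) {
      p <- as.numeric(p)
      if (anyNA(p) || length(p) < 2L || length(p) > 3L) {
        stop("invalid time of day: expected HH:MM[:SS]")
      }
      sum(p * c(3600, 60, 1)[seq_along(p)])
    }, numeric(1))
  } else {
    secs <- as.numeric(t)
  }
  (2 * pi * secs / 86400) %% (2 * pi)
}

#' Mean resultant length of a circular sample
#'
#' @param theta angles in radians.
#' @return Rbar in \code{[0, 1]}.
#' @export
mean_resultant_length <- function(theta) {
  if (!length(theta)) stop("empty circular sample")
  sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
}

# A(kappa) = I1(kappa)/I0(kappa), computed on the exponentially scaled
# Bessel functions so large kappa does not overflow.
vm_A <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
}

#' Maximum-likelihood von Mises concentration
#'
#' Solves A(kappa) = Rbar by bracketed root-finding on
#' \code{[1e-12, 1e3]} to relative tolerance 1e-8, then caps the result
#' at \code{kappa_max}. The cap keeps kernel bandwidths sensible on very
#' concentrated samples.
#'
#' @param theta angles in radians (sample of size >= 1).
#' @param kappa_max cap on the returned concentration (default 3).
#' @return the capped ML estimate, >= 0.
#' @export
vm_kappa_ml <- function(theta, kappa_max = 3) {
  rbar <- mean_resultant_length(theta)
  if (rbar <= vm_A(1e-12)) return(0)
  if (rbar >= vm_A(1e3)) return(kappa_max)
  k <- uniroot(function(k) vm_A(k) - rbar, c(1e-12, 1e3),
               tol = 1e-8 * max(1, rbar))$root
  min(k, kappa_max)
}

#' Plug-in kernel concentration for the von Mises kernel
#'
#' Smoothing parameter of the circular kernel estimator:
#' \deqn{\kappa^* = c \left[\frac{3 n \hat\kappa^2 I_2(2\hat\kappa)}
#'   {4 \sqrt{\pi} I_0(\hat\kappa)^2}\right]^{2/5}}
#' where \code{c} is the adjustment multiplier (0.8 for Dhat1 on small
#' samples, 1.0 for Dhat4). A larger \code{adjust} gives a spikier fit.
#'
#' @param kappa_ml ML concentration of the sample.
#' @param n sample size.
#' @param adjust positive multiplier.
#' @return the kernel concentration, 0 when \code{kappa_ml} is 0.
#' @export
kernel_concentration <- function(kappa_ml, n, adjust = 1) {
  stopifnot(kappa_ml >= 0, n >= 1, adjust > 0)
  if (kappa_ml == 0) return(0)
  base <- 3 * n * kappa_ml^2 * besselI(2 * kappa_ml, 2) /
    (4 * sqrt(pi) * besselI(kappa_ml, 0)^2)
  adjust * base^(2 / 5)
}

#' Fit a diel activity density by von Mises kernel estimation
#'
#' @param theta angles in radians in \code{[0, 2*pi)}.
#' @param adjust bandwidth adjustment multiplier (see
#'   \code{\link{kernel_concentration}}).
#' @param grid_size number of evaluation points around the circle
#'   (default 144, i.e. one every 10 minutes).
#' @param n_min minimum sample size (default 2); smaller samples should
#'   be pooled before estimation.
#' @param kappa_max cap passed to \code{\link{vm_kappa_ml}}.
#' @param kappa_kernel optional explicit kernel concentration, bypassing
#'   the plug-in rule (used for constructed reference densities).
#' @param label optional label, e.g. \code{"red_fox/spring_summer"}.
#' @param compute_grid evaluate the density on the grid at fit time
#'   (default TRUE; estimators that only need densities at data points
#'   skip it).
#' @return an object of class \code{density_estimate} with elements
#'   \code{theta} (the sample), \code{kappa_ml}, \code{adjust},
#'   \code{kappa_kernel}, \code{grid} and \code{grid_density}.
#' @export
fit_activity_density <- function(theta, adjust = 1, grid_size = 144,
                                 n_min = 2, kappa_max = 3,
                                 kappa_kernel = NULL, label = NULL,
                                 compute_grid = TRUE) {
  theta <- as.numeric(theta) %% (2 * pi)
  if (length(theta) < n_min) {
    stop(sprintf("sample size %d below n_min = %d; pool detections before fitting",
                 length(theta), n_min))
  }
  kml <- vm_kappa_ml(theta, kappa_max = kappa_max)
  kstar <- if (is.null(kappa_kernel)) {
    kernel_concentration(kml, length(theta), adjust)
  } else {
    kappa_kernel
  }
  grid <- 2 * pi * (seq_len(grid_size) - 1L) / grid_size
  d <- list(theta = theta, n = length(theta), kappa_ml = kml,
            adjust = adjust, kappa_kernel = kstar, grid_size = grid_size,
            grid = grid, label = label)
  class(d) <- "density_estimate"
  if (compute_grid) d$grid_density <- evaluate_density(d, grid)
  d
}

#' Evaluate a fitted activity density
#'
#' The kernel estimate at angle \code{theta} is
#' \code{mean(exp(kstar * cos(theta - x_i))) / (2 * pi * I0(kstar))};
#' a zero kernel concentration gives the uniform density 1/(2*pi).
#'
#' @param d a \code{density_estimate}.
#' @param angles angles in radians.
#' @return density values, one per angle.
#' @export
evaluate_density <- function(d, angles) {
  stopifnot(inherits(d, "density_estimate"))
  k <- d$kappa_kernel
  if (k == 0) return(rep(1 / (2 * pi), length(angles)))
  # exponentially scaled I0 guards against overflow at large kstar
  m <- exp(k * (cos(outer(angles, d$theta, "-")) - 1))
  rowMeans(m) / (2 * pi * besselI(k, 0, expon.scaled = TRUE))
}

#' @exportS3Method base::print
print.density_estimate <- function(x, ...) {
  cat(sprintf("von Mises kernel density%s: n = %d, kappa_ml = %.3f, adjust = %.2f, kappa_kernel = %.3f, grid = %d\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$n, x$kappa_ml, x$adjust, x$kappa_kernel, x$grid_size))
  invisible(x)
}

#' Export a fitted density as a table
#'
#' @param d a \code{density_estimate}.
#' @return data frame with \code{angle_rad}, \code{time_hhmm},
#'   \code{density}.
#' @export
density_table <- function(d) {
  stopifnot(inherits(d, "density_estimate"))
  mins <- round(d$grid / (2 * pi) * 1440)
  data.frame(angle_rad = d$grid,
             time_hhmm = sprintf("%02d:%02d", mins %/% 60, mins %% 60),
             density = d$grid_density)
}
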