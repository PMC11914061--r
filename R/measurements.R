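# Per-cell derived quantities: nuclear-size allometry, SPCH concentration,
# exponential decay constants, percent decline, dip detection, bleaching
# rate, and neighbour contact fractions.

#' Fit the ln-ln cell-to-nuclear-area allometry
#'
#' Ordinary least squares of ln(nuclear area) on ln(cell area). The residual
#' scale `sigma_eps` is the residual standard deviation with the usual n - 2
#' denominator.
#'
#' @param pairs data.frame with positive columns `cell_area_um2` and
#'   `nuclear_area_um2` (>= 3 rows).
#' @return object of class `allometry_fit` with `alpha` (intercept, ln um^2),
#'   `beta` (slope), `sigma_eps`, `se_alpha`, `se_beta`, `n`.
#' @export
fit_nuclear_allometry <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("cell_area_um2", "nuclear_area_um2") %in% names(pairs)))
  if (nrow(pairs) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (any(pairs$cell_area_um2 <= 0) || any(pairs$nuclear_area_um2 <= 0)) {
    stop("areas must be positive for the ln-ln fit", call. = FALSE)
  }
  x <- log(pairs$cell_area_um2)
  if (stats::var(x) == 0) {
    stop("zero variance in cell area; allometry slope is unidentifiable",
         call. = FALSE)
  }
  fit <- stats::lm(log(nuclear_area_um2) ~ log(cell_area_um2), data = pairs)
  sm <- suppressWarnings(summary(fit))  # noiseless input triggers a perfect-fit note
  structure(list(alpha = unname(stats::coef(fit)[1]),
                 beta = unname(stats::coef(fit)[2]),
                 sigma_eps = sm$sigma,
                 se_alpha = sm$coefficients[1, 2],
                 se_beta = sm$coefficients[2, 2],
                 n = nrow(pairs)),
            class = "allometry_fit")
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat(sprintf(
    "<allometry_fit> ln(nuclear) = %.3f ln(cell) + %.3f, sigma = %.4f (n = %d)\n",
    x$beta, x$alpha, x$sigma_eps, x$n))
  invisible(x)
}

# default fit: the encoded allometric relation
default_allometry_fit <- function() {
  structure(list(alpha = 1.82, beta = 0.19, sigma_eps = 0.027,
                 se_alpha = 0.14, se_beta = 0.032, n = NA_integer_),
            class = "allometry_fit")
}

#' Estimate nuclear area from cell area
#'
#' Applies the allometric map `exp(beta * ln(area) + alpha + eps)`; `eps` is
#' zero with `noise = "off"` or a Gaussian draw of scale `sigma_eps` with
#' `noise = "draw"`. Vectorized over `cell_area`.
#'
#' @param cell_area cell area(s) in um^2, all positive.
#' @param fit an `allometry_fit` (defaults to the encoded relation,
#'   alpha = 1.82, beta = 0.19, sigma = 0.027).
#' @param noise `"off"` or `"draw"`.
#' @param seed optional integer seed (used when drawing).
#' @return estimated nuclear area(s), um^2.
#' @export
estimate_nuclear_area <- function(cell_area, fit = default_allometry_fit(),
                                  noise = c("off", "draw"), seed = NULL) {
  noise <- match.arg(noise)
  if (any(cell_area <= 0)) stop("cell_area must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  eps <- if (noise == "draw") {
    stats::rnorm(length(cell_area), 0, fit$sigma_eps)
  } else 0
  exp(fit$beta * log(cell_area) + fit$alpha + eps)
}

#' SPCH nuclear concentration
#'
#' @param intensity SPCH intensity, a.u. (>= 0).
#' @param nuclear_area nuclear area, um^2 (> 0).
#' @return intensity / nuclear_area, a.u./um^2.
#' @export
spch_concentration <- function(intensity, nuclear_area) {
  if (any(nuclear_area <= 0)) stop("nuclear_area must be positive",
                                   call. = FALSE)
  if (any(intensity < 0)) stop("intensity must be >= 0", call. = FALSE)
  intensity / nuclear_area
}

#' Fit an exponential decay to a trajectory
#'
#' Fits `N(t) = N0 * exp(lambda t)` by log-linear OLS of ln(intensity) on
#' time in hours, over the samples inside the fit window (default birth to
#' 200 min). Zero intensities inside the window are dropped with a count kept
#' in the fit record; rising SPCH (lambda > 0) is retained and flagged, never
#' silently excluded.
#'
#' @param traj a [trajectory()] object.
#' @param window_min `c(start, end)` of the fit window, minutes.
#' @return object of class `decay_fit` with `N0`, `lambda_per_h`, `window`,
#'   `r_squared`, `n_points`, `n_dropped`, `rising`.
#' @export
fit_decay <- function(traj, window_min = c(0, 200)) {
  stopifnot(inherits(traj, "trajectory"), length(window_min) == 2L)
  sel <- traj$time_min >= window_min[1] & traj$time_min <= window_min[2]
  t_min <- traj$time_min[sel]
  intensity <- traj$intensity[sel]
  zero <- intensity <= 0
  n_dropped <- sum(zero)
  if (n_dropped > 0) {
    warning(sprintf("dropped %d non-positive intensity sample(s) from cell %s",
                    n_dropped, traj$cell_id), call. = FALSE)
    t_min <- t_min[!zero]
    intensity <- intensity[!zero]
  }
  if (length(t_min) < 2L) {
    stop("insufficient data: need >= 2 positive-intensity samples in window",
         call. = FALSE)
  }
  t_h <- t_min / 60
  fit <- stats::lm(log(intensity) ~ t_h)
  sm <- suppressWarnings(summary(fit))  # noiseless data triggers a perfect-fit note
  lambda <- unname(stats::coef(fit)[2])
  structure(list(cell_id = traj$cell_id,
                 N0 = exp(unname(stats::coef(fit)[1])),
                 lambda_per_h = lambda,
                 window = window_min,
                 r_squared = sm$r.squared,
                 n_points = length(t_h),
                 n_dropped = n_dropped,
                 rising = lambda > 0),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> cell %s: lambda = %.3f /h, N0 = %.1f (n = %d, r2 = %.3f)\n",
              x$cell_id, x$lambda_per_h, x$N0, x$n_points, x$r_squared))
  invisible(x)
}

#' Percent SPCH lost per hour
#'
#' Converts a decay constant to the overall rate of decline,
#' `100 * (1 - exp(lambda))`. Negative values (rising SPCH, lambda > 0) are
#' permitted.
#'
#' @param lambda_per_h decay constant, per hour.
#' @return percent of SPCH lost per hour.
#' @export
pct_decline_per_hour <- function(lambda_per_h) {
  stopifnot(all(is.finite(lambda_per_h)))
  100 * (1 - exp(lambda_per_h))
}

#' Locate the SPCH intensity dip
#'
#' Smooths the intensity series with a centred moving average of width
#' `smooth_k` (partial windows at the edges) and takes the global minimum of
#' the smoothed series within the search window; ties go to the earliest
#' time. If the trajectory carries nuclear areas, the concentration at the
#' dip divides the (raw) dip intensity by the nuclear area at that sample.
#'
#' @param traj a [trajectory()] object with at least `smooth_k` samples.
#' @param search_window_min `c(start, end)` window in minutes (default
#'   0-400).
#' @param smooth_k odd moving-average width (default 3).
#' @return list with `t_dip_min`, `intensity_at_dip` (smoothed),
#'   `concentration_at_dip` (or `NA` without nuclear areas).
#' @export
find_dip <- function(traj, search_window_min = c(0, 400), smooth_k = 3) {
  stopifnot(inherits(traj, "trajectory"), smooth_k %% 2 == 1)
  if (length(traj$time_min) < smooth_k) {
    stop("trajectory shorter than the smoothing width", call. = FALSE)
  }
  smoothed <- zoo::rollapply(traj$intensity, width = smooth_k, FUN = mean,
                             partial = TRUE, align = "center")
  sel <- which(traj$time_min >= search_window_min[1] &
                 traj$time_min <= search_window_min[2])
  if (length(sel) == 0L) {
    stop("search window excludes all samples", call. = FALSE)
  }
  i <- sel[which.min(smoothed[sel])]  # which.min takes the earliest tie
  conc <- if (!is.null(traj$nuclear_area_um2)) {
    spch_concentration(smoothed[i], traj$nuclear_area_um2[i])
  } else NA_real_
  list(t_dip_min = traj$time_min[i],
       intensity_at_dip = smoothed[i],
       concentration_at_dip = conc)
}

#' Estimate the photobleaching rate
#'
#' Pools the samples of all tracked nuclei, regresses intensity on time in
#' hours by OLS, and returns `-100 * slope / intercept`: the percent of the
#' initial intensity lost per hour (positive = loss).
#'
#' @param tracks list of [trajectory()] objects (>= 3 pooled samples).
#' @return bleaching rate, percent per hour.
#' @export
estimate_bleaching_rate <- function(tracks) {
  if (inherits(tracks, "trajectory")) tracks <- list(tracks)
  t_h <- unlist(lapply(tracks, function(tr) tr$time_min)) / 60
  intensity <- unlist(lapply(tracks, function(tr) tr$intensity))
  if (length(t_h) < 3L) stop("need >= 3 pooled samples", call. = FALSE)
  fit <- stats::lm(intensity ~ t_h)
  intercept <- unname(stats::coef(fit)[1])
  if (abs(intercept) < 1e-9 * mean(intensity)) {
    stop("degenerate fit: intercept is numerically zero", call. = FALSE)
  }
  -100 * unname(stats::coef(fit)[2]) / intercept
}

#' Fraction of an SLGC's perimeter in contact with a neighbour
#'
#' Computes `0.5 * (P_slgc + P_neighbour - P_union) / P_slgc` from the
#' perimeters of the SLGC, the neighbour, and their union. A result outside
#' [0, 1] by more than 1e-9 is clamped with a warning (never silently).
#'
#' @param p_slgc,p_neighbour,p_union perimeters in um, all positive;
#'   `p_union` may not exceed `p_slgc + p_neighbour`.
#' @return contact fraction in [0, 1].
#' @export
contact_fraction <- function(p_slgc, p_neighbour, p_union) {
  if (any(p_slgc <= 0) || any(p_neighbour <= 0) || any(p_union <= 0)) {
    stop("perimeters must be positive", call. = FALSE)
  }
  if (any(p_union > p_slgc + p_neighbour)) {
    stop("geometry error: P_union exceeds P_slgc + P_neighbour",
         call. = FALSE)
  }
  f <- 0.5 * (p_slgc + p_neighbour - p_union) / p_slgc
  out_of_range <- f < -1e-9 | f > 1 + 1e-9
  if (any(out_of_range)) {
    warning(sprintf("%d contact fraction(s) outside [0, 1]; clamped",
                    sum(out_of_range)), call. = FALSE)
  }
  pmin(pmax(f, 0), 1)
}

#' Measure a cohort
#'
#' Convenience pipeline over a cell table and matching trajectories:
#' estimates nuclear area from birth size (noise off), birth concentration,
#' the decay constant and percent decline (log-linear fit over the decay
#' window), and the dip time/concentration. Cells whose trajectory is absent
#' or unusable get `NA`s.
#'
#' @param cells validated cell table.
#' @param trajectories named list of [trajectory()] keyed by `cell_id`.
#' @param fit allometry fit used for nuclear-area estimation.
#' @param decay_window_min decay-fit window, minutes.
#' @return `cells` with appended columns `nuclear_area_um2_est`,
#'   `conc_birth`, `lambda_per_h`, `pct_decline_per_h`, `t_dip_min`,
#'   `conc_at_dip`.
#' @export
measure_cohort <- function(cells, trajectories,
                           fit = default_allometry_fit(),
                           decay_window_min = c(0, 200)) {
  validate_cell_table(cells)
  cells$nuclear_area_um2_est <- estimate_nuclear_area(cells$birth_area_um2,
                                                      fit, noise = "off")
  lambda <- t_dip <- conc_dip <- conc_birth <- rep(NA_real_, nrow(cells))
  for (i in seq_len(nrow(cells))) {
    tr <- trajectories[[cells$cell_id[i]]]
    if (is.null(tr)) next
    conc_birth[i] <- spch_concentration(tr$intensity[1],
                                        cells$nuclear_area_um2_est[i])
    fitd <- tryCatch(suppressWarnings(fit_decay(tr, decay_window_min)),
                     error = function(e) NULL)
    if (!is.null(fitd)) lambda[i] <- fitd$lambda_per_h
    dip <- tryCatch(find_dip(tr), error = function(e) NULL)
    if (!is.null(dip)) {
      t_dip[i] <- dip$t_dip_min
      conc_dip[i] <- if (is.na(dip$concentration_at_dip)) {
        spch_concentration(dip$intensity_at_dip, cells$nuclear_area_um2_est[i])
      } else dip$concentration_at_dip
    }
  }
  cells$conc_birth <- conc_birth
  cells$lambda_per_h <- lambda
  cells$pct_decline_per_h <- ifelse(is.na(lambda), NA_real_,
                                    pct_decline_per_hour(lambda))
  cells$t_dip_min <- t_dip
  cells$conc_at_dip <- conc_dip
  cells
}
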