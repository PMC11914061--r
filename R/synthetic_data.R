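# Synthetic cohort generator: emits SLGC cell tables and SPCH trajectories
# with the statistical structure the downstream analyses assume, plus a
# latent table holding every drawn quantity (ground truth).

#' Generator ground truth
#'
#' All parameters of the synthetic cohort generator. The distributional
#' components reuse [sim_inputs()]; on top of those it fixes the fate model
#' (degradation mode + logistic coefficients), the trajectory sampling scheme,
#' the multiplicative measurement noise, and the photobleaching rate.
#' Defaults encode the study conditions: the printed allometric relation
#' ln(nuclear area) = 0.19 ln(cell area) + 1.82 with residual SD 0.027,
#' gamma/normal/Poisson mother states, beta(4, 12) division asymmetry,
#' exponential decay-constant magnitudes giving mean declines inside the
#' reported 23-42 %/h band, a bleaching rate inside the reported
#' 1.5-2.2 %/h band, 40-min sampling, and a neighbour-stratified degradation
#' mode with a full (size + [SPCH] + neighbours) logistic fate rule.
#'
#' @param inputs [sim_inputs()] distributional parameters.
#' @param model [model_spec()] degradation mode + fate rule.
#' @param bleach_pct_per_h photobleaching rate, percent intensity lost/hour.
#' @param dt_min trajectory sampling interval, minutes.
#' @param duration_min trajectory length, minutes.
#' @param noise_cv coefficient of variation of multiplicative log-normal
#'   measurement noise on intensities.
#' @param t_dip_min minutes from birth to the SPCH dip.
#' @return object of class `generator_truth`.
#' @export
generator_truth <- function(inputs = sim_inputs(),
                            model = model_spec(
                              "neighbour",
                              c(intercept = 1.6, size = -0.02,
                                conc_dip = 0.25, neighbours = -0.8),
                              id = "truth"),
                            bleach_pct_per_h = 1.8,
                            dt_min = 40,
                            duration_min = 400,
                            noise_cv = 0.05,
                            t_dip_min = 200) {
  stopifnot(inherits(inputs, "sim_inputs"), inherits(model, "model_spec"),
            bleach_pct_per_h >= 0, dt_min > 0, duration_min > 0,
            noise_cv >= 0, t_dip_min > 0)
  structure(list(inputs = inputs, model = model,
                 bleach_pct_per_h = bleach_pct_per_h, dt_min = dt_min,
                 duration_min = duration_min, noise_cv = noise_cv,
                 t_dip_min = t_dip_min),
            class = "generator_truth")
}

# mean-one multiplicative log-normal factors with coefficient of variation cv
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate one synthetic SPCH trajectory
#'
#' Samples at times 0, dt, 2dt, ... with expectation `N0 * exp(lambda * t)`
#' (t in hours) under mean-one multiplicative log-normal noise of coefficient
#' of variation `noise_cv`. A duration shorter than the sampling interval
#' yields a single-sample trajectory flagged via the `"single_sample"`
#' attribute, not an error.
#'
#' @param N0 initial intensity, a.u. (> 0).
#' @param lambda_per_hour decay constant (negative = decline).
#' @param duration_min trajectory length in minutes.
#' @param dt_min sampling interval in minutes (> 0).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed optional integer seed.
#' @param cell_id identifier for the trajectory.
#' @return a [trajectory()] object.
#' @export
generate_trajectory <- function(N0, lambda_per_hour, duration_min, dt_min,
                                noise_cv = 0, seed = NULL, cell_id = "sim") {
  stopifnot(N0 > 0, dt_min > 0, noise_cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, duration_min, by = dt_min)
  mean_i <- N0 * exp(lambda_per_hour * times / 60)
  tr <- trajectory(cell_id, times, mean_i * lognormal_noise(length(times),
                                                            noise_cv))
  attr(tr, "single_sample") <- length(times) == 1L
  tr
}

#' Generate synthetic allometry pairs
#'
#' Draws ln cell areas uniformly on `ln_area_range` and nuclear areas from
#' the linear model ln(nuclear) = beta * ln(cell) + alpha + eps with
#' eps ~ N(0, sigma_eps). Defaults are the encoded allometric parameters;
#' the default range [2.5, 5.5] on the ln scale spans roughly 12-245 um^2 of
#' cell area.
#'
#' @param n number of pairs (>= 3).
#' @param alpha intercept on the ln um^2 scale.
#' @param beta slope.
#' @param sigma_eps residual standard deviation (>= 0).
#' @param ln_area_range `c(lo, hi)` of ln cell area, hi > lo.
#' @param seed optional integer seed.
#' @return data.frame with columns `cell_area_um2`, `nuclear_area_um2`.
#' @export
generate_allometry_sample <- function(n, alpha = 1.82, beta = 0.19,
                                      sigma_eps = 0.027,
                                      ln_area_range = c(2.5, 5.5),
                                      seed = NULL) {
  if (n < 3) stop("n must be >= 3", call. = FALSE)
  if (sigma_eps < 0) stop("sigma_eps must be >= 0", call. = FALSE)
  if (ln_area_range[2] <= ln_area_range[1]) {
    stop("degenerate ln_area_range (hi <= lo)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  ln_cell <- stats::runif(n, ln_area_range[1], ln_area_range[2])
  ln_nuc <- beta * ln_cell + alpha + stats::rnorm(n, 0, sigma_eps)
  data.frame(cell_area_um2 = exp(ln_cell), nuclear_area_um2 = exp(ln_nuc))
}

#' Generate a synthetic SLGC cohort with known ground truth
#'
#' For each individual, draws mother states, applies the asymmetric division
#' rule, degrades SPCH under the truth's degradation mode, and assigns each
#' SLGC's behaviour with one Bernoulli draw from the truth's logistic fate
#' rule. Emits (1) a validated cell table in the [read_cell_table()] schema,
#' (2) one SPCH trajectory per cell following
#' `N(t) = N0 * exp(lambda t) * exp(-b t)` (b the bleaching rate) under
#' multiplicative log-normal measurement noise, and (3) a latent table
#' recording every drawn quantity (mother state, asymmetry, lambda, fate
#' probability), sufficient to compute any downstream "true" value without
#' re-simulation.
#'
#' @param truth [generator_truth()] object.
#' @param n_individuals number of simulated plants.
#' @param n_cells SLGCs per individual.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return list with `cells` (data.frame), `trajectories` (named list of
#'   [trajectory()]), `latent` (data.frame) and `truth`.
#' @export
generate_cohort <- function(truth = generator_truth(), n_individuals = 4,
                            n_cells = 1000, seed = NULL) {
  stopifnot(inherits(truth, "generator_truth"))
  if (n_individuals < 1 || n_cells < 1) {
    stop("n_individuals and n_cells must be positive", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  inputs <- truth$inputs

  per_ind <- lapply(seq_len(n_individuals), function(ind) {
    mothers <- init_mothers(inputs, n = n_cells, individual = ind)
    slgcs <- divide_mothers(mothers, inputs)
    slgcs <- degrade_spch(slgcs, truth$model$degradation_mode, inputs,
                          t_dip_min = truth$t_dip_min)
    decide_fate(slgcs, truth$model)
  })
  slgcs <- do.call(rbind, per_ind)
  n <- nrow(slgcs)

  # decorative fields: birth times, positions, perimeters, neighbour census
  birth_time <- round(stats::runif(n, 0, 600))
  # perimeter from a circularity draw (4*pi*A / P^2): epidermal cells range
  # from roundish to lobed, so circularity spans a wide band
  circularity <- stats::runif(n, 0.4, 0.8)
  perimeter <- sqrt(4 * pi * slgcs$size / circularity)
  n_sig <- slgcs$neighbours
  census <- vapply(n_sig, function(k) {
    as.integer(stats::rmultinom(1, k, prob = c(0.80, 0.15, 0.05)))
  }, integer(3))
  n_total <- n_sig + stats::rpois(n, 3)
  contact <- pmin(0.99, n_sig * stats::runif(n, 0.06, 0.18))

  cells <- data.frame(
    cell_id = slgcs$cell_id,
    individual = slgcs$individual,
    mother_id = slgcs$mother_id,
    birth_time_min = birth_time,
    birth_area_um2 = slgcs$size,
    perimeter_um = perimeter,
    pos_x_um = stats::runif(n, 0, 1000),
    pos_y_um = stats::runif(n, 0, 1000),
    n_neighbours_total = n_total,
    n_sig_neighbours = n_sig,
    n_meristemoid_nb = census[1, ],
    n_gmc_nb = census[2, ],
    n_stoma_nb = census[3, ],
    sig_contact_fraction = contact,
    behaviour = slgcs$fate,
    stringsAsFactors = FALSE
  )
  validate_cell_table(cells)

  bleach_lambda <- -truth$bleach_pct_per_h / 100  # per hour, exponential factor
  times <- seq(0, truth$duration_min, by = truth$dt_min)
  t_h <- times / 60
  trajectories <- lapply(seq_len(n), function(i) {
    mean_i <- slgcs$intensity[i] *
      exp((slgcs$lambda_per_h[i] + bleach_lambda) * t_h)
    trajectory(slgcs$cell_id[i], times,
               mean_i * lognormal_noise(length(times), truth$noise_cv),
               nuclear_area_um2 = rep(slgcs$nuclear_area[i], length(times)))
  })
  names(trajectories) <- slgcs$cell_id

  latent <- data.frame(
    cell_id = slgcs$cell_id,
    individual = slgcs$individual,
    mother_size = slgcs$mother_size,
    mother_intensity = slgcs$mother_intensity,
    mother_neighbours = slgcs$neighbours - 1L,
    asymmetry = slgcs$asymmetry,
    size = slgcs$size,
    meristemoid_size = slgcs$meristemoid_size,
    intensity_birth = slgcs$intensity,
    nuclear_area = slgcs$nuclear_area,
    lambda_per_h = slgcs$lambda_per_h,
    intensity_dip = slgcs$intensity_dip,
    conc_dip = slgcs$conc_dip,
    fate_prob = slgcs$fate_prob,
    fate = slgcs$fate,
    stringsAsFactors = FALSE
  )
  list(cells = cells, trajectories = trajectories, latent = latent,
       truth = truth)
}
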