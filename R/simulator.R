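# One-generation stochastic lineage model: 1000 mother cells per individual
# are initialized from fitted distributions, divide asymmetrically, degrade
# SPCH until the intensity dip, and then choose a fate (asymmetric division
# vs differentiation) from a logistic rule.

DEGRADATION_MODES <- c("random", "neighbour", "size", "neighbour_and_size")

#' Simulator input distributions
#'
#' Container for the per-population fitted distributions the lineage model
#' draws from: gamma mother birth sizes, normal mother SPCH intensities,
#' Poisson mother signaling-neighbour counts, beta division asymmetry
#' (supported on (0, 0.5) after truncation), and exponential magnitudes of
#' the SPCH decay constant. Decay magnitudes are kept pooled and stratified
#' by signaling-neighbour class (1 vs 2+), both on the per-cell scale
#' (per hour) and on the per-square-micron scale used by the size-based
#' degradation modes.
#'
#' @param size_gamma `c(shape, scale)` of mother birth size, um^2.
#' @param spch_normal `c(mean, sd)` of mother SPCH intensity, a.u.
#' @param neighbours_poisson mean mother signaling-neighbour count.
#' @param asymmetry_beta `c(shape1, shape2)` of the asymmetry parameter
#'   a = 1 - SLGC size / mother size.
#' @param decay_mean_abs named `c("1" = , "2+" = )` mean |lambda| per hour by
#'   SLGC neighbour class.
#' @param decay_mean_abs_per_um2 named `c("1" = , "2+" = )` mean per-um^2
#'   |lambda| by neighbour class.
#' @param allometry list with `alpha`, `beta`, `sigma` of the ln-ln
#'   cell-to-nuclear-area relation.
#' @return object of class `sim_inputs`.
#' @export
sim_inputs <- function(size_gamma = c(shape = 4, scale = 30),
                       spch_normal = c(mean = 500, sd = 150),
                       neighbours_poisson = 1,
                       asymmetry_beta = c(shape1 = 4, shape2 = 12),
                       decay_mean_abs = c("1" = 0.30, "2+" = 0.50),
                       decay_mean_abs_per_um2 = c("1" = 0.0020, "2+" = 0.0035),
                       allometry = list(alpha = 1.82, beta = 0.19,
                                        sigma = 0.027)) {
  stopifnot(all(size_gamma > 0), spch_normal[2] > 0, neighbours_poisson > 0,
            all(asymmetry_beta > 0), all(decay_mean_abs > 0),
            all(decay_mean_abs_per_um2 > 0), allometry$sigma >= 0)
  stopifnot(all(c("1", "2+") %in% names(decay_mean_abs)),
            all(c("1", "2+") %in% names(decay_mean_abs_per_um2)))
  structure(list(size_gamma = size_gamma, spch_normal = spch_normal,
                 neighbours_poisson = neighbours_poisson,
                 asymmetry_beta = asymmetry_beta,
                 decay_mean_abs = decay_mean_abs,
                 decay_mean_abs_per_um2 = decay_mean_abs_per_um2,
                 allometry = allometry),
            class = "sim_inputs")
}

#' Fate-determination model specification
#'
#' A candidate model couples one SPCH degradation mode with a logistic fate
#' rule over some subset of `size` (um^2), `conc_dip` (SPCH concentration at
#' the dip, a.u./um^2) and `neighbours` (signaling-neighbour count), plus
#' optional pairwise interaction terms written as e.g. `"size:conc_dip"`.
#' `k`, the number of non-intercept coefficients, is the parameter count
#' used in AICc.
#'
#' @param degradation_mode one of `"random"`, `"neighbour"`, `"size"`,
#'   `"neighbour_and_size"`.
#' @param coefficients named numeric vector; must contain `"intercept"`, all
#'   other names drawn from the three features and their `:` interactions.
#' @param id optional model identifier.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(degradation_mode, coefficients, id = NULL) {
  degradation_mode <- match.arg(degradation_mode, DEGRADATION_MODES)
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            all(is.finite(coefficients)))
  if (!"intercept" %in% names(coefficients)) {
    stop("model_spec coefficients must include an 'intercept'", call. = FALSE)
  }
  terms <- setdiff(names(coefficients), "intercept")
  if (length(terms) < 1L) {
    stop("model_spec needs at least one non-intercept coefficient (k >= 1)",
         call. = FALSE)
  }
  base <- c("size", "conc_dip", "neighbours")
  ok <- vapply(terms, function(tm) {
    all(strsplit(tm, ":", fixed = TRUE)[[1L]] %in% base)
  }, logical(1))
  if (!all(ok)) {
    stop("unknown fate model term(s): ", paste(terms[!ok], collapse = ", "),
         call. = FALSE)
  }
  if (is.null(id)) {
    id <- paste0(degradation_mode, "/", paste(terms, collapse = "+"))
  }
  structure(list(id = id, degradation_mode = degradation_mode,
                 coefficients = coefficients, k = length(terms)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: degradation = %s, k = %d\n",
              x$id, x$degradation_mode, x$k))
  invisible(x)
}

#' Initialize a population of mother cells
#'
#' Draws `n` mothers with birth size from the gamma distribution (rounded to
#' the nearest integer um^2, redrawing sub-half-micron values so all sizes
#' are >= 1), SPCH intensity from the normal distribution (negative draws
#' redrawn), and signaling-neighbour count from the Poisson distribution.
#'
#' @param inputs [sim_inputs()] object.
#' @param n number of mothers (default 1000).
#' @param individual identifier stored with each cell.
#' @param seed optional integer seed.
#' @return data.frame with columns `individual`, `mother_id`, `size`,
#'   `intensity`, `neighbours`.
#' @export
init_mothers <- function(inputs, n = 1000, individual = 1L, seed = NULL) {
  stopifnot(inherits(inputs, "sim_inputs"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  size <- stats::rgamma(n, shape = inputs$size_gamma[[1]],
                        scale = inputs$size_gamma[[2]])
  for (i in seq_len(100L)) {
    small <- size < 0.5
    if (!any(small)) break
    size[small] <- stats::rgamma(sum(small), shape = inputs$size_gamma[[1]],
                                 scale = inputs$size_gamma[[2]])
  }
  intensity <- stats::rnorm(n, inputs$spch_normal[[1]], inputs$spch_normal[[2]])
  for (i in seq_len(100L)) {
    neg <- intensity < 0
    if (!any(neg)) break
    intensity[neg] <- stats::rnorm(sum(neg), inputs$spch_normal[[1]],
                                   inputs$spch_normal[[2]])
  }
  data.frame(
    individual = individual,
    mother_id = sprintf("i%s_m%04d", individual, seq_len(n)),
    size = round(size),
    intensity = intensity,
    neighbours = stats::rpois(n, inputs$neighbours_poisson),
    stringsAsFactors = FALSE
  )
}

#' Divide mother cells asymmetrically
#'
#' Each mother divides with asymmetry parameter a = 1 - SLGC size / mother
#' size drawn from the beta distribution, perturbed by a noise factor and
#' redrawn (draw and noise together) until a lands in (0, 0.5), so the SLGC
#' is always the larger daughter. The SLGC size is `round(mother * (1 - a))`;
#' the sister meristemoid takes the exact remainder, so daughter sizes sum to
#' the mother size. The SLGC inherits two-thirds of its mother's SPCH
#' intensity and one signaling neighbour more than its mother (the new sister
#' meristemoid). Nuclear area is assigned from the ln-ln allometric relation
#' with its Gaussian residual.
#'
#' @param mothers data.frame from [init_mothers()].
#' @param inputs [sim_inputs()] object.
#' @param noise_mode `"multiplicative"` (factor U(0.5, 1.5) on a, default),
#'   `"additive"` (a + U(-0.5, 0.5)) or `"off"`.
#' @param seed optional integer seed.
#' @param max_redraws cap on reject-and-redraw rounds before a
#'   distribution-configuration error.
#' @return data.frame of SLGCs with columns `individual`, `cell_id`,
#'   `mother_id`, `mother_size`, `mother_intensity`, `asymmetry`, `size`,
#'   `meristemoid_size`, `intensity`, `neighbours`, `nuclear_area`.
#' @export
divide_mothers <- function(mothers, inputs,
                           noise_mode = c("multiplicative", "additive", "off"),
                           seed = NULL, max_redraws = 10000L) {
  noise_mode <- match.arg(noise_mode)
  stopifnot(inherits(inputs, "sim_inputs"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(mothers)
  a <- rep(NA_real_, n)
  todo <- rep(TRUE, n)
  for (round in seq_len(max_redraws)) {
    m <- sum(todo)
    if (m == 0L) break
    draw <- stats::rbeta(m, inputs$asymmetry_beta[[1]],
                         inputs$asymmetry_beta[[2]])
    draw <- switch(noise_mode,
                   multiplicative = draw * stats::runif(m, 0.5, 1.5),
                   additive = draw + stats::runif(m, -0.5, 0.5),
                   off = draw)
    a[todo] <- draw
    todo <- !(a > 0 & a < 0.5)
  }
  if (any(todo)) {
    stop("asymmetry rejection sampling exceeded ", max_redraws,
         " rounds; check the beta/noise configuration", call. = FALSE)
  }
  slgc_size <- round(mothers$size * (1 - a))
  al <- inputs$allometry
  eps <- stats::rnorm(n, 0, al$sigma)
  data.frame(
    individual = mothers$individual,
    cell_id = sub("_m", "_s", mothers$mother_id, fixed = TRUE),
    mother_id = mothers$mother_id,
    mother_size = mothers$size,
    mother_intensity = mothers$intensity,
    asymmetry = a,
    size = slgc_size,
    meristemoid_size = mothers$size - slgc_size,
    intensity = (2 / 3) * mothers$intensity,
    neighbours = mothers$neighbours + 1L,
    nuclear_area = exp(al$beta * log(slgc_size) + al$alpha + eps),
    stringsAsFactors = FALSE
  )
}

neighbour_class <- function(n) ifelse(n >= 2, "2+", "1")

#' Degrade SPCH to the intensity dip
#'
#' Draws the magnitude of each cell's decay constant from the exponential
#' distribution selected by the degradation mode and sets the intensity and
#' concentration at the dip. Modes: `"random"` draws |lambda| from the pooled
#' exponential; `"neighbour"` from one of two exponentials for cells with 1
#' vs 2+ signaling neighbours; `"size"` draws a per-square-micron magnitude
#' and multiplies by cell size; `"neighbour_and_size"` stratifies the
#' per-square-micron draw by neighbour class. Decay acts on intensity,
#' `I_dip = I_birth * exp(lambda * t_dip / 60)` with lambda = -|lambda| per
#' hour; concentration at the dip divides by the allometric nuclear area.
#'
#' @param slgcs data.frame from [divide_mothers()].
#' @param mode degradation mode (see above).
#' @param inputs [sim_inputs()] object.
#' @param t_dip_min minutes from birth to the dip (default 200).
#' @param seed optional integer seed.
#' @return `slgcs` with added columns `lambda_per_h`, `intensity_dip`,
#'   `conc_dip`.
#' @export
degrade_spch <- function(slgcs, mode, inputs, t_dip_min = 200, seed = NULL) {
  mode <- match.arg(mode, DEGRADATION_MODES)
  stopifnot(inherits(inputs, "sim_inputs"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(slgcs)
  cls <- neighbour_class(slgcs$neighbours)
  # pooled means: neighbour-class mixture weighted by the class frequencies
  pool_mean <- function(by_class) {
    w <- prop.table(table(factor(cls, levels = c("1", "2+"))))
    sum(by_class[c("1", "2+")] * as.numeric(w))
  }
  abs_lambda <- switch(
    mode,
    random = stats::rexp(n, rate = 1 / pool_mean(inputs$decay_mean_abs)),
    neighbour = stats::rexp(n, rate = 1 / inputs$decay_mean_abs[cls]),
    size = stats::rexp(n, rate = 1 / pool_mean(inputs$decay_mean_abs_per_um2)) *
      slgcs$size,
    neighbour_and_size =
      stats::rexp(n, rate = 1 / inputs$decay_mean_abs_per_um2[cls]) *
      slgcs$size
  )
  slgcs$lambda_per_h <- -abs_lambda
  slgcs$intensity_dip <- slgcs$intensity * exp(slgcs$lambda_per_h * t_dip_min / 60)
  slgcs$conc_dip <- slgcs$intensity_dip / slgcs$nuclear_area
  slgcs
}

fate_linear_predictor <- function(slgcs, coefficients) {
  feats <- list(size = slgcs$size, conc_dip = slgcs$conc_dip,
                neighbours = slgcs$neighbours)
  eta <- rep(coefficients[["intercept"]], nrow(slgcs))
  for (tm in setdiff(names(coefficients), "intercept")) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1L]]
    val <- Reduce(`*`, feats[parts])
    if (any(vapply(feats[parts], is.null, logical(1)))) {
      stop("fate model requires feature '", tm, "' which is absent",
           call. = FALSE)
    }
    eta <- eta + coefficients[[tm]] * val
  }
  eta
}

#' Decide SLGC fate from the logistic rule
#'
#' Computes p = logistic(intercept + sum coefficient x feature) and draws the
#' fate as one Bernoulli trial per cell: `ACD` (asymmetric division) with
#' probability p, else `DIFF`. The probability is stored alongside the draw.
#'
#' @param slgcs data.frame with dip fields set (see [degrade_spch()]).
#' @param model [model_spec()] object.
#' @param seed optional integer seed.
#' @return `slgcs` with added columns `fate_prob` and `fate`.
#' @export
decide_fate <- function(slgcs, model, seed = NULL) {
  stopifnot(inherits(model, "model_spec"))
  if (is.null(slgcs$conc_dip) &&
      any(grepl("conc_dip", names(model$coefficients)))) {
    stop("fate model requires feature 'conc_dip' which is absent",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  p <- stats::plogis(fate_linear_predictor(slgcs, model$coefficients))
  slgcs$fate_prob <- p
  slgcs$fate <- ifelse(stats::runif(nrow(slgcs)) < p, "ACD", "DIFF")
  slgcs
}

#' Bin signaling-neighbour counts as 1 / 2 / 3+
#'
#' @param n integer vector of counts (values below 1 are folded into bin 1).
#' @return factor with levels `"1"`, `"2"`, `"3+"`.
#' @export
bin_neighbours <- function(n) {
  factor(ifelse(n >= 3, "3+", as.character(pmax(n, 1L))),
         levels = c("1", "2", "3+"))
}

#' Run the one-generation lineage simulation
#'
#' For each individual: initialize mothers, divide, degrade SPCH to the dip
#' under the model's degradation mode, and decide fate with the model's
#' logistic rule. Cells are independent (the model is asynchronous); the run
#' is fully reproducible from the seed.
#'
#' @param inputs [sim_inputs()] object.
#' @param model [model_spec()] object.
#' @param n cells (mothers) per individual, default 1000.
#' @param n_individuals number of simulated individuals, default 4.
#' @param seed integer seed.
#' @param t_dip_min minutes from birth to the dip.
#' @param noise_mode asymmetry noise mode, see [divide_mothers()].
#' @return list with `cells` (one row per SLGC) and `summary`
#'   (`prop_acd`, `prop_acd_by_nb` over bins 1/2/3+, and per-fate mean/sd of
#'   size and dip concentration).
#' @export
run_simulation <- function(inputs, model, n = 1000, n_individuals = 4,
                           seed = NULL, t_dip_min = 200,
                           noise_mode = "multiplicative") {
  stopifnot(inherits(inputs, "sim_inputs"), inherits(model, "model_spec"))
  if (!is.null(seed)) set.seed(seed)
  cells <- do.call(rbind, lapply(seq_len(n_individuals), function(ind) {
    mothers <- init_mothers(inputs, n = n, individual = ind)
    slgcs <- divide_mothers(mothers, inputs, noise_mode = noise_mode)
    slgcs <- degrade_spch(slgcs, model$degradation_mode, inputs,
                          t_dip_min = t_dip_min)
    decide_fate(slgcs, model)
  }))
  list(cells = cells, summary = summarize_sim_cells(cells))
}

#' Summarize a simulated (or measured) SLGC population
#'
#' @param cells data.frame with columns `fate`, `neighbours`, `size`,
#'   `conc_dip`.
#' @return list with overall ACD proportion, ACD proportion by neighbour bin,
#'   and size / dip-concentration moments split by fate.
#' @export
summarize_sim_cells <- function(cells) {
  acd <- cells$fate == "ACD"
  bins <- bin_neighbours(cells$neighbours)
  prop_by_nb <- tapply(acd, bins, mean)
  stat <- function(x, f) c(mean = mean(x[f]), sd = stats::sd(x[f]))
  list(
    n = nrow(cells),
    prop_acd = mean(acd),
    prop_acd_by_nb = prop_by_nb,
    n_by_nb = as.numeric(table(bins)),
    size_by_fate = list(ACD = stat(cells$size, acd),
                        DIFF = stat(cells$size, !acd)),
    conc_by_fate = list(ACD = stat(cells$conc_dip, acd),
                        DIFF = stat(cells$conc_dip, !acd))
  )
}

#' Fit simulator input distributions to data
#'
#' Maximum-likelihood fits of the simulator's input distributions: gamma for
#' mother birth size and beta for the division asymmetry (both via
#' `fitdistrplus`), normal for mother SPCH intensity (sample moments),
#' Poisson for mother signaling-neighbour count (sample mean), and
#' exponential for the magnitude of the decay constant (mean |lambda| of
#' declining cells, i.e. lambda < 0, per neighbour class 1 vs 2+, on both the
#' per-cell and per-square-micron scales). Rising cells (lambda > 0) are
#' excluded from decay fitting, as an exponential is supported on positives.
#'
#' @param mothers data.frame with columns `size`, `intensity`, `neighbours`.
#' @param asymmetries numeric vector of asymmetry parameters in (0, 0.5).
#' @param decays data.frame with columns `lambda_per_h`, `neighbours`, and
#'   `size` (um^2, used for the per-square-micron scale).
#' @param min_per_class minimum declining cells required per neighbour class.
#' @param allometry allometric parameters to carry into the inputs (defaults
#'   to the packaged ln-ln relation).
#' @return list with `inputs` ([sim_inputs()]) and `diagnostics` (standard
#'   errors of every fitted parameter).
#' @export
fit_input_distributions <- function(mothers, asymmetries, decays,
                                    min_per_class = 5L,
                                    allometry = list(alpha = 1.82,
                                                     beta = 0.19,
                                                     sigma = 0.027)) {
  stopifnot(nrow(mothers) >= 20L)
  if (any(asymmetries <= 0 | asymmetries >= 0.5)) {
    stop("asymmetries must lie in (0, 0.5)", call. = FALSE)
  }
  gfit <- fitdistrplus::fitdist(as.numeric(mothers$size), "gamma",
                                method = "mle", lower = c(1e-8, 1e-8))
  gamma_shape <- unname(gfit$estimate["shape"])
  gamma_scale <- 1 / unname(gfit$estimate["rate"])
  bfit <- fitdistrplus::fitdist(asymmetries, "beta", method = "mle",
                                lower = c(1e-8, 1e-8))
  n_m <- nrow(mothers)
  norm_mean <- mean(mothers$intensity)
  norm_sd <- stats::sd(mothers$intensity)
  pois_mean <- mean(mothers$neighbours)

  declining <- decays[decays$lambda_per_h < 0, , drop = FALSE]
  cls <- neighbour_class(declining$neighbours)
  exp_fit <- function(x, label) {
    if (length(x) < min_per_class) {
      stop("insufficient decay observations in neighbour class '", label,
           "' (", length(x), " < ", min_per_class, ")", call. = FALSE)
    }
    m <- mean(x)
    c(mean = m, se = m / sqrt(length(x)))
  }
  d1 <- exp_fit(abs(declining$lambda_per_h[cls == "1"]), "1")
  d2 <- exp_fit(abs(declining$lambda_per_h[cls == "2+"]), "2+")
  per_um2 <- abs(declining$lambda_per_h) / declining$size
  u1 <- exp_fit(per_um2[cls == "1"], "1")
  u2 <- exp_fit(per_um2[cls == "2+"], "2+")

  inputs <- sim_inputs(
    size_gamma = c(shape = gamma_shape, scale = gamma_scale),
    spch_normal = c(mean = norm_mean, sd = norm_sd),
    neighbours_poisson = pois_mean,
    asymmetry_beta = c(shape1 = unname(bfit$estimate["shape1"]),
                       shape2 = unname(bfit$estimate["shape2"])),
    decay_mean_abs = c("1" = unname(d1["mean"]), "2+" = unname(d2["mean"])),
    decay_mean_abs_per_um2 = c("1" = unname(u1["mean"]),
                               "2+" = unname(u2["mean"])),
    allometry = allometry
  )
  diagnostics <- list(
    gamma_se = c(shape = unname(gfit$sd["shape"]),
                 rate = unname(gfit$sd["rate"])),
    beta_se = c(shape1 = unname(bfit$sd["shape1"]),
                shape2 = unname(bfit$sd["shape2"])),
    normal_se = c(mean = norm_sd / sqrt(n_m),
                  sd = norm_sd / sqrt(2 * (n_m - 1))),
    poisson_se = sqrt(pois_mean / n_m),
    decay_se = c("1" = unname(d1["se"]), "2+" = unname(d2["se"])),
    decay_per_um2_se = c("1" = unname(u1["se"]), "2+" = unname(u2["se"])),
    n_declining = nrow(declining),
    n_rising = nrow(decays) - nrow(declining)
  )
  list(inputs = inputs, diagnostics = diagnostics)
}

#' Write / read simulator inputs as JSON
#'
#' @param inputs [sim_inputs()] object.
#' @param path file path.
#' @return `path` (write) or a [sim_inputs()] object (read).
#' @export
write_sim_inputs <- function(inputs, path) {
  stopifnot(inherits(inputs, "sim_inputs"))
  jsonlite::write_json(unclass(inputs), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_sim_inputs
#' @export
read_sim_inputs <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_inputs(
    size_gamma = stats::setNames(unlist(raw$size_gamma),
                                 c("shape", "scale")),
    spch_normal = stats::setNames(unlist(raw$spch_normal), c("mean", "sd")),
    neighbours_poisson = unname(unlist(raw$neighbours_poisson)),
    asymmetry_beta = stats::setNames(unlist(raw$asymmetry_beta),
                                     c("shape1", "shape2")),
    decay_mean_abs = stats::setNames(unlist(raw$decay_mean_abs),
                                     c("1", "2+")),
    decay_mean_abs_per_um2 = stats::setNames(
      unlist(raw$decay_mean_abs_per_um2), c("1", "2+")),
    allometry = lapply(raw$allometry, unlist)
  )
}
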