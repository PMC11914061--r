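test_that("mother initialization respects rounding, positivity and the gamma mean", {
  inputs <- sim_inputs()
  a <- init_mothers(inputs, n = 1000, seed = 1)
  b <- init_mothers(inputs, n = 1000, seed = 1)
  expect_identical(a, b)
  expect_true(all(a$size >= 1))
  expect_true(all(a$size == round(a$size)))
  expect_true(all(a$intensity > 0))
  gamma_mean <- inputs$size_gamma[[1]] * inputs$size_gamma[[2]]
  gamma_se <- sqrt(inputs$size_gamma[[1]]) * inputs$size_gamma[[2]] / sqrt(1000)
  expect_lt(abs(mean(a$size) - gamma_mean), 3 * gamma_se)
})

test_that("asymmetric division conserves size and applies the inheritance rules", {
  inputs <- sim_inputs()
  mothers <- init_mothers(inputs, n = 2000, seed = 2)
  slgcs <- divide_mothers(mothers, inputs, seed = 3)
  # conservation is exact for every division
  expect_identical(slgcs$size + slgcs$meristemoid_size, slgcs$mother_size)
  # SLGC size follows the asymmetry definition a = 1 - SLGC/mother
  expect_equal(slgcs$size, round(slgcs$mother_size * (1 - slgcs$asymmetry)))
  expect_true(all(slgcs$asymmetry > 0 & slgcs$asymmetry < 0.5))
  # two-thirds SPCH inheritance: mother at 90 a.u. gives an SLGC at 60
  expect_equal(slgcs$intensity, (2 / 3) * slgcs$mother_intensity)
  expect_equal((2 / 3) * 90, 60)
  # one signaling neighbour more than the mother: 1 -> 2
  expect_equal(slgcs$neighbours, mothers$neighbours + 1L)
  # a pathological configuration trips the redraw guard
  bad <- sim_inputs(asymmetry_beta = c(shape1 = 2000, shape2 = 10))
  expect_error(divide_mothers(mothers[1:5, ], bad, max_redraws = 50L),
               "rejection")
})

test_that("SPCH degradation is monotone and follows the dip arithmetic", {
  inputs <- sim_inputs()
  mothers <- init_mothers(inputs, n = 5000, seed = 4)
  slgcs <- divide_mothers(mothers, inputs, seed = 5)
  for (mode in c("random", "neighbour", "size", "neighbour_and_size")) {
    deg <- degrade_spch(slgcs, mode, inputs, seed = 6)
    expect_true(all(deg$lambda_per_h <= 0))
    expect_true(all(deg$intensity_dip <= deg$intensity))
    expect_true(all(deg$intensity_dip > 0))
    # the dip arithmetic: I_dip = I_birth * exp(lambda * t_dip / 60)
    expect_equal(deg$intensity_dip,
                 deg$intensity * exp(deg$lambda_per_h * 200 / 60),
                 tolerance = 1e-12)
    expect_equal(deg$conc_dip, deg$intensity_dip / deg$nuclear_area,
                 tolerance = 1e-12)
  }
  # size mode arithmetic: a 0.002/um^2/h draw on a 100 um^2 cell gives
  # lambda = -0.2/h, i.e. dip intensity ~ 0.513 of birth
  expect_equal(exp(-0.002 * 100 * 200 / 60), 0.5134, tolerance = 1e-4)
  expect_error(degrade_spch(slgcs, "bogus", inputs), "arg")

  # neighbour mode: cells with 2+ signaling neighbours lose more SPCH
  deg <- degrade_spch(slgcs, "neighbour", inputs, seed = 7)
  frac <- deg$intensity_dip / deg$intensity
  expect_lt(mean(frac[deg$neighbours >= 2]), mean(frac[deg$neighbours == 1]))
})

test_that("fate decisions follow the logistic rule", {
  inputs <- sim_inputs()
  slgcs <- degrade_spch(divide_mothers(init_mothers(inputs, 10000, seed = 8),
                                       inputs),
                        "neighbour", inputs)
  sure <- decide_fate(slgcs, model_spec("neighbour",
                                        c(intercept = 500, size = 0)))
  expect_true(all(sure$fate == "ACD"))
  never <- decide_fate(slgcs, model_spec("neighbour",
                                         c(intercept = -500, size = 0)))
  expect_true(all(never$fate == "DIFF"))
  # intercept-only rule at p = 0.3: ACD fraction within 3 binomial SE
  coin <- decide_fate(slgcs, model_spec("neighbour",
                                        c(intercept = stats::qlogis(0.3),
                                          size = 0)),
                      seed = 9)
  expect_lt(abs(mean(coin$fate == "ACD") - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
  expect_equal(coin$fate_prob, rep(0.3, nrow(coin)))
  # interaction terms enter the linear predictor multiplicatively
  inter <- decide_fate(slgcs[1:5, ],
                       model_spec("neighbour",
                                  c(intercept = 0, `size:conc_dip` = 0.01)))
  expect_equal(inter$fate_prob,
               stats::plogis(0.01 * slgcs$size[1:5] * slgcs$conc_dip[1:5]))
})

test_that("the one-generation run is deterministic and conserves size", {
  inputs <- sim_inputs()
  model <- model_spec("neighbour", c(intercept = 1.6, size = -0.02,
                                     conc_dip = 0.25, neighbours = -0.8))
  a <- run_simulation(inputs, model, n = 500, n_individuals = 2, seed = 10)
  b <- run_simulation(inputs, model, n = 500, n_individuals = 2, seed = 10)
  expect_identical(a$cells, b$cells)
  expect_identical(a$cells$size + a$cells$meristemoid_size,
                   a$cells$mother_size)
  # a negative neighbour coefficient makes division decline with neighbours
  big <- run_simulation(inputs, model, n = 1000, n_individuals = 4, seed = 11)
  p <- big$summary$prop_acd_by_nb
  expect_true(p[["1"]] > p[["2"]] && p[["2"]] > p[["3+"]])
})

test_that("input-distribution fitting recovers known parameters", {
  set.seed(12)
  x <- rgamma(2000, shape = 2, scale = 40)
  mothers <- data.frame(size = round(x), intensity = rnorm(2000, 500, 150),
                        neighbours = rpois(2000, 1))
  asym <- rbeta(2000, 4, 12)
  asym <- asym[asym > 0 & asym < 0.5]
  decays <- data.frame(
    lambda_per_h = -rexp(2000, rate = 1 / 0.4),
    neighbours = mothers$neighbours + 1L,
    size = round(x)
  )
  fit <- fit_input_distributions(mothers, asym, decays)
  expect_lt(abs(fit$inputs$size_gamma[["shape"]] / 2 - 1), 0.1)
  # the Poisson MLE is the sample mean, exactly
  expect_identical(fit$inputs$neighbours_poisson, mean(mothers$neighbours))
  expect_identical(fit$inputs$spch_normal[["mean"]], mean(mothers$intensity))
  # class sizes below the floor raise an error naming the class
  few <- decays[c(which(decays$neighbours == 1)[1:3],
                  which(decays$neighbours >= 2)[1:50]), ]
  expect_error(fit_input_distributions(mothers, asym, few), "class '1'")
})

test_that("fitting closes the loop on a simulated cohort", {
  truth <- generator_truth()
  coh <- generate_cohort(truth, n_individuals = 4, n_cells = 1000, seed = 13)
  lat <- coh$latent
  mothers <- data.frame(size = lat$mother_size,
                        intensity = lat$mother_intensity,
                        neighbours = lat$mother_neighbours)
  decays <- data.frame(lambda_per_h = lat$lambda_per_h,
                       neighbours = coh$cells$n_sig_neighbours,
                       size = lat$size)
  fit <- fit_input_distributions(mothers, lat$asymmetry, decays)
  inp <- truth$inputs
  dg <- fit$diagnostics

  expect_lt(abs(fit$inputs$size_gamma[["shape"]] - inp$size_gamma[["shape"]]),
            3 * dg$gamma_se[["shape"]] + 0.05)  # +0.05 absorbs integer rounding
  expect_lt(abs(fit$inputs$spch_normal[["mean"]] - inp$spch_normal[["mean"]]),
            3 * dg$normal_se[["mean"]])
  expect_lt(abs(fit$inputs$spch_normal[["sd"]] - inp$spch_normal[["sd"]]),
            3 * dg$normal_se[["sd"]])
  expect_lt(abs(fit$inputs$neighbours_poisson - inp$neighbours_poisson),
            3 * dg$poisson_se)
  expect_lt(abs(fit$inputs$decay_mean_abs[["1"]] - inp$decay_mean_abs[["1"]]),
            3 * dg$decay_se[["1"]])
  expect_lt(abs(fit$inputs$decay_mean_abs[["2+"]] - inp$decay_mean_abs[["2+"]]),
            3 * dg$decay_se[["2+"]])

  # the beta asymmetry closes the loop when division noise is off (with the
  # noise factor on, the observed asymmetries are no longer beta distributed)
  slgcs <- divide_mothers(init_mothers(truth$inputs, 3000, seed = 14),
                          truth$inputs, noise_mode = "off")
  fit2 <- fit_input_distributions(mothers, slgcs$asymmetry, decays)
  expect_lt(abs(fit2$inputs$asymmetry_beta[["shape1"]] -
                  inp$asymmetry_beta[["shape1"]]),
            3 * fit2$diagnostics$beta_se[["shape1"]] + 0.1)

  # per-square-micron decay means close the loop under a size-stratified mode
  truth_sz <- generator_truth(model = model_spec(
    "neighbour_and_size", c(intercept = 1.6, conc_dip = 0.25)))
  coh2 <- generate_cohort(truth_sz, n_individuals = 4, n_cells = 1000,
                          seed = 15)
  decays2 <- data.frame(lambda_per_h = coh2$latent$lambda_per_h,
                        neighbours = coh2$cells$n_sig_neighbours,
                        size = coh2$latent$size)
  fit3 <- fit_input_distributions(mothers, lat$asymmetry, decays2)
  for (cl in c("1", "2+")) {
    expect_lt(abs(fit3$inputs$decay_mean_abs_per_um2[[cl]] -
                    inp$decay_mean_abs_per_um2[[cl]]),
              3 * fit3$diagnostics$decay_per_um2_se[[cl]])
  }
})

test_that("simulator inputs round-trip through JSON", {
  inp <- sim_inputs()
  path <- withr::local_tempfile(fileext = ".json")
  write_sim_inputs(inp, path)
  back <- read_sim_inputs(path)
  expect_equal(back$size_gamma, inp$size_gamma)
  expect_equal(back$decay_mean_abs, inp$decay_mean_abs)
  expect_equal(back$allometry, inp$allometry)
})
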