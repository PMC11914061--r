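test_that("Welch's t-test matches theory and the stats reference", {
  r <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  # means one pooled SD apart at n = 100 per group: |t| = 1/sqrt(2/100)
  x <- as.numeric(scale(rnorm(100))) + 1  # mean exactly 1, sd exactly 1
  y <- as.numeric(scale(rnorm(100)))      # mean exactly 0, sd exactly 1
  expect_equal(abs(welch_t_test(x, y)$t), 1 / sqrt(2 / 100),
               tolerance = 1e-10)

  expect_error(welch_t_test(rep(1, 5), rep(2, 5)), "zero variance")

  # parity with stats::t.test on 100 random sample pairs
  set.seed(21)
  for (i in 1:100) {
    x <- rnorm(sample(5:60, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:60, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    mine <- welch_t_test(x, y)
    ref <- stats::t.test(x, y)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-8)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-8)
  }
})

test_that("TOST declares equivalence for identical samples and not without power", {
  set.seed(22)
  x <- rnorm(200)
  y <- rnorm(200)
  r <- tost_equivalence(x, y)  # bound defaults to one SD of x
  expect_true(r$equivalent)
  expect_lt(r$p_lower, 1e-6)
  expect_lt(r$p_upper, 1e-6)

  # n = 2 per sample with a zero bound: no power, verdict false
  r0 <- tost_equivalence(c(1, 2), c(1.5, 2.5), bound = 0)
  expect_false(r0$equivalent)
  # the verdict is exactly "both one-sided p below alpha"
  expect_identical(r$equivalent, r$p_lower < 0.05 && r$p_upper < 0.05)
})

test_that("SSE over neighbour bins is the sum of squared proportion gaps", {
  p <- c("1" = 0.6, "2" = 0.4, "3+" = 0.2)
  expect_equal(sse_by_neighbours(p, p), 0)
  q <- p; q[["2"]] <- 0.5
  expect_equal(sse_by_neighbours(p, q), 0.01)
  r <- p + c(0.1, 0.2, 0.05)
  expect_equal(sse_by_neighbours(r, p), 0.1^2 + 0.2^2 + 0.05^2)
  expect_error(sse_by_neighbours(p[1:2], p), "3\\+")
})

test_that("AICc reproduces the printed small-sample formula", {
  # independent arithmetic: N log(SSE/N) + 2(k+1) + (2k^2+2k)/(N-k-1)
  expect_equal(aicc(1.0, 262, 3), -1450.813, tolerance = 1e-3)
  expect_equal(aicc(262, 262, 3), 2 * 4 + 24 / 258)  # log term vanishes
  # penalty is strictly increasing in k at fixed SSE
  ks <- 1:8
  vals <- vapply(ks, function(k) aicc(0.5, 262, k), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(aicc(0, 262, 3), "positive")
  expect_error(aicc(1, 4, 3), "N > k")
})

test_that("model evaluation composes its three steps faithfully", {
  truth <- generator_truth()
  inputs <- truth$inputs
  model <- truth$model
  data_run <- run_simulation(inputs, model, n = 250, n_individuals = 4,
                             seed = 31)
  sim_run <- run_simulation(inputs, model, n = 1000, n_individuals = 4,
                            seed = 32)
  ev <- evaluate_model(sim_run$cells, data_run$cells, k = model$k,
                       model_id = "self")
  # compositional identity: SSE and AICc fields reproduce the primitives
  expect_equal(ev$sse_total, sum(ev$sse_by_individual))
  expect_equal(ev$aicc, aicc(ev$sse_total, nrow(data_run$cells), model$k))

  # sizes shifted by three data SDs must fail the size TOST gate
  shifted <- sim_run$cells
  shifted$size <- shifted$size + 3 * stats::sd(data_run$cells$size)
  ev_shift <- evaluate_model(shifted, data_run$cells, k = model$k)
  expect_false(ev_shift$tost$size_ACD$equivalent)
  expect_false(ev_shift$tost$size_DIFF$equivalent)
  expect_false(ev_shift$step1_pass)

  # an empty fate class is a recorded step failure, not an exception
  all_acd <- sim_run$cells
  all_acd$fate <- "ACD"
  ev_deg <- evaluate_model(all_acd, data_run$cells, k = model$k)
  expect_false(ev_deg$step1_pass)
  expect_false(ev_deg$gate_pass)
})

test_that("simulations from the data's own truth pass the TOST gates", {
  truth <- generator_truth()
  ok <- vapply(1:20, function(s) {
    data_run <- run_simulation(truth$inputs, truth$model, n = 250,
                               n_individuals = 4, seed = sub_seed(33, s))
    sim_run <- run_simulation(truth$inputs, truth$model, n = 1000,
                              n_individuals = 4, seed = sub_seed(34, s))
    ev <- evaluate_model(sim_run$cells, data_run$cells, k = truth$model$k)
    ev$step1_pass
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("sweeping candidates ranks the generating model first", {
  truth <- generator_truth()
  wins <- vapply(1:20, function(s) {
    data_run <- run_simulation(truth$inputs, truth$model, n = 250,
                               n_individuals = 4, seed = sub_seed(35, s))
    cand <- list(truth$model,
                 model_spec("random", c(intercept = stats::qlogis(0.4),
                                        conc_dip = 0), id = "intercept-only"))
    tab <- sweep_models(truth$inputs, cand, data_run$cells, n = 1000,
                        n_individuals = 4, seed = sub_seed(36, s))
    tab$rank[tab$model_id == "truth"] == 1L
  }, logical(1))
  expect_gte(mean(wins), 0.9)

  # identical candidates: deterministic tie-break by declaration order
  data_run <- run_simulation(truth$inputs, truth$model, n = 250,
                             n_individuals = 4, seed = 37)
  same <- list(model_spec("neighbour", truth$model$coefficients, id = "A"),
               model_spec("neighbour", truth$model$coefficients, id = "B"))
  tab <- sweep_models(truth$inputs, same, data_run$cells, n = 500,
                      n_individuals = 4, seed = 38)
  expect_identical(tab$model_id[order(tab$rank)], c("A", "B"))
  expect_equal(tab$aicc[1], tab$aicc[2])  # same seed, same simulation
})

test_that("proportion tests wrap the continuity-corrected references", {
  r <- two_proportion_test(50, 100, 50, 100)
  expect_equal(r$chisq, 0)
  expect_equal(r$p, 1)
  # Yates arithmetic oracle for (30/50) vs (10/50)
  k1 <- 30; n1 <- 50; k2 <- 10; n2 <- 50
  p <- (k1 + k2) / (n1 + n2)
  e <- c(n1 * p, n1 * (1 - p), n2 * p, n2 * (1 - p))
  o <- c(k1, n1 - k1, k2, n2 - k2)
  yates <- sum((abs(o - e) - 0.5)^2 / e)
  r2 <- two_proportion_test(30, 50, 10, 50)
  expect_equal(r2$chisq, yates, tolerance = 1e-10)
  expect_equal(r2$chisq, 15.04167, tolerance = 1e-5)
  expect_error(two_proportion_test(5, 0, 1, 10), ">= 1")
  expect_error(two_proportion_test(11, 10, 1, 10), "0 <= k")
})

test_that("the trend test detects ordered proportions and ignores orientation", {
  flat <- suppressWarnings(trend_in_proportions_test(c(20, 20, 20), c(100, 100, 100)))
  expect_lt(flat$chisq, 1e-10)
  expect_equal(flat$p, 1, tolerance = 1e-6)

  up <- suppressWarnings(trend_in_proportions_test(c(10, 30, 50), c(100, 100, 100)))
  expect_lt(up$p, 0.001)
  # closed-form Cochran-Armitage statistic with scores 1,2,3
  k <- c(10, 30, 50); n <- c(100, 100, 100); s <- 1:3
  pbar <- sum(k) / sum(n)
  num <- sum(k * s) - sum(n * s) * pbar
  den <- pbar * (1 - pbar) * (sum(n * s^2) - sum(n * s)^2 / sum(n))
  expect_equal(up$chisq, num^2 / den, tolerance = 1e-8)

  down <- suppressWarnings(trend_in_proportions_test(rev(c(10, 30, 50)), n))
  expect_equal(up$p, down$p, tolerance = 1e-12)
  expect_error(trend_in_proportions_test(c(1, 2), c(10, 10)), ">= 3")
})

test_that("Holm adjustment is step-down with monotonicity", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  set.seed(39)
  p <- runif(20)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
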