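# Three-step statistical evaluation of candidate simulator models:
# (1) TOST equivalence of simulated vs observed sizes and [SPCH] within each
# fate class, (2) Welch t-tests for divided-vs-differentiated differences,
# (3) SSE on the proportion divided by signaling-neighbour bin, ranked by
# AICc. Plus the proportion-test utilities used throughout the analysis.

#' Welch's two-sample t-test
#'
#' Unpooled-variance t statistic with Satterthwaite degrees of freedom,
#' testing `mean(x) - mean(y) = mu`. Implemented from the formulas (it is the
#' building block of the TOST procedure); parity with [stats::t.test()] is
#' checked in the test suite.
#'
#' @param x,y numeric samples (each n >= 2).
#' @param mu difference under the null (default 0).
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return list with `t`, `df`, `p`, `estimate` (mean difference), `se`.
#' @export
welch_t_test <- function(x, y, mu = 0,
                         alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  nx <- length(x)
  ny <- length(y)
  if (nx < 2 || ny < 2) stop("each sample needs n >= 2", call. = FALSE)
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    stop("degenerate: zero variance in both samples", call. = FALSE)
  }
  se <- sqrt(vx / nx + vy / ny)
  df <- se^4 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  t_stat <- (mean(x) - mean(y) - mu) / se
  p <- switch(alternative,
              two.sided = 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE),
              less = stats::pt(t_stat, df),
              greater = stats::pt(t_stat, df, lower.tail = FALSE))
  list(t = t_stat, df = df, p = p, estimate = mean(x) - mean(y), se = se)
}

#' TOST equivalence test
#'
#' Two one-sided Welch t-tests of the mean difference against the equivalence
#' bounds -bound and +bound: equivalence is declared at level `alpha` when
#' both one-sided nulls (difference beyond a bound) are rejected. The default
#' bound is one standard deviation of the reference sample `x` (the
#' experimental data in model selection), matching an effect size of one SD.
#'
#' @param x reference sample (its SD sets the default bound).
#' @param y comparison sample.
#' @param bound equivalence bound on the mean difference (default `sd(x)`).
#' @param alpha significance level (default 0.05).
#' @return list with `bound`, `t_lower`, `p_lower` (H0: diff <= -bound),
#'   `t_upper`, `p_upper` (H0: diff >= +bound), `df`, `equivalent`.
#' @export
tost_equivalence <- function(x, y, bound = NULL, alpha = 0.05) {
  if (is.null(bound)) bound <- stats::sd(x)
  upper <- welch_t_test(x, y, mu = bound, alternative = "less")
  lower <- welch_t_test(x, y, mu = -bound, alternative = "greater")
  list(bound = bound,
       t_lower = lower$t, p_lower = lower$p,
       t_upper = upper$t, p_upper = upper$p,
       df = upper$df,
       equivalent = lower$p < alpha && upper$p < alpha)
}

#' Sum of squared errors over neighbour bins
#'
#' `sum over bins of (p_sim - p_data)^2` for the proportion of cells that
#' divided in each signaling-neighbour bin (1, 2, 3+).
#'
#' @param p_sim,p_data named numeric vectors of proportions; both must define
#'   every bin in `bins`.
#' @param bins bin labels (default `c("1", "2", "3+")`).
#' @return the SSE.
#' @export
sse_by_neighbours <- function(p_sim, p_data, bins = c("1", "2", "3+")) {
  for (b in bins) {
    if (!b %in% names(p_sim) || is.na(p_sim[[b]])) {
      stop("simulated proportions missing bin '", b, "'", call. = FALSE)
    }
    if (!b %in% names(p_data) || is.na(p_data[[b]])) {
      stop("data proportions missing bin '", b, "'", call. = FALSE)
    }
  }
  sum((unlist(p_sim[bins]) - unlist(p_data[bins]))^2)
}

#' Corrected Akaike information criterion from an SSE
#'
#' `AICc = N * log(SSE / N) + 2 (k + 1) + (2 k^2 + 2 k) / (N - k - 1)` with
#' the natural logarithm; `N` is the total number of cells in the data and
#' `k` the number of parameters of the fate-determining logistic model,
#' excluding the intercept.
#'
#' @param sse_total total sum of squared errors (> 0).
#' @param N total number of cells in the data.
#' @param k number of non-intercept model parameters.
#' @return the AICc value.
#' @export
aicc <- function(sse_total, N, k) {
  if (sse_total <= 0) stop("sse_total must be positive", call. = FALSE)
  if (N <= k + 1) stop("need N > k + 1", call. = FALSE)
  N * log(sse_total / N) + 2 * (k + 1) + (2 * k^2 + 2 * k) / (N - k - 1)
}

prop_acd_by_bin <- function(cells, fate_col, nb_col) {
  bins <- bin_neighbours(cells[[nb_col]])
  tapply(cells[[fate_col]] == "ACD", bins, mean)
}

# fate / neighbour column names for simulated vs data tables
cells_columns <- function(cells) {
  if ("fate" %in% names(cells)) {
    list(fate = "fate", nb = "neighbours", size = "size", conc = "conc_dip")
  } else {
    list(fate = "behaviour", nb = "n_sig_neighbours", size = "birth_area_um2",
         conc = "conc_at_dip")
  }
}

#' Evaluate one candidate model against data
#'
#' The three-step procedure for a single candidate. Step 1: TOST equivalence
#' (bound = one data SD) of simulated vs observed cell sizes and [SPCH] at
#' the dip, separately for dividing and differentiating cells (four
#' comparisons). Step 2: Welch t-tests of divided-vs-differentiated
#' differences in size and [SPCH] within the simulation and within the data;
#' the simulation passes when its significance pattern (at 0.05) matches the
#' data's. Step 3: the proportion divided per signaling-neighbour bin is
#' compared per individual, the squared errors summed across individuals, and
#' AICc computed with N = number of data cells. An empty fate class in the
#' simulation is recorded as a step failure, not an error.
#'
#' Simulated cells use columns `fate`, `neighbours`, `size`, `conc_dip`
#' (as returned by [run_simulation()]); data cells may instead carry the
#' measured-cohort columns `behaviour`, `n_sig_neighbours`, `birth_area_um2`,
#' `conc_at_dip`.
#'
#' @param sim_cells simulated SLGC table.
#' @param data_cells observed (or synthetic reference) SLGC table.
#' @param k number of non-intercept fate-model parameters.
#' @param model_id identifier carried into the result.
#' @param alpha significance level for both steps (default 0.05).
#' @return list of class `selection_result`: TOST results, t-test results,
#'   `pattern_match`, `sse_by_individual`, `sse_total`, `aicc`, `gate_pass`.
#' @export
evaluate_model <- function(sim_cells, data_cells, k, model_id = "model",
                           alpha = 0.05) {
  sc <- cells_columns(sim_cells)
  dc <- cells_columns(data_cells)
  sim_fate <- sim_cells[[sc$fate]]
  data_fate <- data_cells[[dc$fate]]

  tost <- list()
  step1_pass <- TRUE
  step1_complete <- TRUE
  for (cls in c("ACD", "DIFF")) {
    for (feat in c("size", "conc")) {
      key <- paste(feat, cls, sep = "_")
      d <- data_cells[[dc[[feat]]]][data_fate == cls]
      s <- sim_cells[[sc[[feat]]]][sim_fate == cls]
      if (length(s) < 2 || length(d) < 2) {
        tost[[key]] <- NA
        step1_complete <- FALSE
        next
      }
      res <- tost_equivalence(d, s, alpha = alpha)
      tost[[key]] <- res
      step1_pass <- step1_pass && res$equivalent
    }
  }
  step1_pass <- step1_pass && step1_complete

  welch_pair <- function(cells, cols, feat) {
    f <- cells[[cols$fate]]
    a <- cells[[cols[[feat]]]][f == "ACD"]
    b <- cells[[cols[[feat]]]][f == "DIFF"]
    if (length(a) < 2 || length(b) < 2) return(NULL)
    welch_t_test(a, b)
  }
  ttests <- list()
  pattern_match <- TRUE
  step2_complete <- TRUE
  for (feat in c("size", "conc")) {
    sim_t <- welch_pair(sim_cells, sc, feat)
    dat_t <- welch_pair(data_cells, dc, feat)
    ttests[[feat]] <- list(sim = sim_t, data = dat_t)
    if (is.null(sim_t) || is.null(dat_t)) {
      step2_complete <- FALSE
    } else {
      pattern_match <- pattern_match &&
        ((sim_t$p < alpha) == (dat_t$p < alpha))
    }
  }
  step2_pass <- pattern_match && step2_complete

  # step 3: per-individual SSE on proportion divided by neighbour bin;
  # simulated individual i is compared with data individual i (sorted order).
  # With unequal individual counts the populations are pooled into one term.
  sim_inds <- sort(unique(sim_cells$individual))
  dat_inds <- sort(unique(data_cells$individual))
  sse_one <- function(sim_sub, dat_sub) {
    sse_by_neighbours(as.list(prop_acd_by_bin(sim_sub, sc$fate, sc$nb)),
                      as.list(prop_acd_by_bin(dat_sub, dc$fate, dc$nb)))
  }
  if (length(sim_inds) == length(dat_inds)) {
    sse_ind <- vapply(seq_along(sim_inds), function(i) {
      sse_one(sim_cells[sim_cells$individual == sim_inds[i], , drop = FALSE],
              data_cells[data_cells$individual == dat_inds[i], , drop = FALSE])
    }, numeric(1))
  } else {
    sse_ind <- sse_one(sim_cells, data_cells)
  }
  sse_total <- sum(sse_ind)
  # a literally perfect fit (SSE = 0) ranks ahead of everything
  aicc_val <- if (sse_total > 0) aicc(sse_total, N = nrow(data_cells), k = k)
              else -Inf

  structure(list(model_id = model_id, k = k,
                 tost = tost, step1_pass = step1_pass,
                 ttests = ttests, pattern_match = pattern_match,
                 step2_pass = step2_pass,
                 sse_by_individual = sse_ind, sse_total = sse_total,
                 aicc = aicc_val,
                 gate_pass = step1_pass && step2_pass),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: gate %s, SSE = %.4f, AICc = %.2f (k = %d)\n",
              x$model_id, if (x$gate_pass) "pass" else "FAIL",
              x$sse_total, x$aicc, x$k))
  invisible(x)
}

#' Simulate and rank candidate models
#'
#' Runs the one-generation simulation for every candidate [model_spec()]
#' (each from the same seed, so the ranking does not depend on candidate
#' order), evaluates each against the data with [evaluate_model()], and
#' ranks: candidates passing the step-1/step-2 gates come first in ascending
#' AICc, then failers in ascending AICc; remaining ties keep declaration
#' order.
#'
#' @param inputs [sim_inputs()] used for every candidate.
#' @param models list of [model_spec()] candidates (>= 2).
#' @param data_cells observed (or synthetic reference) SLGC table.
#' @param n,n_individuals simulation size per candidate.
#' @param seed integer seed (reused for each candidate).
#' @param alpha significance level for the gates.
#' @return data.frame with one row per candidate: `model_id`, `gate_pass`,
#'   `sse_total`, `k`, `aicc`, `rank`; the full [evaluate_model()] results in
#'   `attr(, "results")`.
#' @export
sweep_models <- function(inputs, models, data_cells, n = 1000,
                         n_individuals = 4, seed = 1, alpha = 0.05) {
  if (length(models) < 2) stop("need >= 2 candidate models", call. = FALSE)
  results <- lapply(seq_along(models), function(i) {
    m <- models[[i]]
    sim <- run_simulation(inputs, m, n = n, n_individuals = n_individuals,
                          seed = seed)
    evaluate_model(sim$cells, data_cells, k = m$k, model_id = m$id,
                   alpha = alpha)
  })
  tab <- data.frame(
    model_id = vapply(results, `[[`, character(1), "model_id"),
    gate_pass = vapply(results, `[[`, logical(1), "gate_pass"),
    sse_total = vapply(results, `[[`, numeric(1), "sse_total"),
    k = vapply(results, `[[`, numeric(1), "k"),
    aicc = vapply(results, `[[`, numeric(1), "aicc"),
    stringsAsFactors = FALSE
  )
  ord <- order(!tab$gate_pass, tab$aicc, seq_len(nrow(tab)))
  tab$rank <- NA_integer_
  tab$rank[ord] <- seq_len(nrow(tab))
  attr(tab, "results") <- results
  tab
}

#' Two-sample test for equality of proportions
#'
#' Chi-squared test on the 2x2 table with Yates continuity correction
#' (wraps [stats::prop.test()]).
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @return list with `chisq`, `p`, `estimate` (the two proportions).
#' @export
two_proportion_test <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1) stop("group sizes must be >= 1", call. = FALSE)
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) {
    stop("need 0 <= k <= n in both groups", call. = FALSE)
  }
  res <- stats::prop.test(c(k1, k2), c(n1, n2), correct = TRUE)
  list(chisq = unname(res$statistic), p = res$p.value,
       estimate = unname(res$estimate))
}

#' Chi-squared test for trend in proportions
#'
#' Cochran-Armitage trend test with equally spaced scores across ordered
#' groups (wraps [stats::prop.trend.test()]).
#'
#' @param successes vector of successes per ordered group (>= 3 groups).
#' @param totals matching vector of group sizes.
#' @return list with `chisq` and `p`.
#' @export
trend_in_proportions_test <- function(successes, totals) {
  if (length(successes) < 3) stop("need >= 3 ordered groups", call. = FALSE)
  stopifnot(length(successes) == length(totals))
  res <- stats::prop.trend.test(successes, totals)
  list(chisq = unname(res$statistic), p = res$p.value)
}

#' Holm-Bonferroni p-value adjustment
#'
#' Step-down Holm adjustment with monotonicity enforcement (wraps
#' [stats::p.adjust()]).
#'
#' @param p vector of raw p-values in [0, 1].
#' @return adjusted p-values.
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "holm")
}
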