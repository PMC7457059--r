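# Intra-observer repeatability study: operator-perturbed trials, per-cell
# ordinary least squares of mean strain on trial index, and the repeatable
# fraction at a chosen alpha.

#' Run repeated operator-perturbed trials of the load battery
#'
#' Emulates the repeated manual construction of the model: for each trial
#' the spring attachment landmarks are re-placed with Gaussian operator
#' noise, the model rebuilt (rest lengths from the trial's own geometry),
#' and the full scenario battery solved and averaged into the 48-cell grid.
#'
#' @param base_lm Canonical `pelvis_landmarks`.
#' @param noise An [operator_noise()] model (its seed drives the per-trial
#'   seeds unless `seeds` is given).
#' @param n_trials Number of trials (default 5, minimum 2).
#' @param seeds Optional integer vector of per-trial seeds.
#' @param scenarios Scenario battery (default [default_scenarios()]).
#' @param materials,config,solver_opts Passed through to [build_model()] and
#'   [solve_static()].
#' @param perturb_first Perturb the first trial too (default TRUE; set
#'   FALSE to keep trial 1 at the unperturbed canonical geometry).
#' @return A stacked strain grid tibble (`trial`, `scenario`, `group`,
#'   `side`, `mean_strain`, `n_springs`) with solver failures, if any, in
#'   attribute `failures`.
#' @export
run_trials <- function(base_lm, noise, n_trials = 5, seeds = NULL,
                       scenarios = default_scenarios(),
                       materials = default_materials(), config = list(),
                       solver_opts = list(), perturb_first = TRUE) {
  stopifnot(inherits(base_lm, "pelvis_landmarks"),
            inherits(noise, "sij_noise_model"))
  if (n_trials < 2) {
    abort("`n_trials` must be at least 2.",
          class = "sijstrain_invalid_parameter")
  }
  if (is.null(seeds)) {
    seeds <- withr_seed(noise$seed, sample.int(.Machine$integer.max, n_trials))
  }
  if (length(seeds) != n_trials) {
    abort("one seed per trial is required.",
          class = "sijstrain_invalid_parameter")
  }
  grids <- vector("list", n_trials)
  failures <- character()
  for (t in seq_len(n_trials)) {
    lm_t <- if (t == 1L && !perturb_first) base_lm else {
      perturb_landmarks(base_lm, operator_noise(noise$sd, seeds[t], noise$targets))
    }
    model_t <- build_model(lm_t, materials, config)
    recs <- run_battery(model_t, scenarios, solver_opts)
    fl <- attr(recs, "failures")
    if (length(fl)) failures <- c(failures, paste0("trial ", t, ": ", fl))
    grids[[t]] <- average_by_group(recs) %>% mutate(trial = t, .before = 1)
  }
  out <- bind_rows(grids)
  attr(out, "failures") <- failures
  attr(out, "seeds") <- seeds
  out
}

#' Closed-form OLS slope test for a per-trial strain series
#'
#' Ordinary least squares of the cell's mean strain on the trial index,
#' with the t-based two-sided p-value and confidence interval for the
#' slope (n - 2 degrees of freedom). Degenerate series are flagged: a
#' constant series (`zero_variance`) has slope 0 and an undefined
#' t-statistic and is treated as repeatable by convention; an exact
#' nonzero-slope line (`perfect_fit`) has zero residual variance and is
#' treated as p = 0 (not repeatable).
#'
#' @param values Numeric per-trial responses (length >= 2).
#' @param trial_index Regressor (default 1..n).
#' @param conf_level Confidence level for the slope interval.
#' @return One-row tibble: `n`, `slope`, `intercept`, `se`, `ci_lower`,
#'   `ci_upper`, `statistic`, `p_value`, `zero_variance`, `perfect_fit`.
#' @export
ols_slope <- function(values, trial_index = seq_along(values),
                      conf_level = 0.95) {
  n <- length(values)
  if (n < 2 || length(trial_index) != n) {
    abort("at least 2 paired observations are required.",
          class = "sijstrain_insufficient_data")
  }
  x <- as.numeric(trial_index); y <- as.numeric(values)
  Sxx <- sum((x - mean(x))^2)
  Sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- Sxy / Sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- sum((y - intercept - slope * x)^2)
  df <- n - 2L
  zero_var <- max(y) == min(y)
  scale2 <- max(sum(y^2), .Machine$double.xmin)
  perfect <- !zero_var && rss <= 1e-20 * scale2 && slope != 0
  if (zero_var) {
    se <- 0; stat <- NA_real_; p <- NA_real_; lo <- 0; hi <- 0
    slope <- 0; intercept <- y[1]
  } else if (df == 0L || perfect) {
    se <- 0; stat <- Inf; p <- if (perfect) 0 else NA_real_
    lo <- slope; hi <- slope
  } else {
    se <- sqrt(rss / df / Sxx)
    stat <- slope / se
    p <- 2 * pt(-abs(stat), df)
    tq <- qt(1 - (1 - conf_level) / 2, df)
    lo <- slope - tq * se; hi <- slope + tq * se
  }
  tibble(n = n, slope = slope, intercept = intercept, se = se,
         ci_lower = lo, ci_upper = hi, statistic = stat, p_value = p,
         zero_variance = zero_var, perfect_fit = perfect)
}

#' Repeatability report over the 48-cell grid
#'
#' Runs one slope regression per (scenario, ligament group, side) cell of a
#' stacked multi-trial strain grid and counts the repeatable cells: those
#' failing to reject the zero-slope null at `alpha` (constant cells count
#' as repeatable by convention; exact nonzero-slope cells as not
#' repeatable).
#'
#' @param stacked Stacked grid from [run_trials()] (columns `trial`,
#'   `scenario`, `group`, `side`, `mean_strain`).
#' @param alpha Significance level of the slope test (default 0.05).
#' @return A `sij_repeatability` object: `results` (one row per cell with
#'   the regression summary and `repeatable` flag), `alpha`, `n_trials`,
#'   `n_cells`, `n_repeatable`, `fraction_repeatable`.
#' @export
repeatability_report <- function(stacked, alpha = 0.05) {
  need <- c("trial", "scenario", "group", "side", "mean_strain")
  if (!all(need %in% names(stacked))) {
    abort("`stacked` must carry trial, scenario, group, side, mean_strain.",
          class = "sijstrain_invalid_parameter")
  }
  counts <- stacked %>% count(.data$scenario, .data$group, .data$side)
  n_trials <- length(unique(stacked$trial))
  if (n_trials < 2) {
    abort("at least 2 trials are required.",
          class = "sijstrain_insufficient_data")
  }
  if (any(counts$n != n_trials)) {
    missing <- counts %>% filter(.data$n != n_trials)
    abort(paste0("incomplete grids: ", nrow(missing), " cell(s) lack trials."),
          class = "sijstrain_aggregation_error")
  }
  results <- stacked %>%
    arrange(.data$scenario, .data$group, .data$side, .data$trial) %>%
    group_by(.data$scenario, .data$group, .data$side) %>%
    summarise(ols_slope(.data$mean_strain, .data$trial), .groups = "drop") %>%
    mutate(repeatable = .data$zero_variance |
             (!.data$perfect_fit & !is.na(.data$p_value) & .data$p_value >= alpha))
  structure(
    list(results = results, alpha = alpha, n_trials = n_trials,
         n_cells = nrow(results),
         n_repeatable = sum(results$repeatable),
         fraction_repeatable = mean(results$repeatable)),
    class = "sij_repeatability"
  )
}

#' @export
print.sij_repeatability <- function(x, ...) {
  cat(sprintf("Repeatability over %d cells (%d trials, alpha = %g): %d/%d repeatable (%.1f%%)\n",
              x$n_cells, x$n_trials, x$alpha, x$n_repeatable, x$n_cells,
              100 * x$fraction_repeatable))
  invisible(x)
}

#' @rdname repeatability_report
#' @param x,object A `sij_repeatability`.
#' @param ... Unused.
#' @export
tidy.sij_repeatability <- function(x, ...) x$results

#' @rdname repeatability_report
#' @export
glance.sij_repeatability <- function(x, ...) {
  tibble(n_cells = x$n_cells, n_trials = x$n_trials, alpha = x$alpha,
         n_repeatable = x$n_repeatable,
         fraction_repeatable = x$fraction_repeatable)
}

#' @rdname repeatability_report
#' @export
autoplot.sij_repeatability <- function(object, ...) {
  ggplot(object$results,
         aes(x = factor(.data$scenario), y = .data$slope,
             ymin = .data$ci_lower, ymax = .data$ci_upper,
             colour = .data$repeatable)) +
    geom_point() +
    ggplot2::geom_errorbar(width = 0.25) +
    facet_grid(group ~ side) +
    labs(x = "load scenario", y = "slope (strain per trial)",
         colour = "repeatable") +
    theme_minimal()
}
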