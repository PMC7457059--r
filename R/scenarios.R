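# The eight-scenario load battery and per-ligament-group strain averaging.

#' The default eight-scenario load battery
#'
#' The battery applies eight in-plane force loads (N) to the sacral load
#' point: pure +/-y, pure +/-x, and the four diagonals at 141.4 N per
#' component (200 cos 45 deg, rounded to one decimal and stored exactly as
#' printed). x is lateral (right positive), y is dorsal positive.
#'
#' @return A tibble with columns `scenario` (1..8), `fx`, `fy` (N).
#' @export
default_scenarios <- function() {
  tibble(
    scenario = 1:8,
    fx = c(0, 0, 200, -200, 141.4, -141.4, 141.4, -141.4),
    fy = c(200, -200, 0, 0, 141.4, -141.4, -141.4, 141.4)
  )
}

#' Run the load battery on a model
#'
#' Solves static equilibrium for each scenario row and returns per-spring
#' strain records. A scenario whose solve fails is recorded with `converged
#' = FALSE` and NA strains (tagged in the `failures` attribute), never
#' silently dropped.
#'
#' @param model A `sij_model`.
#' @param scenarios Scenario tibble (default [default_scenarios()]).
#' @param opts Solver options passed to [solve_static()].
#' @return Tibble with one row per spring per scenario: `scenario`, `id`,
#'   `group`, `side`, `strain`, `force`, `converged`. The list of
#'   `sij_equilibrium` results is attached as attribute `results`.
#' @export
run_battery <- function(model, scenarios = default_scenarios(), opts = list()) {
  stopifnot(inherits(model, "sij_model"))
  scenarios <- as_tibble(scenarios)
  if (!all(c("scenario", "fx", "fy") %in% names(scenarios))) {
    abort("`scenarios` needs columns scenario, fx, fy.",
          class = "sijstrain_invalid_parameter")
  }
  results <- vector("list", nrow(scenarios))
  failures <- character()
  recs <- vector("list", nrow(scenarios))
  for (i in seq_len(nrow(scenarios))) {
    row <- scenarios[i, ]
    res <- tryCatch(solve_static(model, row, opts), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures,
                    sprintf("scenario %s: %s", row$scenario, conditionMessage(res)))
      recs[[i]] <- model$springs %>%
        select("id", "group", "side") %>%
        mutate(scenario = row$scenario, strain = NA_real_, force = NA_real_,
               converged = FALSE)
    } else {
      results[[i]] <- res
      recs[[i]] <- res$springs %>%
        select("id", "group", "side", "strain", "force") %>%
        mutate(scenario = row$scenario, converged = res$converged)
    }
  }
  out <- bind_rows(recs) %>%
    select("scenario", "id", "group", "side", "strain", "force", "converged")
  attr(out, "results") <- results
  attr(out, "failures") <- failures
  out
}

#' Average per-spring strains into the ligament-group x side grid
#'
#' Arithmetic mean of the spring strains within each (scenario, ligament
#' group, side) cell (and trial, when a `trial` column is present). By
#' default the three named ligament groups are kept (dorsal and ventral
#' sacroiliac averaged over 10 springs, sacrotuberous over 2) and the SIJ
#' springs are excluded, giving the 8 x 3 x 2 = 48-cell grid; set
#' `include_sij = TRUE` for a 64-cell exploratory grid.
#'
#' @param records Per-spring records from [run_battery()] (optionally
#'   stacked over trials with a `trial` column).
#' @param include_sij Include the SIJ spring group as a fourth group.
#' @return Tibble with columns (`trial`,) `scenario`, `group`, `side`,
#'   `mean_strain`, `n_springs`.
#' @export
average_by_group <- function(records, include_sij = FALSE) {
  groups <- c("dorsal_si", "sacrotuberous", "ventral_si")
  if (include_sij) groups <- c(groups, "sij")
  dat <- records %>% filter(.data$group %in% groups)
  keys <- intersect(c("trial", "scenario", "group", "side"), names(dat))
  out <- dat %>%
    group_by(across(all_of(keys))) %>%
    summarise(mean_strain = mean(.data$strain), n_springs = n(),
              .groups = "drop")
  per_trial <- out %>%
    group_by(across(all_of(setdiff(keys, c("scenario", "group", "side"))))) %>%
    summarise(cells = n(), .groups = "drop")
  expected <- length(unique(dat$scenario)) * length(groups) *
    length(unique(dat$side))
  if (any(per_trial$cells != expected)) {
    abort("incomplete strain grid: a (scenario, group, side) cell is missing records.",
          class = "sijstrain_aggregation_error")
  }
  out
}

#' Heatmap of a strain grid
#'
#' @param object A grid from [average_by_group()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_strain_grid <- function(object, ...) {
  ggplot(object, aes(x = factor(.data$scenario), y = .data$group,
                     fill = .data$mean_strain)) +
    geom_tile() +
    facet_wrap(~side, labeller = ggplot2::label_both) +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick",
                         midpoint = 0) +
    labs(x = "load scenario", y = NULL, fill = "mean strain") +
    theme_minimal()
}
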