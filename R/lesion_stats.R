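# Lesion-count cohort statistics: synthetic Poisson cohorts, one-way
# ANOVA, Fisher's protected LSD, and a factorial ANOVA with sex/age
# interactions. The ANOVA/LSD arithmetic is implemented in closed form
# (textbook sums of squares) so the test suite can cross-check it against
# stats::aov / car::Anova as independent references.

#' The seven CT lesion categories
#' @return Character vector of lesion type identifiers.
#' @export
lesion_types <- function() {
  c("subchondral_sclerosis", "subchondral_cyst", "subchondral_erosion",
    "subarticular_cleft", "intra_articular_ankylosis",
    "para_articular_ankylosis", "intra_articular_bone_spur")
}

#' Default per-group mean lesion counts
#'
#' Per-dog mean total counts per lesion type for the three work status
#' groups, used as the synthetic cohort generator's defaults. Per-side
#' Poisson means are half the total.
#'
#' @return Tibble: `work_status`, `lesion_type`, `mean_total`.
#' @export
default_lesion_means <- function() {
  types <- c(subchondral_cyst = "SCy", subchondral_erosion = "SE",
             subchondral_sclerosis = "SS", para_articular_ankylosis = "PAA",
             intra_articular_ankylosis = "IAA", subarticular_cleft = "SCl",
             intra_articular_bone_spur = "IBS")
  vals <- rbind(
    Breeder   = c(SCy = 0.42, SE = 1.58, SS = 1.17, PAA = 0, IAA = 1.33, SCl = 0.50, IBS = 0.50),
    Detection = c(SCy = 0.85, SE = 1.20, SS = 0.40, PAA = 0, IAA = 0.70, SCl = 1.10, IBS = 0.45),
    Other     = c(SCy = 1.58, SE = 1.75, SS = 0.67, PAA = 0, IAA = 0.58, SCl = 1.17, IBS = 1.08)
  )
  expand_grid(work_status = rownames(vals), lesion_type = names(types)) %>%
    mutate(mean_total = vals[cbind(.data$work_status, types[.data$lesion_type])])
}

#' Simulate a lesion-count cohort
#'
#' Draws independent Poisson counts per dog, lesion type and joint side
#' (per-side mean = half the group's per-dog total mean), with covariates
#' assigned by simple group conventions: Breeders are intact females;
#' Detection and Other dogs get sexes drawn with the stated male
#' probability; age group is drawn uniformly. Reproducible under `seed`.
#'
#' @param group_sizes Named integer vector of dogs per work status group.
#' @param means Mean table as from [default_lesion_means()].
#' @param seed Integer seed.
#' @param p_male Probability a non-Breeder dog is male.
#' @param p_older Probability a dog is in the older (31-48 months) group.
#' @return Tibble with one row per dog: `id`, `work_status`, `sex`,
#'   `neuter`, `age_group`, then `<lesion_type>_L` / `_R` count columns.
#' @export
simulate_cohort <- function(group_sizes = c(Breeder = 6, Detection = 10, Other = 6),
                            means = default_lesion_means(), seed = 1L,
                            p_male = 0.6, p_older = 0.4) {
  if (any(group_sizes < 1)) {
    abort("all group sizes must be >= 1.", class = "sijstrain_invalid_parameter")
  }
  if (any(means$mean_total < 0)) {
    abort("mean counts must be non-negative.", class = "sijstrain_invalid_parameter")
  }
  withr_seed(seed, {
    dogs <- tibble(
      work_status = rep(names(group_sizes), group_sizes)
    ) %>%
      mutate(id = sprintf("dog_%02d", row_number()),
             sex = ifelse(.data$work_status == "Breeder", "F",
                          ifelse(runif(n()) < p_male, "M", "F")),
             neuter = ifelse(.data$work_status == "Breeder", "intact",
                             sample(c("intact", "spayed", "neutered"), n(),
                                    replace = TRUE, prob = c(0.8, 0.1, 0.1))),
             age_group = sample(c("younger", "older"), n(), replace = TRUE,
                                prob = c(1 - p_older, p_older))) %>%
      select("id", "work_status", "sex", "neuter", "age_group")
    for (ty in unique(means$lesion_type)) {
      mu <- means$mean_total[match(paste(dogs$work_status, ty),
                                   paste(means$work_status, means$lesion_type))] / 2
      dogs[[paste0(ty, "_L")]] <- rpois(nrow(dogs), mu)
      dogs[[paste0(ty, "_R")]] <- rpois(nrow(dogs), mu)
    }
    dogs
  })
}

#' Pivot a cohort to long per-type/side counts
#'
#' Adds the per-type `total` side (L + R).
#'
#' @param cohort Wide cohort from [simulate_cohort()] or [read_cohort_csv()].
#' @return Long tibble: covariates, `lesion_type`, `side` (L, R, total),
#'   `count`.
#' @export
cohort_long <- function(cohort) {
  long <- cohort %>%
    pivot_longer(cols = dplyr::matches("_(L|R)$"),
                 names_to = c("lesion_type", "side"),
                 names_pattern = "(.*)_(L|R)$",
                 values_to = "count")
  totals <- long %>%
    group_by(across(!all_of(c("side", "count")))) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    mutate(side = "total")
  bind_rows(long, totals)
}

#' Read / write cohort CSVs
#'
#' One row per dog: `id`, `work_status`, `sex`, `neuter`, `age_group`,
#' then the fourteen `<lesion_type>_L` / `_R` count columns.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  dat <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) {
                    abort(paste0("cannot parse cohort CSV: ", conditionMessage(e)),
                          class = "sijstrain_parse_error")
                  })
  need <- c("id", "work_status", "sex", "neuter", "age_group")
  if (!all(need %in% names(dat))) {
    abort(paste0("cohort CSV lacks columns: ",
                 paste(setdiff(need, names(dat)), collapse = ", ")),
          class = "sijstrain_parse_error")
  }
  cols <- grep("_(L|R)$", names(dat), value = TRUE)
  bad <- which(!complete.cases(dat[cols]) |
                 apply(dat[cols] < 0, 1, any, na.rm = TRUE))
  if (length(bad)) {
    abort(sprintf("cohort CSV line(s) %s: missing or negative counts.",
                  paste(bad + 1L, collapse = ", ")),
          class = "sijstrain_parse_error")
  }
  as_tibble(dat)
}

#' One-way analysis of variance (closed form)
#'
#' Textbook between/within sum-of-squares decomposition with the F test on
#' `k - 1` and `N - k` degrees of freedom. When every group mean is equal
#' (zero between-group SS) the result is F = 0, p = 1.
#'
#' @param values Numeric response.
#' @param groups Grouping vector (coerced to factor), >= 2 levels.
#' @return A `sij_anova`: `F`, `df_between`, `df_within`, `p_value`,
#'   `group_means` tibble, `mse`, and the SS decomposition.
#' @export
oneway_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) {
    abort("at least 2 groups are required.", class = "sijstrain_invalid_parameter")
  }
  if (length(values) != length(groups) || anyNA(values)) {
    abort("`values` and `groups` must be complete and equal length.",
          class = "sijstrain_invalid_parameter")
  }
  k <- nlevels(groups); N <- length(values)
  if (N <= k) {
    abort("degenerate design: no within-group degrees of freedom.",
          class = "sijstrain_invalid_parameter")
  }
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  grand <- mean(values)
  ss_between <- sum(gn * (gm - grand)^2)
  ss_within <- sum((values - gm[groups])^2)
  df_b <- k - 1L; df_w <- N - k
  mse <- ss_within / df_w
  f <- if (ss_between == 0) 0 else (ss_between / df_b) / mse
  p <- if (ss_between == 0) 1 else pf(f, df_b, df_w, lower.tail = FALSE)
  structure(
    list(F = f, df_between = df_b, df_within = df_w, p_value = p,
         ss_between = ss_between, ss_within = ss_within,
         ss_total = ss_between + ss_within, mse = mse,
         group_means = tibble(group = names(gm), n = as.integer(gn),
                              mean = as.numeric(gm)),
         data = tibble(value = as.numeric(values), group = groups)),
    class = "sij_anova"
  )
}

#' @export
print.sij_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p_value))
  print(as.data.frame(x$group_means), row.names = FALSE)
  invisible(x)
}

#' @rdname oneway_anova
#' @param x,object A `sij_anova`.
#' @param ... Unused.
#' @export
tidy.sij_anova <- function(x, ...) {
  tibble(term = c("between", "within"),
         df = c(x$df_between, x$df_within),
         sumsq = c(x$ss_between, x$ss_within),
         meansq = c(x$ss_between / x$df_between, x$mse),
         statistic = c(x$F, NA), p_value = c(x$p_value, NA))
}

#' @rdname oneway_anova
#' @export
glance.sij_anova <- function(x, ...) {
  tibble(statistic = x$F, df_between = x$df_between, df_within = x$df_within,
         p_value = x$p_value, mse = x$mse)
}

#' Fisher's protected LSD pairwise comparisons
#'
#' Pairwise pooled-variance t-tests using the omnibus ANOVA's mean squared
#' error and within-group degrees of freedom, evaluated only when the
#' omnibus p-value passes the protection threshold; otherwise every pair
#' is marked not evaluated. Two-sided p-values are reported.
#'
#' @param anova A `sij_anova` from [oneway_anova()].
#' @param protect_alpha Omnibus protection threshold (default 0.10,
#'   matching an exploratory-screening convention).
#' @param pair_alpha Pairwise significance level (default 0.05).
#' @return A `sij_lsd`: tibble of pairs (`group_1`, `group_2`, `estimate`,
#'   `se`, `statistic`, `p_value`, `significant`, `evaluated`), plus the
#'   protection state.
#' @export
protected_lsd <- function(anova, protect_alpha = 0.10, pair_alpha = 0.05) {
  stopifnot(inherits(anova, "sij_anova"))
  gm <- anova$group_means
  protected <- anova$p_value < protect_alpha
  pairs <- utils::combn(nrow(gm), 2)
  out <- tibble(
    group_1 = gm$group[pairs[1, ]],
    group_2 = gm$group[pairs[2, ]],
    estimate = gm$mean[pairs[1, ]] - gm$mean[pairs[2, ]],
    se = sqrt(anova$mse * (1 / gm$n[pairs[1, ]] + 1 / gm$n[pairs[2, ]]))
  )
  if (protected) {
    out <- out %>%
      mutate(statistic = .data$estimate / .data$se,
             p_value = 2 * pt(-abs(.data$statistic), anova$df_within),
             significant = .data$p_value < pair_alpha,
             evaluated = TRUE)
  } else {
    out <- out %>%
      mutate(statistic = NA_real_, p_value = NA_real_,
             significant = NA, evaluated = FALSE)
  }
  structure(list(pairs = out, protected = protected,
                 protect_alpha = protect_alpha, pair_alpha = pair_alpha,
                 omnibus_p = anova$p_value, df = anova$df_within),
            class = "sij_lsd")
}

#' @export
print.sij_lsd <- function(x, ...) {
  cat(sprintf("Fisher's protected LSD (omnibus p = %.4g, protection alpha = %g): %s\n",
              x$omnibus_p, x$protect_alpha,
              if (x$protected) "pairs evaluated" else "pairs NOT evaluated"))
  print(as.data.frame(x$pairs), row.names = FALSE)
  invisible(x)
}

#' @rdname protected_lsd
#' @param x A `sij_lsd`.
#' @param ... Unused.
#' @export
tidy.sij_lsd <- function(x, ...) x$pairs

#' Factorial ANOVA with work-status interactions
#'
#' General-linear-model F tests for the main effects of work status, sex
#' and age group plus the interactions of work status with sex and age,
#' using Type III sums of squares (sum-to-zero contrasts; each term tested
#' by removing its columns from the full model). Factors with a single
#' observed level are dropped and reported as inestimable; aliased columns
#' (e.g. empty design cells) are dropped and reported, not an error.
#'
#' @param data Data frame holding the response and factor columns.
#' @param response Name of the response column.
#' @param factors Main-effect factor names; the first is crossed with the
#'   others (default `c("work_status", "sex", "age_group")`).
#' @param type Sum-of-squares type, `"III"` (default) or `"II"`.
#' @return A `sij_factorial`: `effects` tibble (`term`, `df`, `sumsq`,
#'   `statistic`, `p_value`), `dropped` (inestimable terms), `aliased`
#'   (dropped columns), residual df and MSE.
#' @export
factorial_anova <- function(data, response,
                            factors = c("work_status", "sex", "age_group"),
                            type = c("III", "II")) {
  type <- match.arg(type)
  if (!response %in% names(data)) {
    abort(sprintf("response column '%s' not found.", response),
          class = "sijstrain_invalid_parameter")
  }
  for (f in factors) data[[f]] <- factor(data[[f]])
  lv <- vapply(factors, function(f) nlevels(data[[f]]), 1L)
  dropped <- factors[lv < 2]
  keep <- factors[lv >= 2]
  if (!length(keep)) {
    abort("no factor has two or more levels; nothing is estimable.",
          class = "sijstrain_invalid_parameter")
  }
  main <- keep
  inter <- if (keep[1] == factors[1] && length(keep) > 1) {
    paste(keep[1], keep[-1], sep = ":")
  } else character()
  terms_all <- c(main, inter)
  fml <- as.formula(paste(response, "~", paste(terms_all, collapse = " + ")))
  contr <- lapply(keep, function(f) "contr.sum")
  names(contr) <- keep
  mm <- model.matrix(fml, data = data, contrasts.arg = contr)
  y <- data[[response]]
  assign <- attr(mm, "assign")
  term_labels <- attr(stats::terms(fml), "term.labels")

  qr_full <- qr(mm)
  aliased_cols <- if (qr_full$rank < ncol(mm)) {
    colnames(mm)[-qr_full$pivot[seq_len(qr_full$rank)]]
  } else character()
  keep_cols <- setdiff(seq_len(ncol(mm)), match(aliased_cols, colnames(mm)))
  mmr <- mm[, keep_cols, drop = FALSE]
  assign_r <- assign[keep_cols]
  rss_full <- sum(stats::lm.fit(mmr, y)$residuals^2)
  df_res <- nrow(mmr) - ncol(mmr)
  if (df_res < 1) {
    abort("saturated design: no residual degrees of freedom.",
          class = "sijstrain_invalid_parameter")
  }
  mse <- rss_full / df_res

  test_term <- function(i) {
    cols <- which(assign_r == i)
    if (!length(cols)) {
      return(tibble(term = term_labels[i], df = 0L, sumsq = NA_real_,
                    statistic = NA_real_, p_value = NA_real_))
    }
    drop_set <- if (type == "III") cols else {
      # Type II: also drop any higher-order term containing this one
      contains <- vapply(seq_along(term_labels), function(j) {
        j != i && all(strsplit(term_labels[i], ":")[[1]] %in%
                        strsplit(term_labels[j], ":")[[1]])
      }, logical(1))
      which(assign_r %in% c(i, which(contains)))
    }
    base_cols <- if (type == "II") {
      # Type II compares against the model without this term but with all
      # terms not containing it
      setdiff(seq_len(ncol(mmr)), which(assign_r == i | assign_r %in%
        which(vapply(seq_along(term_labels), function(j) {
          j != i && all(strsplit(term_labels[i], ":")[[1]] %in%
                          strsplit(term_labels[j], ":")[[1]])
        }, logical(1)))))
    } else setdiff(seq_len(ncol(mmr)), cols)
    rss_red <- sum(stats::lm.fit(mmr[, base_cols, drop = FALSE], y)$residuals^2)
    rss_cmp <- if (type == "II") {
      sum(stats::lm.fit(mmr[, sort(c(base_cols, cols)), drop = FALSE],
                        y)$residuals^2)
    } else rss_full
    q <- length(cols)
    ss <- rss_red - rss_cmp
    if (mse == 0) {   # degenerate all-constant response
      f <- NA_real_; p <- NA_real_
    } else {
      f <- (ss / q) / mse
      p <- pf(f, q, df_res, lower.tail = FALSE)
    }
    tibble(term = term_labels[i], df = q, sumsq = ss, statistic = f,
           p_value = p)
  }
  effects <- bind_rows(lapply(seq_along(term_labels), test_term))
  structure(
    list(effects = effects, dropped = dropped, aliased = aliased_cols,
         df_residual = df_res, mse = mse, rss = rss_full, type = type),
    class = "sij_factorial"
  )
}

#' @export
print.sij_factorial <- function(x, ...) {
  cat(sprintf("Factorial ANOVA (Type %s SS), residual df %d:\n",
              x$type, x$df_residual))
  print(as.data.frame(x$effects), row.names = FALSE)
  if (length(x$dropped)) cat("inestimable (single-level):",
                             paste(x$dropped, collapse = ", "), "\n")
  if (length(x$aliased)) cat("aliased columns dropped:",
                             paste(x$aliased, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname factorial_anova
#' @param x A `sij_factorial`.
#' @param ... Unused.
#' @export
tidy.sij_factorial <- function(x, ...) x$effects

#' Full lesion-count analysis over types and sides
#'
#' For each of the seven lesion types and each side (L, R, total): omnibus
#' one-way ANOVA of per-dog counts across work status groups, Fisher's
#' protected LSD, and the factorial ANOVA with sex/age interactions.
#'
#' @param cohort Wide cohort tibble.
#' @param protect_alpha,pair_alpha Passed to [protected_lsd()].
#' @return A `sij_lesion_report` with tibbles `omnibus` (21 rows), `lsd`
#'   and `factorial`.
#' @export
analyze_lesions <- function(cohort, protect_alpha = 0.10, pair_alpha = 0.05) {
  long <- cohort_long(cohort)
  combos <- long %>% distinct(.data$lesion_type, .data$side)
  omnibus <- list(); lsd <- list(); fact <- list()
  for (i in seq_len(nrow(combos))) {
    sub <- long %>%
      filter(.data$lesion_type == combos$lesion_type[i],
             .data$side == combos$side[i])
    an <- oneway_anova(sub$count, sub$work_status)
    omnibus[[i]] <- glance(an) %>%
      mutate(lesion_type = combos$lesion_type[i], side = combos$side[i],
             .before = 1)
    ls <- protected_lsd(an, protect_alpha, pair_alpha)
    lsd[[i]] <- tidy(ls) %>%
      mutate(lesion_type = combos$lesion_type[i], side = combos$side[i],
             omnibus_p = an$p_value, .before = 1)
    fa <- tryCatch(factorial_anova(as.data.frame(sub), "count"),
                   error = function(e) NULL)
    if (!is.null(fa)) {
      fact[[i]] <- tidy(fa) %>%
        mutate(lesion_type = combos$lesion_type[i], side = combos$side[i],
               .before = 1)
    }
  }
  structure(list(omnibus = bind_rows(omnibus), lsd = bind_rows(lsd),
                 factorial = bind_rows(fact),
                 protect_alpha = protect_alpha, pair_alpha = pair_alpha),
            class = "sij_lesion_report")
}

#' @export
print.sij_lesion_report <- function(x, ...) {
  cat(sprintf("Lesion-count report: %d omnibus tests, protection alpha %g\n",
              nrow(x$omnibus), x$protect_alpha))
  sig <- x$omnibus %>% filter(.data$p_value < x$protect_alpha)
  if (nrow(sig)) {
    cat("omnibus evidence (p < protection alpha):\n")
    print(as.data.frame(sig[, c("lesion_type", "side", "statistic", "p_value")]),
          row.names = FALSE)
  } else cat("no omnibus test passed the protection threshold.\n")
  invisible(x)
}
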