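# Cohort-level statistical report and the analytic enhancement-count
# correlation model used to calibrate the histology linkage.

#' Group-comparison report for a cohort
#'
#' Reproduces the study's analysis structure on a cohort table:
#' per-group summaries (n, mean, SD) of normalized MVE and both microvessel
#' counts; omnibus one-way ANOVA of normalized MVE across the groups that
#' carry it; all-pairs Dunnett-T3 comparisons with the control-vs-group
#' rows flagged; and Pearson correlations of normalized MVE with each
#' marker count. Group-5 rows, which carry no normalized MVE, are excluded
#' from the MVE summaries, the ANOVA, the T3 family and the correlations,
#' but appear in the count summaries.
#'
#' @param cohort A [build_cohort_table()] data.frame.
#' @param control_group Id of the control group (default 0); must be
#'   present in the cohort.
#' @return A list of class `ceus_report`: `group_summary` (data.frame),
#'   `anova` (`test_result`), `pairwise` ([dunnett_t3()] data.frame with a
#'   `vs_control` flag), `correlations` (data.frame, one row per marker).
#' @export
group_comparison_report <- function(cohort, control_group = 0) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!control_group %in% cohort$group_id)
    ceus_stop(sprintf("control group %s absent from cohort", control_group),
              "configuration_error")
  gids <- sort(unique(cohort$group_id))
  summ <- do.call(rbind, lapply(gids, function(g) {
    d <- cohort[cohort$group_id == g, ]
    nm <- d$nmve[!is.na(d$nmve)]
    data.frame(group_id = g, n = nrow(d),
               nmve_n = length(nm),
               nmve_mean = if (length(nm)) mean(nm) else NA_real_,
               nmve_sd = if (length(nm) > 1) stats::sd(nm) else NA_real_,
               cd31_mean = mean(d$cd31_mean), cd31_sd = stats::sd(d$cd31_mean),
               vegf_mean = mean(d$vegf_mean), vegf_sd = stats::sd(d$vegf_mean))
  }))

  mve_rows <- cohort[!is.na(cohort$nmve), ]
  mve_groups <- split(mve_rows$nmve, mve_rows$group_id)
  mve_groups <- mve_groups[vapply(mve_groups, length, 1L) >= 2L]
  anova <- if (length(mve_groups) >= 2L) one_way_anova(mve_groups) else NULL
  pairwise <- if (length(mve_groups) >= 2L) {
    pw <- dunnett_t3(mve_groups, labels = names(mve_groups))
    pw$vs_control <- pw$group_i == as.character(control_group) |
      pw$group_j == as.character(control_group)
    pw
  } else NULL

  correlations <- NULL
  if (nrow(mve_rows) >= 3L) {
    correlations <- do.call(rbind, lapply(c("vegf", "cd31"), function(mk) {
      cr <- tryCatch(
        pearson_correlation(mve_rows$nmve, mve_rows[[paste0(mk, "_mean")]]),
        undefined_correlation = function(e)
          list(r = NA_real_, n = nrow(mve_rows), t_statistic = NA_real_,
               p_value = NA_real_, conf_int = c(NA_real_, NA_real_)))
      data.frame(marker = mk, r = cr$r, n = cr$n, t_statistic = cr$t_statistic,
                 p_value = cr$p_value,
                 ci_lower = cr$conf_int[1], ci_upper = cr$conf_int[2],
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(group_summary = summ, anova = anova, pairwise = pairwise,
                 correlations = correlations, control_group = control_group),
            class = "ceus_report")
}

#' @export
print.ceus_report <- function(x, ...) {
  cat("Cohort comparison report\n\nPer-group summaries:\n")
  print(x$group_summary, row.names = FALSE, digits = 4)
  if (!is.null(x$anova)) { cat("\nOmnibus "); print(x$anova) }
  if (!is.null(x$pairwise)) {
    cat("\nDunnett T3 (control vs group rows):\n")
    print(as.data.frame(x$pairwise[x$pairwise$vs_control, ]),
          row.names = FALSE, digits = 4)
  }
  if (!is.null(x$correlations)) {
    cat("\nNormalized MVE vs microvessel counts:\n")
    print(x$correlations, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Write a cohort report to CSV and JSON
#'
#' Emits `<prefix>_group_summary.csv`, `<prefix>_pairwise.csv`,
#' `<prefix>_correlations.csv` and `<prefix>_report.json`.
#'
#' @param report A `ceus_report`.
#' @param out_prefix Path prefix for the four output files.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_report <- function(report, out_prefix) {
  stopifnot(inherits(report, "ceus_report"))
  num_cols <- function(df) {
    for (cn in names(df)) if (is.numeric(df[[cn]]) && cn != "group_id" &&
                              cn != "n" && cn != "nmve_n")
      df[[cn]] <- format_num(df[[cn]])
    df
  }
  paths <- c(group_summary = paste0(out_prefix, "_group_summary.csv"),
             pairwise = paste0(out_prefix, "_pairwise.csv"),
             correlations = paste0(out_prefix, "_correlations.csv"),
             json = paste0(out_prefix, "_report.json"))
  utils::write.csv(num_cols(report$group_summary), paths["group_summary"],
                   row.names = FALSE)
  if (!is.null(report$pairwise))
    utils::write.csv(num_cols(as.data.frame(report$pairwise)),
                     paths["pairwise"], row.names = FALSE)
  if (!is.null(report$correlations))
    utils::write.csv(num_cols(report$correlations), paths["correlations"],
                     row.names = FALSE)
  payload <- list(
    control_group = report$control_group,
    group_summary = report$group_summary,
    anova = if (!is.null(report$anova))
      list(statistic = report$anova$statistic, df = report$anova$df,
           p_value = report$anova$p_value) else NULL,
    pairwise = if (!is.null(report$pairwise)) as.data.frame(report$pairwise) else NULL,
    correlations = report$correlations)
  jsonlite::write_json(payload, paths["json"], auto_unbox = TRUE, digits = 9,
                       dataframe = "rows", null = "null")
  invisible(paths)
}

#' Model correlation between normalized MVE and a microvessel count
#'
#' Closed-form population Pearson correlation implied by the cohort
#' generative model, between the per-animal true enhancement ratio
#' R = D * L and the observer-mean count N. Here D is the latent density
#' (uniform over the groups' values weighted by group size), L the mean-1
#' lognormal biological multiplier with log-SD `gsd`, and
#' N | D the mean of `n_observers` independent Poisson(a + b D) counts.
#' Writing V = Var(D), mu = E(D):
#' \deqn{cov(R, N) = b V, \quad Var(R) = E(D^2) e^{gsd^2} - mu^2,}
#' \deqn{Var(N) = b^2 V + (a + b mu) / n_{obs}}
#' and r = cov / sqrt(Var(R) Var(N)). Used to calibrate the linkage slope
#' to a target correlation and as the reference truth in recovery tests.
#'
#' @param densities Per-group latent densities.
#' @param a,b Histology linkage intercept and slope.
#' @param gsd Lognormal log-SD of the biological multiplier.
#' @param weights Group sizes (default equal).
#' @param n_observers Observers averaged per count (default 2).
#' @return The model correlation, a single number in [0, 1).
#' @export
model_mve_count_correlation <- function(densities, a, b, gsd,
                                        weights = NULL, n_observers = 2) {
  stopifnot(is.numeric(densities), length(densities) >= 1L, all(densities >= 0))
  if (is.null(weights)) weights <- rep(1, length(densities))
  w <- weights / sum(weights)
  mu <- sum(w * densities)
  ed2 <- sum(w * densities^2)
  v <- ed2 - mu^2
  cov_rn <- b * v
  var_r <- ed2 * exp(gsd^2) - mu^2
  var_n <- b^2 * v + (a + b * mu) / n_observers
  if (var_r <= 0 || var_n <= 0) return(0)
  cov_rn / sqrt(var_r * var_n)
}

#' Calibrate the histology linkage slope to a target correlation
#'
#' Solves [model_mve_count_correlation()] for the slope `b` that makes the
#' model correlation between normalized MVE and the marker count equal
#' `target_r`, holding the intercept and all other cohort parameters fixed.
#' The correlation is increasing in `b` and bounded above by
#' sqrt(Var(D) / Var(D L)); a target at or above the bound is an error.
#'
#' @param target_r Desired model correlation, in (0, 1).
#' @param densities,a,gsd,weights,n_observers As in
#'   [model_mve_count_correlation()].
#' @return The calibrated slope `b`.
#' @export
calibrate_count_linkage <- function(target_r, densities, a, gsd,
                                    weights = NULL, n_observers = 2) {
  stopifnot(is_number(target_r), target_r > 0, target_r < 1)
  f <- function(b) model_mve_count_correlation(densities, a, b, gsd,
                                               weights, n_observers) - target_r
  upper_r <- model_mve_count_correlation(densities, a, 1e9, gsd,
                                         weights, n_observers)
  if (target_r >= upper_r)
    ceus_stop(sprintf(
      "target correlation %.3f is unattainable: model bound is %.3f (biological scatter)",
      target_r, upper_r), "configuration_error")
  stats::uniroot(f, c(1e-9, 1e6), tol = 1e-10)$root
}
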