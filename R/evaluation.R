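#' Normalized root mean square imputation error for one variable
#'
#' Computed over the masked (imputed) cells of a continuous variable:
#' `sqrt(mean((xhat - x)^2)) / mean(x)`, where `x` are the true and
#' `xhat` the imputed values of the masked cells. The denominator is the
#' mean of the true values over those cells; a (near-)zero-mean target
#' makes the statistic undefined and raises an error rather than
#' silently rescaling.
#'
#' @param imputed A complete tibble of imputed values.
#' @param truth The complete ground-truth tibble.
#' @param mask 0/1 matrix with named columns, 1 = observed; cells with 0
#'   are the ones scored.
#' @param variable Name of a continuous variable.
#' @return A non-negative scalar.
#' @export
nrmse <- function(imputed, truth, mask, variable) {
  scored <- mask[, variable] == 0L
  if (!any(scored)) abort(sprintf("no masked cells for variable '%s'", variable))
  x <- truth[[variable]][scored]
  xhat <- imputed[[variable]][scored]
  if (!is.numeric(x)) abort(sprintf("nrmse requires a continuous variable, not '%s'", variable))
  denom <- mean(x)
  if (abs(denom) <= 1e-12) abort(sprintf("NRMSE undefined for zero-mean target '%s'", variable))
  sqrt(mean((xhat - x)^2)) / denom
}

#' Proportion of falsely classified cells for one categorical variable
#'
#' `1 - N_correct / N` over the masked (imputed) cells: the fraction of
#' imputed categorical cells assigned a category different from the
#' truth. Always in `[0, 1]`.
#'
#' @inheritParams nrmse
#' @param variable Name of a categorical variable.
#' @return A scalar in `[0, 1]`.
#' @export
pfc <- function(imputed, truth, mask, variable) {
  scored <- mask[, variable] == 0L
  if (!any(scored)) abort(sprintf("no masked cells for variable '%s'", variable))
  x <- truth[[variable]][scored]
  xhat <- imputed[[variable]][scored]
  1 - sum(xhat == x) / length(x)
}

#' Aggregate imputation errors over repeated imputations
#'
#' For every independent variable, computes NRMSE (continuous) or PFC
#' (categorical) for each imputation in the list, then reports the mean
#' and standard deviation over the repeats.
#'
#' @param imputed_list A list of complete tibbles (repeated imputations
#'   of the same incomplete dataset).
#' @param truth The complete ground-truth tibble.
#' @param mask 0/1 matrix, 0 marking the amputed (scored) cells.
#' @param schema A [mixed_schema].
#' @param method Label recorded in the report.
#' @return A tibble: `method`, `variable`, `metric` (`"nrmse"`/`"pfc"`),
#'   `mean`, `sd`, `m` (number of repeats), `n_cells` (scored cells).
#' @export
evaluate_imputations <- function(imputed_list, truth, mask, schema, method = "method") {
  stopifnot(length(imputed_list) >= 1L)
  vars <- schema[schema$role == "independent", ]
  rows <- purrr::map(seq_len(nrow(vars)), function(i) {
    nm <- vars$name[i]
    metric <- if (vars$kind[i] == "continuous") "nrmse" else "pfc"
    f <- if (metric == "nrmse") nrmse else pfc
    vals <- vapply(imputed_list, f, numeric(1), truth = truth, mask = mask, variable = nm)
    tibble::tibble(
      method = method, variable = nm, metric = metric,
      mean = mean(vals), sd = if (length(vals) > 1L) sd(vals) else 0,
      m = length(vals), n_cells = sum(mask[, nm] == 0L)
    )
  })
  dplyr::bind_rows(rows)
}

# Per-repeat metric values in long form, used by compare_methods().
per_repeat_metrics <- function(imputed_list, truth, mask, schema, method = "method") {
  vars <- schema[schema$role == "independent", ]
  rows <- purrr::map(seq_len(nrow(vars)), function(i) {
    nm <- vars$name[i]
    metric <- if (vars$kind[i] == "continuous") "nrmse" else "pfc"
    f <- if (metric == "nrmse") nrmse else pfc
    tibble::tibble(
      method = method, variable = nm, metric = metric,
      rep = seq_along(imputed_list),
      value = vapply(imputed_list, f, numeric(1), truth = truth, mask = mask, variable = nm)
    )
  })
  dplyr::bind_rows(rows)
}

#' Compare imputation methods variable by variable
#'
#' For each variable, the per-repeat metric values of all methods are
#' tested for normality (Shapiro-Wilk on the pooled within-method
#' residuals). If normality is not rejected at 0.05, methods are
#' compared by one-way ANOVA and, when the omnibus test is significant,
#' pairwise Welch t-tests; otherwise Kruskal-Wallis and pairwise
#' Wilcoxon rank-sum tests. P-values are reported raw (no multiplicity
#' correction).
#'
#' @param per_repeat_values A long tibble with columns `method`,
#'   `variable`, `metric`, `value` (one row per repeat), e.g. built by
#'   stacking [evaluate_imputations()] inputs per method.
#' @param alpha Significance level gating the pairwise comparisons.
#' @return A tibble with one row per variable: `variable`, `metric`,
#'   `normality_p`, `omnibus_test`, `omnibus_p`, and a `pairwise`
#'   list-column of tibbles (`method1`, `method2`, `p`, `significant`).
#' @export
compare_methods <- function(per_repeat_values, alpha = 0.05) {
  req <- c("method", "variable", "metric", "value")
  if (!all(req %in% names(per_repeat_values))) {
    abort(sprintf("per_repeat_values needs columns: %s", paste(req, collapse = ", ")))
  }
  counts <- dplyr::count(per_repeat_values, .data$method, .data$variable)
  if (any(counts$n < 3L)) abort("comparison tests need at least 3 repeats per method")
  if (dplyr::n_distinct(per_repeat_values$method) < 2L) abort("need at least 2 methods to compare")

  per_repeat_values |>
    dplyr::group_by(.data$variable, .data$metric) |>
    dplyr::group_modify(function(df, key) compare_one_variable(df, alpha)) |>
    dplyr::ungroup() |>
    dplyr::select("variable", "metric", dplyr::everything())
}

compare_one_variable <- function(df, alpha) {
  methods <- unique(df$method)
  resid <- df$value - stats::ave(df$value, df$method)
  degenerate <- stats::var(df$value) < 1e-24
  if (degenerate) {
    return(tibble::tibble(
      normality_p = NA_real_, omnibus_test = "none", omnibus_p = 1,
      pairwise = list(empty_pairwise())
    ))
  }
  normality_p <- if (stats::var(resid) < 1e-24) NA_real_ else shapiro.test(resid)$p.value
  normal <- !is.na(normality_p) && normality_p > alpha
  grp <- factor(df$method, levels = methods)
  if (normal) {
    omnibus_test <- "anova"
    omnibus_p <- summary(aov(df$value ~ grp))[[1]][["Pr(>F)"]][1]
  } else {
    omnibus_test <- "kruskal"
    omnibus_p <- kruskal.test(df$value, grp)$p.value
  }
  pairwise <- empty_pairwise()
  if (is.finite(omnibus_p) && omnibus_p < alpha) {
    combs <- utils::combn(methods, 2L)
    pairwise <- purrr::map(seq_len(ncol(combs)), function(j) {
      a <- df$value[df$method == combs[1, j]]
      b <- df$value[df$method == combs[2, j]]
      p <- if (normal) t.test(a, b)$p.value else suppressWarnings(wilcox.test(a, b)$p.value)
      tibble::tibble(method1 = combs[1, j], method2 = combs[2, j], p = p, significant = p < alpha)
    }) |> dplyr::bind_rows()
  }
  tibble::tibble(
    normality_p = normality_p, omnibus_test = omnibus_test, omnibus_p = omnibus_p,
    pairwise = list(pairwise)
  )
}

empty_pairwise <- function() {
  tibble::tibble(method1 = character(), method2 = character(), p = numeric(), significant = logical())
}

#' Plot an imputation error report
#'
#' Bar chart of mean error (with +/- one SD bars) per variable, filled
#' by method, faceted by metric.
#'
#' @param report One or more [evaluate_imputations()] reports, row-bound.
#' @return A ggplot object.
#' @export
plot_eval_report <- function(report) {
  ggplot2::ggplot(report, ggplot2::aes(x = .data$variable, y = .data$mean, fill = .data$method)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.85), width = 0.8) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.85), width = 0.25, linewidth = 0.3
    ) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "imputation error", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
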