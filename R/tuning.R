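#' Hold out observed cells for hyperparameter validation
#'
#' Hides an additional fraction of the currently observed
#' independent-variable cells uniformly at random, on top of any
#' missingness already present. Dependent columns are never hidden. The
#' true values of the hidden cells stay in the caller's table and are
#' used only for scoring.
#'
#' @param data A tibble (`NA` = already-missing cells).
#' @param schema A [mixed_schema].
#' @param holdout_fraction Fraction of observed independent cells to
#'   hide, in (0, 1).
#' @param seed Integer seed.
#' @return A 0/1 mask matrix (0 = missing-or-held-out) to be applied
#'   with [apply_mask()].
#' @export
make_validation_mask <- function(data, schema, holdout_fraction = 0.1, seed = 1L) {
  assert_scalar_number(holdout_fraction, "holdout_fraction", 1e-12, 1 - 1e-12)
  mask <- mask_from_data(data)
  indep <- schema$name[schema$role == "independent"]
  obs_cells <- which(mask[, indep, drop = FALSE] == 1L)
  n_hide <- round(holdout_fraction * length(obs_cells))
  hide <- with_seed(seed, sample(obs_cells, n_hide))
  sub <- mask[, indep, drop = FALSE]
  sub[hide] <- 0L
  mask[, indep] <- sub
  short <- colSums(mask[, indep, drop = FALSE]) < 2L
  if (any(short)) {
    abort(sprintf("holdout would leave column '%s' with < 2 observed values", indep[short][1]))
  }
  mask
}

#' Score a GAIN configuration on a validation holdout
#'
#' Trains on the data with the validation mask applied, imputes, and
#' scores the held-out cells: the mean per-variable NRMSE over
#' continuous holdouts plus the mean per-variable PFC over categorical
#' holdouts (unweighted sum of the two means; lower is better).
#' Deterministic given `config$seed`.
#'
#' @param config A [gain_config()].
#' @param data The tibble the validation mask was built from.
#' @param schema A [mixed_schema].
#' @param val_mask A [make_validation_mask()] result.
#' @return A non-negative scalar score.
#' @export
score_config <- function(config, data, schema, val_mask) {
  train <- apply_mask(data, val_mask)
  fit <- gain(train, schema, config)
  imp <- impute_gain(fit, train)
  score_imputation(imp, data, schema, val_mask)
}

# Holdout score shared by score_config and any external imputer:
# cells observed in `truth` but hidden by `val_mask` are scored.
score_imputation <- function(imputed, truth, schema, val_mask) {
  scoring <- mask_from_data(truth) * 0L + 1L
  held <- (mask_from_data(truth) == 1L) & (val_mask == 0L)
  scoring[held] <- 0L
  vars <- schema[schema$role == "independent", ]
  nr <- c(); pf <- c()
  for (i in seq_len(nrow(vars))) {
    nm <- vars$name[i]
    if (!any(scoring[, nm] == 0L)) next
    if (vars$kind[i] == "continuous") {
      nr <- c(nr, nrmse(imputed, truth, scoring, nm))
    } else {
      pf <- c(pf, pfc(imputed, truth, scoring, nm))
    }
  }
  (if (length(nr)) mean(nr) else 0) + (if (length(pf)) mean(pf) else 0)
}

# Canonical sweep order: network structure first, then optimization,
# then loss weights, then adversarial knobs.
GREEDY_ORDER <- c(
  "n_iterations", "hidden_layers", "neurons_per_layer", "learning_rate",
  "optimizer", "activation", "alpha", "beta", "p_hint", "k"
)

#' Greedy coordinate-wise hyperparameter search
#'
#' Starting from `base_config`, sweeps one hyperparameter at a time in a
#' fixed order, evaluating every candidate with the other
#' hyperparameters held at their current values and keeping the best
#' (ties go to the first candidate). One full pass by default.
#'
#' @param data A tibble with `NA` marking missing cells.
#' @param schema A [mixed_schema].
#' @param grid Named list: one vector of candidate values per
#'   hyperparameter of [gain_config()]. Hyperparameters are swept in the
#'   canonical order (`n_iterations`, `hidden_layers`,
#'   `neurons_per_layer`, `learning_rate`, `optimizer`, `activation`,
#'   `alpha`, `beta`, `p_hint`, `k`); names outside that list error.
#' @param base_config Starting [gain_config()].
#' @param holdout_fraction Passed to [make_validation_mask()].
#' @param seed Seed for the validation holdout.
#' @param passes Number of full greedy passes.
#' @return A list: `config` (the selected [gain_config()]), `score` (its
#'   validation score) and `log` (a tibble of every evaluation: `pass`,
#'   `hyperparameter`, `candidate`, `score`, `selected`).
#' @export
gain_greedy_search <- function(data, schema, grid, base_config = gain_config(),
                               holdout_fraction = 0.1, seed = 1L, passes = 1L) {
  if (!length(grid) || is.null(names(grid)) || any(names(grid) == "")) {
    abort("grid must be a named list of candidate vectors")
  }
  unknown <- setdiff(names(grid), GREEDY_ORDER)
  if (length(unknown)) abort(sprintf("not tunable hyperparameters: %s", paste(unknown, collapse = ", ")))
  if (any(vapply(grid, length, integer(1)) < 1L)) abort("candidate lists must be non-empty")
  sweep_order <- intersect(GREEDY_ORDER, names(grid))
  val_mask <- make_validation_mask(data, schema, holdout_fraction, seed)

  current <- base_config
  current_score <- NULL
  log_rows <- list()
  for (pass in seq_len(assert_count(passes, "passes"))) {
    for (hp in sweep_order) {
      cands <- grid[[hp]]
      scores <- vapply(seq_along(cands), function(ci) {
        cfg <- current
        cfg[[hp]] <- if (hp %in% c("optimizer", "activation")) as.character(cands[ci]) else cands[ci]
        score_config(cfg, data, schema, val_mask)
      }, numeric(1))
      best <- which.min(scores) # ties: first candidate
      log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
        pass = pass, hyperparameter = hp, candidate = as.character(cands),
        score = scores, selected = seq_along(cands) == best
      )
      current[[hp]] <- if (hp %in% c("optimizer", "activation")) as.character(cands[best]) else cands[best]
      current_score <- scores[best]
    }
  }
  list(config = current, score = current_score, log = dplyr::bind_rows(log_rows))
}
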