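#' Configuration for the iterative chained-model baseline imputer
#'
#' Mirrors the reference missForest-style settings used for comparison:
#' 20 trees, `sqrt(d)` candidate variables per split and at most 10
#' sweeps, with the standard difference-based early stop.
#'
#' @param predictor Per-variable model family: `"random_forest"`
#'   (regression/classification forests) or `"linear"` (least squares for
#'   continuous targets; a linear probability model with arg-max
#'   classification for categorical targets — a transparent stand-in, not
#'   a reimplementation of predictive mean matching).
#' @param n_trees Trees per forest.
#' @param max_iterations Maximum number of sweeps over the variables.
#' @param seed Integer seed (forest fitting is stochastic).
#' @return A list of class `iterative_config`.
#' @export
iterative_config <- function(predictor = c("random_forest", "linear"),
                             n_trees = 20L, max_iterations = 10L, seed = 1L) {
  cfg <- list(
    predictor = match.arg(predictor),
    n_trees = assert_count(n_trees, "n_trees"),
    max_iterations = assert_count(max_iterations, "max_iterations", min = 0L),
    seed = as.integer(seed)
  )
  class(cfg) <- "iterative_config"
  cfg
}

#' Mean/mode single imputation
#'
#' The null baseline: missing continuous cells get the observed column
#' mean, missing categorical cells the observed modal category (ties
#' broken by schema category order). Observed cells are untouched.
#'
#' @param data A tibble with `NA` marking missing cells.
#' @param schema A [mixed_schema].
#' @return A complete tibble.
#' @export
impute_mean_mode <- function(data, schema) {
  out <- data
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    x <- out[[nm]]
    miss <- is.na(x)
    if (!any(miss)) next
    if (all(miss)) abort(sprintf("column '%s' has no observed values", nm))
    if (schema$kind[i] == "continuous") {
      x[miss] <- mean(x[!miss])
    } else {
      cats <- schema$categories[[i]]
      counts <- vapply(cats, function(cc) sum(x[!miss] == cc), numeric(1))
      x[miss] <- cats[which.max(counts)]
    }
    out[[nm]] <- x
  }
  out
}

#' Iterative chained-model imputation
#'
#' Initializes with [impute_mean_mode()], then repeatedly re-fits a
#' per-variable predictor on the currently completed data (variables
#' visited in order of increasing missingness) and re-predicts the
#' missing cells. Sweeping stops at `max_iterations` or as soon as the
#' difference criterion between successive imputations first increases,
#' in which case the previous iterate is returned (the standard
#' missForest stopping rule: normalized squared difference for
#' continuous variables plus changed-cell proportion for categorical
#' ones).
#'
#' @inheritParams impute_mean_mode
#' @param config An [iterative_config()].
#' @return A complete tibble.
#' @export
impute_iterative <- function(data, schema, config = iterative_config()) {
  stopifnot(inherits(config, "iterative_config"))
  if (nrow(schema) < 2L) abort("iterative imputation needs at least 2 variables")
  miss_by_var <- vapply(schema$name, function(nm) sum(is.na(data[[nm]])), numeric(1))
  order_vars <- schema$name[order(miss_by_var)]
  targets <- order_vars[miss_by_var[order_vars] > 0]
  current <- impute_mean_mode(data, schema)
  if (!length(targets) || config$max_iterations == 0L) return(current)

  frame <- function(tbl) { # factors for model fitting
    df <- as.data.frame(tbl)
    for (i in seq_len(nrow(schema))) {
      if (schema$kind[i] == "categorical") {
        df[[schema$name[i]]] <- factor(df[[schema$name[i]]], levels = schema$categories[[i]])
      }
    }
    df
  }

  with_seed(config$seed, {
    prev <- current
    prev_crit <- Inf
    for (iter in seq_len(config$max_iterations)) {
      for (nm in targets) {
        miss <- is.na(data[[nm]])
        df <- frame(current)
        pred_ok <- fit_and_predict(df, nm, miss, schema, config)
        current[[nm]][miss] <- pred_ok
      }
      crit <- imputation_difference(current, prev, data, schema)
      if (crit > prev_crit) return(prev) # first increase: keep previous iterate
      prev <- current
      prev_crit <- crit
    }
    current
  })
}

fit_and_predict <- function(df, nm, miss, schema, config) {
  i <- match(nm, schema$name)
  rhs <- df[setdiff(names(df), nm)]
  y <- df[[nm]]
  kind <- schema$kind[i]
  tryCatch({
    if (config$predictor == "random_forest") {
      yfit <- y[!miss]
      if (is.factor(yfit)) yfit <- droplevels(yfit) # empty classes are not modelled
      fit_df <- cbind(.y = yfit, rhs[!miss, , drop = FALSE])
      new_df <- rhs[miss, , drop = FALSE]
      mtry <- max(1L, floor(sqrt(ncol(rhs))))
      rf <- randomForest::randomForest(.y ~ ., data = fit_df, ntree = config$n_trees, mtry = mtry)
      pred <- predict(rf, newdata = new_df)
      if (kind == "categorical") as.character(pred) else as.numeric(pred)
    } else {
      # least squares on a hand-built dummy design (QR with pivoting, so
      # collinear or constant covariates are aliased away, not fatal)
      X <- cbind(`(Intercept)` = 1, dummy_design(rhs))
      lstsq <- function(yy) {
        fit <- stats::lm.fit(X[!miss, , drop = FALSE], yy)
        beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
        as.numeric(X[miss, , drop = FALSE] %*% beta)
      }
      if (kind == "continuous") {
        lstsq(y[!miss])
      } else {
        # linear probability model per category, arg-max classification
        cats <- schema$categories[[i]]
        scores <- vapply(cats, function(cc) lstsq(as.numeric(y[!miss] == cc)), numeric(sum(miss)))
        if (sum(miss) == 1L) scores <- matrix(scores, nrow = 1L)
        cats[max.col(scores, ties.method = "first")]
      }
    }
  }, error = function(e) {
    abort(sprintf("predictor fit failed for variable '%s': %s", nm, conditionMessage(e)))
  })
}

# Treatment-coded indicators (all levels but the first) for factor
# columns; numeric columns pass through.
dummy_design <- function(rhs) {
  blocks <- lapply(names(rhs), function(cn) {
    x <- rhs[[cn]]
    if (is.factor(x)) {
      lev <- levels(x)[-1]
      if (!length(lev)) return(NULL)
      ind <- vapply(lev, function(l) as.numeric(x == l), numeric(length(x)))
      if (length(x) == 1L) ind <- matrix(ind, nrow = 1L)
      colnames(ind) <- paste0(cn, lev)
      ind
    } else {
      matrix(x, ncol = 1L, dimnames = list(NULL, cn))
    }
  })
  do.call(cbind, blocks[!vapply(blocks, is.null, logical(1))])
}

# missForest-style difference criterion between successive completed
# tables, computed over originally missing cells.
imputation_difference <- function(new, old, data, schema) {
  d_cont <- 0; denom_cont <- 0
  changed <- 0; n_cat <- 0
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    miss <- is.na(data[[nm]])
    if (!any(miss)) next
    if (schema$kind[i] == "continuous") {
      d_cont <- d_cont + sum((new[[nm]][miss] - old[[nm]][miss])^2)
      denom_cont <- denom_cont + sum(new[[nm]][miss]^2)
    } else {
      changed <- changed + sum(new[[nm]][miss] != old[[nm]][miss])
      n_cat <- n_cat + sum(miss)
    }
  }
  crit <- 0
  if (denom_cont > 0) crit <- crit + d_cont / denom_cont
  if (n_cat > 0) crit <- crit + changed / n_cat
  crit
}
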