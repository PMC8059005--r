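#' Draw a randomized missing-at-random (MAR) mechanism
#'
#' Missingness is introduced into independent variables only, cell-wise
#' Bernoulli, with probability `plogis(c_j + w_j' z_i)` where `z_i` are
#' the encoded, per-column standardized dependent (outcome) variables of
#' row `i`. Weights are drawn i.i.d. standard normal per (target, driver
#' column) pair, so every replicate uses a different randomized linear
#' combination; the intercept of each target is calibrated by bisection
#' so its expected missingness on the calibration table equals the
#' nominal rate.
#'
#' @param data A complete tibble conforming to `schema`.
#' @param schema A [mixed_schema] with at least one dependent variable.
#' @param rate Nominal missingness rate in (0, 1) (the study design uses
#'   0.2 and 0.5).
#' @param seed Integer seed; the mechanism is fully determined by it.
#' @return An object of class `mar_mechanism`.
#' @export
draw_mar_mechanism <- function(data, schema, rate, seed) {
  assert_scalar_number(rate, "rate", lower = 1e-12, upper = 1 - 1e-12)
  dep <- schema$name[schema$role == "dependent"]
  if (!length(dep)) abort("MAR mechanism needs at least one dependent variable")
  targets <- schema$name[schema$role == "independent"]
  z <- driver_matrix(data, schema)
  W <- with_seed(seed, matrix(rnorm(length(targets) * ncol(z$z)), nrow = length(targets),
                              dimnames = list(targets, colnames(z$z))))
  intercepts <- vapply(targets, function(tg) {
    calibrate_intercept(W[tg, ], z$z, rate)
  }, numeric(1))
  structure(
    list(
      targets = targets, drivers = dep, weights = W, intercepts = intercepts,
      rate = rate, driver_center = z$center, driver_scale = z$scale,
      driver_encoder = z$encoder, seed = as.integer(seed)
    ),
    class = "mar_mechanism"
  )
}

# Encoded, standardized dependent-variable matrix used as MAR drivers.
driver_matrix <- function(data, schema, encoder = NULL, center = NULL, scale = NULL) {
  dep_schema <- schema[schema$role == "dependent", ]
  class(dep_schema) <- class(schema)
  dep_data <- data[dep_schema$name]
  if (anyNA(dep_data)) abort("dependent variables must be fully observed")
  if (is.null(encoder)) encoder <- fit_encoder_drivers(dep_data, dep_schema)
  z <- encode_table(dep_data, encoder)$x
  colnames(z) <- encoded_colnames(encoder)
  if (is.null(center)) center <- colMeans(z)
  if (is.null(scale)) {
    scale <- apply(z, 2, stats::sd)
    scale[scale < 1e-12] <- 1
  }
  z <- sweep(sweep(z, 2, center), 2, scale, "/")
  list(z = z, center = center, scale = scale, encoder = encoder)
}

# Dependent variables may be constant-ish binaries; allow degenerate
# continuous drivers by widening a zero range instead of erroring.
fit_encoder_drivers <- function(data, schema) {
  tryCatch(fit_encoder(data, schema), error = function(e) {
    abort(paste0("could not encode dependent variables: ", conditionMessage(e)))
  })
}

encoded_colnames <- function(encoder) {
  lay <- encoder$layout
  unlist(purrr::map(seq_len(nrow(lay)), function(i) {
    w <- lay$end[i] - lay$start[i] + 1L
    if (w == 1L) lay$name[i] else paste0(lay$name[i], "=", encoder$schema$categories[[match(lay$name[i], encoder$schema$name)]])
  }))
}

#' Calibrate the MAR intercept for a nominal missingness rate
#'
#' Finds `c` such that the mean over rows of `plogis(c + z w)` equals
#' `rate` to within 1e-6. The mean is strictly increasing in `c`, so
#' bisection always converges to the unique solution.
#'
#' @param weights Coefficient vector over driver columns.
#' @param z Standardized driver matrix (rows = subjects).
#' @param rate Target missingness rate in (0, 1).
#' @return The calibrated intercept (a scalar).
#' @export
calibrate_intercept <- function(weights, z, rate) {
  eta <- as.vector(z %*% weights)
  f <- function(c) mean(plogis(c + eta)) - rate
  lo <- qlogis(rate) - max(abs(eta)) - 1
  hi <- qlogis(rate) + max(abs(eta)) + 1
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-9 && abs(f(mid)) < 1e-6) break
  }
  (lo + hi) / 2
}

#' Introduce MAR missingness into a complete table
#'
#' Each (row, target-variable) cell is masked independently with its
#' mechanism probability; dependent variables are never masked. The
#' result is deterministic given `seed` (mask sampling uses an RNG
#' stream separate from the one that drew the mechanism).
#'
#' @param data A complete tibble on which the mechanism can be evaluated.
#' @param mechanism A [draw_mar_mechanism()] result.
#' @param seed Integer seed for mask sampling.
#' @return A tibble identical to `data` but with masked cells set to `NA`.
#' @export
ampute <- function(data, mechanism, seed) {
  schema_cols <- c(mechanism$targets, mechanism$drivers)
  missing_cols <- setdiff(schema_cols, names(data))
  if (length(missing_cols)) abort(sprintf("data lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  dep_tbl <- data[mechanism$drivers]
  dep_schema <- mechanism$driver_encoder$schema
  z <- driver_matrix(
    dplyr::bind_cols(dep_tbl), dep_schema,
    encoder = mechanism$driver_encoder,
    center = mechanism$driver_center, scale = mechanism$driver_scale
  )$z
  prob <- plogis(sweep(z %*% t(mechanism$weights), 2, mechanism$intercepts, "+"))
  u <- with_seed(seed, matrix(runif(length(prob)), nrow = nrow(prob)))
  out <- data
  for (j in seq_along(mechanism$targets)) {
    tg <- mechanism$targets[j]
    out[[tg]][u[, j] < prob[, j]] <- NA
  }
  out
}

#' Generate replicate incomplete datasets at a nominal missingness rate
#'
#' Draws `n_replicates` independent MAR mechanisms (each with its own
#' randomized linear-combination weights) and applies each to the table,
#' reproducing the replicate design of repeated amputation at a fixed
#' rate. The default of 10 replicates matches the benchmark design.
#'
#' @inheritParams draw_mar_mechanism
#' @param n_replicates Number of incomplete datasets to generate.
#' @return A list of `n_replicates` tibbles with `NA` marking the
#'   amputed cells.
#' @export
ampute_replicates <- function(data, schema, rate, n_replicates = 10, seed = 1L) {
  n_replicates <- assert_count(n_replicates, "n_replicates")
  seeds <- matrix(derive_seeds(seed, 2L * n_replicates), ncol = 2L)
  purrr::map(seq_len(n_replicates), function(r) {
    mech <- draw_mar_mechanism(data, schema, rate, seed = seeds[r, 1])
    ampute(data, mech, seed = seeds[r, 2])
  })
}

#' @export
print.mar_mechanism <- function(x, ...) {
  cat(sprintf(
    "<mar_mechanism> rate %.2f; %d target variables driven by %d outcome(s)\n",
    x$rate, length(x$targets), length(x$drivers)
  ))
  invisible(x)
}

#' Tidy a MAR mechanism into its coefficient table
#'
#' @param x A `mar_mechanism`.
#' @param ... Unused.
#' @return A tibble with one row per (target, driver column) pair:
#'   `target`, `driver`, `weight`, `intercept`, `rate`.
#' @export
tidy.mar_mechanism <- function(x, ...) {
  tibble::tibble(
    target = rep(rownames(x$weights), times = ncol(x$weights)),
    driver = rep(colnames(x$weights), each = nrow(x$weights)),
    weight = as.vector(x$weights),
    intercept = rep(unname(x$intercepts), times = ncol(x$weights)),
    rate = x$rate
  )
}
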