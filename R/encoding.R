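#' Fit the encoder that maps a mixed-type table onto [0, 1]
#'
#' Continuous variables are min-max scaled using their observed range;
#' categorical variables are one-hot encoded in schema category order.
#' The resulting block layout assigns each variable a contiguous range of
#' encoded columns. Min-max (rather than z-scoring) is used so that a
#' sigmoid/softmax generator output is directly decodable back into the
#' variable's observed range.
#'
#' @param data A tibble conforming to `schema` (`NA` = missing).
#' @param schema A [mixed_schema].
#' @return An object of class `gain_encoder`: the schema, per-variable
#'   `min`/`max` (continuous), and a `layout` tibble mapping each
#'   variable to its encoded column range (`start`, `end`).
#' @export
fit_encoder <- function(data, schema) {
  validate_schema(schema)
  start <- 1L
  rows <- purrr::map(seq_len(nrow(schema)), function(i) {
    nm <- schema$name[i]
    x <- data[[nm]]
    obs <- x[!is.na(x)]
    if (schema$kind[i] == "continuous") {
      if (length(unique(obs)) < 2L) {
        abort(sprintf("degenerate scale: continuous variable '%s' needs >= 2 distinct observed values", nm))
      }
      w <- 1L
      lo <- min(obs); hi <- max(obs)
    } else {
      if (length(obs) < 1L) {
        abort(sprintf("categorical variable '%s' has no observed values", nm))
      }
      w <- length(schema$categories[[i]])
      lo <- NA_real_; hi <- NA_real_
    }
    r <- tibble::tibble(
      name = nm, kind = schema$kind[i], role = schema$role[i],
      start = start, end = start + w - 1L, min = lo, max = hi
    )
    start <<- start + w
    r
  })
  enc <- list(schema = schema, layout = dplyr::bind_rows(rows), width = start - 1L)
  class(enc) <- "gain_encoder"
  enc
}

#' @export
print.gain_encoder <- function(x, ...) {
  cat(sprintf(
    "<gain_encoder> %d variables -> %d encoded columns\n",
    nrow(x$layout), x$width
  ))
  print(x$layout)
  invisible(x)
}

#' Encode a mixed-type table into the matrix representation GAIN trains on
#'
#' Continuous cells become `(x - min) / (max - min)` clipped to `[0, 1]`;
#' categorical cells become one-hot blocks. Missing cells are encoded as 0
#' with encoded-mask 0; the variable-level mask is replicated across the
#' columns of a categorical block (a category is observed or missing as a
#' whole).
#'
#' @param data A tibble conforming to the encoder's schema.
#' @param encoder A [fit_encoder()] result.
#' @return A list with `x` (n x D numeric matrix in `[0, 1]`) and
#'   `m` (n x D 0/1 encoded mask).
#' @export
encode_table <- function(data, encoder) {
  lay <- encoder$layout
  n <- nrow(data)
  X <- matrix(0, n, encoder$width)
  M <- matrix(1, n, encoder$width)
  for (i in seq_len(nrow(lay))) {
    nm <- lay$name[i]
    x <- data[[nm]]
    cols <- lay$start[i]:lay$end[i]
    miss <- is.na(x)
    if (lay$kind[i] == "continuous") {
      z <- (x - lay$min[i]) / (lay$max[i] - lay$min[i])
      z <- pmin(pmax(z, 0), 1)
      z[miss] <- 0
      X[, cols] <- z
    } else {
      cats <- encoder$schema$categories[[match(nm, encoder$schema$name)]]
      idx <- match(x, cats)
      if (any(!miss & is.na(idx))) {
        bad <- which(!miss & is.na(idx))[1]
        abort(sprintf("value '%s' in column '%s' (row %d) outside schema categories", x[bad], nm, bad))
      }
      oh <- matrix(0, n, length(cols))
      ok <- which(!miss)
      oh[cbind(ok, idx[ok])] <- 1
      X[, cols] <- oh
    }
    M[miss, cols] <- 0
  }
  list(x = X, m = M)
}

#' Replace missing encoded entries by observed column means
#'
#' The mean-value fill used as the generator's noise substitute: each
#' missing encoded entry is replaced by the mean of its column over
#' observed entries (for a one-hot block this is the observed class
#' frequency vector). Observed entries are untouched, so the operation is
#' idempotent.
#'
#' @param x Encoded n x D matrix.
#' @param m Encoded 0/1 mask of the same shape.
#' @return The filled n x D matrix.
#' @export
mean_fill <- function(x, m) {
  n_obs <- colSums(m)
  if (any(n_obs == 0)) {
    abort(sprintf("encoded column %d has no observed entries", which(n_obs == 0)[1]))
  }
  mu <- colSums(x * m) / n_obs
  x * m + (1 - m) * rep(mu, each = nrow(x))
}

#' Decode an encoded matrix back into a mixed-type table
#'
#' Continuous columns are mapped back by `min + y * (max - min)`;
#' categorical blocks decode to the arg-max category, ties broken by the
#' lowest category index for reproducibility.
#'
#' @param x Encoded n x D numeric matrix.
#' @param encoder A [fit_encoder()] result.
#' @return A tibble with one column per schema variable.
#' @export
decode_table <- function(x, encoder) {
  lay <- encoder$layout
  out <- purrr::map(seq_len(nrow(lay)), function(i) {
    cols <- lay$start[i]:lay$end[i]
    if (lay$kind[i] == "continuous") {
      lay$min[i] + x[, cols] * (lay$max[i] - lay$min[i])
    } else {
      cats <- encoder$schema$categories[[match(lay$name[i], encoder$schema$name)]]
      block <- x[, cols, drop = FALSE]
      cats[max.col(block, ties.method = "first")]
    }
  })
  names(out) <- lay$name
  tibble::as_tibble(out)
}
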