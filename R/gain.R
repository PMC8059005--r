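#' GAIN hyperparameter configuration
#'
#' All hyperparameters of the adversarial imputation model. Together with
#' the data they fully determine training: two runs with the same config
#' and data produce bit-identical models.
#'
#' @param k Discriminator updates per generator update (positive integer).
#' @param p_hint Probability that the hint matrix reveals a mask entry to
#'   the discriminator, in `[0, 1]`.
#' @param alpha Weight of the continuous (squared-error) reconstruction
#'   loss on observed entries.
#' @param beta Weight of the categorical (cross-entropy) reconstruction
#'   loss on observed blocks.
#' @param n_iterations Number of training iterations (each = `k`
#'   discriminator steps plus one generator step).
#' @param hidden_layers Number of hidden layers in each network.
#' @param neurons_per_layer Width of each hidden layer; `NULL` (default)
#'   means the encoded data width `D`.
#' @param activation Hidden activation, `"relu"` or `"tanh"`.
#' @param learning_rate Step size for the optimizer.
#' @param optimizer `"sgd"`, `"momentum"` (0.9) or `"adam"`.
#' @param batch_size Minibatch size (rows sampled uniformly per step).
#' @param batchnorm_discriminator Also batch-normalize the discriminator's
#'   hidden layers (off by default: generator-only batch normalization is
#'   the stabler choice for adversarial training).
#' @param seed Integer seed controlling initialization, minibatch
#'   sampling and hint sampling.
#' @return A list of class `gain_config`.
#' @export
gain_config <- function(k = 1L, p_hint = 0.9, alpha = 10, beta = 10,
                        n_iterations = 5000L, hidden_layers = 2L,
                        neurons_per_layer = NULL, activation = c("relu", "tanh"),
                        learning_rate = 0.01, optimizer = c("sgd", "momentum", "adam"),
                        batch_size = 128L, batchnorm_discriminator = FALSE,
                        seed = 1L) {
  cfg <- list(
    k = assert_count(k, "k"),
    p_hint = assert_scalar_number(p_hint, "p_hint", 0, 1),
    alpha = assert_scalar_number(alpha, "alpha", 0),
    beta = assert_scalar_number(beta, "beta", 0),
    n_iterations = assert_count(n_iterations, "n_iterations", min = 0L),
    hidden_layers = assert_count(hidden_layers, "hidden_layers"),
    neurons_per_layer = if (is.null(neurons_per_layer)) NULL else assert_count(neurons_per_layer, "neurons_per_layer"),
    activation = match.arg(activation),
    learning_rate = assert_scalar_number(learning_rate, "learning_rate", 1e-12),
    optimizer = match.arg(optimizer),
    batch_size = assert_count(batch_size, "batch_size"),
    batchnorm_discriminator = isTRUE(batchnorm_discriminator),
    seed = as.integer(seed)
  )
  class(cfg) <- "gain_config"
  cfg
}

#' @export
print.gain_config <- function(x, ...) {
  cat("<gain_config>\n")
  flds <- setdiff(names(x), NULL)
  for (f in flds) cat(sprintf("  %s: %s\n", f, format(x[[f]] %||% "(data width)")))
  invisible(x)
}

# Column-block structure of the encoded space: indices of continuous
# columns, the list of categorical blocks, and one representative column
# per variable (used to collapse an encoded mask to variable level).
encoder_blocks <- function(encoder) {
  lay <- encoder$layout
  cont_cols <- lay$start[lay$kind == "continuous"]
  cat_rows <- which(lay$kind == "categorical")
  cat_blocks <- purrr::map(cat_rows, function(i) lay$start[i]:lay$end[i])
  var_cols <- purrr::map(seq_len(nrow(lay)), function(i) lay$start[i]:lay$end[i])
  list(
    cont_cols = cont_cols, cat_blocks = cat_blocks, var_cols = var_cols,
    var_rep_col = lay$start
  )
}

#' Sample a hint matrix for the discriminator
#'
#' For each (row, variable) the true mask value is revealed with
#' probability `p_hint`; otherwise the hint is the non-committal 0.5.
#' Reveal decisions are made per variable and replicated across the
#' columns of a categorical block. Draws come from the current RNG
#' state, so wrap in a seeded context for reproducibility.
#'
#' @param m Encoded 0/1 mask (n x D).
#' @param encoder The [fit_encoder()] state defining the block layout.
#' @param p_hint Reveal probability in `[0, 1]`.
#' @return An n x D matrix with entries in `{0, 0.5, 1}`.
#' @export
sample_hint <- function(m, encoder, p_hint) {
  blocks <- encoder_blocks(encoder)
  n <- nrow(m)
  nv <- length(blocks$var_cols)
  b_var <- matrix(rbinom(n * nv, 1L, p_hint), n, nv)
  h <- matrix(0, n, ncol(m))
  for (j in seq_len(nv)) {
    cols <- blocks$var_cols[[j]]
    bj <- b_var[, j]
    h[, cols] <- bj * m[, cols, drop = FALSE] + 0.5 * (1 - bj)
  }
  h
}

#' Discriminator loss: cross-entropy of observedness probabilities
#'
#' Mean over all encoded entries of the binary cross-entropy between the
#' discriminator's observedness probability and the true mask.
#' Probabilities are clipped to `[1e-8, 1 - 1e-8]`.
#'
#' @param d_prob n x D matrix of discriminator probabilities.
#' @param m Encoded 0/1 mask of the same shape.
#' @return A scalar loss.
#' @export
gain_discriminator_loss <- function(d_prob, m) {
  p <- pmin(pmax(d_prob, 1e-8), 1 - 1e-8)
  -mean(m * log(p) + (1 - m) * log(1 - p))
}

#' Generator loss: adversarial term plus weighted reconstruction
#'
#' The adversarial term is the mean of `-log p` over missing entries
#' (the generator wants the discriminator to believe they are observed).
#' Reconstruction adds `alpha` times the mean squared error over observed
#' continuous entries and `beta` times the mean cross-entropy over
#' observed categorical blocks, the mixed-type loss combination.
#' Normalizers are counts of observed entries/blocks so the weights keep
#' their meaning across missingness rates.
#'
#' @param d_prob Discriminator probabilities on the imputed matrix.
#' @param m Encoded 0/1 mask.
#' @param generated Generator output (n x D, in `[0, 1]`).
#' @param target Encoded true data (n x D).
#' @param encoder The [fit_encoder()] state (block layout).
#' @param alpha,beta Reconstruction weights for continuous/categorical
#'   parts.
#' @return A scalar loss.
#' @export
gain_generator_loss <- function(d_prob, m, generated, target, encoder, alpha, beta) {
  blocks <- encoder_blocks(encoder)
  p <- pmin(pmax(d_prob, 1e-8), 1 - 1e-8)
  n_miss <- sum(1 - m)
  adv <- if (n_miss > 0) -sum((1 - m) * log(p)) / n_miss else 0
  g <- pmin(pmax(generated, 1e-8), 1 - 1e-8)
  rec_cont <- 0
  if (length(blocks$cont_cols)) {
    mc <- m[, blocks$cont_cols, drop = FALSE]
    n_obs <- sum(mc)
    if (n_obs > 0) {
      diff2 <- (target[, blocks$cont_cols, drop = FALSE] - g[, blocks$cont_cols, drop = FALSE])^2
      rec_cont <- sum(mc * diff2) / n_obs
    }
  }
  rec_cat <- 0
  if (length(blocks$cat_blocks)) {
    tot <- 0
    n_blocks <- 0
    for (blk in blocks$cat_blocks) {
      mb <- m[, blk[1]]
      n_blocks <- n_blocks + sum(mb)
      tot <- tot - sum(mb * rowSums(target[, blk, drop = FALSE] * log(g[, blk, drop = FALSE])))
    }
    if (n_blocks > 0) rec_cat <- tot / n_blocks
  }
  adv + alpha * rec_cont + beta * rec_cat
}

#' Fit a GAIN imputation model
#'
#' Trains the adversarial pair on an incomplete mixed-type table. The
#' generator receives the mean-filled encoded data concatenated with the
#' mask and proposes values for every entry; the discriminator receives
#' the imputed matrix concatenated with a hint matrix and predicts which
#' entries were actually observed. Each iteration performs `k`
#' discriminator updates followed by one generator update on fresh
#' uniform minibatches. Generator hidden layers are batch-normalized.
#'
#' @param data A tibble with `NA` marking missing cells.
#' @param schema A [mixed_schema].
#' @param config A [gain_config()].
#' @return An object of class `gain_fit` with the trained networks, the
#'   encoder, the config and a per-iteration loss trace.
#' @seealso [impute_gain()], [gain_multiple_impute()]
#' @export
gain <- function(data, schema, config = gain_config()) {
  stopifnot(inherits(config, "gain_config"))
  encoder <- fit_encoder(data, schema)
  enc <- encode_table(data, encoder)
  D <- encoder$width
  width <- config$neurons_per_layer %||% D
  sizes <- c(2L * D, rep(width, config$hidden_layers), D)
  blocks <- encoder_blocks(encoder)
  x_fill <- mean_fill(enc$x, enc$m)
  n <- nrow(enc$x)
  bs <- min(config$batch_size, n)

  with_seed(config$seed, {
    g_net <- mlp_init(sizes, bn = TRUE)
    d_net <- mlp_init(sizes, bn = config$batchnorm_discriminator)
    g_state <- opt_init(g_net)
    d_state <- opt_init(d_net)
    trace <- matrix(NA_real_, config$n_iterations, 2L)
    t_d <- 0L
    t_g <- 0L

    for (it in seq_len(config$n_iterations)) {
      d_loss <- NA_real_
      for (s in seq_len(config$k)) {
        idx <- sample.int(n, bs)
        xb <- enc$x[idx, , drop = FALSE]
        mb <- enc$m[idx, , drop = FALSE]
        fb <- x_fill[idx, , drop = FALSE]
        gfwd <- mlp_forward(g_net, cbind(fb, mb), config$activation, training = TRUE)
        g_net <- gfwd$net
        gout <- output_heads(gfwd$logits, blocks$cont_cols, blocks$cat_blocks)
        xhat <- mb * xb + (1 - mb) * gout
        h <- sample_hint(mb, encoder, config$p_hint)
        dfwd <- mlp_forward(d_net, cbind(xhat, h), config$activation, training = TRUE)
        d_net <- dfwd$net
        p <- plogis(dfwd$logits)
        d_loss <- gain_discriminator_loss(p, mb)
        if (!is.finite(d_loss)) abort(sprintf("non-finite discriminator loss at iteration %d", it))
        dlogits <- (p - mb) / length(mb)
        bwd <- mlp_backward(d_net, dfwd$caches, dlogits, config$activation)
        upd <- opt_step(d_net, bwd$grads, d_state, config$optimizer, config$learning_rate, t_d <- t_d + 1L)
        d_net <- upd$net
        d_state <- upd$state
      }

      idx <- sample.int(n, bs)
      xb <- enc$x[idx, , drop = FALSE]
      mb <- enc$m[idx, , drop = FALSE]
      fb <- x_fill[idx, , drop = FALSE]
      gfwd <- mlp_forward(g_net, cbind(fb, mb), config$activation, training = TRUE)
      g_net <- gfwd$net
      gout <- output_heads(gfwd$logits, blocks$cont_cols, blocks$cat_blocks)
      xhat <- mb * xb + (1 - mb) * gout
      h <- sample_hint(mb, encoder, config$p_hint)
      dfwd <- mlp_forward(d_net, cbind(xhat, h), config$activation, training = TRUE)
      p <- plogis(dfwd$logits)
      g_loss <- gain_generator_loss(p, mb, gout, xb, encoder, config$alpha, config$beta)
      if (!is.finite(g_loss)) abort(sprintf("non-finite generator loss at iteration %d", it))

      # Adversarial gradient: through the discriminator into its input.
      n_miss <- sum(1 - mb)
      dg <- matrix(0, nrow(gout), ncol(gout))
      if (n_miss > 0) {
        pc <- pmin(pmax(p, 1e-8), 1 - 1e-8)
        d_dlogits <- -(1 - mb) * (1 - pc) / n_miss
        dbwd <- mlp_backward(d_net, dfwd$caches, d_dlogits, config$activation)
        dg <- dbwd$dinput[, seq_len(D), drop = FALSE] * (1 - mb)
      }
      # Reconstruction gradients on observed entries.
      gclip <- pmin(pmax(gout, 1e-8), 1 - 1e-8)
      if (length(blocks$cont_cols)) {
        mc <- mb[, blocks$cont_cols, drop = FALSE]
        n_obs <- sum(mc)
        if (n_obs > 0) {
          dg[, blocks$cont_cols] <- dg[, blocks$cont_cols, drop = FALSE] +
            config$alpha * 2 * mc *
              (gout[, blocks$cont_cols, drop = FALSE] - xb[, blocks$cont_cols, drop = FALSE]) / n_obs
        }
      }
      if (length(blocks$cat_blocks)) {
        n_blocks <- sum(vapply(blocks$cat_blocks, function(blk) sum(mb[, blk[1]]), numeric(1)))
        if (n_blocks > 0) {
          for (blk in blocks$cat_blocks) {
            mbk <- mb[, blk[1]]
            dg[, blk] <- dg[, blk, drop = FALSE] -
              config$beta * mbk * xb[, blk, drop = FALSE] / gclip[, blk, drop = FALSE] / n_blocks
          }
        }
      }
      dlogits_g <- output_heads_backward(dg, gout, blocks$cont_cols, blocks$cat_blocks)
      gbwd <- mlp_backward(g_net, gfwd$caches, dlogits_g, config$activation)
      upd <- opt_step(g_net, gbwd$grads, g_state, config$optimizer, config$learning_rate, t_g <- t_g + 1L)
      g_net <- upd$net
      g_state <- upd$state

      trace[it, ] <- c(d_loss, g_loss)
    }

    fit <- list(
      generator = g_net, discriminator = d_net, encoder = encoder,
      config = config,
      trace = tibble::tibble(
        iteration = seq_len(config$n_iterations),
        discriminator_loss = trace[, 1], generator_loss = trace[, 2]
      )
    )
    class(fit) <- "gain_fit"
    fit
  })
}

#' Impute an incomplete table with a trained GAIN model
#'
#' Produces `M * X + (1 - M) * G(mean_fill(X), M)` in encoded space and
#' decodes it. Observed cells are copied from the input exactly (never
#' round-tripped through the encoding), imputed categorical cells are
#' valid schema categories, and imputed continuous values lie within the
#' observed range of their column.
#'
#' @param fit A [gain()] model.
#' @param data A tibble conforming to the model's schema; defaults to
#'   imputing the kinds of tables the model was trained on.
#' @return A complete tibble.
#' @export
impute_gain <- function(fit, data) {
  stopifnot(inherits(fit, "gain_fit"))
  encoder <- fit$encoder
  enc <- encode_table(data, encoder)
  blocks <- encoder_blocks(encoder)
  x_fill <- mean_fill(enc$x, enc$m)
  gfwd <- mlp_forward(fit$generator, cbind(x_fill, enc$m), fit$config$activation, training = FALSE)
  gout <- output_heads(gfwd$logits, blocks$cont_cols, blocks$cat_blocks)
  xhat <- enc$m * enc$x + (1 - enc$m) * gout
  out <- decode_table(xhat, encoder)
  for (nm in names(out)) { # observed cells preserved exactly
    obs <- !is.na(data[[nm]])
    out[[nm]][obs] <- data[[nm]][obs]
  }
  out
}

#' Repeated GAIN imputation
#'
#' Runs `m` independently seeded train-and-impute cycles (the seed
#' stream is derived from `config$seed`), mirroring the repeated
#' imputation design used to measure imputation uncertainty; the study
#' design repeats 100 times per incomplete dataset.
#'
#' @inheritParams gain
#' @param m Number of repeated imputations.
#' @return A list of `m` complete tibbles.
#' @export
gain_multiple_impute <- function(data, schema, config = gain_config(), m = 100L) {
  m <- assert_count(m, "m")
  seeds <- derive_seeds(config$seed, m)
  purrr::map(seq_len(m), function(i) {
    cfg <- config
    cfg$seed <- seeds[i]
    fit <- gain(data, schema, cfg)
    impute_gain(fit, data)
  })
}

#' @export
print.gain_fit <- function(x, ...) {
  cat(sprintf(
    "<gain_fit> %d encoded columns, %d iterations (%s, lr %g)\n",
    x$encoder$width, x$config$n_iterations, x$config$optimizer, x$config$learning_rate
  ))
  if (x$config$n_iterations > 0) {
    lastd <- tail(x$trace$discriminator_loss, 1)
    lastg <- tail(x$trace$generator_loss, 1)
    cat(sprintf("  final losses: discriminator %.4f, generator %.4f\n", lastd, lastg))
  }
  invisible(x)
}

#' Tidy the training trace of a GAIN fit
#'
#' @param x A `gain_fit`.
#' @param ... Unused.
#' @return A tibble with one row per (iteration, loss component):
#'   `iteration`, `loss`, `value`.
#' @export
tidy.gain_fit <- function(x, ...) {
  tidyr::pivot_longer(x$trace, -"iteration", names_to = "loss", values_to = "value")
}

#' One-row summary of a GAIN fit
#'
#' @param x A `gain_fit`.
#' @param ... Unused.
#' @return A tibble with encoded width, iteration count and final losses.
#' @export
glance.gain_fit <- function(x, ...) {
  tibble::tibble(
    encoded_width = x$encoder$width,
    n_iterations = x$config$n_iterations,
    optimizer = x$config$optimizer,
    final_discriminator_loss = if (x$config$n_iterations > 0) tail(x$trace$discriminator_loss, 1) else NA_real_,
    final_generator_loss = if (x$config$n_iterations > 0) tail(x$trace$generator_loss, 1) else NA_real_
  )
}

#' Plot GAIN training losses
#'
#' @param object A `gain_fit`.
#' @param ... Unused.
#' @return A ggplot of discriminator and generator loss by iteration.
#' @export
autoplot.gain_fit <- function(object, ...) {
  df <- tidy.gain_fit(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value, colour = .data$loss)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "iteration", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}
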