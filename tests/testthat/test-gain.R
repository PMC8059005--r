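# Independent straight-line implementations of the loss formulas,
# written against the formulas themselves (explicit loops).
oracle_disc_loss <- function(p, m) {
  eps <- 1e-8
  tot <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      pc <- min(max(p[i, j], eps), 1 - eps)
      tot <- tot - (m[i, j] * log(pc) + (1 - m[i, j]) * log(1 - pc))
    }
  }
  tot / length(p)
}

oracle_gen_loss <- function(p, m, g, x, encoder, alpha, beta) {
  eps <- 1e-8
  lay <- encoder$layout
  adv_sum <- 0; n_miss <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (m[i, j] == 0) {
      adv_sum <- adv_sum - log(min(max(p[i, j], eps), 1 - eps))
      n_miss <- n_miss + 1
    }
  }
  mse_sum <- 0; n_cont <- 0
  ce_sum <- 0; n_blk <- 0
  for (v in seq_len(nrow(lay))) {
    cols <- lay$start[v]:lay$end[v]
    if (lay$kind[v] == "continuous") {
      for (i in seq_len(nrow(p))) {
        if (m[i, cols] == 1) {
          mse_sum <- mse_sum + (x[i, cols] - min(max(g[i, cols], eps), 1 - eps))^2
          n_cont <- n_cont + 1
        }
      }
    } else {
      for (i in seq_len(nrow(p))) {
        if (m[i, cols[1]] == 1) {
          for (cc in cols) ce_sum <- ce_sum - x[i, cc] * log(min(max(g[i, cc], eps), 1 - eps))
          n_blk <- n_blk + 1
        }
      }
    }
  }
  (if (n_miss > 0) adv_sum / n_miss else 0) +
    alpha * (if (n_cont > 0) mse_sum / n_cont else 0) +
    beta * (if (n_blk > 0) ce_sum / n_blk else 0)
}

random_encoded_instance <- function(seed, n = 6) {
  res <- random_table(n, 2, 2, seed = seed)
  enc <- fit_encoder(res$data, res$schema)
  set.seed(seed + 1)
  lay <- enc$layout
  m <- matrix(1, n, enc$width)
  for (v in seq_len(nrow(lay))) {
    miss <- rbinom(n, 1, 0.4) == 1
    m[miss, lay$start[v]:lay$end[v]] <- 0
  }
  g <- matrix(runif(n * enc$width, 0.05, 0.95), n, enc$width)
  for (v in which(lay$kind == "categorical")) {
    cols <- lay$start[v]:lay$end[v]
    g[, cols] <- g[, cols] / rowSums(g[, cols, drop = FALSE])
  }
  list(
    x = encode_table(res$data, enc)$x, m = m, g = g,
    p = matrix(runif(n * enc$width, 0.01, 0.99), n, enc$width),
    encoder = enc
  )
}

test_that("hint matrix reveals the mask with probability p_hint", {
  res <- random_table(1000, 2, 2, seed = 3)
  enc <- fit_encoder(res$data, res$schema)
  m <- encode_table(res$data, enc)$m
  set.seed(3)
  lay <- enc$layout
  for (v in seq_len(nrow(lay))) { # whole variables go missing together
    m[rbinom(1000, 1, 0.3) == 1, lay$start[v]:lay$end[v]] <- 0
  }

  expect_identical(with_seed_ <- withr::with_seed(1, sample_hint(m, enc, 1)), m)
  h0 <- withr::with_seed(1, sample_hint(m, enc, 0))
  expect_true(all(h0 == 0.5))

  h <- withr::with_seed(2, sample_hint(m, enc, 0.9))
  expect_true(all(h %in% c(0, 0.5, 1)))
  revealed <- mean(h != 0.5 | (h == 0.5 & m == 0.5)) # 0.5 only arises unrevealed
  expect_lt(abs(mean(h != 0.5) - 0.9), 0.01)
  # replication across blocks: hint constant within each variable block
  lay <- enc$layout
  for (v in which(lay$end > lay$start)) {
    blk <- h[, lay$start[v]:lay$end[v]]
    expect_true(all((blk == 0.5) == (blk[, 1] == 0.5)))
  }
})

test_that("discriminator loss matches ln 2 at chance, ~0 when perfect, and the formula", {
  m <- matrix(rbinom(12, 1, 0.5), 3, 4)
  expect_equal(gain_discriminator_loss(matrix(0.5, 3, 4), m), log(2), tolerance = 1e-10)
  expect_lt(gain_discriminator_loss(m, m), 1e-7)
  set.seed(9)
  p <- matrix(runif(6), 3, 2)
  m2 <- matrix(rbinom(6, 1, 0.5), 3, 2)
  expect_equal(gain_discriminator_loss(p, m2), oracle_disc_loss(p, m2), tolerance = 1e-12)
})

test_that("generator loss reduces to its reconstruction and adversarial parts", {
  inst <- random_encoded_instance(21)
  ones <- inst$m * 0 + 1
  # full mask: adversarial term vanishes, alpha*MSE + beta*CE remains
  full <- gain_generator_loss(inst$p, ones, inst$g, inst$x, inst$encoder, alpha = 2, beta = 3)
  expect_equal(full, oracle_gen_loss(inst$p, ones, inst$g, inst$x, inst$encoder, 2, 3),
               tolerance = 1e-10)
  # alpha = beta = 0: adversarial only
  advonly <- gain_generator_loss(inst$p, inst$m, inst$g, inst$x, inst$encoder, 0, 0)
  expect_equal(advonly, oracle_gen_loss(inst$p, inst$m, inst$g, inst$x, inst$encoder, 0, 0),
               tolerance = 1e-10)
  # perfect reconstruction: only the adversarial term remains
  perfect <- gain_generator_loss(inst$p, inst$m, inst$x, inst$x, inst$encoder, 5, 5)
  cats <- any(inst$encoder$layout$kind == "categorical")
  if (!cats) expect_equal(perfect, advonly, tolerance = 1e-10)
  expect_gte(perfect, 0)
})

test_that("loss formulas agree with straight-line oracles on random instances", {
  for (seed in 1:20) {
    inst <- random_encoded_instance(300 + seed)
    expect_equal(
      gain_discriminator_loss(inst$p, inst$m),
      oracle_disc_loss(inst$p, inst$m),
      tolerance = 1e-10
    )
    expect_equal(
      gain_generator_loss(inst$p, inst$m, inst$g, inst$x, inst$encoder, 1.5, 2.5),
      oracle_gen_loss(inst$p, inst$m, inst$g, inst$x, inst$encoder, 1.5, 2.5),
      tolerance = 1e-10
    )
  }
})

test_that("training is seed-deterministic and records its trace", {
  res <- random_table(80, 2, 1, seed = 31)
  data <- res$data
  set.seed(99)
  for (nm in c("x1", "x2", "c1")) data[[nm]][sample(80, 15)] <- NA

  f0 <- gain(data, res$schema, gain_config(n_iterations = 0, seed = 5))
  expect_equal(nrow(f0$trace), 0L)

  cfg <- gain_config(n_iterations = 30, batch_size = 32, seed = 5)
  f1 <- gain(data, res$schema, cfg)
  f2 <- gain(data, res$schema, cfg)
  expect_identical(f1$generator, f2$generator)
  expect_identical(f1$discriminator, f2$discriminator)
  expect_identical(f1$trace, f2$trace)
  expect_equal(nrow(f1$trace), 30L)
  expect_true(all(is.finite(f1$trace$generator_loss)))
  # a different seed gives different parameters
  f3 <- gain(data, res$schema, gain_config(n_iterations = 30, batch_size = 32, seed = 6))
  expect_false(identical(f1$generator, f3$generator))

  expect_s3_class(glance(f1), "tbl_df")
  expect_equal(nrow(tidy(f1)), 60L)
  expect_s3_class(autoplot(f1), "ggplot")
})

test_that("imputation preserves observed cells exactly and respects the schema", {
  res <- random_table(60, 2, 2, seed = 41)
  data <- res$data
  set.seed(7)
  for (nm in c("x1", "x2", "c1", "c2")) data[[nm]][sample(60, 12)] <- NA
  fit <- gain(data, res$schema, gain_config(n_iterations = 50, batch_size = 32, seed = 2))

  # complete table: output identical to input
  complete <- impute_mean_mode(data, res$schema)
  expect_identical(impute_gain(fit, complete), complete)

  imp <- impute_gain(fit, data)
  expect_false(anyNA(imp))
  for (nm in res$schema$name) {
    obs <- !is.na(data[[nm]])
    expect_identical(imp[[nm]][obs], data[[nm]][obs])
  }
  for (i in which(res$schema$kind == "categorical")) {
    nm <- res$schema$name[i]
    expect_true(all(imp[[nm]] %in% res$schema$categories[[i]]))
  }
  for (i in which(res$schema$kind == "continuous")) {
    nm <- res$schema$name[i]
    rng <- range(data[[nm]], na.rm = TRUE)
    expect_true(all(imp[[nm]] >= rng[1] & imp[[nm]] <= rng[2]))
  }
})

test_that("generator softmax blocks sum to one within 1e-6", {
  res <- random_table(40, 1, 2, seed = 51)
  data <- res$data
  set.seed(8)
  data$c1[sample(40, 10)] <- NA
  fit <- gain(data, res$schema, gain_config(n_iterations = 20, batch_size = 20, seed = 3))
  enc <- encode_table(data, fit$encoder)
  ns <- asNamespace("mixgain")
  blocks <- ns$encoder_blocks(fit$encoder)
  fwd <- ns$mlp_forward(fit$generator, cbind(mean_fill(enc$x, enc$m), enc$m), "relu", training = FALSE)
  g <- ns$output_heads(fwd$logits, blocks$cont_cols, blocks$cat_blocks)
  for (blk in blocks$cat_blocks) {
    expect_equal(rowSums(g[, blk, drop = FALSE]), rep(1, 40), tolerance = 1e-6)
  }
})

test_that("with p_hint = 1 the discriminator drives its loss toward zero", {
  res <- random_table(120, 2, 1, seed = 61)
  data <- res$data
  set.seed(4)
  for (nm in c("x1", "x2")) data[[nm]][sample(120, 40)] <- NA
  cfg <- gain_config(
    n_iterations = 300, batch_size = 64, p_hint = 1,
    optimizer = "adam", learning_rate = 0.005, seed = 1
  )
  fit <- gain(data, res$schema, cfg)
  late <- mean(tail(fit$trace$discriminator_loss, 20))
  expect_lt(late, 0.1) # hint reveals the answer; chance level is ln 2
})

test_that("repeated imputation derives independent seeds from the config", {
  res <- random_table(100, 2, 1, seed = 71)
  data <- res$data
  set.seed(12)
  for (nm in c("x1", "x2", "c1")) data[[nm]][sample(100, 50)] <- NA
  cfg <- gain_config(n_iterations = 40, batch_size = 32, seed = 10)

  imps <- gain_multiple_impute(data, res$schema, cfg, m = 2)
  expect_length(imps, 2L)
  expect_false(identical(imps[[1]], imps[[2]])) # different derived seeds differ

  one <- gain_multiple_impute(data, res$schema, cfg, m = 1)
  seed1 <- with_seed_helper <- asNamespace("mixgain")$derive_seeds(10, 1)
  cfg1 <- cfg
  cfg1$seed <- seed1
  direct <- impute_gain(gain(data, res$schema, cfg1), data)
  expect_identical(one[[1]], direct)
})
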