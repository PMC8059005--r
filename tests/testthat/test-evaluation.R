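# Brute-force metric oracles: explicit loops over cells, straight from
# the printed formulas.
oracle_nrmse <- function(xhat, x, scored) {
  num <- 0; n <- 0; s <- 0
  for (i in seq_along(x)) {
    if (scored[i]) {
      num <- num + (xhat[i] - x[i])^2
      s <- s + x[i]
      n <- n + 1
    }
  }
  sqrt(num / n) / (s / n)
}

oracle_pfc <- function(xhat, x, scored) {
  correct <- 0; n <- 0
  for (i in seq_along(x)) {
    if (scored[i]) {
      n <- n + 1
      if (xhat[i] == x[i]) correct <- correct + 1
    }
  }
  1 - correct / n
}

eval_fixture <- function(seed = 1, n = 50) {
  res <- random_table(n, 2, 2, seed = seed)
  truth <- res$data
  set.seed(seed + 500)
  incomplete <- truth
  for (nm in c("x1", "x2", "c1", "c2")) incomplete[[nm]][sample(n, n %/% 4)] <- NA
  mask <- mask_from_data(incomplete)
  list(truth = truth, mask = mask, schema = res$schema)
}

test_that("nrmse matches the printed formula and its worked example", {
  fx <- eval_fixture()
  expect_equal(nrmse(fx$truth, fx$truth, fx$mask, "x1"), 0) # perfect imputation

  # x_hat = (1, 2, 3) vs x = (2, 2, 2): sqrt(2/3)/2
  truth <- tibble::tibble(v = c(2, 2, 2))
  imp <- tibble::tibble(v = c(1, 2, 3))
  mask <- matrix(0L, 3, 1, dimnames = list(NULL, "v"))
  expect_equal(nrmse(imp, truth, mask, "v"), sqrt(2 / 3) / 2, tolerance = 1e-12)

  # scale invariance
  expect_equal(
    nrmse(dplyr::mutate(imp, v = 7 * v), dplyr::mutate(truth, v = 7 * v), mask, "v"),
    nrmse(imp, truth, mask, "v"),
    tolerance = 1e-12
  )

  # unmasked cells have no influence
  imp2 <- fx$truth
  imp2$x1[fx$mask[, "x1"] == 1L] <- 999
  expect_equal(nrmse(imp2, fx$truth, fx$mask, "x1"), 0)

  zero <- tibble::tibble(v = c(-1, 0, 1))
  expect_error(nrmse(tibble::tibble(v = c(0, 0, 0)), zero, mask, "v"), "zero-mean")
  allobs <- matrix(1L, 3, 1, dimnames = list(NULL, "v"))
  expect_error(nrmse(imp, truth, allobs, "v"), "no masked cells")
})

test_that("pfc counts misclassified masked cells", {
  truth <- tibble::tibble(c = c("a", "b", "a", "b", "a"))
  mask <- matrix(0L, 5, 1, dimnames = list(NULL, "c"))
  expect_equal(pfc(truth, truth, mask, "c"), 0)
  expect_equal(pfc(tibble::tibble(c = c("b", "a", "b", "a", "b")), truth, mask, "c"), 1)
  expect_equal(pfc(tibble::tibble(c = c("a", "b", "a", "a", "b")), truth, mask, "c"), 0.4)
  expect_error(pfc(truth, truth, matrix(1L, 5, 1, dimnames = list(NULL, "c")), "c"), "no masked")
})

test_that("metrics agree with brute-force recomputation on random instances", {
  for (seed in 1:40) {
    fx <- eval_fixture(seed = seed, n = 30)
    set.seed(seed + 900)
    imp <- fx$truth
    imp$x1 <- imp$x1 + rnorm(30)
    imp$c1 <- sample(unique(fx$truth$c1), 30, replace = TRUE)
    scored1 <- fx$mask[, "x1"] == 0L
    expect_equal(nrmse(imp, fx$truth, fx$mask, "x1"),
                 oracle_nrmse(imp$x1, fx$truth$x1, scored1), tolerance = 1e-12)
    scoredc <- fx$mask[, "c1"] == 0L
    expect_equal(pfc(imp, fx$truth, fx$mask, "c1"),
                 oracle_pfc(imp$c1, fx$truth$c1, scoredc), tolerance = 1e-12)
    expect_gte(pfc(imp, fx$truth, fx$mask, "c1"), 0)
    expect_lte(pfc(imp, fx$truth, fx$mask, "c1"), 1)
  }
})

test_that("evaluate_imputations aggregates per-variable metrics across repeats", {
  fx <- eval_fixture(seed = 7)
  set.seed(11)
  imps <- lapply(1:5, function(i) {
    imp <- fx$truth
    imp$x1 <- imp$x1 + rnorm(50, sd = 0.5)
    imp$x2 <- imp$x2 + rnorm(50, sd = 0.5)
    imp
  })
  rep1 <- evaluate_imputations(imps[1], fx$truth, fx$mask, fx$schema, method = "jitter")
  expect_equal(rep1$sd, rep(0, nrow(rep1)))
  expect_equal(rep1$m, rep(1L, nrow(rep1)))

  same <- evaluate_imputations(rep(imps[1], 10), fx$truth, fx$mask, fx$schema)
  expect_equal(same$sd, rep(0, nrow(same)))

  rep5 <- evaluate_imputations(imps, fx$truth, fx$mask, fx$schema, method = "jitter")
  expect_setequal(rep5$variable, c("x1", "x2", "c1", "c2"))
  # recomputation oracle: mean equals the average of per-imputation metrics
  for (v in c("x1", "x2")) {
    vals <- vapply(imps, nrmse, numeric(1), truth = fx$truth, mask = fx$mask, variable = v)
    expect_equal(rep5$mean[rep5$variable == v], mean(vals), tolerance = 1e-12)
    expect_equal(rep5$sd[rep5$variable == v], sd(vals), tolerance = 1e-12)
  }
  # permutation invariance in the order of imputations
  shuffled <- evaluate_imputations(rev(imps), fx$truth, fx$mask, fx$schema, method = "jitter")
  expect_equal(rep5$mean, shuffled$mean, tolerance = 1e-15)
  expect_equal(rep5$sd, shuffled$sd, tolerance = 1e-15)

  expect_s3_class(plot_eval_report(rep5), "ggplot")
})

test_that("method comparison gates pairwise tests on the omnibus result", {
  per_repeat <- function(vals_by_method, variable = "x1", metric = "nrmse") {
    dplyr::bind_rows(purrr::imap(vals_by_method, function(v, m) {
      tibble::tibble(method = m, variable = variable, metric = metric, value = v)
    }))
  }
  # identical methods: no difference, no flags
  same <- per_repeat(list(a = rep(0.3, 10), b = rep(0.3, 10)))
  cmp <- compare_methods(same)
  expect_equal(cmp$omnibus_p, 1)
  expect_equal(nrow(cmp$pairwise[[1]]), 0L)

  # overwhelming separation: flagged
  set.seed(2)
  apart <- per_repeat(list(a = rnorm(100, 0.1, 0.01), b = rnorm(100, 0.5, 0.01)))
  cmp <- compare_methods(apart)
  expect_lt(cmp$omnibus_p, 0.05)
  pw <- cmp$pairwise[[1]]
  expect_true(all(pw$significant))

  # three identical methods: omnibus not significant, no pairwise tests
  trip <- per_repeat(list(a = rep(0.2, 5), b = rep(0.2, 5), c = rep(0.2, 5)))
  cmp <- compare_methods(trip)
  expect_equal(nrow(cmp$pairwise[[1]]), 0L)

  expect_error(compare_methods(per_repeat(list(a = c(0.1, 0.2), b = c(0.1, 0.2)))), "at least 3")
  expect_error(compare_methods(per_repeat(list(a = rnorm(5)))), "at least 2 methods")
})

test_that("non-normal metric values fall back to rank-based tests", {
  set.seed(3)
  skewed <- dplyr::bind_rows(
    tibble::tibble(method = "a", variable = "x1", metric = "nrmse", value = exp(rnorm(80, 0, 1.5))),
    tibble::tibble(method = "b", variable = "x1", metric = "nrmse", value = exp(rnorm(80, 2, 1.5)))
  )
  cmp <- compare_methods(skewed)
  expect_equal(cmp$omnibus_test, "kruskal")
  expect_lt(cmp$omnibus_p, 0.05)
})
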