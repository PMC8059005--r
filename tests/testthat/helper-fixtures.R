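# Shared fixtures: small schemas/tables built in code, plus the
# strongly correlated synthetic cohort used by the GAIN experiments.

tiny_schema <- function() {
  mixed_schema(
    name = c("sbp", "glucose", "smoker", "died"),
    kind = c("continuous", "continuous", "categorical", "categorical"),
    role = c("independent", "independent", "independent", "dependent"),
    categories = list(NULL, NULL, c("no", "yes"), c("no", "yes"))
  )
}

tiny_data <- function() {
  tibble::tibble(
    sbp = c(120, 140, NA, 160, 110),
    glucose = c(5.1, NA, 6.2, 7.8, 5.5),
    smoker = c("no", "yes", "yes", NA, "no"),
    died = c("no", "no", "yes", "no", "yes")
  )
}

# Random valid complete table + schema, for property tests.
random_table <- function(n, d_cont, d_cat, seed) {
  set.seed(seed)
  cont <- if (d_cont > 0) paste0("x", seq_len(d_cont)) else character()
  cat <- if (d_cat > 0) paste0("c", seq_len(d_cat)) else character()
  cat_levels <- lapply(seq_len(d_cat), function(i) paste0("L", seq_len(sample(2:4, 1))))
  schema <- mixed_schema(
    name = c(cont, cat, "outcome"),
    kind = c(rep("continuous", d_cont), rep("categorical", d_cat), "categorical"),
    role = c(rep("independent", d_cont + d_cat), "dependent"),
    categories = c(vector("list", d_cont), cat_levels, list(c("no", "yes")))
  )
  cols <- c(
    lapply(seq_len(d_cont), function(i) rnorm(n, mean = runif(1, -50, 50), sd = runif(1, 0.5, 20))),
    lapply(seq_len(d_cat), function(i) sample(cat_levels[[i]], n, replace = TRUE)),
    list(sample(c("no", "yes"), n, replace = TRUE))
  )
  names(cols) <- schema$name
  # guarantee >= 2 distinct values per continuous column even at n = 1..2
  data <- tibble::as_tibble(cols)
  list(data = data, schema = schema)
}

# The correlated mixed-type cohort used for GAIN sanity experiments:
# 3 continuous + 2 categorical predictors under an exchangeable 0.85
# latent correlation, one binary outcome.
correlated_spec <- function(n = 2000, rho = 0.85, seed = 11) {
  p <- 5
  corr <- matrix(rho, p, p)
  diag(corr) <- 1
  synthetic_spec(
    n = n,
    continuous = tibble::tibble(
      name = c("x1", "x2", "x3"), family = "normal",
      location = c(100, 50, 10), scale = c(15, 8, 2)
    ),
    categorical = tibble::tibble(
      name = c("c1", "c2"),
      categories = list(c("a", "b"), c("u", "v", "w")),
      proportions = list(c(0.55, 0.45), c(0.4, 0.35, 0.25))
    ),
    correlation = corr,
    outcomes = tibble::tibble(
      name = "y", coefficients = list(c(0.8, 0.5, -0.5, 0.6, 0.4)), intercept = -1
    ),
    seed = seed
  )
}

# The experiment configuration used for GAIN-vs-baseline comparisons
# (reference GAIN practice: Adam with dominant reconstruction weights).
experiment_gain_config <- function(n_iterations = 2000L, seed = 1L, ...) {
  gain_config(
    n_iterations = n_iterations, optimizer = "adam", learning_rate = 0.001,
    alpha = 100, beta = 100, seed = seed, ...
  )
}

mean_metric <- function(imputed, truth, mask, vars, f) {
  mean(vapply(vars, function(v) f(imputed, truth, mask, v), numeric(1)))
}
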