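#' @keywords internal
#' @importFrom rlang abort warn .data :=
#' @importFrom stats rnorm runif rbinom qnorm quantile sd var median
#'   plogis qlogis glm binomial coef lm predict aov kruskal.test t.test
#'   wilcox.test shapiro.test anova setNames complete.cases
#' @importFrom utils head tail
"_PACKAGE"

# Evaluate `code` under a temporarily seeded RNG, restoring the caller's
# RNG state afterwards so library calls never perturb user simulations.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive `n` independent child seeds from one parent seed. Keeps every
# derived seed strictly below 2^31 so it is a valid R integer.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
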