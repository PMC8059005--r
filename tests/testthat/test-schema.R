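test_that("schema constructor enforces its invariants", {
  expect_s3_class(tiny_schema(), "mixed_schema")
  expect_error(mixed_schema(c("a", "a"), "continuous"), "duplicate")
  expect_error(mixed_schema("a", "categorical"), "non-empty category list")
  expect_error(
    mixed_schema("a", "categorical", categories = list(c("x", "x"))),
    "unique"
  )
  expect_error(
    mixed_schema("a", "continuous", categories = list("x")),
    "must not declare categories"
  )
  expect_error(mixed_schema("a", "count"), "unknown variable kind")
})

test_that("complete CSV reads with an all-ones mask and empty cells map to mask zero", {
  schema <- tiny_schema()
  data <- tiny_data()
  complete <- impute_mean_mode(data, schema)
  path <- withr::local_tempfile(fileext = ".csv")
  write_mixed_table(complete, path, schema)
  got <- read_mixed_table(path, schema)
  expect_true(all(got$mask == 1L))

  write_mixed_table(data, path, schema)
  got <- read_mixed_table(path, schema)
  expect_equal(got$mask[3, "sbp"], c(sbp = 0L))
  expect_equal(got$mask[2, "glucose"], c(glucose = 0L))
  expect_equal(sum(got$mask == 0L), 3L)
})

test_that("reading rejects schema violations with the offending cell named", {
  schema <- tiny_schema()
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sbp,glucose,smoker,died", "120,5.0,maybe,no"), path)
  expect_error(read_mixed_table(path, schema), "maybe.*smoker.*row 1")
  writeLines(c("sbp,glucose,smoker,died", "high,5.0,no,no"), path)
  expect_error(read_mixed_table(path, schema), "non-numeric.*sbp")
  writeLines(c("sbp,glucose,smoker,died,extra", "120,5.0,no,no,1"), path)
  expect_error(read_mixed_table(path, schema), "unknown column")
})

test_that("write/read round-trip is exact for values, mask and quoted labels", {
  res <- random_table(10, 3, 2, seed = 5)
  # awkward labels: delimiter and quotes must survive RFC-4180 quoting
  res$schema$categories[[4]] <- c("a,b", "with \"quote\"", "plain")
  res$data$c1 <- sample(res$schema$categories[[4]], 10, replace = TRUE)
  res$data$x1[c(2, 7)] <- NA
  res$data$c1[5] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  mpath <- withr::local_tempfile(fileext = ".csv")
  write_mixed_table(res$data, path, res$schema, mask_path = mpath)
  got <- read_mixed_table(path, res$schema)
  expect_identical(got$data, res$data)
  expect_identical(got$mask, mask_from_data(res$data))
  expect_identical(read_mask(mpath, res$schema), mask_from_data(res$data))
  # raw CSV has empty fields where the mask is 0
  line3 <- readr::read_lines(path)[3]
  expect_match(line3, "^,")
})

test_that("read/write identity holds across random table shapes", {
  for (case in list(c(1, 1, 0), c(3, 0, 2), c(25, 4, 3), c(200, 6, 4))) {
    res <- random_table(case[1], case[2], case[3], seed = sum(case) + 13)
    path <- withr::local_tempfile(fileext = ".csv")
    spath <- withr::local_tempfile(fileext = ".yaml")
    write_schema(res$schema, spath)
    write_mixed_table(res$data, path, res$schema)
    got <- read_mixed_table(path, spath)
    expect_identical(got$data, res$data)
    expect_equal(tibble::as_tibble(got$schema), tibble::as_tibble(res$schema))
  }
})

test_that("validate_mixed reports violations instead of throwing", {
  schema <- tiny_schema()
  data <- tiny_data()
  expect_identical(nrow(validate_mixed(impute_mean_mode(data, schema), schema)), 0L)

  bad <- data
  bad$died[2] <- NA # masked dependent cell
  v <- validate_mixed(bad, schema)
  expect_true(any(v$rule == "dependent_observed"))
  expect_match(v$message[v$rule == "dependent_observed"], "fully observed")

  infbad <- impute_mean_mode(data, schema)
  infbad$sbp[1] <- Inf
  v <- validate_mixed(infbad, schema)
  expect_true(any(v$rule == "finite" & v$row == 1L & v$column == "sbp"))

  # NaN: in R it carries the missing sentinel, so a mask claiming the
  # cell observed is a mask/data inconsistency
  nanbad <- impute_mean_mode(data, schema)
  mask <- mask_from_data(nanbad)
  nanbad$sbp[1] <- NaN
  v <- validate_mixed(nanbad, schema, mask)
  expect_true(any(v$rule == "mask_consistency" & v$row == 1L))

  # mask says observed but value missing
  complete <- impute_mean_mode(data, schema)
  mask <- mask_from_data(complete)
  withval <- complete
  withval$sbp[4] <- NA
  v <- validate_mixed(withval, schema, mask)
  expect_true(any(v$rule == "mask_consistency"))
})

test_that("validate_mixed always flags a masked dependent column", {
  for (seed in 1:5) {
    res <- random_table(20, 2, 1, seed = seed)
    data <- res$data
    set.seed(seed)
    data$outcome[sample(20, 3)] <- NA
    v <- validate_mixed(data, res$schema)
    expect_true(any(v$rule == "dependent_observed"), info = paste("seed", seed))
  }
})
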