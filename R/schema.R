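#' Declare the schema of a mixed-type table
#'
#' A schema declares, for every column of a dataset, whether it is
#' continuous or categorical, the legal category labels, and its role:
#' `"independent"` variables are imputation targets, `"dependent"`
#' variables (outcomes) are always fully observed and drive the
#' missing-at-random amputation mechanism.
#'
#' @param name Character vector of unique variable names.
#' @param kind Character vector, each `"continuous"` or `"categorical"`.
#' @param role Character vector, each `"independent"` or `"dependent"`.
#' @param categories List of character vectors of category labels, one per
#'   variable; must be `NULL` for continuous variables and a non-empty
#'   vector of unique labels for categorical ones. The order given here is
#'   the canonical category order used throughout encoding and decoding.
#'
#' @return A tibble of class `mixed_schema` with columns `name`, `kind`,
#'   `role` and the list-column `categories`.
#' @examples
#' mixed_schema(
#'   name = c("sbp", "smoker", "died"),
#'   kind = c("continuous", "categorical", "categorical"),
#'   role = c("independent", "independent", "dependent"),
#'   categories = list(NULL, c("no", "yes"), c("no", "yes"))
#' )
#' @export
mixed_schema <- function(name, kind, role = "independent", categories = NULL) {
  d <- length(name)
  role <- rep_len(role, d)
  kind <- rep_len(kind, d)
  if (is.null(categories)) categories <- vector("list", d)
  out <- tibble::tibble(
    name = as.character(name),
    kind = as.character(kind),
    role = as.character(role),
    categories = categories
  )
  class(out) <- c("mixed_schema", class(out))
  validate_schema(out)
  out
}

validate_schema <- function(schema) {
  if (nrow(schema) < 1L) abort("schema must declare at least one variable")
  if (anyDuplicated(schema$name)) {
    abort(sprintf(
      "duplicate variable names in schema: %s",
      paste(unique(schema$name[duplicated(schema$name)]), collapse = ", ")
    ))
  }
  bad_kind <- setdiff(unique(schema$kind), c("continuous", "categorical"))
  if (length(bad_kind)) abort(sprintf("unknown variable kind: %s", paste(bad_kind, collapse = ", ")))
  bad_role <- setdiff(unique(schema$role), c("independent", "dependent"))
  if (length(bad_role)) abort(sprintf("unknown variable role: %s", paste(bad_role, collapse = ", ")))
  for (i in seq_len(nrow(schema))) {
    cats <- schema$categories[[i]]
    if (schema$kind[i] == "categorical") {
      if (is.null(cats) || length(cats) < 1L) {
        abort(sprintf("categorical variable '%s' needs a non-empty category list", schema$name[i]))
      }
      if (anyDuplicated(cats)) {
        abort(sprintf("categories of '%s' must be unique", schema$name[i]))
      }
    } else if (!is.null(cats)) {
      abort(sprintf("continuous variable '%s' must not declare categories", schema$name[i]))
    }
  }
  invisible(schema)
}

#' Read or write a schema sidecar file
#'
#' The sidecar is a YAML document with one record per variable
#' (`name`, `kind`, `role`, and `categories` for categorical variables).
#'
#' @param path Path to the YAML sidecar.
#' @return `read_schema()` returns a [mixed_schema] tibble;
#'   `write_schema()` returns `path` invisibly.
#' @export
read_schema <- function(path) {
  recs <- yaml::read_yaml(path)
  if (!length(recs)) abort(sprintf("empty schema file: %s", path))
  mixed_schema(
    name = vapply(recs, function(r) r$name, character(1)),
    kind = vapply(recs, function(r) r$kind, character(1)),
    role = vapply(recs, function(r) r$role %||% "independent", character(1)),
    categories = lapply(recs, function(r) {
      if (is.null(r$categories)) NULL else as.character(r$categories)
    })
  )
}

#' @param schema A [mixed_schema].
#' @rdname read_schema
#' @export
write_schema <- function(schema, path) {
  validate_schema(schema)
  recs <- lapply(seq_len(nrow(schema)), function(i) {
    r <- list(name = schema$name[i], kind = schema$kind[i], role = schema$role[i])
    if (schema$kind[i] == "categorical") r$categories <- as.list(schema$categories[[i]])
    r
  })
  yaml::write_yaml(recs, path)
  invisible(path)
}

#' Read a mixed-type table and its observedness mask from CSV
#'
#' Reads an RFC-4180 CSV whose header must match the schema's variable
#' names; empty fields denote missing cells. Every cell is validated
#' against the schema and violations raise an error naming the offending
#' row and column.
#'
#' @param path Path to the data CSV.
#' @param schema A [mixed_schema] or path to a schema sidecar file.
#' @param mask_path Optional path to a 0/1 mask CSV (1 = observed) with
#'   the same header; when supplied, cells with mask 0 are forced missing.
#' @return A list with elements `data` (a tibble, `NA` marking missing
#'   cells), `schema`, and `mask` (integer matrix, 1 = observed).
#' @export
read_mixed_table <- function(path, schema, mask_path = NULL) {
  if (is.character(schema)) schema <- read_schema(schema)
  validate_schema(schema)
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  extra <- setdiff(names(raw), schema$name)
  if (length(extra)) abort(sprintf("unknown column(s) in %s: %s", path, paste(extra, collapse = ", ")))
  missing_cols <- setdiff(schema$name, names(raw))
  if (length(missing_cols)) abort(sprintf("column(s) missing from %s: %s", path, paste(missing_cols, collapse = ", ")))
  raw <- raw[schema$name]
  data <- parse_mixed_columns(raw, schema)
  mask <- mask_from_data(data)
  if (!is.null(mask_path)) {
    mask2 <- read_mask(mask_path, schema)
    if (!identical(dim(mask2), dim(mask))) abort("mask file shape does not match data")
    data <- apply_mask(data, mask2)
    mask <- mask2
  }
  viols <- validate_mixed(data, schema, mask)
  if (nrow(viols)) {
    abort(sprintf(
      "invalid table %s: %s%s", path,
      paste(utils::head(viols$message, 5), collapse = "; "),
      if (nrow(viols) > 5) sprintf(" (and %d more)", nrow(viols) - 5L) else ""
    ))
  }
  list(data = data, schema = schema, mask = mask)
}

parse_mixed_columns <- function(raw, schema) {
  out <- purrr::map2(schema$name, seq_len(nrow(schema)), function(nm, i) {
    x <- raw[[nm]]
    x[!is.na(x) & x == ""] <- NA_character_
    if (schema$kind[i] == "continuous") {
      y <- suppressWarnings(as.numeric(x))
      bad <- which(!is.na(x) & is.na(y))
      if (length(bad)) {
        abort(sprintf(
          "non-numeric value '%s' in continuous column '%s' (row %d)",
          x[bad[1]], nm, bad[1]
        ))
      }
      y
    } else {
      cats <- schema$categories[[i]]
      bad <- which(!is.na(x) & !(x %in% cats))
      if (length(bad)) {
        abort(sprintf(
          "value '%s' in column '%s' (row %d) is not one of: %s",
          x[bad[1]], nm, bad[1], paste(cats, collapse = ", ")
        ))
      }
      x
    }
  })
  names(out) <- schema$name
  tibble::as_tibble(out)
}

#' Write a mixed-type table (and optionally its mask) to CSV
#'
#' Missing cells are written as empty fields. Continuous values are
#' serialized with 17 significant digits so that reading the file back
#' reproduces them bit-exactly.
#'
#' @param data A tibble conforming to `schema` (`NA` = missing).
#' @param path Output CSV path.
#' @param schema A [mixed_schema].
#' @param mask_path Optional path for the companion 0/1 mask CSV.
#' @return `path`, invisibly.
#' @export
write_mixed_table <- function(data, path, schema, mask_path = NULL) {
  validate_schema(schema)
  chr <- purrr::map2(schema$name, schema$kind, function(nm, kind) {
    x <- data[[nm]]
    out <- if (kind == "continuous") {
      formatC(x, digits = 17, format = "g", mode = "double")
    } else {
      as.character(x)
    }
    out[is.na(x)] <- NA_character_
    out
  })
  names(chr) <- schema$name
  readr::write_csv(tibble::as_tibble(chr), path, na = "", progress = FALSE)
  if (!is.null(mask_path)) write_mask(mask_from_data(data), mask_path)
  invisible(path)
}

#' Observedness masks
#'
#' A mask is an integer matrix with one column per variable and entries
#' 1 (observed) or 0 (missing). `mask_from_data()` derives it from the
#' `NA` pattern; `apply_mask()` blanks cells with mask 0.
#'
#' @param data A tibble of mixed-type data.
#' @return `mask_from_data()`: an integer matrix; `apply_mask()`: `data`
#'   with masked cells set to `NA`.
#' @export
mask_from_data <- function(data) {
  m <- 1L - vapply(data, function(x) as.integer(is.na(x)), integer(nrow(data)))
  if (nrow(data) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(data)))
  m
}

#' @param mask An integer 0/1 matrix with columns matching `data`.
#' @rdname mask_from_data
#' @export
apply_mask <- function(data, mask) {
  for (j in seq_along(data)) {
    data[[j]][mask[, j] == 0L] <- NA
  }
  data
}

#' @rdname read_schema
#' @param path Path to a 0/1 CSV with the same header as the data.
#' @export
read_mask <- function(path, schema) {
  if (is.character(schema)) schema <- read_schema(schema)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_integer()), progress = FALSE)
  if (!setequal(names(raw), schema$name)) abort("mask header does not match schema")
  m <- as.matrix(raw[schema$name])
  if (any(!m %in% c(0L, 1L))) abort("mask entries must be 0 or 1")
  storage.mode(m) <- "integer"
  m
}

write_mask <- function(mask, path) {
  readr::write_csv(tibble::as_tibble(as.data.frame(mask)), path, progress = FALSE)
  invisible(path)
}

#' Validate a mixed-type table against its schema
#'
#' Unlike [read_mixed_table()], which throws, `validate_mixed()` returns
#' every violation found as a row of a tibble, so callers can report them
#' all at once.
#'
#' @param data A tibble (`NA` = missing cells).
#' @param schema A [mixed_schema].
#' @param mask Optional mask matrix; defaults to the `NA` pattern of
#'   `data`. Supplying it additionally checks mask/data consistency.
#' @return A tibble with columns `row` (`NA` for table-level rules),
#'   `column`, `rule`, `message`; zero rows iff the table is valid.
#' @export
validate_mixed <- function(data, schema, mask = NULL) {
  validate_schema(schema)
  v <- list()
  add <- function(row, column, rule, message) {
    v[[length(v) + 1L]] <<- tibble::tibble(
      row = as.integer(row), column = column, rule = rule, message = message
    )
  }
  if (!setequal(names(data), schema$name)) {
    add(NA, NA_character_, "columns", "data columns do not match schema names")
    return(dplyr::bind_rows(v))
  }
  if (nrow(data) < 1L) add(NA, NA_character_, "shape", "table must have at least one row")
  if (is.null(mask)) mask <- mask_from_data(data)
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    x <- data[[nm]]
    obs <- mask[, nm] == 1L
    if (any(obs & is.na(x))) {
      for (r in which(obs & is.na(x))) {
        add(r, nm, "mask_consistency", sprintf("cell (%d, %s) marked observed but missing", r, nm))
      }
    }
    if (any(!obs & !is.na(x))) {
      for (r in which(!obs & !is.na(x))) {
        add(r, nm, "mask_consistency", sprintf("cell (%d, %s) marked missing but carries a value", r, nm))
      }
    }
    if (schema$kind[i] == "continuous") {
      bad <- which(obs & !is.na(x) & !is.finite(x))
      for (r in bad) add(r, nm, "finite", sprintf("non-finite value in continuous cell (%d, %s)", r, nm))
    } else {
      cats <- schema$categories[[i]]
      bad <- which(obs & !is.na(x) & !(x %in% cats))
      for (r in bad) {
        add(r, nm, "category", sprintf("value '%s' in cell (%d, %s) outside schema categories", x[r], r, nm))
      }
    }
    if (schema$role[i] == "dependent" && any(mask[, nm] == 0L)) {
      add(which(mask[, nm] == 0L)[1], nm, "dependent_observed",
          sprintf("dependent variables must be fully observed ('%s' has missing cells)", nm))
    }
  }
  if (!length(v)) {
    return(tibble::tibble(
      row = integer(), column = character(), rule = character(), message = character()
    ))
  }
  dplyr::bind_rows(v)
}
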