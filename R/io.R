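# Table schemas: one per pipeline table.  A schema is a list of column specs;
# validation is total — every offending row is collected and reported with its
# row number.

#' Table schema for a pipeline CSV
#'
#' @param name one of `"subjects"`, `"choices"`, `"time_probes"`, `"items"`,
#'   `"truth"`.
#' @return schema object understood by [read_table()].
#' @export
dd_schema <- function(name = c("subjects", "choices", "time_probes", "items", "truth")) {
  name <- match.arg(name)
  col <- function(type, min = -Inf, max = Inf, values = NULL, required = TRUE)
    list(type = type, min = min, max = max, values = values, required = required)
  sch <- switch(name,
    subjects = list(
      subject_id = col("character"),
      sex = col("character", values = c("male", "female")),
      group_label = col("character", required = FALSE),
      chronological_age = col("numeric", min = 0),
      physical_age = col("numeric", min = 0),
      psychological_age = col("numeric", min = 0),
      physical_health = col("numeric", min = 1, max = 5),
      psychological_health = col("numeric", min = 1, max = 5),
      childhood_ses = col("numeric", min = 1, max = 7),
      lhs = col("numeric", min = 1, max = 7),
      ftp = col("numeric", min = 1, max = 7),
      age_bias = col("numeric", required = FALSE)),
    choices = list(
      subject_id = col("character"),
      item_id = col("character"),
      ss_amount = col("numeric", min = 0, required = FALSE),
      ll_amount = col("numeric", min = 0, required = FALSE),
      delay_days = col("numeric", min = 0, required = FALSE),
      chose_ss = col("numeric", values = c(0, 1))),
    time_probes = list(
      subject_id = col("character"),
      horizon_months = col("numeric", min = 1e-9),
      slider_mm = col("numeric", min = 0, max = 150)),
    items = list(
      item_id = col("character"),
      ss_amount = col("numeric", min = 1e-9),
      ll_amount = col("numeric", min = 1e-9),
      delay_days = col("numeric", min = 1e-9)),
    truth = list(
      subject_id = col("character"),
      k_true = col("numeric", min = 1e-12),
      log_k_true = col("numeric"),
      sigma_true = col("numeric", min = 0),
      alpha_true = col("numeric", min = 0),
      beta_true = col("numeric", min = 0),
      is_random_responder = col("logical", required = FALSE),
      is_time_outlier = col("logical", required = FALSE)))
  structure(list(name = name, columns = sch,
                 key = switch(name,
                              subjects = "subject_id",
                              items = "item_id",
                              choices = c("subject_id", "item_id"),
                              NULL)),
            class = "dd_schema")
}

#' Read and validate a pipeline table
#'
#' Reads a CSV, checks that every required column is present, coerces types,
#' and validates every row against the schema's ranges and value sets.  All
#' violations are collected and reported together with their row numbers;
#' duplicate keys are rejected.  An empty-but-valid table is allowed.
#'
#' @param path CSV file.
#' @param schema a [dd_schema()].
#' @return validated data.frame.
#' @export
read_table <- function(path, schema) {
  stopifnot(inherits(schema, "dd_schema"))
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_table(df, schema, label = path)
}

#' @rdname read_table
#' @param df in-memory data.frame to validate against the schema.
#' @param label name used in error messages.
#' @export
validate_table <- function(df, schema, label = schema$name) {
  req <- names(schema$columns)[vapply(schema$columns, function(s)
    isTRUE(s$required), TRUE)]
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_input(label, ": missing required column(s): ", paste(miss, collapse = ", "))

  problems <- character(0)
  for (cn in intersect(names(schema$columns), names(df))) {
    colspec <- schema$columns[[cn]]
    v <- df[[cn]]
    if (colspec$type == "numeric") {
      v <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(v) & !is.na(df[[cn]]))
      if (length(bad))
        problems <- c(problems, paste0(cn, ": non-numeric at row(s) ",
                                       paste(head(bad, 5), collapse = ", ")))
      df[[cn]] <- v
    } else if (colspec$type == "logical") {
      df[[cn]] <- as.logical(v)
    } else {
      df[[cn]] <- as.character(v)
    }
    v <- df[[cn]]
    if (!is.null(colspec$values)) {
      bad <- which(!is.na(v) & !(v %in% colspec$values))
    } else if (colspec$type == "numeric") {
      bad <- which(!is.na(v) & (v < colspec$min | v > colspec$max))
    } else bad <- integer(0)
    if (length(bad))
      problems <- c(problems, paste0(cn, ": value out of range/set at row(s) ",
                                     paste(head(bad, 5), collapse = ", ")))
  }
  if (!is.null(schema$key) && nrow(df)) {
    dup <- which(duplicated(df[schema$key]))
    if (length(dup))
      problems <- c(problems, paste0("duplicate key (", paste(schema$key, collapse = ","),
                                     ") at row(s) ", paste(head(dup, 5), collapse = ", ")))
  }
  if (length(problems))
    stop_input(label, ": validation failed\n  - ", paste(problems, collapse = "\n  - "))
  df
}

#' Load a cohort configuration from a YAML file
#'
#' Keys map one-to-one onto [cohort_config()] arguments; absent keys take the
#' defaults, unknown keys are rejected.  An empty file yields the full default
#' configuration.
#'
#' @param path YAML file.
#' @return a [cohort_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop_input("config must be a key-value document")
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop_input("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(cohort_config, vals)
}
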