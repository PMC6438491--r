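#' Read a subject-level dataset from CSV
#'
#' Expects the header `subject_id,regime,F,L` with an optional `D` column.
#' Malformed rows (non-binary F/L/D, regime other than pre/post) are
#' reported with their line numbers in the file (header = line 1).
#'
#' @param path path to a CSV file.
#' @return A validated `data.frame` as produced by [sample_dataset()]. An
#'   empty table (header only) is returned as a zero-row data frame;
#'   downstream operations raise their own errors.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "regime", "F", "L")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) return(df)
  check_bin <- function(col, nm) {
    bad <- which(!(df[[col]] %in% c(0, 1)))
    if (length(bad))
      stop(sprintf("non-binary %s value on line(s): %s", nm,
                   paste(bad + 1L, collapse = ", ")), call. = FALSE)
  }
  check_bin("F", "F")
  check_bin("L", "L")
  if ("D" %in% names(df)) check_bin("D", "D")
  bad <- which(!(df$regime %in% c("pre", "post")))
  if (length(bad))
    stop("invalid regime tag on line(s): ", paste(bad + 1L, collapse = ", "),
         call. = FALSE)
  df
}

#' Write a subject-level dataset to CSV
#'
#' @param dataset a data frame with the [read_dataset()] schema.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  .validate_dataset(dataset)
  utils::write.csv(dataset, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.is_yaml_path <- function(path) grepl("\\.ya?ml$", path, ignore.case = TRUE)

#' Read a parameter record
#'
#' Flat key-value documents (JSON or YAML by file extension) with keys
#' `delta, phi0, phi1, lambda0, lambda1` and optionally `delta_prime`.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return A list with `params` ([lca_params]) and `delta_prime` (`NULL`
#'   when absent).
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  rec <- if (.is_yaml_path(path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  params <- as_lca_params(rec)
  dp <- rec$delta_prime
  if (!is.null(dp)) .check_prob(dp, "delta_prime")
  list(params = params, delta_prime = dp)
}

#' Write a parameter record
#'
#' Numbers are serialised as decimal text with 17 significant digits so a
#' read-back reproduces them exactly.
#'
#' @param params an [lca_params] object.
#' @param path output path (`.json`, `.yaml` or `.yml`).
#' @param delta_prime optional post-intervention prevalence to include.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path, delta_prime = NULL) {
  stopifnot(inherits(params, "lca_params"))
  rec <- unclass(params)
  if (!is.null(delta_prime)) {
    .check_prob(delta_prime, "delta_prime")
    rec$delta_prime <- delta_prime
  }
  write_results(rec, path)
}

# strip S3 classes recursively so records serialise as plain documents
.plainify <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, .plainify)
    attributes(x) <- list(names = names(x))
    x
  } else {
    unclass(x)
  }
}

#' Write a result record
#'
#' Serialises any list-like record (solution sets, posterior summaries,
#' parameter records, frequency tables) as a flat JSON or YAML document.
#' Numeric fields survive a round trip to at least 15 significant digits.
#'
#' @param record a (possibly nested) list of numbers, strings and vectors.
#' @param path output path; format chosen by extension (`.yaml`/`.yml` for
#'   YAML, anything else JSON).
#' @return `path`, invisibly.
#' @export
write_results <- function(record, path) {
  rec <- .plainify(record)
  if (.is_yaml_path(path)) {
    yaml::write_yaml(rec, path, precision = 17L)
  } else {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  invisible(path)
}

#' Read back a result record
#'
#' @param path path written by [write_results()].
#' @return The record as a plain list.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (.is_yaml_path(path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
}
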