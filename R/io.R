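## CSV round-trip I/O for the package's standard tabular formats.

#' Read / write a Q-matrix CSV
#'
#' Format: header row of attribute names, one row per item, first column
#' the item id, entries 0/1.
#'
#' @param path file path.
#' @return binary Q-matrix with item-id rownames.
#' @export
read_q_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  q <- as.matrix(df[, -1, drop = FALSE])
  rownames(q) <- df[[1]]
  storage.mode(q) <- "numeric"
  validate_q_matrix(q)
  q
}

#' @rdname read_q_matrix
#' @param q Q-matrix to write.
#' @export
write_q_matrix <- function(q, path) {
  validate_q_matrix(q)
  df <- data.frame(item = rownames(q) %||% paste0("item", seq_len(nrow(q))),
                   q, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a response-matrix CSV
#'
#' Format: first column person id, one column per item id, entries 0/1.
#'
#' @param path file path.
#' @return binary response matrix with person-id rownames.
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  y <- as.matrix(df[, -1, drop = FALSE])
  rownames(y) <- df[[1]]
  storage.mode(y) <- "numeric"
  validate_responses(y)
  y
}

#' @rdname read_responses
#' @param y response matrix to write.
#' @export
write_responses <- function(y, path) {
  validate_responses(y)
  df <- data.frame(person = rownames(y) %||% paste0("p", seq_len(nrow(y))),
                   y, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write an item-feature CSV
#'
#' Format: first column item id, one column per feature; header names are
#' preserved into reports.
#'
#' @param path file path.
#' @return numeric feature matrix with item-id rownames.
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  z <- as.matrix(df[, -1, drop = FALSE])
  rownames(z) <- df[[1]]
  storage.mode(z) <- "numeric"
  validate_features(z)
  z
}

#' @rdname read_features
#' @param z feature matrix to write.
#' @export
write_features <- function(z, path) {
  validate_features(z)
  df <- data.frame(item = rownames(z) %||% paste0("item", seq_len(nrow(z))),
                   z, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON echo of a resolved configuration plus the package version, written
#' alongside every command-line run for reproducibility.
#'
#' @param config named list.
#' @param path output path.
#' @export
write_manifest <- function(config, path) {
  config$package_version <-
    as.character(utils::packageVersion("iedina"))
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
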