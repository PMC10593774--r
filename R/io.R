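#' Tabular readers and writers
#'
#' Wide feature tables are CSV/TSV files with a `subject_id` column
#' followed by numeric feature columns; square similarity matrices are CSV
#' with subject ids as header and first column.
#'
#' @name io
NULL

#' Read a wide feature table
#'
#' @param path CSV (`.csv`) or TSV (`.tsv`/`.txt`) file with a
#'   `subject_id` column and numeric feature columns.
#' @return numeric matrix with subject ids as rownames, feature column
#'   order preserved.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty table: ", path)
  if (!"subject_id" %in% names(df)) stop("missing subject_id column: ", path)
  ids <- as.character(df$subject_id)
  if (anyDuplicated(ids))
    stop("duplicate subject id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  feats <- df[, setdiff(names(df), "subject_id"), drop = FALSE]
  nonnum <- names(feats)[!vapply(feats, is.numeric, logical(1L))]
  if (length(nonnum))
    stop("non-numeric feature column(s): ", paste(nonnum, collapse = ", "))
  X <- as.matrix(feats)
  rownames(X) <- ids
  X
}

#' Write a wide feature table
#'
#' @param values matrix with subject ids as rownames.
#' @param path output CSV path.
#' @export
write_feature_table <- function(values, path) {
  df <- data.frame(subject_id = rownames(values), values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a square similarity matrix
#'
#' @param mat symmetric matrix with subject ids as dimnames.
#' @param path output CSV path.
#' @export
write_similarity_matrix <- function(mat, path) {
  df <- data.frame(subject_id = rownames(mat), unclass(mat),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a square similarity matrix written by [write_similarity_matrix()]
#'
#' @param path CSV path.
#' @export
read_similarity_matrix <- function(path) {
  X <- read_feature_table(path)
  colnames(X) <- rownames(X)
  X
}

#' Write embedding scores
#'
#' Scores as CSV (`subject_id`, `embedding_1..k`) with the eigenvalues in
#' a JSON sidecar.
#'
#' @param emb an `embedding_result`.
#' @param path output CSV path.
#' @export
write_embedding <- function(emb, path) {
  df <- data.frame(subject_id = emb$subject_ids, emb$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(eigenvalues = emb$eigenvalues),
                       sub("\\.csv$", "_eigenvalues.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize a fitted transfer model to JSON
#'
#' @param model a `tradaboost_model`.
#' @param path output JSON path.
#' @export
write_model <- function(model, path) {
  obj <- list(
    coefficients = lapply(model$estimators, `[[`, "coef"),
    intercepts = vapply(model$estimators, `[[`, numeric(1L), "intercept"),
    estimator_weights = model$estimator_weights,
    beta_t = model$beta_t,
    beta_source = model$beta_source,
    center = as.list(stats::setNames(model$center, model$columns)),
    scale = as.list(stats::setNames(model$scale, model$columns)),
    columns = model$columns)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a transfer model serialized by [write_model()]
#'
#' @param path JSON path.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    estimators = lapply(seq_along(obj$intercepts), function(i)
      list(coef = as.numeric(if (is.list(obj$coefficients))
                               obj$coefficients[[i]]
                             else obj$coefficients[i, ]),
           intercept = obj$intercepts[i])),
    estimator_weights = obj$estimator_weights,
    beta_t = obj$beta_t,
    beta_source = obj$beta_source,
    center = unlist(obj$center),
    scale = unlist(obj$scale),
    columns = obj$columns),
    class = "tradaboost_model")
}

#' Read a pipeline configuration file
#'
#' YAML with per-module blocks (`snf`, `embed`, `combat`, `elastic_net`,
#' `transfer`, `associate`), input paths and a top-level `seed`; missing
#' keys fall back to package defaults.
#'
#' @param path YAML file.
#' @return nested config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path)
  yaml::read_yaml(path)
}
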