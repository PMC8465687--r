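# On-disk formats.
#
# Graph series layout: one directory per series holding
#   meta.json                 {"n_vertices": n, "weighted": bool,
#                              "label": str, "T": int}
#   0001.tsv, 0002.tsv, ...   per-time-point edge lists, columns u, v
#                             [, weight], vertex ids 0-based, each
#                             undirected edge listed once
# Dense whitespace-delimited adjacency text and GraphML (read-only) are
# also accepted for single graphs.

#' Write a graph series to a directory
#'
#' @param gs a [graph_series()].
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_graph_series <- function(gs, path) {
  stopifnot(inherits(gs, "graph_series"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(n_vertices = gs$n_vertices, weighted = gs$weighted,
               label = gs$label, T = length(gs$graphs))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE)
  for (t in seq_along(gs$graphs)) {
    A <- gs$graphs[[t]]
    idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
    df <- data.frame(u = idx[, 1] - 1L, v = idx[, 2] - 1L)
    if (gs$weighted) df$weight <- A[idx]
    utils::write.table(df, file.path(path, sprintf("%04d.tsv", t)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a graph series from a directory
#'
#' Edge lists are mirrored into symmetric adjacency matrices; vertex ids
#' must be 0-based and below `n_vertices`; duplicate edges are rejected.
#'
#' @param path directory written by [write_graph_series()].
#' @param one_based treat vertex ids in the files as 1-based.
#' @return a [graph_series()].
#' @export
read_graph_series <- function(path, one_based = FALSE) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file))
    stop("missing meta.json in ", path, call. = FALSE)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  n <- as.integer(meta$n_vertices)
  files <- sort(list.files(path, pattern = "^[0-9]+\\.tsv$",
                           full.names = TRUE))
  if (!length(files)) stop("no edge-list files in ", path, call. = FALSE)
  graphs <- lapply(files, function(f)
    read_edge_list(f, n, weighted = isTRUE(meta$weighted),
                   one_based = one_based))
  graph_series(graphs, label = meta$label %||% basename(path),
               weighted = isTRUE(meta$weighted))
}

read_edge_list <- function(file, n_vertices, weighted = FALSE,
                           one_based = FALSE) {
  df <- utils::read.table(file, header = TRUE, sep = "\t")
  need <- if (weighted) c("u", "v", "weight") else c("u", "v")
  if (!all(need %in% names(df)))
    stop(file, ": expected columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (weighted && !is.numeric(df$weight))
    stop(file, ": non-numeric weight column", call. = FALSE)
  u <- as.integer(df$u) + if (one_based) 0L else 1L
  v <- as.integer(df$v) + if (one_based) 0L else 1L
  if (nrow(df)) {
    bad <- which(u < 1L | u > n_vertices | v < 1L | v > n_vertices |
                   is.na(u) | is.na(v))
    if (length(bad))
      stop(file, ": line ", bad[1] + 1L,
           ": vertex id outside [", if (one_based) 1L else 0L, ", ",
           n_vertices - if (one_based) 0L else 1L, "]", call. = FALSE)
    if (any(u == v))
      stop(file, ": self-loop at line ",
           which(u == v)[1] + 1L, call. = FALSE)
    key <- paste(pmin(u, v), pmax(u, v))
    if (anyDuplicated(key))
      stop(file, ": duplicate edge at line ",
           which(duplicated(key))[1] + 1L, call. = FALSE)
  }
  A <- matrix(0, n_vertices, n_vertices)
  w <- if (weighted) df$weight else rep(1, nrow(df))
  A[cbind(u, v)] <- w
  A[cbind(v, u)] <- w
  A
}

#' Read a dense adjacency matrix from whitespace-delimited text
#'
#' @param file path to the text file (n rows of n numbers).
#' @param weighted validate as weighted (real entries) rather than binary.
#' @return validated adjacency matrix.
#' @export
read_adjacency <- function(file, weighted = FALSE) {
  A <- as.matrix(utils::read.table(file, header = FALSE))
  dimnames(A) <- NULL
  validate_adjacency(A, weighted = weighted)
  A
}

#' Read a graph from GraphML (read-only interchange)
#'
#' @param file GraphML file path.
#' @param weighted extract a `weight` edge attribute if present.
#' @return adjacency matrix.
#' @export
read_graphml <- function(file, weighted = FALSE) {
  g <- igraph::read_graph(file, format = "graphml")
  g <- igraph::as_undirected(g, mode = "collapse")
  A <- as.matrix(igraph::as_adjacency_matrix(
    g, sparse = TRUE,
    attr = if (weighted && "weight" %in% igraph::edge_attr_names(g))
      "weight" else NULL))
  dimnames(A) <- NULL
  storage.mode(A) <- "double"
  diag(A) <- 0
  A
}

#' Write / read a feature series as TSV
#'
#' One row per time point, one column per series, header row of series
#' labels.
#'
#' @param y a [feature_series()] (or T x k matrix).
#' @param file path.
#' @return `file` (writer, invisibly) or a [feature_series()] (reader).
#' @export
write_feature_series <- function(y, file) {
  utils::write.table(as.matrix(y), file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' @rdname write_feature_series
#' @param feature feature name recorded on the object read back.
#' @export
read_feature_series <- function(file, feature = "spectral_radius") {
  m <- as.matrix(utils::read.table(file, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  feature_series(m, feature = feature)
}

#' Serialize a fitted VAR model to JSON
#'
#' Coefficients are stored nested by source series, target series and lag,
#' alongside order, labels, intercepts and the residual covariance.
#'
#' @param model a `var_model`.
#' @param file path; if `NULL` the JSON string is returned.
#' @return `file` invisibly, or the JSON string.
#' @export
write_var_model <- function(model, file = NULL) {
  stopifnot(inherits(model, "var_model"))
  p <- model$order; k <- model$k
  coef_list <- lapply(seq_len(k), function(i)
    lapply(seq_len(k), function(j)
      as.numeric(model$coefficients[coef_index(i, seq_len(p), p), j])))
  names(coef_list) <- model$labels
  for (i in seq_len(k)) names(coef_list[[i]]) <- model$labels
  obj <- list(order = p, k = k, labels = model$labels,
              intercepts = as.numeric(model$intercepts),
              coefficients = coef_list,
              sigma = unname(model$sigma),
              sigma_df = model$sigma_df)
  if (is.null(file))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Write a test-result table
#'
#' TSV columns: source, target, statistic, df, p_value, method, n_boot.
#'
#' @param results a `gc_test_table` from [test_all_pairs()] or
#'   [graph_granger()]`$results`.
#' @param file path; `.json` extension switches to JSON output.
#' @return `file`, invisibly.
#' @export
write_results <- function(results, file) {
  df <- as.data.frame(results)
  if (grepl("\\.json$", file)) {
    jsonlite::write_json(df, file, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(df, file, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(file)
}
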