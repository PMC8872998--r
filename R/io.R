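#' Read / write a tab-delimited expression matrix
#'
#' The on-disk format is a header line of sample ids and one row per probe
#' with the probe id in the first column — the usual flat microarray
#' export.
#'
#' @param path file path.
#' @return numeric matrix, probes x samples, with dimnames.
#' @export
read_expression_matrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- as.character(d[[1]])
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("non-finite values in expression matrix")
  m
}

#' @rdname read_expression_matrix
#' @param m probes x samples matrix.
#' @param id_col name of the probe-id column (default `"probe_id"`).
#' @export
write_expression_matrix <- function(m, path, id_col = "probe_id") {
  d <- data.frame(rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d)[1] <- id_col
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member ids, tab-separated.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, "", 1)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(!is.null(names(sets)))
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), ""), path)
  invisible(path)
}

#' Read an undirected edge list
#'
#' Two tab-separated node-id columns, no header.
#'
#' @param path file path.
#' @return data.frame with columns `from`, `to`.
#' @export
read_edge_list <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(from = as.character(d[[1]]), to = as.character(d[[2]]),
             stringsAsFactors = FALSE)
}

#' Read the longitudinal visit table / subject covariate table
#'
#' Plain tab-delimited tables with a header. The visit table needs
#' `subject_id`, `age`, `outcome`; the subject table needs `subject_id`
#' plus whatever covariates downstream calls use.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_visits <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "outcome")
  if (!all(need %in% names(d)))
    stop("visit table must have columns: ", paste(need, collapse = ", "))
  d
}

#' @rdname read_visits
#' @export
read_subjects <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(d))
    stop("subject table must have a subject_id column")
  d
}
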