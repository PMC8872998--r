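#' Hypergeometric enrichment of a query gene set against an annotation list
#'
#' Builds the 2x2 overlap table of `query` against `annotation` within
#' `universe` (the annotation is intersected with the universe first) and
#' reports the odds ratio `(a*d)/(b*c)` — with a Haldane-Anscombe 0.5 added
#' to every cell only when some cell is zero — and the upper-tail
#' hypergeometric probability of an overlap at least as large as observed.
#'
#' @param query character vector of gene ids; must be a subset of
#'   `universe`.
#' @param annotation character vector of gene ids (the curated list).
#' @param universe character vector: the selection pool (typically all
#'   features surviving the variance filter).
#' @param name label carried into the result (default the annotation's
#'   deparse).
#' @return one-row data.frame: `list_name`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p`.
#' @export
enrichment_test <- function(query, annotation, universe,
                            name = "annotation") {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  query <- unique(as.character(query))
  if (length(setdiff(query, universe)))
    stop("query contains ids outside the universe")
  annotation <- intersect(unique(as.character(annotation)), universe)
  a <- length(intersect(query, annotation))
  b <- length(query) - a
  cc <- length(annotation) - a
  d <- length(universe) - a - b - cc
  or <- if (any(c(a, b, cc, d) == 0))
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  else (a * d) / (b * cc)
  p <- stats::phyper(a - 1, length(annotation),
                     length(universe) - length(annotation),
                     length(query), lower.tail = FALSE)
  data.frame(list_name = name, a = a, b = b, c = cc, d = d,
             odds_ratio = or, p = p, stringsAsFactors = FALSE)
}

#' Enrichment of a query set against many annotation lists, with FDR
#'
#' Runs [enrichment_test()] per list and appends Benjamini-Hochberg
#' q-values across the lists.
#'
#' @param query character vector of gene ids.
#' @param annotations named list of character vectors.
#' @param universe the selection pool.
#' @return data.frame, one row per list, with a `q` column.
#' @export
enrichment_table <- function(query, annotations, universe) {
  stopifnot(length(annotations) >= 1)
  nm <- names(annotations)
  if (is.null(nm)) nm <- paste0("list_", seq_along(annotations))
  out <- do.call(rbind, lapply(seq_along(annotations), function(i)
    enrichment_test(query, annotations[[i]], universe, name = nm[i])))
  out$q <- bh_fdr(out$p)
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Classic step-up q-values: sort the p-values, multiply by `m / rank`,
#' enforce monotonicity from the largest rank down, clip at 1, and return
#' in the original order.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(o)]
}

#' Edge-count permutation test for network connectivity of a gene set
#'
#' Counts the undirected edges with both endpoints in `set` and compares
#' with the edge counts of `B` uniformly drawn node sets of the same size
#' (sampled without replacement from all network nodes). `expected_edges`
#' is the null mean and `p = (1 + #\{null >= observed\}) / (B + 1)`. This
#' is a stand-in for interaction-database connectivity statistics whose
#' proprietary null models cannot be re-derived.
#'
#' @param set character vector of gene ids (nodes); at least 2 must map to
#'   the network.
#' @param network data.frame with two character columns of node ids
#'   (undirected edges), or a list with `from`/`to`.
#' @param B permutations (default 1000).
#' @param seed integer seed.
#' @param degree_preserving if `TRUE`, null sets are sampled with
#'   probability proportional to node degree (hub-bias check); default
#'   uniform.
#' @return object of class `edge_enrichment`: `observed_edges`,
#'   `expected_edges`, `null_counts`, `p`, `B`, `seed`, `n_mapped`.
#' @export
edge_enrichment_test <- function(set, network, B = 1000, seed = 1L,
                                 degree_preserving = FALSE) {
  ed <- as.data.frame(network, stringsAsFactors = FALSE)
  stopifnot(ncol(ed) >= 2, B >= 1)
  from <- as.character(ed[[1]]); to <- as.character(ed[[2]])
  if (any(from == to)) stop("self-loops are not allowed")
  key <- paste(pmin(from, to), pmax(from, to))
  if (anyDuplicated(key)) stop("duplicate edges in network")
  nodes <- unique(c(from, to))
  set <- unique(as.character(set))
  mapped <- intersect(set, nodes)
  if (length(mapped) < 2)
    stop("need >= 2 query genes mapped to network nodes")
  fi <- match(from, nodes); ti <- match(to, nodes)
  count_edges <- function(flag) sum(flag[fi] & flag[ti])
  flag <- nodes %in% mapped
  observed <- count_edges(flag)
  m <- length(mapped)
  deg <- tabulate(c(fi, ti), nbins = length(nodes))
  set.seed(seed)
  null_counts <- vapply(seq_len(B), function(b) {
    pick <- if (degree_preserving)
      sample.int(length(nodes), m, prob = deg + 1e-9)
    else sample.int(length(nodes), m)
    fl <- logical(length(nodes)); fl[pick] <- TRUE
    count_edges(fl)
  }, numeric(1))
  structure(list(observed_edges = observed,
                 expected_edges = mean(null_counts),
                 null_counts = null_counts,
                 p = perm_pvalue(observed, null_counts,
                                 larger_is_extreme = TRUE),
                 B = B, seed = seed, n_mapped = m),
            class = "edge_enrichment")
}

#' @export
print.edge_enrichment <- function(x, ...) {
  cat("edge_enrichment:", x$n_mapped, "mapped genes; observed edges =",
      x$observed_edges, ", expected =", signif(x$expected_edges, 4),
      ", p =", signif(x$p, 4), "\n")
  invisible(x)
}
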