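#' Voxelwise one-sample t-test across a stack of expression maps
#'
#' Given G per-gene spatial expression maps over a common voxel grid, tests
#' at every in-mask voxel whether the mean across maps differs from zero:
#' `t = mean / (sd / sqrt(G))` with `G - 1` degrees of freedom, p-values
#' two-sided by default, Benjamini-Hochberg q-values computed across the
#' in-mask voxels only, and a significance mask at `q < q_threshold`.
#' Voxels whose across-map SD is zero have no defined t; they are dropped
#' from the result with a warning.
#'
#' @param stack G x V numeric matrix (maps in rows), or a list of equally
#'   shaped numeric arrays (3-D volumes), one per gene.
#' @param mask optional logical vector/array selecting the voxels to test;
#'   default all voxels.
#' @param q_threshold FDR level for the significance mask (default 0.05).
#' @param alternative `"two.sided"` (default) or `"greater"` (high
#'   expression only).
#' @param standardize_maps z-score each map over the in-mask voxels before
#'   testing (default FALSE).
#' @return object of class `tmap_result`: `t`, `df`, `p`, `q` (vectors over
#'   tested voxels), `voxels` (their indices in the input grid),
#'   `sig_mask` (logical over the full grid), `dim` (grid dimensions),
#'   `n_maps`, `alternative`, `q_threshold`.
#' @export
voxelwise_one_sample_t <- function(stack, mask = NULL, q_threshold = 0.05,
                                   alternative = c("two.sided", "greater"),
                                   standardize_maps = FALSE) {
  alternative <- match.arg(alternative)
  if (is.list(stack)) {
    dims <- lapply(stack, dim)
    if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
      stop("all maps must share the same shape")
    grid_dim <- dim(stack[[1]])
    stack <- do.call(rbind, lapply(stack, as.numeric))
  } else {
    stack <- as.matrix(stack)
    grid_dim <- ncol(stack)
  }
  G <- nrow(stack); V <- ncol(stack)
  if (G < 3) stop("need at least 3 maps")
  if (is.null(mask)) mask <- rep(TRUE, V)
  mask <- as.logical(mask)
  stopifnot(length(mask) == V)
  vox <- which(mask)
  M <- stack[, vox, drop = FALSE]
  if (any(!is.finite(M))) stop("non-finite values inside the mask")
  if (standardize_maps)
    M <- t(scale(t(M)))
  mu <- colMeans(M)
  sdv <- sqrt(colSums(sweep(M, 2, mu)^2) / (G - 1))
  degenerate <- sdv == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " voxel(s) with zero across-map SD excluded")
    vox <- vox[!degenerate]
    mu <- mu[!degenerate]; sdv <- sdv[!degenerate]
  }
  tt <- mu / (sdv / sqrt(G))
  df <- G - 1
  p <- if (alternative == "two.sided")
    2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  else stats::pt(tt, df, lower.tail = FALSE)
  q <- bh_fdr(p)
  sig <- rep(FALSE, V)
  sig[vox[q < q_threshold]] <- TRUE
  structure(list(t = tt, df = df, p = p, q = q, voxels = vox,
                 sig_mask = sig, dim = grid_dim, n_maps = G,
                 alternative = alternative, q_threshold = q_threshold),
            class = "tmap_result")
}

#' @export
print.tmap_result <- function(x, ...) {
  cat("tmap_result:", x$n_maps, "maps,", length(x$voxels),
      "voxels tested; df =", x$df, ";", sum(x$sig_mask),
      "significant at q <", x$q_threshold, "\n")
  invisible(x)
}
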