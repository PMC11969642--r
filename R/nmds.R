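#' Non-metric multidimensional scaling
#'
#' Embeds samples in k dimensions so that inter-point distances preserve the
#' rank order of the input dissimilarities, minimising Kruskal stress-1 by
#' iterative monotone regression (vegan's global-model engine). One start
#' from metric (principal-coordinate) scaling plus `n_restarts - 1` random
#' starts are tried and the lowest-stress solution returned, centred at the
#' origin. Deterministic given `seed`.
#'
#' @param dis A `pmf_dist` or symmetric dissimilarity matrix.
#' @param k Embedding dimension (>= 1; n must exceed k).
#' @param n_restarts Number of starts (default 50).
#' @param seed Integer seed for the random starts.
#' @return An `nmds_result`: list with `coordinates` (samples x k, centred),
#'   `stress` (Kruskal stress-1), `converged`, `seed`.
#' @export
nmds <- function(dis, k = 2L, n_restarts = 50L, seed = 1L) {
  d <- as.matrix(dis)
  if (any(!is.finite(d))) stop("non-finite dissimilarities")
  n <- nrow(d)
  if (k < 1L) stop("k must be >= 1")
  if (n < k + 1L) stop("need at least k + 1 samples")
  set.seed(seed)
  dd <- stats::as.dist(d)
  best <- NULL
  starts <- vector("list", max(1L, n_restarts))
  starts[[1L]] <- tryCatch(stats::cmdscale(d, k = k), error = function(e) NULL)
  if (is.null(starts[[1L]]) || ncol(starts[[1L]]) < k)
    starts[[1L]] <- base::matrix(stats::rnorm(n * k), n, k)
  if (n_restarts > 1L)
    for (s in 2L:n_restarts)
      starts[[s]] <- base::matrix(stats::rnorm(n * k), n, k)
  for (s in seq_along(starts)) {
    fit <- vegan::monoMDS(dd, y = starts[[s]], k = k, model = "global",
                          maxit = 300L, sratmax = 1 - 1e-6)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  coords <- scale(best$points, center = TRUE, scale = FALSE)
  attr(coords, "scaled:center") <- NULL
  dimnames(coords) <- list(rownames(d), paste0("MDS", seq_len(k)))
  structure(list(coordinates = coords, stress = best$stress,
                 converged = isTRUE(best$maxits == 0) ||
                   best$iters < best$maxits %||% 300L,
                 seed = seed),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat("nMDS: ", nrow(x$coordinates), " samples in ", ncol(x$coordinates),
      " dimensions, Kruskal stress-1 = ", format(x$stress, digits = 4),
      "\n", sep = "")
  invisible(x)
}
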