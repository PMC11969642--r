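#' SIMPER: within-group similarity breakdown
#'
#' Decomposes each group's mean Bray-Curtis similarity into per-feature
#' contributions. For a within-group sample pair (j, k), feature i
#' contributes \deqn{100 \cdot 2\min(x_{ij}, x_{ik}) / \sum_f (x_{fj} + x_{fk})}
#' to the pair's similarity; a feature's contribution is the mean over all
#' within-group pairs and the contributions sum exactly to the group's mean
#' Bray-Curtis similarity. Abundant, consistently present features therefore
#' contribute most; the contribution/SD ratio (SD across pairs) flags
#' features that contribute consistently rather than erratically.
#'
#' @param matrix A [peak_matrix].
#' @param labels Character vector of group labels, one per sample (defaults
#'   to the matrix's family labels).
#' @return A list of `simper_result`, one per group with >= 2 samples
#'   (singleton groups are skipped with a warning). Each holds `scope`,
#'   `type` (`"similarity"`), `average_score`, and `table`: a data frame of
#'   (mz, contribution, contribution_pct, cumulative_pct, sd_ratio) rows
#'   sorted by contribution descending (ties by ascending m/z).
#' @export
simper_within <- function(matrix, labels = NULL) {
  stopifnot(inherits(matrix, "peak_matrix"))
  labels <- .resolve_labels(matrix, labels)
  x <- matrix$values
  out <- list()
  for (g in sort(unique(labels))) {
    idx <- which(labels == g)
    if (length(idx) < 2L) {
      warning("skipping singleton group '", g, "'")
      next
    }
    pairs <- .pair_index(length(idx))
    contrib <- base::matrix(0, nrow(pairs), ncol(x))
    for (p in seq_len(nrow(pairs))) {
      a <- x[idx[pairs[p, "i"]], ]; b <- x[idx[pairs[p, "j"]], ]
      contrib[p, ] <- 100 * 2 * pmin(a, b) / sum(a + b)
    }
    out[[g]] <- .simper_result(g, "similarity", contrib, matrix$mz)
  }
  out
}

#' SIMPER: between-group dissimilarity breakdown
#'
#' For each unordered group pair, feature i's contribution to the
#' dissimilarity of a cross-group sample pair (j, k) is
#' \deqn{100 \cdot |x_{ij} - x_{ik}| / \sum_f (x_{fj} + x_{fk}),}
#' averaged over all cross-group pairs; contributions sum exactly to the
#' pair of groups' mean Bray-Curtis dissimilarity.
#'
#' @inheritParams simper_within
#' @return A list of `simper_result` (one per group pair, `type`
#'   `"dissimilarity"`, `scope` the pair).
#' @export
simper_between <- function(matrix, labels = NULL) {
  stopifnot(inherits(matrix, "peak_matrix"))
  labels <- .resolve_labels(matrix, labels)
  x <- matrix$values
  groups <- sort(unique(labels))
  if (length(groups) < 2L) stop("need >= 2 groups")
  out <- list()
  for (combo in utils::combn(groups, 2L, simplify = FALSE)) {
    ia <- which(labels == combo[1L]); ib <- which(labels == combo[2L])
    contrib <- base::matrix(0, length(ia) * length(ib), ncol(x))
    p <- 0L
    for (j in ia) for (k in ib) {
      p <- p + 1L
      contrib[p, ] <- 100 * abs(x[j, ] - x[k, ]) / sum(x[j, ] + x[k, ])
    }
    out[[paste(combo, collapse = " vs ")]] <-
      .simper_result(combo, "dissimilarity", contrib, matrix$mz)
  }
  out
}

.resolve_labels <- function(matrix, labels) {
  if (is.null(labels)) labels <- matrix$labels$family
  labels <- as.character(labels)
  if (length(labels) != nrow(matrix$values))
    stop("one label per sample required")
  if (anyNA(labels)) stop("NA group labels")
  labels
}

.simper_result <- function(scope, type, contrib, mz) {
  mean_contrib <- colMeans(contrib)
  sds <- apply(contrib, 2L, stats::sd)
  avg <- sum(mean_contrib)
  ord <- order(-mean_contrib, mz)
  pct <- if (avg > 0) 100 * mean_contrib[ord] / avg else
    rep(0, length(mean_contrib))
  tab <- data.frame(
    mz = mz[ord],
    contribution = mean_contrib[ord],
    contribution_pct = pct,
    cumulative_pct = cumsum(pct),
    sd_ratio = ifelse(sds[ord] > 0, mean_contrib[ord] / sds[ord], Inf))
  structure(list(scope = scope, type = type, average_score = avg,
                 n_pairs = nrow(contrib), table = tab),
            class = "simper_result")
}

#' @export
print.simper_result <- function(x, ...) {
  cat("SIMPER ", x$type, " (", paste(x$scope, collapse = " vs "),
      "): average ", x$type, " ", format(x$average_score, digits = 4),
      " over ", x$n_pairs, " pairs\n", sep = "")
  print(utils::head(x$table, 5L), row.names = FALSE)
  invisible(x)
}

#' Top contributors to a SIMPER score
#'
#' Returns the minimal prefix of features (sorted by contribution
#' descending, ties broken by ascending m/z) whose cumulative contribution
#' percentage reaches `cutoff_percent` — e.g. the peaks forming the top 70%
#' of a group's similarity.
#'
#' @param result A `simper_result`.
#' @param cutoff_percent Cumulative cutoff in (0, 100].
#' @return The corresponding rows of `result$table`.
#' @export
top_contributors <- function(result, cutoff_percent) {
  stopifnot(inherits(result, "simper_result"))
  if (cutoff_percent <= 0 || cutoff_percent > 100)
    stop("cutoff_percent must lie in (0, 100]")
  tab <- result$table
  k <- which(tab$cumulative_pct >= cutoff_percent - 1e-9)[1L]
  if (is.na(k)) k <- nrow(tab)
  tab[seq_len(k), , drop = FALSE]
}
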