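#' Analysis of Similarity (ANOSIM)
#'
#' Rank-based test of whether between-group dissimilarities exceed
#' within-group dissimilarities. All n(n-1)/2 pairwise dissimilarities are
#' ranked with midranks for ties; with rB the mean rank of between-group
#' pairs and rW the mean rank of within-group pairs,
#' \deqn{R = \frac{rB - rW}{c}, \qquad c = n(n-1)/4,}
#' so R lies in \[-1, 1\], reaching 1 exactly when every between-group
#' dissimilarity is larger than every within-group one and 0 when groups are
#' indistinguishable. Significance is assessed by permuting group labels:
#' permutations are sampled uniformly (excluding the identity) and
#' \deqn{sig\% = 100 \frac{n_{\ge} + 1}{n_{perm} + 1}} where n_ge counts
#' permuted R values at least as large as the observed one — the convention
#' under which 44 exceedances in 999 permutations print as 4.5\%.
#'
#' @param dis A `pmf_dist` (or symmetric dissimilarity matrix).
#' @param labels Character vector of group labels, one per sample (in
#'   `dis` order); >= 2 groups each with >= 2 samples.
#' @param n_permutations Number of label permutations (>= 1; 0 skips the
#'   significance test).
#' @param seed Integer seed making the permutation stream reproducible.
#' @return An `anosim_result`: list with `R`, `r_between`, `r_within`, `c`,
#'   `n`, `sig_percent`, `n_permutations`, `n_ge_observed`,
#'   `possible_perms`, `groups`.
#' @export
anosim <- function(dis, labels, n_permutations = 999L, seed = 1L) {
  d <- as.matrix(dis)
  n <- nrow(d)
  labels <- as.character(labels)
  if (length(labels) != n) stop("one label per sample required")
  sizes <- table(labels)
  if (length(sizes) < 2L) stop("need >= 2 groups")
  if (any(sizes < 2L))
    stop("group(s) with a single sample: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  pairs <- .pair_index(n)
  dvec <- d[pairs]
  if (length(unique(dvec)) == 1L) {
    warning("all pairwise dissimilarities equal; R = 0")
    return(structure(list(R = 0, r_between = NA_real_, r_within = NA_real_,
                          c = n * (n - 1) / 4, n = n, sig_percent = 100,
                          n_permutations = 0L, n_ge_observed = 0L,
                          possible_perms = .possible_perms(sizes),
                          groups = "global"),
                     class = "anosim_result"))
  }
  ranks <- rank(dvec, ties.method = "average")
  cconst <- n * (n - 1) / 4
  stat <- function(lab) {
    within <- lab[pairs[, "i"]] == lab[pairs[, "j"]]
    (mean(ranks[!within]) - mean(ranks[within])) / cconst
  }
  R <- stat(labels)
  within <- labels[pairs[, "i"]] == labels[pairs[, "j"]]
  rB <- mean(ranks[!within]); rW <- mean(ranks[within])
  n_ge <- NA_integer_; sig <- NA_real_
  if (n_permutations >= 1L) {
    set.seed(seed)
    perm_R <- vapply(seq_len(n_permutations), function(k) {
      repeat {
        p <- sample.int(n)
        if (!identical(p, seq_len(n))) break
      }
      stat(labels[p])
    }, numeric(1L))
    n_ge <- sum(perm_R >= R)
    sig <- 100 * (n_ge + 1) / (n_permutations + 1)
  }
  structure(list(R = R, r_between = rB, r_within = rW, c = cconst, n = n,
                 sig_percent = sig, n_permutations = as.integer(n_permutations),
                 n_ge_observed = n_ge,
                 possible_perms = .possible_perms(sizes), groups = "global"),
            class = "anosim_result")
}

# distinct label rearrangements: multinomial coefficient n!/(n1!...nk!),
# reported numerically up to 1e9, else the "very large" sentinel
.possible_perms <- function(sizes) {
  lg <- lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1))
  if (lg > log(1e9)) "very large" else round(exp(lg))
}

#' Permutation-test significance percentage
#'
#' @param n_ge_observed Count of permuted statistics >= the observed one.
#' @param n_permutations Number of permutations drawn.
#' @return `100 * (n_ge_observed + 1) / (n_permutations + 1)`.
#' @examples
#' significance_percent(44, 999)  # 4.5
#' @export
significance_percent <- function(n_ge_observed, n_permutations) {
  100 * (n_ge_observed + 1) / (n_permutations + 1)
}

#' @export
print.anosim_result <- function(x, ...) {
  cat("ANOSIM (", paste(x$groups, collapse = " vs "), "): R = ",
      format(x$R, digits = 4), sep = "")
  if (!is.na(x$sig_percent))
    cat(", sig = ", format(x$sig_percent, digits = 3), "% (",
        x$n_ge_observed, "/", x$n_permutations, " perms >= observed)",
        sep = "")
  cat("\n  n = ", x$n, ", possible perms = ",
      format(x$possible_perms, big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Pairwise ANOSIM over all group pairs
#'
#' Runs [anosim()] on the sub-matrix of every unordered pair of groups,
#' reporting for each the count of distinct label arrangements
#' (n1+n2)!/(n1! n2!) — as a number when <= 1e9, else `"very large"`.
#'
#' @inheritParams anosim
#' @return List of `anosim_result`, one per group pair, with `groups` set to
#'   the pair. Seeds for the per-pair permutation streams are derived from
#'   `seed`.
#' @export
pairwise_anosim <- function(dis, labels, n_permutations = 999L, seed = 1L) {
  d <- as.matrix(dis)
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) < 2L) stop("need >= 2 groups")
  combos <- utils::combn(groups, 2L, simplify = FALSE)
  out <- vector("list", length(combos))
  for (k in seq_along(combos)) {
    g <- combos[[k]]
    idx <- which(labels %in% g)
    res <- anosim(d[idx, idx, drop = FALSE], labels[idx],
                  n_permutations = n_permutations,
                  seed = (seed + k - 1L) %% .Machine$integer.max)
    res$groups <- g
    n1 <- sum(labels == g[1L]); n2 <- sum(labels == g[2L])
    res$possible_perms <- .possible_perms(c(n1, n2))
    out[[k]] <- res
  }
  names(out) <- vapply(combos, paste, character(1L), collapse = " vs ")
  out
}

#' Tabulate ANOSIM results
#'
#' @param results List of `anosim_result` (e.g. from [pairwise_anosim()]).
#' @return Data frame with one row per result: groups, R, sig_percent,
#'   possible_perms, n_permutations, n_ge_observed.
#' @export
anosim_table <- function(results) {
  if (inherits(results, "anosim_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(groups = paste(r$groups, collapse = ", "),
               R = r$R, sig_percent = r$sig_percent,
               possible_perms = as.character(r$possible_perms),
               n_permutations = r$n_permutations,
               n_ge_observed = r$n_ge_observed)
  }))
}
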