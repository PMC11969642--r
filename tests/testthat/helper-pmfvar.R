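# shared fixtures and independent oracles for the test suite

# tiny peak matrix from explicit values
toy_matrix <- function(values, mz = NULL, family = NULL,
                       mode = "intensity") {
  values <- as.matrix(values)
  if (is.null(mz)) mz <- 1000.5 + seq_len(ncol(values))
  labels <- data.frame(sample_id = paste0("s", seq_len(nrow(values))))
  if (!is.null(family)) labels$family <- family
  peak_matrix(values, mz, labels, mode = mode)
}

# symmetric dissimilarity matrix from an upper-triangle specification
dist_from_pairs <- function(n, pairs) {
  d <- matrix(0, n, n)
  for (p in pairs) d[p[1L], p[2L]] <- d[p[2L], p[1L]] <- p[3L]
  as_pmf_dist(d)
}

# the constructed 2-group instance where all between > all within (R = 1)
separable_dist <- function() {
  dist_from_pairs(4L, list(c(1, 2, 1), c(3, 4, 2), c(1, 3, 3),
                           c(1, 4, 4), c(2, 3, 5), c(2, 4, 6)))
}

# independent brute-force ANOSIM: explicit rank enumeration, no shared code
# with the package implementation
brute_anosim_R <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  vals <- numeric(0); within <- logical(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    vals <- c(vals, d[i, j])
    within <- c(within, labels[i] == labels[j])
  }
  ranks <- vapply(vals, function(v)
    sum(vals < v) + (sum(vals == v) + 1) / 2, numeric(1))
  (mean(ranks[!within]) - mean(ranks[within])) / (n * (n - 1) / 4)
}

# exhaustive permutation p (as a proportion) for small n by enumerating all
# distinct assignments of the multiset of labels to positions
brute_anosim_exact_p <- function(d, labels) {
  n <- length(labels)
  groups <- unique(labels)
  obs <- brute_anosim_R(d, labels)
  counts <- table(labels)
  assignments <- list(rep(NA_character_, n))
  remaining <- list(seq_len(n))
  for (g in groups) {
    k <- counts[[g]]
    new_assign <- list(); new_rem <- list()
    for (a in seq_along(assignments)) {
      sel <- utils::combn(remaining[[a]], k, simplify = FALSE)
      for (s in sel) {
        lab <- assignments[[a]]; lab[s] <- g
        new_assign[[length(new_assign) + 1L]] <- lab
        new_rem[[length(new_rem) + 1L]] <- setdiff(remaining[[a]], s)
      }
    }
    assignments <- new_assign; remaining <- new_rem
  }
  Rs <- vapply(assignments, function(lab) brute_anosim_R(d, lab), numeric(1))
  mean(Rs >= obs - 1e-12)
}

# random intensity matrix with grouped labels; sizes is one count per group
random_grouped_matrix <- function(sizes, n_features, seed) {
  set.seed(seed)
  n <- sum(sizes)
  values <- matrix(stats::runif(n * n_features, 0.1, 10), n, n_features)
  toy_matrix(values, family = rep(LETTERS[seq_along(sizes)], times = sizes))
}

# taxonomy draw conditioned on leaf-pair EDs actually spanning shallow to
# deep splits (criterion-style input: EDs 20-300 Mya)
spanning_taxonomy <- function(seed, n_families = 8L, depth_mya = 300,
                              min_shallow = 40) {
  s <- seed
  repeat {
    tree <- simulate_taxonomy(n_families, depth_mya, seed = s)
    ed <- pairwise_ed(tree)
    if (min(ed[upper.tri(ed)]) <= min_shallow) return(tree)
    s <- s + 100003L
  }
}

# full synthetic pipeline: spectra -> normalized, aligned, filtered matrix
pipeline_matrix <- function(spectra, transform = "sqrt", tolerance = 0.3) {
  m <- align_peaks(normalize_spectra(spectra), tolerance = tolerance)
  m <- suppressWarnings(filter_nonbiological(m))
  switch(transform,
         sqrt = sqrt_transform(m),
         binary = suppressWarnings(binarize(m)),
         none = m)
}
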