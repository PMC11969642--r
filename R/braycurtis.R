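#' Bray-Curtis dissimilarity on the 0-100 scale
#'
#' For samples x and y over features f,
#' \deqn{d(x, y) = 100 \frac{\sum_f |x_f - y_f|}{\sum_f (x_f + y_f)}}
#' and similarity = 100 - d. The 0-100 scale matches the convention of
#' community-ecology software, where group similarity scores are printed as
#' percentages.
#'
#' @param matrix A [peak_matrix] (intensity or binary mode) with >= 2
#'   samples, each having at least one positive value.
#' @return A `pmf_dist` object: a symmetric numeric matrix of
#'   dissimilarities in \[0, 100\] with zero diagonal, sample ids as
#'   dimnames, and the label table as an attribute.
#' @examples
#' m <- peak_matrix(rbind(c(4, 1, 0), c(1, 1, 3)), c(1000.5, 1105.58, 2000.9),
#'                  data.frame(sample_id = c("a", "b")))
#' bray_curtis(m)  # d = 60
#' @export
bray_curtis <- function(matrix) {
  stopifnot(inherits(matrix, "peak_matrix"))
  x <- matrix$values
  if (nrow(x) < 2L) stop("need >= 2 samples")
  zero <- rowSums(x) == 0
  if (any(zero))
    stop("sample(s) with all-zero values: ",
         paste(matrix$labels$sample_id[zero], collapse = ", "))
  n <- nrow(x)
  d <- base::matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <-
        100 * sum(abs(x[i, ] - x[j, ])) / sum(x[i, ] + x[j, ])
    }
  }
  structure(d, class = c("pmf_dist", "matrix"),
            labels = matrix$labels)
}

#' Coerce a plain symmetric matrix to a pmf_dist
#'
#' @param d Symmetric numeric matrix with zero diagonal, values in
#'   \[0, 100\].
#' @param sample_ids Optional sample ids (default existing dimnames or
#'   `s1..sn`).
#' @return A `pmf_dist` object.
#' @export
as_pmf_dist <- function(d, sample_ids = NULL) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d))))
    stop("d must be a symmetric square matrix")
  if (any(diag(d) != 0)) stop("d must have a zero diagonal")
  if (any(d < 0) || any(d > 100)) stop("dissimilarities must lie in [0, 100]")
  if (is.null(sample_ids))
    sample_ids <- rownames(d) %||% paste0("s", seq_len(nrow(d)))
  dimnames(d) <- list(sample_ids, sample_ids)
  structure(d, class = c("pmf_dist", "matrix"),
            labels = data.frame(sample_id = sample_ids))
}

#' @export
print.pmf_dist <- function(x, ...) {
  cat("pmf_dist: ", nrow(x), " samples, Bray-Curtis scale 0-100\n", sep = "")
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  invisible(x)
}

# lower-triangle pair index helper shared by anosim/simper
.pair_index <- function(n) {
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  cbind(i = i, j = j)
}
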