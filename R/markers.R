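#' Shannon entropy of a two-class label vector
#'
#' @param labels Vector (any type) with at most two distinct values.
#' @return Entropy in bits, with 0 log 0 taken as 0.
#' @examples
#' entropy(c("T", "T", "N", "N"))  # 1 bit
#' @export
entropy <- function(labels) {
  if (!length(labels)) stop("empty label vector")
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of a binary feature for a two-class split
#'
#' ID3-style gain: H(labels) minus the presence-weighted mean conditional
#' entropy of the labels given the feature state,
#' \deqn{IG = H(y) - \sum_{v \in \{0,1\}} \frac{n_v}{n} H(y \mid x = v).}
#'
#' @param feature 0/1 (or logical) presence vector.
#' @param labels Class vector of the same length.
#' @return Gain in bits; always in \[0, H(labels)\].
#' @export
information_gain <- function(feature, labels) {
  feature <- as.numeric(feature)
  if (length(feature) != length(labels)) stop("unequal lengths")
  h <- entropy(labels)
  n <- length(labels)
  cond <- 0
  for (v in unique(feature)) {
    idx <- feature == v
    cond <- cond + sum(idx) / n * entropy(labels[idx])
  }
  h - cond
}

#' Identify diagnostic marker peaks by one-vs-rest information gain
#'
#' For each taxon at the chosen level, labels samples taxon-vs-rest, scores
#' every feature of a binary matrix by [information_gain()], and keeps
#' features with gain at or above `gain_threshold` (at most `max_markers`,
#' highest gain first). Each marker records its expected presence state: the
#' feature state enriched within the taxon relative to the rest.
#'
#' @param matrix A binary-mode [peak_matrix].
#' @param level `"family"` or `"genus"` — which label column defines taxa.
#' @param gain_threshold Minimum gain in bits (default 0.3).
#' @param max_markers Maximum markers kept per taxon (default 10).
#' @return A list of `marker_set` objects, one per taxon with >= 2 samples
#'   (smaller taxa are skipped with a warning). Each holds `taxon`,
#'   `markers` (data frame: mz, expected_present, gain), `gain_threshold`,
#'   `max_markers`.
#' @export
identify_markers <- function(matrix, level = c("family", "genus"),
                             gain_threshold = 0.3, max_markers = 10L) {
  stopifnot(inherits(matrix, "peak_matrix"))
  if (matrix$mode != "binary")
    stop("identify_markers requires a binary-mode matrix (see binarize())")
  level <- match.arg(level)
  taxa_labels <- as.character(matrix$labels[[level]])
  if (anyNA(taxa_labels)) stop("NA labels at level '", level, "'")
  taxa <- sort(unique(taxa_labels))
  if (length(taxa) < 2L) stop("need >= 2 taxa at level '", level, "'")
  x <- matrix$values
  out <- list()
  for (tx in taxa) {
    in_taxon <- taxa_labels == tx
    if (sum(in_taxon) < 2L) {
      warning("skipping taxon '", tx, "' with < 2 samples")
      next
    }
    gains <- apply(x, 2L, information_gain, labels = in_taxon)
    keep <- which(gains >= gain_threshold)
    if (!length(keep)) {
      warning("no features reach gain ", gain_threshold,
              " bits for taxon '", tx, "'")
      markers <- data.frame(mz = numeric(0), expected_present = integer(0),
                            gain = numeric(0))
    } else {
      ord <- keep[order(-gains[keep], matrix$mz[keep])]
      ord <- ord[seq_len(min(length(ord), max_markers))]
      expected <- as.integer(colMeans(x[in_taxon, ord, drop = FALSE]) >
                               colMeans(x[!in_taxon, ord, drop = FALSE]))
      markers <- data.frame(mz = matrix$mz[ord], expected_present = expected,
                            gain = unname(gains[ord]))
    }
    out[[tx]] <- structure(
      list(taxon = tx, markers = markers, gain_threshold = gain_threshold,
           max_markers = as.integer(max_markers)),
      class = "marker_set")
  }
  out
}

#' @export
print.marker_set <- function(x, ...) {
  cat("marker_set '", x$taxon, "': ", nrow(x$markers),
      " markers (gain >= ", x$gain_threshold, " bits)\n", sep = "")
  if (nrow(x$markers)) print(utils::head(x$markers, 5L), row.names = FALSE)
  invisible(x)
}

#' Classify a sample against taxon marker sets
#'
#' A sample matches a taxon when at least `match_fraction` of that taxon's
#' markers agree with their expected presence state. Exactly one matching
#' taxon yields that taxon; zero or multiple matches yield
#' `"Unclassified"` — the tool prefers an Unclassified outcome over a false
#' positive, and multiple-match ambiguities are reported via a message.
#'
#' @param sample Named 0/1 vector (names = feature m/z as in the binary
#'   matrix columns) or a single row of a binary [peak_matrix]'s values.
#' @param marker_sets List of `marker_set` objects (non-empty).
#' @param match_fraction Fraction of markers that must agree (default 0.8).
#' @param mz Optional numeric m/z for the sample's features (defaults to
#'   `as.numeric(names(sample))`); markers are matched to sample features
#'   within `tolerance`.
#' @param tolerance m/z matching tolerance in Da (default 0.3).
#' @return Character scalar: a taxon name or `"Unclassified"`.
#' @export
classify <- function(sample, marker_sets, match_fraction = 0.8,
                     mz = NULL, tolerance = 0.3) {
  if (!length(marker_sets)) stop("marker_sets must be non-empty")
  if (is.null(mz)) mz <- as.numeric(names(sample))
  if (anyNA(mz)) stop("sample features must carry numeric m/z names")
  sample <- as.numeric(sample)
  taxa <- vapply(marker_sets, function(ms) ms$taxon, character(1L))
  matched <- vapply(marker_sets, function(ms) {
    mk <- ms$markers
    if (!nrow(mk)) return(FALSE)
    agree <- vapply(seq_len(nrow(mk)), function(r) {
      hit <- which(abs(mz - mk$mz[r]) <= tolerance)
      present <- length(hit) > 0L && any(sample[hit] > 0)
      as.integer(present) == mk$expected_present[r]
    }, logical(1L))
    mean(agree) >= match_fraction
  }, logical(1L))
  hits <- taxa[matched]
  if (length(hits) == 1L) return(hits)
  if (length(hits) > 1L)
    message("ambiguous classification (matches: ",
            paste(hits, collapse = ", "), "); returning Unclassified")
  "Unclassified"
}

#' Classify every sample of a binary matrix
#'
#' @param matrix Binary-mode [peak_matrix].
#' @inheritParams classify
#' @return Named character vector of predictions (names = sample ids).
#' @export
classify_matrix <- function(matrix, marker_sets, match_fraction = 0.8,
                            tolerance = 0.3) {
  stopifnot(inherits(matrix, "peak_matrix"))
  if (matrix$mode != "binary") stop("binary-mode matrix required")
  preds <- vapply(seq_len(nrow(matrix$values)), function(i)
    classify(matrix$values[i, ], marker_sets,
             match_fraction = match_fraction, mz = matrix$mz,
             tolerance = tolerance), character(1L))
  stats::setNames(preds, matrix$labels$sample_id)
}

#' Evaluate classifications against ground truth
#'
#' Per taxon: TP = correctly predicted samples of that taxon; FN = samples
#' of that taxon predicted as another taxon or Unclassified; FP = samples of
#' other taxa predicted as this taxon. Sensitivity = TP / (TP + FN), with
#' group mean and SD across taxa.
#'
#' @param predictions Character vector of predicted taxa (may contain
#'   `"Unclassified"`).
#' @param truth Character vector of true taxa, same length/order.
#' @return A `classification_report`: list with `per_taxon` (data frame:
#'   taxon, tp, fp, fn, sensitivity), `mean_sensitivity`, `sd_sensitivity`.
#' @export
evaluate <- function(predictions, truth) {
  if (length(predictions) != length(truth)) stop("length mismatch")
  predictions <- as.character(predictions); truth <- as.character(truth)
  taxa <- sort(unique(truth))
  per <- do.call(rbind, lapply(taxa, function(tx) {
    tp <- sum(predictions == tx & truth == tx)
    fn <- sum(predictions != tx & truth == tx)
    fp <- sum(predictions == tx & truth != tx)
    data.frame(taxon = tx, tp = tp, fp = fp, fn = fn,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
  }))
  structure(list(per_taxon = per,
                 mean_sensitivity = mean(per$sensitivity, na.rm = TRUE),
                 sd_sensitivity = stats::sd(per$sensitivity, na.rm = TRUE)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("classification report: mean sensitivity ",
      format(x$mean_sensitivity, digits = 3), " +/- ",
      format(x$sd_sensitivity, digits = 3), " across ",
      nrow(x$per_taxon), " taxa\n", sep = "")
  print(x$per_taxon, row.names = FALSE)
  invisible(x)
}
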