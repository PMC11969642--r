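#' Sample-by-peak feature matrix
#'
#' A `peak_matrix` is the central container of the pipeline: rows are
#' samples, columns are aligned peak features identified by their reference
#' m/z, values are intensities (or 0/1 in binary mode), and each sample
#' carries family/genus/dataset factor labels.
#'
#' @param values Numeric matrix, samples x features, non-negative.
#' @param mz Numeric vector of strictly increasing reference m/z (Da), one
#'   per column.
#' @param labels Data frame with columns `sample_id` and any of `family`,
#'   `genus`, `dataset`, one row per sample, in row order.
#' @param mode `"intensity"` or `"binary"`.
#' @return An object of class `peak_matrix`.
#' @export
peak_matrix <- function(values, mz, labels, mode = c("intensity", "binary")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  mz <- as.numeric(mz)
  if (ncol(values) != length(mz))
    stop("ncol(values) must equal length(mz)")
  if (length(mz) > 1L && any(diff(mz) <= 0))
    stop("feature m/z must be strictly increasing")
  if (any(values < 0)) stop("negative values in peak matrix")
  if (mode == "binary" && !all(values %in% c(0, 1)))
    stop("binary-mode matrix may contain only 0/1")
  labels <- as.data.frame(labels)
  if (!"sample_id" %in% names(labels))
    stop("labels must contain a sample_id column")
  if (nrow(labels) != nrow(values))
    stop("labels must have one row per sample")
  for (f in c("family", "genus", "dataset"))
    if (!f %in% names(labels)) labels[[f]] <- NA_character_
  labels <- labels[, c("sample_id", "family", "genus", "dataset")]
  if (anyDuplicated(labels$sample_id)) stop("duplicate sample ids")
  if (ncol(values) > 0L) {
    empty <- colSums(values) == 0
    if (any(empty)) {
      warning("dropping ", sum(empty), " all-zero feature column(s)")
      values <- values[, !empty, drop = FALSE]
      mz <- mz[!empty]
    }
  }
  rownames(values) <- labels$sample_id
  colnames(values) <- sprintf("%.2f", mz)
  structure(list(values = values, mz = mz, labels = labels, mode = mode),
            class = "peak_matrix")
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat("peak_matrix: ", nrow(x$values), " samples x ", length(x$mz),
      " features (", x$mode, " mode)\n", sep = "")
  if (length(x$mz))
    cat(sprintf("  m/z range %.2f-%.2f\n", min(x$mz), max(x$mz)))
  fams <- unique(stats::na.omit(x$labels$family))
  if (length(fams))
    cat("  families: ", paste(fams, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.peak_matrix <- function(x) dim(x$values)

#' Align peaks across samples into a feature matrix
#'
#' Pools all peaks, walks them in ascending m/z, and greedily merges peaks
#' into a feature while they fall within `tolerance` of the feature's running
#' intensity-weighted mean m/z; a more distant peak opens a new feature.
#' Merging is then repeated on adjacent feature references until no two
#' features lie within `tolerance`, which also makes the operation
#' idempotent. A sample contributing several peaks to one feature has their
#' intensities summed, so each matrix row conserves the sample's total peak
#' intensity.
#'
#' @param spectra List of [pmf_spectrum] objects (>= 2).
#' @param tolerance Positive merge tolerance in Da (default 0.3, a typical
#'   MALDI-ToF PMF bin width).
#' @return A [peak_matrix] in intensity mode.
#' @export
align_peaks <- function(spectra, tolerance = 0.3) {
  if (tolerance <= 0) stop("tolerance must be positive")
  if (length(spectra) < 2L) stop("need at least 2 spectra to align")
  ids <- vapply(spectra, function(s) s$sample_id, character(1L))
  if (anyDuplicated(ids)) stop("duplicate sample ids among spectra")
  pool <- data.frame(
    mz = unlist(lapply(spectra, `[[`, "mz")),
    intensity = unlist(lapply(spectra, `[[`, "intensity")),
    sample = rep(seq_along(spectra),
                 vapply(spectra, function(s) length(s$mz), integer(1L))))
  if (!nrow(pool)) stop("no peaks present in any spectrum")
  pool <- pool[order(pool$mz), , drop = FALSE]

  # greedy pass: assign each pooled peak to an open feature or start a new one
  feat <- integer(nrow(pool))
  ref <- numeric(0)     # running weighted-mean m/z per feature
  wsum <- numeric(0)    # running intensity weight per feature
  for (i in seq_len(nrow(pool))) {
    m <- pool$mz[i]; w <- max(pool$intensity[i], .Machine$double.eps)
    k <- length(ref)
    if (k > 0L && abs(m - ref[k]) <= tolerance) {
      feat[i] <- k
      wsum[k] <- wsum[k] + w
      ref[k] <- ref[k] + w * (m - ref[k]) / wsum[k]
    } else {
      ref <- c(ref, m); wsum <- c(wsum, w)
      feat[i] <- length(ref)
    }
  }
  # consolidation passes: merge adjacent features whose references collide
  repeat {
    if (length(ref) < 2L) break
    gap <- diff(ref)
    j <- which(gap <= tolerance)
    if (!length(j)) break
    j <- j[1L]
    ref[j] <- (ref[j] * wsum[j] + ref[j + 1L] * wsum[j + 1L]) /
      (wsum[j] + wsum[j + 1L])
    wsum[j] <- wsum[j] + wsum[j + 1L]
    ref <- ref[-(j + 1L)]; wsum <- wsum[-(j + 1L)]
    feat[feat > j] <- feat[feat > j] - 1L
  }

  values <- matrix(0, nrow = length(spectra), ncol = length(ref))
  for (i in seq_len(nrow(pool)))
    values[pool$sample[i], feat[i]] <- values[pool$sample[i], feat[i]] +
      pool$intensity[i]
  labels <- data.frame(
    sample_id = ids,
    family = vapply(spectra, function(s) s$family %||% NA_character_, character(1L)),
    genus = vapply(spectra, function(s) s$genus %||% NA_character_, character(1L)),
    dataset = vapply(spectra, function(s) s$dataset %||% NA_character_, character(1L)))
  peak_matrix(values, ref, labels, mode = "intensity")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Scale each spectrum to a common total intensity
#'
#' MALDI absolute intensities are not comparable across spots; scaling each
#' spectrum to a fixed total (default 100, i.e. relative peak intensity)
#' before matrix assembly puts samples on a common footing.
#'
#' @param spectra List of [pmf_spectrum] objects.
#' @param total Target total intensity per spectrum.
#' @return The rescaled list.
#' @export
normalize_spectra <- function(spectra, total = 100) {
  stopifnot(total > 0)
  lapply(spectra, function(s) {
    ti <- sum(s$intensity)
    if (ti > 0) s$intensity <- s$intensity * (total / ti)
    s
  })
}

#' Square-root transform an intensity matrix
#'
#' The standard variance-stabilising transform applied before Bray-Curtis
#' comparison of intensity fingerprints, down-weighting dominant peaks.
#'
#' @param matrix A [peak_matrix] in intensity mode.
#' @return The transformed [peak_matrix] (still intensity mode).
#' @export
sqrt_transform <- function(matrix) {
  stopifnot(inherits(matrix, "peak_matrix"))
  if (matrix$mode != "intensity")
    stop("sqrt_transform requires an intensity-mode matrix")
  matrix$values <- sqrt(matrix$values)
  matrix
}

#' Reduce a matrix to peak presence/absence
#'
#' Every positive value becomes 1, zeros stay 0, and the mode flips to
#' binary. All-zero samples are retained with a warning.
#'
#' @param matrix A [peak_matrix].
#' @return A binary-mode [peak_matrix].
#' @export
binarize <- function(matrix) {
  stopifnot(inherits(matrix, "peak_matrix"))
  zero_rows <- rowSums(matrix$values) == 0
  if (any(zero_rows))
    warning("all-zero sample row(s) retained: ",
            paste(matrix$labels$sample_id[zero_rows], collapse = ", "))
  matrix$values[] <- as.numeric(matrix$values > 0)
  matrix$mode <- "binary"
  matrix
}

#' Non-biological peak filter rule
#'
#' Tryptic peptides carry a characteristic mass defect (fractional mass) that
#' grows roughly linearly with mass — about 4.95e-4 per Da, the averagine
#' peptide defect — whereas matrix and other chemical-noise peaks sit near
#' integer or 0.1 decimals (e.g. the common matrix peak at m/z 1060.1).
#' The rule removes features below `min_mz` and features whose fractional
#' mass deviates from the expected peptide defect by more than
#' `defect_tolerance` (circular distance, so the rule remains correct above
#' m/z 2000 where peptide defects approach 1).
#'
#' @param min_mz Minimum biologically plausible peptide m/z (default 900).
#' @param defect_slope Expected defect growth per Da (default 4.95e-4).
#' @param defect_tolerance Allowed deviation from the expected defect
#'   (default 0.25; must lie in (0, 0.5)).
#' @return An object of class `filter_rule`.
#' @export
filter_rule <- function(min_mz = 900, defect_slope = 4.95e-4,
                        defect_tolerance = 0.25) {
  if (min_mz <= 0) stop("min_mz must be positive")
  if (defect_tolerance <= 0 || defect_tolerance >= 0.5)
    stop("defect_tolerance must lie in (0, 0.5)")
  structure(list(min_mz = min_mz, defect_slope = defect_slope,
                 defect_tolerance = defect_tolerance),
            class = "filter_rule")
}

#' Remove non-biological features from a peak matrix
#'
#' Applies a [filter_rule] and reports every removal with the rule that
#' triggered it. Samples left with no peaks are dropped with a warning.
#' The operation is idempotent.
#'
#' @param matrix A [peak_matrix].
#' @param rule A [filter_rule].
#' @return The filtered [peak_matrix], with a `removal_report` attribute: a
#'   data frame of (feature m/z, rule) rows.
#' @export
filter_nonbiological <- function(matrix, rule = filter_rule()) {
  stopifnot(inherits(matrix, "peak_matrix"), inherits(rule, "filter_rule"))
  mz <- matrix$mz
  below <- mz < rule$min_mz
  expected <- (rule$defect_slope * mz) %% 1
  observed <- mz %% 1
  dev <- abs(observed - expected)
  dev <- pmin(dev, 1 - dev)  # circular: defect wraps at 1 Da
  bad_defect <- !below & dev > rule$defect_tolerance
  report <- data.frame(
    mz = c(mz[below], mz[bad_defect]),
    rule = c(rep("below_min_mz", sum(below)),
             rep("mass_defect", sum(bad_defect))))
  report <- report[order(report$mz), , drop = FALSE]
  keep <- !(below | bad_defect)
  matrix$values <- matrix$values[, keep, drop = FALSE]
  matrix$mz <- mz[keep]
  empty <- rowSums(matrix$values) == 0
  if (any(empty)) {
    warning("dropping sample(s) left empty by filtering: ",
            paste(matrix$labels$sample_id[empty], collapse = ", "))
    matrix$values <- matrix$values[!empty, , drop = FALSE]
    matrix$labels <- matrix$labels[!empty, , drop = FALSE]
  }
  attr(matrix, "removal_report") <- report
  matrix
}

#' Write / read a peak matrix as CSV
#'
#' The CSV holds one row per sample with label columns first, then one
#' column per feature named by its reference m/z to 2 decimals. The matrix
#' mode is recorded in a `# mode:` header comment so the file round-trips
#' losslessly.
#'
#' @param matrix A [peak_matrix].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_peak_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "peak_matrix"))
  df <- cbind(matrix$labels,
              as.data.frame(matrix$values, check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# mode: ", matrix$mode), con)
  writeLines(paste0("# mz: ", paste(format(matrix$mz, digits = 15),
                                    collapse = ",")), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_matrix
#' @export
read_peak_matrix <- function(path) {
  lines <- readLines(path, n = 2L)
  if (!grepl("^# mode:", lines[1L]) || !grepl("^# mz:", lines[2L]))
    stop("not a peak-matrix CSV (missing mode/mz header): ", path)
  mode <- trimws(sub("^# mode:", "", lines[1L]))
  mz <- as.numeric(strsplit(trimws(sub("^# mz:", "", lines[2L])), ",")[[1L]])
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  labcols <- c("sample_id", "family", "genus", "dataset")
  labels <- df[, intersect(labcols, names(df)), drop = FALSE]
  values <- as.matrix(df[, setdiff(names(df), labcols), drop = FALSE])
  peak_matrix(values, mz, labels, mode = mode)
}
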