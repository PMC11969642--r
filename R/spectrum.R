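#' Construct a peak-list spectrum
#'
#' A `pmf_spectrum` holds one sample's picked MALDI-ToF peak list: a strictly
#' increasing m/z vector, non-negative intensities of the same length, and
#' optional taxonomic labels (family, genus, dataset).
#'
#' @param sample_id Character scalar, unique within a collection.
#' @param mz Numeric vector of mass-to-charge values (Da).
#' @param intensity Numeric vector of non-negative abundances, same length.
#' @param family,genus,dataset Optional character labels (`NA` if unknown).
#' @return An object of class `pmf_spectrum`.
#' @examples
#' pmf_spectrum("s1", c(1105.58, 2869.45), c(200, 50), family = "Bovidae")
#' @export
pmf_spectrum <- function(sample_id, mz, intensity,
                         family = NA_character_, genus = NA_character_,
                         dataset = NA_character_) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L, nzchar(sample_id))
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length for sample '", sample_id, "'")
  if (anyNA(mz) || anyNA(intensity))
    stop("NA values in peak list for sample '", sample_id, "'")
  ord <- order(mz)
  mz <- mz[ord]
  intensity <- intensity[ord]
  if (length(mz) > 1L && any(diff(mz) <= 0))
    stop("duplicate m/z values in sample '", sample_id, "'")
  if (any(intensity < 0))
    stop("negative intensity in sample '", sample_id, "'")
  structure(
    list(sample_id = sample_id, mz = mz, intensity = intensity,
         family = as.character(family), genus = as.character(genus),
         dataset = as.character(dataset)),
    class = "pmf_spectrum")
}

#' @export
print.pmf_spectrum <- function(x, ...) {
  cat("pmf_spectrum '", x$sample_id, "': ", length(x$mz), " peaks",
      if (length(x$mz)) sprintf(", m/z %.2f-%.2f", min(x$mz), max(x$mz)) else "",
      "\n", sep = "")
  labs <- c(family = x$family, genus = x$genus, dataset = x$dataset)
  labs <- labs[!is.na(labs)]
  if (length(labs))
    cat("  ", paste(names(labs), labs, sep = ": ", collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' Peak-picking parameters
#'
#' Controls smoothing, baseline estimation and the signal-to-noise threshold
#' used by [pick_peaks()]. Defaults follow the common MALDIquant-style ZooMS
#' workflow: moving-average smoothing with a 20-point half-window, SNIP-style
#' iterative baseline with 100 iterations, and SNR 3 against an MAD noise
#' estimate.
#'
#' @param half_window Positive integer smoothing window radius, in points.
#' @param snr Positive signal-to-noise threshold.
#' @param baseline_iterations Positive integer SNIP iteration count.
#' @param align_tolerance Positive alignment tolerance in Da (see
#'   [align_peaks()]).
#' @return An object of class `peak_picking_params`.
#' @export
peak_picking_params <- function(half_window = 20L, snr = 3,
                                baseline_iterations = 100L,
                                align_tolerance = 0.3) {
  half_window <- as.integer(half_window)
  baseline_iterations <- as.integer(baseline_iterations)
  if (half_window <= 0L || snr <= 0 || baseline_iterations <= 0L ||
      align_tolerance <= 0)
    stop("all peak-picking parameters must be strictly positive")
  structure(list(half_window = half_window, snr = snr,
                 baseline_iterations = baseline_iterations,
                 align_tolerance = align_tolerance),
            class = "peak_picking_params")
}

#' Read picked peak lists with sample metadata
#'
#' Each input file is a two-column numeric table (m/z, intensity), comma-,
#' tab- or whitespace-delimited, with an optional header line. The sample id
#' is the file stem. Labels are joined from `metadata`, a data frame with a
#' `sample_id` column and any of `family`, `genus`, `dataset`; samples absent
#' from the metadata carry `NA` labels and a warning is raised.
#'
#' @param paths Character vector of file paths.
#' @param metadata Optional data frame mapping sample_id to labels.
#' @return A list of [pmf_spectrum] objects, one per file.
#' @export
read_peak_lists <- function(paths, metadata = NULL) {
  stopifnot(length(paths) >= 1L)
  ids <- sub("\\.[^.]*$", "", basename(paths))
  if (anyDuplicated(ids))
    stop("duplicate sample ids from file stems: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (!"sample_id" %in% names(metadata))
      stop("metadata must contain a sample_id column")
    if (anyDuplicated(metadata$sample_id))
      stop("duplicate sample_id rows in metadata")
  }
  missing_meta <- character()
  spectra <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    tab <- .read_two_column(paths[i])
    labs <- list(family = NA_character_, genus = NA_character_,
                 dataset = NA_character_)
    if (!is.null(metadata)) {
      row <- metadata[metadata$sample_id == ids[i], , drop = FALSE]
      if (nrow(row) == 1L) {
        for (f in c("family", "genus", "dataset"))
          if (f %in% names(row)) labs[[f]] <- as.character(row[[f]][1L])
      } else {
        missing_meta <- c(missing_meta, ids[i])
      }
    }
    spectra[[i]] <- pmf_spectrum(ids[i], tab[[1L]], tab[[2L]],
                                 family = labs$family, genus = labs$genus,
                                 dataset = labs$dataset)
  }
  if (length(missing_meta))
    warning("no metadata for sample(s): ", paste(missing_meta, collapse = ", "))
  names(spectra) <- ids
  spectra
}

.read_two_column <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty peak-list file: ", path)
  parse_line <- function(s) strsplit(trimws(s), "[,\t ]+")[[1L]]
  start <- 1L
  first <- suppressWarnings(as.numeric(parse_line(lines[1L])))
  if (anyNA(first)) start <- 2L  # header line
  if (start > length(lines)) stop("no numeric rows in peak-list file: ", path)
  mz <- numeric(0); intensity <- numeric(0)
  for (k in start:length(lines)) {
    vals <- suppressWarnings(as.numeric(parse_line(lines[k])))
    if (length(vals) < 2L || anyNA(vals[1:2]))
      stop("non-numeric row in ", path, " at line ", k, ": '", lines[k], "'")
    mz <- c(mz, vals[1L]); intensity <- c(intensity, vals[2L])
  }
  data.frame(mz = mz, intensity = intensity)
}

#' Pick peaks from a profile spectrum
#'
#' Smooths the raw trace with a moving average, subtracts a SNIP-style
#' iteratively clipped baseline, estimates noise as the median absolute
#' deviation of the corrected trace, and returns local maxima whose corrected
#' height is at least `snr` times the noise estimate. Because the noise
#' estimate scales with the signal, the picked peaks are invariant to uniform
#' intensity scaling of the profile.
#'
#' @param profile A list with numeric `mz` and `intensity` of equal length
#'   (a raw trace; need not satisfy [pmf_spectrum] peak-list invariants), or a
#'   `pmf_spectrum`.
#' @param params A [peak_picking_params] object.
#' @param sample_id Sample id for the returned spectrum (defaults to the
#'   profile's, or `"profile"`).
#' @return A [pmf_spectrum] of picked peaks.
#' @export
pick_peaks <- function(profile, params = peak_picking_params(),
                       sample_id = NULL) {
  stopifnot(inherits(params, "peak_picking_params"))
  mz <- as.numeric(profile$mz)
  y <- as.numeric(profile$intensity)
  n <- length(y)
  if (n != length(mz)) stop("profile mz/intensity length mismatch")
  if (n < 2L * params$half_window + 1L)
    stop("profile trace shorter than the smoothing window (",
         2L * params$half_window + 1L, " points required)")
  ys <- .moving_average(y, params$half_window)
  base <- .snip_baseline(ys, params$baseline_iterations)
  corr <- ys - base
  # noise on the unsmoothed corrected trace: the raw noise scale, so the
  # SNR threshold refers to point noise, not the smoothing-attenuated one
  noise <- stats::mad(y - base)
  if (noise == 0) noise <- .Machine$double.eps
  is_max <- .local_maxima(corr, params$half_window)
  keep <- is_max & (corr >= params$snr * noise) & (corr > 0)
  if (is.null(sample_id))
    sample_id <- if (!is.null(profile$sample_id)) profile$sample_id else "profile"
  if (!any(keep))
    return(pmf_spectrum(sample_id, numeric(0), numeric(0)))
  pmf_spectrum(sample_id, mz[keep], corr[keep],
               family = if (is.null(profile$family)) NA else profile$family,
               genus = if (is.null(profile$genus)) NA else profile$genus,
               dataset = if (is.null(profile$dataset)) NA else profile$dataset)
}

.moving_average <- function(y, half_window) {
  n <- length(y)
  w <- 2L * half_window + 1L
  padded <- c(rep(y[1L], half_window), y, rep(y[n], half_window))
  as.numeric(stats::filter(padded, rep(1 / w, w), sides = 2L))[
    (half_window + 1L):(half_window + n)]
}

# SNIP-style baseline: iteratively clip each point to the mean of its
# symmetric neighbours at increasing spans.
.snip_baseline <- function(y, iterations) {
  n <- length(y)
  b <- y
  for (k in seq_len(min(iterations, n %/% 2L))) {
    left <- c(rep(b[1L], k), b[seq_len(n - k)])
    right <- c(b[(k + 1L):n], rep(b[n], k))
    b <- pmin(b, (left + right) / 2)
  }
  b
}

.local_maxima <- function(y, half_window) {
  n <- length(y)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half_window); hi <- min(n, i + half_window)
    y[i] == max(y[lo:hi]) && !(i > lo && y[i] == y[i - 1L])
  }, logical(1L))
}
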