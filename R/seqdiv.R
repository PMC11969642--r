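#' Pairwise identity metrics for two aligned sequences
#'
#' Positions where both sequences carry a gap are skipped; a position with a
#' gap in exactly one sequence counts as a difference. Over the remaining
#' compared positions, `count_difference` is the number of differing
#' positions and `identity_percent = 100 * matches / compared`.
#'
#' @param aligned_a,aligned_b Equal-length aligned residue strings (gap
#'   character `-`).
#' @param taxon_a,taxon_b Optional taxon names for the record.
#' @return A `sequence_pair`: list with the taxa, sequences,
#'   `compared_positions`, `count_difference`, `identity_percent`.
#' @examples
#' identity_metrics("GPAG-P", "GPSGAP")  # 2 differences, identity 66.67
#' @export
identity_metrics <- function(aligned_a, aligned_b,
                             taxon_a = "a", taxon_b = "b") {
  a <- strsplit(toupper(aligned_a), "")[[1L]]
  b <- strsplit(toupper(aligned_b), "")[[1L]]
  if (length(a) != length(b)) stop("aligned sequences must have equal length")
  both_gap <- a == "-" & b == "-"
  a <- a[!both_gap]; b <- b[!both_gap]
  if (!length(a)) stop("zero comparable positions")
  diff <- a != b  # includes single-gap positions
  structure(list(taxon_a = taxon_a, taxon_b = taxon_b,
                 compared_positions = length(a),
                 count_difference = sum(diff),
                 identity_percent = 100 * sum(!diff) / length(a)),
            class = "sequence_pair")
}

#' @export
print.sequence_pair <- function(x, ...) {
  cat("sequence_pair ", x$taxon_a, " vs ", x$taxon_b, ": ",
      x$count_difference, " differences over ", x$compared_positions,
      " positions (identity ", format(x$identity_percent, digits = 4),
      "%)\n", sep = "")
  invisible(x)
}

#' Pairwise identity metrics for an aligned FASTA
#'
#' @param path Aligned FASTA file (equal-length sequences).
#' @return Data frame with one row per unordered sequence pair: taxon_a,
#'   taxon_b, compared_positions, count_difference, identity_percent.
#' @export
alignment_metrics <- function(path) {
  seqs <- read_fasta(path)
  if (length(seqs) < 2L) stop("need >= 2 sequences")
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences are not aligned (unequal lengths)")
  combos <- utils::combn(names(seqs), 2L, simplify = FALSE)
  do.call(rbind, lapply(combos, function(p) {
    m <- identity_metrics(seqs[[p[1L]]], seqs[[p[2L]]], p[1L], p[2L])
    data.frame(taxon_a = m$taxon_a, taxon_b = m$taxon_b,
               compared_positions = m$compared_positions,
               count_difference = m$count_difference,
               identity_percent = m$identity_percent)
  }))
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", path)
  names_ <- sub("^>\\s*", "", lines[hdr])
  names_ <- vapply(strsplit(names_, "\\s+"), `[[`, character(1L), 1L)
  starts <- hdr + 1L
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i)
    paste(lines[starts[i]:ends[i]], collapse = ""), character(1L))
  stats::setNames(gsub("\\s", "", seqs), names_)
}

#' Write sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(strsplit(seqs[[nm]], "(?<=.{60})", perl = TRUE)[[1L]], con)
  }
  invisible(path)
}

#' Toy global pairwise aligner
#'
#' Needleman-Wunsch with match +1, mismatch -1, linear gap -2. Intended only
#' for toy inputs and demonstrations; it is not a substitute for curated
#' alignments of real collagen chains.
#'
#' @param a,b Unaligned residue strings.
#' @return List with `aligned_a`, `aligned_b`, `score`.
#' @export
align_global <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(toupper(a), "")[[1L]]; B <- strsplit(toupper(b), "")[[1L]]
  n <- length(A); m <- length(B)
  S <- base::matrix(0, n + 1L, m + 1L)
  S[, 1L] <- gap * 0:n; S[1L, ] <- gap * 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (A[i] == B[j]) match else mismatch
    S[i + 1L, j + 1L] <- max(S[i, j] + s, S[i, j + 1L] + gap,
                             S[i + 1L, j] + gap)
  }
  ra <- character(0); rb <- character(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        S[i + 1L, j + 1L] ==
        S[i, j] + (if (A[i] == B[j]) match else mismatch)) {
      ra <- c(A[i], ra); rb <- c(B[j], rb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      ra <- c(A[i], ra); rb <- c("-", rb); i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(B[j], rb); j <- j - 1L
    }
  }
  list(aligned_a = paste(ra, collapse = ""),
       aligned_b = paste(rb, collapse = ""), score = S[n + 1L, m + 1L])
}

# amino-acid substitution rates per collagen chain (changes per Mya scale
# unit); the fish-specific alpha 3 chain evolves fastest
.chain_rates <- c(COL1A1 = 0.7, COL1A2 = 0.9, COL1A3 = 1.0)

#' Predicted amino-acid change from divergence time
#'
#' Applies the per-chain substitution rate (COL1A1 0.7, COL1A2 0.9,
#' COL1A3 1.0) linearly to the evolutionary distance:
#' `predicted_change = rate * ed_mya * time_scale`. The `time_scale`
#' multiplier makes the rate's time unit explicit and is recorded in the
#' output; ED is treated as the divergence time itself, not doubled.
#'
#' @param ed_mya Median divergence time in Mya (> 0).
#' @param chain One of `"COL1A1"`, `"COL1A2"`, `"COL1A3"`.
#' @param time_scale Changes-per-Mya multiplier (default 1).
#' @param taxon_a,taxon_b Optional taxa for the record.
#' @return A `divergence_record`: list with taxa, `ed_mya`, `chain`,
#'   `rate`, `time_scale`, `predicted_change`.
#' @export
predicted_change <- function(ed_mya, chain, time_scale = 1,
                             taxon_a = NA_character_,
                             taxon_b = NA_character_) {
  if (!is.numeric(ed_mya) || ed_mya <= 0) stop("ed_mya must be > 0")
  if (!chain %in% names(.chain_rates))
    stop("unknown chain '", chain, "' (expected COL1A1/COL1A2/COL1A3)")
  rate <- .chain_rates[[chain]]
  structure(list(taxon_a = taxon_a, taxon_b = taxon_b, ed_mya = ed_mya,
                 chain = chain, rate = rate, time_scale = time_scale,
                 predicted_change = rate * ed_mya * time_scale),
            class = "divergence_record")
}

#' Mean ANOSIM R for one family across its pairwise comparisons
#'
#' @param pairwise List of `anosim_result` from [pairwise_anosim()].
#' @param family Family name; must occur in at least one pair.
#' @return The arithmetic mean R over all pairs involving `family`.
#' @seealso [mean_family_R_table()] for all families with group mean and SD.
#' @export
mean_family_R <- function(pairwise, family) {
  Rs <- unlist(lapply(pairwise, function(r)
    if (family %in% r$groups) r$R else NULL))
  if (is.null(Rs)) stop("family '", family, "' appears in no pair")
  mean(Rs)
}

#' @rdname mean_family_R
#' @return For `mean_family_R_table`: list with `per_family` (data frame:
#'   family, mean_R, n_pairs), `group_mean`, `group_sd`.
#' @export
mean_family_R_table <- function(pairwise) {
  fams <- sort(unique(unlist(lapply(pairwise, `[[`, "groups"))))
  per <- do.call(rbind, lapply(fams, function(f) {
    Rs <- unlist(lapply(pairwise, function(r) if (f %in% r$groups) r$R))
    data.frame(family = f, mean_R = mean(Rs), n_pairs = length(Rs))
  }))
  list(per_family = per, group_mean = mean(per$mean_R),
       group_sd = stats::sd(per$mean_R))
}

#' Simple linear fit with correlation summary
#'
#' Ordinary least squares of y on x with Pearson correlation; for a simple
#' linear fit r-squared equals the squared correlation coefficient.
#'
#' @param x,y Numeric vectors, n >= 3, finite, x non-constant.
#' @return A `fit_result`: list with `slope`, `intercept`, `pearson_r`,
#'   `r_squared`, `n`.
#' @export
fit_linear <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (stats::var(x) == 0) stop("zero variance in x")
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  r <- if (stats::var(y) == 0) 0 else stats::cor(x, y)
  structure(list(slope = slope, intercept = intercept, pearson_r = r,
                 r_squared = r^2, n = length(x)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("linear fit (n = %d): y = %.4g x + %.4g, r = %.3f, R2 = %.3f\n",
              x$n, x$slope, x$intercept, x$pearson_r, x$r_squared))
  invisible(x)
}

#' Filter divergence records by maximum evolutionary distance
#'
#' Deep splits blur the linear relation between fingerprint dissimilarity
#' and divergence time; this retains records with `ed_mya <= max_ed`
#' (boundary kept) and reports the retained/removed counts via a message.
#'
#' @param records Data frame with an `ed_mya` column (or list of
#'   `divergence_record`).
#' @param max_ed Maximum ED in Mya (> 0).
#' @return The retained records (same shape as the input).
#' @export
filter_by_ed <- function(records, max_ed) {
  if (max_ed <= 0) stop("max_ed must be > 0")
  eds <- if (is.data.frame(records)) records$ed_mya
         else vapply(records, `[[`, numeric(1L), "ed_mya")
  keep <- eds <= max_ed
  message(sum(keep), " record(s) retained, ", sum(!keep),
          " removed at ED <= ", max_ed, " Mya")
  if (!any(keep)) warning("no records survive the ED filter")
  if (is.data.frame(records)) records[keep, , drop = FALSE]
  else records[keep]
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-sided p-value.
#'
#' @param a,b Numeric vectors, each n >= 2 with positive variance.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("degenerate variance in both groups")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}
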