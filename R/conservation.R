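# Per-column residue conservation of the query alignment, scored with
# Jensen-Shannon divergence against a background distribution. High scores
# mark conserved (background-unlike) columns.

#' Amino-acid profile of one alignment column
#'
#' Counts residues in the alignment column aligned to the given 1-based query
#' position. Non-standard letters count as gaps. With `weights`, each row
#' contributes its weight instead of 1.
#'
#' @param alignment a `varmod_alignment`.
#' @param position 1-based position in the degapped query.
#' @param weights optional per-row weights (default: unweighted).
#' @return List with `freqs` (named 20-vector summing to 1 unless the column
#'   is all gaps), `gap_fraction`, `position`.
#' @export
column_profile <- function(alignment, position, weights = NULL) {
  cols <- query_columns(alignment)
  if (position < 1L || position > length(cols)) {
    stop(sprintf("position %d outside degapped query length %d",
                 position, length(cols)), call. = FALSE)
  }
  col <- substr(alignment$rows, cols[position], cols[position])
  col <- toupper(col)
  if (is.null(weights)) weights <- rep(1, length(col))
  stopifnot(length(weights) == length(col), all(weights >= 0))
  is_aa <- col %in% AA_ALPHABET
  w_total <- sum(weights)
  counts <- stats::setNames(numeric(20), AA_ALPHABET)
  if (any(is_aa)) {
    tab <- tapply(weights[is_aa], col[is_aa], sum)
    counts[names(tab)] <- tab
  }
  gap_fraction <- if (w_total > 0) 1 - sum(counts) / w_total else 1
  freqs <- if (sum(counts) > 0) counts / sum(counts) else counts
  list(freqs = freqs, gap_fraction = gap_fraction, position = position)
}

# Kullback-Leibler divergence in bits with the 0 log 0 = 0 convention.
.kl_bits <- function(p, q) {
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / q[nz]))
}

#' Jensen-Shannon divergence conservation score of a column profile
#'
#' Computes `(1 - gap_fraction) * JSD(p, q)` where
#' `JSD(p, q) = KL(p||m)/2 + KL(q||m)/2`, `m = (p + q)/2`, with base-2
#' logarithms (so JSD is bounded by 1), and clamps to `[0, 1]`. An all-gap
#' column scores 0 and is flagged `no_data`.
#'
#' @param profile output of [column_profile()].
#' @param background strictly positive 20-vector summing to 1
#'   (default BLOSUM62 frequencies).
#' @return List with `position`, `score`, `no_data`.
#' @export
jsd_score <- function(profile, background = aa_background()) {
  stopifnot(length(background) == 20L, all(background > 0),
            abs(sum(background) - 1) < 1e-9)
  if (profile$gap_fraction >= 1) {
    return(list(position = profile$position, score = 0, no_data = TRUE))
  }
  p <- profile$freqs
  q <- as.numeric(background[AA_ALPHABET])
  m <- (p + q) / 2
  jsd <- 0.5 * .kl_bits(p, m) + 0.5 * .kl_bits(q, m)
  score <- (1 - profile$gap_fraction) * jsd
  list(position = profile$position,
       score = min(max(score, 0), 1), no_data = FALSE)
}

#' Conservation track over the full query
#'
#' One JSD conservation score per degapped query position.
#'
#' @param alignment a `varmod_alignment`.
#' @param background see [jsd_score()].
#' @param window optional odd window size; when given, each score is replaced
#'   by the mean over the window (truncated at the ends). Default: no
#'   windowing.
#' @param weights optional per-row sequence weights.
#' @return data.frame with columns `position`, `residue`, `score`, `no_data`.
#' @export
conservation_track <- function(alignment, background = aa_background(),
                               window = NULL, weights = NULL) {
  qs <- strsplit(alignment$query_seq, "")[[1]]
  n <- length(qs)
  scores <- vapply(seq_len(n), function(i) {
    jsd_score(column_profile(alignment, i, weights = weights), background)$score
  }, 0)
  no_data <- vapply(seq_len(n), function(i) {
    column_profile(alignment, i, weights = weights)$gap_fraction >= 1
  }, TRUE)
  if (!is.null(window)) {
    stopifnot(window %% 2 == 1, window >= 1)
    h <- (window - 1) / 2
    scores <- vapply(seq_len(n), function(i) {
      mean(scores[max(1, i - h):min(n, i + h)])
    }, 0)
  }
  data.frame(position = seq_len(n), residue = qs, score = scores,
             no_data = no_data, stringsAsFactors = FALSE)
}

#' Write a conservation track to TSV
#'
#' @param track output of [conservation_track()].
#' @param path output path.
#' @export
write_conservation <- function(track, path) {
  utils::write.table(track[, c("position", "residue", "score")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
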