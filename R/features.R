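# The fixed-order feature vector: four sequence features followed by the
# structural block. The schema is versioned; models refuse to score feature
# vectors from another schema version.

#' Feature schema
#'
#' Names, in order, of the numeric feature vector encoding one variant, plus
#' the schema version used to guard model/feature compatibility.
#'
#' @return List with `version` (character) and `names` (character vector,
#'   length 23).
#' @export
feature_schema <- function() {
  list(version = "1",
       names = c("jsd_conservation", "mass_ratio", "charge_change",
                 "functional_group_change",
                 "ligand_distance", "binding_extra_a", "binding_extra_b",
                 "interface_distance",
                 paste0("ss8_", .SS8_LEVELS),
                 paste0("ss3_", .SS3_LEVELS),
                 "relative_sasa", "structure_missing",
                 "ligand_site_missing", "interface_site_missing"))
}

#' Assemble the feature vector of one variant
#'
#' Concatenates the conservation score at the variant position, the three
#' sequence-change features, and the structural block, in schema order.
#' Sequence features are mandatory; a missing conservation value is an error.
#'
#' @param variant a `varmod_variant`.
#' @param conservation output of [conservation_track()].
#' @param tables output of [aa_tables()].
#' @param structural named vector from [structural_feature_block()] (built
#'   with sentinel values when no structure is available).
#' @return Named numeric vector in [feature_schema()] order.
#' @export
assemble_features <- function(variant, conservation, tables = aa_tables(),
                              structural = NULL) {
  row <- conservation$score[conservation$position == variant$pos]
  if (length(row) != 1L || !is.finite(row)) {
    stop(sprintf("no conservation score at variant position %d", variant$pos),
         call. = FALSE)
  }
  if (is.null(structural)) {
    structural <- structural_feature_block(NULL, list(), variant$pos)
  }
  sq <- sequence_change_features(variant, tables)
  x <- c(jsd_conservation = row, sq, structural)
  schema <- feature_schema()
  x <- x[schema$names]
  names(x) <- schema$names
  stopifnot(all(is.finite(x)))
  x
}

#' Feature matrix for a labelled variant table
#'
#' Runs the full feature-extraction stack over every variant of every
#' protein: conservation from the protein's alignment, sequence-change
#' features, and structural features when a structure is supplied.
#' Per-protein secondary structure and SASA are computed once and reused.
#'
#' @param labelled data.frame with columns `protein_id`, `wt`, `pos`, `mut`
#'   (and optionally `label`).
#' @param msas named list of `varmod_alignment`, one per protein id.
#' @param structures named list of `varmod_structure` (or `NULL` entries).
#' @param sites named list of lists of `varmod_site` per protein id.
#' @param tables output of [aa_tables()].
#' @param background conservation background distribution.
#' @return Numeric matrix, one row per variant, columns in schema order.
#' @export
feature_matrix <- function(labelled, msas, structures = list(),
                           sites = list(), tables = aa_tables(),
                           background = aa_background()) {
  schema <- feature_schema()
  X <- matrix(NA_real_, nrow(labelled), length(schema$names),
              dimnames = list(NULL, schema$names))
  for (pid in unique(labelled$protein_id)) {
    idx <- which(labelled$protein_id == pid)
    aln <- msas[[pid]]
    if (is.null(aln)) stop("no alignment for protein ", pid, call. = FALSE)
    track <- conservation_track(aln, background = background)
    struct <- structures[[pid]]
    p_sites <- if (is.null(sites[[pid]])) list() else sites[[pid]]
    pre <- NULL
    if (!is.null(struct)) {
      pre <- list(ss = assign_secondary_structure(struct),
                  sasa = sasa(struct))
    }
    for (i in idx) {
      v <- new_variant(labelled$wt[i], labelled$pos[i], labelled$mut[i])
      sb <- structural_feature_block(struct, p_sites, v$pos,
                                     precomputed = pre)
      X[i, ] <- assemble_features(v, track, tables, sb)
    }
  }
  X
}

#' Write a feature matrix (with identifiers) to TSV
#'
#' @param labelled the variant table the rows correspond to.
#' @param X feature matrix from [feature_matrix()].
#' @param path output path.
#' @export
write_feature_table <- function(labelled, X, path) {
  df <- cbind(labelled[, intersect(c("protein_id", "wt", "pos", "mut",
                                     "label"), names(labelled))],
              as.data.frame(X))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path TSV path.
#' @return List with `labelled` (identifier columns) and `X` (feature
#'   matrix in schema order).
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  schema <- feature_schema()
  nm <- make.names(schema$names)
  if (!all(nm %in% names(df))) {
    stop("feature table does not match the current feature schema",
         call. = FALSE)
  }
  X <- as.matrix(df[, nm])
  colnames(X) <- schema$names
  list(labelled = df[, setdiff(names(df), nm), drop = FALSE], X = X)
}
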