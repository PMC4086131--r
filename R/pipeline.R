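# End-to-end convenience wrappers tying the modules together: one call from
# files/objects to per-variant predictions.

#' Predict the effect of variants on one protein
#'
#' Runs the full feature stack for each validated variant — conservation at
#' the variant position, sequence-change features, structural block — and
#' scores it with a trained ensemble. Variants failing validation are
#' reported with `NA` probability and the failure reason; the run continues
#' for the others.
#'
#' @param model a `varmod_ensemble` (from [train_ensemble()] or
#'   [read_model()]).
#' @param msa a `varmod_alignment` of the query and its homologues.
#' @param variants list of `varmod_variant` or a token string like
#'   `"A45C,R12Q"`.
#' @param structure optional `varmod_structure`.
#' @param sites list of `varmod_site` annotations.
#' @param tables amino-acid tables, see [aa_tables()].
#' @param threshold probability threshold for the call.
#' @return data.frame: one row per variant with `token`, `valid`, `reason`,
#'   `probability`, `call`, per-member probabilities and all feature values.
#' @export
varmod_predict <- function(model, msa, variants, structure = NULL,
                           sites = list(), tables = aa_tables(),
                           threshold = 0.5) {
  if (is.character(variants)) variants <- parse_variant_list(variants)
  val <- validate_variants(variants, msa$query_seq)
  track <- conservation_track(msa)
  pre <- NULL
  if (!is.null(structure)) {
    pre <- list(ss = assign_secondary_structure(structure),
                sasa = sasa(structure))
  }
  ok <- which(val$valid)
  schema <- feature_schema()
  X <- matrix(NA_real_, length(ok), length(schema$names),
              dimnames = list(NULL, schema$names))
  for (r in seq_along(ok)) {
    v <- variants[[ok[r]]]
    sb <- structural_feature_block(structure, sites, v$pos,
                                   precomputed = pre)
    X[r, ] <- assemble_features(v, track, tables, sb)
  }
  out <- val
  out$probability <- rep(NA_real_, nrow(val))
  out$call <- rep(NA_character_, nrow(val))
  feat_df <- as.data.frame(matrix(NA_real_, nrow(val), length(schema$names),
                                  dimnames = list(NULL, schema$names)),
                           check.names = FALSE)
  member_cols <- paste0("member_", seq_along(model$members))
  for (mc in member_cols) out[[mc]] <- rep(NA_real_, nrow(val))
  if (length(ok) > 0L) {
    preds <- predict_ensemble(model, X, threshold = threshold)
    out$probability[ok] <- preds$probability
    out$call[ok] <- preds$call
    for (mc in member_cols) out[[mc]][ok] <- preds[[mc]]
    feat_df[ok, ] <- X
  }
  cbind(out, feat_df)
}

#' Train an ensemble from files
#'
#' Reads a labelled variant TSV plus per-protein alignments (and optional
#' structures/sites), extracts the feature matrix, and trains the five-fold
#' ensemble.
#'
#' @param labelled_path labelled-variant TSV, see [read_labelled_variants()].
#' @param msa_paths named character vector protein_id -> aligned FASTA path.
#' @param pdb_paths optional named vector protein_id -> PDB path.
#' @param site_paths optional named vector protein_id -> site TSV path.
#' @param seed,C_grid,j_grid passed to [train_ensemble()].
#' @return A `varmod_ensemble`.
#' @export
varmod_train <- function(labelled_path, msa_paths, pdb_paths = NULL,
                         site_paths = NULL, seed = 17L,
                         C_grid = c(0.01, 0.1, 1, 10, 100),
                         j_grid = c(0.5, 1, 2, 4)) {
  labelled <- read_labelled_variants(labelled_path)
  msas <- lapply(msa_paths, read_alignment)
  structures <- if (is.null(pdb_paths)) list() else
    lapply(pdb_paths, read_structure)
  sites <- if (is.null(site_paths)) list() else lapply(site_paths, read_sites)
  X <- feature_matrix(labelled, msas, structures, sites)
  train_ensemble(labelled, X, seed = seed, C_grid = C_grid, j_grid = j_grid)
}
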