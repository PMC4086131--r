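# Synthetic input generator. Everything the pipeline consumes — alignments,
# structures, site annotations, labelled variants — can be generated with
# controlled statistical structure, so every module and the end-to-end
# pipeline are testable without external data. The class signal is injected
# at the input-generating level (where variants sit relative to conserved
# columns and annotated sites, and how drastic the substitution is), never
# directly in feature space, so tests exercise the whole extraction stack.

# Ideal backbone internal coordinates (Angstrom / degrees, trans peptide).
.BB_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, omega = 180
)

#' Fixture generation parameters
#'
#' @param n_proteins number of synthetic proteins.
#' @param variants_per_protein labelled variants per protein.
#' @param effect_size delta >= 0 controlling class separation: informative
#'   placement happens with probability `1 - exp(-delta)`, so 0 makes the
#'   two classes exchangeable and ~3 gives a strong signal.
#' @param msa_depth rows per synthetic alignment (including the query).
#' @param protein_length residues per synthetic protein.
#' @param conserved_fraction fraction of columns made conserved.
#' @param fraction_with_structure fraction of proteins given a structure.
#' @param gap_rate per-cell gap probability in non-query alignment rows.
#' @param seed integer RNG seed.
#' @return List of validated parameters (class `varmod_fixture_spec`).
#' @export
fixture_spec <- function(n_proteins = 50L, variants_per_protein = 10L,
                         effect_size = 3, msa_depth = 50L,
                         protein_length = 100L, conserved_fraction = 0.3,
                         fraction_with_structure = 0.8, gap_rate = 0.02,
                         seed = 17L) {
  stopifnot(n_proteins >= 1L, variants_per_protein >= 1L, effect_size >= 0,
            msa_depth >= 1L, protein_length >= 10L,
            conserved_fraction >= 0, conserved_fraction <= 1,
            fraction_with_structure >= 0, fraction_with_structure <= 1,
            gap_rate >= 0, gap_rate < 1)
  structure(as.list(environment()), class = "varmod_fixture_spec")
}

.AA1TO3 <- stats::setNames(names(.AA3TO1), unname(.AA3TO1))

#' Generate a synthetic multiple sequence alignment
#'
#' Row 1 is the query. In conserved columns every row carries the query
#' letter with probability 0.95 (background draw otherwise); other columns
#' are background draws. Non-query rows are gapped at `gap_rate`.
#'
#' @param length number of columns.
#' @param depth number of rows including the query.
#' @param conserved_positions integer positions made conserved.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @param query optional query sequence string (default: background draw).
#' @param gap_rate per-cell gap probability for non-query rows.
#' @return A `varmod_alignment` with ids `query`, `hom_2`, ...
#' @export
make_msa <- function(length, depth, conserved_positions = integer(),
                     seed = NULL, query = NULL, gap_rate = 0) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(conserved_positions >= 1L),
            all(conserved_positions <= length))
  bg <- aa_background()
  qs <- if (is.null(query)) {
    sample(AA_ALPHABET, length, replace = TRUE, prob = bg)
  } else {
    strsplit(toupper(query), "")[[1]]
  }
  stopifnot(length(qs) == length)
  rows <- matrix("", nrow = depth, ncol = length)
  rows[1, ] <- qs
  if (depth > 1L) {
    conserved <- seq_len(length) %in% conserved_positions
    for (r in 2:depth) {
      draw <- sample(AA_ALPHABET, length, replace = TRUE, prob = bg)
      keep <- conserved & stats::runif(length) < 0.95
      draw[keep] <- qs[keep]
      if (gap_rate > 0) {
        draw[stats::runif(length) < gap_rate] <- "-"
      }
      rows[r, ] <- draw
    }
  }
  new_alignment(ids = c("query", if (depth > 1L) paste0("hom_", 2:depth)),
                rows = apply(rows, 1, paste, collapse = ""))
}

# Build a backbone chain from per-residue (phi, psi) dihedrals with ideal
# bond geometry; returns a list of per-residue N/CA/C/O coordinate rows.
.build_backbone <- function(phi, psi) {
  g <- .BB_GEOM
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 2L)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$n_ca, 0, 0)
  th <- (180 - g$ang_n_ca_c) * pi / 180
  C[1, ] <- CA[1, ] + g$ca_c * c(cos(th), sin(th), 0)
  for (i in 2:n) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         g$c_n, g$ang_ca_c_n, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          g$n_ca, g$ang_c_n_ca, g$omega)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         g$ca_c, g$ang_n_ca_c, phi[i])
  }
  for (i in seq_len(n)) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         g$c_o, g$ang_ca_c_o, psi[i] + 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

.backbone_to_structure <- function(bb, seq_pos, res_names, chain = "A") {
  n <- length(seq_pos)
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(seq_pos = seq_pos[i], res_name = res_names[i],
               atom_name = c("N", "CA", "C", "O"),
               element = c("N", "C", "C", "O"),
               x = c(bb$N[i, 1], bb$CA[i, 1], bb$C[i, 1], bb$O[i, 1]),
               y = c(bb$N[i, 2], bb$CA[i, 2], bb$C[i, 2], bb$O[i, 2]),
               z = c(bb$N[i, 3], bb$CA[i, 3], bb$C[i, 3], bb$O[i, 3]),
               het = FALSE, stringsAsFactors = FALSE)
  }))
  new_structure(atoms, chain = chain)
}

#' Build an ideal helix structure
#'
#' Poly-backbone chain (N, CA, C, O per residue) from ideal bond geometry at
#' the given dihedrals; the defaults are the ideal alpha-helix.
#'
#' @param n_residues chain length (>= 6).
#' @param phi,psi backbone dihedrals in degrees.
#' @param sequence optional one-letter sequence for residue names
#'   (default poly-alanine).
#' @return A `varmod_structure`.
#' @export
make_helix <- function(n_residues, phi = -57, psi = -47, sequence = NULL) {
  stopifnot(n_residues >= 6L)
  res_names <- if (is.null(sequence)) {
    rep("ALA", n_residues)
  } else {
    unname(.AA1TO3[strsplit(toupper(sequence), "")[[1]]])
  }
  stopifnot(length(res_names) == n_residues, !anyNA(res_names))
  bb <- .build_backbone(rep(phi, n_residues), rep(psi, n_residues))
  .backbone_to_structure(bb, seq_len(n_residues), res_names)
}

#' Build an idealised antiparallel strand pair
#'
#' Two extended strands (phi = -139, psi = 135) of `n_per_strand` residues.
#' The second strand is flipped to run antiparallel and its rigid-body
#' placement is refined so the canonical narrow inter-strand
#' N-H...O=C pairs reach hydrogen-bonding geometry. The strands are given
#' non-contiguous residue numbers so they are treated as separate chain
#' segments.
#'
#' @param n_per_strand residues per strand (>= 4).
#' @return A `varmod_structure` with residues `1..n` and
#'   `n+3 .. 2n+2`.
#' @export
make_strand_pair <- function(n_per_strand = 6L) {
  stopifnot(n_per_strand >= 4L)
  n <- n_per_strand
  bb <- .build_backbone(rep(-139, n), rep(135, n))
  s1 <- .backbone_to_structure(bb, seq_len(n), rep("ALA", n))
  # start from a 180-degree flip about z (reverses the strand direction),
  # shifted to overlap in x and offset 4.8 A in y; then refine placement
  x_span <- max(s1$atoms$x) + min(s1$atoms$x)
  base <- transform_structure(s1, rotation_matrix(c(0, 0, 1), pi),
                              c(x_span, 4.8, 0))
  # pair residue i of strand 1 with residue n + 1 - i of strand 2;
  # narrow (mutually H-bonded) pairs at every other residue
  pairs <- cbind(seq(2, n - 1, by = 2), n + 1 - seq(2, n - 1, by = 2))
  target <- function(par) {
    rot <- rotation_matrix(c(0, 0, 1), par[4]) %*%
      rotation_matrix(c(0, 1, 0), par[5]) %*%
      rotation_matrix(c(1, 0, 0), par[6])
    s2 <- transform_structure(base, rot, par[1:3])
    err <- 0
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; m <- pairs[r, 2]
      O1 <- residue_xyz(s1, i, "O")[1, ]
      N1 <- residue_xyz(s1, i, "N")[1, ]
      O2 <- residue_xyz(s2, m, "O")[1, ]
      N2 <- residue_xyz(s2, m, "N")[1, ]
      err <- err + (vnorm(O1 - N2) - 2.9)^2 + (vnorm(O2 - N1) - 2.9)^2
    }
    err
  }
  opt <- stats::optim(c(0, 0, 0, 0, 0, 0), target, method = "BFGS",
                      control = list(maxit = 500L, reltol = 1e-12))
  rot <- rotation_matrix(c(0, 0, 1), opt$par[4]) %*%
    rotation_matrix(c(0, 1, 0), opt$par[5]) %*%
    rotation_matrix(c(1, 0, 0), opt$par[6])
  s2 <- transform_structure(base, rot, opt$par[1:3])
  s2$atoms$seq_pos <- s2$atoms$seq_pos + n + 2L  # separate chain segment
  atoms <- rbind(s1$atoms, s2$atoms)
  new_structure(atoms)
}

# Charge-flipping mutant letter for an informative pathogenic variant.
.drastic_mutant <- function(wt) {
  grp <- .AA_CHARGE_GROUP[[wt]]
  pool <- switch(grp,
                 positive = c("D", "E"),
                 negative = c("K", "R"),
                 neutral = c("K", "R", "D", "E"))
  sample(pool, 1L)
}

# Same-functional-group (conservative) mutant letter, if one exists.
.conservative_mutant <- function(wt) {
  grp <- .AA_FUNCTIONAL_GROUP[[wt]]
  pool <- setdiff(names(.AA_FUNCTIONAL_GROUP)[.AA_FUNCTIONAL_GROUP == grp],
                  wt)
  if (length(pool) == 0L) pool <- setdiff(AA_ALPHABET, wt)
  sample(pool, 1L)
}

#' Generate a fully synthetic labelled dataset
#'
#' Per protein: a query sequence, an alignment with a conserved subset of
#' columns, optionally an ideal-helix structure, and one ligand plus one
#' interface site annotation. Pathogenic-class variants are placed at
#' conserved or site positions with a charge-flipping substitution with
#' probability `1 - exp(-effect_size)`; neutral-class variants at
#' unconserved, off-site positions with a conservative substitution. With
#' `effect_size = 0` both classes draw from the identical uninformative
#' mechanism and are exchangeable.
#'
#' @param spec a [fixture_spec()].
#' @return List with `labelled` (data.frame `protein_id`, `wt`, `pos`,
#'   `mut`, `label`), `msas`, `structures`, `sites` (named lists keyed by
#'   protein id), and `spec`.
#' @export
make_labelled_dataset <- function(spec = fixture_spec()) {
  set.seed(spec$seed)
  p_eff <- 1 - exp(-spec$effect_size)
  L <- spec$protein_length
  msas <- list(); structures <- list(); sites <- list()
  rows <- list()
  for (k in seq_len(spec$n_proteins)) {
    pid <- sprintf("prot_%03d", k)
    conserved <- sort(sample.int(L, round(spec$conserved_fraction * L)))
    aln <- make_msa(L, spec$msa_depth, conserved, seed = NULL,
                    gap_rate = spec$gap_rate)
    qs <- strsplit(aln$query_seq, "")[[1]]
    has_structure <- stats::runif(1) < spec$fraction_with_structure
    struct <- NULL
    if (has_structure) {
      struct <- make_helix(L, sequence = aln$query_seq)
    }
    lig_start <- sample.int(L - 3L, 1L)
    ifc_start <- sample.int(L - 3L, 1L)
    p_sites <- list(
      new_site("ligand", lig_start:(lig_start + 3L),
               confidence_a = stats::runif(1, 5, 25),
               confidence_b = stats::runif(1)),
      new_site("interface", ifc_start:(ifc_start + 3L),
               confidence_a = stats::runif(1, 5, 25),
               confidence_b = stats::runif(1))
    )
    site_pos <- sort(unique(unlist(lapply(p_sites, `[[`, "positions"))))
    hot <- sort(unique(c(conserved, site_pos)))
    cold <- setdiff(seq_len(L), hot)
    if (length(cold) == 0L) cold <- seq_len(L)
    for (v in seq_len(spec$variants_per_protein)) {
      label <- stats::rbinom(1L, 1L, 0.5)
      informative <- stats::runif(1) < p_eff
      if (informative && label == 1L) {
        pos <- hot[sample.int(length(hot), 1L)]
        mut <- .drastic_mutant(qs[pos])
      } else if (informative && label == 0L) {
        pos <- cold[sample.int(length(cold), 1L)]
        mut <- .conservative_mutant(qs[pos])
      } else {
        pos <- sample.int(L, 1L)
        mut <- sample(setdiff(AA_ALPHABET, qs[pos]), 1L)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = pid, wt = qs[pos], pos = pos, mut = mut,
        label = label, stringsAsFactors = FALSE)
    }
    msas[[pid]] <- aln
    structures[[pid]] <- struct
    sites[[pid]] <- p_sites
  }
  list(labelled = do.call(rbind, rows), msas = msas,
       structures = structures, sites = sites, spec = spec)
}

#' Write a synthetic dataset to standard files
#'
#' Writes, under `dir`: one aligned FASTA and one site TSV per protein, PDB
#' files for proteins with structures, and `labelled_variants.tsv`.
#'
#' @param dataset output of [make_labelled_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (pid in names(dataset$msas)) {
    write_alignment(dataset$msas[[pid]],
                    file.path(dir, paste0(pid, ".aln.fasta")))
    write_sites(dataset$sites[[pid]],
                file.path(dir, paste0(pid, ".sites.tsv")))
    if (!is.null(dataset$structures[[pid]])) {
      write_structure(dataset$structures[[pid]],
                      file.path(dir, paste0(pid, ".pdb")))
    }
  }
  write_labelled_variants(dataset$labelled,
                          file.path(dir, "labelled_variants.tsv"))
  invisible(dir)
}
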