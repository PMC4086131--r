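# Canonical in-memory data model and readers/writers for every external
# format the tool touches: variants, aligned FASTA, PDB structures, site
# annotation TSV, labelled-variant TSV.

.NONSTANDARD_AA <- c("B", "J", "O", "U", "X", "Z")

#' Parse a variant token such as "A45C"
#'
#' Tokens follow `<wt><pos><mut>`: wild-type one-letter code, 1-based sequence
#' position, mutant one-letter code. Letters are case-insensitive. Identity
#' substitutions (same letter twice) are accepted and flagged.
#'
#' @param token character scalar, e.g. `"A45C"`.
#' @return An object of class `varmod_variant`: list with `wt`, `pos`, `mut`,
#'   `identity` (logical).
#' @examples
#' parse_variant("A45C")
#' @export
parse_variant <- function(token) {
  stopifnot(is.character(token), length(token) == 1L)
  tok <- trimws(token)
  m <- regmatches(tok, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", tok))[[1]]
  if (length(m) != 4L) {
    stop(sprintf("malformed variant token '%s': expected <letter><digits><letter>",
                 token), call. = FALSE)
  }
  wt <- toupper(m[2]); mut <- toupper(m[4])
  for (aa in c(wt, mut)) {
    if (aa %in% .NONSTANDARD_AA) {
      stop(sprintf("non-standard amino acid letter '%s' in token '%s'",
                   aa, token), call. = FALSE)
    }
    if (!aa %in% AA_ALPHABET) {
      stop(sprintf("unknown amino acid letter '%s' in token '%s'", aa, token),
           call. = FALSE)
    }
  }
  pos <- suppressWarnings(as.integer(m[3]))
  if (is.na(pos) || pos < 1L) {
    stop(sprintf("variant position must be >= 1 in token '%s'", token),
         call. = FALSE)
  }
  new_variant(wt, pos, mut)
}

#' Construct a variant record
#'
#' @param wt,mut standard one-letter amino-acid codes.
#' @param pos 1-based position in the query sequence.
#' @export
new_variant <- function(wt, pos, mut) {
  structure(list(wt = wt, pos = as.integer(pos), mut = mut,
                 identity = identical(wt, mut)),
            class = "varmod_variant")
}

#' @export
format.varmod_variant <- function(x, ...) paste0(x$wt, x$pos, x$mut)

#' @export
print.varmod_variant <- function(x, ...) {
  cat("<variant ", format(x), if (x$identity) " (identity)", ">\n", sep = "")
  invisible(x)
}

#' Parse a comma/whitespace separated list of variant tokens
#'
#' @param text character scalar like `"A45C,R12Q"` or a character vector of
#'   tokens.
#' @return List of `varmod_variant`.
#' @export
parse_variant_list <- function(text) {
  toks <- unlist(strsplit(text, "[,;[:space:]]+"))
  toks <- toks[nzchar(toks)]
  lapply(toks, parse_variant)
}

#' Read an aligned FASTA multiple sequence alignment
#'
#' All rows must have equal length. The query row is the first record unless
#' `query_id` names another one; the degapped query row is the submitted
#' sequence all positions refer to.
#'
#' @param path path to an aligned FASTA file.
#' @param query_id optional record identifier of the query row.
#' @return An object of class `varmod_alignment`: list with `ids` (character),
#'   `rows` (character vector of aligned sequences, upper case),
#'   `query_index`, `query_seq` (degapped query).
#' @export
read_alignment <- function(path, query_id = NULL) {
  aln <- Biostrings::readBStringSet(path)
  if (length(aln) == 0L) stop("empty alignment file: ", path, call. = FALSE)
  new_alignment(ids = names(aln), rows = toupper(as.character(aln)),
                query_id = query_id)
}

#' Construct an alignment object from id/row vectors
#'
#' @param ids character vector of record identifiers.
#' @param rows character vector of aligned sequences (same length each).
#' @param query_id optional identifier of the query row (default: first row).
#' @export
new_alignment <- function(ids, rows, query_id = NULL) {
  stopifnot(length(ids) == length(rows), length(ids) >= 1L)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop(sprintf("ragged alignment: row lengths %s",
                 paste(unique(widths), collapse = ", ")), call. = FALSE)
  }
  ids <- vapply(strsplit(ids, "[[:space:]]+"), `[[`, "", 1L)
  qi <- 1L
  if (!is.null(query_id)) {
    qi <- match(query_id, ids)
    if (is.na(qi)) stop("query id '", query_id, "' not found in alignment",
                        call. = FALSE)
  }
  rows <- unname(toupper(rows))
  query_seq <- gsub("[-.]", "", rows[qi])
  structure(list(ids = ids, rows = rows, query_index = qi,
                 query_seq = query_seq, width = widths[1]),
            class = "varmod_alignment")
}

#' @export
print.varmod_alignment <- function(x, ...) {
  cat(sprintf("<alignment: %d rows x %d cols, query '%s' (%d aa)>\n",
              length(x$rows), x$width, x$ids[x$query_index],
              nchar(x$query_seq)))
  invisible(x)
}

#' Write an alignment back to aligned FASTA
#'
#' @param alignment a `varmod_alignment`.
#' @param path output path.
#' @export
write_alignment <- function(alignment, path) {
  x <- Biostrings::BStringSet(alignment$rows)
  names(x) <- alignment$ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# Map each degapped query position to its alignment column.
query_columns <- function(alignment) {
  q <- strsplit(alignment$rows[alignment$query_index], "")[[1]]
  which(!q %in% c("-", "."))
}

#' Read a protein structure from PDB-format text
#'
#' Parses ATOM records of one chain. Alternate locations are resolved by
#' highest occupancy, then first seen. HETATM records are skipped unless
#' `keep_hetatm_names` lists residue names to retain (e.g. ligands used for
#' site distances). By default PDB residue numbers are taken to be 1-based
#' query positions; supply `residue_map` (named vector pdb_number -> query
#' position) to override.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier; default the first chain seen.
#' @param keep_hetatm_names character vector of HETATM residue names to keep.
#' @param residue_map optional named integer vector mapping PDB residue
#'   numbers (names) to query positions (values).
#' @return An object of class `varmod_structure`: list with `atoms` (data.frame
#'   with columns `seq_pos`, `res_name`, `atom_name`, `element`, `x`, `y`, `z`,
#'   `het`), `chain`, and `residues` (data.frame `seq_pos`, `res_name`,
#'   `has_backbone`, `has_ca`).
#' @export
read_structure <- function(path, chain = NULL, keep_hetatm_names = character(),
                           residue_map = NULL) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- rec == "ATOM  " | (rec == "HETATM" &
            trimws(substr(lines, 18, 20)) %in% keep_hetatm_names)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no ATOM records in ", path, call. = FALSE)
  df <- data.frame(
    het = substr(lines, 1, 6) == "HETATM",
    atom_name = trimws(substr(lines, 13, 16)),
    altloc = substr(lines, 17, 17),
    res_name = trimws(substr(lines, 18, 20)),
    chain = substr(lines, 22, 22),
    res_num = as.integer(trimws(substr(lines, 23, 26))),
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)),
    occ = suppressWarnings(as.numeric(substr(lines, 55, 60))),
    element = trimws(substr(lines, 77, 78)),
    stringsAsFactors = FALSE
  )
  df$occ[is.na(df$occ)] <- 1
  if (is.null(chain)) chain <- df$chain[1]
  df <- df[df$chain == chain, , drop = FALSE]
  if (nrow(df) == 0L) stop("chain '", chain, "' not present in ", path,
                           call. = FALSE)
  # element fallback from atom name when columns 77-78 are blank
  blank <- !nzchar(df$element)
  df$element[blank] <- substr(gsub("[0-9]", "", df$atom_name[blank]), 1, 1)
  df$element <- toupper(df$element)
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    stop("non-finite coordinates in ", path, call. = FALSE)
  }
  # altloc resolution: highest occupancy then first seen, per residue+atom
  key <- paste(df$res_num, df$atom_name, sep = "|")
  ord <- order(match(key, unique(key)), -df$occ,
               seq_len(nrow(df)))
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(paste(df$res_num, df$atom_name, sep = "|")), ,
           drop = FALSE]
  df <- df[order(df$res_num), , drop = FALSE]
  seq_pos <- df$res_num
  if (!is.null(residue_map)) {
    mapped <- residue_map[as.character(df$res_num)]
    if (anyNA(mapped)) {
      stop("residue_map does not cover all PDB residue numbers",
           call. = FALSE)
    }
    seq_pos <- as.integer(mapped)
  }
  df$seq_pos <- seq_pos
  new_structure(df[, c("seq_pos", "res_name", "atom_name", "element",
                       "x", "y", "z", "het")], chain = chain)
}

#' Construct a structure object from an atom table
#'
#' @param atoms data.frame with columns `seq_pos`, `res_name`, `atom_name`,
#'   `element`, `x`, `y`, `z` and optionally `het`.
#' @param chain chain identifier.
#' @export
new_structure <- function(atoms, chain = "A") {
  if (is.null(atoms$het)) atoms$het <- FALSE
  atoms <- atoms[order(atoms$seq_pos), , drop = FALSE]
  rownames(atoms) <- NULL
  prot <- atoms[!atoms$het, , drop = FALSE]
  pos <- unique(prot$seq_pos)
  has_atom <- function(p, nm) nm %in% prot$atom_name[prot$seq_pos == p]
  residues <- data.frame(
    seq_pos = pos,
    res_name = vapply(pos, function(p) prot$res_name[prot$seq_pos == p][1], ""),
    has_ca = vapply(pos, has_atom, TRUE, nm = "CA"),
    has_backbone = vapply(pos, function(p) {
      all(c("N", "CA", "C", "O") %in% prot$atom_name[prot$seq_pos == p])
    }, TRUE),
    stringsAsFactors = FALSE
  )
  structure(list(atoms = atoms, residues = residues, chain = chain),
            class = "varmod_structure")
}

#' @export
print.varmod_structure <- function(x, ...) {
  cat(sprintf("<structure: chain %s, %d residues, %d atoms>\n",
              x$chain, nrow(x$residues), nrow(x$atoms)))
  invisible(x)
}

#' Write a structure to PDB format
#'
#' Minimal ATOM-record writer used by the fixture generator.
#'
#' @param structure a `varmod_structure`.
#' @param path output path.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  lines <- sprintf(
    "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(a$het, "HETATM", "ATOM"), seq_len(nrow(a)),
    ifelse(nchar(a$atom_name) < 4, paste0(" ", a$atom_name), a$atom_name),
    " ", a$res_name, structure$chain, a$seq_pos, " ",
    a$x, a$y, a$z, 1, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Validate variants against the query sequence
#'
#' Checks, per variant, that the position lies within the query and that the
#' wild-type letter matches the query residue there. Failures become error
#' records; the run continues for the remaining variants.
#'
#' @param variants list of `varmod_variant`.
#' @param query_sequence character scalar (degapped query).
#' @return data.frame with columns `token`, `wt`, `pos`, `mut`, `valid`,
#'   `reason`.
#' @export
validate_variants <- function(variants, query_sequence) {
  stopifnot(nchar(query_sequence) > 0L)
  if (length(variants) == 0L) {
    return(data.frame(token = character(), wt = character(),
                      pos = integer(), mut = character(),
                      valid = logical(), reason = character(),
                      stringsAsFactors = FALSE))
  }
  qs <- strsplit(toupper(query_sequence), "")[[1]]
  res <- lapply(variants, function(v) {
    reason <- NA_character_
    valid <- TRUE
    if (v$pos > length(qs)) {
      valid <- FALSE
      reason <- sprintf("position %d beyond query length %d", v$pos,
                        length(qs))
    } else if (qs[v$pos] != v$wt) {
      valid <- FALSE
      reason <- sprintf("wild-type mismatch at %d: variant says %s, query has %s",
                        v$pos, v$wt, qs[v$pos])
    }
    data.frame(token = format(v), wt = v$wt, pos = v$pos, mut = v$mut,
               valid = valid, reason = reason, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Read site annotations from TSV
#'
#' Expected columns: `site_type` (`ligand`/`interface`), `positions`
#' (comma-separated 1-based query positions), `confidence_a`, `confidence_b`.
#'
#' @param path path to the TSV file.
#' @return List of site annotations, each a list with `site_type`,
#'   `positions` (integer vector), `confidence_a`, `confidence_b`.
#' @export
read_sites <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("site_type", "positions", "confidence_a", "confidence_b")
  if (!all(need %in% names(df))) {
    stop("site annotation TSV must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    new_site(df$site_type[i],
             as.integer(strsplit(df$positions[i], ",")[[1]]),
             df$confidence_a[i], df$confidence_b[i])
  })
}

#' Construct a site annotation
#'
#' @param site_type `"ligand"` or `"interface"`.
#' @param positions integer vector of 1-based query positions (non-empty).
#' @param confidence_a,confidence_b non-negative site confidence values.
#' @export
new_site <- function(site_type, positions, confidence_a = 0,
                     confidence_b = 0) {
  site_type <- match.arg(site_type, c("ligand", "interface"))
  positions <- as.integer(positions)
  stopifnot(length(positions) >= 1L, all(positions >= 1L),
            confidence_a >= 0, confidence_b >= 0)
  structure(list(site_type = site_type, positions = sort(unique(positions)),
                 confidence_a = confidence_a, confidence_b = confidence_b),
            class = "varmod_site")
}

#' Write site annotations to TSV
#'
#' @param sites list of `varmod_site`.
#' @param path output path.
#' @export
write_sites <- function(sites, path) {
  df <- data.frame(
    site_type = vapply(sites, `[[`, "", "site_type"),
    positions = vapply(sites, function(s) paste(s$positions, collapse = ","),
                       ""),
    confidence_a = vapply(sites, `[[`, 0, "confidence_a"),
    confidence_b = vapply(sites, `[[`, 0, "confidence_b"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labelled variant table from TSV
#'
#' Expected columns: `protein_id`, `variant` (token form) and `label`
#' (1 = functional/pathogenic, 0 = non-functional/neutral).
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `protein_id`, `wt`, `pos`, `mut`, `label`.
#' @export
read_labelled_variants <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "variant", "label")
  if (!all(need %in% names(df))) {
    stop("labelled variant TSV must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!all(df$label %in% c(0L, 1L))) {
    stop("labels must be binary 0/1", call. = FALSE)
  }
  vs <- lapply(df$variant, parse_variant)
  data.frame(protein_id = df$protein_id,
             wt = vapply(vs, `[[`, "", "wt"),
             pos = vapply(vs, `[[`, 1L, "pos"),
             mut = vapply(vs, `[[`, "", "mut"),
             label = as.integer(df$label),
             stringsAsFactors = FALSE)
}

#' Write a labelled variant table to TSV
#'
#' @param labelled data.frame with columns `protein_id`, `wt`, `pos`, `mut`,
#'   `label`.
#' @param path output path.
#' @export
write_labelled_variants <- function(labelled, path) {
  df <- data.frame(protein_id = labelled$protein_id,
                   variant = paste0(labelled$wt, labelled$pos, labelled$mut),
                   label = labelled$label, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
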