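# Built-in amino-acid property tables. All tables are keyed by the 20
# standard one-letter codes and are overridable through `aa_tables()`.

#' The 20 standard amino-acid one-letter codes
#'
#' Alphabetical order; this ordering fixes the layout of column profiles and
#' background distributions throughout the package.
#' @export
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Average residue (peptide-bonded) masses in Da. Residue masses, not free
# amino-acid masses: the in-chain convention (free mass minus one water).
.AA_MASS <- c(
  A =  71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G =  57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P =  97.1167, Q = 128.1307, R = 156.1875,
  S =  87.0782, T = 101.1051, V =  99.1326, W = 186.2132, Y = 163.1760
)

# Side-chain charge at physiological pH. Histidine is counted as positive
# (titratable; grouped with K/R as in standard charge partitions).
.AA_CHARGE_GROUP <- c(
  A = "neutral", C = "neutral", D = "negative", E = "negative",
  F = "neutral", G = "neutral", H = "positive", I = "neutral",
  K = "positive", L = "neutral", M = "neutral", N = "neutral",
  P = "neutral", Q = "neutral", R = "positive", S = "neutral",
  T = "neutral", V = "neutral", W = "neutral", Y = "neutral"
)

# Side-chain chemical functional groups (stand-in partition; the published
# grouping can be dropped in through aa_tables(functional_group = ...)).
.AA_FUNCTIONAL_GROUP <- c(
  A = "aliphatic", V = "aliphatic", L = "aliphatic", I = "aliphatic",
  G = "aliphatic", P = "aliphatic",
  F = "aromatic", W = "aromatic", Y = "aromatic",
  S = "hydroxyl", T = "hydroxyl",
  C = "sulfur", M = "sulfur",
  N = "amide", Q = "amide",
  D = "acidic", E = "acidic",
  K = "basic", R = "basic", H = "basic"
)

# BLOSUM62 background amino-acid frequencies (normalised at load).
.BLOSUM62_BG <- c(
  A = 0.074, C = 0.025, D = 0.054, E = 0.054, F = 0.047,
  G = 0.074, H = 0.026, I = 0.068, K = 0.058, L = 0.099,
  M = 0.025, N = 0.045, P = 0.039, Q = 0.034, R = 0.052,
  S = 0.057, T = 0.051, V = 0.073, W = 0.013, Y = 0.032
)
.BLOSUM62_BG <- .BLOSUM62_BG / sum(.BLOSUM62_BG)

# Theoretical maximum accessible surface areas (Angstrom^2) per residue type,
# Tien et al. 2013 theoretical values; denominators for relative SASA.
.AA_MAX_SASA <- c(
  A = 129.0, C = 167.0, D = 193.0, E = 223.0, F = 240.0,
  G = 104.0, H = 224.0, I = 197.0, K = 236.0, L = 201.0,
  M = 224.0, N = 195.0, P = 159.0, Q = 225.0, R = 274.0,
  S = 155.0, T = 172.0, V = 174.0, W = 285.0, Y = 263.0
)

# Van der Waals radii (Angstrom) by element for SASA.
.ELEMENT_RADII <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  H = 1.20, SE = 1.90
)
.DEFAULT_RADIUS <- 1.70

# Three-to-one residue-name map for PDB parsing.
.AA3TO1 <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
  GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
  MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
  SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y"
)

.default_charge_change_matrix <- function() {
  groups <- c("negative", "neutral", "positive")
  m <- matrix(1, 3, 3, dimnames = list(groups, groups))
  diag(m) <- 0
  m["positive", "negative"] <- 2
  m["negative", "positive"] <- 2
  m
}

#' Amino-acid property tables
#'
#' Returns the bundled property tables used by the sequence-change features,
#' optionally overriding any of them. Overrides must cover all 20 standard
#' residues.
#'
#' @param mass named numeric vector of residue masses (Da).
#' @param charge_group named character vector mapping each residue to one of
#'   `"positive"`, `"negative"`, `"neutral"`.
#' @param functional_group named character vector of side-chain group labels.
#' @param charge_change_matrix square numeric matrix of charge-group change
#'   severities, with row/column names equal to the charge-group labels. The
#'   diagonal (no change) must hold the matrix minimum.
#' @return A list with elements `mass`, `charge_group`, `functional_group`,
#'   `charge_change_matrix`.
#' @examples
#' tabs <- aa_tables()
#' tabs$mass[["W"]] / tabs$mass[["G"]]
#' @export
aa_tables <- function(mass = NULL, charge_group = NULL,
                      functional_group = NULL, charge_change_matrix = NULL) {
  check_cover <- function(x, what) {
    missing <- setdiff(AA_ALPHABET, names(x))
    if (length(missing) > 0L) {
      stop(sprintf("%s table missing residues: %s", what,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    x[AA_ALPHABET]
  }
  mass <- check_cover(if (is.null(mass)) .AA_MASS else mass, "mass")
  if (any(!is.finite(mass)) || any(mass <= 0)) {
    stop("residue masses must be finite and positive", call. = FALSE)
  }
  cg <- check_cover(
    if (is.null(charge_group)) .AA_CHARGE_GROUP else charge_group,
    "charge_group")
  fg <- check_cover(
    if (is.null(functional_group)) .AA_FUNCTIONAL_GROUP else functional_group,
    "functional_group")
  ccm <- if (is.null(charge_change_matrix)) {
    .default_charge_change_matrix()
  } else {
    charge_change_matrix
  }
  if (!all(unique(cg) %in% rownames(ccm))) {
    stop("charge_change_matrix rows must cover all charge groups",
         call. = FALSE)
  }
  if (any(diag(ccm) != min(ccm))) {
    stop("charge_change_matrix diagonal must equal the matrix minimum",
         call. = FALSE)
  }
  list(mass = mass, charge_group = cg, functional_group = fg,
       charge_change_matrix = ccm)
}

#' Load amino-acid tables from a JSON config
#'
#' The JSON object may contain any of the keys accepted by [aa_tables()];
#' `charge_change_matrix` is given as a nested object
#' `{from: {to: value, ...}, ...}`.
#'
#' @param path path to a JSON file.
#' @return See [aa_tables()].
#' @export
read_aa_tables <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  ccm <- NULL
  if (!is.null(cfg$charge_change_matrix)) {
    ccm <- as.matrix(as.data.frame(cfg$charge_change_matrix))
    # read as columns 'from'; transpose so rows index the source group
    ccm <- t(ccm)
  }
  aa_tables(mass = unlist(cfg$mass),
            charge_group = unlist(cfg$charge_group),
            functional_group = unlist(cfg$functional_group),
            charge_change_matrix = ccm)
}

#' Background amino-acid distribution
#'
#' @param kind `"blosum62"` (default) for BLOSUM62 marginal frequencies or
#'   `"uniform"` for 1/20 each.
#' @return Named numeric 20-vector over [AA_ALPHABET], summing to 1.
#' @export
aa_background <- function(kind = c("blosum62", "uniform")) {
  kind <- match.arg(kind)
  if (kind == "uniform") {
    stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  } else {
    .BLOSUM62_BG[AA_ALPHABET]
  }
}
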