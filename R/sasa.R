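# Solvent-accessible surface area by the Shrake-Rupley sphere-sampling
# algorithm: deterministic quasi-uniform points on each atom's solvent
# sphere, a point counts as exposed when no other atom's solvent sphere
# covers it.

# Deterministic quasi-uniform points on the unit sphere (Fibonacci spiral).
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  y <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - y^2))
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (k - 0.5)
  cbind(x = r * cos(phi), y = y, z = r * sin(phi))
}

# Van der Waals radius per element symbol.
element_radius <- function(element) {
  r <- .ELEMENT_RADII[toupper(element)]
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("unknown element(s) ",
            paste(unique(toupper(element)[unknown]), collapse = ", "),
            "; using default radius ", .DEFAULT_RADIUS)
    r[unknown] <- .DEFAULT_RADIUS
  }
  unname(r)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Computes per-atom SASA over the protein heavy atoms: each atom's solvent
#' sphere of radius `r + probe` is sampled with `points` quasi-uniform
#' points; SASA = (exposed fraction) * 4 pi (r + probe)^2. Residue SASA is
#' the sum over the residue's atoms; relative SASA divides by the residue
#' type's theoretical maximum and clamps to [0, 1].
#'
#' @param structure a `varmod_structure`.
#' @param probe probe radius in Angstrom (water: 1.4).
#' @param points number of sphere sample points per atom.
#' @return List with `atoms` (data.frame `seq_pos`, `atom_name`, `area`) and
#'   `residues` (data.frame `seq_pos`, `res_name`, `absolute_sasa`,
#'   `relative_sasa`).
#' @export
sasa <- function(structure, probe = 1.4, points = 960L) {
  a <- structure$atoms
  sel <- !a$het & a$element != "H"
  a <- a[sel, , drop = FALSE]
  n <- nrow(a)
  if (n == 0L) stop("structure has no heavy atoms", call. = FALSE)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- element_radius(a$element) + probe
  sp <- sphere_points(points)
  area <- numeric(n)
  for (i in seq_len(n)) {
    # candidate occluders: solvent spheres that can intersect atom i's
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (rad + rad[i])^2 & seq_len(n) != i)
    if (length(nb) == 0L) {
      area[i] <- 4 * pi * rad[i]^2
      next
    }
    pts <- sweep(sp * rad[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, points)
    for (j in nb[order(d2[nb])]) {
      if (!any(exposed)) break
      dj <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      exposed <- exposed & dj >= rad[j]^2
    }
    area[i] <- mean(exposed) * 4 * pi * rad[i]^2
  }
  atoms_df <- data.frame(seq_pos = a$seq_pos, atom_name = a$atom_name,
                         area = area, stringsAsFactors = FALSE)
  res <- structure$residues
  abs_sasa <- vapply(res$seq_pos, function(p) sum(area[a$seq_pos == p]), 0)
  aa1 <- .AA3TO1[res$res_name]
  max_sasa <- .AA_MAX_SASA[aa1]
  rel <- ifelse(is.na(max_sasa), NA_real_,
                pmin(1, pmax(0, abs_sasa / max_sasa)))
  list(atoms = atoms_df,
       residues = data.frame(seq_pos = res$seq_pos, res_name = res$res_name,
                             absolute_sasa = abs_sasa, relative_sasa = rel,
                             stringsAsFactors = FALSE))
}
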