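# 3D vector helpers and internal-coordinate atom placement shared by the
# secondary-structure module and the fixture builders.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n == 0) stop("cannot normalise zero vector", call. = FALSE)
  a / n
}

#' Dihedral angle of four points
#'
#' @param p1,p2,p3,p4 numeric xyz triples.
#' @return Signed dihedral in degrees, in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  atan2(sum(vunit(b2) * vcross(n1, n2)), sum(n1 * n2)) * 180 / pi
}

#' Place an atom from internal coordinates
#'
#' Natural-extension (NeRF) placement: returns the point `d` at `bond`
#' Angstrom from `c`, with angle `b-c-d` equal to `angle` and dihedral
#' `a-b-c-d` equal to `torsion`.
#'
#' @param a,b,c numeric xyz triples of the three reference atoms.
#' @param bond bond length (Angstrom).
#' @param angle bond angle (degrees).
#' @param torsion dihedral angle (degrees).
#' @return Numeric xyz triple.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d_local <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

# Rotation matrix for a rotation of `theta` radians about unit axis `u`.
rotation_matrix <- function(u, theta) {
  u <- vunit(u)
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),       ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),       uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), 3, 3, byrow = TRUE)
}

#' Rigid-body transform of a structure
#'
#' Rotates all atom coordinates by `rotation` (3x3) then translates by
#' `translation`. Used in invariance tests and fixture assembly.
#'
#' @param structure a `varmod_structure`.
#' @param rotation 3x3 rotation matrix.
#' @param translation numeric xyz triple.
#' @return Transformed `varmod_structure`.
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

# xyz matrix of one residue's atoms (optionally by atom name), or NULL.
residue_xyz <- function(structure, pos, atom_name = NULL, heavy_only = TRUE) {
  a <- structure$atoms
  sel <- a$seq_pos == pos & !a$het
  if (heavy_only) sel <- sel & a$element != "H"
  if (!is.null(atom_name)) sel <- sel & a$atom_name == atom_name
  if (!any(sel)) return(NULL)
  unname(as.matrix(a[sel, c("x", "y", "z")]))
}
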