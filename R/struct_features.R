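# Structure-derived features of a variant: distance to ligand-binding and
# protein-protein interface sites, binding-site confidence pass-through,
# secondary-structure class and relative solvent accessibility.

#' Sentinel value for missing structural features
#'
#' Features that cannot be computed (no structure covering the variant, no
#' site annotation of the required type) take this value, and the matching
#' missingness indicator in the feature vector is set to 1.
#' @export
MISSING_SENTINEL <- -1

#' Distance from a variant residue to an annotated site
#'
#' Minimum Euclidean distance between any heavy atom of the variant residue
#' and any heavy atom of any site residue. A variant listed in the site has
#' distance 0 by definition.
#'
#' @param structure a `varmod_structure`.
#' @param variant_pos 1-based query position of the variant.
#' @param site a `varmod_site`.
#' @param ca_only if `TRUE`, use C-alpha atoms only.
#' @return List with `site_type`, `distance` (Angstrom; `NA` when missing),
#'   `in_site`, `missing`.
#' @export
site_distance <- function(structure, variant_pos, site, ca_only = FALSE) {
  res <- list(site_type = site$site_type, distance = NA_real_,
              in_site = FALSE, missing = FALSE)
  if (variant_pos %in% site$positions) {
    res$distance <- 0
    res$in_site <- TRUE
    return(res)
  }
  atom_sel <- if (ca_only) "CA" else NULL
  v_xyz <- residue_xyz(structure, variant_pos, atom_name = atom_sel)
  if (is.null(v_xyz)) {
    res$missing <- TRUE
    return(res)
  }
  s_xyz <- do.call(rbind, lapply(site$positions, residue_xyz,
                                 structure = structure,
                                 atom_name = atom_sel))
  if (is.null(s_xyz) || nrow(s_xyz) == 0L) {
    res$missing <- TRUE
    return(res)
  }
  # cross distances via the expanded-square identity, min over all pairs
  cross <- outer(rowSums(v_xyz^2), rowSums(s_xyz^2), "+") -
    2 * v_xyz %*% t(s_xyz)
  res$distance <- sqrt(max(0, min(cross)))
  res
}

#' Binding-site confidence pass-through features
#'
#' When the variant lies inside at least one ligand-binding site, returns
#' that site's two confidence values (the site with the highest
#' `confidence_a` when several apply); otherwise the features are not
#' applicable and take the missing sentinel.
#'
#' @param variant_pos 1-based query position.
#' @param sites list of `varmod_site` (non-ligand entries are ignored).
#' @return List with `confidence_a`, `confidence_b`, `applicable`.
#' @export
binding_site_extras <- function(variant_pos, sites) {
  lig <- Filter(function(s) s$site_type == "ligand" &&
                  variant_pos %in% s$positions, sites)
  if (length(lig) == 0L) {
    return(list(confidence_a = MISSING_SENTINEL,
                confidence_b = MISSING_SENTINEL, applicable = FALSE))
  }
  best <- lig[[which.max(vapply(lig, `[[`, 0, "confidence_a"))]]
  list(confidence_a = best$confidence_a, confidence_b = best$confidence_b,
       applicable = TRUE)
}

.SS8_LEVELS <- c("H", "G", "I", "E", "B", "T", "S", "-")
.SS3_LEVELS <- c("helix", "sheet", "coil")

#' Structural feature block for one variant position
#'
#' Assembles the structural part of the feature vector: ligand-site distance,
#' two binding-site confidences, interface-site distance, eight- and
#' three-state secondary-structure one-hots, relative SASA, plus missingness
#' indicators. When no structure covers the position all structural fields
#' take the sentinel and the structure-missing indicator is 1.
#'
#' @param structure a `varmod_structure` or `NULL`.
#' @param sites list of `varmod_site` (possibly empty).
#' @param variant_pos 1-based query position.
#' @param precomputed optional list with `ss` (from
#'   [assign_secondary_structure()]) and `sasa` (from [sasa()]) to avoid
#'   recomputation across variants of the same protein.
#' @param ca_only passed to [site_distance()].
#' @return Named numeric vector of length 17 (see [feature_schema()]).
#' @export
structural_feature_block <- function(structure, sites, variant_pos,
                                     precomputed = NULL, ca_only = FALSE) {
  ss8_hot <- stats::setNames(numeric(8), paste0("ss8_", .SS8_LEVELS))
  ss3_hot <- stats::setNames(numeric(3), paste0("ss3_", .SS3_LEVELS))
  out <- c(ligand_distance = MISSING_SENTINEL,
           binding_extra_a = MISSING_SENTINEL,
           binding_extra_b = MISSING_SENTINEL,
           interface_distance = MISSING_SENTINEL,
           ss8_hot, ss3_hot,
           relative_sasa = MISSING_SENTINEL,
           structure_missing = 1,
           ligand_site_missing = 1,
           interface_site_missing = 1)
  covered <- !is.null(structure) &&
    variant_pos %in% structure$residues$seq_pos
  if (covered) {
    out["structure_missing"] <- 0
    ss <- if (!is.null(precomputed$ss)) precomputed$ss else
      assign_secondary_structure(structure)
    row <- ss[ss$seq_pos == variant_pos, ]
    out[paste0("ss8_", row$ss8)] <- 1
    out[paste0("ss3_", row$ss3)] <- 1
    sas <- if (!is.null(precomputed$sasa)) precomputed$sasa else
      sasa(structure)
    rel <- sas$residues$relative_sasa[sas$residues$seq_pos == variant_pos]
    if (length(rel) == 1L && is.finite(rel)) out["relative_sasa"] <- rel
    for (ty in c("ligand", "interface")) {
      ty_sites <- Filter(function(s) s$site_type == ty, sites)
      if (length(ty_sites) == 0L) next
      ds <- lapply(ty_sites, site_distance, structure = structure,
                   variant_pos = variant_pos, ca_only = ca_only)
      ok <- !vapply(ds, `[[`, TRUE, "missing")
      if (!any(ok)) next
      dmin <- min(vapply(ds[ok], `[[`, 0, "distance"))
      key <- if (ty == "ligand") "ligand_distance" else "interface_distance"
      out[key] <- dmin
      out[paste0(ty, "_site_missing")] <- 0
    }
    extras <- binding_site_extras(variant_pos, sites)
    if (extras$applicable) {
      out["binding_extra_a"] <- extras$confidence_a
      out["binding_extra_b"] <- extras$confidence_b
    }
  }
  out
}

#' Per-residue structural summary table
#'
#' Secondary structure, SASA and minimum site distances for every residue of
#' the structure; suitable for TSV export.
#'
#' @param structure a `varmod_structure`.
#' @param sites list of `varmod_site`.
#' @return data.frame with one row per residue.
#' @export
residue_structure_table <- function(structure, sites = list()) {
  ss <- assign_secondary_structure(structure)
  sas <- sasa(structure)
  pos <- structure$residues$seq_pos
  min_dist <- function(ty) {
    vapply(pos, function(p) {
      ty_sites <- Filter(function(s) s$site_type == ty, sites)
      if (length(ty_sites) == 0L) return(NA_real_)
      ds <- vapply(ty_sites, function(s) {
        d <- site_distance(structure, p, s)
        if (d$missing) NA_real_ else d$distance
      }, 0)
      if (all(is.na(ds))) NA_real_ else min(ds, na.rm = TRUE)
    }, 0)
  }
  data.frame(
    position = pos,
    aa = unname(.AA3TO1[structure$residues$res_name]),
    ss8 = ss$ss8, ss3 = ss$ss3,
    absolute_sasa = sas$residues$absolute_sasa,
    relative_sasa = sas$residues$relative_sasa,
    ligand_distance = min_dist("ligand"),
    interface_distance = min_dist("interface"),
    stringsAsFactors = FALSE
  )
}
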