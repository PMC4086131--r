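# Secondary-structure assignment from backbone geometry following the
# Kabsch-Sander scheme: electrostatic hydrogen-bond model, n-turns, helices,
# bridges/ladders, turns and bends. Residues lacking a full N/CA/C/O
# backbone are left unassigned ('-').

# Hydrogen-bond energy constant: 0.084 e^2 partial charges * 332 conversion.
.HB_Q <- 0.084 * 332
.HB_CUTOFF <- -0.5       # kcal/mol; bond iff E < cutoff
.HB_MIN_DIST <- 0.5      # atoms closer than this -> clash energy
.HB_CLASH_E <- -9.9

#' Kabsch-Sander hydrogen-bond energy
#'
#' Electrostatic energy (kcal/mol) of a putative backbone hydrogen bond
#' between an acceptor C=O group and a donor N-H group:
#' `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)`.
#' A bond is assigned when `E < -0.5`.
#'
#' @param r_on,r_ch,r_oh,r_cn inter-atom distances in Angstrom (O/C of the
#'   acceptor carbonyl; N/H of the donor amide).
#' @return Energy in kcal/mol.
#' @export
hbond_energy <- function(r_on, r_ch, r_oh, r_cn) {
  if (min(r_on, r_ch, r_oh, r_cn) < .HB_MIN_DIST) return(.HB_CLASH_E)
  .HB_Q * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

# Backbone coordinate table: one row per residue with full backbone, in
# seq_pos order, with reconstructed amide H.
.backbone_table <- function(structure) {
  res <- structure$residues[structure$residues$has_backbone, , drop = FALSE]
  n <- nrow(res)
  get <- function(pos, nm) residue_xyz(structure, pos, nm)[1, ]
  N <- t(vapply(res$seq_pos, get, numeric(3), nm = "N"))
  CA <- t(vapply(res$seq_pos, get, numeric(3), nm = "CA"))
  C <- t(vapply(res$seq_pos, get, numeric(3), nm = "C"))
  O <- t(vapply(res$seq_pos, get, numeric(3), nm = "O"))
  # peptide bond present between consecutive rows?
  bonded <- rep(FALSE, n)
  if (n > 1L) {
    dCN <- sqrt(rowSums((C[-n, , drop = FALSE] - N[-1, , drop = FALSE])^2))
    bonded[-1] <- dCN < 2.5
  }
  # amide H: 1.01 A from N, opposite the bisector of the previous C and O
  # directions (standard reconstruction for structures without hydrogens)
  H <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (i == 1L || !bonded[i] || res$res_name[i] == "PRO") next
    u <- vunit(vunit(N[i, ] - C[i - 1, ]) + vunit(N[i, ] - O[i - 1, ]))
    H[i, ] <- N[i, ] + 1.01 * u
  }
  list(seq_pos = res$seq_pos, res_name = res$res_name,
       N = N, CA = CA, C = C, O = O, H = H, bonded = bonded, n = n)
}

# Logical matrix HB[i, j]: C=O of residue i accepts an H-bond from N-H of j.
.hbond_matrix <- function(bb) {
  n <- bb$n
  HB <- matrix(FALSE, n, n)
  if (n < 3L) return(HB)
  ca_d2 <- as.matrix(stats::dist(bb$CA))^2
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) < 2L) next
      if (ca_d2[i, j] > 81) next          # CA-CA > 9 A: no bond possible
      if (is.na(bb$H[j, 1])) next          # donor has no amide H
      e <- hbond_energy(
        vnorm(bb$O[i, ] - bb$N[j, ]),
        vnorm(bb$C[i, ] - bb$H[j, ]),
        vnorm(bb$O[i, ] - bb$H[j, ]),
        vnorm(bb$C[i, ] - bb$N[j, ]))
      HB[i, j] <- e < .HB_CUTOFF
    }
  }
  HB
}

#' Assign secondary structure
#'
#' Eight-state assignment (H, G, I, E, B, T, S, '-') from backbone hydrogen
#' bonding: 4-turn pairs make alpha-helix (H), bridge ladders make strand (E)
#' with isolated bridges as B, 3-/5-turn pairs make 3-10 (G) and pi (I)
#' helix, remaining turns T, and bends (kappa > 70 degrees) S. Also returns
#' the three-state reduction helix/sheet/coil.
#'
#' @param structure a `varmod_structure`; residues used must carry backbone
#'   N, CA, C, O atoms (amide H is reconstructed geometrically).
#' @return data.frame with columns `seq_pos`, `ss8`, `ss3`. Residues missing
#'   backbone atoms get `ss8 = "-"`. Chains shorter than 3 assigned residues
#'   are all `"-"`.
#' @export
assign_secondary_structure <- function(structure) {
  all_pos <- structure$residues$seq_pos
  out <- data.frame(seq_pos = all_pos, ss8 = "-", ss3 = "coil",
                    stringsAsFactors = FALSE)
  bb <- .backbone_table(structure)
  n <- bb$n
  if (n >= 3L) {
    HB <- .hbond_matrix(bb)
    ss <- rep("-", n)
    # n-turns: CO(i) bonded to NH(i+k), only across unbroken chain
    turn_at <- function(k) {
      t <- rep(FALSE, n)
      for (i in seq_len(n - k)) {
        if (HB[i, i + k] && all(bb$bonded[(i + 1):(i + k)])) t[i] <- TRUE
      }
      t
    }
    t3 <- turn_at(3L); t4 <- turn_at(4L); t5 <- turn_at(5L)
    # alpha helix: consecutive 4-turns
    for (i in 2:max(2L, n - 4L)) {
      if (i + 3L <= n && t4[i - 1] && t4[i]) ss[i:(i + 3L)] <- "H"
    }
    # bridges
    btype <- matrix("", n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j - i < 3L) next
        para <- (i > 1L && i < n && HB[i - 1, j] && HB[j, i + 1]) ||
                (j > 1L && j < n && HB[j - 1, i] && HB[i, j + 1])
        anti <- (HB[i, j] && HB[j, i]) ||
                (i > 1L && j < n && i < n && j > 1L &&
                 HB[i - 1, j + 1] && HB[j - 1, i + 1])
        if (para) { btype[i, j] <- "P"; btype[j, i] <- "P" }
        if (anti) { btype[i, j] <- "A"; btype[j, i] <- "A" }
      }
    }
    has_bridge <- apply(btype, 1, function(r) any(nzchar(r)))
    # ladders: bridge residues adjacent to another bridge residue with
    # correspondingly adjacent partners extend to strand E
    strand <- rep(FALSE, n)
    for (i in seq_len(n)) {
      js <- which(nzchar(btype[i, ]))
      for (j in js) {
        ty <- btype[i, j]
        step <- if (ty == "P") 1L else -1L
        ext <- (i + 1L <= n && j + step >= 1L && j + step <= n &&
                  btype[i + 1L, j + step] == ty) ||
               (i - 1L >= 1L && j - step >= 1L && j - step <= n &&
                  btype[i - 1L, j - step] == ty)
        if (ext) strand[i] <- TRUE
      }
    }
    ss[ss == "-" & strand] <- "E"
    ss[ss == "-" & has_bridge] <- "B"
    # 3-10 helix
    if (n >= 5L) {
      for (i in 2:(n - 3L)) {
        if (t3[i - 1] && t3[i] && all(ss[i:(i + 2L)] %in% c("-", "T", "S"))) {
          ss[i:(i + 2L)] <- "G"
        }
      }
    }
    # pi helix
    if (n >= 7L) {
      for (i in 2:(n - 5L)) {
        if (t5[i - 1] && t5[i] && all(ss[i:(i + 4L)] %in% c("-", "T", "S"))) {
          ss[i:(i + 4L)] <- "I"
        }
      }
    }
    # hydrogen-bonded turns
    for (k in c(3L, 4L, 5L)) {
      tt <- list(`3` = t3, `4` = t4, `5` = t5)[[as.character(k)]]
      for (i in which(tt)) {
        idx <- (i + 1L):(i + k - 1L)
        ss[idx][ss[idx] == "-"] <- "T"
      }
    }
    # bends: kappa angle at CA(i) between (CA_i - CA_{i-2}) and
    # (CA_{i+2} - CA_i) greater than 70 degrees
    if (n >= 5L) {
      for (i in 3:(n - 2L)) {
        if (!all(bb$bonded[(i - 1L):(i + 2L)])) next
        u <- bb$CA[i, ] - bb$CA[i - 2L, ]
        v <- bb$CA[i + 2L, ] - bb$CA[i, ]
        kappa <- acos(pmin(1, pmax(-1, sum(u * v) / (vnorm(u) * vnorm(v)))))
        if (kappa * 180 / pi > 70 && ss[i] == "-") ss[i] <- "S"
      }
    }
    out$ss8[match(bb$seq_pos, all_pos)] <- ss
  }
  out$ss3 <- reduce_ss(out$ss8)
  out
}

#' Reduce eight-state secondary structure to three states
#'
#' `{H, G, I}` -> helix, `{E, B}` -> sheet, `{T, S, '-'}` -> coil.
#'
#' @param ss8 character vector of eight-state codes.
#' @return Character vector over `helix`, `sheet`, `coil`.
#' @export
reduce_ss <- function(ss8) {
  out <- rep("coil", length(ss8))
  out[ss8 %in% c("H", "G", "I")] <- "helix"
  out[ss8 %in% c("E", "B")] <- "sheet"
  out
}
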