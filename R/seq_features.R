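# Physicochemical change features of an amino-acid substitution. All three
# depend only on (wt, mut), never on position or structure.

#' Mass ratio of a substitution
#'
#' Ratio of the average residue mass of the mutant to the wild-type amino
#' acid (or the reverse with `direction = "wt_over_mut"`).
#'
#' @param variant a `varmod_variant`.
#' @param tables output of [aa_tables()].
#' @param direction `"mut_over_wt"` (default) or `"wt_over_mut"`.
#' @return Positive numeric scalar; 1 for identity substitutions.
#' @export
mass_ratio <- function(variant, tables = aa_tables(),
                       direction = c("mut_over_wt", "wt_over_mut")) {
  direction <- match.arg(direction)
  r <- tables$mass[[variant$mut]] / tables$mass[[variant$wt]]
  if (direction == "wt_over_mut") 1 / r else r
}

#' Charge-group change severity of a substitution
#'
#' Amino acids are partitioned into positive / negative / neutral charge
#' groups; the feature is the configured severity of moving from the
#' wild-type group to the mutant group. The default matrix scores 0 for no
#' group change, 1 for neutral<->charged, 2 for a sign flip.
#'
#' @param variant a `varmod_variant`.
#' @param tables output of [aa_tables()].
#' @return Non-negative numeric scalar.
#' @export
charge_change <- function(variant, tables = aa_tables()) {
  g_wt <- tables$charge_group[[variant$wt]]
  g_mut <- tables$charge_group[[variant$mut]]
  tables$charge_change_matrix[g_wt, g_mut]
}

#' Functional-group change of a substitution
#'
#' 0 when wild type and mutant share a side-chain chemical group, otherwise a
#' positive value from `group_change_table` (default: the 0/1 indicator).
#'
#' @param variant a `varmod_variant`.
#' @param tables output of [aa_tables()].
#' @param group_change_table optional square numeric matrix with functional
#'   group labels as dimnames; ignored diagonal (always 0).
#' @return Non-negative numeric scalar.
#' @export
functional_group_change <- function(variant, tables = aa_tables(),
                                    group_change_table = NULL) {
  g_wt <- tables$functional_group[[variant$wt]]
  g_mut <- tables$functional_group[[variant$mut]]
  if (identical(g_wt, g_mut)) return(0)
  if (is.null(group_change_table)) return(1)
  group_change_table[g_wt, g_mut]
}

#' All three sequence-change features of a substitution
#'
#' @inheritParams mass_ratio
#' @return Named numeric vector `mass_ratio`, `charge_change`,
#'   `functional_group_change`.
#' @export
sequence_change_features <- function(variant, tables = aa_tables()) {
  c(mass_ratio = mass_ratio(variant, tables),
    charge_change = unname(charge_change(variant, tables)),
    functional_group_change = functional_group_change(variant, tables))
}
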