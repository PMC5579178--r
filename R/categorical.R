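#' Lung-RADS v1.0 baseline categories
#'
#' Assigns the ACR Lung-RADS (version 1.0) assessment category to each
#' nodule using baseline information only: growth-based branches and the
#' subjective 4X upgrade are not applied.  Diameters are rounded to the
#' nearest whole millimetre (halves up) before any threshold test, per the
#' system's definition of size.
#'
#' Rules applied (baseline, after rounding):
#' \itemize{
#'   \item benign-pattern calcification (complete, central, popcorn,
#'     concentric rings) -> category 1;
#'   \item solid (including perifissural, scored by size like any solid
#'     nodule): `<6` -> 2, `6-7` -> 3, `8-14` -> 4A, `>=15` -> 4B;
#'   \item part-solid: solid component `>=8` -> 4B; total `>=6` with solid
#'     component `>=6` -> 4A; total `>=6` with solid component `<6` -> 3;
#'     total `<6` -> 2;
#'   \item pure ground-glass: `<20` -> 2, `>=20` -> 3.
#' }
#'
#' @param nodules a nodules data.frame or [nodule_cohort()].
#' @param defn size definition (default `"mean3d"`, the system's own
#'   "average diameter" from volumetric segmentation).
#' @return Character vector of labels in `{"1","2","3","4A","4B"}`.
#' @examples
#' n <- data.frame(nodule_id = "n1", participant_id = "p1", type = "solid",
#'                 is_pfn = FALSE, calcification = "none", spiculated = FALSE,
#'                 upper_lobe = FALSE, d_longest_axial = 9, d_perp_axial = 8,
#'                 d_mean3d = 8.4, volume = NA, d_longest_axial_solid = NA,
#'                 d_perp_axial_solid = NA, d_mean3d_solid = NA,
#'                 malignant = FALSE)
#' lung_rads_category(n)  # "4A"
#' @export
lung_rads_category <- function(nodules, defn = "mean3d") {
  if (inherits(nodules, "nodule_cohort")) nodules <- nodules$nodules
  defn <- match_size_definition(defn)
  if (nrow(nodules) == 0L) return(character(0))
  total <- round_half_up(nodule_size(nodules, defn, "whole"))
  ps <- nodules$type == "part_solid"
  solid_comp <- rep(NA_real_, nrow(nodules))
  if (any(ps)) {
    solid_comp[ps] <- round_half_up(
      nodule_size(nodules[ps, , drop = FALSE], defn, "solid"))
  }

  out <- character(nrow(nodules))
  for (i in seq_len(nrow(nodules))) {
    out[i] <- if (nodules$calcification[i] == "benign_pattern") {
      "1"
    } else if (nodules$type[i] == "ground_glass") {
      if (total[i] < 20) "2" else "3"
    } else if (ps[i]) {
      if (solid_comp[i] >= 8) "4B"
      else if (total[i] >= 6 && solid_comp[i] >= 6) "4A"
      else if (total[i] >= 6) "3"
      else "2"
    } else {  # solid, incl. perifissural
      if (total[i] < 6) "2"
      else if (total[i] < 8) "3"
      else if (total[i] < 15) "4A"
      else "4B"
    }
  }
  out
}

#' NCCN v1.2016 categories
#'
#' Assigns the NCCN (version 1.2016) screening nodule-management category
#' using baseline information only; growth branches and the
#' multiple-ground-glass-nodule rules are not applied.  No rounding is
#' performed.  Solid and part-solid nodules are categorized by their
#' *total* diameter: `<6` mm -> 1, `[6, 8]` mm -> 5, `>8` mm -> 6.  Pure
#' ground-glass nodules: `<=5` mm -> 2, `(5, 10]` mm -> 3, `>10` mm -> 4.
#' Benign-pattern calcified nodules are assigned category 1 (the
#' guideline states no calcification rule; this mirrors Lung-RADS
#' category 1 and the PanCan 0\% convention).  Perifissural nodules are
#' scored as solid nodules of their size.
#'
#' @param nodules a nodules data.frame or [nodule_cohort()].
#' @param defn size definition (default `"mean_axial"`, the guideline's
#'   mean of longest and perpendicular axial diameters).
#' @return Character vector of labels `"1"`..`"6"`.
#' @export
nccn_category <- function(nodules, defn = "mean_axial") {
  if (inherits(nodules, "nodule_cohort")) nodules <- nodules$nodules
  defn <- match_size_definition(defn)
  if (nrow(nodules) == 0L) return(character(0))
  total <- nodule_size(nodules, defn, "whole")

  out <- character(nrow(nodules))
  for (i in seq_len(nrow(nodules))) {
    out[i] <- if (nodules$calcification[i] == "benign_pattern") {
      "1"
    } else if (nodules$type[i] == "ground_glass") {
      if (total[i] <= 5) "2" else if (total[i] <= 10) "3" else "4"
    } else {  # solid or part-solid, by total diameter
      if (total[i] < 6) "1" else if (total[i] <= 8) "5" else "6"
    }
  }
  out
}

system_names <- function() c("pancan", "lung_rads", "nccn")

#' Default size definition of each scoring system
#'
#' The definitions under which each system was published: longest axial
#' diameter for PanCan, volumetric mean diameter for Lung-RADS, mean
#' axial diameter for NCCN.
#'
#' @param system `"pancan"`, `"lung_rads"` or `"nccn"`.
#' @return A size-definition string.
#' @export
default_size_definition <- function(system) {
  switch(match.arg(system, system_names()),
         pancan = "longest_c",
         lung_rads = "mean3d",
         nccn = "mean_axial")
}

lung_rads_rank <- function(label) {
  unname(c("1" = 1, "2" = 2, "3" = 3, "4A" = 4, "4B" = 5)[label])
}

#' Score every nodule of a cohort under one system
#'
#' Vectorized driver producing one row per nodule with the system's
#' continuous risk (PanCan only), the ordinal category label, and a
#' numeric rank that increases with management intensity (PanCan: the
#' risk index itself; Lung-RADS: 1, 2, 3, 4A, 4B -> 1..5; NCCN: the
#' numeric category).  Ranks are comparable within a system only.
#'
#' @param cohort a [nodule_cohort()].
#' @param system `"pancan"`, `"lung_rads"` or `"nccn"`.
#' @param defn size definition; `NULL` uses the system's published default
#'   (see [default_size_definition()]).
#' @param coeffs PanCan coefficients ([load_pancan_coefficients()]);
#'   ignored for the categorical systems.
#' @return data.frame with columns `nodule_id`, `participant_id`,
#'   `system`, `defn`, `risk_percent` (NA for categorical systems),
#'   `category_label`, `rank`.
#' @examples
#' coh <- simulate_cohort(n_participants = 15, seed = 2)
#' head(score_cohort(coh, "nccn"))
#' @export
score_cohort <- function(cohort, system = c("pancan", "lung_rads", "nccn"),
                         defn = NULL, coeffs = NULL) {
  stopifnot(inherits(cohort, "nodule_cohort"))
  system <- match.arg(system)
  defn <- match_size_definition(defn %||% default_size_definition(system))
  n <- cohort$nodules

  if (system == "pancan") {
    risk <- pancan_risk(n, cohort$participants, coeffs, defn)
    label <- pancan_category(risk)
    rank <- risk
  } else if (system == "lung_rads") {
    risk <- rep(NA_real_, nrow(n))
    label <- lung_rads_category(n, defn)
    rank <- lung_rads_rank(label)
  } else {
    risk <- rep(NA_real_, nrow(n))
    label <- nccn_category(n, defn)
    rank <- as.numeric(label)
  }
  data.frame(nodule_id = n$nodule_id, participant_id = n$participant_id,
             system = rep(system, nrow(n)), defn = rep(defn, nrow(n)),
             risk_percent = risk, category_label = label, rank = rank,
             stringsAsFactors = FALSE)
}
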