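# Builders for hand-made fixtures used across test files.

make_nodule <- function(nodule_id = "n1", participant_id = "p1",
                        type = "solid", is_pfn = FALSE,
                        calcification = "none", spiculated = FALSE,
                        upper_lobe = FALSE, d_longest_axial = 10,
                        d_perp_axial = 8, d_mean3d = 9, volume = NA,
                        d_longest_axial_solid = NA, d_perp_axial_solid = NA,
                        d_mean3d_solid = NA, malignant = FALSE) {
  data.frame(nodule_id = nodule_id, participant_id = participant_id,
             type = type, is_pfn = is_pfn, calcification = calcification,
             spiculated = spiculated, upper_lobe = upper_lobe,
             d_longest_axial = d_longest_axial, d_perp_axial = d_perp_axial,
             d_mean3d = d_mean3d, volume = volume,
             d_longest_axial_solid = d_longest_axial_solid,
             d_perp_axial_solid = d_perp_axial_solid,
             d_mean3d_solid = d_mean3d_solid, malignant = malignant,
             stringsAsFactors = FALSE)
}

make_participant <- function(participant_id = "p1", age = 60, sex = "male",
                             family_history_lung_cancer = FALSE,
                             emphysema = FALSE,
                             nodule_count_additional = 0L,
                             has_cancer = NA) {
  data.frame(participant_id = participant_id, age = age, sex = sex,
             family_history_lung_cancer = family_history_lung_cancer,
             emphysema = emphysema,
             nodule_count_additional = nodule_count_additional,
             has_cancer = has_cancer, stringsAsFactors = FALSE)
}

# A small, fully hand-specified cohort: 2 participants, 3 nodules.
make_fixture_cohort <- function() {
  part <- rbind(
    make_participant("p1", age = 58, sex = "female",
                     family_history_lung_cancer = TRUE, emphysema = FALSE,
                     nodule_count_additional = NA),
    make_participant("p2", age = 67, sex = "male",
                     family_history_lung_cancer = FALSE, emphysema = TRUE,
                     nodule_count_additional = NA))
  nod <- rbind(
    make_nodule("n1", "p1", type = "solid", d_longest_axial = 7.5,
                d_perp_axial = 6.25, d_mean3d = 6.5, upper_lobe = TRUE),
    make_nodule("n2", "p1", type = "ground_glass", d_longest_axial = 12.5,
                d_perp_axial = 10.5, d_mean3d = 11.25),
    make_nodule("n3", "p2", type = "part_solid", d_longest_axial = 14.5,
                d_perp_axial = 12.5, d_mean3d = 12.25,
                d_longest_axial_solid = 7.25, d_perp_axial_solid = 6.5,
                d_mean3d_solid = 6.125, spiculated = TRUE,
                malignant = TRUE))
  nodule_cohort(part, nod)
}

# Worked published examples of category assignment: six nodules with all
# three printed diameters (perpendicular back-solved from the mean axial
# diameter), plus their known Lung-RADS / NCCN categories under each
# system's own size definition.
worked_examples <- function() {
  w <- function(id, type, dl, dma, d3, dls = NA, dmas = NA, d3s = NA) {
    make_nodule(id, "p1", type = type, d_longest_axial = dl,
                d_perp_axial = 2 * dma - dl, d_mean3d = d3,
                d_longest_axial_solid = dls,
                d_perp_axial_solid = if (is.na(dmas)) NA else 2 * dmas - dls,
                d_mean3d_solid = d3s)
  }
  nod <- rbind(
    w("ggn_small",   "ground_glass", 10.0,  8.8,  9.4),
    w("ps_small",    "part_solid",    9.4,  8.8,  8.5, 7.2, 6.0, 6.2),
    w("solid_mid",   "solid",        10.5,  9.1,  8.4),
    w("ggn_large",   "ground_glass", 12.4, 11.7,  9.8),
    w("ps_large",    "part_solid",   17.4, 15.7, 14.7, 7.1, 6.3, 5.2),
    w("solid_large", "solid",        15.2, 13.2, 13.5))
  list(nodules = nod,
       lung_rads = c("2", "4A", "4A", "2", "3", "4A"),
       nccn = c("3", "6", "6", "4", "6", "6"))
}

# Dense size grid over all nodule types (part-solid at several
# solid-component fractions), used for exhaustiveness/monotonicity sweeps.
grid_nodules <- function() {
  sizes <- seq(0.6, 40, by = 0.2)
  rows <- list()
  for (type in c("solid", "ground_glass")) {
    rows[[type]] <- make_nodule(paste0(type, seq_along(sizes)), "p",
                                type = type, d_longest_axial = sizes,
                                d_perp_axial = sizes, d_mean3d = sizes)
  }
  solid_fracs <- c(0.2, 0.5, 0.9, 1.0)
  for (f in solid_fracs) {
    rows[[paste0("ps", f)]] <- make_nodule(
      paste0("ps", f, "_", seq_along(sizes)), "p", type = "part_solid",
      d_longest_axial = sizes, d_perp_axial = sizes, d_mean3d = sizes,
      d_longest_axial_solid = sizes * f, d_perp_axial_solid = sizes * f,
      d_mean3d_solid = sizes * f)
  }
  do.call(rbind, rows)
}

# Brute-force AUC oracle: explicit count over all positive-negative pairs,
# ties worth 1/2.  Independent of the midrank implementation.
auc_pair_counting <- function(labels, scores) {
  x <- scores[labels]
  y <- scores[!labels]
  tot <- 0
  for (xi in x) tot <- tot + sum(xi > y) + 0.5 * sum(xi == y)
  tot / (length(x) * length(y))
}

random_roc_instance <- function(max_n = 60) {
  n <- sample(4:max_n, 1L)
  m <- sample(seq_len(n - 1L), 1L)
  labels <- sample(rep(c(TRUE, FALSE), c(m, n - m)))
  # coarse scores so ties are frequent
  scores <- sample(1:8, n, replace = TRUE) + labels * sample(0:3, n, TRUE)
  list(labels = labels, scores = scores)
}
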