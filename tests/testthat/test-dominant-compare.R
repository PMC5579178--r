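test_that("the single nodule of a participant is always dominant", {
  coh <- make_fixture_cohort()
  sel <- select_dominant(coh, score_cohort(coh, "nccn"), seed = 1)
  expect_equal(nrow(sel), 2L)
  expect_identical(sel$nodule_id[sel$participant_id == "p2"], "n3")
  expect_identical(sel$has_cancer, c(FALSE, TRUE))
})

test_that("rank ties are broken reproducibly by the seed", {
  part <- make_participant("p1")
  nod <- rbind(
    make_nodule("a", "p1", d_longest_axial = 4, d_perp_axial = 4,
                d_mean3d = 4),                                   # NCCN 1
    make_nodule("b", "p1", d_longest_axial = 9, d_perp_axial = 9,
                d_mean3d = 9),                                   # NCCN 6
    make_nodule("c", "p1", d_longest_axial = 12, d_perp_axial = 12,
                d_mean3d = 12))                                  # NCCN 6
  coh <- nodule_cohort(part, nod)
  scores <- score_cohort(coh, "nccn")
  picks <- vapply(1:40, function(s) {
    select_dominant(coh, scores, seed = s)$nodule_id
  }, "")
  expect_true(all(picks %in% c("b", "c")))   # never the rank-1 nodule
  expect_true(length(unique(picks)) == 2L)   # both ties are reachable
  # deterministic and idempotent for a fixed seed
  expect_identical(select_dominant(coh, scores, seed = 7),
                   select_dominant(coh, scores, seed = 7))
})

test_that("the three systems can crown three different dominant nodules", {
  part <- make_participant("p1")
  nod <- rbind(
    # small solid: highest NCCN category (5) of the three
    make_nodule("n_nccn", "p1", d_longest_axial = 6.5, d_perp_axial = 5.7,
                d_mean3d = 5.8),
    # solid with large 3D mean: Lung-RADS 4A, but mean-axial < 6 -> NCCN 1
    make_nodule("n_lr", "p1", d_longest_axial = 9.0, d_perp_axial = 2.9,
                d_mean3d = 8.7),
    # big ground-glass: largest PanCan size term, NCCN 4, Lung-RADS 2
    make_nodule("n_pancan", "p1", type = "ground_glass",
                d_longest_axial = 14.3, d_perp_axial = 12, d_mean3d = 13))
  coh <- nodule_cohort(part, nod)
  dom <- vapply(c("pancan", "lung_rads", "nccn"), function(sys) {
    select_dominant(coh, score_cohort(coh, sys), seed = 1)$nodule_id
  }, "")
  expect_identical(unname(dom),
                   c("n_pancan", "n_lr", "n_nccn"))
})

test_that("compare_systems assembles consistent AUC and DeLong tables", {
  coh <- simulate_cohort(n_participants = 150, seed = 21)
  cmp <- compare_systems(coh, seed = 21)
  expect_s3_class(cmp, "system_comparison")
  expect_identical(cmp$auc$defn,
                   c("as_published", "longest_c", "mean3d", "mean_axial"))
  expect_equal(nrow(cmp$pairwise), 12L)       # 4 rows x 3 system pairs
  expect_equal(nrow(cmp$defn_pairwise), 9L)   # 3 systems x 3 defn pairs
  expect_equal(cmp$threshold, 0.05 / 3)
  expect_true(all(cmp$pairwise$p >= 0 & cmp$pairwise$p <= 1))
  expect_identical(cmp$pairwise$significant, cmp$pairwise$p < 0.05 / 3)
  # AUC table agrees with the pairwise rows
  row1 <- cmp$pairwise[cmp$pairwise$defn == "mean3d" &
                         cmp$pairwise$system_a == "pancan" &
                         cmp$pairwise$system_b == "nccn", ]
  expect_equal(row1$auc_a, cmp$auc$pancan[cmp$auc$defn == "mean3d"])
  expect_equal(row1$auc_b, cmp$auc$nccn[cmp$auc$defn == "mean3d"])
  # deterministic given the seed
  cmp2 <- compare_systems(coh, seed = 21)
  expect_equal(cmp$auc, cmp2$auc)
  expect_equal(cmp$pairwise, cmp2$pairwise)
  # the as-published row uses each system's own definition
  expect_equal(cmp$auc$pancan[1], cmp$auc$pancan[cmp$auc$defn == "longest_c"])
  expect_equal(cmp$auc$lung_rads[1], cmp$auc$lung_rads[cmp$auc$defn == "mean3d"])
  expect_equal(cmp$auc$nccn[1], cmp$auc$nccn[cmp$auc$defn == "mean_axial"])
})

test_that("participant-level labels stay positive when the dominant pick is benign", {
  # one cancer participant whose malignant nodule is NOT NCCN-dominant
  part <- rbind(make_participant("p1"), make_participant("p2"))
  nod <- rbind(
    make_nodule("m", "p1", d_longest_axial = 4, d_perp_axial = 4,
                d_mean3d = 4, malignant = TRUE),          # NCCN 1, malignant
    make_nodule("b", "p1", d_longest_axial = 10, d_perp_axial = 10,
                d_mean3d = 10),                           # NCCN 6, benign
    make_nodule("x", "p2", d_longest_axial = 5, d_perp_axial = 5,
                d_mean3d = 5))
  coh <- nodule_cohort(part, nod)
  sel <- select_dominant(coh, score_cohort(coh, "nccn"), seed = 1)
  p1 <- sel[sel$participant_id == "p1", ]
  expect_identical(p1$nodule_id, "b")   # benign nodule selected
  expect_true(p1$has_cancer)            # but the participant stays a case
})

test_that("comparison reports serialize to CSV and Markdown", {
  coh <- simulate_cohort(n_participants = 120, seed = 30)
  cmp <- compare_systems(coh, seed = 30)
  dir <- tempfile()
  write_comparison_report(cmp, dir)
  expect_true(all(file.exists(file.path(
    dir, c("auc.csv", "pairwise_systems.csv", "pairwise_definitions.csv",
           "report.md")))))
  back <- read.csv(file.path(dir, "auc.csv"))
  expect_equal(back$pancan, cmp$auc$pancan, tolerance = 1e-12)
  md <- readLines(file.path(dir, "report.md"))
  expect_true(any(grepl("p < 0.0167", md)))
  expect_output(print(cmp), "Bonferroni")
})

test_that("demographics_table computes group summaries and test p-values", {
  # identical covariate patterns in both groups: p = 1 (or NA when a
  # category is absent everywhere)
  part <- do.call(rbind, lapply(1:8, function(i) {
    make_participant(paste0("p", i), age = c(55, 70)[1 + i %% 2],
                     sex = c("male", "female")[1 + i %% 2])
  }))
  nod <- do.call(rbind, lapply(1:8, function(i) {
    make_nodule(paste0("n", i), paste0("p", i),
                d_longest_axial = c(6, 12)[1 + i %% 2],
                d_perp_axial = c(5, 10)[1 + i %% 2],
                d_mean3d = c(5, 10)[1 + i %% 2],
                malignant = i <= 4)
  }))
  coh <- nodule_cohort(part, nod)
  tab <- demographics_table(coh)
  expect_true(all(is.na(tab$p_value) | tab$p_value > 0.999))
  expect_identical(tab$parameter[1], "n nodules")

  # family-history imbalance like the published cohort: 17/64 vs 90/549
  part2 <- do.call(rbind, lapply(1:613, function(i) {
    cancer <- i <= 64
    make_participant(paste0("q", i), age = 50 + (i %% 20),
                     family_history_lung_cancer =
                       (cancer && i <= 17) || (!cancer && i <= 64 + 90))
  }))
  nod2 <- do.call(rbind, lapply(1:613, function(i) {
    make_nodule(paste0("m", i), paste0("q", i), malignant = i <= 64,
                d_longest_axial = 8 + (i %% 7), d_perp_axial = 6,
                d_mean3d = 6 + (i %% 5))
  }))
  coh2 <- nodule_cohort(part2, nod2)
  tab2 <- demographics_table(coh2)
  fam <- tab2[tab2$parameter == "family history of lung cancer", ]
  expect_lt(fam$p_value, 0.05)
  expect_match(fam$malignant, "17 \\(27%\\)")
  expect_match(fam$benign, "90 \\(16%\\)")

  # a single-group cohort is rejected
  all_benign <- nodule_cohort(make_participant("p1"),
                              make_nodule("n1", "p1"))
  expect_error(demographics_table(all_benign), "both malignant and benign")
})
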