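test_that("published worked examples reproduce under each system's own definition", {
  w <- worked_examples()
  expect_identical(lung_rads_category(w$nodules), w$lung_rads)
  expect_identical(nccn_category(w$nodules), w$nccn)
  # a 6.1 mm mean-axial solid nodule is NCCN category 5
  n <- make_nodule("s", "p1", d_longest_axial = 6.5, d_perp_axial = 5.7,
                   d_mean3d = 5.8)
  expect_identical(nccn_category(n), "5")
})

test_that("Lung-RADS rounds half-up before applying thresholds", {
  solid <- function(d) make_nodule("n", "p", d_longest_axial = d + 2,
                                   d_perp_axial = d, d_mean3d = d)
  # 5.4 -> 5 (<6) -> 2 ; 5.5 -> 6 -> 3 ; 7.5 -> 8 -> 4A ; 8.4 -> 8 -> 4A
  # 14.5 -> 15 -> 4B ; 14.4 -> 14 -> 4A
  expect_identical(lung_rads_category(solid(5.4)), "2")
  expect_identical(lung_rads_category(solid(5.5)), "3")
  expect_identical(lung_rads_category(solid(7.5)), "4A")
  expect_identical(lung_rads_category(solid(8.4)), "4A")
  expect_identical(lung_rads_category(solid(14.4)), "4A")
  expect_identical(lung_rads_category(solid(14.5)), "4B")
  ggn <- function(d) make_nodule("n", "p", type = "ground_glass",
                                 d_longest_axial = d + 2, d_perp_axial = d,
                                 d_mean3d = d)
  expect_identical(lung_rads_category(ggn(19.4)), "2")
  expect_identical(lung_rads_category(ggn(19.5)), "3")
})

test_that("Lung-RADS part-solid rules use total and solid-component sizes", {
  ps <- function(total, solid) {
    make_nodule("n", "p", type = "part_solid", d_longest_axial = total + 2,
                d_perp_axial = total, d_mean3d = total,
                d_longest_axial_solid = solid + 1, d_perp_axial_solid = solid,
                d_mean3d_solid = solid)
  }
  expect_identical(lung_rads_category(ps(5.4, 3)), "2")    # total < 6
  expect_identical(lung_rads_category(ps(8, 5.4)), "3")    # solid < 6
  expect_identical(lung_rads_category(ps(8, 6)), "4A")     # solid 6-7
  expect_identical(lung_rads_category(ps(8, 7.4)), "4A")
  expect_identical(lung_rads_category(ps(20, 8)), "4B")    # solid >= 8
  expect_error(lung_rads_category(ps(8, NA)), "missing measurement")
})

test_that("NCCN bands are unrounded with the stated open/closed boundaries", {
  solid <- function(d) make_nodule("n", "p", d_longest_axial = d,
                                   d_perp_axial = d, d_mean3d = d)
  ggn <- function(d) make_nodule("n", "p", type = "ground_glass",
                                 d_longest_axial = d, d_perp_axial = d,
                                 d_mean3d = d)
  # solid/part-solid by total: <6 -> 1, [6,8] -> 5, >8 -> 6
  expect_identical(nccn_category(solid(5.999)), "1")
  expect_identical(nccn_category(solid(6)), "5")
  expect_identical(nccn_category(solid(8)), "5")
  expect_identical(nccn_category(solid(8.001)), "6")
  # pure ground-glass: <=5 -> 2, (5,10] -> 3, >10 -> 4
  expect_identical(nccn_category(ggn(5)), "2")
  expect_identical(nccn_category(ggn(5.001)), "3")
  expect_identical(nccn_category(ggn(10)), "3")
  expect_identical(nccn_category(ggn(10.001)), "4")
  # part-solid is categorized by its *total* diameter
  ps <- make_nodule("n", "p", type = "part_solid", d_longest_axial = 8.8,
                    d_perp_axial = 8.8, d_mean3d = 8,
                    d_longest_axial_solid = 6, d_perp_axial_solid = 6,
                    d_mean3d_solid = 5)
  expect_identical(nccn_category(ps), "6")
})

test_that("benign-pattern calcification maps to category 1, PFNs score as solid", {
  calc <- make_nodule("n", "p", calcification = "benign_pattern",
                      d_longest_axial = 25, d_perp_axial = 25, d_mean3d = 25)
  expect_identical(lung_rads_category(calc), "1")
  expect_identical(nccn_category(calc), "1")
  other <- make_nodule("n", "p", calcification = "other",
                       d_longest_axial = 25, d_perp_axial = 25, d_mean3d = 25)
  expect_identical(lung_rads_category(other), "4B")
  expect_identical(nccn_category(other), "6")
  pfn <- make_nodule("n", "p", is_pfn = TRUE, d_longest_axial = 9,
                     d_perp_axial = 9, d_mean3d = 9)
  expect_identical(lung_rads_category(pfn), "4A")
  expect_identical(nccn_category(pfn), "6")
})

test_that("every grid combination maps to exactly one category in each system", {
  g <- grid_nodules()
  for (defn in c("longest_c", "mean3d", "mean_axial")) {
    lr <- lung_rads_category(g, defn)
    expect_true(all(lr %in% c("1", "2", "3", "4A", "4B")))
    nc <- nccn_category(g, defn)
    expect_true(all(nc %in% as.character(1:6)))
  }
  calc <- g
  calc$calcification <- "benign_pattern"
  expect_true(all(lung_rads_category(calc) == "1"))
  expect_true(all(nccn_category(calc) == "1"))
})

test_that("category rank is monotone in total size for every type", {
  sizes <- seq(1, 40, by = 0.1)
  for (type in c("solid", "ground_glass", "part_solid")) {
    n <- make_nodule(paste0("m", seq_along(sizes)), "p", type = type,
                     d_longest_axial = sizes, d_perp_axial = sizes,
                     d_mean3d = sizes,
                     d_longest_axial_solid = if (type == "part_solid") sizes * 0.5 else NA,
                     d_perp_axial_solid = if (type == "part_solid") sizes * 0.5 else NA,
                     d_mean3d_solid = if (type == "part_solid") sizes * 0.5 else NA)
    lr_rank <- c("1" = 1, "2" = 2, "3" = 3, "4A" = 4, "4B" = 5)[
      lung_rads_category(n)]
    expect_true(all(diff(lr_rank) >= 0))
    expect_true(all(diff(as.numeric(nccn_category(n))) >= 0))
  }
})

test_that("score_cohort is deterministic, row-independent and complete", {
  coh <- simulate_cohort(n_participants = 40, seed = 5)
  for (sys in c("pancan", "lung_rads", "nccn")) {
    s1 <- score_cohort(coh, sys)
    expect_equal(nrow(s1), nrow(nodules(coh)))
    expect_false(anyNA(s1$rank))
    expect_identical(s1, score_cohort(coh, sys))
    # permuting nodule rows permutes scores identically
    perm <- sample(nrow(coh$nodules))
    coh2 <- coh
    coh2$nodules <- coh$nodules[perm, , drop = FALSE]
    s2 <- score_cohort(coh2, sys)
    expect_equal(s2$rank, s1$rank[perm])
  }
  empty <- simulate_cohort(n_participants = 0, seed = 1)
  expect_equal(nrow(score_cohort(empty, "nccn")), 0L)
  expect_equal(nrow(score_cohort(empty, "pancan")), 0L)
})
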