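#' Select the risk-dominant nodule per participant
#'
#' For one scoring system and size definition, picks for every participant
#' the nodule with the highest rank (risk index or category).  When
#' several nodules tie at the maximal rank, one is selected uniformly at
#' random from a seeded generator, so the selection is reproducible given
#' the seed.  Participants without nodules are dropped with a warning.
#'
#' @param cohort a [nodule_cohort()].
#' @param scores output of [score_cohort()] covering every nodule of the
#'   cohort.
#' @param seed integer seed governing tie-breaking.
#' @return data.frame with one row per participant: `participant_id`,
#'   `nodule_id`, `rank`, `has_cancer`; attributes `system`, `defn`,
#'   `seed`.
#' @export
select_dominant <- function(cohort, scores, seed = 1L) {
  stopifnot(inherits(cohort, "nodule_cohort"))
  missing <- setdiff(cohort$nodules$nodule_id, scores$nodule_id)
  if (length(missing)) {
    abort_usage(sprintf("scores do not cover nodule(s): %s",
                        paste(utils::head(missing, 3L), collapse = ", ")))
  }
  system <- unique(scores$system)
  defn <- unique(scores$defn)
  part <- cohort$participants
  sub_seed <- derive_seed(seed, paste("dominant", system[1L], defn[1L]))

  sc <- scores[scores$nodule_id %in% cohort$nodules$nodule_id,
               c("participant_id", "nodule_id", "rank")]
  by_part <- split(sc, sc$participant_id)
  sel <- with_seed(sub_seed, {
    rows <- lapply(part$participant_id, function(pid) {
      s <- by_part[[pid]]
      if (is.null(s) || nrow(s) == 0L) return(NULL)
      top <- s[s$rank == max(s$rank), , drop = FALSE]
      top[if (nrow(top) == 1L) 1L else sample.int(nrow(top), 1L), ,
          drop = FALSE]
    })
    do.call(rbind, rows)
  })
  if (is.null(sel)) {
    sel <- data.frame(participant_id = character(0), nodule_id = character(0),
                      rank = numeric(0), stringsAsFactors = FALSE)
  }
  dropped <- setdiff(part$participant_id, sel$participant_id)
  if (length(dropped)) {
    warning(sprintf("%d participant(s) without nodules excluded",
                    length(dropped)))
  }
  sel$has_cancer <- part$has_cancer[match(sel$participant_id,
                                          part$participant_id)]
  rownames(sel) <- NULL
  attr(sel, "system") <- system
  attr(sel, "defn") <- defn
  attr(sel, "seed") <- seed
  sel
}

# Participant-level ROC of one system under one size definition:
# labels = participant has_cancer (even when that system's dominant pick
# is a benign nodule of a cancer participant), scores = rank of the
# risk-dominant nodule.
participant_roc <- function(cohort, system, defn, coeffs, seed) {
  scores <- score_cohort(cohort, system, defn, coeffs)
  sel <- select_dominant(cohort, scores, seed)
  r <- roc(sel$has_cancer, sel$rank)
  r$system <- system
  r$defn <- defn
  if (system == "pancan") {
    cuts <- c(1.5, 6, 30)
    r$operating_points <- data.frame(
      threshold = cuts,
      fpr = vapply(cuts, function(t) mean(sel$rank[!sel$has_cancer] >= t), 0),
      tpr = vapply(cuts, function(t) mean(sel$rank[sel$has_cancer] >= t), 0))
  } else {
    r$operating_points <- r$curve[-1L, c("threshold", "fpr", "tpr")]
  }
  list(roc = r, selection = sel)
}

#' Compare the three scoring systems across size definitions
#'
#' Runs the full comparison pipeline: per-nodule scoring, risk-dominant
#' nodule selection per participant, participant-level ROC per system,
#' and paired DeLong tests -- first with every system's own published size
#' definition ("as published": PanCan with the longest axial diameter,
#' Lung-RADS with the volumetric mean diameter, NCCN with the mean axial
#' diameter), then uniformly under each definition in `defns`.  Pairwise
#' system differences within a row use a Bonferroni-corrected threshold
#' `alpha_family / n_comparisons` (0.05/3 = 0.0167 by default); the same
#' threshold is applied to the per-system comparisons between size
#' definitions.
#'
#' @param cohort a [nodule_cohort()].
#' @param coeffs PanCan coefficients (`NULL` = bundled default).
#' @param defns size definitions for the uniform rows.
#' @param alpha_family family-wise significance level (default 0.05).
#' @param n_comparisons number of comparisons per family (default 3).
#' @param seed integer seed (tie-breaking in dominant-nodule selection).
#' @return An object of class `system_comparison`: list with
#'   \describe{
#'     \item{auc}{data.frame of AUCs per row (size definition) and system.}
#'     \item{pairwise}{data.frame of the three system pairs per row with
#'       AUCs, DeLong `z`, two-sided `p` and the significance flag.}
#'     \item{defn_pairwise}{data.frame of per-system comparisons between
#'       size definitions.}
#'     \item{roc}{named list of participant-level `roc_result`s.}
#'     \item{alpha, threshold, seed}{analysis parameters.}
#'   }
#' @examples
#' coh <- simulate_cohort(n_participants = 120, seed = 7)
#' cmp <- compare_systems(coh, seed = 7)
#' cmp$auc
#' @export
compare_systems <- function(cohort, coeffs = NULL,
                            defns = c("longest_c", "mean3d", "mean_axial"),
                            alpha_family = 0.05, n_comparisons = 3L,
                            seed = 1L) {
  stopifnot(inherits(cohort, "nodule_cohort"))
  coeffs <- coeffs %||% load_pancan_coefficients()
  defns <- vapply(defns, match_size_definition, "")
  systems <- system_names()
  threshold <- alpha_family / n_comparisons

  rows <- c("as_published", defns)
  rocs <- list()
  sels <- list()
  for (row in rows) {
    for (sys in systems) {
      defn <- if (row == "as_published") default_size_definition(sys) else row
      key <- paste(sys, row, sep = "|")
      pr <- participant_roc(cohort, sys, defn, coeffs, seed)
      rocs[[key]] <- pr$roc
      sels[[key]] <- pr$selection
    }
  }

  auc_tab <- do.call(rbind, lapply(rows, function(row) {
    data.frame(defn = row,
               pancan = rocs[[paste0("pancan|", row)]]$auc,
               lung_rads = rocs[[paste0("lung_rads|", row)]]$auc,
               nccn = rocs[[paste0("nccn|", row)]]$auc,
               stringsAsFactors = FALSE)
  }))

  pairs <- utils::combn(systems, 2L, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(rows, function(row) {
    do.call(rbind, lapply(pairs, function(pr) {
      sa <- sels[[paste(pr[1L], row, sep = "|")]]
      sb <- sels[[paste(pr[2L], row, sep = "|")]]
      stopifnot(identical(sa$participant_id, sb$participant_id))
      dt <- delong_test(sa$has_cancer, sa$rank, sb$rank)
      data.frame(defn = row, system_a = pr[1L], system_b = pr[2L],
                 auc_a = dt$auc_a, auc_b = dt$auc_b, z = dt$z, p = dt$p,
                 significant = dt$p < threshold, stringsAsFactors = FALSE)
    }))
  }))

  defn_pairs <- utils::combn(defns, 2L, simplify = FALSE)
  defn_pairwise <- do.call(rbind, lapply(systems, function(sys) {
    do.call(rbind, lapply(defn_pairs, function(dp) {
      sa <- sels[[paste(sys, dp[1L], sep = "|")]]
      sb <- sels[[paste(sys, dp[2L], sep = "|")]]
      dt <- delong_test(sa$has_cancer, sa$rank, sb$rank)
      data.frame(system = sys, defn_a = dp[1L], defn_b = dp[2L],
                 auc_a = dt$auc_a, auc_b = dt$auc_b, z = dt$z, p = dt$p,
                 significant = dt$p < threshold, stringsAsFactors = FALSE)
    }))
  }))

  structure(list(auc = auc_tab, pairwise = pairwise,
                 defn_pairwise = defn_pairwise, roc = rocs,
                 alpha = alpha_family, n_comparisons = n_comparisons,
                 threshold = threshold, seed = seed),
            class = "system_comparison")
}

#' @export
print.system_comparison <- function(x, digits = 3, ...) {
  cat("Comparison of nodule risk-stratification systems\n")
  cat(sprintf("Bonferroni-corrected significance threshold: p < %.4f (%g/%d)\n\n",
              x$threshold, x$alpha, x$n_comparisons))
  cat("AUC per size definition and system:\n")
  tab <- x$auc
  tab[-1L] <- lapply(tab[-1L], round, digits)
  print(tab, row.names = FALSE)
  cat("\nPairwise system comparisons (paired DeLong):\n")
  pw <- x$pairwise
  pw$auc_a <- round(pw$auc_a, digits)
  pw$auc_b <- round(pw$auc_b, digits)
  pw$z <- round(pw$z, 2)
  pw$p <- signif(pw$p, 2)
  print(pw, row.names = FALSE)
  cat("\nPer-system comparisons between size definitions:\n")
  dp <- x$defn_pairwise
  dp$auc_a <- round(dp$auc_a, digits)
  dp$auc_b <- round(dp$auc_b, digits)
  dp$z <- round(dp$z, 2)
  dp$p <- signif(dp$p, 2)
  print(dp, row.names = FALSE)
  invisible(x)
}

#' Plot participant-level ROC curves of the three systems
#'
#' Draws, for one comparison row (a size definition or `"as_published"`),
#' the ROC curve of each system with its category operating points; the
#' PanCan curve is continuous (risk index) with its four-category
#' operating points marked.
#'
#' @param x a `system_comparison`.
#' @param defn which row to plot (default `"as_published"`).
#' @param ... passed to [graphics::plot()].
#' @export
plot.system_comparison <- function(x, defn = "as_published", ...) {
  cols <- c(pancan = "#D55E00", lung_rads = "#0072B2", nccn = "#009E73")
  first <- TRUE
  for (sys in system_names()) {
    r <- x$roc[[paste(sys, defn, sep = "|")]]
    plot(r, add = !first, col = cols[[sys]], points = FALSE,
         main = if (first) paste("Size definition:", defn) else NULL, ...)
    op <- r$operating_points
    graphics::points(op$fpr, op$tpr, col = cols[[sys]], pch = 16)
    first <- FALSE
  }
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("%s (AUC %.3f)", names(cols),
                                    vapply(names(cols), function(s)
                                      x$roc[[paste(s, defn, sep = "|")]]$auc, 0)),
                   col = cols, lwd = 2)
  invisible(x)
}

#' Write a comparison report to CSV and Markdown
#'
#' Serializes the AUC table, both pairwise tables and the analysis
#' parameters into `dir` as CSV files plus a single Markdown rendering.
#'
#' @param x a `system_comparison`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_comparison_report <- function(x, dir) {
  stopifnot(inherits(x, "system_comparison"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(x$auc, file.path(dir, "auc.csv"), row.names = FALSE)
  utils::write.csv(x$pairwise, file.path(dir, "pairwise_systems.csv"),
                   row.names = FALSE)
  utils::write.csv(x$defn_pairwise, file.path(dir, "pairwise_definitions.csv"),
                   row.names = FALSE)
  md <- c("# System comparison",
          "",
          sprintf("Significance threshold (Bonferroni): p < %.4f (%g/%d)",
                  x$threshold, x$alpha, x$n_comparisons),
          sprintf("Seed: %d", x$seed), "",
          "## AUC per size definition", "",
          md_table(x$auc), "",
          "## Pairwise system comparisons (paired DeLong)", "",
          md_table(x$pairwise), "",
          "## Per-system comparisons between size definitions", "",
          md_table(x$defn_pairwise), "")
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

md_table <- function(df) {
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.4g", col) else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1L)
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(fmt, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
}

#' Demographics table of risk-dominant nodules
#'
#' Builds the malignant-versus-benign characteristics table over the union
#' of risk-dominant nodules selected by the three systems (a nodule
#' appears once even if several systems select it; participants
#' contributing dominant nodules to both groups appear in both).
#' Categorical rows are compared with a chi-square test (no continuity
#' correction), continuous rows with Welch's unequal-variance t-test.
#'
#' @param cohort a [nodule_cohort()].
#' @param selections list of [select_dominant()] results (one per system);
#'   `NULL` runs the three systems under their published definitions.
#' @param seed seed for dominant-nodule tie-breaking when `selections` is
#'   `NULL`.
#' @param coeffs PanCan coefficients (`NULL` = bundled default).
#' @return data.frame with columns `parameter`, `malignant`, `benign`,
#'   `p_value`, `test`.
#' @export
demographics_table <- function(cohort, selections = NULL, seed = 1L,
                               coeffs = NULL) {
  stopifnot(inherits(cohort, "nodule_cohort"))
  if (is.null(selections)) {
    selections <- lapply(system_names(), function(sys) {
      select_dominant(cohort, score_cohort(cohort, sys, coeffs = coeffs),
                      seed)
    })
  }
  ids <- unique(unlist(lapply(selections, `[[`, "nodule_id")))
  n <- cohort$nodules[cohort$nodules$nodule_id %in% ids, , drop = FALSE]
  p <- cohort$participants
  n <- cbind(n, p[match(n$participant_id, p$participant_id),
                  setdiff(participant_columns(), "participant_id"),
                  drop = FALSE])
  g <- n$malignant
  if (!any(g) || all(g)) abort_data("both malignant and benign groups required")

  rows <- list()
  add <- function(parameter, mal, ben, p_value, test) {
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = parameter, malignant = mal, benign = ben,
      p_value = p_value, test = test, stringsAsFactors = FALSE)
  }
  cont <- function(parameter, v) {
    s <- function(x) sprintf("median %.1f, mean %.1f (%.1f-%.1f)",
                             stats::median(x), mean(x), min(x), max(x))
    # Welch by default; undefined (NA) when both groups are constant
    pv <- tryCatch(stats::t.test(v[g], v[!g])$p.value,
                   error = function(e) NA_real_)
    add(parameter, s(v[g]), s(v[!g]), pv, "Welch t-test")
  }
  cat2 <- function(parameter, flag) {
    tab <- table(factor(g, c(TRUE, FALSE)), factor(flag, c(TRUE, FALSE)))
    pv <- if (any(colSums(tab) == 0)) NA_real_ else {
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    }
    s <- function(grp) sprintf("%d (%.0f%%)", sum(flag[grp]),
                               100 * mean(flag[grp]))
    add(parameter, s(g), s(!g), pv, "chi-square")
  }

  add("n nodules", sprintf("%d", sum(g)), sprintf("%d", sum(!g)), NA,
      "")
  cont("age (years)", n$age)
  cat2("sex: male", n$sex == "male")
  cat2("family history of lung cancer", n$family_history_lung_cancer)
  cat2("emphysema", n$emphysema)
  cont("d_longest_axial (mm)", n$d_longest_axial)
  cont("d_mean3d (mm)", n$d_mean3d)
  cont("d_mean_axial (mm)", mean_axial(n$d_longest_axial, n$d_perp_axial))
  tab <- table(factor(g, c(TRUE, FALSE)),
               factor(n$type, c("solid", "part_solid", "ground_glass")))
  pv <- suppressWarnings(stats::chisq.test(tab)$p.value)
  tystr <- function(grp) {
    tt <- table(factor(n$type[grp], c("solid", "part_solid", "ground_glass")))
    sprintf("solid %d (%.0f%%), part-solid %d (%.0f%%), non-solid %d (%.0f%%)",
            tt[1L], 100 * tt[1L] / sum(tt), tt[2L], 100 * tt[2L] / sum(tt),
            tt[3L], 100 * tt[3L] / sum(tt))
  }
  add("nodule type", tystr(g), tystr(!g), pv, "chi-square")
  cat2("perifissural", n$is_pfn)
  cat2("calcified (benign pattern)", n$calcification == "benign_pattern")
  cont("additional nodule count", as.numeric(n$nodule_count_additional))
  cat2("upper lobe", n$upper_lobe)
  cat2("spiculation", n$spiculated)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
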