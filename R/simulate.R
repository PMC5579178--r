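#' Configuration of the synthetic cohort generator
#'
#' Defines the study conditions emulated by [simulate_cohort()]: a
#' screening-trial-like case-control cohort of participants with
#' baseline-detected nodules, calibrated to published risk-dominant
#' nodule characteristics of a lung-screening case-control cohort
#' (group size medians/means, type mix, spiculation, calcification,
#' perifissural fraction, demographics).
#'
#' The size model: each nodule has a latent "true" size `s`, log-normal
#' within its malignancy group (parameterized by median and log-scale
#' spread), and the three diameter definitions observe `s` with
#' definition-specific noise:
#' \itemize{
#'   \item volumetric mean diameter `d_mean3d = s * c`, compactness
#'     `c` in (0.85, 1] (the least noisy measure, using the full 3D
#'     extent);
#'   \item longest axial diameter `d_longest = s * e`, elongation
#'     `e = exp(Exponential(rate))` >= 1 (the noisiest: elongated or
#'     irregular nodules overestimate size in one axis);
#'   \item perpendicular axial diameter `d_perp = s * u`, `u` in
#'     (0.75, 1], so the mean axial diameter `s (u + e) / 2` is
#'     intermediate.
#' }
#' By construction `d_perp <= d_longest` and
#' `d_mean3d <= d_mean_axial <= d_longest` ordering holds in the typical
#' case, with `d_mean3d <= d_longest` always.  The latent-size medians are
#' calibrated so the *observed* longest-diameter group medians and means
#' match the published values (benign median 6.1 mm, mean 7.6 mm;
#' malignant median 13.9 mm, mean 16.5 mm).
#'
#' Malignancy is assigned at the participant level first (prevalence
#' 64/613); each cancer participant receives exactly one malignant nodule
#' plus a group-specific Poisson number of additional benign nodules.
#' Malignant nodules are never perifissural or benign-pattern calcified.
#' Covariates are drawn independently given cancer status.
#'
#' @param n_participants number of participants (default 613).
#' @param cancer_prevalence probability a participant has cancer
#'   (default 64/613).
#' @param extra_nodule_mean named vector: mean number of additional benign
#'   nodules per participant, by group.
#' @param size_malignant,size_benign lists with `median` and `sdlog` of
#'   the latent size distribution.
#' @param elongation_rate rate of the exponential log-elongation.
#' @param type_probs_malignant,type_probs_benign probabilities of
#'   solid / part-solid / ground-glass.
#' @param p_spiculation,p_calcified,p_pfn_given_solid,p_upper_lobe,
#'   p_female,p_family_history,p_emphysema named `c(malignant=, benign=)`
#'   probabilities (calcified and PFN are forced to 0 for malignant).
#' @param age_mean,age_sd named `c(malignant=, benign=)` parameters of the
#'   truncated-normal age distribution on `[49, 80]`.
#' @param solid_fraction_range range of the uniform solid-component
#'   fraction of part-solid nodules.
#' @return An object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(
    n_participants = 613L,
    cancer_prevalence = 64 / 613,
    extra_nodule_mean = c(malignant = 0.3, benign = 0.5),
    size_malignant = list(median = 11.4079, sdlog = 0.5402),
    size_benign = list(median = 5.0063, sdlog = 0.6234),
    elongation_rate = 5,
    type_probs_malignant = c(solid = 0.66, part_solid = 0.23,
                             ground_glass = 0.11),
    type_probs_benign = c(solid = 0.87, part_solid = 0.03,
                          ground_glass = 0.10),
    p_spiculation = c(malignant = 0.28, benign = 0.01),
    p_calcified = c(malignant = 0, benign = 0.14),
    p_pfn_given_solid = c(malignant = 0, benign = 0.092),
    p_upper_lobe = c(malignant = 0.58, benign = 0.48),
    p_female = c(malignant = 0.45, benign = 0.47),
    p_family_history = c(malignant = 0.27, benign = 0.16),
    p_emphysema = c(malignant = 0.73, benign = 0.67),
    age_mean = c(malignant = 61, benign = 58),
    age_sd = c(malignant = 5.5, benign = 5),
    solid_fraction_range = c(0.35, 0.9)) {
  cfg <- as.list(environment())
  for (tp in list(cfg$type_probs_malignant, cfg$type_probs_benign)) {
    if (length(tp) != 3L || any(tp < 0) || abs(sum(tp) - 1) > 1e-8) {
      abort_usage("type probabilities must be 3 non-negative values summing to 1")
    }
  }
  probs <- c(cfg$cancer_prevalence, cfg$p_spiculation, cfg$p_calcified,
             cfg$p_pfn_given_solid, cfg$p_upper_lobe, cfg$p_female,
             cfg$p_family_history, cfg$p_emphysema)
  if (any(probs < 0 | probs > 1)) {
    abort_usage("probabilities must lie in [0, 1]")
  }
  if (cfg$n_participants < 0) abort_usage("n_participants must be >= 0")
  structure(cfg, class = "cohort_sim_config")
}

# Truncated normal draw by rejection (cheap at these scales).
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

# Draw `n` nodules of one malignancy group; returns a nodules data.frame
# without ids.
draw_nodules <- function(n, malignant, cfg) {
  grp <- if (malignant) "malignant" else "benign"
  size <- if (malignant) cfg$size_malignant else cfg$size_benign
  tp <- if (malignant) cfg$type_probs_malignant else cfg$type_probs_benign

  s <- stats::rlnorm(n, log(size$median), size$sdlog)
  e <- exp(stats::rexp(n, cfg$elongation_rate))
  u <- 0.75 + 0.25 * stats::rbeta(n, 2, 2)
  comp <- 0.85 + 0.15 * stats::rbeta(n, 2, 2)
  d_longest <- s * e
  d_perp <- s * u
  d_mean3d <- s * comp

  type <- sample(names(tp), n, replace = TRUE, prob = tp)
  calc <- stats::runif(n) < cfg$p_calcified[[grp]]
  pfn <- type == "solid" & !calc &
    stats::runif(n) < cfg$p_pfn_given_solid[[grp]]
  spic <- stats::runif(n) < cfg$p_spiculation[[grp]]
  upper <- stats::runif(n) < cfg$p_upper_lobe[[grp]]

  frac <- stats::runif(n, cfg$solid_fraction_range[1L],
                       cfg$solid_fraction_range[2L])
  ps <- type == "part_solid"
  data.frame(
    type = type, is_pfn = pfn,
    calcification = ifelse(calc, "benign_pattern", "none"),
    spiculated = spic, upper_lobe = upper,
    d_longest_axial = d_longest, d_perp_axial = d_perp,
    d_mean3d = d_mean3d, volume = NA_real_,
    d_longest_axial_solid = ifelse(ps, frac * d_longest, NA_real_),
    d_perp_axial_solid = ifelse(ps, frac * d_perp, NA_real_),
    d_mean3d_solid = ifelse(ps, frac * d_mean3d, NA_real_),
    malignant = rep(malignant, n), stringsAsFactors = FALSE)
}

#' Simulate a screening-like nodule cohort
#'
#' Generates a seed-deterministic synthetic cohort under a
#' [cohort_sim_config()]: participant cancer status, covariates, nodules
#' with consistent size measurements under all three diameter definitions,
#' and malignancy labels.  The result always passes [validate_cohort()].
#'
#' @param n_participants overrides `config$n_participants` when given.
#' @param seed integer seed; the same seed reproduces the same cohort.
#' @param config a [cohort_sim_config()].
#' @return A [nodule_cohort()].
#' @examples
#' coh <- simulate_cohort(n_participants = 50, seed = 42)
#' coh
#' @export
simulate_cohort <- function(n_participants = NULL, seed = 1L,
                            config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  if (!is.null(n_participants)) config$n_participants <- n_participants
  np <- as.integer(config$n_participants)
  empty <- nodule_cohort(
    data.frame(participant_id = character(0), age = numeric(0),
               sex = character(0), family_history_lung_cancer = logical(0),
               emphysema = logical(0)),
    data.frame(nodule_id = character(0), participant_id = character(0),
               type = character(0), is_pfn = logical(0),
               calcification = character(0), spiculated = logical(0),
               upper_lobe = logical(0), d_longest_axial = numeric(0),
               d_perp_axial = numeric(0), d_mean3d = numeric(0),
               malignant = logical(0)))
  if (np == 0L) return(empty)

  with_seed(derive_seed(seed, "cohort-generation"), {
    cancer <- stats::runif(np) < config$cancer_prevalence
    grp <- ifelse(cancer, "malignant", "benign")
    part <- data.frame(
      participant_id = sprintf("P%04d", seq_len(np)),
      age = round(rnorm_trunc(np, config$age_mean[grp], config$age_sd[grp],
                              49, 80)),
      sex = ifelse(stats::runif(np) < config$p_female[grp],
                   "female", "male"),
      family_history_lung_cancer =
        stats::runif(np) < config$p_family_history[grp],
      emphysema = stats::runif(np) < config$p_emphysema[grp],
      stringsAsFactors = FALSE)

    n_extra <- pmin(stats::rpois(np, config$extra_nodule_mean[grp]), 5L)
    # every participant carries at least one nodule; for cancer
    # participants that nodule is the malignant one
    n_benign <- n_extra + ifelse(cancer, 0L, 1L)

    mal <- draw_nodules(sum(cancer), TRUE, config)
    mal$participant_id <- part$participant_id[cancer]
    ben <- draw_nodules(sum(n_benign), FALSE, config)
    ben$participant_id <- rep(part$participant_id, n_benign)
    nod <- rbind(mal, ben)
    nod <- nod[order(nod$participant_id, !nod$malignant), , drop = FALSE]
    nod$nodule_id <- sprintf("N%05d", seq_len(nrow(nod)))
    nodule_cohort(part, nod)
  })
}
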