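#' Load PanCan model coefficients
#'
#' The PanCan (Brock) malignancy-risk model is a logistic regression on
#' subject and nodule covariates.  Its coefficients are not hard-coded:
#' they are read from a JSON (or YAML) configuration so alternative
#' parameterizations can be swapped in.  The bundled default,
#' `pancan_model2b.json`, carries the published full-model-with-spiculation
#' coefficients (McWilliams et al. 2013) and documents their provenance.
#'
#' Required fields (all on the log-odds scale unless noted):
#' `intercept`, `beta_age` (per year) with `age_center`,
#' `beta_sex_female`, `beta_family_history`, `beta_emphysema`,
#' `beta_size` with `size_transform` (a list with `type = "power"`,
#' `scale_mm`, `power`, `offset`: the size covariate is
#' `(d/scale_mm)^power - offset`), `beta_nonsolid`, `beta_partsolid`,
#' `beta_upper_lobe`, `beta_count` with `count_center` and
#' `count_variable` (`"total"` counts the nodule itself plus the
#' additional nodules on the scan; `"additional"` counts only the
#' additional ones), and `beta_spiculation`.
#'
#' @param path path to a JSON or YAML coefficient file; `NULL` (default)
#'   loads the bundled published set.
#' @return An object of class `pancan_coefficients`.
#' @examples
#' coef <- load_pancan_coefficients()
#' coef$beta_spiculation
#' @export
load_pancan_coefficients <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pancan_model2b.json",
                        package = "nodulerisk", mustWork = TRUE)
  }
  if (!file.exists(path)) abort_usage(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort_usage("YAML coefficient files require the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  as_pancan_coefficients(raw)
}

#' @rdname load_pancan_coefficients
#' @param x a named list of coefficient values.
#' @export
as_pancan_coefficients <- function(x) {
  required <- c("intercept", "beta_age", "beta_sex_female",
                "beta_family_history", "beta_emphysema", "beta_size",
                "size_transform", "beta_nonsolid", "beta_partsolid",
                "beta_upper_lobe", "beta_count", "beta_spiculation")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort_schema(sprintf("coefficient set is missing field(s): %s",
                         paste(missing, collapse = ", ")))
  }
  x$age_center <- x$age_center %||% 0
  x$count_center <- x$count_center %||% 0
  x$count_variable <- x$count_variable %||% "additional"
  if (!x$count_variable %in% c("total", "additional")) {
    abort_schema("count_variable must be 'total' or 'additional'")
  }
  st <- x$size_transform
  if (!is.list(st) || !identical(st$type, "power") ||
      is.null(st$power) || is.null(st$scale_mm)) {
    abort_schema("size_transform must be a list with type='power', scale_mm, power (and optional offset)")
  }
  st$offset <- st$offset %||% 0
  x$size_transform <- st
  for (f in setdiff(required, "size_transform")) {
    if (!is.numeric(x[[f]]) || length(x[[f]]) != 1L || is.na(x[[f]])) {
      abort_schema(sprintf("coefficient '%s' must be a single number", f))
    }
  }
  structure(x, class = "pancan_coefficients")
}

#' @export
print.pancan_coefficients <- function(x, ...) {
  cat("PanCan model coefficients")
  if (!is.null(x$name)) cat(": ", x$name, sep = "")
  cat("\n")
  flds <- c("intercept", "beta_age", "beta_sex_female", "beta_family_history",
            "beta_emphysema", "beta_size", "beta_nonsolid", "beta_partsolid",
            "beta_upper_lobe", "beta_count", "beta_spiculation")
  for (f in flds) cat(sprintf("  %-20s % .4f\n", f, x[[f]]))
  cat(sprintf("  size covariate: (d/%g)^%g - %g\n",
              x$size_transform$scale_mm, x$size_transform$power,
              x$size_transform$offset))
  invisible(x)
}

#' PanCan nodule risk index
#'
#' Computes the continuous malignancy-risk index (percent, 0-100) of the
#' PanCan logistic model for each nodule, joining each nodule to its
#' participant's covariates.  Completely (benign-pattern) calcified
#' nodules and perifissural nodules fall outside the model's derivation
#' population and are assigned a risk index of exactly 0\%.
#'
#' @param nodules a nodules data.frame or [nodule_cohort()].
#' @param participants the participants data.frame (ignored when `nodules`
#'   is a cohort).
#' @param coeffs a `pancan_coefficients` object; `NULL` loads the bundled
#'   default.
#' @param defn size definition for the size covariate (default
#'   `"longest_c"`, the model's published definition).
#' @return Numeric vector of risk percentages in `[0, 100]`.
#' @examples
#' coh <- simulate_cohort(n_participants = 10, seed = 1)
#' pancan_risk(coh)
#' @export
pancan_risk <- function(nodules, participants = NULL, coeffs = NULL,
                        defn = "longest_c") {
  if (inherits(nodules, "nodule_cohort")) {
    participants <- nodules$participants
    nodules <- nodules$nodules
  }
  if (is.null(participants)) abort_usage("participants table is required")
  coeffs <- coeffs %||% load_pancan_coefficients()
  if (!inherits(coeffs, "pancan_coefficients")) {
    coeffs <- as_pancan_coefficients(coeffs)
  }
  if (nrow(nodules) == 0L) return(numeric(0))

  idx <- match(nodules$participant_id, participants$participant_id)
  if (anyNA(idx)) {
    abort_data(sprintf("nodule %s: unknown participant_id",
                       nodules$nodule_id[which(is.na(idx))[1L]]))
  }
  p <- participants[idx, , drop = FALSE]
  for (f in c("age", "sex", "family_history_lung_cancer", "emphysema",
              "nodule_count_additional")) {
    if (anyNA(p[[f]])) {
      abort_data(sprintf("participant %s: missing covariate '%s'",
                         p$participant_id[which(is.na(p[[f]]))[1L]], f))
    }
  }

  size <- nodule_size(nodules, defn, "whole")
  st <- coeffs$size_transform
  size_x <- (size / st$scale_mm)^st$power - st$offset
  count <- p$nodule_count_additional +
    if (coeffs$count_variable == "total") 1L else 0L

  lp <- coeffs$intercept +
    coeffs$beta_age * (p$age - coeffs$age_center) +
    coeffs$beta_sex_female * (p$sex == "female") +
    coeffs$beta_family_history * p$family_history_lung_cancer +
    coeffs$beta_emphysema * p$emphysema +
    coeffs$beta_size * size_x +
    coeffs$beta_nonsolid * (nodules$type == "ground_glass") +
    coeffs$beta_partsolid * (nodules$type == "part_solid") +
    coeffs$beta_upper_lobe * nodules$upper_lobe +
    coeffs$beta_count * (count - coeffs$count_center) +
    coeffs$beta_spiculation * nodules$spiculated

  risk <- 100 * stats::plogis(lp)
  risk[nodules$calcification == "benign_pattern" | nodules$is_pfn] <- 0
  risk
}

#' PanCan risk categories
#'
#' Maps the continuous nodule risk index to the four published management
#' categories: `<1.5%` -> 1, `[1.5, 6)%` -> 2, `[6, 30)%` -> 3,
#' `>=30%` -> 4.  All bands are closed on the left.
#'
#' @param risk_percent numeric vector of risk indices in `[0, 100]`.
#' @return Character vector of category labels `"1"`..`"4"`.
#' @examples
#' pancan_category(c(0, 1.5, 5.9, 6, 29.9, 30))
#' @export
pancan_category <- function(risk_percent) {
  if (length(risk_percent) &&
      (anyNA(risk_percent) || any(risk_percent < 0 | risk_percent > 100))) {
    abort_data("risk_percent must lie in [0, 100]")
  }
  as.character(findInterval(risk_percent, c(1.5, 6, 30)) + 1L)
}
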