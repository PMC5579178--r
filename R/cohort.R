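#' @title Cohort container for screen-detected pulmonary nodules
#'
#' @description
#' A `nodule_cohort` bundles two tables: one row per participant
#' (subject-level covariates used by the PanCan risk model plus cancer
#' status) and one row per nodule (morphology, calcification, size
#' measurements and the malignancy label).  All scoring and analysis
#' functions in the package consume this container.
#'
#' @details
#' Participant columns:
#' \describe{
#'   \item{participant_id}{unique identifier.}
#'   \item{age}{years.}
#'   \item{sex}{`"male"` or `"female"`.}
#'   \item{family_history_lung_cancer}{logical; first-degree relatives.}
#'   \item{emphysema}{logical; presence on the scan, dichotomous.}
#'   \item{nodule_count_additional}{number of additional nodules on the
#'     scan beyond the one being scored; derived as (number of linked
#'     nodules - 1) when absent.}
#'   \item{has_cancer}{logical; must equal "any linked nodule is
#'     malignant" and is derived when absent.}
#' }
#'
#' Nodule columns:
#' \describe{
#'   \item{nodule_id, participant_id}{identifiers; every nodule must link
#'     to a participant.}
#'   \item{type}{`"solid"`, `"part_solid"` or `"ground_glass"` (pure
#'     ground-glass / non-solid).}
#'   \item{is_pfn}{logical; perifissural nodule.  PFNs are solid by
#'     definition, so `is_pfn` implies `type == "solid"`.}
#'   \item{calcification}{`"none"`, `"benign_pattern"` (complete, central,
#'     popcorn or concentric rings) or `"other"`.}
#'   \item{spiculated, upper_lobe, malignant}{logicals.}
#'   \item{d_longest_axial, d_perp_axial}{longest and perpendicular
#'     diameter on axial sections, mm; perpendicular cannot exceed
#'     longest.}
#'   \item{d_mean3d}{volumetric mean diameter, mm: the diameter of the
#'     sphere best matching the nodule's three-dimensional extent.  May be
#'     omitted when `volume` is given, in which case it is derived as the
#'     volume-equivalent-sphere diameter.}
#'   \item{volume}{segmented volume, mm^3 (optional if `d_mean3d` given).
#'     If both are present they must agree within 1\% relative tolerance.}
#'   \item{d_longest_axial_solid, d_perp_axial_solid, d_mean3d_solid}{the
#'     same measurements for the solid component; required for part-solid
#'     nodules, must not exceed the whole-nodule counterparts, and must be
#'     absent for other types.}
#' }
#'
#' Units are fixed: millimetres for diameters, cubic millimetres for
#' volumes.  No unit auto-detection is attempted; malformed input fails
#' loudly with a row-level message naming the offending `nodule_id`.
#'
#' @param participants data.frame of participant covariates (see Details).
#' @param nodules data.frame of per-nodule measurements (see Details).
#' @param validate logical; run full invariant validation (default `TRUE`).
#' @return An object of class `nodule_cohort`: a list with elements
#'   `participants` and `nodules`.
#' @examples
#' coh <- simulate_cohort(n_participants = 20, seed = 1)
#' coh
#' nrow(nodules(coh))
#' @seealso [read_cohort()], [write_cohort()], [simulate_cohort()]
#' @export
nodule_cohort <- function(participants, nodules, validate = TRUE) {
  participants <- as.data.frame(participants, stringsAsFactors = FALSE)
  nodules <- as.data.frame(nodules, stringsAsFactors = FALSE)
  check_columns(participants, setdiff(participant_columns(),
                                      c("nodule_count_additional", "has_cancer")),
                "participants")
  check_columns(nodules, setdiff(nodule_columns(),
                                 c("d_mean3d", "volume",
                                   "d_longest_axial_solid",
                                   "d_perp_axial_solid", "d_mean3d_solid")),
                "nodules")
  for (col in setdiff(nodule_columns(), names(nodules))) {
    nodules[[col]] <- rep(NA_real_, nrow(nodules))
  }
  if (!"nodule_count_additional" %in% names(participants)) {
    participants$nodule_count_additional <- rep(NA_integer_, nrow(participants))
  }
  if (!"has_cancer" %in% names(participants)) {
    participants$has_cancer <- rep(NA, nrow(participants))
  }
  participants <- coerce_participant_types(participants)
  nodules <- coerce_nodule_types(nodules)

  # Derived fields ------------------------------------------------------
  n_per_part <- table(nodules$participant_id)
  linked <- as.integer(n_per_part[participants$participant_id])
  linked[is.na(linked)] <- 0L
  derived_count <- pmax(linked - 1L, 0L)
  missing_count <- is.na(participants$nodule_count_additional)
  participants$nodule_count_additional[missing_count] <-
    derived_count[missing_count]

  derived_cancer <- derive_has_cancer(participants, nodules)
  missing_cancer <- is.na(participants$has_cancer)
  participants$has_cancer[missing_cancer] <- derived_cancer[missing_cancer]

  # Derive volumetric mean diameter from volume where only the volume was
  # measured; check consistency where both are present.
  only_vol <- is.na(nodules$d_mean3d) & !is.na(nodules$volume)
  nodules$d_mean3d[only_vol] <- mean3d_from_volume(nodules$volume[only_vol])

  participants <- participants[, participant_columns(), drop = FALSE]
  nodules <- nodules[, nodule_columns(), drop = FALSE]
  rownames(participants) <- NULL
  rownames(nodules) <- NULL
  out <- structure(list(participants = participants, nodules = nodules),
                   class = "nodule_cohort")
  if (validate) validate_cohort(out)
  out
}

participant_columns <- function() {
  c("participant_id", "age", "sex", "family_history_lung_cancer",
    "emphysema", "nodule_count_additional", "has_cancer")
}

nodule_columns <- function() {
  c("nodule_id", "participant_id", "type", "is_pfn", "calcification",
    "spiculated", "upper_lobe", "d_longest_axial", "d_perp_axial",
    "d_mean3d", "volume", "d_longest_axial_solid", "d_perp_axial_solid",
    "d_mean3d_solid", "malignant")
}

derive_has_cancer <- function(participants, nodules) {
  if (nrow(nodules) == 0L) return(rep(FALSE, nrow(participants)))
  mal_by_part <- tapply(nodules$malignant, nodules$participant_id, any)
  derived <- as.logical(mal_by_part[participants$participant_id])
  derived[is.na(derived)] <- FALSE
  derived
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort_schema(sprintf("%s table is missing required column(s): %s",
                         what, paste(missing, collapse = ", ")))
  }
}

coerce_participant_types <- function(p) {
  p$participant_id <- as.character(p$participant_id)
  p$age <- as.numeric(p$age)
  p$sex <- tolower(as.character(p$sex))
  for (col in c("family_history_lung_cancer", "emphysema", "has_cancer")) {
    p[[col]] <- as.logical(p[[col]])
  }
  p$nodule_count_additional <- as.integer(p$nodule_count_additional)
  p
}

coerce_nodule_types <- function(n) {
  n$nodule_id <- as.character(n$nodule_id)
  n$participant_id <- as.character(n$participant_id)
  n$type <- tolower(as.character(n$type))
  n$calcification <- tolower(as.character(n$calcification))
  for (col in c("is_pfn", "spiculated", "upper_lobe", "malignant")) {
    n[[col]] <- as.logical(n[[col]])
  }
  for (col in c("d_longest_axial", "d_perp_axial", "d_mean3d", "volume",
                "d_longest_axial_solid", "d_perp_axial_solid",
                "d_mean3d_solid")) {
    n[[col]] <- as.numeric(n[[col]])
  }
  n
}

#' Validate a nodule cohort against its invariants
#'
#' Checks referential integrity between participants and nodules, value
#' domains, measurement-ordering invariants (perpendicular <= longest;
#' solid component <= whole nodule for part-solid), PFN implies solid,
#' volume/diameter consistency, and agreement between `has_cancer` and the
#' nodule-level malignancy labels.  Errors name the first offending
#' nodule or participant.
#'
#' @param cohort a [nodule_cohort()].
#' @return `cohort`, invisibly, when valid; otherwise an error of class
#'   `nodulerisk_data_error`.
#' @export
validate_cohort <- function(cohort) {
  p <- cohort$participants
  n <- cohort$nodules

  if (anyDuplicated(p$participant_id)) {
    abort_data("duplicate participant_id in participants table")
  }
  if (anyDuplicated(n$nodule_id)) {
    abort_data("duplicate nodule_id in nodules table")
  }
  orphan <- setdiff(n$participant_id, p$participant_id)
  if (length(orphan)) {
    abort_data(sprintf("nodule rows reference unknown participant_id: %s",
                       paste(utils::head(orphan, 3L), collapse = ", ")))
  }

  bad_sex <- !p$sex %in% c("male", "female")
  if (any(bad_sex)) {
    abort_data(sprintf("participant %s: sex must be 'male' or 'female'",
                       p$participant_id[which(bad_sex)[1L]]))
  }
  bad_age <- !is.finite(p$age) | p$age <= 0
  if (any(bad_age)) {
    abort_data(sprintf("participant %s: age must be a positive number",
                       p$participant_id[which(bad_age)[1L]]))
  }
  bad_cnt <- is.na(p$nodule_count_additional) | p$nodule_count_additional < 0L
  if (any(bad_cnt)) {
    abort_data(sprintf("participant %s: nodule_count_additional must be >= 0",
                       p$participant_id[which(bad_cnt)[1L]]))
  }
  for (col in c("family_history_lung_cancer", "emphysema", "has_cancer")) {
    if (anyNA(p[[col]])) {
      abort_data(sprintf("participant %s: %s must be TRUE/FALSE",
                         p$participant_id[which(is.na(p[[col]]))[1L]], col))
    }
  }

  if (nrow(n)) {
    fail <- function(idx, msg) {
      abort_data(sprintf("nodule %s: %s", n$nodule_id[idx[1L]], msg))
    }
    bad <- !n$type %in% c("solid", "part_solid", "ground_glass")
    if (any(bad)) fail(which(bad), "type must be solid/part_solid/ground_glass")
    bad <- !n$calcification %in% c("none", "benign_pattern", "other")
    if (any(bad)) fail(which(bad), "calcification must be none/benign_pattern/other")
    for (col in c("is_pfn", "spiculated", "upper_lobe", "malignant")) {
      if (anyNA(n[[col]])) fail(which(is.na(n[[col]])), paste(col, "must be TRUE/FALSE"))
    }
    bad <- !is.finite(n$d_longest_axial) | n$d_longest_axial <= 0
    if (any(bad)) fail(which(bad), "d_longest_axial must be > 0")
    bad <- !is.finite(n$d_perp_axial) | n$d_perp_axial <= 0
    if (any(bad)) fail(which(bad), "d_perp_axial must be > 0")
    bad <- n$d_perp_axial > n$d_longest_axial
    if (any(bad)) fail(which(bad), "d_perp_axial exceeds d_longest_axial")

    bad <- is.na(n$d_mean3d) & is.na(n$volume)
    if (any(bad)) fail(which(bad), "one of d_mean3d or volume is required")
    bad <- (!is.na(n$d_mean3d) & n$d_mean3d <= 0) |
      (!is.na(n$volume) & n$volume <= 0)
    if (any(bad)) fail(which(bad), "d_mean3d and volume must be > 0")
    both <- !is.na(n$d_mean3d) & !is.na(n$volume)
    if (any(both)) {
      implied <- mean3d_from_volume(n$volume[both])
      off <- abs(implied - n$d_mean3d[both]) / n$d_mean3d[both] > 0.01
      if (any(off)) {
        fail(which(both)[off],
             "volume and d_mean3d disagree beyond 1% relative tolerance")
      }
    }

    bad <- n$is_pfn & n$type != "solid"
    if (any(bad)) fail(which(bad), "perifissural nodules must have type 'solid'")

    ps <- n$type == "part_solid"
    solid_cols <- c("d_longest_axial_solid", "d_perp_axial_solid",
                    "d_mean3d_solid")
    whole_cols <- c("d_longest_axial", "d_perp_axial", "d_mean3d")
    for (k in seq_along(solid_cols)) {
      s <- n[[solid_cols[k]]]
      bad <- ps & (is.na(s) | s <= 0)
      if (any(bad)) {
        fail(which(bad),
             sprintf("part-solid nodules require %s > 0", solid_cols[k]))
      }
      bad <- ps & !is.na(s) & s > n[[whole_cols[k]]]
      if (any(bad)) {
        fail(which(bad),
             sprintf("%s exceeds its whole-nodule counterpart", solid_cols[k]))
      }
      bad <- !ps & !is.na(s)
      if (any(bad)) {
        fail(which(bad),
             sprintf("%s must be absent for non-part-solid nodules", solid_cols[k]))
      }
    }
  }

  bad <- p$has_cancer != derive_has_cancer(p, n)
  if (any(bad)) {
    abort_data(sprintf(
      "participant %s: has_cancer disagrees with nodule malignancy labels",
      p$participant_id[which(bad)[1L]]))
  }
  invisible(cohort)
}

#' @export
print.nodule_cohort <- function(x, ...) {
  n <- x$nodules
  cat(sprintf(
    "nodule_cohort: %d participants (%d with cancer), %d nodules (%d malignant)\n",
    nrow(x$participants), sum(x$participants$has_cancer),
    nrow(n), sum(n$malignant)))
  if (nrow(n)) {
    tp <- table(factor(n$type, c("solid", "part_solid", "ground_glass")))
    cat(sprintf("  type: solid %d, part-solid %d, ground-glass %d\n",
                tp[[1L]], tp[[2L]], tp[[3L]]))
    cat(sprintf("  median d_longest_axial: %.1f mm (malignant %.1f, benign %.1f)\n",
                stats::median(n$d_longest_axial),
                if (any(n$malignant)) stats::median(n$d_longest_axial[n$malignant]) else NA,
                if (any(!n$malignant)) stats::median(n$d_longest_axial[!n$malignant]) else NA))
  }
  invisible(x)
}

#' Accessors for the two tables of a cohort
#'
#' @param cohort a [nodule_cohort()].
#' @return The participants or nodules data.frame.
#' @export
participants <- function(cohort) cohort$participants

#' @rdname participants
#' @export
nodules <- function(cohort) cohort$nodules

#' Read a nodule cohort from CSV/TSV
#'
#' Two layouts are supported.  With `participants_path = NULL`, `path` is
#' a single flat file with one nodule per row and the participant
#' covariates repeated on each row.  With `participants_path` given,
#' `path` holds only nodule columns and the participant table is read from
#' the second file.  Files are comma-separated (`dialect = "csv"`) or
#' tab-separated (`dialect = "tsv"`), UTF-8, `.` decimal separator.
#'
#' @param path path to the nodule (or flat) file.
#' @param dialect `"csv"` or `"tsv"`.
#' @param participants_path optional path to a separate participants file.
#' @return A validated [nodule_cohort()].
#' @export
read_cohort <- function(path, dialect = c("csv", "tsv"),
                        participants_path = NULL) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  if (!file.exists(path)) abort_usage(sprintf("file not found: %s", path))
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""),
                           colClasses = NA, fileEncoding = "UTF-8")
  if (is.null(participants_path)) {
    check_columns(raw, setdiff(union(nodule_columns(), participant_columns()),
                               c("d_mean3d", "volume", "d_longest_axial_solid",
                                 "d_perp_axial_solid", "d_mean3d_solid",
                                 "nodule_count_additional", "has_cancer")),
                  "flat cohort")
    pcols <- intersect(participant_columns(), names(raw))
    part <- unique(raw[, pcols, drop = FALSE])
    if (anyDuplicated(part$participant_id)) {
      abort_data("participant covariates differ across rows of the same participant_id")
    }
    nod <- raw[, intersect(nodule_columns(), names(raw)), drop = FALSE]
  } else {
    if (!file.exists(participants_path)) {
      abort_usage(sprintf("file not found: %s", participants_path))
    }
    part <- utils::read.table(participants_path, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE,
                              na.strings = c("NA", ""),
                              fileEncoding = "UTF-8")
    nod <- raw
  }
  nodule_cohort(part, nod)
}

#' Write a nodule cohort to CSV/TSV
#'
#' The inverse of [read_cohort()]: writes either a single flat file
#' (participant covariates repeated per nodule row) or, when
#' `participants_path` is given, separate nodule and participant files.
#' Column order is fixed and numeric values are written with full
#' precision, so `read_cohort(write_cohort(x))` reproduces `x` exactly and
#' repeated writes are byte-identical.
#'
#' @inheritParams read_cohort
#' @param cohort a validated [nodule_cohort()].
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, dialect = c("csv", "tsv"),
                         participants_path = NULL) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  stopifnot(inherits(cohort, "nodule_cohort"))
  fmt <- function(df) {
    for (col in names(df)) {
      if (is.numeric(df[[col]]) && !is.integer(df[[col]])) {
        v <- df[[col]]
        df[[col]] <- ifelse(is.na(v), NA, sprintf("%.17g", v))
      }
    }
    df
  }
  write_one <- function(df, p) {
    con <- file(p, open = "wb")
    on.exit(close(con))
    utils::write.table(fmt(df), con, sep = sep, row.names = FALSE,
                       quote = FALSE, na = "", eol = "\n",
                       fileEncoding = "UTF-8")
  }
  if (is.null(participants_path)) {
    flat <- merge(cohort$nodules, cohort$participants, by = "participant_id",
                  sort = FALSE)
    flat <- flat[order(match(flat$nodule_id, cohort$nodules$nodule_id)), ,
                 drop = FALSE]
    flat <- flat[, c(nodule_columns(),
                     setdiff(participant_columns(), "participant_id")),
                 drop = FALSE]
    write_one(flat, path)
  } else {
    write_one(cohort$nodules, path)
    write_one(cohort$participants, participants_path)
  }
  invisible(path)
}
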