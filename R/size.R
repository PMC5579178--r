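#' Nodule size definitions
#'
#' Three interchangeable definitions of nodule diameter are used by the
#' scoring systems:
#' \describe{
#'   \item{`"longest_c"`}{longest diameter on axial sections, from
#'     semi-automated segmentation (also accepts `"longest_m"` for
#'     manually measured longest diameters stored in the same field).}
#'   \item{`"mean3d"`}{volumetric mean diameter: the diameter of the
#'     sphere best matching the nodule's extent in all three dimensions.}
#'   \item{`"mean_axial"`}{mean of the longest and perpendicular diameter
#'     on axial sections.}
#' }
#' By default the PanCan model uses `"longest_c"`, Lung-RADS `"mean3d"`
#' and NCCN `"mean_axial"`; any system can be re-run under any definition
#' for sensitivity analysis.
#'
#' @name size_definitions
#' @keywords internal
NULL

size_definitions <- function() c("longest_c", "longest_m", "mean3d", "mean_axial")

match_size_definition <- function(defn) {
  defn <- tolower(as.character(defn))
  if (length(defn) != 1L || !defn %in% size_definitions()) {
    abort_usage(sprintf(
      "unknown size definition '%s' (use one of %s)", defn,
      paste(size_definitions(), collapse = ", ")))
  }
  defn
}

#' Volume-equivalent-sphere diameter
#'
#' Converts a segmented volume to the volumetric mean diameter: the
#' diameter of the sphere with the same volume, \eqn{d = (6V/\pi)^{1/3}}.
#'
#' @param volume nodule volume(s) in mm^3; must be positive.
#' @return Diameter(s) in mm.
#' @examples
#' mean3d_from_volume(pi / 6 * 1000)  # 10 mm sphere
#' @export
mean3d_from_volume <- function(volume) {
  if (length(volume) && (anyNA(volume) || any(volume <= 0))) {
    abort_data("volume must be positive")
  }
  (6 * volume / pi)^(1 / 3)
}

#' Mean axial diameter
#'
#' Arithmetic mean of the longest and perpendicular diameters measured on
#' axial sections.
#'
#' @param d_longest longest axial diameter, mm.
#' @param d_perp perpendicular axial diameter, mm; must satisfy
#'   `0 < d_perp <= d_longest`.
#' @return Mean diameter(s) in mm.
#' @examples
#' mean_axial(16.6, 13.4)
#' @export
mean_axial <- function(d_longest, d_perp) {
  if (length(d_longest) &&
      (anyNA(d_longest) || anyNA(d_perp) ||
       any(d_perp <= 0) || any(d_perp > d_longest))) {
    abort_data("require 0 < d_perp <= d_longest")
  }
  (d_longest + d_perp) / 2
}

#' Nodule size under a chosen definition
#'
#' Dispatches to the stored or derived measurement for the requested size
#' definition, for either the whole nodule or (part-solid nodules only)
#' its solid component.  Diameters are returned at full precision;
#' rounding, where a scoring system requires it, is that system's
#' responsibility.
#'
#' @param nodules a nodules data.frame (see [nodule_cohort()]) or a cohort.
#' @param defn one of `"longest_c"`, `"longest_m"`, `"mean3d"`,
#'   `"mean_axial"`.
#' @param component `"whole"` or `"solid"`; `"solid"` is only valid for
#'   part-solid nodules.
#' @return Numeric vector of diameters in mm, one per nodule row.
#' @export
nodule_size <- function(nodules, defn, component = c("whole", "solid")) {
  if (inherits(nodules, "nodule_cohort")) nodules <- nodules$nodules
  defn <- match_size_definition(defn)
  component <- match.arg(component)
  if (component == "solid") {
    bad <- nodules$type != "part_solid"
    if (any(bad)) {
      abort_usage(sprintf(
        "solid-component size requested for non-part-solid nodule %s",
        nodules$nodule_id[which(bad)[1L]]))
    }
  }
  pick <- function(whole, solid) {
    v <- if (component == "whole") nodules[[whole]] else nodules[[solid]]
    if (anyNA(v)) {
      abort_data(sprintf("nodule %s: missing measurement for %s (%s)",
                         nodules$nodule_id[which(is.na(v))[1L]],
                         defn, component))
    }
    v
  }
  switch(defn,
    longest_c = ,
    longest_m = pick("d_longest_axial", "d_longest_axial_solid"),
    mean3d = pick("d_mean3d", "d_mean3d_solid"),
    mean_axial = {
      if (component == "whole") {
        mean_axial(pick("d_longest_axial", NULL),
                   nodules$d_perp_axial)
      } else {
        mean_axial(nodules$d_longest_axial_solid,
                   nodules$d_perp_axial_solid)
      }
    }
  )
}
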