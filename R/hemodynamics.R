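#' Fractional velocity reduction at a single bend
#'
#' When the flow axis deviates by `theta`, only the axial component of the
#' velocity vector survives, so the centre-line velocity drops by a factor
#' `cos(theta)`; the fractional reduction is `1 - cos(theta)`.  The model is
#' undefined at 90 degrees and beyond (the cosine would stop being a positive
#' velocity fraction), so such angles are rejected.
#'
#' @param theta_deg Bend angle(s) in degrees, each in `[0, 90)`.
#' @return The fractional reduction(s) in `[0, 1)`; `0` at `0` degrees,
#'   `0.134` at 30 degrees, `0.5` at 60 degrees.
#' @examples
#' velocity_reduction(c(0, 30, 60))
#' @export
velocity_reduction <- function(theta_deg) {
  check_angle(theta_deg)
  1 - cospi(theta_deg / 180)
}

check_angle <- function(theta_deg, what = "bend angle") {
  if (length(theta_deg) > 0 &&
      (anyNA(theta_deg) || any(theta_deg < 0 | theta_deg >= 90))) {
    abort(paste0(what, " must lie in [0, 90) degrees"),
          class = "carotidflow_domain_error")
  }
  invisible(theta_deg)
}

#' Cumulative velocity factor over a cascade of bends
#'
#' In a multi-bend (S-shaped, tortuous) vessel each bend attenuates the
#' velocity by its own cosine, so after traversing bends `theta_1 .. theta_k`
#' the remaining fraction of the inflow velocity is `prod(cos(theta_i))`.
#' The product is commutative: the order the bends are met in does not change
#' the remaining fraction.
#'
#' @param angles_deg Angles (degrees, each in `[0, 90)`) of the bends
#'   traversed, in any order; an empty vector means no bends.
#' @return The remaining velocity fraction in `(0, 1]`.
#' @examples
#' cumulative_velocity_factor(c(20, 51, 52, 60, 30)) # ~0.16
#' cumulative_velocity_factor(c(28, 48))             # ~0.59
#' @export
cumulative_velocity_factor <- function(angles_deg) {
  check_angle(angles_deg)
  prod(cospi(angles_deg / 180))
}

#' Cross-sectional area of a vessel
#'
#' @param radius_mm Lumen radius/radii in millimetres, `> 0`.
#' @return A tibble with `radius_mm`, `area_mm2` and `area_cm2`
#'   (`pi * r^2` in each unit system; the cm^2 value feeds the stress index,
#'   the mm^2 value matches how section tables report area).
#' @examples
#' cross_sectional_area(c(10, 5, 1.5))
#' @export
cross_sectional_area <- function(radius_mm) {
  check_radius(radius_mm)
  tibble::tibble(
    radius_mm = radius_mm,
    area_mm2 = pi * radius_mm^2,
    area_cm2 = pi * (radius_mm / 10)^2
  )
}

check_radius <- function(radius_mm) {
  if (length(radius_mm) == 0 || anyNA(radius_mm) || any(radius_mm <= 0)) {
    abort("radius must be a positive length",
          class = "carotidflow_domain_error")
  }
  invisible(radius_mm)
}

#' Drag (wall shear) stress index of a segment
#'
#' The stress exerted on the endothelium scales as the driving force over the
#' cross-sectional area; with the force fixed by the pumping heart, the
#' stress at a segment is the remaining velocity fraction divided by the
#' area in cm^2, expressed as a dimensionless multiple of the cardiac driving
#' force per cm^2.  Low values mark candidate atherosclerosis-prone sites.
#'
#' @param cum_velocity_factor Remaining velocity fraction(s) in `(0, 1]`.
#' @param radius_mm Lumen radius/radii in millimetres.
#' @return Stress index (multiples of the driving force per cm^2).
#' @examples
#' drag_stress(1, 8.5)                                    # ~0.44
#' drag_stress(cumulative_velocity_factor(20), 5.0)       # ~1.20
#' @export
drag_stress <- function(cum_velocity_factor, radius_mm) {
  check_radius(radius_mm)
  if (anyNA(cum_velocity_factor) || any(cum_velocity_factor <= 0) ||
      any(cum_velocity_factor > 1)) {
    abort("cum_velocity_factor must lie in (0, 1]",
          class = "carotidflow_domain_error")
  }
  cum_velocity_factor / (pi * (radius_mm / 10)^2)
}

#' Split a volumetric flow between daughter branches
#'
#' At a bifurcation the flow volume per second divides between the daughter
#' vessels in the ratio of their cross-sectional areas, so each daughter
#' receives `inflow * r_i^2 / sum(r_j^2)`.  Volume is conserved exactly: the
#' returned rates sum to `inflow`.
#'
#' @param child_radii_mm Radii (mm) of the daughter vessels; at least two.
#' @param inflow Volumetric inflow rate (any unit), `> 0`.  Default 1 gives
#'   the flow fractions.
#' @return Numeric vector of daughter flow rates, same order as the radii.
#' @examples
#' flow_split(c(5.0, 5.5)) # external vs internal carotid fractions
#' @export
flow_split <- function(child_radii_mm, inflow = 1) {
  if (length(child_radii_mm) < 2) {
    abort("a bifurcation needs at least two daughter radii",
          class = "carotidflow_domain_error")
  }
  check_radius(child_radii_mm)
  if (length(inflow) != 1 || is.na(inflow) || inflow <= 0) {
    abort("inflow must be a single positive rate",
          class = "carotidflow_domain_error")
  }
  w <- child_radii_mm^2
  rates <- inflow * w / sum(w)
  # pin the last share so the sum is exact, not merely within rounding
  rates[length(rates)] <- inflow - sum(rates[-length(rates)])
  rates
}

#' Hemodynamic profile of every segment in a tree
#'
#' Walks each root-to-segment path and accumulates the cosine attenuation of
#' every bend traversed — a bend's own cosine applies at the bend's own
#' section (inclusive convention), an `upstream_angle_deg` applies just before
#' its segment, and bifurcations contribute no cosine (their effect enters
#' through radius/area and [flow_split()] only).  The stress index divides
#' the cumulative velocity factor by the cross-sectional area in cm^2, using
#' `stress_radius_mm` where a documented override is present.
#'
#' @param tree A validated [arterial_tree()].
#' @return A `stress_profile`: a tibble with one row per segment —
#'   `segment_id`, `kind`, `radius_mm`, `effective_radius_mm`, `area_mm2`,
#'   `area_cm2`, `cum_velocity_factor`, `stress_index` (multiples of the
#'   cardiac driving force per cm^2) and `stokes_index`
#'   (`cum_velocity_factor / radius_cm`, the velocity-over-radius
#'   proportionality on a relative scale).
#' @examples
#' profile_tree(carotid_fixture()$tree)
#' @export
profile_tree <- function(tree) {
  validate_tree(tree)
  seg <- tibble::as_tibble(tree)
  parent <- setNames(seg$parent_id, seg$id)
  own_factor <- function(i) {
    f <- 1
    if (!is.na(seg$upstream_angle_deg[i])) {
      check_angle(seg$upstream_angle_deg[i], "upstream angle")
      f <- f * cospi(seg$upstream_angle_deg[i] / 180)
    }
    if (seg$kind[i] == "bend") {
      f <- f * cospi(seg$bend_angle_deg[i] / 180)
    }
    f
  }
  factors <- setNames(rep(NA_real_, nrow(seg)), seg$id)
  cum_factor <- function(id) {
    if (!is.na(factors[[id]])) return(factors[[id]])
    i <- match(id, seg$id)
    f <- own_factor(i)
    p <- parent[[id]]
    if (!is.na(p)) f <- f * cum_factor(p)
    factors[[id]] <<- f
    f
  }
  cvf <- purrr::map_dbl(seg$id, cum_factor)
  r_eff <- dplyr::coalesce(seg$stress_radius_mm, seg$radius_mm)
  area <- cross_sectional_area(r_eff)
  out <- tibble::tibble(
    segment_id = seg$id,
    kind = seg$kind,
    radius_mm = seg$radius_mm,
    effective_radius_mm = r_eff,
    area_mm2 = area$area_mm2,
    area_cm2 = area$area_cm2,
    cum_velocity_factor = cvf,
    stress_index = drag_stress(cvf, r_eff),
    stokes_index = cvf / (r_eff / 10)
  )
  tibble::new_tibble(out, class = "stress_profile")
}

#' Site-risk classification rule
#'
#' The model flags a site as atherosclerosis-prone when its drag-stress index
#' is low.  Two modes:
#' * `"relative"` (default): prone when the stress index falls below a
#'   quantile (default the median) of the stress indices of the tree's
#'   *straight* segments — the within-tree baseline of undisturbed flow.
#'   If a tree has no straight segment the quantile is taken over all
#'   segments.
#' * `"absolute"`: prone when the physical wall shear stress falls below
#'   `threshold_dynes` (default 5 dynes/cm^2, the conventional boundary
#'   between undisturbed arterial shear, around 15 dynes/cm^2, and disturbed
#'   low shear).  Requires `f_d_dynes`, the calibration of one stress-index
#'   unit in dynes/cm^2.
#'
#' Bends, bifurcations and wide segments are all judged by the same stress
#' criterion, not by their kind.
#'
#' @param mode `"relative"` or `"absolute"`.
#' @param quantile Baseline quantile for relative mode, in `[0, 1]`.
#' @param f_d_dynes Calibration (dynes/cm^2 per stress-index unit) for
#'   absolute mode.
#' @param threshold_dynes Absolute low-shear boundary, dynes/cm^2.
#' @return A `risk_rule` object.
#' @seealso [classify_sites()]
#' @export
risk_rule <- function(mode = c("relative", "absolute"), quantile = 0.5,
                      f_d_dynes = NULL, threshold_dynes = 5) {
  mode <- match.arg(mode)
  if (length(quantile) != 1 || is.na(quantile) || quantile < 0 || quantile > 1) {
    abort("quantile must lie in [0, 1]", class = "carotidflow_domain_error")
  }
  if (mode == "absolute") {
    if (is.null(f_d_dynes) || !is.numeric(f_d_dynes) || f_d_dynes <= 0) {
      abort("absolute mode needs a positive f_d_dynes calibration",
            class = "carotidflow_domain_error")
    }
  }
  structure(list(mode = mode, quantile = quantile, f_d_dynes = f_d_dynes,
                 threshold_dynes = threshold_dynes),
            class = "risk_rule")
}

#' Coerce a configuration block to a risk rule
#'
#' Accepts a [risk_rule()], a plain list (e.g. parsed from a JSON/YAML
#' configuration block with keys `mode`, `quantile`, `f_d_dynes`,
#' `threshold_dynes`), or a path to a `.json`/`.yaml` file holding one.
#'
#' @param x Rule, list, or file path.
#' @return A validated `risk_rule`.
#' @export
as_risk_rule <- function(x) {
  if (inherits(x, "risk_rule")) return(x)
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) {
      abort(paste0("no such rule file: ", x), class = "carotidflow_io_error")
    }
    x <- if (grepl("\\.ya?ml$", x, ignore.case = TRUE)) {
      yaml::read_yaml(x)
    } else {
      jsonlite::fromJSON(x)
    }
  }
  if (!is.list(x)) {
    abort("cannot interpret risk-rule configuration",
          class = "carotidflow_domain_error")
  }
  known <- c("mode", "quantile", "f_d_dynes", "threshold_dynes")
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown risk-rule key(s): ", paste(unknown, collapse = ", ")),
          class = "carotidflow_domain_error")
  }
  do.call(risk_rule, x)
}

#' Flag atherosclerosis-prone sites by low drag stress
#'
#' @param profiles A `stress_profile` from [profile_tree()].
#' @param rule A [risk_rule()] (or anything [as_risk_rule()] accepts).
#' @return The profile tibble with `threshold` and logical `prone` columns.
#' @examples
#' classify_sites(profile_tree(carotid_fixture()$tree))
#' @export
classify_sites <- function(profiles, rule = risk_rule()) {
  if (!is.data.frame(profiles) || nrow(profiles) == 0) {
    abort("profiles must be a non-empty stress profile",
          class = "carotidflow_domain_error")
  }
  rule <- as_risk_rule(rule)
  if (rule$mode == "relative") {
    base <- profiles$stress_index[profiles$kind == "straight"]
    if (length(base) == 0) base <- profiles$stress_index
    thr <- unname(quantile(base, rule$quantile, type = 7))
  } else {
    thr <- rule$threshold_dynes / rule$f_d_dynes
  }
  out <- dplyr::mutate(tibble::as_tibble(profiles),
                       threshold = thr,
                       prone = .data$stress_index < thr)
  tibble::new_tibble(out, class = "stress_profile")
}
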