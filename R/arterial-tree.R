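#' Construct an arterial tree
#'
#' An arterial tree is a rooted tree of vessel segments: one row per segment,
#' linked by `parent_id`, with exactly one root (the inflow segment, usually
#' the proximal common carotid).  Geometry is deliberately minimal — the
#' reduced-order model needs only each segment's lumen radius, its kind
#' (`straight`, `bend`, or `bifurcation`) and, for bends, the angle the flow
#' axis deviates by.
#'
#' @param segments A data frame with one row per vessel segment.  Required
#'   columns:
#'   * `id` — short unique label, e.g. `"ECA-3"`.
#'   * `kind` — one of `"straight"`, `"bend"`, `"bifurcation"`.
#'   * `radius_mm` — lumen radius in millimetres, `> 0`.
#'   * `bend_angle_deg` — flow-deviation angle in degrees, in `[0, 90)`;
#'     required for bends and must be absent (`NA`) otherwise.
#'   * `parent_id` — label of the upstream segment; `NA` marks the root.
#'
#'   Optional columns (filled with `NA` when missing):
#'   * `branch_label` — name of the artery arising at a bifurcation
#'     (e.g. `"STA"`, `"LA"`).
#'   * `upstream_angle_deg` — angle of an unsectioned bend lying between this
#'     segment and its parent; its cosine enters the cascade just before the
#'     segment's own.  Used when a bend in the vessel course has no sampled
#'     cross-section of its own.
#'   * `stress_radius_mm` — documented override of the radius used for the
#'     stress computation only, for sections whose recorded radius is known
#'     to refer to a different level of the vessel than the stress estimate.
#'
#' @return A validated `arterial_tree`, a tibble subclass with the columns
#'   above in canonical order.
#' @seealso [read_tree()], [profile_tree()], [path_to_root()]
#' @examples
#' arterial_tree(data.frame(
#'   id = c("root", "b1"), kind = c("straight", "bend"),
#'   radius_mm = c(4, 3.5), bend_angle_deg = c(NA, 30),
#'   parent_id = c(NA, "root")
#' ))
#' @export
arterial_tree <- function(segments) {
  stopifnot(is.data.frame(segments))
  seg <- tibble::as_tibble(segments)
  for (col in c("bend_angle_deg", "branch_label", "upstream_angle_deg",
                "stress_radius_mm", "parent_id")) {
    if (!col %in% names(seg)) seg[[col]] <- NA
  }
  seg <- dplyr::mutate(
    seg,
    id = as.character(.data$id),
    kind = as.character(.data$kind),
    radius_mm = as.numeric(.data$radius_mm),
    bend_angle_deg = as.numeric(.data$bend_angle_deg),
    parent_id = as.character(.data$parent_id),
    branch_label = as.character(.data$branch_label),
    upstream_angle_deg = as.numeric(.data$upstream_angle_deg),
    stress_radius_mm = as.numeric(.data$stress_radius_mm)
  )
  seg <- seg[, c("id", "kind", "radius_mm", "bend_angle_deg", "parent_id",
                 "branch_label", "upstream_angle_deg", "stress_radius_mm")]
  out <- tibble::new_tibble(seg, class = "arterial_tree")
  validate_tree(out)
  out
}

#' Validate arterial-tree invariants
#'
#' Checks every segment-level invariant (positive radius, bend iff angle,
#' angles within `[0, 90)`) and every tree-level invariant (unique ids,
#' exactly one root, resolvable parents, acyclicity).  Called by every
#' constructor and reader; exposed so that hand-built tibbles can be checked.
#'
#' @param tree An `arterial_tree` or a data frame in the same shape.
#' @return `tree`, invisibly, if valid; otherwise an error naming the
#'   offending segment and field.
#' @export
validate_tree <- function(tree) {
  seg <- tibble::as_tibble(tree)
  required <- c("id", "kind", "radius_mm", "bend_angle_deg", "parent_id")
  missing_cols <- setdiff(required, names(seg))
  if (length(missing_cols) > 0) {
    abort(paste0("arterial tree is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "carotidflow_validation_error")
  }
  if (nrow(seg) == 0) {
    abort("arterial tree has no segments",
          class = "carotidflow_validation_error")
  }
  bad_field <- function(id, field, why) {
    abort(sprintf("segment '%s': invalid %s (%s)", id, field, why),
          class = "carotidflow_validation_error")
  }
  if (any(is.na(seg$id) | seg$id == "")) {
    abort("every segment needs a non-empty id",
          class = "carotidflow_validation_error")
  }
  dup <- seg$id[duplicated(seg$id)]
  if (length(dup) > 0) {
    abort(paste0("duplicated segment id(s): ", paste(unique(dup), collapse = ", ")),
          class = "carotidflow_validation_error")
  }
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    if (!s$kind %in% c("straight", "bend", "bifurcation")) {
      bad_field(s$id, "kind", paste0("got '", s$kind, "'"))
    }
    if (is.na(s$radius_mm) || s$radius_mm <= 0) {
      bad_field(s$id, "radius_mm", "must be > 0")
    }
    if (s$kind == "bend") {
      if (is.na(s$bend_angle_deg)) {
        bad_field(s$id, "bend_angle_deg", "bend segments need an angle")
      }
      if (s$bend_angle_deg < 0 || s$bend_angle_deg >= 90) {
        bad_field(s$id, "bend_angle_deg", "must lie in [0, 90)")
      }
    } else if (!is.na(s$bend_angle_deg)) {
      bad_field(s$id, "bend_angle_deg",
                "only bend segments carry an angle")
    }
    if ("upstream_angle_deg" %in% names(seg) && !is.na(s$upstream_angle_deg) &&
        (s$upstream_angle_deg < 0 || s$upstream_angle_deg >= 90)) {
      bad_field(s$id, "upstream_angle_deg", "must lie in [0, 90)")
    }
    if ("stress_radius_mm" %in% names(seg) && !is.na(s$stress_radius_mm) &&
        s$stress_radius_mm <= 0) {
      bad_field(s$id, "stress_radius_mm", "must be > 0")
    }
  }
  roots <- seg$id[is.na(seg$parent_id)]
  if (length(roots) != 1) {
    abort(sprintf("arterial tree must have exactly one root, found %d (%s)",
                  length(roots), paste(roots, collapse = ", ")),
          class = "carotidflow_validation_error")
  }
  unknown <- setdiff(seg$parent_id[!is.na(seg$parent_id)], seg$id)
  if (length(unknown) > 0) {
    abort(paste0("parent_id refers to unknown segment(s): ",
                 paste(unknown, collapse = ", ")),
          class = "carotidflow_validation_error")
  }
  # acyclicity: walking up from every segment must reach the root
  parent <- setNames(seg$parent_id, seg$id)
  for (id in seg$id) {
    seen <- character()
    cur <- id
    while (!is.na(parent[[cur]])) {
      if (cur %in% seen) {
        abort(sprintf("cycle detected through segment '%s'", cur),
              class = "carotidflow_validation_error")
      }
      seen <- c(seen, cur)
      cur <- parent[[cur]]
    }
  }
  invisible(tree)
}

#' Root segment id of a tree
#' @param tree An `arterial_tree`.
#' @return The id of the unique segment without a parent.
#' @export
root_id <- function(tree) {
  tree$id[is.na(tree$parent_id)][1]
}

#' Segments on the path from the root to a segment
#'
#' The cascade of bend attenuations acts along this path: the cumulative
#' velocity factor of a segment is the product of `cos(theta)` over every bend
#' the flow has traversed to reach it.
#'
#' @param tree An `arterial_tree`.
#' @param segment_id Id of the target segment.
#' @return A tibble of segments ordered root-first, ending at `segment_id`.
#' @examples
#' fx <- carotid_fixture()
#' path_to_root(fx$tree, "ICA-2")$id
#' @export
path_to_root <- function(tree, segment_id) {
  if (!segment_id %in% tree$id) {
    abort(sprintf("unknown segment id '%s'", segment_id),
          class = "carotidflow_lookup_error")
  }
  parent <- setNames(tree$parent_id, tree$id)
  ids <- segment_id
  cur <- segment_id
  while (!is.na(parent[[cur]])) {
    cur <- parent[[cur]]
    ids <- c(cur, ids)
  }
  out <- tibble::as_tibble(tree)[match(ids, tree$id), ]
  tibble::as_tibble(out)
}

#' @export
print.arterial_tree <- function(x, ...) {
  cat(sprintf("<arterial_tree: %d segments, root '%s'>\n", nrow(x), root_id(x)))
  NextMethod()
}
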