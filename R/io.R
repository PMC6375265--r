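#' Read an arterial tree from disk
#'
#' Two dialects are supported.  JSON is canonical: a top-level object with
#' `root_id` and a `segments` array, one object per segment with the
#' [arterial_tree()] field names.  CSV mirrors the layout of a section
#' measurement table, with header
#' `section,kind,radius_mm,angle_deg,parent,thickness_mm,remark`
#' (plus optional `upstream_angle_deg` and `stress_radius_mm` columns);
#' the thickness and remark columns are ignored when building the tree —
#' use [read_sections()] to recover them.
#'
#' @param path File to read.
#' @param dialect `"json"` or `"csv"`; default guesses from the extension.
#' @return A validated [arterial_tree()].
#' @export
read_tree <- function(path, dialect = c("auto", "json", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "carotidflow_io_error")
  }
  seg <- switch(dialect,
    json = read_tree_json(path),
    csv  = read_tree_csv(path)
  )
  arterial_tree(seg)
}

read_tree_json <- function(path) {
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
    error = function(e) {
      abort(paste0("malformed JSON in '", path, "': ", conditionMessage(e)),
            class = "carotidflow_parse_error")
    }
  )
  if (!is.list(obj) || is.null(obj$segments)) {
    abort(paste0("malformed tree file '", path, "': no 'segments' array"),
          class = "carotidflow_parse_error")
  }
  seg <- tibble::as_tibble(obj$segments)
  if (!is.null(obj$root_id) && nrow(seg) > 0) {
    stated_roots <- seg$id[is.na(seg$parent_id %||% rep(NA, nrow(seg)))]
    if (!identical(obj$root_id, stated_roots[1]) || length(stated_roots) != 1) {
      abort(sprintf(
        "tree file '%s': root_id '%s' does not match the parentless segment",
        path, obj$root_id), class = "carotidflow_parse_error")
    }
  }
  seg
}

read_tree_csv <- function(path) {
  raw <- read_sections_csv(path, required = c("section", "kind", "radius_mm",
                                              "angle_deg", "parent"))
  tibble::tibble(
    id = raw$section,
    kind = raw$kind,
    radius_mm = raw$radius_mm,
    bend_angle_deg = raw$angle_deg,
    parent_id = raw$parent,
    branch_label = raw$branch_label %||% NA_character_,
    upstream_angle_deg = raw$upstream_angle_deg %||% NA_real_,
    stress_radius_mm = raw$stress_radius_mm %||% NA_real_
  )
}

read_sections_csv <- function(path,
                              required = c("section", "radius_mm")) {
  raw <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE),
    error = function(e) {
      abort(paste0("malformed CSV in '", path, "': ", conditionMessage(e)),
            class = "carotidflow_parse_error")
    }
  )
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("CSV '", path, "' is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "carotidflow_parse_error")
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  dplyr::mutate(raw,
    radius_mm = num(.data$radius_mm),
    angle_deg = if ("angle_deg" %in% names(raw)) num(raw$angle_deg)
      else NA_real_,
    parent = if ("parent" %in% names(raw)) dplyr::na_if(raw$parent, "")
      else NA_character_,
    branch_label = if ("branch_label" %in% names(raw))
      dplyr::na_if(raw$branch_label, "") else NA_character_,
    upstream_angle_deg = if ("upstream_angle_deg" %in% names(raw))
      num(raw$upstream_angle_deg) else NA_real_,
    stress_radius_mm = if ("stress_radius_mm" %in% names(raw))
      num(raw$stress_radius_mm) else NA_real_
  )
}

#' Write an arterial tree to disk
#'
#' Round-trips with [read_tree()]: reading a written file reproduces the tree
#' field for field.
#'
#' @param tree A validated [arterial_tree()].
#' @param path Destination file.
#' @param dialect `"json"` (canonical) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path, dialect = c("auto", "json", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  validate_tree(tree)
  seg <- tibble::as_tibble(tree)
  if (dialect == "json") {
    payload <- list(
      format = "arterial-tree",
      root_id = root_id(tree),
      segments = seg
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    out <- tibble::tibble(
      section = seg$id,
      kind = seg$kind,
      radius_mm = seg$radius_mm,
      angle_deg = seg$bend_angle_deg,
      parent = seg$parent_id,
      thickness_mm = NA_character_,
      remark = NA_character_,
      branch_label = seg$branch_label,
      upstream_angle_deg = seg$upstream_angle_deg,
      stress_radius_mm = seg$stress_radius_mm
    )
    readr::write_csv(out, path, na = "", progress = FALSE)
  }
  invisible(path)
}

#' Parse a plaque-thickness entry
#'
#' Section tables record intimal plaque thickness as a range (`"19-39"`), a
#' single value (`"22"`, stored as the degenerate range), or `"NIL"` — plaque
#' looked for and not seen, which is distinct from a missing measurement
#' (empty / `NA`).
#'
#' @param x Character vector of thickness entries.
#' @return A tibble with one row per entry: `thickness_low_mm`,
#'   `thickness_high_mm` (both `NA` unless plaque was measured) and
#'   `plaque_observed` (`TRUE`, `FALSE` for NIL, `NA` for missing).
#' @examples
#' parse_thickness(c("19-39", "22", "NIL", NA))
#' @export
parse_thickness <- function(x) {
  one <- function(s) {
    if (is.na(s) || trimws(s) == "") {
      return(tibble::tibble(thickness_low_mm = NA_real_,
                            thickness_high_mm = NA_real_,
                            plaque_observed = NA))
    }
    s <- trimws(s)
    if (toupper(s) == "NIL") {
      return(tibble::tibble(thickness_low_mm = NA_real_,
                            thickness_high_mm = NA_real_,
                            plaque_observed = FALSE))
    }
    parts <- suppressWarnings(as.numeric(strsplit(s, "-", fixed = TRUE)[[1]]))
    if (length(parts) == 1 && !is.na(parts)) parts <- c(parts, parts)
    if (length(parts) != 2 || anyNA(parts) || parts[1] <= 0 ||
        parts[1] > parts[2]) {
      abort(paste0("cannot parse thickness entry '", s,
                   "' (expect 'low-high', a single value, or NIL)"),
            class = "carotidflow_parse_error")
    }
    tibble::tibble(thickness_low_mm = parts[1], thickness_high_mm = parts[2],
                   plaque_observed = TRUE)
  }
  purrr::list_rbind(purrr::map(as.character(x), one))
}

#' Read section measurements from a CSV table
#'
#' Reads the `thickness_mm` and `remark` columns that [read_tree()] ignores,
#' yielding one measurement record per histological section.
#'
#' @param path CSV file in the tree/section dialect (see [read_tree()]).
#' @return A tibble: `section_id`, `radius_mm`, `bend_angle_deg`,
#'   `thickness_low_mm`, `thickness_high_mm`, `thickness_mid_mm`,
#'   `plaque_observed`, `remark`.
#' @export
read_sections <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "carotidflow_io_error")
  }
  raw <- read_sections_csv(path)
  th <- parse_thickness(raw$thickness_mm %||% rep(NA_character_, nrow(raw)))
  tibble::tibble(
    section_id = raw$section,
    radius_mm = raw$radius_mm,
    bend_angle_deg = raw$angle_deg,
    thickness_low_mm = th$thickness_low_mm,
    thickness_high_mm = th$thickness_high_mm,
    thickness_mid_mm = (th$thickness_low_mm + th$thickness_high_mm) / 2,
    plaque_observed = th$plaque_observed,
    remark = as.character(raw$remark %||% NA_character_)
  )
}

#' Write section measurements in the section-table CSV dialect
#'
#' @param sections A measurements tibble as returned by [read_sections()] or
#'   [generate_plaque()].
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_sections <- function(sections, path) {
  fmt <- function(lo, hi, obs) {
    dplyr::case_when(
      is.na(obs) ~ NA_character_,
      !obs ~ "NIL",
      lo == hi ~ formatC(lo, format = "fg", digits = 8),
      TRUE ~ paste0(formatC(lo, format = "fg", digits = 8), "-",
                    formatC(hi, format = "fg", digits = 8))
    )
  }
  out <- tibble::tibble(
    section = sections$section_id,
    radius_mm = sections$radius_mm,
    angle_deg = sections$bend_angle_deg,
    thickness_mm = fmt(sections$thickness_low_mm, sections$thickness_high_mm,
                       sections$plaque_observed),
    remark = sections$remark %||% NA_character_
  )
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
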