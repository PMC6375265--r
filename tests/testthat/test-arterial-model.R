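test_that("the packaged fixture parses to a validated 15-segment tree", {
  fx <- carotid_fixture()
  expect_s3_class(fx$tree, "arterial_tree")
  expect_equal(nrow(fx$tree), 15)
  expect_equal(root_id(fx$tree), "CCA-1")
  expect_equal(sum(fx$tree$kind == "bend"), 6)
  expect_equal(sum(fx$tree$kind == "bifurcation"), 5)
  # the CSV dialect describes the same tree as the canonical JSON
  csv_tree <- read_tree(system.file("extdata", "carotid_sections.csv",
                                    package = "carotidflow"), "csv")
  cols <- c("id", "kind", "radius_mm", "bend_angle_deg", "parent_id",
            "upstream_angle_deg", "stress_radius_mm")
  expect_equal(as.data.frame(csv_tree)[cols], as.data.frame(fx$tree)[cols])
})

test_that("tree validation rejects malformed input and names the culprit", {
  expect_s3_class(single_segment_tree(), "arterial_tree")
  base <- data.frame(id = c("a", "b"), kind = "straight",
                     radius_mm = 1, bend_angle_deg = NA,
                     parent_id = c(NA, "a"))
  dangling <- base
  dangling$parent_id[2] <- "ghost"
  expect_error(arterial_tree(dangling), "ghost",
               class = "carotidflow_validation_error")
  two_roots <- base
  two_roots$parent_id[2] <- NA
  expect_error(arterial_tree(two_roots), "exactly one root",
               class = "carotidflow_validation_error")
  dup <- base
  dup$id <- c("a", "a")
  expect_error(arterial_tree(dup), "duplicated",
               class = "carotidflow_validation_error")
  cyc <- data.frame(id = c("r", "b", "c"), kind = "straight",
                    radius_mm = 1, bend_angle_deg = NA,
                    parent_id = c(NA, "c", "b"))
  expect_error(arterial_tree(cyc), "cycle",
               class = "carotidflow_validation_error")
  bend_no_angle <- data.frame(id = "r", kind = "bend", radius_mm = 1,
                              bend_angle_deg = NA, parent_id = NA)
  expect_error(arterial_tree(bend_no_angle), "angle",
               class = "carotidflow_validation_error")
  steep <- data.frame(id = "r", kind = "bend", radius_mm = 1,
                      bend_angle_deg = 90, parent_id = NA)
  expect_error(arterial_tree(steep), "\\[0, 90\\)",
               class = "carotidflow_validation_error")
  straight_with_angle <- data.frame(id = "r", kind = "straight",
                                    radius_mm = 1, bend_angle_deg = 10,
                                    parent_id = NA)
  expect_error(arterial_tree(straight_with_angle), "only bend",
               class = "carotidflow_validation_error")
  flat <- data.frame(id = "r", kind = "straight", radius_mm = 0,
                     bend_angle_deg = NA, parent_id = NA)
  expect_error(arterial_tree(flat), "radius",
               class = "carotidflow_validation_error")
})

test_that("read/write round-trips both dialects field for field", {
  fx <- carotid_fixture()
  for (dialect in c("json", "csv")) {
    path <- withr::local_tempfile(fileext = paste0(".", dialect))
    write_tree(fx$tree, path, dialect)
    back <- read_tree(path, dialect)
    expect_equal(as.data.frame(back), as.data.frame(fx$tree))
  }
  # property: generated trees round-trip too
  for (seed in 1:5) {
    tr <- generate_tree(synth_config(n_segments = 50, seed = seed))
    for (dialect in c("json", "csv")) {
      path <- withr::local_tempfile(fileext = paste0(".", dialect))
      write_tree(tr, path, dialect)
      expect_equal(as.data.frame(read_tree(path, dialect)),
                   as.data.frame(tr))
    }
  }
})

test_that("writing an invalid tree fails before touching the file", {
  tr <- as.data.frame(single_segment_tree())
  tr$id <- ""
  broken <- structure(tr, class = c("arterial_tree", "data.frame"))
  path <- withr::local_tempfile(fileext = ".json")
  expect_error(write_tree(broken, path, "json"),
               class = "carotidflow_validation_error")
  expect_false(file.exists(path))
  expect_error(read_tree(withr::local_tempfile(fileext = ".json")),
               class = "carotidflow_io_error")
})

test_that("path_to_root returns the unique root-first path", {
  fx <- carotid_fixture()
  expect_equal(path_to_root(fx$tree, "ICA-2")$id,
               c("CCA-1", "CCA-2", "CCA-3", "ICA-1", "ICA-2"))
  expect_equal(path_to_root(fx$tree, "CCA-1")$id, "CCA-1")
  expect_equal(nrow(path_to_root(fx$tree, "ECA-9")), 12)
  expect_error(path_to_root(fx$tree, "ECA-99"),
               class = "carotidflow_lookup_error")
  for (id in fx$tree$id) {
    p <- path_to_root(fx$tree, id)$id
    expect_lte(length(p), nrow(fx$tree))
    expect_false(anyDuplicated(p) > 0)
  }
})

test_that("thickness entries parse as range, single value, NIL or missing", {
  th <- parse_thickness(c("19-39", "22", "NIL", NA, ""))
  expect_equal(th$thickness_low_mm, c(19, 22, NA, NA, NA))
  expect_equal(th$thickness_high_mm, c(39, 22, NA, NA, NA))
  expect_equal(th$plaque_observed, c(TRUE, TRUE, FALSE, NA, NA))
  expect_error(parse_thickness("5-2"), class = "carotidflow_parse_error")
  expect_error(parse_thickness("0-3"), class = "carotidflow_parse_error")
  expect_error(parse_thickness("thick"), class = "carotidflow_parse_error")
})

test_that("section measurements round-trip through the CSV dialect", {
  fx <- carotid_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_sections(fx$sections, path)
  back <- read_sections(path)
  expect_equal(back$section_id, fx$sections$section_id)
  expect_equal(back$thickness_low_mm, fx$sections$thickness_low_mm)
  expect_equal(back$thickness_high_mm, fx$sections$thickness_high_mm)
  expect_equal(back$plaque_observed, fx$sections$plaque_observed)
})
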