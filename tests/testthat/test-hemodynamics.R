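test_that("single-bend velocity reduction follows the cosine rule", {
  expect_identical(velocity_reduction(0), 0)
  expect_equal(round(velocity_reduction(30), 3), 0.134)
  expect_equal(velocity_reduction(60), 0.5)
  expect_error(velocity_reduction(-1), class = "carotidflow_domain_error")
  expect_error(velocity_reduction(90), class = "carotidflow_domain_error")
  expect_error(velocity_reduction(120), class = "carotidflow_domain_error")
})

test_that("cumulative velocity factor is the cosine product over a cascade", {
  expect_identical(cumulative_velocity_factor(numeric(0)), 1)
  expect_equal(round(cumulative_velocity_factor(c(20, 51, 52, 60, 30)), 2), 0.16)
  expect_equal(round(cumulative_velocity_factor(c(28, 48)), 2), 0.59)
  expect_error(cumulative_velocity_factor(c(20, 95)),
               class = "carotidflow_domain_error")
  # order invariance: the cascade is a commutative product
  withr::with_seed(404, {
    for (i in 1:50) {
      angles <- runif(sample(2:8, 1), 0, 89.9)
      expect_equal(cumulative_velocity_factor(sample(angles)),
                   cumulative_velocity_factor(angles), tolerance = 1e-12)
    }
  })
})

test_that("cross-sectional area matches the reported mm^2 values", {
  a <- cross_sectional_area(c(10, 5.0, 1.5))
  expect_equal(round(a$area_mm2[1]), 314)
  expect_equal(signif(a$area_mm2[2], 2), 79)
  expect_equal(signif(a$area_mm2[3], 1), 7)
  expect_equal(a$area_cm2, a$area_mm2 / 100)
  expect_error(cross_sectional_area(0), class = "carotidflow_domain_error")
  expect_error(cross_sectional_area(-2), class = "carotidflow_domain_error")
})

test_that("drag stress reproduces the reported per-section multiples", {
  expect_equal(round(drag_stress(1, 8.5), 2), 0.44)
  expect_equal(round(drag_stress(1, 10), 2), 0.32)
  expect_equal(round(drag_stress(cumulative_velocity_factor(20), 5.0), 2), 1.20)
  expect_equal(round(drag_stress(cumulative_velocity_factor(c(20, 51, 52)), 4.0), 2),
               0.72)
  expect_error(drag_stress(0, 1), class = "carotidflow_domain_error")
  expect_error(drag_stress(1.5, 1), class = "carotidflow_domain_error")
  expect_error(drag_stress(1, 0), class = "carotidflow_domain_error")
})

test_that("flow splits in the ratio of daughter areas and conserves volume", {
  expect_equal(flow_split(c(1, 1)), c(0.5, 0.5))
  expect_equal(flow_split(c(sqrt(3), 1)), c(0.75, 0.25))
  expect_equal(round(flow_split(c(5.0, 5.5)), 4), c(0.4525, 0.5475))
  withr::with_seed(707, {
    for (i in 1:200) {
      radii <- runif(sample(2:6, 1), 0.5, 12)
      inflow <- runif(1, 0.1, 50)
      rates <- flow_split(radii, inflow)
      expect_lt(abs(sum(rates) - inflow), 1e-12)
      expect_true(all(rates > 0))
      # proportionality to areas
      expect_equal(rates / rates[1], radii^2 / radii[1]^2, tolerance = 1e-9)
    }
  })
  expect_error(flow_split(5), class = "carotidflow_domain_error")
  expect_error(flow_split(c(1, 0)), class = "carotidflow_domain_error")
  expect_error(flow_split(c(1, 1), inflow = 0),
               class = "carotidflow_domain_error")
})

test_that("profile_tree cascades cosines along root paths", {
  fx <- carotid_fixture()
  prof <- profile_tree(fx$tree)
  stress <- setNames(prof$stress_index, prof$segment_id)
  expect_equal(round(stress[["ICA-1"]], 2), 0.93)
  expect_equal(round(stress[["ICA-2"]], 2), 0.62)
  # single straight root: no attenuation at all
  p1 <- profile_tree(single_segment_tree(radius_mm = 3))
  expect_identical(p1$cum_velocity_factor, 1)
  expect_equal(p1$stress_index, 1 / (pi * 0.3^2))
  # limit agreement: all-zero angles reduce to pure geometry exactly
  zero <- arterial_tree(data.frame(
    id = c("r", "b1", "b2"), kind = c("straight", "bend", "bend"),
    radius_mm = c(4, 3, 2), bend_angle_deg = c(NA, 0, 0),
    parent_id = c(NA, "r", "b1")
  ))
  pz <- profile_tree(zero)
  expect_identical(pz$cum_velocity_factor, c(1, 1, 1))
  expect_equal(pz$stress_index, 1 / (pi * (c(4, 3, 2) / 10)^2))
})

test_that("profile_tree agrees with a brute-force path-walking oracle", {
  for (n in c(5, 20, 60, 100)) {
    tr <- generate_tree(synth_config(n_segments = n, seed = n + 3))
    prof <- profile_tree(tr)
    oracle <- brute_profile(tr)
    expect_equal(prof$cum_velocity_factor, unname(oracle[, "factor"]),
                 tolerance = 1e-12)
    expect_equal(prof$stress_index, unname(oracle[, "stress"]),
                 tolerance = 1e-12)
  }
  # and on the fixture, whose tree carries an upstream angle and an override
  fx <- carotid_fixture()
  expect_equal(profile_tree(fx$tree)$stress_index,
               unname(brute_profile(fx$tree)[, "stress"]), tolerance = 1e-12)
})

test_that("adding a bend never increases downstream velocity or stress", {
  withr::with_seed(1234, {
    for (trial in 1:1000) {
      tr <- generate_tree(synth_config(n_segments = 8,
                                       seed = sample.int(1e6, 1)))
      before <- profile_tree(tr)
      at <- sample(tr$id, 1)
      bent <- add_bend_above(tr, at, runif(1, 1, 80))
      after <- profile_tree(bent)
      joined <- merge(as.data.frame(before), as.data.frame(after),
                      by = "segment_id", suffixes = c("_0", "_1"))
      expect_true(all(joined$cum_velocity_factor_1 <=
                        joined$cum_velocity_factor_0 + 1e-12))
      expect_true(all(joined$stress_index_1 <= joined$stress_index_0 + 1e-12))
    }
  })
})

test_that("site classification flags the low-stress segments", {
  fx <- carotid_fixture()
  flagged <- classify_sites(profile_tree(fx$tree))
  expect_equal(flagged$segment_id[flagged$prone],
               c("CCA-1", "CCA-2", "CCA-3"))
  expect_false(flagged$prone[flagged$segment_id == "ECA-6"])
  # ECA-6's stress index ranks among the highest — consistent with its
  # plaque-free histology
  expect_gte(rank(flagged$stress_index)[flagged$segment_id == "ECA-6"], 9)
  # a uniform straight tree has no below-median segment
  uni <- arterial_tree(data.frame(
    id = paste0("s", 1:4), kind = "straight", radius_mm = 3,
    bend_angle_deg = NA, parent_id = c(NA, paste0("s", 1:3))
  ))
  expect_false(any(classify_sites(profile_tree(uni))$prone))
  expect_error(classify_sites(tibble::tibble()),
               class = "carotidflow_domain_error")
})

test_that("risk rules accept config blocks and reject unknown keys", {
  fx <- carotid_fixture()
  prof <- profile_tree(fx$tree)
  # absolute mode: with 1 stress unit = 10 dynes/cm^2 the 5 dynes/cm^2
  # boundary sits at index 0.5
  abs_rule <- risk_rule("absolute", f_d_dynes = 10)
  flagged <- classify_sites(prof, abs_rule)
  expect_equal(flagged$threshold[1], 0.5)
  expect_equal(flagged$segment_id[flagged$prone],
               c("CCA-1", "CCA-2", "CCA-3"))
  expect_error(risk_rule("absolute"), class = "carotidflow_domain_error")
  # config block from a JSON file
  cfgfile <- withr::local_tempfile(fileext = ".json")
  writeLines('{"mode": "relative", "quantile": 0.25}', cfgfile)
  rule <- as_risk_rule(cfgfile)
  expect_equal(rule$quantile, 0.25)
  expect_error(as_risk_rule(list(mode = "relative", spam = 1)),
               class = "carotidflow_domain_error")
})
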