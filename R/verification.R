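#' Recompute the reference stress values for the carotid fixture
#'
#' Runs [profile_tree()] and compares every computed quantity with the values
#' reported for the cadaveric dataset, after rounding to the reported
#' precision (two decimals for stress indices, whole percent for the cascade
#' percentages, one decimal for single-bend reduction percentages).  Reported
#' values that do not follow from the stated model are flagged `discrepant` —
#' they are never silently matched.
#'
#' @param tree An [arterial_tree()]; defaults to the packaged fixture.  For a
#'   tree that does not carry the fixture's section ids all rows come back
#'   `unprinted` (no reported value to compare with).
#' @return A `repro_report`: list with tibbles `sections` (per-segment
#'   computed stress, reported value, `status` in
#'   `matched`/`discrepant`/`unprinted`, note), `checks` (cascade-level
#'   quantities) and `summary` (counts).
#' @examples
#' rep <- reproduce_reference()
#' glance(rep)
#' @export
reproduce_reference <- function(tree = carotid_fixture()$tree) {
  prof <- profile_tree(tree)
  sections <- dplyr::left_join(
    dplyr::select(tibble::as_tibble(prof), "segment_id", "kind",
                  "cum_velocity_factor", "stress_index"),
    reference_section_values(),
    by = c(segment_id = "section_id")
  )
  sections <- dplyr::mutate(
    sections,
    computed_2dp = round(.data$stress_index, 2),
    status = dplyr::case_when(
      is.na(.data$reported_stress) ~ "unprinted",
      .data$computed_2dp == .data$reported_stress ~ "matched",
      TRUE ~ "discrepant"
    ),
    note = dplyr::if_else(
      .data$status == "discrepant",
      sprintf("reported %.2f does not follow from the model (computed %.2f)",
              .data$reported_stress, .data$computed_2dp),
      NA_character_
    )
  )

  checks <- reference_check_values()
  computed_checks <- c(
    single_bend_reduction_30deg_pct = 100 * velocity_reduction(30),
    single_bend_reduction_60deg_pct = 100 * velocity_reduction(60),
    eca_remaining_velocity_pct = if ("ECA-7" %in% prof$segment_id) {
      100 * prof$cum_velocity_factor[prof$segment_id == "ECA-7"]
    } else NA_real_,
    ica_remaining_velocity_pct = if ("ICA-2" %in% prof$segment_id) {
      100 * prof$cum_velocity_factor[prof$segment_id == "ICA-2"]
    } else NA_real_,
    straight_part_stress_r2mm = drag_stress(1, 2.0)
  )
  checks <- dplyr::mutate(
    checks,
    computed = unname(computed_checks[.data$quantity]),
    computed_rounded = round(.data$computed, .data$digits),
    status = dplyr::case_when(
      is.na(.data$computed) ~ "unprinted",
      .data$computed_rounded == .data$reported ~ "matched",
      TRUE ~ "discrepant"
    ),
    note = dplyr::if_else(
      .data$status == "discrepant",
      sprintf("reported %g does not follow from the model (computed %g)",
              .data$reported, .data$computed_rounded),
      NA_character_
    )
  )

  summary <- tibble::tibble(
    n_sections = nrow(sections),
    matched = sum(sections$status == "matched") + sum(checks$status == "matched"),
    discrepant = sum(sections$status == "discrepant") +
      sum(checks$status == "discrepant"),
    unprinted = sum(sections$status == "unprinted")
  )
  structure(list(sections = sections, checks = checks, summary = summary),
            class = "repro_report")
}

#' @export
print.repro_report <- function(x, ...) {
  cat("Reference reproduction report\n")
  cat(sprintf("  %d matched, %d discrepant, %d section(s) without a reported value\n\n",
              x$summary$matched, x$summary$discrepant, x$summary$unprinted))
  print(x$sections, n = nrow(x$sections))
  cat("\nCascade-level checks:\n")
  print(x$checks)
  invisible(x)
}

#' @rdname reproduce_reference
#' @param x A `repro_report`.
#' @param ... Unused.
#' @export
tidy.repro_report <- function(x, ...) {
  sec <- dplyr::transmute(x$sections,
    quantity = .data$segment_id, kind = "section stress index",
    computed = .data$stress_index, reported = .data$reported_stress,
    status = .data$status, note = .data$note)
  chk <- dplyr::transmute(x$checks,
    quantity = .data$quantity, kind = "cascade check",
    computed = .data$computed, reported = .data$reported,
    status = .data$status, note = .data$note)
  dplyr::bind_rows(sec, chk)
}

#' @rdname reproduce_reference
#' @export
glance.repro_report <- function(x, ...) x$summary

# ---- permutation rank test ----------------------------------------------

# all permutations of 1..n as an n! x n integer matrix (n <= 8 in practice)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    idx <- row + seq_len(nrow(sub))
    out[idx, 1] <- k
    out[idx, -1] <- matrix(rest[sub], nrow(sub), n - 1)
    row <- row + nrow(sub)
  }
  out
}

spearman_rho <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  cor(rx, ry)
}

#' Permutation test for a rank correlation
#'
#' Spearman rank correlation with a permutation null: one margin is permuted
#' and the tail probability of the observed coefficient computed.  For
#' `n <= 8` the null is enumerated exactly over all `n!` permutations
#' (including the identity, so the p-value is strictly positive); for larger
#' `n` it is estimated by Monte-Carlo with a fixed seed, with the usual
#' add-one correction.
#'
#' @param x,y Paired numeric vectors.
#' @param alternative `"less"` (default — the hemodynamic model predicts a
#'   negative stress/plaque association), `"greater"`, or `"two.sided"`.
#' @param n_perm Monte-Carlo draws when the null is not enumerated.
#' @param seed Seed for the Monte-Carlo draws (local; the global RNG state is
#'   untouched).
#' @param method `"auto"` (exact for `n <= 8`, Monte-Carlo beyond), or force
#'   `"exact"` / `"monte-carlo"`.
#' @return A list: `rho`, `p_value`, `n`, `method` (`"exact"` or
#'   `"monte-carlo"`).  With all-tied input the coefficient is undefined and
#'   both `rho` and `p_value` are `NA`.
#' @export
perm_rank_test <- function(x, y, alternative = c("less", "greater", "two.sided"),
                           n_perm = 10000, seed = 20260101,
                           method = c("auto", "exact", "monte-carlo")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) {
    abort("need at least 3 complete pairs", class = "carotidflow_domain_error")
  }
  obs <- spearman_rho(x, y)
  if (is.na(obs)) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "undefined (tied input)"))
  }
  tail_prob <- function(rhos, n_total) {
    eps <- 1e-12
    switch(alternative,
      less = sum(rhos <= obs + eps) / n_total,
      greater = sum(rhos >= obs - eps) / n_total,
      two.sided = sum(abs(rhos) >= abs(obs) - eps) / n_total
    )
  }
  if (method == "auto") method <- if (n <= 8) "exact" else "monte-carlo"
  if (method == "exact") {
    if (n > 10) {
      abort("exact enumeration is limited to n <= 10",
            class = "carotidflow_domain_error")
    }
    perms <- all_permutations(n)
    rhos <- apply(perms, 1, function(p) spearman_rho(x, y[p]))
    p <- tail_prob(rhos, nrow(perms))
  } else {
    rhos <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(i) spearman_rho(x, sample(y)), 0)
    })
    # add-one correction counts the observed arrangement itself
    eps <- 1e-12
    hits <- switch(alternative,
      less = sum(rhos <= obs + eps),
      greater = sum(rhos >= obs - eps),
      two.sided = sum(abs(rhos) >= abs(obs) - eps)
    )
    p <- (1 + hits) / (1 + n_perm)
  }
  list(rho = obs, p_value = p, n = n, method = method)
}

# ---- concordance ---------------------------------------------------------

#' Model-versus-histology concordance
#'
#' Pairs the model's per-section predictions with the observed plaque
#' measurements and summarizes agreement two ways:
#' * a 2x2 table of predicted-prone (low drag stress, see
#'   [classify_sites()]) against plaque presence (NIL = absent), with
#'   sensitivity and specificity of the prone flag for plaque;
#' * a rank correlation between the stress index and the plaque-thickness
#'   midpoint over sections with a measured thickness (NIL sections have no
#'   midpoint and are excluded from the ranks), with a permutation p-value
#'   ([perm_rank_test()]; the model predicts a *negative* association).
#'
#' @param profiles A `stress_profile` from [profile_tree()].
#' @param sections A measurements tibble ([read_sections()] /
#'   [generate_plaque()] shape).
#' @param rule Risk rule used to flag prone sites.
#' @param alternative,n_perm,seed Passed to [perm_rank_test()].
#' @return A `concordance_report`: list with `pairs` (the joined per-section
#'   table), `binary_table` (2x2 matrix), `sensitivity`, `specificity`,
#'   `rank_statistic`, `p_value`, `n`, `n_rank`, `method`.
#' @examples
#' fx <- carotid_fixture()
#' concordance(profile_tree(fx$tree), fx$sections)
#' @export
concordance <- function(profiles, sections, rule = risk_rule(),
                        alternative = c("less", "greater", "two.sided"),
                        n_perm = 10000, seed = 20260101) {
  alternative <- match.arg(alternative)
  flagged <- classify_sites(profiles, rule)
  pairs <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(flagged), "segment_id",
                  "stress_index", "prone"),
    dplyr::select(sections, "section_id", "thickness_mid_mm",
                  "plaque_observed"),
    by = c(segment_id = "section_id")
  )
  if (nrow(pairs) == 0) {
    abort("profiles and sections share no section ids",
          class = "carotidflow_domain_error")
  }
  known <- dplyr::filter(pairs, !is.na(.data$plaque_observed))
  tab <- table(
    predicted = factor(known$prone, levels = c(TRUE, FALSE),
                       labels = c("prone", "not prone")),
    observed = factor(known$plaque_observed, levels = c(TRUE, FALSE),
                      labels = c("plaque", "no plaque"))
  )
  sens <- tab["prone", "plaque"] / sum(tab[, "plaque"])
  spec <- tab["not prone", "no plaque"] / sum(tab[, "no plaque"])
  # positive predictive value of the prone flag: fraction of flagged sites
  # where plaque was in fact observed
  ppv <- tab["prone", "plaque"] / sum(tab["prone", ])
  ranked <- dplyr::filter(pairs, !is.na(.data$thickness_mid_mm))
  if (nrow(ranked) >= 3) {
    test <- perm_rank_test(ranked$stress_index, ranked$thickness_mid_mm,
                           alternative = alternative, n_perm = n_perm,
                           seed = seed)
  } else {
    test <- list(rho = NA_real_, p_value = NA_real_, n = nrow(ranked),
                 method = "not computed (fewer than 3 measured sections)")
  }
  structure(list(
    pairs = pairs, binary_table = tab,
    sensitivity = unname(sens), specificity = unname(spec),
    ppv = unname(ppv),
    rank_statistic = test$rho, p_value = test$p_value,
    n = nrow(known), n_rank = test$n, method = test$method,
    alternative = alternative
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Model-vs-histology concordance\n\n")
  print(x$binary_table)
  cat(sprintf("\nsensitivity %.3f, specificity %.3f, PPV %.3f (n = %d)\n",
              x$sensitivity, x$specificity, x$ppv, x$n))
  if (is.na(x$rank_statistic)) {
    cat(sprintf("rank correlation: %s\n", x$method))
  } else {
    cat(sprintf(
      "rank correlation (stress vs thickness midpoint, n = %d): rho = %.3f, %s permutation p = %.4g (alternative: %s)\n",
      x$n_rank, x$rank_statistic, x$method, x$p_value, x$alternative))
  }
  invisible(x)
}

#' @rdname concordance
#' @param x A `concordance_report`.
#' @param ... Unused.
#' @export
tidy.concordance_report <- function(x, ...) tibble::as_tibble(x$pairs)

#' @rdname concordance
#' @export
glance.concordance_report <- function(x, ...) {
  tibble::tibble(
    sensitivity = x$sensitivity, specificity = x$specificity,
    ppv = x$ppv,
    rank_statistic = x$rank_statistic, p_value = x$p_value,
    n = x$n, n_rank = x$n_rank, method = x$method
  )
}
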