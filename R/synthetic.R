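#' Configuration for the synthetic tree-and-plaque generator
#'
#' The generator emulates the statistical shape of the cadaveric fixture so
#' that every analysis stage can be exercised without cadaveric data: a
#' rooted vessel tree with radii tapering from the root, bend angles drawn
#' uniformly from a bounded range, and plaque laid down where the drag-stress
#' index is low.  Defaults mirror the fixture: 15 segments, 6/15 bends,
#' 5/15 bifurcations, angles on `[0, 60]` degrees, 8.5 mm root radius.
#'
#' The plaque model is a hinge with multiplicative lognormal noise: with
#' stress index `s`, expected thickness is `a * max(0, s0 - s)`; the observed
#' midpoint is that times `exp(rnorm(1, 0, noise_sd))`, and anything below
#' `detection_floor_mm` is recorded as NIL (looked for, not seen).  This is a
#' synthetic stand-in for an unknown biological dose-response; it encodes
#' only the monotone low-stress-more-plaque assumption.
#'
#' @param n_segments Number of segments, `>= 1`.
#' @param bend_fraction,bifurcation_fraction Probabilities that a new segment
#'   is a bend / a bifurcation (remainder: straight); must sum to at most 1.
#' @param angle_range Two-element degree range in `[0, 90)` for bend angles.
#' @param root_radius_mm Radius of the inflow segment, mm.
#' @param taper_factor Multiplicative radius shrink per generation, in
#'   `(0, 1]`.
#' @param min_radius_mm Radius floor, mm: tapering never goes below it.
#'   Default 1.5, the narrowest vessel in the fixture — the model addresses
#'   the macrocirculation, and narrower vessels belong to the differently
#'   regulated microcirculation.
#' @param s0 Stress breakpoint of the hinge (stress-index units): no plaque
#'   forms where stress exceeds it.
#' @param a Thickness laid down per unit stress deficit, mm.
#' @param noise_sd Lognormal sigma of the multiplicative thickness noise.
#' @param detection_floor_mm Thickness below which plaque is recorded NIL.
#' @param seed Integer seed; the whole simulated study is reproducible from
#'   it.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_segments = 15, bend_fraction = 6 / 15,
                         bifurcation_fraction = 5 / 15,
                         angle_range = c(0, 60), root_radius_mm = 8.5,
                         taper_factor = 0.9, min_radius_mm = 1.5,
                         s0 = 1.0, a = 10,
                         noise_sd = 0.1, detection_floor_mm = 0.5,
                         seed = 1L) {
  cfg <- list(n_segments = as.integer(n_segments),
              bend_fraction = bend_fraction,
              bifurcation_fraction = bifurcation_fraction,
              angle_range = as.numeric(angle_range),
              root_radius_mm = root_radius_mm, taper_factor = taper_factor,
              min_radius_mm = min_radius_mm,
              s0 = s0, a = a, noise_sd = noise_sd,
              detection_floor_mm = detection_floor_mm,
              seed = as.integer(seed))
  if (is.na(cfg$n_segments) || cfg$n_segments < 1) {
    abort("n_segments must be a positive count",
          class = "carotidflow_domain_error")
  }
  fr <- c(cfg$bend_fraction, cfg$bifurcation_fraction)
  if (anyNA(fr) || any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    abort("bend/bifurcation fractions must lie in [0, 1] and sum to at most 1",
          class = "carotidflow_domain_error")
  }
  if (length(cfg$angle_range) != 2 || anyNA(cfg$angle_range) ||
      cfg$angle_range[1] < 0 || cfg$angle_range[2] >= 90 ||
      cfg$angle_range[1] > cfg$angle_range[2]) {
    abort("angle_range must be an increasing pair within [0, 90)",
          class = "carotidflow_domain_error")
  }
  if (cfg$root_radius_mm <= 0 || cfg$taper_factor <= 0 ||
      cfg$taper_factor > 1) {
    abort("root_radius_mm must be positive and taper_factor in (0, 1]",
          class = "carotidflow_domain_error")
  }
  if (cfg$min_radius_mm <= 0 || cfg$min_radius_mm > cfg$root_radius_mm) {
    abort("min_radius_mm must lie in (0, root_radius_mm]",
          class = "carotidflow_domain_error")
  }
  if (cfg$s0 <= 0 || cfg$a <= 0 || cfg$noise_sd < 0 ||
      cfg$detection_floor_mm < 0) {
    abort("plaque-model scales must be positive (noise_sd and floor >= 0)",
          class = "carotidflow_domain_error")
  }
  structure(cfg, class = "synth_config")
}

# derived substream so tree and plaque draws are independent yet both
# reproducible from the one config seed (Knuth multiplicative hash, kept
# inside 32-bit integer range)
plaque_seed <- function(seed) {
  as.integer((as.double(seed) * 2654435761) %% 2147483647)
}

#' Generate a random arterial tree
#'
#' Grows a rooted tree segment by segment.  Each new segment is either a
#' *side branch* (probability `bifurcation_fraction`) that arises from a
#' uniformly chosen existing segment — whose own section thereby sits at a
#' branch point and is relabelled `bifurcation` unless it is a bend — or a
#' *continuation* of a uniformly chosen open distal end, drawn as a bend
#' (probability `bend_fraction`, angle uniform on `angle_range`) or a
#' straight section otherwise.  Radii taper by `taper_factor` per generation
#' down to `min_radius_mm`.  Because side branches arise anywhere along the
#' existing vessels (as they do anatomically), depth grows logarithmically
#' with size and the stress range of a large tree stays comparable to a
#' small one.  Bit-identical output for the same seed.
#'
#' @param config A [synth_config()].
#' @return A validated [arterial_tree()] with ids `S1 .. Sn`, root `S1`.
#' @examples
#' generate_tree(synth_config(n_segments = 10, seed = 7))
#' @export
generate_tree <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_segments
  withr::with_seed(config$seed, {
    id <- paste0("S", seq_len(n))
    kind <- character(n)
    radius <- numeric(n)
    angle <- rep(NA_real_, n)
    parent <- rep(NA_character_, n)
    kind[1] <- "straight"
    radius[1] <- config$root_radius_mm
    open <- c(1L)                       # indices with a free distal end
    for (i in seq_len(n)[-1]) {
      u <- runif(1)
      if (u < config$bifurcation_fraction) {
        # side branch off any existing segment; the parent section sits at a
        # branch point now
        pick <- if (i == 2) 1L else sample(seq_len(i - 1L), 1)
        if (kind[pick] == "straight") kind[pick] <- "bifurcation"
        kind[i] <- "straight"
      } else {
        pick <- if (length(open) == 1) open else sample(open, 1)
        open <- open[-match(pick, open)]
        if (u < config$bifurcation_fraction + config$bend_fraction) {
          kind[i] <- "bend"
          angle[i] <- runif(1, config$angle_range[1], config$angle_range[2])
        } else {
          kind[i] <- "straight"
        }
      }
      parent[i] <- id[pick]
      radius[i] <- max(radius[pick] * config$taper_factor,
                       config$min_radius_mm)
      open <- c(open, i)
    }
    arterial_tree(tibble::tibble(
      id = id, kind = kind, radius_mm = radius,
      bend_angle_deg = angle, parent_id = parent
    ))
  })
}

#' Generate synthetic plaque measurements for a tree
#'
#' Applies the hinge-plus-lognormal plaque model of [synth_config()] to the
#' tree's computed stress profile.  Each segment's thickness midpoint is
#' `a * max(0, s0 - stress) * exp(rnorm(1, 0, noise_sd))`; midpoints below
#' the detection floor are recorded NIL.  Measured thicknesses are reported
#' as the range `(0.8, 1.2)` times the midpoint, mimicking how section
#' tables record a low-high span around what was seen.
#'
#' @param tree An [arterial_tree()] (typically from [generate_tree()]).
#' @param config The same [synth_config()] used to generate the tree; the
#'   plaque draws use a substream derived from `config$seed`.
#' @return A measurements tibble in the [read_sections()] shape.
#' @export
generate_plaque <- function(tree, config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  prof <- profile_tree(tree)
  deficit <- pmax(0, config$s0 - prof$stress_index)
  mid <- withr::with_seed(plaque_seed(config$seed), {
    config$a * deficit * exp(rnorm(nrow(prof), 0, config$noise_sd))
  })
  observed <- mid >= config$detection_floor_mm
  tibble::tibble(
    section_id = prof$segment_id,
    radius_mm = prof$radius_mm,
    bend_angle_deg = tree$bend_angle_deg[match(prof$segment_id, tree$id)],
    thickness_low_mm = dplyr::if_else(observed, 0.8 * mid, NA_real_),
    thickness_high_mm = dplyr::if_else(observed, 1.2 * mid, NA_real_),
    thickness_mid_mm = dplyr::if_else(observed, mid, NA_real_),
    plaque_observed = observed,
    remark = prof$kind
  )
}

#' Recover the plaque-model parameters from measurements
#'
#' Least-squares fit of the hinge model on the log scale: for sections with
#' measured plaque, `log(midpoint) = log(a) + log(s0 - stress) + noise`, so
#' the sum of squared log residuals is minimized over `(s0, log a)` by
#' Nelder-Mead.  Percentile bootstrap intervals come from refitting on
#' resampled sections.
#'
#' @param sections Measurements tibble (needs `section_id`,
#'   `thickness_mid_mm`, `plaque_observed`).
#' @param profiles Matching `stress_profile` from [profile_tree()].
#' @param n_boot Bootstrap replicates for the intervals (0 to skip).
#' @param conf_level Interval coverage.
#' @param seed Seed for the bootstrap resampling (local).
#' @return A `hinge_fit`: list with `s0`, `a`, `sigma` (residual sd of log
#'   thickness), `n`, `conf` (tibble of percentile intervals), `convergence`.
#' @examples
#' cfg <- synth_config(n_segments = 60, seed = 42)
#' tr <- generate_tree(cfg)
#' fit <- recover_parameters(generate_plaque(tr, cfg), profile_tree(tr))
#' tidy(fit)
#' @export
recover_parameters <- function(sections, profiles, n_boot = 200,
                               conf_level = 0.95, seed = 20260101) {
  dat <- dplyr::inner_join(
    dplyr::select(sections, "section_id", "thickness_mid_mm",
                  "plaque_observed"),
    dplyr::select(tibble::as_tibble(profiles), "segment_id", "stress_index"),
    by = c(section_id = "segment_id")
  )
  dat <- dplyr::filter(dat, !is.na(.data$plaque_observed) &
                         .data$plaque_observed &
                         .data$thickness_mid_mm > 0)
  if (nrow(dat) < 20) {
    abort("need at least 20 sections with measured plaque to fit the hinge",
          class = "carotidflow_domain_error")
  }
  fit_one <- function(s, t) {
    obj <- function(par) {
      s0 <- par[1]
      pred <- log(pmax(s0 - s, 1e-9)) + par[2]
      sum((log(t) - pred)^2)
    }
    init_s0 <- max(s) * 1.05 + 0.01
    init_la <- log(median(t / pmax(init_s0 - s, 1e-9)))
    opt <- optim(c(init_s0, init_la), obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 2000))
    c(s0 = opt$par[1], a = exp(opt$par[2]), value = opt$value,
      convergence = opt$convergence)
  }
  est <- fit_one(dat$stress_index, dat$thickness_mid_mm)
  resid_df <- max(nrow(dat) - 2, 1)
  sigma <- sqrt(est[["value"]] / resid_df)
  conf <- NULL
  if (n_boot > 0) {
    boots <- withr::with_seed(seed, {
      purrr::map(seq_len(n_boot), function(b) {
        idx <- sample.int(nrow(dat), replace = TRUE)
        fit_one(dat$stress_index[idx], dat$thickness_mid_mm[idx])
      })
    })
    bs0 <- purrr::map_dbl(boots, "s0")
    ba <- purrr::map_dbl(boots, "a")
    alpha <- (1 - conf_level) / 2
    conf <- tibble::tibble(
      term = c("s0", "a"),
      conf.low = c(quantile(bs0, alpha), quantile(ba, alpha)),
      conf.high = c(quantile(bs0, 1 - alpha), quantile(ba, 1 - alpha))
    )
  }
  structure(list(
    s0 = unname(est[["s0"]]), a = unname(est[["a"]]), sigma = unname(sigma),
    n = nrow(dat), conf = conf, conf_level = conf_level,
    convergence = unname(est[["convergence"]]),
    data = dat
  ), class = "hinge_fit")
}

#' @export
print.hinge_fit <- function(x, ...) {
  cat(sprintf(
    "Hinge plaque-model fit (n = %d measured sections)\n  s0 = %.4f, a = %.4f, residual log-sd = %.4f\n",
    x$n, x$s0, x$a, x$sigma))
  if (!is.null(x$conf)) {
    cat(sprintf("  %g%% bootstrap intervals: s0 [%.4f, %.4f], a [%.4f, %.4f]\n",
                100 * x$conf_level, x$conf$conf.low[1], x$conf$conf.high[1],
                x$conf$conf.low[2], x$conf$conf.high[2]))
  }
  invisible(x)
}

#' @rdname recover_parameters
#' @param x A `hinge_fit`.
#' @param ... Unused.
#' @export
tidy.hinge_fit <- function(x, ...) {
  out <- tibble::tibble(term = c("s0", "a"), estimate = c(x$s0, x$a))
  if (!is.null(x$conf)) out <- dplyr::left_join(out, x$conf, by = "term")
  out
}

#' @rdname recover_parameters
#' @export
glance.hinge_fit <- function(x, ...) {
  tibble::tibble(sigma = x$sigma, n = x$n,
                 converged = x$convergence == 0)
}
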