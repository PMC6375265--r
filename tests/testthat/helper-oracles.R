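# Independent oracles and fixture builders for the test suite.  These
# deliberately re-derive results by different algorithms than the package
# (plain cos() loops instead of memoised cospi() recursion, recursive
# insertion enumeration instead of the package's permutation matrix) so that
# agreement is evidence, not tautology.

# brute-force stress profile: for every segment, walk its root path
# independently and accumulate cosines with a plain loop
brute_profile <- function(tree) {
  df <- as.data.frame(tree)
  rownames(df) <- df$id
  one <- function(id) {
    # collect the root path by repeated parent lookup
    path <- id
    while (!is.na(df[path[1], "parent_id"])) {
      path <- c(df[path[1], "parent_id"], path)
    }
    f <- 1
    for (p in path) {
      if (!is.na(df[p, "upstream_angle_deg"])) {
        f <- f * cos(df[p, "upstream_angle_deg"] * pi / 180)
      }
      if (df[p, "kind"] == "bend") {
        f <- f * cos(df[p, "bend_angle_deg"] * pi / 180)
      }
    }
    r <- df[id, "stress_radius_mm"]
    if (is.na(r)) r <- df[id, "radius_mm"]
    c(factor = f, stress = f / (pi * (r / 10)^2))
  }
  t(vapply(df$id, one, c(factor = 0, stress = 0)))
}

# recursive insertion enumeration of all permutations (different algorithm
# from the package's positional expansion)
oracle_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (p in oracle_perms(v[-1])) {
    for (k in 0:length(p)) {
      out[[length(out) + 1]] <- append(p, v[1], after = k)
    }
  }
  out
}

# exact one-sided (lower-tail) permutation p-value for Spearman's rho via
# stats::cor(method = "spearman")
oracle_perm_p <- function(x, y, alternative = "less") {
  obs <- cor(x, y, method = "spearman")
  rhos <- vapply(oracle_perms(seq_along(y)),
                 function(p) cor(x, y[p], method = "spearman"), 0)
  eps <- 1e-12
  switch(alternative,
    less = mean(rhos <= obs + eps),
    greater = mean(rhos >= obs - eps),
    two.sided = mean(abs(rhos) >= abs(obs) - eps)
  )
}

# a minimal single-segment tree
single_segment_tree <- function(radius_mm = 1.0) {
  arterial_tree(data.frame(id = "root", kind = "straight",
                           radius_mm = radius_mm, bend_angle_deg = NA,
                           parent_id = NA))
}

# splice a bend of `angle` between segment `at` and its parent, returning the
# modified tree (used by the monotonicity property)
add_bend_above <- function(tree, at, angle) {
  df <- as.data.frame(tree)
  i <- match(at, df$id)
  new <- df[i, ]
  new$id <- "spliced-bend"
  new$kind <- "bend"
  new$bend_angle_deg <- angle
  new$upstream_angle_deg <- NA
  new$stress_radius_mm <- NA
  new$parent_id <- df$parent_id[i]
  df$parent_id[i] <- "spliced-bend"
  arterial_tree(rbind(df, new))
}
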