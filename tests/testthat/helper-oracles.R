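# Independent brute-force oracles and small fixture builders used across the
# test files. These deliberately avoid the package's own code paths.

# Adjacency bonus computed from first principles: group the four stimulus
# names by the context feature and count groups whose fingers are adjacent.
oracle_adjacency <- function(view) {
  asg <- unclass(view$assignment)
  feats <- strsplit(names(asg), ".", fixed = TRUE)
  ctx <- vapply(feats, `[`, "", if (view$context == "color") 1L else 2L)
  groups <- split(unname(asg), ctx)
  sum(vapply(groups, function(g) abs(g[1] - g[2]) == 1, logical(1)))
}

# Canonical-form pattern oracle: the class of a view is identified by the
# invariant pair (a of this view, a of the other view) plus the P5/P6
# convention, derived by brute force, with no use of classify_pattern().
oracle_pattern_class <- function(view) {
  a1 <- oracle_adjacency(view)
  other <- structure_view(view$assignment,
                          if (view$context == "color") "shape" else "color")
  a2 <- oracle_adjacency(other)
  key <- paste(sort(c(a1, a2), decreasing = TRUE), collapse = "")
  switch(key,
         "20" = if (a1 == 2) "P1" else "P2",
         "10" = if (a1 == 1) "P3" else "P4",
         "21" = if (a1 == 2) "P5" else "P6",
         stop("unexpected adjacency pair ", key))
}

# Exact two-sided binomial p-value by direct pmf enumeration.
oracle_binom_p <- function(k, n, p0 = 0.5) {
  d <- stats::dbinom(0:n, n, p0)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# Adjacency bias by direct elementwise kernel summation.
oracle_adjacency_bias <- function(pi_other) {
  neighbors <- list(2L, c(1L, 3L), c(2L, 4L), 3L)
  bias <- numeric(4)
  for (i in 1:4) {
    for (a in neighbors[[i]]) {
      bias[a] <- bias[a] + pi_other[i] / length(neighbors[[i]])
    }
  }
  bias
}

# Assignment fixtures: color-as-context views of known classes.
fixture_view <- function(class) {
  asg <- switch(class,
    P1 = c(c1.s1 = 1, c1.s2 = 2, c2.s1 = 3, c2.s2 = 4),  # {12|34} vs {13|24}
    P3 = c(c1.s1 = 2, c1.s2 = 3, c2.s1 = 4, c2.s2 = 1),  # {23|14} vs {24|13}
    P5 = c(c1.s1 = 1, c1.s2 = 2, c2.s1 = 4, c2.s2 = 3)   # {12|34} vs {14|23}
  )
  structure_view(contingency_assignment(asg), "color")
}

expect_distribution <- function(p, tol = 1e-12) {
  expect_true(all(p >= -tol))
  expect_equal(sum(p), 1, tolerance = tol)
}
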