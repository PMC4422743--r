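# Shared fixtures, built in code. Expensive objects (the small conformer
# pool and its Debye profiles) are computed once per test run and memoised
# in this environment.

.fixtures <- new.env(parent = emptyenv())

# a tiny 5-residue toy structure with printed coordinates
toy_structure <- function(shift = c(0, 0, 0)) {
  n <- 5
  at <- do.call(rbind, lapply(seq_len(n), function(i) {
    base <- c(3.8 * i, (i %% 2), 0.5 * i)
    data.frame(resno = i, resname = "ALA",
               atom = c("N", "CA", "C", "O", "CB"),
               element = c("N", "C", "C", "O", "C"),
               x = base[1] + c(0, 1.4, 2.4, 2.9, 1.6) + shift[1],
               y = base[2] + c(0, 0.4, -0.3, -1.4, 1.8) + shift[2],
               z = base[3] + c(0, 0.9, 1.7, 1.7, 0.8) + shift[3],
               stringsAsFactors = FALSE)
  }))
  xs_structure(at)
}

# apply a rigid rotation (about z by `angle` degrees) + translation
rigid_move <- function(s, angle = 0, shift = c(0, 0, 0)) {
  th <- angle * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  set_coords(s, sweep(coords(s) %*% t(R), 2, shift, "+"))
}

# small three-level conformer pool + vacuum-free Debye profiles, memoised
fixture_pool <- function() {
  if (is.null(.fixtures$pool)) {
    .fixtures$pool <- generate_pool(
      levels = data.frame(u = c(0, 0.3, 1), undock = c(FALSE, TRUE, FALSE),
                          count = c(17, 17, 16)),
      seed = 11)
  }
  .fixtures$pool
}

fixture_profiles <- function() {
  if (is.null(.fixtures$P)) {
    q <- default_q_grid()
    .fixtures$P <- vapply(fixture_pool(), function(s)
      debye_profile(s, q = q)$intensity, numeric(length(q)))
  }
  .fixtures$P
}

fixture_pool_rg <- function() {
  vapply(fixture_pool(), radius_of_gyration, numeric(1))
}

# uniformly filled sphere of unit point scatterers (Monte Carlo)
sphere_points <- function(n, radius, seed = 42) {
  set.seed(seed)
  pts <- matrix(nrow = 0, ncol = 3)
  while (nrow(pts) < n) {
    cand <- matrix(stats::runif(3 * n, -radius, radius), ncol = 3)
    cand <- cand[rowSums(cand^2) <= radius^2, , drop = FALSE]
    pts <- rbind(pts, cand)
  }
  pts[seq_len(n), ]
}

# analytic sphere form factor, normalized to 1 at q = 0
sphere_form_factor <- function(q, radius) {
  x <- q * radius
  (3 * (sin(x) - x * cos(x)) / x^3)^2
}

# independent naive implementation of the neighbor-count clustering
# (recomputes all counts from scratch every step) — the oracle
naive_daura <- function(m, cutoff) {
  n <- nrow(m)
  unassigned <- seq_len(n)
  clusters <- list()
  while (length(unassigned)) {
    counts <- vapply(unassigned, function(i)
      sum(m[i, unassigned] <= cutoff) - 1L, integer(1))
    founder <- unassigned[which.max(counts)]
    members <- sort(unassigned[m[founder, unassigned] <= cutoff])
    clusters[[length(clusters) + 1L]] <- members
    unassigned <- setdiff(unassigned, members)
  }
  sizes <- lengths(clusters)
  clusters[order(-sizes, vapply(clusters, min, integer(1)))]
}

# random symmetric distance matrix
random_distance_matrix <- function(n, scale = 5) {
  m <- matrix(stats::runif(n * n, 0, scale), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}
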