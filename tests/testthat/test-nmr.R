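test_that("amide vectors are unit length and skip residue 1 and prolines", {
  s <- build_chain(chain_spec(), unfold_spec(0), seed = 91)
  v <- nh_vectors(s)
  expect_equal(unname(sqrt(rowSums(v^2))), rep(1, nrow(v)), tolerance = 1e-12)
  expect_false("1" %in% rownames(v))
  expect_true(any(grepl("N-terminal", attr(v, "skipped"))))
  # proline residues are skipped
  sp <- build_chain(chain_spec(sequence = paste0("AAAPA",
                                                 strrep("A", 56)),
                               helix_segments = list(c(10, 22))),
                    unfold_spec(0.2), seed = 92)
  vp <- nh_vectors(sp)
  expect_false("4" %in% rownames(vp))
  expect_true(any(grepl("proline", attr(vp, "skipped"))))
})

test_that("reconstructed amide H anti-bisects the C(prev)-N-CA angle", {
  # hand-built planar 3-residue geometry: all heavy atoms in the z = 0 plane
  at <- data.frame(
    resno  = c(1, 1, 1, 2, 2, 2),
    resname = "ALA",
    atom   = c("N", "CA", "C", "N", "CA", "C"),
    element = c("N", "C", "C", "N", "C", "C"),
    x = c(0, 1.46, 2.0, 3.3, 4.3, 5.8),
    y = c(0, 0, 1.4, 1.5, 0.5, 0.6),
    z = 0)
  s <- xs_structure(at)
  v <- nh_vectors(s)
  expect_equal(rownames(v), "2")
  # in-plane
  expect_equal(as.numeric(v[1, 3]), 0, tolerance = 1e-12)
  # anti-parallel to the bisector of the C(prev)-N-CA angle
  N <- c(3.3, 1.5, 0); Cp <- c(2.0, 1.4, 0); CA <- c(4.3, 0.5, 0)
  u1 <- (Cp - N) / sqrt(sum((Cp - N)^2))
  u2 <- (CA - N) / sqrt(sum((CA - N)^2))
  bis <- (u1 + u2) / sqrt(sum((u1 + u2)^2))
  expect_equal(as.numeric(v[1, ]), as.numeric(-bis), tolerance = 1e-12)
})

test_that("SVD tensor fit inverts noiseless synthetic couplings exactly", {
  s <- build_chain(chain_spec(), unfold_spec(0), seed = 93)
  tensor <- alignment_tensor(c(3, -2, 1.5, -1, 2.5))
  rdc <- synth_rdc(s, tensor)
  fit <- fit_tensor_svd(nh_vectors(s), rdc)
  expect_equal(fit$tensor$saupe, tensor$saupe, tolerance = 1e-9)
  expect_lt(fit$q, 1e-10)
  # reconstructed Saupe matrix is symmetric and traceless
  M <- fit$tensor$matrix
  expect_equal(M, t(M), tolerance = 1e-12)
  expect_equal(sum(diag(M)), 0, tolerance = 1e-12)
  # all-zero observations: zero tensor, zero predictions
  rdc0 <- rdc_set(rdc$residue, rep(0, nrow(rdc)))
  fit0 <- fit_tensor_svd(nh_vectors(s), rdc0)
  expect_equal(fit0$tensor$saupe, rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(fit0$d_calc), rep(0, length(fit0$d_calc)),
               tolerance = 1e-12)
  expect_error(fit_tensor_svd(nh_vectors(s), rdc, subset = 2:5),
               "underdetermined")
})

test_that("tensor fit is least-squares optimal against random tensors", {
  s <- build_chain(chain_spec(), unfold_spec(0), seed = 94)
  v <- nh_vectors(s)
  tensor <- alignment_tensor(c(2, -1, 1, 3, -2))
  rdc <- synth_rdc(s, tensor, noise_sigma = 2, seed = 95)
  fit <- fit_tensor_svd(v, rdc)
  obs <- rdc$d_obs[match(fit$residues, rdc$residue)]
  best <- sum((fit$d_calc - obs)^2)
  set.seed(96)
  for (i in 1:25) {
    other <- fit$tensor$saupe + rnorm(5, 0, 0.5)
    alt <- predict_rdc(other, v[as.character(fit$residues), ])
    expect_gte(sum((alt - obs)^2), best - 1e-9)
  }
})

test_that("noisy axial-tensor recovery is accurate over many seeds", {
  s <- build_chain(chain_spec(), unfold_spec(0), seed = 97)
  v <- nh_vectors(s)
  axial <- alignment_tensor(c(-1, 2, 0, 0, 0))   # Szz = 2, axially symmetric
  da_true <- axial$Da
  da_hat <- vapply(1:100, function(k) {
    rdc <- synth_rdc(s, axial, noise_sigma = 1, seed = 1000 + k)
    fit_tensor_svd(v, rdc)$tensor$Da
  }, numeric(1))
  expect_lt(abs(mean(da_hat) - da_true) / abs(da_true), 0.1)
})

test_that("Q factor matches hand-computed values and scaling invariance", {
  expect_equal(q_factor(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(q_factor(c(0, 0), c(3, 4)), 1)
  expect_equal(q_factor(c(4, 0), c(4, 3)), 0.6, tolerance = 1e-12)
  d <- rnorm(10); dc <- d + rnorm(10, 0, 0.3)
  expect_equal(q_factor(3 * dc, 3 * d), q_factor(dc, d), tolerance = 1e-12)
  expect_error(q_factor(c(1, 2), c(0, 0)), "undefined")
  expect_error(q_factor(1:3, 1:2), "equal")
})

test_that("self-consistent couplings give a uniformly tiny Q map", {
  s <- build_chain(chain_spec(n_residues = 30,
                              helix_segments = list(c(3, 12), c(17, 28))),
                   unfold_spec(0), seed = 98)
  rdc <- synth_rdc(s, alignment_tensor(c(2, -1, 1, 3, -2)))
  qmap <- sliding_window_q(s, rdc, min_window = 7)
  expect_true(all(qmap$long$q < 1e-9))
  expect_true(all(qmap$long$below_cutoff))
  # windows shorter than min_window are absent
  expect_true(all(qmap$long$end - qmap$long$start + 1 >= 7))
})

test_that("hinge displacement shows up as high whole-range, low core Q", {
  spec <- chain_spec()
  s0 <- build_chain(spec, unfold_spec(0), seed = 99)
  # rotate+shift helix 1 (residues 1-22) rigidly: an undocked intermediate
  idx <- which(s0$atoms$resno <= 22)
  xyz <- coords(s0)
  th <- 70 * pi / 180
  R <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)),
              3, 3, byrow = TRUE)
  ctr <- colMeans(xyz[idx, ])
  xyz[idx, ] <- sweep(sweep(xyz[idx, ], 2, ctr) %*% t(R), 2, ctr + 8, "+")
  s_hinge <- set_coords(s0, xyz)
  rdc <- synth_rdc(s_hinge, alignment_tensor(c(3, -2, 1.5, -1, 2.5)))
  qmap <- sliding_window_q(s0, rdc, min_window = 7)
  long <- qmap$long
  # whole-range windows spanning the hinge disagree
  whole <- long[long$start <= 10 & long$end >= 55, ]
  expect_gt(min(whole$q), 0.25)
  # windows inside the intact 23-61 core still agree (tensor refit per window)
  core <- long[long$start >= 23 & long$end <= 61, ]
  expect_gt(nrow(core), 0)
  expect_lt(max(core$q), 0.05)
})

test_that("power averaging matches hand values and the power-mean ordering", {
  # two members with restraint distances 2 and 4 at n = 3
  expect_equal(((2^-3 + 4^-3) / 2)^(-1 / 3), 2.4228275,
               tolerance = 1e-7)
  at <- function(d) xs_structure(data.frame(
    resno = c(1, 3), resname = "ALA", atom = c("CA", "CA"),
    element = c("C", "C"), x = c(0, d), y = 0, z = 0))
  restr <- restraint_set(1, "CA", 3, "CA", upper = 3)
  ens <- list(at(2), at(4))
  expect_equal(power_average_distances(ens, restr, n = 3),
               ((2^-3 + 4^-3) / 2)^(-1 / 3), tolerance = 1e-12)
  # single member and all-equal cases
  expect_equal(power_average_distances(at(2.5), restr), 2.5, tolerance = 1e-12)
  expect_equal(power_average_distances(list(at(3), at(3), at(3)), restr), 3,
               tolerance = 1e-12)
  # un-normalized literal form: N identical distances average to d N^(-1/n)
  expect_equal(power_average_distances(list(at(3), at(3)), restr,
                                       normalized = FALSE),
               3 * 2^(-1 / 3), tolerance = 1e-12)
  # ordering min <= d(6) <= d(3) <= arithmetic mean on random ensembles
  set.seed(17)
  for (rep in 1:30) {
    ds <- runif(sample(2:6, 1), 2, 8)
    ens <- lapply(ds, at)
    d3 <- power_average_distances(ens, restr, n = 3)
    d6 <- power_average_distances(ens, restr, n = 6)
    expect_lte(min(ds), d6 + 1e-12)
    expect_lte(d6, d3 + 1e-12)
    expect_lte(d3, mean(ds) + 1e-12)
  }
  expect_error(power_average_distances(at(2), restraint_set(1, "CA", 5, "XX", 3)),
               "missing atom")
})

test_that("violation counting honors bounds, tolerance and reporting", {
  s <- build_chain(chain_spec(), unfold_spec(0), seed = 101)
  restr <- synth_restraints(s, seed = 102)
  dbar <- power_average_distances(s, restr)
  v <- count_violations(dbar, restr)
  expect_equal(v$count, 0)          # margin > 0: none of its own restraints
  expect_equal(v$fraction, 0)
  # plant 3 violations in a 735-restraint set
  expect_equal(v$total, 735)
  d2 <- dbar; d2[c(10, 200, 700)] <- restr$upper[c(10, 200, 700)] + 1
  v2 <- count_violations(d2, restr)
  expect_equal(v2$count, 3)
  expect_equal(v2$fraction, 3 / 735, tolerance = 1e-12)
  expect_equal(sort(as.integer(names(v2$excess))), c(10L, 200L, 700L))
  # tolerance semantics: excesses (0.3, 0.7) at tolerance 0.5 -> one violation
  d3 <- dbar; d3[c(1, 2)] <- restr$upper[c(1, 2)] + c(0.3, 0.7)
  expect_equal(count_violations(d3, restr, tolerance = 0.5)$count, 1)
  # count is non-increasing in tolerance
  set.seed(5)
  d4 <- dbar + runif(735, -0.5, 0.5)
  counts <- vapply(c(0, 0.2, 0.5, 1), function(tol)
    count_violations(d4, restr, tol)$count, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("unfolded conformers violate native-derived restraints heavily", {
  native <- build_chain(chain_spec(), unfold_spec(0), seed = 103)
  restr <- synth_restraints(native, seed = 104)
  unfolded <- build_chain(chain_spec(), unfold_spec(1), seed = 105)
  v <- count_violations(power_average_distances(unfolded, restr), restr)
  expect_gt(v$fraction, 0.05)
})

test_that("RDC and restraint tables round-trip through TSV", {
  rdc <- rdc_set(2:20, rnorm(19, 0, 5), error = 0.5)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_rdc(rdc, tmp)
  back <- read_rdc(tmp)
  expect_equal(back$residue, rdc$residue)
  expect_equal(back$d_obs, rdc$d_obs, tolerance = 1e-9)
  s <- build_chain(chain_spec(), unfold_spec(0), seed = 106)
  restr <- synth_restraints(s, max_count = 50, seed = 107)
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_restraints(restr, tmp2)
  back2 <- read_restraints(tmp2)
  expect_equal(nrow(back2), 50)
  expect_equal(back2$upper, restr$upper, tolerance = 1e-9)
  expect_equal(back2$atom_i, restr$atom_i)
  expect_error(rdc_set(c(1, 1), c(2, 3)), "unique")
  expect_error(restraint_set(1, "CA", 1, "CA", 3), "distinct")
  expect_error(restraint_set(1, "CA", 2, "CA", -1), "positive")
})
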