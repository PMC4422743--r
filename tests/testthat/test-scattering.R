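test_that("profile invariants guard against bad grids and unit mix-ups", {
  expect_error(scattering_profile(c(0.1, 0.1, 0.2), c(1, 1, 1)), "increasing")
  expect_error(scattering_profile(c(1, 2, 3), c(1, 1, 1)), "\\[0, 1\\]")
  expect_error(scattering_profile(c(0.1, 0.2), c(1, -1)), "positive")
  expect_error(scattering_profile(c(0.1, 0.2), c(1, 1), sigma = c(1, 0)),
               "sigma")
})

test_that("profile files round-trip through the 3-column text format", {
  p <- scattering_profile(seq(0.01, 0.5, by = 0.01),
                          100 * exp(-seq(0.01, 0.5, by = 0.01)^2 * 50),
                          sigma = rep(0.5, 50), label = "toy")
  tmp <- withr::local_tempfile(fileext = ".dat")
  write_profile(p, tmp)
  back <- read_profile(tmp)
  expect_equal(back$q, p$q)
  expect_equal(back$intensity, p$intensity, tolerance = 1e-6)
  expect_equal(back$sigma, p$sigma, tolerance = 1e-6)
})

test_that("form factors reproduce electron counts at q = 0", {
  expect_equal(atomic_form_factor("C", 0), 6, tolerance = 2e-3)
  expect_equal(atomic_form_factor("N", 0), 7, tolerance = 6e-3)
  expect_equal(atomic_form_factor("O", 0), 8, tolerance = 2e-3)
  expect_equal(atomic_form_factor("H", 0), 1, tolerance = 2e-3)
  expect_equal(atomic_form_factor("S", 0), 16, tolerance = 8e-3)
  expect_error(atomic_form_factor("ZZ", 0.1), "no form-factor entry")
})

test_that("single-atom and two-point Debye sums match closed forms", {
  one_c <- xs_structure(data.frame(resno = 1, resname = "LIG", atom = "C1",
                                   element = "C", x = 0, y = 0, z = 0))
  q <- c(0.01, 0.1, 0.5)
  p <- debye_profile(one_c, q = q, vacuum = TRUE, method = "direct")
  expect_equal(p$intensity, atomic_form_factor("C", q)^2, tolerance = 1e-12)
  # two identical scatterers at distance d: I = 2 f^2 (1 + sin(qd)/(qd))
  d <- 4
  two <- xs_structure(data.frame(resno = 1:2, resname = "LIG",
                                 atom = c("C1", "C2"), element = "C",
                                 x = c(0, d), y = 0, z = 0))
  q2 <- c(0.05, 0.2, pi / d)
  f <- atomic_form_factor("C", q2)
  p2 <- debye_profile(two, q = q2, vacuum = TRUE, method = "direct")
  expect_equal(p2$intensity, 2 * f^2 * (1 + sin(q2 * d) / (q2 * d)),
               tolerance = 1e-12)
  # at q = pi/d the cross term vanishes: I = 2 f^2
  expect_equal(p2$intensity[3], 2 * f[3]^2, tolerance = 1e-12)
  expect_error(debye_profile(xs_structure(
    data.frame(resno = 1, resname = "LIG", atom = "X1", element = "XX",
               x = 0, y = 0, z = 0)), q = q), "no form-factor entry")
})

test_that("Monte-Carlo sphere matches the analytic sphere form factor", {
  pts <- sphere_points(2000, 15)
  # unit point scatterers: use the direct pair sum with constant factor 1
  q <- seq(0.01, 0.3, by = 0.005)
  D <- stats::dist(pts)
  dv <- as.vector(D)
  I <- vapply(q, function(qq)
    2000 + 2 * sum(sin(qq * dv) / (qq * dv)), numeric(1))
  I0 <- 2000 + 2 * length(dv)
  dev <- I / I0 - sphere_form_factor(q, 15)
  expect_lt(sqrt(mean(dev^2)), 0.02)
})

test_that("pair-histogram acceleration agrees with the direct double sum", {
  s <- build_chain(chain_spec(), unfold_spec(0.3), seed = 71)
  ph <- debye_profile(s)
  pd <- debye_profile(s, method = "direct")
  rel <- ph$intensity / pd$intensity - 1
  expect_lt(sqrt(mean(rel^2)), 1e-3)
  expect_true(all(ph$intensity > 0))
  expect_error(debye_profile(s, bin_width = 0.5), "bin_width")
})

test_that("I(0) equals the squared sum of effective factors", {
  s <- build_chain(chain_spec(n_residues = 10,
                              helix_segments = list(c(2, 9))),
                   unfold_spec(0), seed = 72)
  for (vac in c(TRUE, FALSE)) {
    p0 <- debye_profile(s, q = c(0, 0.05), vacuum = vac, method = "direct")
    # at q = 0 every sinc is 1, so I(0) = (sum_i g_i(0))^2; the builder
    # emits explicit amide H, so no united-atom increments apply
    elem <- toupper(s$atoms$element)
    nh <- if (any(elem == "H")) integer(nrow(s$atoms))
          else saxsens:::.implicit_h(s$atoms)
    g0 <- vapply(seq_along(elem), function(i) {
      f <- atomic_form_factor(elem[i], 0) + nh[i] * atomic_form_factor("H", 0)
      V <- saxsens:::.displaced_volume[[elem[i]]] +
        nh[i] * saxsens:::.displaced_volume[["H"]]
      f - (if (vac) 0 else 0.340) * V
    }, numeric(1))
    expect_equal(p0$intensity[1], sum(g0)^2, tolerance = 1e-9)
  }
})

test_that("Guinier fit recovers the exact model and rejects flat profiles", {
  q <- seq(0.01, 0.1, by = 0.002)
  p <- scattering_profile(q, 100 * exp(-q^2 * 13^2 / 3))
  g <- guinier_fit(p, c(0.01, 0.1))
  expect_equal(g$rg, 13, tolerance = 1e-6)
  expect_equal(g$i0, 100, tolerance = 1e-6)
  flat <- scattering_profile(q, rep(5, length(q)))
  expect_error(guinier_fit(flat), "no Guinier decay")
  expect_error(guinier_fit(p, c(0.01, 0.015)), "fewer than 5")
  wide <- scattering_profile(seq(0.01, 0.4, 0.002),
                             100 * exp(-seq(0.01, 0.4, 0.002)^2 * 13^2 / 3))
  expect_warning(guinier_fit(wide, c(0.01, 0.4)), "1.3")
})

test_that("Guinier Rg of a Debye profile matches the coordinate Rg", {
  s <- build_chain(chain_spec(), unfold_spec(0), seed = 3)
  rg_coord <- radius_of_gyration(s)
  p <- debye_profile(s, vacuum = TRUE)
  g <- guinier_fit(p, q_window = c(0.01, 1.3 / rg_coord))
  expect_lt(abs(g$rg - rg_coord) / rg_coord, 0.02)
})

test_that("Guinier Rg increases with coordinate Rg across conformers", {
  pool <- lapply(1:5, function(k)
    build_chain(chain_spec(), unfold_spec(u = (k - 1) / 4), seed = 80 + k))
  rg_coord <- vapply(pool, radius_of_gyration, numeric(1))
  ord <- order(rg_coord)
  rg_guinier <- vapply(pool[ord], function(s)
    guinier_fit(debye_profile(s, vacuum = TRUE),
                q_window = c(0.01, 1.3 / radius_of_gyration(s)))$rg,
    numeric(1))
  expect_true(all(diff(rg_guinier) > 0))
})

test_that("log-space resampling is exact on its own grid and refuses extrapolation", {
  q <- seq(0.01, 0.5, by = 0.005)
  p <- scattering_profile(q, 80 * exp(-25 * q), sigma = 0.01 * 80 * exp(-25 * q))
  expect_equal(resample_log(p, q)$intensity, p$intensity, tolerance = 1e-12)
  mid <- (q[-1] + q[-length(q)]) / 2
  r <- resample_log(p, mid)
  expect_equal(r$intensity, 80 * exp(-25 * mid), tolerance = 5e-3)
  expect_equal(r$sigma, approx(q, p$sigma, mid)$y, tolerance = 1e-12)
  expect_error(resample_log(p, c(0.005, 0.1)), "outside")
})

test_that("ensemble averaging is a count-weighted mean in intensity space", {
  q <- seq(0.05, 0.3, by = 0.05)
  p1 <- scattering_profile(q, rep(4, 6))
  p2 <- scattering_profile(q, rep(8, 6))
  expect_equal(ensemble_average(list(p1), 1)$intensity, p1$intensity)
  avg <- ensemble_average(list(p1, p2), c(3, 1))
  expect_equal(avg$intensity, 0.75 * p1$intensity + 0.25 * p2$intensity)
  # permutation with matched counts changes nothing
  expect_equal(ensemble_average(list(p2, p1), c(1, 3))$intensity,
               avg$intensity)
  # all-equal counts = plain mean
  expect_equal(ensemble_average(list(p1, p2), c(2, 2))$intensity,
               (p1$intensity + p2$intensity) / 2)
  expect_error(ensemble_average(list(p1, p2), c(1.5, 1)), "integers")
  p3 <- scattering_profile(q + 0.01, rep(4, 6))
  expect_error(ensemble_average(list(p1, p3), c(1, 1)), "grids")
})

test_that("fit target is scale-invariant with the closed-form log scale", {
  q <- seq(0.07, 0.7, by = 0.005)
  m <- scattering_profile(q, 50 * exp(-10 * q) + 1)
  expect_equal(fit_target(m, m)$score, 0, tolerance = 1e-12)
  expect_equal(fit_target(m, m)$scale, 1, tolerance = 1e-12)
  ten <- scattering_profile(q, 10 * m$intensity)
  ft <- fit_target(m, ten)
  expect_equal(ft$score, 0, tolerance = 1e-12)
  expect_equal(ft$scale, 10, tolerance = 1e-12)
  # multiplying either curve by a positive constant leaves the score alone
  half <- scattering_profile(q, 0.5 * m$intensity)
  noisy <- scattering_profile(q, m$intensity * exp(rnorm(length(q), 0, 0.05)))
  expect_equal(fit_target(half, noisy)$score, fit_target(m, noisy)$score,
               tolerance = 1e-9)
  expect_error(fit_target(m, m, q_window = c(0.8, 0.9)), "empty")
})

test_that("alternating log-residuals give score m * delta^2", {
  # 6-point toy grid with ln-space residuals +d, -d, ... mean-centering
  # leaves residuals at exactly +/- d, so the score is 6 d^2
  q <- seq(0.1, 0.6, by = 0.1)
  delta <- 0.3
  base <- c(20, 15, 11, 8, 6, 5)
  expt <- scattering_profile(q, base * exp(delta * c(1, -1, 1, -1, 1, -1)))
  model <- scattering_profile(q, base)
  expect_equal(fit_target(model, expt, q_window = c(0.05, 0.7))$score,
               6 * delta^2, tolerance = 1e-12)
})
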