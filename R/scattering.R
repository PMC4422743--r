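# Solution X-ray scattering: Debye-equation profiles with excluded-volume
# solvent correction, Guinier analysis, grid handling, ensemble averaging and
# the log-intensity least-squares fit target.

#' Scattering profile object
#'
#' Intensity (and optional uncertainty) on a momentum-transfer grid.
#' q is in inverse Angstrom and restricted to [0, 1] to guard against
#' accidental nm^-1 input; intensities are strictly positive (arbitrary
#' units).
#'
#' @param q strictly increasing grid, 1/Angstrom.
#' @param intensity positive intensities, same length as `q`.
#' @param sigma optional positive uncertainties, same length.
#' @param label provenance tag (temperature, structure id, ...).
#' @return An object of class `xs_profile`.
#' @export
scattering_profile <- function(q, intensity, sigma = NULL, label = NULL) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (length(q) != length(intensity))
    stop("q and intensity lengths differ")
  if (any(!is.finite(q)) || any(q < 0) || any(q > 1))
    stop("q must be finite and within [0, 1] 1/Angstrom (nm^-1 input?)")
  if (is.unsorted(q, strictly = TRUE)) stop("q must be strictly increasing")
  if (any(!is.finite(intensity)) || any(intensity <= 0))
    stop("intensity must be finite and strictly positive")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q) || any(!is.finite(sigma)) || any(sigma <= 0))
      stop("sigma must be positive and the same length as q")
  }
  structure(list(q = q, intensity = intensity, sigma = sigma, label = label),
            class = "xs_profile")
}

#' @export
print.xs_profile <- function(x, ...) {
  cat(sprintf("<xs_profile>%s %d points, q [%.3f, %.3f] 1/A\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' @export
plot.xs_profile <- function(x, ..., log = "y") {
  graphics::plot(x$q, x$intensity, type = "l", log = log,
                 xlab = expression(q ~ (ring(A)^-1)), ylab = "I(q) (a.u.)",
                 main = x$label, ...)
  invisible(x)
}

#' Default q grid
#'
#' Uniform grid 0.01 to 0.7 1/Angstrom in steps of 0.005, mirroring a
#' typical measured S/WAXS range; structural fitting then uses the
#' [0.07, 0.7] window (below 0.07 particle/aggregation scattering
#' dominates).
#'
#' @param q_min,q_max,step grid limits and spacing, 1/Angstrom.
#' @return numeric vector.
#' @export
default_q_grid <- function(q_min = 0.01, q_max = 0.7, step = 0.005) {
  seq(q_min, q_max, by = step)
}

#' Read / write 3-column scattering profiles
#'
#' Whitespace-delimited text (q in 1/Angstrom, I, optional sigma), `#`
#' comments — the de facto ATSAS .dat layout.
#'
#' @param path file path.
#' @param label optional label attached on read.
#' @return `read_profile`: an `xs_profile`. `write_profile`: `path`,
#'   invisibly.
#' @export
read_profile <- function(path, label = NULL) {
  tab <- utils::read.table(path, comment.char = "#")
  if (ncol(tab) < 2) stop("profile file must have at least 2 columns")
  scattering_profile(tab[[1]], tab[[2]],
                     sigma = if (ncol(tab) >= 3) tab[[3]] else NULL,
                     label = if (is.null(label)) basename(path) else label)
}

#' @param p an `xs_profile`.
#' @rdname read_profile
#' @export
write_profile <- function(p, path) {
  hdr <- sprintf("# q(1/A) I(q)%s%s", if (is.null(p$sigma)) "" else " sigma",
                 if (is.null(p$label)) "" else paste0("  [", p$label, "]"))
  m <- if (is.null(p$sigma)) cbind(p$q, p$intensity)
       else cbind(p$q, p$intensity, p$sigma)
  writeLines(c(hdr, apply(m, 1, function(r)
    paste(formatC(r, digits = 8, format = "g"), collapse = " "))), path)
  invisible(path)
}

# ---- form factors -----------------------------------------------------------

# Four-Gaussian vacuum form factors (International Tables convention,
# f(q) = sum a_i exp(-b_i (q/4pi)^2) + c) and per-atom displaced solvent
# volumes (dummy-atom spheres at bulk density).
.cromer_mann <- list(
  H = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
           b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305),
  C = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
           b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
           b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
           b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  S = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
           b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900),
  # ideal unit point scatterer (f = 1 at all q): geometric oracles such as
  # the uniform-sphere form factor use it to probe the pair sum alone
  X = list(a = c(0, 0, 0, 0), b = c(0, 0, 0, 0), c = 1)
)

.displaced_volume <- c(H = 5.15, C = 16.44, N = 2.49, O = 9.13, S = 19.86,
                       X = 1)

#' Element form-factor and displaced-volume table
#'
#' Per-element q-dependent vacuum form factors (sum-of-Gaussians) and
#' displaced solvent volumes. In united-atom mode the electrons and volume
#' of hydrogens bonded to a heavy atom are folded into that atom, so
#' hydrogen-less backbone models scatter correctly. The pseudo-element `X`
#' is an ideal unit point scatterer (f identically 1) used by geometric
#' oracles (e.g. the uniform-sphere form factor) that probe the Debye pair
#' sum independent of atomic form-factor decay.
#'
#' @return An object of class `xs_fftable` (list of coefficient sets and
#'   volumes).
#' @export
form_factor_table <- function() {
  structure(list(cm = .cromer_mann, volume = .displaced_volume),
            class = "xs_fftable")
}

#' Vacuum atomic form factor
#'
#' @param element element symbol present in the table.
#' @param q momentum transfer, 1/Angstrom.
#' @param table an `xs_fftable`.
#' @return f(q), electrons.
#' @export
atomic_form_factor <- function(element, q, table = form_factor_table()) {
  cm <- table$cm[[toupper(element)]]
  if (is.null(cm)) stop("no form-factor entry for element ", element)
  s2 <- (q / (4 * pi))^2
  f <- rep(cm$c, length(q))
  for (i in seq_along(cm$a)) f <- f + cm$a[i] * exp(-cm$b[i] * s2)
  f
}

#' Bulk-solvent model
#'
#' @param electron_density bulk solvent electron density, electrons per
#'   cubic Angstrom (default 0.340, i.e. 340 e/nm^3, the value for water
#'   matched to experiment).
#' @param shell_contrast hydration-shell contrast, e/A^3 (default 0: for a
#'   small protein with fast side-chain dynamics the shell term is dropped).
#' @return An object of class `xs_solvent`.
#' @export
solvent_model <- function(electron_density = 0.340, shell_contrast = 0) {
  if (electron_density < 0.30 || electron_density > 0.40)
    stop("electron_density outside the plausible range [0.30, 0.40] e/A^3")
  if (shell_contrast < 0) stop("shell_contrast must be >= 0")
  structure(list(electron_density = electron_density,
                 shell_contrast = shell_contrast), class = "xs_solvent")
}

# implicit hydrogen count for united-atom mode: backbone + CB chemistry
.implicit_h <- function(atoms) {
  nh <- integer(nrow(atoms))
  at <- atoms$atom; rn <- atoms$resname
  nh[at == "N"]  <- ifelse(rn[at == "N"] == "PRO", 0L, 1L)
  nh[at == "CA"] <- ifelse(rn[at == "CA"] == "GLY", 2L, 1L)
  nh[at == "CB"] <- ifelse(rn[at == "CB"] == "ALA", 3L, 2L)
  nh
}

#' Theoretical scattering profile by the Debye equation
#'
#' Computes I(q) = sum_ij g_i(q) g_j(q) sin(q d_ij)/(q d_ij) with
#' g_i(q) = f_i(q) - rho_s V_i exp(-pi V_i^(2/3) q^2), the solvent-corrected
#' effective form factor of the dummy-atom excluded-volume convention.
#' The diagonal and q -> 0 limits use sin(x)/x -> 1. When the structure
#' carries no explicit hydrogens, hydrogen electrons and volumes are folded
#' into the bonded heavy atoms (united-atom mode).
#'
#' The default evaluation bins pair distances (bin width `bin_width`,
#' contributions taken at the per-bin mean distance) which reduces the cost
#' from n_pairs x n_q to n_bins x n_q; `method = "direct"` evaluates the
#' exact double sum and serves as the internal reference.
#'
#' @param s an `xs_structure`.
#' @param q q grid, 1/Angstrom, within [0, 1].
#' @param solvent an `xs_solvent`; use `electron_density = 0` via
#'   `vacuum = TRUE` for vacuum scattering.
#' @param table an `xs_fftable`.
#' @param method `"hist"` (pair-distance binning) or `"direct"`.
#' @param bin_width histogram bin width in Angstrom (must be <= 0.1).
#' @param vacuum logical; ignore the solvent term.
#' @return An `xs_profile` labelled with the structure's model id.
#' @export
debye_profile <- function(s, q = default_q_grid(), solvent = solvent_model(),
                          table = form_factor_table(),
                          method = c("hist", "direct"), bin_width = 0.02,
                          vacuum = FALSE) {
  method <- match.arg(method)
  if (bin_width > 0.1) stop("bin_width must be <= 0.1 Angstrom")
  if (any(q < 0) || any(q > 1)) stop("q grid outside [0, 1] 1/Angstrom")
  atoms <- s$atoms
  elem <- toupper(atoms$element)
  unknown <- setdiff(unique(elem), names(table$cm))
  if (length(unknown))
    stop("no form-factor entry for element(s): ",
         paste(unknown, collapse = ", "), " (atoms ",
         paste(utils::head(which(elem %in% unknown), 5), collapse = ","), ")")
  united <- !any(elem == "H")
  nh <- if (united) .implicit_h(atoms) else integer(nrow(atoms))
  rho <- if (vacuum) 0 else solvent$electron_density

  cls <- paste0(elem, ".", nh)
  ucls <- unique(cls)
  idx_by_cls <- split(seq_len(nrow(atoms)), factor(cls, levels = ucls))
  # effective factor per class: f_elem + nH * f_H - rho * V * exp(-pi V^(2/3) q^2)
  g <- vapply(ucls, function(k) {
    i <- idx_by_cls[[k]][1]
    f <- atomic_form_factor(elem[i], q, table) +
      nh[i] * atomic_form_factor("H", q, table)
    V <- table$volume[[elem[i]]] + nh[i] * table$volume[["H"]]
    f - rho * V * exp(-pi * V^(2 / 3) * q^2)
  }, numeric(length(q)))                      # n_q x n_class

  xyz <- coords(s)
  D <- as.matrix(stats::dist(xyz))
  nq <- length(q)
  I <- numeric(nq)
  nc <- length(ucls)
  for (a in seq_len(nc)) {
    for (b in a:nc) {
      ia <- idx_by_cls[[a]]; ib <- idx_by_cls[[b]]
      if (a == b) {
        I <- I + length(ia) * g[, a]^2        # self terms
        if (length(ia) < 2) next
        dsub <- D[ia, ia, drop = FALSE]
        dvec <- dsub[upper.tri(dsub)]
      } else {
        dvec <- as.vector(D[ia, ib, drop = FALSE])
      }
      coef <- 2 * g[, a] * g[, b]
      I <- I + coef * .debye_pair_sum(dvec, q, method, bin_width)
    }
  }
  scattering_profile(q, I, label = sprintf("model %d", s$model_id))
}

# sum over pairs of sinc(q d); histogram path uses per-bin mean distances
.debye_pair_sum <- function(dvec, q, method, bin_width) {
  if (!length(dvec)) return(numeric(length(q)))
  if (method == "hist") {
    bins <- pmax(1L, ceiling(dvec / bin_width))
    cnt <- tabulate(bins)
    nz <- which(cnt > 0)
    sums <- rowsum(dvec, bins)
    dbar <- as.vector(sums) / cnt[nz]
    w <- cnt[nz]
  } else {
    dbar <- dvec
    w <- rep(1, length(dvec))
  }
  x <- outer(q, dbar)                          # n_q x n_d
  sinc <- ifelse(x == 0, 1, sin(x) / ifelse(x == 0, 1, x))
  as.vector(sinc %*% w)
}

# ---- Guinier ----------------------------------------------------------------

#' Guinier fit
#'
#' Least-squares line of ln I against q^2 inside the given window;
#' Rg = sqrt(-3 slope). Warns when q_hi * Rg exceeds 1.3, the usual validity
#' limit of the Guinier approximation.
#'
#' @param p an `xs_profile`.
#' @param q_window `c(q_lo, q_hi)` in 1/Angstrom (default `c(0.01, 0.1)`,
#'   appropriate for a small protein).
#' @return list with `rg` (Angstrom), `i0`, `n_points`, and `q_rg_max`.
#' @export
guinier_fit <- function(p, q_window = c(0.01, 0.1)) {
  keep <- p$q >= q_window[1] & p$q <= q_window[2]
  if (sum(keep) < 5) stop("fewer than 5 grid points in the Guinier window")
  q2 <- p$q[keep]^2
  lnI <- log(p$intensity[keep])
  fit <- stats::lm.fit(cbind(1, q2), lnI)
  slope <- fit$coefficients[2]
  if (!is.finite(slope) || slope >= -1e-12)
    stop("no Guinier decay: ln I does not decrease with q^2 in the window")
  rg <- sqrt(-3 * slope)
  qrg <- max(p$q[keep]) * rg
  if (qrg > 1.3)
    warning(sprintf("Guinier window extends to q*Rg = %.2f (> 1.3)", qrg))
  list(rg = unname(rg), i0 = unname(exp(fit$coefficients[1])),
       n_points = sum(keep), q_rg_max = unname(qrg))
}

#' Resample a profile onto a target grid
#'
#' Linear interpolation of ln I (and of sigma) against q; extrapolation is
#' refused.
#'
#' @param p an `xs_profile`.
#' @param grid target q grid inside the source range.
#' @return An `xs_profile` on `grid`.
#' @export
resample_log <- function(p, grid) {
  if (min(grid) < min(p$q) || max(grid) > max(p$q))
    stop(sprintf("target grid [%g, %g] outside source range [%g, %g]",
                 min(grid), max(grid), min(p$q), max(p$q)))
  lnI <- stats::approx(p$q, log(p$intensity), xout = grid)$y
  sig <- if (is.null(p$sigma)) NULL else stats::approx(p$q, p$sigma, xout = grid)$y
  scattering_profile(grid, exp(lnI), sigma = sig, label = p$label)
}

#' Repetition-weighted ensemble average of profiles
#'
#' Ibar(q) = sum_k c_k I_k(q) / sum_k c_k — averaging in intensity space
#' (never in log space), with integer multiplicities playing the role of
#' weights.
#'
#' @param profiles list of `xs_profile` objects on identical q grids, or a
#'   numeric matrix of intensities (n_q x n_profiles) with attribute-free
#'   columns.
#' @param counts positive integer multiplicities, one per profile.
#' @param q q grid when `profiles` is a matrix.
#' @return An `xs_profile`.
#' @export
ensemble_average <- function(profiles, counts = NULL, q = NULL) {
  if (is.matrix(profiles)) {
    P <- profiles
    if (is.null(q)) stop("q grid required with a matrix of intensities")
  } else {
    q <- profiles[[1]]$q
    for (p in profiles)
      if (length(p$q) != length(q) || any(p$q != q))
        stop("profiles are not on identical q grids")
    P <- vapply(profiles, function(p) p$intensity, numeric(length(q)))
  }
  if (is.null(counts)) counts <- rep(1L, ncol(P))
  if (length(counts) != ncol(P)) stop("one count per profile required")
  if (any(counts <= 0) || any(counts != round(counts)))
    stop("counts must be positive integers")
  scattering_profile(q, as.vector(P %*% counts) / sum(counts),
                     label = "ensemble average")
}

#' Log-intensity least-squares fit target
#'
#' The optimization target: after the closed-form log-space scale
#' ln c = mean(ln I_exp - ln I_model), the score is
#' sum_q (ln I_exp - ln(c I_model))^2 over the fitting window. The free
#' multiplicative scale makes the target independent of concentration and
#' absolute calibration.
#'
#' @param model,experiment `xs_profile` objects. If their grids differ the
#'   model is resampled (log-linearly) onto the experimental grid within the
#'   window.
#' @param q_window fitting window, default `c(0.07, 0.7)` 1/Angstrom (the
#'   low-q cut excludes aggregation-affected scattering).
#' @param sigma_weight weight residuals by 1/sigma of the experiment
#'   (default FALSE: plain square difference).
#' @return list with `score` (>= 0) and `scale`.
#' @export
fit_target <- function(model, experiment, q_window = c(0.07, 0.7),
                       sigma_weight = FALSE) {
  keep <- experiment$q >= q_window[1] & experiment$q <= q_window[2]
  if (!any(keep)) stop("empty fitting window")
  qg <- experiment$q[keep]
  same <- length(model$q) == length(experiment$q) &&
    all(model$q == experiment$q)
  Imod <- if (same) model$intensity[keep] else resample_log(model, qg)$intensity
  lexp <- log(experiment$intensity[keep])
  lmod <- log(Imod)
  w <- if (sigma_weight) {
    if (is.null(experiment$sigma)) stop("experiment has no sigma column")
    (experiment$intensity[keep] / experiment$sigma[keep])^2  # weights on ln I
  } else rep(1, length(qg))
  lnc <- sum(w * (lexp - lmod)) / sum(w)
  r <- lexp - lmod - lnc
  list(score = sum(w * r^2), scale = exp(lnc))
}
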