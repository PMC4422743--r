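# Synthetic data with known ground truth: conformer pools with controlled
# unfolding (emulating MD sampling of a small three-helix bundle), mixture
# scattering "experiments" with noise, RDC sets from known alignment
# tensors, and NOE-style restraint sets harvested from a reference
# structure.

#' Chain specification for the synthetic conformer generator
#'
#' Describes a small helical protein: by default a 61-residue chain with
#' three helical segments (the three-helix-bundle topology of a
#' homeodomain), poly-alanine with glycine at the inter-helix turns.
#'
#' @param n_residues chain length (default 61).
#' @param helix_segments list of `c(first, last)` residue ranges (default
#'   10-22, 28-38, 42-55).
#' @param sequence optional 1-letter sequence string overriding the
#'   default.
#' @return An object of class `chain_spec`.
#' @export
chain_spec <- function(n_residues = 61L,
                       helix_segments = list(c(10L, 22L), c(28L, 38L),
                                             c(42L, 55L)),
                       sequence = NULL) {
  n_residues <- as.integer(n_residues)
  for (seg in helix_segments)
    if (seg[1] < 1 || seg[2] > n_residues || seg[1] > seg[2])
      stop("helix segment outside [1, n_residues]")
  segs <- do.call(rbind, helix_segments)
  if (nrow(segs) > 1) {
    o <- order(segs[, 1]); segs <- segs[o, , drop = FALSE]
    if (any(segs[-1, 1] <= segs[-nrow(segs), 2]))
      stop("helix segments must be disjoint")
  }
  helical <- logical(n_residues)
  for (seg in helix_segments) helical[seg[1]:seg[2]] <- TRUE
  if (is.null(sequence)) {
    aa <- rep("ALA", n_residues)
    core <- seq(min(segs[, 1]), max(segs[, 2]))
    aa[core[!helical[core]]] <- "GLY"          # glycine at the turns
  } else {
    if (nchar(sequence) != n_residues)
      stop("sequence length must equal n_residues")
    map <- c(A = "ALA", G = "GLY", P = "PRO")
    aa1 <- strsplit(toupper(sequence), "")[[1]]
    aa <- map[aa1]
    if (anyNA(aa)) stop("sequence may only contain A, G, P (backbone model)")
  }
  structure(list(n_residues = n_residues, helix_segments = helix_segments,
                 helical = helical, resnames = unname(aa)),
            class = "chain_spec")
}

#' Unfolding specification
#'
#' Controls how far a generated conformer departs from the native helical
#' topology. With probability `u` each helical residue's dihedrals are
#' resampled from the coil model (turn residues always are); `undock`
#' additionally displaces the first helix rigidly by 10-20 Angstrom with a
#' random rotation (an intermediate-like conformer whose H2-H3 unit stays
#' intact). Native draws (`u = 0`, no undock) are accepted only below
#' `rg_max`, emulating sampling confined to the compact native basin;
#' random turn dihedrals alone do not encode tertiary docking, so without
#' the acceptance bound "native" chains would occasionally splay open.
#'
#' @param u unfolding degree in \[0, 1\].
#' @param undock rigidly displace the first helix (plus its N-terminal
#'   tail).
#' @param coil_weights mixture weights of the beta, PPII and alpha-R coil
#'   basins.
#' @param coil_sd circular standard deviation of the coil basins, degrees.
#' @param rg_max acceptance bound on Rg, Angstrom; default 15.5 for native
#'   draws, unbounded otherwise.
#' @return An object of class `unfold_spec`.
#' @export
unfold_spec <- function(u = 0, undock = FALSE,
                        coil_weights = c(beta = 0.4, ppii = 0.4, alpha = 0.2),
                        coil_sd = 20, rg_max = NULL) {
  if (u < 0 || u > 1) stop("u must be in [0, 1]")
  if (is.null(rg_max)) rg_max <- if (u == 0 && !undock) 15.5 else Inf
  structure(list(u = u, undock = isTRUE(undock),
                 coil_weights = coil_weights / sum(coil_weights),
                 coil_sd = coil_sd, rg_max = rg_max),
            class = "unfold_spec")
}

# coil (phi, psi) basins: beta, polyproline-II, alpha-R (degrees)
.coil_basins <- matrix(c(-120, 130, -75, 145, -60, -45), ncol = 2,
                       byrow = TRUE)

.draw_coil <- function(n, unfold) {
  k <- sample.int(3L, n, replace = TRUE, prob = unfold$coil_weights)
  cbind(phi = .coil_basins[k, 1] + stats::rnorm(n, 0, unfold$coil_sd),
        psi = .coil_basins[k, 2] + stats::rnorm(n, 0, unfold$coil_sd))
}

# NeRF placement: position of a new atom bonded to c, given the chain
# a-b-c, the bond length, the angle b-c-new and the dihedral a-b-c-new
# (degrees)
.place_atom <- function(a, b, c, bond, angle, dihedral) {
  th <- angle * pi / 180; chi <- dihedral * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(th), bond * sin(th) * cos(chi),
         -bond * sin(th) * sin(chi))
  c + d[1] * bc + d[2] * m + d[3] * n
}

#' Dihedral angle of four points
#'
#' @param a,b,c,d 3-vectors.
#' @return signed dihedral in degrees.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  m1 <- cr(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# uniform random rotation matrix (quaternion method)
.random_rotation <- function() {
  qv <- stats::rnorm(4)
  qv <- qv / sqrt(sum(qv^2))
  w <- qv[1]; x <- qv[2]; y <- qv[3]; z <- qv[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Build one synthetic conformer
#'
#' Constructs a backbone (N, CA, C, O, CB, amide H) by sequential
#' internal-coordinate placement with idealized geometry (N-CA 1.458,
#' CA-C 1.525, C-N 1.329 Angstrom, omega = 180 degrees). Helical residues
#' get (phi, psi) = (-57, -47) degrees; with probability `u` a helical
#' residue is instead drawn from the coil model, and turn/terminal residues
#' always are. Chains with CA-CA clashes (< 3.5 Angstrom between residues
#' at least 4 apart) or outside the Rg acceptance bound are resampled up to
#' `max_retries` times.
#'
#' @param spec a `chain_spec`.
#' @param unfold an `unfold_spec`.
#' @param seed optional integer seed (otherwise the current RNG state is
#'   used).
#' @param model_id model label for the resulting structure.
#' @param max_retries resampling cap.
#' @return An `xs_structure` with ground-truth generation parameters in
#'   `meta`.
#' @export
build_chain <- function(spec = chain_spec(), unfold = unfold_spec(),
                        seed = NULL, model_id = 1L, max_retries = 500L) {
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(max_retries)) {
    s <- .build_chain_once(spec, unfold, model_id)
    if (is.null(s)) next
    if (radius_of_gyration(s) >= unfold$rg_max) next
    s$meta$u <- unfold$u; s$meta$undock <- unfold$undock
    s$meta$retries <- try - 1L
    return(s)
  }
  stop("chain generation failed after ", max_retries,
       " retries (u = ", unfold$u,
       if (!is.null(seed)) paste0(", seed = ", seed) else "", ")")
}

.build_chain_once <- function(spec, unfold, model_id) {
  n <- spec$n_residues
  phi_psi <- .draw_coil(n, unfold)
  hel <- spec$helical & (stats::runif(n) >= unfold$u)
  phi_psi[hel, 1] <- -57; phi_psi[hel, 2] <- -47
  rows <- vector("list", n)
  # residue 1 backbone in the xy-plane
  N <- c(0, 0, 0); CA <- c(1.458, 0, 0)
  C <- CA + 1.525 * c(cos(pi - 111.2 * pi / 180),
                      sin(pi - 111.2 * pi / 180), 0)
  Cprev <- NULL
  for (i in seq_len(n)) {
    if (i > 1) {
      Np <- N; CAp <- CA; Cp <- C
      N <- .place_atom(Np, CAp, Cp, 1.329, 116.2, phi_psi[i - 1, 2])
      CA <- .place_atom(CAp, Cp, N, 1.458, 121.7, 180)        # omega
      C <- .place_atom(Cp, N, CA, 1.525, 111.2, phi_psi[i, 1]) # phi
      Cprev <- Cp
    }
    O <- .place_atom(N, CA, C, 1.231, 120.8, phi_psi[i, 2] + 180)
    res <- list(N = N, CA = CA, C = C, O = O)
    if (spec$resnames[i] != "GLY")
      res$CB <- .place_atom(N, C, CA, 1.521, 110.5, 122.6)
    if (i > 1 && spec$resnames[i] != "PRO") {
      u1 <- Cprev - N; u1 <- u1 / sqrt(sum(u1^2))
      u2 <- CA - N; u2 <- u2 / sqrt(sum(u2^2))
      bis <- u1 + u2
      res$H <- N - 1.01 * bis / sqrt(sum(bis^2))
    }
    xyz <- do.call(rbind, res)
    rows[[i]] <- data.frame(resno = i, resname = spec$resnames[i],
                            atom = names(res),
                            element = substr(names(res), 1, 1),
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, rows)
  s <- xs_structure(at, model_id = model_id)
  if (unfold$undock) s <- .undock_helix1(s, spec)
  # CA-CA self-clash check between residues >= 4 apart
  ca <- coords(s, which(s$atoms$atom == "CA"))
  D <- as.matrix(stats::dist(ca))
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  if (any(D[sep >= 4] < 3.5)) return(NULL)
  s
}

# rigid 10-20 A displacement + random rotation of the first helix and its
# N-terminal tail (the undocked-intermediate construction)
.undock_helix1 <- function(s, spec) {
  seg <- spec$helix_segments[[1]]
  idx <- which(s$atoms$resno <= seg[2])
  xyz <- coords(s, idx)
  ctr <- colMeans(xyz)
  R <- .random_rotation()
  dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
  shift <- stats::runif(1, 10, 20) * dir
  moved <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr + shift, "+")
  all <- coords(s)
  all[idx, ] <- moved
  set_coords(s, all)
}

#' Generate a conformer pool with ground-truth level labels
#'
#' @param spec a `chain_spec`.
#' @param levels data.frame with columns `u`, `undock`, `count` (one row
#'   per sampling level); the default emulates a native / undocked-
#'   intermediate / unfolded three-level pool.
#' @param seed integer seed.
#' @return list of `xs_structure` objects, each tagged with `meta$level`;
#'   model ids run 1..n.
#' @export
generate_pool <- function(spec = chain_spec(),
                          levels = data.frame(
                            u = c(0, 0.1, 1), undock = c(FALSE, TRUE, FALSE),
                            count = c(20L, 20L, 20L)),
                          seed = 1L) {
  if (any(levels$count < 1)) stop("level counts must be >= 1")
  set.seed(seed)
  pool <- list()
  for (lv in seq_len(nrow(levels))) {
    uf <- unfold_spec(u = levels$u[lv], undock = levels$undock[lv])
    for (k in seq_len(levels$count[lv])) {
      s <- build_chain(spec, uf, model_id = length(pool) + 1L)
      s$meta$level <- lv
      pool[[length(pool) + 1L]] <- s
    }
  }
  pool
}

#' Noise model for synthetic scattering experiments
#'
#' Multiplicative Gaussian noise with a q-dependent relative level.
#'
#' @param relative_sigma a positive constant or a function of q (default
#'   0.01, i.e. 1 percent).
#' @return An object of class `noise_model` (a function of q).
#' @export
noise_model <- function(relative_sigma = 0.01) {
  f <- if (is.function(relative_sigma)) relative_sigma
       else function(q) rep(relative_sigma, length(q))
  structure(f, class = c("noise_model", "function"))
}

#' Synthetic mixture scattering experiment
#'
#' I_exp(q) = (sum_k w_k I_k(q)) (1 + eps(q)) with eps ~ N(0, sigma_rel^2)
#' i.i.d. per grid point; the sigma column is sigma_rel times the mixture
#' intensity. The generating weights are stored in the profile's `truth`
#' attribute, so recovery tests always carry their answer key.
#'
#' @param pool_profiles list of `xs_profile`s on a common grid (or an
#'   intensity matrix with `q` supplied).
#' @param true_weights nonnegative weights summing to 1, aligned with the
#'   pool.
#' @param noise a `noise_model`.
#' @param seed optional integer seed.
#' @param q q grid when `pool_profiles` is a matrix.
#' @param label profile label.
#' @return An `xs_profile` with attribute `truth = true_weights`.
#' @export
synth_experiment <- function(pool_profiles, true_weights,
                             noise = noise_model(), seed = NULL, q = NULL,
                             label = "synthetic experiment") {
  if (!is.null(seed)) set.seed(seed)
  if (any(true_weights < 0)) stop("weights must be nonnegative")
  if (abs(sum(true_weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (is.matrix(pool_profiles)) {
    P <- pool_profiles
    if (is.null(q)) stop("q required with a matrix")
  } else {
    q <- pool_profiles[[1]]$q
    P <- vapply(pool_profiles, function(p) p$intensity, numeric(length(q)))
  }
  if (ncol(P) != length(true_weights))
    stop("one weight per pool profile required")
  mix <- as.vector(P %*% true_weights)
  rel <- noise(q)
  if (any(rel <= 0)) stop("relative noise level must be positive")
  I <- mix * (1 + stats::rnorm(length(q), 0, rel))
  if (any(I <= 0)) I <- pmax(I, 1e-12 * max(mix))
  p <- scattering_profile(q, I, sigma = rel * mix, label = label)
  attr(p, "truth") <- true_weights
  p
}

#' Synthetic RDC set from a known alignment tensor
#'
#' D_obs = D_calc(tensor, N-H vector) + N(0, noise_sigma^2), for every
#' residue with a usable amide vector (prolines and the N-terminus are
#' absent).
#'
#' @param s an `xs_structure`.
#' @param tensor an `alignment_tensor` (or length-5 Saupe vector).
#' @param noise_sigma coupling noise, Hz.
#' @param seed optional integer seed.
#' @param label condition label.
#' @return An `rdc_set` with the generating tensor in its `truth`
#'   attribute.
#' @export
synth_rdc <- function(s, tensor, noise_sigma = 0, seed = NULL, label = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vecs <- nh_vectors(s)
  d <- predict_rdc(tensor, vecs)
  if (noise_sigma > 0) d <- d + stats::rnorm(length(d), 0, noise_sigma)
  out <- rdc_set(as.integer(rownames(vecs)), d, error = noise_sigma,
                 label = label)
  attr(out, "truth") <- tensor
  out
}

#' Harvest NOE-style upper-bound restraints from a reference structure
#'
#' All inter-residue heavy-atom pairs (residue separation >= 2) closer than
#' `cutoff` become restraints with upper bound distance + `margin`;
#' uniformly subsampled to `max_count` when more candidates exist (default
#' 735, a typical experimental NOE set size for a protein of this size).
#' The reference structure violates none of its own restraints.
#'
#' @param s reference `xs_structure`.
#' @param cutoff harvesting distance cutoff, Angstrom.
#' @param margin added to each distance to form the upper bound.
#' @param max_count maximum number of restraints kept.
#' @param seed optional integer seed (used for the subsampling draw).
#' @return A `restraint_set`.
#' @export
synth_restraints <- function(s, cutoff = 5.0, margin = 0.5, max_count = 735L,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  heavy <- which(toupper(s$atoms$element) != "H")
  at <- s$atoms[heavy, ]
  xyz <- coords(s, heavy)
  D <- as.matrix(stats::dist(xyz))
  sep <- abs(outer(at$resno, at$resno, "-"))
  cand <- which(upper.tri(D) & D <= cutoff & sep >= 2, arr.ind = TRUE)
  if (!nrow(cand)) stop("no restraint candidates below the cutoff")
  if (nrow(cand) > max_count)
    cand <- cand[sort(sample.int(nrow(cand), max_count)), , drop = FALSE]
  restraint_set(at$resno[cand[, 1]], at$atom[cand[, 1]],
                at$resno[cand[, 2]], at$atom[cand[, 2]],
                D[cand] + margin)
}
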