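# Cross-validation of structures and ensembles against NMR observables:
# H(N)-N residual dipolar couplings via SVD-fitted Saupe alignment tensors,
# Cornilescu Q factors with sliding-window residue-range maps, and
# power-averaged NOE distance-restraint violation counting.

#' RDC table constructor / I-O
#'
#' A set of observed H(N)-N residual dipolar couplings: one row per residue
#' with the observed coupling (Hz) and its error. Files are TSV with
#' columns residue, D_obs_Hz, error_Hz.
#'
#' @param residue integer residue indices (unique).
#' @param d_obs observed couplings, Hz.
#' @param error measurement errors, Hz (>= 0; default 0).
#' @param label condition label (e.g. temperature).
#' @return An object of class `rdc_set` (a data.frame).
#' @export
rdc_set <- function(residue, d_obs, error = 0, label = NULL) {
  if (anyDuplicated(residue)) stop("residue indices must be unique")
  if (any(error < 0)) stop("errors must be >= 0")
  out <- data.frame(residue = as.integer(residue), d_obs = as.numeric(d_obs),
                    error = as.numeric(rep_len(error, length(residue))))
  attr(out, "label") <- label
  class(out) <- c("rdc_set", "data.frame")
  out
}

#' @param path file path.
#' @rdname rdc_set
#' @export
read_rdc <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  rdc_set(tab[[1]], tab[[2]], if (ncol(tab) >= 3) tab[[3]] else 0,
          label = basename(path))
}

#' @param rdc an `rdc_set`.
#' @rdname rdc_set
#' @export
write_rdc <- function(rdc, path) {
  utils::write.table(
    data.frame(residue = rdc$residue, D_obs_Hz = rdc$d_obs,
               error_Hz = rdc$error),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Amide N-H bond unit vectors
#'
#' Unit vectors from backbone N to amide H per residue, in the structure
#' frame. Residue 1 and prolines are skipped (no amide proton of interest).
#' When a residue lacks an explicit H, it is reconstructed in the
#' C(prev)-N-CA plane at 1.01 Angstrom from N, anti-bisecting the
#' C(prev)-N-CA angle.
#'
#' @param s an `xs_structure`.
#' @param residues optional integer vector restricting the residue range.
#' @return matrix with rows named by residue index, plus attribute
#'   `skipped` (residues left out and why).
#' @export
nh_vectors <- function(s, residues = NULL) {
  at <- s$atoms
  resnos <- unique(at$resno)
  if (!is.null(residues)) resnos <- intersect(resnos, residues)
  vecs <- list(); skipped <- character(0)
  get_atom <- function(resno, name) {
    i <- which(at$resno == resno & at$atom == name)
    if (length(i)) as.numeric(at[i[1], c("x", "y", "z")]) else NULL
  }
  for (r in resnos) {
    rname <- at$resname[match(r, at$resno)]
    if (r == min(unique(at$resno))) {
      skipped <- c(skipped, sprintf("%d (N-terminal)", r)); next
    }
    if (identical(rname, "PRO")) {
      skipped <- c(skipped, sprintf("%d (proline)", r)); next
    }
    N <- get_atom(r, "N")
    if (is.null(N)) stop("residue ", r, " has no N atom")
    H <- get_atom(r, "H")
    if (is.null(H)) {
      Cp <- get_atom(r - 1L, "C"); CA <- get_atom(r, "CA")
      if (is.null(Cp) || is.null(CA)) {
        skipped <- c(skipped, sprintf("%d (cannot rebuild H)", r)); next
      }
      u1 <- (Cp - N) / sqrt(sum((Cp - N)^2))
      u2 <- (CA - N) / sqrt(sum((CA - N)^2))
      bis <- u1 + u2
      H <- N - 1.01 * bis / sqrt(sum(bis^2))
    }
    v <- H - N
    vecs[[as.character(r)]] <- v / sqrt(sum(v^2))
  }
  if (!length(vecs)) stop("no usable amide vectors")
  out <- do.call(rbind, vecs)
  attr(out, "skipped") <- skipped
  out
}

# design matrix mapping the 5 independent Saupe components
# (Syy, Szz, Sxy, Sxz, Syz; Sxx = -Syy - Szz) to D = sum_kl S_kl u_k u_l
.saupe_design <- function(u) {
  cbind(u[, 2]^2 - u[, 1]^2,
        u[, 3]^2 - u[, 1]^2,
        2 * u[, 1] * u[, 2],
        2 * u[, 1] * u[, 3],
        2 * u[, 2] * u[, 3])
}

#' Assemble an alignment tensor from 5 Saupe components
#'
#' @param saupe numeric length-5 vector (Syy, Szz, Sxy, Sxz, Syz), with the
#'   dipolar prefactor absorbed so that predicted couplings are in Hz.
#' @return An object of class `alignment_tensor`: the 5 components, the
#'   reconstructed traceless symmetric 3x3 matrix, and the axial (Da) and
#'   rhombic (R) magnitudes from its eigenvalues.
#' @export
alignment_tensor <- function(saupe) {
  stopifnot(length(saupe) == 5)
  syy <- saupe[1]; szz <- saupe[2]
  M <- matrix(c(-syy - szz, saupe[3], saupe[4],
                saupe[3],   syy,      saupe[5],
                saupe[4],   saupe[5], szz), 3, 3)
  ev <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  # order eigenvalues by magnitude: |Azz| >= |Ayy| >= |Axx|
  ev <- ev[order(abs(ev))]
  Da <- ev[3] / 2
  R <- if (abs(Da) > 0) (ev[2] - ev[1]) / (3 * abs(Da)) else 0
  structure(list(saupe = as.numeric(saupe), matrix = M, Da = Da, R = R),
            class = "alignment_tensor")
}

#' Predict RDCs from a tensor and bond vectors
#'
#' @param tensor an `alignment_tensor` (or length-5 Saupe vector).
#' @param vectors unit-vector matrix as from [nh_vectors()].
#' @return named numeric vector of predicted couplings, Hz.
#' @export
predict_rdc <- function(tensor, vectors) {
  s <- if (inherits(tensor, "alignment_tensor")) tensor$saupe else tensor
  d <- as.vector(.saupe_design(vectors) %*% s)
  names(d) <- rownames(vectors)
  d
}

#' Least-squares (SVD) alignment-tensor fit
#'
#' Finds the 5 independent Saupe components minimizing
#' sum (D_calc - D_obs)^2 over the usable (vector, coupling) pairs, via the
#' singular value decomposition of the orientation design matrix. The
#' dipolar prefactor is absorbed into the tensor. Requires at least 5 pairs
#' and full rank; rank-deficient subsets are rejected.
#'
#' @param vectors unit-vector matrix from [nh_vectors()] (rows named by
#'   residue).
#' @param rdc an `rdc_set`.
#' @param subset optional residue indices restricting the fit.
#' @return list with `tensor` (an `alignment_tensor`), `d_calc` (predicted
#'   couplings for the fitted residues), `d_obs`, `residues`, and `q` (the
#'   Cornilescu Q factor of the fit).
#' @export
fit_tensor_svd <- function(vectors, rdc, subset = NULL) {
  res <- intersect(as.integer(rownames(vectors)), rdc$residue)
  if (!is.null(subset)) res <- intersect(res, subset)
  if (length(res) < 5)
    stop("underdetermined: only ", length(res),
         " usable (vector, coupling) pairs (need >= 5)")
  u <- vectors[as.character(res), , drop = FALSE]
  d_obs <- rdc$d_obs[match(res, rdc$residue)]
  A <- .saupe_design(u)
  sv <- svd(A)
  if (sum(sv$d > max(sv$d) * 1e-10) < 5)
    stop("underdetermined: orientation design matrix has rank < 5")
  saupe <- as.vector(sv$v %*% ((t(sv$u) %*% d_obs) / sv$d))
  d_calc <- as.vector(A %*% saupe)
  list(tensor = alignment_tensor(saupe),
       d_calc = stats::setNames(d_calc, res),
       d_obs = stats::setNames(d_obs, res),
       residues = res,
       q = if (any(d_obs != 0)) q_factor(d_calc, d_obs) else NA_real_)
}

#' Cornilescu Q factor
#'
#' Q = rms(D_calc - D_obs) / rms(D_obs). Q below 0.25 indicates agreement
#' comparable to a high-resolution structure.
#'
#' @param d_calc,d_obs equal-length coupling vectors, Hz.
#' @return Q (>= 0).
#' @export
q_factor <- function(d_calc, d_obs) {
  if (length(d_calc) != length(d_obs) || !length(d_obs))
    stop("d_calc and d_obs must have equal, nonzero length")
  rms_obs <- sqrt(mean(d_obs^2))
  if (rms_obs == 0) stop("Q undefined: all observed couplings are zero")
  sqrt(mean((d_calc - d_obs)^2)) / rms_obs
}

#' Sliding-window Q-factor map
#'
#' For every residue window \[start, end\] of at least `min_window`
#' residues with at least 5 usable pairs, refits the alignment tensor on
#' that window only and records the Cornilescu Q factor. Cells below the
#' minimum size or with an underdetermined fit are absent (NA). The
#' resulting map localizes which residue ranges of a structure agree with
#' the couplings (Q below the 0.25 cutoff) and which do not.
#'
#' @param s an `xs_structure`.
#' @param rdc an `rdc_set` sharing the structure's residue numbering.
#' @param min_window minimum window length in residues (default 7, safely
#'   above the 5 unknowns of the Saupe tensor).
#' @param cutoff agreement cutoff (default 0.25).
#' @param global_tensor refit per window (FALSE, default) or reuse one
#'   tensor fitted on all residues (TRUE).
#' @return An object of class `q_window_map`: list with `q` (matrix indexed
#'   \[start, end\]), `long` (data.frame start, end, q, below_cutoff),
#'   `cutoff`, `min_window`.
#' @export
sliding_window_q <- function(s, rdc, min_window = 7L, cutoff = 0.25,
                             global_tensor = FALSE) {
  vecs <- nh_vectors(s)
  res_all <- sort(intersect(as.integer(rownames(vecs)), rdc$residue))
  lo <- min(res_all); hi <- max(res_all)
  Q <- matrix(NA_real_, hi, hi)
  gt <- if (global_tensor) fit_tensor_svd(vecs, rdc)$tensor else NULL
  rows <- list()
  for (st in lo:(hi - min_window + 1L)) {
    for (en in (st + min_window - 1L):hi) {
      res <- res_all[res_all >= st & res_all <= en]
      if (length(res) < 5) next
      qv <- tryCatch({
        if (global_tensor) {
          u <- vecs[as.character(res), , drop = FALSE]
          q_factor(predict_rdc(gt, u), rdc$d_obs[match(res, rdc$residue)])
        } else {
          fit_tensor_svd(vecs, rdc, subset = res)$q
        }
      }, error = function(e) NA_real_)
      if (is.na(qv)) next
      Q[st, en] <- qv
      rows[[length(rows) + 1L]] <- data.frame(start = st, end = en, q = qv)
    }
  }
  long <- do.call(rbind, rows)
  long$below_cutoff <- long$q < cutoff
  structure(list(q = Q, long = long, cutoff = cutoff,
                 min_window = as.integer(min_window)),
            class = "q_window_map")
}

#' @export
print.q_window_map <- function(x, ...) {
  cat(sprintf("<q_window_map> %d windows (min length %d), %.0f%% below Q = %.2f\n",
              nrow(x$long), x$min_window,
              100 * mean(x$long$below_cutoff), x$cutoff))
  invisible(x)
}

#' @export
plot.q_window_map <- function(x, ...) {
  n <- nrow(x$q)
  graphics::image(seq_len(n), seq_len(n), pmin(x$q, 2 * x$cutoff),
                  col = grDevices::hcl.colors(32, "Blue-Red"),
                  xlab = "Window start", ylab = "Window end",
                  main = sprintf("sliding-window Q (cutoff %.2f)", x$cutoff),
                  ...)
  invisible(x)
}

#' Write a Q-window map
#'
#' Writes both the triangular matrix (TSV, NA for absent cells) and a
#' long-format table (start, end, q, below_cutoff).
#'
#' @param m a `q_window_map`.
#' @param path_matrix,path_long output paths.
#' @return invisibly, the pair of paths.
#' @export
write_q_map <- function(m, path_matrix, path_long) {
  utils::write.table(m$q, path_matrix, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(m$long, path_long, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path_matrix, path_long))
}

# ---- NOE restraints ---------------------------------------------------------

#' Distance-restraint table constructor / I-O
#'
#' Atom-pair upper-bound distance restraints. Files are TSV with columns
#' res_i, atom_i, res_j, atom_j, upper_A.
#'
#' @param res_i,atom_i,res_j,atom_j atom addresses (residue index + atom
#'   name).
#' @param upper upper bounds, Angstrom (> 0).
#' @return An object of class `restraint_set` (a data.frame).
#' @export
restraint_set <- function(res_i, atom_i, res_j, atom_j, upper) {
  if (any(upper <= 0)) stop("upper bounds must be positive")
  same <- res_i == res_j & atom_i == atom_j
  if (any(same)) stop("restraint atom pairs must be distinct atoms")
  out <- data.frame(res_i = as.integer(res_i), atom_i = as.character(atom_i),
                    res_j = as.integer(res_j), atom_j = as.character(atom_j),
                    upper = as.numeric(upper))
  class(out) <- c("restraint_set", "data.frame")
  out
}

#' @param path file path.
#' @rdname restraint_set
#' @export
read_restraints <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  restraint_set(tab[[1]], tab[[2]], tab[[3]], tab[[4]], tab[[5]])
}

#' @param restraints a `restraint_set`.
#' @rdname restraint_set
#' @export
write_restraints <- function(restraints, path) {
  utils::write.table(
    data.frame(res_i = restraints$res_i, atom_i = restraints$atom_i,
               res_j = restraints$res_j, atom_j = restraints$atom_j,
               upper_A = restraints$upper),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# per-member restraint distances: n_restraints x n_members
.restraint_distances <- function(ensemble, restraints) {
  vapply(ensemble, function(s) {
    at <- s$atoms
    key <- paste(at$resno, at$atom)
    ii <- match(paste(restraints$res_i, restraints$atom_i), key)
    jj <- match(paste(restraints$res_j, restraints$atom_j), key)
    if (anyNA(ii) || anyNA(jj)) {
      k <- which(is.na(ii) | is.na(jj))[1]
      stop(sprintf("restraint %d (%d %s - %d %s) references a missing atom",
                   k, restraints$res_i[k], restraints$atom_i[k],
                   restraints$res_j[k], restraints$atom_j[k]))
    }
    xyz <- coords(s)
    sqrt(rowSums((xyz[ii, , drop = FALSE] - xyz[jj, , drop = FALSE])^2))
  }, numeric(nrow(restraints)))
}

#' Power-averaged ensemble distances
#'
#' For each restraint, the ensemble-averaged distance
#' dbar = ((1/N) sum_i d_i^(-n))^(-1/n) over the N ensemble members, with
#' n = 3 by default. The average is dominated by the shortest distances,
#' matching NOE physics, and always lies between the minimum member
#' distance and the arithmetic mean. `normalized = FALSE` drops the 1/N
#' factor (the literal un-normalized sum, under which N identical distances
#' d average to d N^(-1/n)).
#'
#' @param ensemble list of `xs_structure` objects (or a single one).
#' @param restraints a `restraint_set`.
#' @param n averaging power (>= 1; default 3).
#' @param normalized include the 1/N normalization (default TRUE).
#' @return numeric vector of averaged distances, one per restraint.
#' @export
power_average_distances <- function(ensemble, restraints, n = 3,
                                    normalized = TRUE) {
  if (inherits(ensemble, "xs_structure")) ensemble <- list(ensemble)
  if (n < 1) stop("power n must be >= 1")
  D <- .restraint_distances(ensemble, restraints)
  D <- matrix(D, nrow = nrow(restraints))
  s <- rowSums(D^(-n))
  if (normalized) s <- s / ncol(D)
  s^(-1 / n)
}

#' Count restraint violations
#'
#' A restraint is violated when the (ensemble-averaged) distance exceeds
#' its upper bound by more than `tolerance`.
#'
#' @param averaged per-restraint averaged distances (Angstrom), aligned
#'   with `restraints`.
#' @param restraints a `restraint_set`.
#' @param tolerance violation tolerance, Angstrom (default 0).
#' @return list with `count`, `fraction`, `total`, and `excess` (named
#'   vector of d - upper for the violated restraints).
#' @export
count_violations <- function(averaged, restraints, tolerance = 0) {
  if (length(averaged) != nrow(restraints))
    stop("averaged distances must cover all restraints")
  exc <- averaged - restraints$upper
  bad <- which(exc > tolerance)
  list(count = length(bad),
       fraction = length(bad) / nrow(restraints),
       total = nrow(restraints),
       excess = stats::setNames(exc[bad], bad))
}
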