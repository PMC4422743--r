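# Rigid-body superposition, RMSD and radius of gyration.

.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974, SE = 78.971)

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' matched point sets, via the SVD of the covariance matrix with the usual
#' sign correction, so a reflection is never returned.
#'
#' @param mobile,reference numeric n x 3 coordinate matrices, n >= 3,
#'   matched row-by-row.
#' @return list with `rotation` (3 x 3, determinant +1), `translation`
#'   (length-3), and `rmsd` (Angstrom); the transform maps mobile onto the
#'   reference as `mobile %*% t(rotation) + translation` (row vectors).
#' @export
superpose_kabsch <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (ncol(mobile) != 3L || ncol(reference) != 3L)
    stop("coordinate matrices must have 3 columns")
  if (nrow(mobile) != nrow(reference))
    stop("point counts differ: ", nrow(mobile), " vs ", nrow(reference))
  if (nrow(mobile) < 3L)
    stop("superposition is underdetermined with fewer than 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- crossprod(A, B)                      # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)  # maps mobile frame -> reference
  fit <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fit - B)^2)))
  list(rotation = R, translation = as.numeric(cr - cm %*% t(R)), rmsd = rmsd)
}

#' Root-mean-square deviation between two structures
#'
#' RMSD over a matched atom selection, optionally after optimal
#' superposition. The selection is resolved pairwise, so atoms missing on
#' either side (e.g. glycine CB in the `mainchain_cb` set) are skipped on
#' both.
#'
#' @param a,b `xs_structure` objects over the same residue sequence.
#' @param sel an `xs_selection` (default `mainchain_cb`, the clustering
#'   criterion set).
#' @param superpose superpose before measuring (default TRUE).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, sel = atom_selection("mainchain_cb"), superpose = TRUE) {
  pr <- resolve_pair(sel, a, b)
  xa <- coords(a, pr$ia); xb <- coords(b, pr$ib)
  if (superpose) {
    superpose_kabsch(xa, xb)$rmsd
  } else {
    sqrt(mean(rowSums((xa - xb)^2)))
  }
}

#' Radius of gyration
#'
#' Rg = sqrt( sum_i w_i |r_i - rbar|^2 / sum_i w_i ) with rbar the weighted
#' centroid. Mass weighting (the MD convention) is the default; hydrogens
#' count when present. An element missing from the mass table triggers a
#' warning and a fall back to uniform weights.
#'
#' @param s an `xs_structure`.
#' @param weighting `"mass"` or `"uniform"`.
#' @return radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(s, weighting = c("mass", "uniform")) {
  weighting <- match.arg(weighting)
  xyz <- coords(s)
  if (weighting == "mass") {
    w <- .atomic_masses[toupper(s$atoms$element)]
    if (anyNA(w)) {
      warning("unknown element(s) ",
              paste(unique(s$atoms$element[is.na(w)]), collapse = ", "),
              " in mass table; falling back to uniform weights")
      w <- rep(1, nrow(xyz))
    }
  } else {
    w <- rep(1, nrow(xyz))
  }
  ctr <- colSums(xyz * w) / sum(w)
  sq <- rowSums(sweep(xyz, 2, ctr)^2)
  sqrt(sum(w * sq) / sum(w))
}
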