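# GROMOS-style (Daura) neighbor-count clustering of conformer pools in
# pairwise-RMSD space, with the >= 10-member retention filter and the
# medoid centroid rule.

#' Pairwise RMSD matrix over a conformer pool
#'
#' Entry (i, j) is the superposed RMSD of the selected atoms between pool
#' members i and j. `stride` subsamples the pool (members 1, 1+stride, ...)
#' before the matrix is built, mirroring the usual trajectory thinning.
#'
#' @param pool list of `xs_structure` objects with identical residue
#'   sequences.
#' @param sel an `xs_selection` (default `mainchain_cb`, the clustering
#'   criterion).
#' @param stride positive integer subsampling stride.
#' @return An object of class `xs_rmsd_matrix`: a symmetric matrix with
#'   attributes `selection`, `stride`, and `pool_index` (indices of the
#'   retained pool members).
#' @export
rmsd_matrix <- function(pool, sel = atom_selection("mainchain_cb"), stride = 1L) {
  stopifnot(length(pool) >= 1, stride >= 1)
  idx <- seq(1L, length(pool), by = stride)
  n <- length(idx)
  # resolve matched selections once against the first member; a sequence
  # mismatch anywhere surfaces as a pair-resolution error
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      m[i, j] <- m[j, i] <- rmsd(pool[[idx[i]]], pool[[idx[j]]], sel = sel)
    }
  }
  structure(m, class = c("xs_rmsd_matrix", "matrix"),
            selection = sel$name, stride = as.integer(stride),
            pool_index = idx)
}

#' Daura (GROMOS) neighbor-count clustering
#'
#' Iteratively: count, for every unassigned structure, its unassigned
#' neighbors within `cutoff` (self excluded from the count); the structure
#' with the most neighbors (ties to the smallest index) founds a cluster of
#' itself plus those neighbors; remove them and repeat. Singletons are
#' allowed. Clusters are reported by decreasing size, ties by smallest
#' member index.
#'
#' @param m an `xs_rmsd_matrix` (or plain symmetric matrix of distances).
#' @param cutoff neighbor cutoff in Angstrom (> 0).
#' @param min_size retention threshold used to set the `retained` flags
#'   (default 10: only clusters of ten or more members feed the scattering
#'   fit).
#' @return An object of class `daura_clustering`: list with `clusters`
#'   (list of member-index vectors), `centroids`, `sizes`, `retained`,
#'   `cutoff`, `n`.
#' @export
daura_cluster <- function(m, cutoff, min_size = 10L) {
  if (cutoff <= 0) stop("cutoff must be positive")
  m <- unclass(m)
  n <- nrow(m)
  if (any(abs(m - t(m)) > 1e-9)) stop("distance matrix is not symmetric")
  unassigned <- rep(TRUE, n)
  adj <- (m <= cutoff)
  diag(adj) <- FALSE
  clusters <- list()
  while (any(unassigned)) {
    cand <- which(unassigned)
    counts <- colSums(adj[cand, cand, drop = FALSE])
    founder <- cand[which.max(counts)]        # which.max ties -> smallest index
    members <- sort(c(founder, cand[adj[cand, founder]]))
    clusters[[length(clusters) + 1L]] <- members
    unassigned[members] <- FALSE
  }
  sizes <- lengths(clusters)
  ord <- order(-sizes, vapply(clusters, min, integer(1)))
  clusters <- clusters[ord]
  sizes <- sizes[ord]
  res <- structure(list(clusters = clusters,
                        centroids = vapply(clusters, centroid_structure,
                                           integer(1), m = m),
                        sizes = sizes,
                        retained = sizes >= min_size,
                        cutoff = cutoff, n = n),
                   class = "daura_clustering")
  res
}

#' @export
print.daura_clustering <- function(x, ...) {
  cat(sprintf("<daura_clustering> %d structures, cutoff %.2f A: %d clusters (%d retained)\n",
              x$n, x$cutoff, length(x$clusters), sum(x$retained)))
  k <- min(length(x$clusters), 8L)
  for (i in seq_len(k))
    cat(sprintf("  #%d size %d centroid %d%s\n", i, x$sizes[i], x$centroids[i],
                if (x$retained[i]) "" else " (dropped)"))
  if (length(x$clusters) > k) cat("  ...\n")
  invisible(x)
}

#' Cluster centroid (medoid)
#'
#' The member closest to the center of the cluster in RMSD space,
#' operationalized as the member minimizing the sum of RMSDs to all other
#' members; ties go to the smallest index.
#'
#' @param cluster integer vector of member indices.
#' @param m distance matrix.
#' @return the centroid's index (integer).
#' @export
centroid_structure <- function(cluster, m) {
  m <- unclass(m)
  if (!length(cluster)) stop("empty cluster")
  if (length(cluster) == 1L) return(as.integer(cluster))
  rs <- rowSums(m[cluster, cluster, drop = FALSE])
  as.integer(cluster[which.min(rs)])          # which.min ties -> smallest index
}

#' Re-flag clusters by a minimum size
#'
#' Marks clusters of fewer than `min_size` members as not retained. The
#' partition itself is unchanged — filtering marks, never deletes, so the
#' bookkeeping stays exhaustive.
#'
#' @param r a `daura_clustering`.
#' @param min_size retention threshold (default 10).
#' @return the updated `daura_clustering`.
#' @export
filter_clusters <- function(r, min_size = 10L) {
  r$retained <- r$sizes >= min_size
  r
}

#' Write a cluster report as TSV
#'
#' Columns: cluster_id, size, retained, centroid_model_id, member_model_ids
#' (comma-separated).
#'
#' @param r a `daura_clustering`.
#' @param path output path.
#' @param model_ids optional integer vector mapping matrix indices to model
#'   ids (defaults to the indices themselves).
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(r, path, model_ids = NULL) {
  if (is.null(model_ids)) model_ids <- seq_len(r$n)
  df <- data.frame(
    cluster_id = seq_along(r$clusters),
    size = r$sizes,
    retained = r$retained,
    centroid_model_id = model_ids[r$centroids],
    member_model_ids = vapply(r$clusters, function(cl)
      paste(model_ids[cl], collapse = ","), character(1)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
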