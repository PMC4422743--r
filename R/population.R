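# Classification of fitted ensemble weight into native / intermediate /
# unfolded groups by radius of gyration, and the temperature-series
# population table.

#' Radius-of-gyration group boundaries
#'
#' Native: Rg < `native_max`; intermediate: `native_max` <= Rg <
#' `intermediate_max`; unfolded: Rg >= `intermediate_max`. Intervals are
#' half-open `[lo, hi)`. The defaults (14.25 and 17.0 Angstrom) interpolate
#' the observed group ranges for a 61-residue three-helix bundle: native
#' structures cluster around 13-14 A and intermediates between roughly 14.5
#' and 17 A.
#'
#' @param native_max upper Rg bound of the native group, Angstrom.
#' @param intermediate_max upper Rg bound of the intermediate group.
#' @return An object of class `rg_boundaries`.
#' @export
rg_boundaries <- function(native_max = 14.25, intermediate_max = 17.0) {
  if (!(native_max > 0 && native_max < intermediate_max))
    stop("need 0 < native_max < intermediate_max")
  structure(list(native_max = native_max, intermediate_max = intermediate_max),
            class = "rg_boundaries")
}

#' Group label per structure
#'
#' @param rg per-structure radii of gyration, Angstrom.
#' @param b an `rg_boundaries`.
#' @return factor with levels N, I, U.
#' @export
rg_group <- function(rg, b = rg_boundaries()) {
  if (any(!is.finite(rg))) stop("non-finite radius of gyration")
  factor(ifelse(rg < b$native_max, "N",
                ifelse(rg < b$intermediate_max, "I", "U")),
         levels = c("N", "I", "U"))
}

#' Classify ensemble weight into N/I/U populations
#'
#' Each group's population is the summed mean weight of its member
#' structures; the group standard deviation combines the member sds in
#' quadrature (an upper-bound heuristic that assumes independence across
#' structures).
#'
#' @param weights per-structure mean weights, summing to 1.
#' @param rg per-structure radii of gyration, Angstrom.
#' @param b an `rg_boundaries`.
#' @param weights_sd optional per-structure weight sds (default 0).
#' @param label condition label for the row (e.g. temperature).
#' @return one-row data.frame: condition, fraction_N, fraction_I,
#'   fraction_U, sd_N, sd_I, sd_U.
#' @export
classify_by_rg <- function(weights, rg, b = rg_boundaries(),
                           weights_sd = NULL, label = NA) {
  if (length(weights) != length(rg))
    stop("weights and rg must have equal length")
  if (abs(sum(weights) - 1) > 1e-6)
    stop("weights must sum to 1 (got ", signif(sum(weights), 6), ")")
  if (is.null(weights_sd)) weights_sd <- rep(0, length(weights))
  grp <- rg_group(rg, b)
  frac <- vapply(levels(grp), function(g) sum(weights[grp == g]), numeric(1))
  sdg <- vapply(levels(grp), function(g) sqrt(sum(weights_sd[grp == g]^2)),
                numeric(1))
  data.frame(condition = label,
             fraction_N = frac[["N"]], fraction_I = frac[["I"]],
             fraction_U = frac[["U"]],
             sd_N = sdg[["N"]], sd_I = sdg[["I"]], sd_U = sdg[["U"]])
}

#' Population table across conditions
#'
#' One `classify_by_rg` row per condition (e.g. temperature), in ascending
#' condition order, from a named list of ensemble fits. Structures' radii
#' are taken from each fit's `pool_rg` unless given explicitly.
#'
#' @param fits named list of `ensemble_fit` objects; names are the
#'   condition labels (coerced to numeric for ordering when possible).
#' @param b an `rg_boundaries`.
#' @param rg optional common per-structure Rg vector overriding `pool_rg`.
#' @return An object of class `population_table` (a data.frame).
#' @export
temperature_series <- function(fits, b = rg_boundaries(), rg = NULL) {
  if (!length(fits)) stop("at least one condition required")
  labs <- names(fits)
  if (is.null(labs)) labs <- as.character(seq_along(fits))
  num <- suppressWarnings(as.numeric(labs))
  ord <- if (!any(is.na(num))) order(num) else order(labs)
  rows <- lapply(ord, function(i) {
    f <- fits[[i]]
    rgs <- if (is.null(rg)) f$pool_rg else rg
    if (is.null(rgs)) stop("no pool Rg available for condition ", labs[i])
    classify_by_rg(f$weights, rgs, b, weights_sd = f$weights_sd,
                   label = labs[i])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("population_table", "data.frame")
  out
}

#' @export
print.population_table <- function(x, ...) {
  cat("Populations by condition (N = native, I = intermediate, U = unfolded):\n")
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], round, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a population table as TSV
#'
#' @param tab a `population_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_population_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Most populated structures within a group
#'
#' The `k` highest-mean-weight structures whose Rg falls in the requested
#' group; ties go to the smaller structure index, and fewer than `k` rows
#' are returned when the group is smaller.
#'
#' @param fit an `ensemble_fit` with `pool_rg` set (or supply `rg`).
#' @param group one of `"N"`, `"I"`, `"U"`.
#' @param k number of structures to return (default 4).
#' @param b an `rg_boundaries`.
#' @param rg optional per-structure Rg vector overriding `pool_rg`.
#' @return data.frame: group, rank, structure, rg, weight.
#' @export
top_structures <- function(fit, group, k = 4L, b = rg_boundaries(), rg = NULL) {
  if (!group %in% c("N", "I", "U"))
    stop("unknown group '", group, "' (use N, I or U)")
  rgs <- if (is.null(rg)) fit$pool_rg else rg
  if (is.null(rgs)) stop("no pool Rg available")
  grp <- rg_group(rgs, b)
  idx <- which(grp == group)
  if (!length(idx)) stop("group ", group, " is empty")
  ord <- idx[order(-fit$weights[idx], idx)]
  ord <- ord[seq_len(min(k, length(ord)))]
  data.frame(group = group, rank = seq_along(ord), structure = ord,
             rg = rgs[ord], weight = fit$weights[ord])
}
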