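# Genetic-algorithm ensemble selection: evolve fixed-capacity multisets of
# pool indices (chromosomes) so the repetition-weighted ensemble-average
# scattering minimizes the log-intensity squared error against an
# experimental curve; aggregate structure weights over independent repeats.

#' Genetic-algorithm configuration
#'
#' Defaults follow the full optimization protocol: 20 elite ensembles per
#' generation, 10000 iterations, 50 independent repeats, ensemble capacity
#' 20; the crossover operator produces as many chromosomes as the elite
#' population and the mutation operator twice as many (the divergence that
#' drives rapid convergence). Desk-scale studies typically pass
#' `iterations = 2000, repeats = 20`.
#'
#' @param population elite count kept per generation.
#' @param iterations generations per repeat.
#' @param repeats independent optimization repeats.
#' @param capacity chromosome length L (ensemble capacity; repetition of an
#'   index encodes its weight in steps of 1/L).
#' @param crossover_offspring children from crossover per generation
#'   (default `population`).
#' @param mutation_offspring children from mutation per generation
#'   (default `2 * population`).
#' @param mutation_rate per-gene mutation probability (default
#'   `2 / capacity`, i.e. two genes hit per child on average).
#' @param mutation_reinforce fraction of mutated genes that copy another
#'   gene of the same chromosome instead of drawing uniformly from the pool
#'   (default 0.5). Reinforcing moves consolidate weight on structures the
#'   chromosome already carries, which a uniform reset almost never does
#'   (building up 12 copies of one index by uniform draws is vanishingly
#'   rare) and which the repetition-as-weight encoding needs; set to 0 for
#'   the plain uniform-reset kernel.
#' @param seed base seed; repeat r uses `seed + r` so repeats are
#'   independent yet reproducible.
#' @param early_stop stop a repeat after `plateau` generations without
#'   improvement greater than `plateau_tol` (default TRUE; set FALSE to
#'   force the full iteration count).
#' @param plateau,plateau_tol plateau length and improvement tolerance.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population = 20L, iterations = 10000L, repeats = 50L,
                      capacity = 20L,
                      crossover_offspring = population,
                      mutation_offspring = 2L * population,
                      mutation_rate = 2 / capacity,
                      mutation_reinforce = 0.5,
                      seed = 1L, early_stop = TRUE,
                      plateau = 500L, plateau_tol = 1e-12) {
  cfg <- list(population = as.integer(population),
              iterations = as.integer(iterations),
              repeats = as.integer(repeats),
              capacity = as.integer(capacity),
              crossover_offspring = as.integer(crossover_offspring),
              mutation_offspring = as.integer(mutation_offspring),
              mutation_rate = mutation_rate,
              mutation_reinforce = mutation_reinforce,
              seed = as.integer(seed),
              early_stop = isTRUE(early_stop),
              plateau = as.integer(plateau),
              plateau_tol = plateau_tol)
  if (any(vapply(cfg[c("population", "iterations", "repeats", "capacity",
                       "crossover_offspring", "mutation_offspring")],
                 function(x) x < 1L, logical(1))))
    stop("all GA counts must be positive")
  if (cfg$mutation_rate <= 0 || cfg$mutation_rate > 1)
    stop("mutation_rate must be in (0, 1]")
  if (cfg$mutation_reinforce < 0 || cfg$mutation_reinforce > 1)
    stop("mutation_reinforce must be in [0, 1]")
  structure(cfg, class = "ga_config")
}

# ---- chromosome operators ---------------------------------------------------

#' Initialize a chromosome population
#'
#' Each chromosome holds `capacity` genes drawn uniformly with replacement
#' from the pool. Uses the current RNG state; seed it for reproducibility.
#'
#' @param pool_size number of pool structures (>= 1).
#' @param cfg a `ga_config`.
#' @return integer matrix, `capacity` x `population`, one chromosome per
#'   column.
#' @export
init_population <- function(pool_size, cfg = ga_config()) {
  if (pool_size < 1L) stop("empty pool: no structures to select from")
  matrix(sample.int(pool_size, cfg$capacity * cfg$population, replace = TRUE),
         nrow = cfg$capacity, ncol = cfg$population)
}

#' Uniform gene-wise crossover
#'
#' Each child draws a pair of distinct parents uniformly from the elite
#' list, then takes every gene position from either parent with
#' probability 1/2.
#'
#' @param parents integer matrix of chromosomes (columns).
#' @param n_children number of children to produce.
#' @return integer matrix with `n_children` columns.
#' @export
crossover <- function(parents, n_children) {
  np <- ncol(parents)
  if (np < 2L) stop("crossover needs at least 2 parents")
  L <- nrow(parents)
  out <- matrix(0L, L, n_children)
  for (k in seq_len(n_children)) {
    pr <- sample.int(np, 2L)
    mask <- stats::runif(L) < 0.5
    out[, k] <- ifelse(mask, parents[, pr[1]], parents[, pr[2]])
  }
  out
}

#' Per-gene mutation with reinforcing moves
#'
#' Each child copies a uniformly drawn parent, then every gene is
#' independently mutated with probability `rate`. A mutated gene draws its
#' new value uniformly from the pool with probability `1 - reinforce`, or
#' copies a uniformly chosen gene of its own (pre-mutation) chromosome with
#' probability `reinforce` — the weight-consolidation move that lets the
#' search concentrate multiplicity on already-selected structures.
#'
#' @param parents integer matrix of chromosomes (columns).
#' @param n_children number of children to produce.
#' @param rate per-gene mutation probability in \[0, 1\] (0 is allowed as a
#'   testing hook).
#' @param pool_size number of pool structures.
#' @param reinforce fraction of mutations that copy a gene of the same
#'   chromosome (default 0.5; 0 gives the plain uniform-reset kernel).
#' @return integer matrix with `n_children` columns.
#' @export
mutate <- function(parents, n_children, rate, pool_size, reinforce = 0.5) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (reinforce < 0 || reinforce > 1) stop("reinforce must be in [0, 1]")
  L <- nrow(parents)
  out <- parents[, sample.int(ncol(parents), n_children, replace = TRUE),
                 drop = FALSE]
  src <- out                                  # pre-mutation copies
  hit <- matrix(stats::runif(L * n_children) < rate, L, n_children)
  nhit <- sum(hit)
  if (nhit) {
    self <- stats::runif(nhit) < reinforce
    repl <- integer(nhit)
    if (any(!self)) repl[!self] <- sample.int(pool_size, sum(!self),
                                              replace = TRUE)
    if (any(self)) {
      cols <- col(hit)[hit][self]
      repl[self] <- src[cbind(sample.int(L, sum(self), replace = TRUE), cols)]
    }
    out[hit] <- repl
  }
  out
}

# ---- evaluation -------------------------------------------------------------

# Precompute the fitting context: pool intensities resampled to the
# experimental grid restricted to the window, plus log experimental
# intensities.
.ga_context <- function(pool_profiles, experiment, q_window) {
  keep <- experiment$q >= q_window[1] & experiment$q <= q_window[2]
  if (!any(keep)) stop("empty fitting window")
  qg <- experiment$q[keep]
  if (is.matrix(pool_profiles)) {
    if (nrow(pool_profiles) != length(experiment$q))
      stop("intensity matrix rows must match the experimental grid")
    P <- pool_profiles[keep, , drop = FALSE]
  } else {
    P <- vapply(pool_profiles, function(p) {
      if (length(p$q) == length(experiment$q) && all(p$q == experiment$q))
        p$intensity[keep]
      else resample_log(p, qg)$intensity
    }, numeric(length(qg)))
  }
  list(q = qg, P = P, lexp = log(experiment$intensity[keep]),
       pool_size = ncol(P))
}

# batch fitness of chromosome columns: log-space score after the
# closed-form scale, as in fit_target()
.ga_fitness <- function(genes, ctx) {
  L <- nrow(genes)
  C <- apply(genes, 2, tabulate, nbins = ctx$pool_size)
  lmod <- log(ctx$P %*% C / L)
  r <- ctx$lexp - lmod
  r <- sweep(r, 2, colMeans(r))
  colSums(r^2)
}

#' Evaluate one chromosome
#'
#' Fitness = `fit_target` score of the repetition-weighted ensemble average
#' of the gene multiset against the experiment. The fitness depends only on
#' the gene multiset, not on gene order. An optional cache environment,
#' keyed by the sorted multiset, avoids re-evaluation.
#'
#' @param genes integer vector of pool indices (one chromosome).
#' @param pool_profiles list of pool `xs_profile`s (or intensity matrix on
#'   the experimental grid).
#' @param experiment the experimental `xs_profile`.
#' @param q_window fitting window (default `c(0.07, 0.7)`).
#' @param cache optional environment used as a fitness cache.
#' @return the fitness (squared log-residual score).
#' @export
evaluate <- function(genes, pool_profiles, experiment,
                     q_window = c(0.07, 0.7), cache = NULL) {
  ctx <- .ga_context(pool_profiles, experiment, q_window)
  if (any(genes < 1L | genes > ctx$pool_size))
    stop("gene index out of pool range")
  key <- paste(sort(genes), collapse = ",")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  f <- .ga_fitness(matrix(genes, ncol = 1), ctx)
  if (!is.null(cache)) cache[[key]] <- f
  f
}

# ---- main fit ---------------------------------------------------------------

#' Fit a weighted conformer ensemble to a scattering curve
#'
#' The core estimator: a genetic algorithm evolves fixed-capacity multisets
#' of pool indices (repetition encodes weight) so that the ensemble-average
#' scattering of the selected conformers reproduces the experimental curve
#' in log intensity over the fitting window. Each generation, the crossover
#' operator produces `crossover_offspring` children and the mutation
#' operator `mutation_offspring`; survivors are the best `population`
#' distinct multisets among elites plus offspring (mu + lambda selection
#' with duplicate suppression, so the best fitness never increases and the
#' elite set stays diverse). The whole optimization is repeated `repeats`
#' times from
#' independent seeds and per-structure weights are aggregated as the mean
#' and standard deviation of gene fractions across repeats.
#'
#' @param pool_profiles list of pool `xs_profile`s, or an intensity matrix
#'   (rows = experimental grid points).
#' @param experiment experimental `xs_profile`.
#' @param cfg a `ga_config`.
#' @param q_window fitting window, default `c(0.07, 0.7)` 1/Angstrom.
#' @param pool_rg optional per-structure radii of gyration (Angstrom),
#'   carried into the result for weight-vs-Rg analysis.
#' @return An object of class `ensemble_fit` with components `weights`
#'   (mean gene fraction per structure), `weights_sd`, `repeats` (list of
#'   per-repeat best genes, score, scale, trace), `pool_rg`, `config`,
#'   `q`, `experiment`, and `best` (index of the best repeat).
#' @export
ensemble_fit <- function(pool_profiles, experiment, cfg = ga_config(),
                         q_window = c(0.07, 0.7), pool_rg = NULL) {
  ctx <- .ga_context(pool_profiles, experiment, q_window)
  reps <- vector("list", cfg$repeats)
  for (r in seq_len(cfg$repeats)) {
    set.seed(cfg$seed + r)
    reps[[r]] <- .ga_one_repeat(ctx, cfg)
  }
  agg <- aggregate_weights(lapply(reps, `[[`, "genes"), ctx$pool_size)
  scores <- vapply(reps, `[[`, numeric(1), "score")
  structure(list(weights = agg$mean, weights_sd = agg$sd,
                 single_repeat = agg$single_repeat,
                 repeats = reps, best = which.min(scores),
                 pool_rg = pool_rg, config = cfg, q_window = q_window,
                 q = ctx$q, pool_size = ctx$pool_size,
                 experiment = experiment,
                 P = ctx$P),
            class = "ensemble_fit")
}

#' @rdname ensemble_fit
#' @export
run_ga <- function(pool_profiles, experiment, cfg = ga_config(),
                   q_window = c(0.07, 0.7), pool_rg = NULL) {
  ensemble_fit(pool_profiles, experiment, cfg, q_window, pool_rg)
}

.ga_one_repeat <- function(ctx, cfg) {
  pop <- init_population(ctx$pool_size, cfg)
  fit <- .ga_fitness(pop, ctx)
  ord <- order(fit)
  pop <- pop[, ord, drop = FALSE]; fit <- fit[ord]
  trace <- numeric(cfg$iterations)
  last_improve <- 0L
  it_done <- 0L
  for (it in seq_len(cfg$iterations)) {
    kids <- cbind(crossover(pop, cfg$crossover_offspring),
                  mutate(pop, cfg$mutation_offspring, cfg$mutation_rate,
                         ctx$pool_size, reinforce = cfg$mutation_reinforce))
    kfit <- .ga_fitness(kids, ctx)
    allpop <- cbind(pop, kids)
    allfit <- c(fit, kfit)
    keep <- order(allfit, seq_along(allfit))
    # survivors are the best *distinct* multisets, so elites stay diverse;
    # pad with duplicates only when there are too few distinct ones
    key <- apply(allpop[, keep, drop = FALSE], 2,
                 function(g) paste(sort(g), collapse = ","))
    distinct <- keep[!duplicated(key)]
    if (length(distinct) < cfg$population)
      distinct <- c(distinct, setdiff(keep, distinct))
    keep <- distinct[seq_len(cfg$population)]
    pop <- allpop[, keep, drop = FALSE]
    fit <- allfit[keep]
    trace[it] <- fit[1]
    it_done <- it
    if (it > 1L && trace[it] < trace[it - 1L] - cfg$plateau_tol)
      last_improve <- it
    if (cfg$early_stop && (it - last_improve) >= cfg$plateau) break
  }
  sc <- fit_target(
    scattering_profile(ctx$q, as.vector(ctx$P %*% tabulate(pop[, 1],
                                                           ctx$pool_size)) /
                         nrow(pop)),
    scattering_profile(ctx$q, exp(ctx$lexp)),
    q_window = range(ctx$q))
  list(genes = pop[, 1], score = fit[1], scale = sc$scale,
       trace = trace[seq_len(it_done)], iterations = it_done)
}

#' Aggregate per-repeat ensembles into structure weights
#'
#' Per repeat, a structure's weight is its gene fraction (multiplicity /
#' capacity); aggregation reports the mean and standard deviation across
#' repeats, plus (Rg, weight) pairs for histogramming when radii are
#' supplied.
#'
#' @param best_genes list of per-repeat best chromosomes (integer vectors).
#' @param pool_size number of pool structures.
#' @param pool_rg optional per-structure Rg values.
#' @param mode `"mean"` (mean of per-repeat fractions, the default) or
#'   `"pooled"` (fractions of all genes pooled across repeats).
#' @return list with `mean`, `sd` (zero with a `single_repeat` flag when
#'   only one repeat exists), and optionally `rg_weight` (two-column
#'   matrix).
#' @export
aggregate_weights <- function(best_genes, pool_size, pool_rg = NULL,
                              mode = c("mean", "pooled")) {
  mode <- match.arg(mode)
  W <- vapply(best_genes, function(g) tabulate(g, pool_size) / length(g),
              numeric(pool_size))
  W <- matrix(W, nrow = pool_size)
  if (mode == "pooled") {
    wm <- rowSums(W) / ncol(W)
  } else {
    wm <- rowMeans(W)
  }
  single <- ncol(W) == 1L
  ws <- if (single) rep(0, pool_size) else apply(W, 1, stats::sd)
  out <- list(mean = wm, sd = ws, single_repeat = single)
  if (!is.null(pool_rg)) {
    if (length(pool_rg) != pool_size)
      stop("pool_rg length must equal pool_size")
    out$rg_weight <- cbind(rg = pool_rg, weight = wm)
  }
  out
}

# ---- methods ----------------------------------------------------------------

#' @export
print.ensemble_fit <- function(x, ...) {
  scores <- vapply(x$repeats, `[[`, numeric(1), "score")
  cat(sprintf("<ensemble_fit> pool %d, capacity %d, %d repeats\n",
              x$pool_size, x$config$capacity, length(x$repeats)))
  cat(sprintf("  best score %.4g (repeat %d), median %.4g\n",
              min(scores), x$best, stats::median(scores)))
  nz <- which(x$weights > 0)
  nz <- nz[order(-x$weights[nz])]
  k <- min(length(nz), 6L)
  cat("  top structures by mean weight:\n")
  for (i in nz[seq_len(k)])
    cat(sprintf("    #%d: %.3f +/- %.3f%s\n", i, x$weights[i],
                x$weights_sd[i],
                if (!is.null(x$pool_rg))
                  sprintf(" (Rg %.1f A)", x$pool_rg[i]) else ""))
  invisible(x)
}

#' @export
summary.ensemble_fit <- function(object, ...) {
  scores <- vapply(object$repeats, `[[`, numeric(1), "score")
  iters <- vapply(object$repeats, `[[`, numeric(1), "iterations")
  out <- list(pool_size = object$pool_size,
              capacity = object$config$capacity,
              repeats = length(object$repeats),
              score = summary(scores),
              iterations = summary(iters),
              support = sum(object$weights > 0),
              weights = data.frame(
                structure = seq_len(object$pool_size),
                rg = if (is.null(object$pool_rg)) NA_real_ else object$pool_rg,
                mean_weight = object$weights,
                sd_weight = object$weights_sd)[object$weights > 0, ])
  class(out) <- "summary.ensemble_fit"
  out
}

#' @export
print.summary.ensemble_fit <- function(x, ...) {
  cat(sprintf("Ensemble fit: pool %d, capacity %d, %d repeats, support %d structures\n",
              x$pool_size, x$capacity, x$repeats, x$support))
  cat("Best-score distribution over repeats:\n"); print(x$score)
  cat("Structures with nonzero mean weight:\n")
  print(x$weights[order(-x$weights$mean_weight), ], row.names = FALSE)
  invisible(x)
}

#' @export
coef.ensemble_fit <- function(object, ...) {
  stats::setNames(object$weights, seq_along(object$weights))
}

#' Extract the structure-weight table of an ensemble fit
#'
#' @param object an `ensemble_fit`.
#' @param ... unused.
#' @return data.frame with structure index, Rg (if available), mean and sd
#'   weight.
#' @export
weights.ensemble_fit <- function(object, ...) {
  data.frame(structure = seq_len(object$pool_size),
             rg = if (is.null(object$pool_rg)) NA_real_ else object$pool_rg,
             mean_weight = object$weights,
             sd_weight = object$weights_sd)
}

#' @export
fitted.ensemble_fit <- function(object, ...) {
  g <- object$repeats[[object$best]]$genes
  I <- as.vector(object$P %*% tabulate(g, object$pool_size)) / length(g)
  scattering_profile(object$q, I, label = "best-repeat ensemble average")
}

#' @export
residuals.ensemble_fit <- function(object, ...) {
  mod <- fitted(object)
  keep <- object$experiment$q %in% object$q
  lexp <- log(object$experiment$intensity[keep])
  r <- lexp - log(mod$intensity)
  r - mean(r)
}

#' @export
plot.ensemble_fit <- function(x, which = c("fit", "weights"), ...) {
  which <- match.arg(which)
  if (which == "fit") {
    keep <- x$experiment$q %in% x$q
    mod <- fitted(x)
    sc <- fit_target(mod, scattering_profile(x$q,
                                             x$experiment$intensity[keep]),
                     q_window = range(x$q))
    graphics::plot(x$q, x$experiment$intensity[keep], log = "y", pch = 16,
                   cex = 0.4, xlab = expression(q ~ (ring(A)^-1)),
                   ylab = "I(q) (a.u.)", main = "ensemble fit")
    graphics::lines(x$q, sc$scale * mod$intensity, col = 2, lwd = 2)
    graphics::legend("topright", c("experiment", "best ensemble"),
                     pch = c(16, NA), lty = c(NA, 1), col = c(1, 2))
  } else {
    rg <- if (is.null(x$pool_rg)) seq_len(x$pool_size) else x$pool_rg
    nz <- x$weights > 0
    graphics::plot(rg[nz], x$weights[nz], type = "h", lwd = 2,
                   xlab = if (is.null(x$pool_rg)) "structure index"
                   else expression(R[g] ~ (ring(A))),
                   ylab = "mean weight", main = "selected ensemble")
    if (any(x$weights_sd[nz] > 0))
      graphics::arrows(rg[nz], pmax(x$weights[nz] - x$weights_sd[nz], 0),
                       rg[nz], x$weights[nz] + x$weights_sd[nz],
                       angle = 90, code = 3, length = 0.02, col = "grey40")
  }
  invisible(x)
}
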