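# End-to-end orchestration: pool -> profiles -> (clustering) -> GA fit per
# condition -> populations -> NMR validation, driven by a validated config
# list (or YAML file) with a JSON run manifest for reproducibility.

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file holding one) with
#' components:
#' \describe{
#'   \item{seed}{integer; required — no silent nondeterminism.}
#'   \item{out_dir}{output directory (created if absent).}
#'   \item{pool}{either `list(pdb = path)` to read a multi-model PDB, or
#'     `list(synthetic = list(levels = data.frame(u, undock, count)))` to
#'     generate one.}
#'   \item{experiments}{named list: condition label -> either
#'     `list(path = dat_path)` or `list(weights = named group weights)` for
#'     a synthetic mixture (weights over N/I/U groups, see vignette).}
#'   \item{q_window}{fitting window (default `c(0.07, 0.7)`).}
#'   \item{ga}{arguments passed to [ga_config()].}
#'   \item{boundaries}{arguments passed to [rg_boundaries()].}
#'   \item{clustering}{optional: `list(cutoffs = c(1.0, 2.5, 3.5),
#'     min_size = 10, stride = 1)` to cluster the pool and fit over cluster
#'     centroids only.}
#'   \item{nmr}{optional: `list(rdc = path or TRUE, restraints = path or
#'     TRUE)` — TRUE generates synthetic sets from the first pool member.}
#'   \item{noise}{relative noise of synthetic experiments (default 0.01).}
#' }
#'
#' @param config named list or path to a YAML file.
#' @return the validated config list (with defaults filled in).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  if (is.null(config$seed)) stop("config must specify a seed")
  if (is.null(config$out_dir)) stop("config must specify out_dir")
  if (is.null(config$pool)) stop("config must specify a pool source")
  if (!is.null(config$pool$pdb) && !file.exists(config$pool$pdb))
    stop("pool PDB not found: ", config$pool$pdb)
  if (is.null(config$experiments) || !length(config$experiments))
    stop("config must specify at least one experiment")
  for (lab in names(config$experiments)) {
    e <- config$experiments[[lab]]
    if (!is.null(e$path) && !file.exists(e$path))
      stop("experiment profile not found: ", e$path)
    if (is.null(e$path) && is.null(e$weights))
      stop("experiment '", lab, "' needs a path or synthetic weights")
  }
  config$q_window <- config$q_window %||% c(0.07, 0.7)
  config$noise <- config$noise %||% 0.01
  config$seed <- as.integer(config$seed)
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full deconvolution pipeline
#'
#' Executes the stages in dependency order: obtain the conformer pool,
#' compute pool scattering profiles (Debye), optionally cluster the pool
#' and restrict to retained-cluster centroids, fit the ensemble per
#' experimental condition with the genetic algorithm, assemble the
#' population table, and (optionally) validate against RDC and NOE data.
#' Every run writes a JSON manifest (config, seeds, input checksums,
#' package version) so a rerun with the same config is bit-identical.
#'
#' @param config see [validate_config()].
#' @return invisibly, a list with the pool, fits, population table,
#'   validation results, and the manifest path; all tables are also
#'   written under `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- stage 1: pool ---------------------------------------------------------
  if (!is.null(cfg$pool$pdb)) {
    pool <- read_pdb(cfg$pool$pdb)
  } else {
    syn <- cfg$pool$synthetic %||% list()
    levels <- if (is.null(syn$levels)) formals(generate_pool)$levels
              else as.data.frame(syn$levels)
    if (is.call(levels) || is.name(levels)) levels <- eval(levels)
    pool <- generate_pool(spec = chain_spec(), levels = levels,
                          seed = cfg$seed)
    write_pdb(pool, file.path(cfg$out_dir, "pool.pdb"))
  }
  pool_rg <- vapply(pool, radius_of_gyration, numeric(1))

  # --- stage 2: clustering (optional) ---------------------------------------
  cluster_results <- NULL
  fit_idx <- seq_along(pool)
  if (!is.null(cfg$clustering)) {
    cl <- cfg$clustering
    m <- rmsd_matrix(pool, stride = cl$stride %||% 1L)
    cutoffs <- cl$cutoffs %||% c(1.0, 2.5, 3.5)
    cluster_results <- lapply(cutoffs, function(co) {
      r <- daura_cluster(m, co, min_size = cl$min_size %||% 10L)
      write_cluster_report(r, file.path(cfg$out_dir,
                                        sprintf("clusters_%.1fA.tsv", co)),
                           model_ids = attr(m, "pool_index"))
      r
    })
    names(cluster_results) <- sprintf("%.1f", cutoffs)
    sel <- cl$use_cutoff %||% NULL
    if (!is.null(sel)) {
      r <- cluster_results[[sprintf("%.1f", sel)]]
      if (is.null(r)) stop("use_cutoff not among the clustering cutoffs")
      cent <- attr(m, "pool_index")[r$centroids[r$retained]]
      if (length(cent)) fit_idx <- sort(unique(cent))
    }
  }

  # --- stage 3: pool profiles ------------------------------------------------
  q <- default_q_grid()
  profiles <- lapply(pool[fit_idx], debye_profile, q = q)
  P <- vapply(profiles, function(p) p$intensity, numeric(length(q)))

  # --- stage 4: experiments + GA fit per condition --------------------------
  ga_args <- cfg$ga %||% list()
  fits <- list()
  for (lab in names(cfg$experiments)) {
    e <- cfg$experiments[[lab]]
    expt <- if (!is.null(e$path)) {
      read_profile(e$path, label = lab)
    } else {
      w <- .group_weights_to_pool(unlist(e$weights), pool_rg[fit_idx],
                                  do.call(rg_boundaries,
                                          cfg$boundaries %||% list()))
      synth_experiment(P, w, noise_model(cfg$noise),
                       seed = cfg$seed + 1000L + match(lab,
                                                names(cfg$experiments)),
                       q = q, label = lab)
    }
    ga <- do.call(ga_config, c(ga_args, list(seed = cfg$seed)))
    fit <- ensemble_fit(P, resample_log(expt, q),
                        cfg = ga, q_window = cfg$q_window,
                        pool_rg = pool_rg[fit_idx])
    fits[[lab]] <- fit
    utils::write.table(weights(fit),
                       file.path(cfg$out_dir, sprintf("weights_%s.tsv", lab)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    best <- fitted(fit)
    write_profile(best, file.path(cfg$out_dir,
                                  sprintf("best_fit_%s.dat", lab)))
  }

  # --- stage 5: populations --------------------------------------------------
  b <- do.call(rg_boundaries, cfg$boundaries %||% list())
  pops <- temperature_series(fits, b)
  write_population_table(pops, file.path(cfg$out_dir, "populations.tsv"))
  tops <- do.call(rbind, lapply(c("N", "I", "U"), function(g)
    tryCatch(top_structures(fits[[1]], g, b = b), error = function(e) NULL)))
  if (!is.null(tops))
    utils::write.table(tops, file.path(cfg$out_dir, "top_structures.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  # --- stage 6: NMR validation (optional) -----------------------------------
  nmr <- NULL
  if (!is.null(cfg$nmr)) {
    ref <- pool[[1]]
    nmr <- list()
    if (!is.null(cfg$nmr$rdc)) {
      rdc <- if (is.character(cfg$nmr$rdc)) read_rdc(cfg$nmr$rdc)
             else synth_rdc(ref, alignment_tensor(c(2, -1, 1, 3, -2)),
                            noise_sigma = 0.5, seed = cfg$seed + 7L)
      qmap <- sliding_window_q(ref, rdc)
      write_q_map(qmap, file.path(cfg$out_dir, "q_map_matrix.tsv"),
                  file.path(cfg$out_dir, "q_map_long.tsv"))
      nmr$q_map <- qmap
    }
    if (!is.null(cfg$nmr$restraints)) {
      restr <- if (is.character(cfg$nmr$restraints))
        read_restraints(cfg$nmr$restraints)
      else synth_restraints(ref, seed = cfg$seed + 8L)
      best <- fits[[1]]$repeats[[fits[[1]]$best]]$genes
      members <- pool[fit_idx][unique(best)]
      dbar <- power_average_distances(members, restr)
      nmr$violations <- count_violations(dbar, restr)
      utils::write.table(
        data.frame(restraint = seq_along(dbar), d_avg = dbar,
                   upper = restr$upper,
                   violated = dbar > restr$upper),
        file.path(cfg$out_dir, "noe_violations.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # --- manifest --------------------------------------------------------------
  manifest <- list(
    package = "saxsens",
    version = as.character(utils::packageVersion("saxsens")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    n_pool = length(pool),
    n_fit_pool = length(fit_idx),
    conditions = names(cfg$experiments),
    input_checksums = .input_checksums(cfg))
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(pool = pool, pool_rg = pool_rg, clusters = cluster_results,
                 fits = fits, populations = pops, nmr = nmr,
                 manifest = manifest_path))
}

.input_checksums <- function(cfg) {
  paths <- c(cfg$pool$pdb,
             unlist(lapply(cfg$experiments, `[[`, "path")),
             if (is.character(cfg$nmr$rdc)) cfg$nmr$rdc,
             if (is.character(cfg$nmr$restraints)) cfg$nmr$restraints)
  paths <- paths[!vapply(paths, is.null, logical(1))]
  if (!length(paths)) return(list())
  as.list(tools::md5sum(unlist(paths)))
}

# spread N/I/U group weights over the pool members of each group
# (equal split within a group)
.group_weights_to_pool <- function(gw, pool_rg, b) {
  grp <- rg_group(pool_rg, b)
  w <- numeric(length(pool_rg))
  for (g in names(gw)) {
    idx <- which(grp == g)
    if (!length(idx) && gw[[g]] > 0)
      stop("no pool structures in group ", g, " to carry weight")
    if (length(idx)) w[idx] <- gw[[g]] / length(idx)
  }
  w / sum(w)
}
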