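#' Assemble a run configuration
#'
#' Flat list of every tunable knob of the pipeline, with the package
#' defaults. Serializes to (and round-trips through) a flat `key = value`
#' text file via [write_config()] / [read_config()].
#'
#' @param ... overrides of the defaults (see the function body / vignette
#'   for the full list: preprocessing, fitting and trajectory knobs plus
#'   input/prior/output paths).
#' @return list of class `"velotf_config"`.
#' @export
velotf_config <- function(...) {
  cfg <- list(
    # preprocessing
    min_cell_fraction = 0.02, n_top = 2000, n_pcs = 30, n_neighbors = 30,
    # fitting
    n_iters = 20, n_theta_starts = 4, grid = 1000, weight_bound = 20,
    seed = 1,
    # trajectory
    kernel_scale = 0.1, root_quantile = 0.02, n_bins = 50,
    alignment_threshold = 0.5,
    # simulator
    n_genes = 200, n_cells = 1000, n_tfs = 10, noise_sd = 0.55,
    # paths
    input = "", priors = "", outdir = "."
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  validate_config(structure(cfg, class = "velotf_config"))
}

validate_config <- function(cfg) {
  counts <- c("n_top", "n_pcs", "n_neighbors", "n_iters", "n_theta_starts",
              "grid", "n_bins", "n_genes", "n_cells", "n_tfs")
  for (k in counts)
    if (!(cfg[[k]] > 0)) stop("config: ", k, " must be positive", call. = FALSE)
  if (!(cfg$min_cell_fraction > 0 && cfg$min_cell_fraction < 1))
    stop("config: min_cell_fraction must be in (0,1)", call. = FALSE)
  if (!(cfg$weight_bound > 0)) stop("config: weight_bound must be positive",
                                    call. = FALSE)
  cfg
}

#' @rdname velotf_config
#' @param cfg a `"velotf_config"`.
#' @param path file path.
#' @export
write_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    sprintf("%s = %s", k, if (is.character(v)) v else format(v, digits = 15))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname velotf_config
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  defaults <- velotf_config()
  over <- list()
  for (p in kv) {
    k <- trimws(p[1])
    v <- if (length(p) < 2 || is.na(p[2])) "" else trimws(p[2])
    over[[k]] <- if (is.character(defaults[[k]] %||% "")) v else as.numeric(v)
  }
  do.call(velotf_config, over)
}

config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) paste(format(v), collapse=","),
                                character(1)), collapse = ";")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

log_msg <- function(verbose, ...) if (verbose) message(...)

#' Write a benchmark to disk
#'
#' Generates the ground-truth benchmark and writes the expression table
#' (CSV, cells x genes), the prior table (TSV) and the truth bundle (JSON)
#' into `cfg$outdir`.
#'
#' @param cfg a [velotf_config()].
#' @param verbose log progress.
#' @return invisibly, the named list of file paths written.
#' @export
run_simulate <- function(cfg = velotf_config(), verbose = FALSE) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log_msg(verbose, "simulate: config ", config_hash(cfg), ", package ",
          as.character(utils::packageVersion("velotf")))
  bench <- generate_benchmark(n_genes = cfg$n_genes, n_cells = cfg$n_cells,
                              n_tfs = cfg$n_tfs, noise_sd = cfg$noise_sd,
                              seed = cfg$seed)
  paths <- list(
    expression = file.path(cfg$outdir, "benchmark_expression.csv"),
    priors = file.path(cfg$outdir, "benchmark_priors.tsv"),
    truth = file.path(cfg$outdir, "benchmark_truth.json"))
  m <- bench$dataset$matrix
  write.csv(data.frame(cell = rownames(m), m, check.names = FALSE),
            paths$expression, row.names = FALSE)
  writeLines(c("tf\ttarget",
               sprintf("%s\t%s", bench$priors$tf, bench$priors$target)),
             paths$priors)
  truth_json <- lapply(bench$truth, function(sg)
    list(true_W = sg$true_W, true_gamma = sg$true_gamma,
         true_times = sg$true_times, y_clean = sg$y_clean,
         true_velocity = sg$true_velocity))
  jsonlite::write_json(truth_json, paths$truth, digits = NA,
                       auto_unbox = TRUE)
  invisible(paths)
}

#' Fit every target gene of an input dataset
#'
#' End-to-end fitting stage: load expression, filter/select/normalize,
#' smooth moments, assemble one problem per prior-annotated target and fit
#' it. Writes the per-gene parameter table, the sparse TF-weight table, and
#' per-cell latent-time and velocity matrices as CSV into `cfg$outdir`.
#'
#' @param cfg a [velotf_config()] with `input` and `priors` set.
#' @param preprocess set `FALSE` for inputs that are already smooth
#'   abundances (e.g. the bundled simulator output), skipping
#'   filtering/normalization/moments.
#' @param verbose log per-gene progress.
#' @return a `"velotf_fits"` object, invisibly; side effect: result files.
#' @export
run_fit <- function(cfg = velotf_config(), preprocess = TRUE,
                    verbose = FALSE) {
  for (p in c(cfg$input, cfg$priors))
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  set.seed(cfg$seed)
  log_msg(verbose, "fit: config ", config_hash(cfg), ", package ",
          as.character(utils::packageVersion("velotf")))
  ds <- load_expression(cfg$input)
  priors <- load_tf_target_priors(cfg$priors)
  if (preprocess) {
    ds <- filter_and_select(ds, min_cell_fraction = cfg$min_cell_fraction,
                            n_top = cfg$n_top)
    ds <- compute_moments(ds, n_pcs = cfg$n_pcs,
                          n_neighbors = cfg$n_neighbors)
  }
  fits <- fit_targets(ds, priors, verbose = verbose,
                      n_iters = cfg$n_iters,
                      n_theta_starts = cfg$n_theta_starts,
                      grid = cfg$grid, weight_bound = cfg$weight_bound)
  for (g in names(fits$skipped))
    log_msg(verbose, "skipped ", g, ": ", fits$skipped[g])
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  write.csv(fit_parameter_table(fits),
            file.path(cfg$outdir, "gene_parameters.csv"), row.names = FALSE)
  write.csv(fit_weight_table(fits),
            file.path(cfg$outdir, "tf_weights.csv"), row.names = FALSE)
  write.csv(cell_level_table(fits, nrow(ds$matrix), "t"),
            file.path(cfg$outdir, "latent_time.csv"), row.names = FALSE)
  write.csv(cell_level_table(fits, nrow(ds$matrix), "velocity"),
            file.path(cfg$outdir, "velocity.csv"), row.names = FALSE)
  invisible(fits)
}

# cells x genes table of a per-cell fit field (NA outside the kept cells)
cell_level_table <- function(fits, n_cells, field) {
  out <- data.frame(cell = seq_len(n_cells))
  for (g in names(fits$fits)) {
    f <- fits$fits[[g]]
    v <- rep(NA_real_, n_cells)
    v[f$kept_cell_indices] <- f[[field]]
    out[[g]] <- v
  }
  out
}

#' Trajectory stage: pseudotime, roots/ends and stream arrows
#'
#' @param fits a `"velotf_fits"` from [run_fit()] / [fit_targets()].
#' @param ds the dataset the fits came from.
#' @param cfg a [velotf_config()].
#' @param verbose log progress.
#' @return list from [infer_trajectory()] extended with `stream_genes` and
#'   `arrows`; writes `pseudotime.csv` and `stream_arrows.csv` to
#'   `cfg$outdir`.
#' @export
run_pseudotime <- function(fits, ds, cfg = velotf_config(), verbose = FALSE) {
  if (!length(fits$fits)) stop("no fitted genes to build a trajectory from",
                               call. = FALSE)
  traj <- infer_trajectory(fits, ds, n_neighbors = cfg$n_neighbors,
                           kernel_scale = cfg$kernel_scale,
                           quantile_top = cfg$root_quantile)
  traj$stream_genes <- tryCatch(
    select_stream_genes(fits, traj$pseudotime,
                        alignment_threshold = cfg$alignment_threshold,
                        n_bins = cfg$n_bins),
    error = function(e) names(fits$fits))
  emb <- ds$embedding
  if (is.null(emb)) {
    log_msg(verbose, "no embedding provided; using the top 2 PCs")
    emb <- pca_coords(log1p(ds$smoothed %||% ds$matrix), 2)
  }
  traj$arrows <- embed_velocity_stream(traj$transition, emb, traj$neighbors)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(cell = ds$cell_names, pseudotime = traj$pseudotime,
                       is_root = seq_along(ds$cell_names) %in% traj$root,
                       is_end = seq_along(ds$cell_names) %in% traj$end),
            file.path(cfg$outdir, "pseudotime.csv"), row.names = FALSE)
  write.csv(data.frame(cell = ds$cell_names, dx = traj$arrows[, 1],
                       dy = traj$arrows[, 2]),
            file.path(cfg$outdir, "stream_arrows.csv"), row.names = FALSE)
  invisible(traj)
}

#' Evaluation stage: recovery statistics and stream metrics
#'
#' Computes the ground-truth recovery report when a truth bundle is
#' supplied, and the label-based stream metrics when labels are available;
#' each part degrades gracefully when its inputs are absent.
#'
#' @param fits a `"velotf_fits"` object.
#' @param truth optional truth bundle (from [generate_benchmark()]).
#' @param traj optional trajectory list from [run_pseudotime()].
#' @param labels optional per-cell type labels.
#' @param transitions optional list of `c(source, target)` pairs for CBDir.
#' @param cfg a [velotf_config()].
#' @return list with `recovery` (or NULL) and `stream_metrics` (or NULL);
#'   writes `recovery.json` / `stream_metrics.csv` to `cfg$outdir`.
#' @export
run_evaluate <- function(fits, truth = NULL, traj = NULL, labels = NULL,
                         transitions = NULL, cfg = velotf_config()) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- evaluate_recovery(fits, truth)
    jsonlite::write_json(
      list(spearman_weights = recovery$spearman_weights,
           spearman_velocity = recovery$spearman_velocity,
           sign_f1 = recovery$sign_f1, sign_auroc = recovery$sign_auroc),
      file.path(cfg$outdir, "recovery.json"), auto_unbox = TRUE, digits = NA)
  } else warning("no truth bundle supplied; recovery skipped")
  stream <- NULL
  if (!is.null(traj)) {
    rows <- list()
    cons <- velocity_consistency(traj$velocity, traj$neighbors)
    rows$consistency <- data.frame(metric = "velocity_consistency",
                                   group = "all", value = mean(cons))
    if (!is.null(labels)) {
      icc <- in_cluster_coherence(traj$velocity, labels, traj$neighbors)
      rows$icc <- data.frame(metric = "in_cluster_coherence",
                             group = names(icc), value = unname(icc))
      if (!is.null(transitions)) {
        cb <- cross_boundary_direction_correctness(
          traj$velocity, traj$expression, labels, transitions,
          traj$neighbors)
        rows$cb <- data.frame(metric = "cbdir", group = names(cb),
                              value = unname(cb))
      }
    }
    stream <- do.call(rbind, rows)
    write.csv(stream, file.path(cfg$outdir, "stream_metrics.csv"),
              row.names = FALSE)
  }
  list(recovery = recovery, stream_metrics = stream)
}
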