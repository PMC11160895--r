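KNOWN_CONFIG_KEYS <- c("input", "topology", "target", "output_dir", "seed",
                       "selections", "stage_options", "log_level")

#' Read and validate a run configuration
#'
#' Plain YAML with keys: `input` (file path or generator preset),
#' `topology`, `target`, `output_dir`, `seed`, `selections` (named lists of
#' [atom_selection()] arguments), `stage_options` (per-stage parameter
#' lists), `log_level`. Unknown top-level keys are rejected.
#'
#' @param path YAML file path, or a list with the same shape.
#' @return a validated `RunConfig` list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), KNOWN_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key: ", unknown[1], call. = FALSE)
  if (is.null(cfg$output_dir))
    stop("missing required config key: output_dir", call. = FALSE)
  cfg$seed <- cfg$seed %||% 1L
  cfg$log_level <- cfg$log_level %||% "info"
  structure(cfg, class = "RunConfig")
}

resolve_selection <- function(cfg, name) {
  spec <- cfg$selections[[name]]
  if (is.null(spec))
    stop("missing required selection: ", name, call. = FALSE)
  do.call(atom_selection, spec)
}

log_line <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[pmhcdyn %s] %s", format(Sys.time(), "%H:%M:%S"),
                  paste0(...)))
}

write_resolved_config <- function(cfg, out_dir) {
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "resolved-config.yaml"))
}

load_config_trajectory <- function(cfg) {
  if (identical(cfg$input, "synthetic-flip")) {
    opts <- cfg$stage_options$simulate %||% list()
    groove <- build_toy_groove(opts$preset %||% "neoantigen")
    spec <- flip_sim_spec(n_frames = opts$n_frames %||% 500,
                          sigma = opts$sigma %||% 0.08,
                          seed = cfg$seed)
    simulate_flip_trajectory(groove, spec)
  } else {
    top <- if (!is.null(cfg$topology))
      assign_parameters(read_structure(cfg$topology)) else NULL
    traj <- read_trajectory(cfg$input, topology = top)
    traj$topology <- assign_parameters(traj$topology)
    traj
  }
}

#' Run one analysis stage from a configuration
#'
#' Stages: `rmsf`, `rmsd`, `dscore`, `cluster`, `occupancy`, `cavity`,
#' `fit-isotherm`, `fit-decay`, `fit-melt`, `fit-lorentzians`, `demo`.
#' Outputs are delimited text files under `output_dir`, alongside a
#' resolved copy of the configuration.
#'
#' @param config a `RunConfig` (see [read_run_config()]).
#' @param stage stage name.
#' @return invisibly, a list of written artifact paths.
#' @export
run_stage <- function(config, stage) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_resolved_config(config, config$output_dir)
  out <- function(f) file.path(config$output_dir, f)
  opts <- config$stage_options[[stage]] %||% list()
  artifacts <- character(0)
  log_line(config, "stage ", stage, " (seed ", config$seed, ")")
  if (stage == "rmsf") {
    traj <- load_config_trajectory(config)
    sel <- if (!is.null(config$selections$rmsf))
      resolve_selection(config, "rmsf") else atom_selection(heavy = TRUE)
    tab <- mass_weighted_rmsf(traj, sel)
    write.table(tab, out("rmsf.tsv"), sep = "\t", row.names = FALSE,
                quote = FALSE)
    artifacts <- out("rmsf.tsv")
  } else if (stage == "rmsd") {
    traj <- load_config_trajectory(config)
    target <- assign_parameters(read_structure(config$target))
    series <- rmsd_series(traj, target,
                          fit_sel = resolve_selection(config, "fit"),
                          measure_sel = resolve_selection(config, "measure"))
    write.table(data.frame(frame = seq_along(series), rmsd = series),
                out("rmsd.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
    artifacts <- out("rmsd.tsv")
  } else if (stage == "cluster") {
    traj <- load_config_trajectory(config)
    m <- pairwise_rmsd(traj,
                       measure_sel = resolve_selection(config, "measure"))
    model <- cluster_conformations(m, k_range = opts$k_range %||% 2:15,
                                   linkage = opts$linkage %||% "average")
    write_cluster_table(model, out("clusters.tsv"))
    if (!is.null(model$tree)) write_dendrogram_newick(model, out("dendrogram.nwk"))
    artifacts <- c(out("clusters.tsv"), out("dendrogram.nwk"))
  } else if (stage == "occupancy") {
    traj <- load_config_trajectory(config)
    grid <- occupancy_grid(traj, resolve_selection(config, "track"),
                           spacing = opts$spacing %||% 0.1)
    write_grid_table(grid, out("occupancy.tsv"))
    write_grid_dx(grid, out("occupancy.dx"))
    artifacts <- c(out("occupancy.tsv"), out("occupancy.dx"))
  } else if (stage == "cavity") {
    s <- assign_parameters(read_structure(config$input))
    rep <- find_cavities(s, resolve_selection(config, "peptide"),
                         resolve_selection(config, "floor"),
                         probe = opts$probe %||% 1.4,
                         spacing = opts$spacing %||% 0.5)
    write.table(data.frame(cavity = seq_along(rep$volumes),
                           volume_A3 = rep$volumes),
                out("cavities.tsv"), sep = "\t", row.names = FALSE,
                quote = FALSE)
    write_cavity_pdb(rep, out("cavities.pdb"))
    artifacts <- c(out("cavities.tsv"), out("cavities.pdb"))
  } else if (stage %in% c("fit-isotherm", "fit-decay", "fit-melt",
                          "fit-lorentzians")) {
    d <- read.table(config$input, header = TRUE)
    fit <- switch(stage,
      "fit-isotherm" = fit_steady_state(
        binding_isotherm(d[[1]], d[[2]])),
      "fit-decay" = fit_dissociation(kinetic_trace(d[[1]], d[[2]]),
                                     phases = opts$phases %||% 1),
      "fit-melt" = fit_melt_derivative(melt_curve(d[[1]], d[[2]]),
                                       components = opts$components %||% 2),
      "fit-lorentzians" = fit_lorentzians(spectrum1d(d[[1]], d[[2]]),
                                          n_peaks = opts$n_peaks %||% 1)$fit)
    writeLines(utils::capture.output(print(fit)), out("fit.txt"))
    write.table(data.frame(parameter = names(fit$parameters),
                           value = as.numeric(fit$parameters),
                           stderr = as.numeric(fit$stderr[names(fit$parameters)])),
                out("fit.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
    artifacts <- c(out("fit.txt"), out("fit.tsv"))
  } else if (stage == "demo") {
    artifacts <- demo_limbo(config$output_dir, seed = config$seed,
                            n_frames = opts$n_frames %||% 400)
  } else {
    stop("unknown stage: ", stage, call. = FALSE)
  }
  log_line(config, "wrote ", paste(basename(artifacts), collapse = ", "))
  invisible(artifacts)
}

#' End-to-end under-peptide flip demo on synthetic data
#'
#' Generates a neoantigen-like flip trajectory, then runs the ensemble
#' stack: per-residue mwRMSF, conformational clustering of the position-6
#' side chain, a voxel occupancy grid, cavity detection on the static
#' groove, and a summary report.
#'
#' @param output_dir output directory.
#' @param seed RNG seed.
#' @param n_frames trajectory length (default 400).
#' @return invisibly, the written artifact paths.
#' @export
demo_limbo <- function(output_dir, seed = 1, n_frames = 400) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(output_dir, f)
  groove <- build_toy_groove("neoantigen")
  traj <- simulate_flip_trajectory(
    groove, flip_sim_spec(n_frames = n_frames, seed = seed))
  rmsf <- mass_weighted_rmsf(traj)
  write.table(rmsf, out("rmsf.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  p6 <- atom_selection(res_seq = 6, sidechain = TRUE)
  m <- pairwise_rmsd(traj, measure_sel = p6)
  model <- cluster_conformations(m, k_range = 2:6)
  write_cluster_table(model, out("clusters.tsv"))
  grid <- occupancy_grid(traj, p6, spacing = 0.5)
  write_grid_table(grid, out("occupancy.tsv"))
  cav <- find_cavities(groove,
                       atom_selection(chain = c("P", "S")),
                       atom_selection(chain = "F"))
  report <- c(
    sprintf("frames: %d (seed %d)", n_frames, seed),
    sprintf("clusters: k = %d, populations %s", model$k,
            paste(sprintf("%.2f", model$populations), collapse = "/")),
    sprintf("largest under-peptide cavity: %.0f A^3", cav$largest_volume),
    sprintf("position-2 anchor mwRMSF: %.3f A",
            rmsf$rmsf[rmsf$res_seq == 2]))
  writeLines(report, out("report.txt"))
  invisible(c(out("rmsf.tsv"), out("clusters.tsv"), out("occupancy.tsv"),
              out("report.txt")))
}
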