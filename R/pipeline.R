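## One-configuration orchestration of the full analysis with a manifest
## and a timestamped log. Identical config + inputs give identical
## outputs.

default_thresholds <- function() {
  list(adsorption_cutoff = 6.0, dccm_cutoff = 0.4, psn_cutoff = 5.0,
       i_min = 3.0, dominance = 0.30, report_threshold = 1.0,
       window_fraction = 0.1)
}

#' Validate and normalize a pipeline run configuration
#'
#' @param config named list or path to a JSON document. Recognized
#'   fields: \code{out_dir} (required), \code{trajectory} (multi-model
#'   PDB path), \code{frame_interval} (ps), \code{groups} (named list of
#'   selection expressions), \code{stages} (named logicals: adsorption,
#'   rmsd, rmsf, strand, dccm, psn, energetics), \code{thresholds}
#'   (defaults mirror the standard cutoffs: adsorption 6 \enc{Å}{Angstrom},
#'   DCCM 0.4, PSN 5 \enc{Å}{Angstrom}, i_min 3 percent, dominance 0.30,
#'   report threshold 1 kcal/mol, window fraction 0.1), \code{psn_pairs}
#'   (list of 2-vectors), \code{energetics} (receptor, ligand, params
#'   path, solvent), \code{seed}.
#' @return Normalized config list.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stopf("config must be a list or a JSON path")
  if (is.null(config$out_dir)) stopf("config needs out_dir")
  th <- default_thresholds()
  for (nm in names(config$thresholds %||% list()))
    th[[nm]] <- config$thresholds[[nm]]
  config$thresholds <- th
  stages <- list(adsorption = FALSE, rmsd = FALSE, rmsf = FALSE,
                 strand = FALSE, dccm = FALSE, psn = FALSE,
                 energetics = FALSE)
  for (nm in names(config$stages %||% list()))
    stages[[nm]] <- isTRUE(config$stages[[nm]])
  config$stages <- stages
  config$seed <- config$seed %||% 1L
  config
}

#' Run the configured analysis pipeline
#'
#' Stages run in dependency order (I/O, adsorption, conformation, DCCM,
#' PSN, energetics); every table is written with
#' \code{\link{write_table}} and the manifest records the configuration
#' (thresholds echoed verbatim), package version and md5 checksum of each
#' output. A stage failure aborts with the stage name after writing a
#' partial manifest.
#'
#' @param config see \code{\link{run_config}}.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  cfg <- run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(fmt, ...) cat(sprintf("[%s] %s\n",
                                         format(Sys.time(), "%H:%M:%S"),
                                         sprintf(fmt, ...)),
                                 file = log_path, append = TRUE)
  outputs <- character()
  manifest <- list(package = "immopsn",
                   version = as.character(utils::packageVersion("immopsn")),
                   config = cfg[setdiff(names(cfg), "out_dir")],
                   stages_run = character())
  write_manifest <- function() {
    manifest$outputs <- as.list(tools::md5sum(outputs))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  set.seed(cfg$seed)
  th <- cfg$thresholds
  traj <- NULL
  if (!is.null(cfg$trajectory)) {
    logf("reading trajectory %s", cfg$trajectory)
    traj <- read_pdb(cfg$trajectory, cfg$frame_interval %||% 2)
    if (!inherits(traj, "trajectory"))
      traj <- trajectory(traj, list(traj$coords), cfg$frame_interval %||% 2)
    for (g in names(cfg$groups %||% list()))
      traj$model <- set_group(traj$model, g,
                              resolve_selection(traj$model, cfg$groups[[g]]))
  }
  need_traj <- function(stage) {
    if (is.null(traj)) {
      write_manifest()
      stopf("stage '%s' failed: no trajectory configured", stage)
    }
  }
  run_stage <- function(stage, fun) {
    if (!isTRUE(cfg$stages[[stage]])) return()
    logf("stage %s (thresholds: %s)", stage,
         paste(sprintf("%s=%g", names(th), unlist(th)), collapse = " "))
    ok <- tryCatch({ fun(); TRUE },
                   error = function(e) {
                     logf("stage %s FAILED: %s", stage, conditionMessage(e))
                     write_manifest()
                     stopf("stage '%s' failed: %s", stage,
                           conditionMessage(e))
                   })
    manifest$stages_run <<- c(manifest$stages_run, stage)
  }

  run_stage("adsorption", function() {
    need_traj("adsorption")
    s <- adsorption_series(traj, cutoff = th$adsorption_cutoff)
    p <- file.path(cfg$out_dir, "adsorption.tsv")
    write_table(data.frame(time_ps = s$times, adsorbed = s$adsorbed_counts,
                           contact_area = s$contact_areas), p)
    outputs <<- c(outputs, p)
  })
  run_stage("rmsd", function() {
    need_traj("rmsd")
    r <- rmsd_series(traj)
    p <- file.path(cfg$out_dir, "rmsd.tsv")
    write_table(data.frame(time_ps = as.numeric(names(r)), rmsd = r), p)
    outputs <<- c(outputs, p)
  })
  run_stage("rmsf", function() {
    need_traj("rmsf")
    r <- rmsf(traj)
    p <- file.path(cfg$out_dir, "rmsf.tsv")
    write_table(data.frame(residue = names(r), rmsf = r), p)
    outputs <<- c(outputs, p)
  })
  run_stage("strand", function() {
    need_traj("strand")
    s <- strand_distance(traj)
    p <- file.path(cfg$out_dir, "strand_distance.tsv")
    write_table(data.frame(time_ps = frame_times(traj),
                           distance = s$per_frame_distance), p)
    outputs <<- c(outputs, p)
  })
  dccm_obj <- NULL
  run_stage("dccm", function() {
    need_traj("dccm")
    w <- window_frames(traj, th$window_fraction)
    dccm_obj <<- dccm_matrix(traj, window = w)
    masked <- average_dccm(list(dccm_obj), cutoff = th$dccm_cutoff)
    p <- file.path(cfg$out_dir, "dccm.tsv")
    write_dccm(masked, p)
    dccm_obj <<- masked
    outputs <<- c(outputs, p)
  })
  run_stage("psn", function() {
    need_traj("psn")
    pairs <- do.call(rbind, lapply(cfg$psn_pairs, function(p)
      data.frame(source = p[[1]], target = p[[2]],
                 stringsAsFactors = FALSE)))
    if (is.null(pairs)) stopf("psn stage needs psn_pairs")
    ps <- path_statistics(traj, pairs, i_min = th$i_min, corr = dccm_obj,
                          dominance = th$dominance, cutoff = th$psn_cutoff,
                          corr_cutoff = th$dccm_cutoff,
                          window = window_frames(traj, th$window_fraction))
    p <- file.path(cfg$out_dir, "paths.json")
    jsonlite::write_json(
      list(ensembles = ps$ensembles,
           node_frequency = as.list(ps$node_frequency),
           n_dominant_combinations = ps$n_dominant_combinations,
           n_dominant_unique_paths = ps$n_dominant_unique_paths),
      p, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    outputs <<- c(outputs, p)
  })
  run_stage("energetics", function() {
    need_traj("energetics")
    en <- cfg$energetics
    if (is.null(en)) stopf("energetics stage needs an energetics block")
    params <- read_params_tsv(en$params)
    solv <- solvent_model(en$solvent %||% "water")
    be <- binding_energy(traj, en$receptor, en$ligand, params, solv,
                         snapshots = en$snapshots,
                         stride_ps = en$stride_ps)
    p <- file.path(cfg$out_dir, "binding_energy.json")
    jsonlite::write_json(unclass(be), p, auto_unbox = TRUE, digits = NA)
    outputs <<- c(outputs, p)
  })

  write_manifest()
  logf("done: %d stage(s)", length(manifest$stages_run))
  invisible(manifest)
}
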