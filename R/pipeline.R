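# Orchestration: configuration, reproducible staged runs, reporting.

SCHEMA_VERSION <- "engulfr-schema-1"

#' Read a run configuration
#'
#' Configuration is a single JSON file. Recognised blocks (all optional,
#' with defaults): `seed`, `outdir`, `simulate` (phantom and cohort specs),
#' `imaging` (channel map, thresholds, ROIs, min_voxels), `ephys`
#' (boundary mode, rate criterion), `stats` (n_boot, n_perm, alpha,
#' comparisons).
#'
#' @param path JSON config path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  default_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg named list of overrides.
#' @export
default_run_config <- function(cfg = list()) {
  base <- list(
    seed = 1L, outdir = "engulfr_run",
    simulate = list(n_animals = 2L, n_sections = 6L,
                    engulfed_fraction = 0.5, blur_sigma = 0.2, noise_sd = 10,
                    n_cells_adapting = 6L, n_cells_nonadapting = 3L,
                    cohort = list(n_per_group = 20L, group_means = c(0, 1),
                                  group_sds = c(1, 1))),
    imaging = list(thresholds = "otsu", min_voxels = 0L),
    ephys = list(boundary = "kmeans", rate_criterion = 10),
    stats = list(n_boot = 5000L, n_perm = 5000L, alpha = 0.05))
  out <- utils::modifyList(base, cfg)
  if (out$stats$alpha <= 0 || out$stats$alpha >= 1) stop("alpha out of range")
  structure(out, class = "run_config")
}

stage_seed <- function(config, stage) {
  # deterministic per-stage split of the single global seed
  offsets <- c(simulate = 101L, engulfment = 202L, puncta = 303L,
               ephys = 404L, stats = 505L)
  (as.integer(config$seed) %% 2000000L) * 1000L + offsets[[stage]]
}

new_manifest <- function(config) {
  list(schema = SCHEMA_VERSION,
       version = as.character(utils::packageVersion("engulfr")),
       config = unclass(config), stages = list(), warnings = character(0),
       started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

collect_warnings <- function(expr) {
  warns <- character(0)
  val <- withCallingHandlers(expr, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  list(value = val, warnings = warns)
}

#' Write stage tables and the run manifest
#'
#' CSV files carry a schema-version header comment line and stable column
#' order; the manifest is JSON and records the config snapshot, per-stage
#' row counts and every QC warning raised during the run.
#'
#' @param tables named list of data.frames.
#' @param manifest manifest list.
#' @param outdir output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(tables, manifest, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(outdir, paste0(nm, ".csv"))
    con <- file(p, "w")
    writeLines(paste0("# ", SCHEMA_VERSION), con)
    utils::write.csv(tables[[nm]], con, row.names = FALSE)
    close(con)
    paths <- c(paths, p)
  }
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(c(paths, mp))
}

read_report_csv <- function(path)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)

run_stage_simulate <- function(config, outdir) {
  sim <- config$simulate
  seed0 <- stage_seed(config, "simulate")
  dir.create(file.path(outdir, "sim"), showWarnings = FALSE, recursive = TRUE)
  meta <- list()
  k <- 0L
  for (an in seq_len(sim$n_animals)) for (se in seq_len(sim$n_sections)) {
    k <- k + 1L
    ph <- gen_engulfment_phantom(engulfment_phantom_spec(
      engulfed_fraction = sim$engulfed_fraction, blur_sigma = sim$blur_sigma,
      noise_sd = sim$noise_sd, seed = seed0 + k))
    p <- file.path(outdir, "sim", sprintf("animal%02d_section%02d.tif", an, se))
    write_volume(ph$volume, p, metadata = list(truth = ph$truth,
                                               animal = an, section = se))
    meta[[k]] <- data.frame(animal = sprintf("animal%02d", an), section = se,
                            path = p, stringsAsFactors = FALSE)
  }
  volumes_meta <- do.call(rbind, meta)
  pp <- gen_puncta_phantom(seed = seed0 + 900L)
  puncta_path <- file.path(outdir, "sim", "puncta.tif")
  write_volume(pp$volume, puncta_path, metadata = list(truth = pp$truth))
  cells <- list()
  n_ad <- sim$n_cells_adapting; n_na <- sim$n_cells_nonadapting
  for (i in seq_len(n_ad + n_na)) {
    cls <- if (i <= n_ad) "adapting" else "nonadapting"
    rec <- gen_spike_recording(spike_sim_spec(cell_class = cls,
                                              seed = seed0 + 2000L + i))
    cp <- file.path(outdir, "sim", sprintf("cell%02d.json", i))
    write_spike_recording(rec, cp)
    cells[[i]] <- data.frame(cell = i, path = cp, true_class = cls,
                             stringsAsFactors = FALSE)
  }
  co <- gen_cohort(cohort_spec(n_per_group = sim$cohort$n_per_group,
                               group_means = sim$cohort$group_means,
                               group_sds = sim$cohort$group_sds,
                               seed = seed0 + 3000L))
  cohort_path <- file.path(outdir, "sim", "cohort.csv")
  write_cohort_csv(co$a, co$b, cohort_path)
  list(volumes = volumes_meta, puncta = puncta_path,
       cells = do.call(rbind, cells), cohort = cohort_path)
}

#' Run the pipeline
#'
#' Subcommands: `simulate` generates a full synthetic input set under
#' `outdir/sim`; `engulfment` quantifies triple-colocalization volumes on
#' the simulated (or configured) volumes; `puncta` segments and counts
#' puncta; `ephys` classifies the cell cohort; `stats` computes effect
#' sizes on the cohort table; `all` chains every stage. Outputs are
#' deterministic given config + seed (the manifest carries wall-clock
#' timestamps; all CSV tables are byte-stable).
#'
#' @param config a `run_config` (see [read_run_config()]) or path to one.
#' @param subcommand one of `"simulate"`, `"engulfment"`, `"puncta"`,
#'   `"ephys"`, `"stats"`, `"all"`.
#' @return The manifest, invisibly; stage tables are written to
#'   `config$outdir`.
#' @export
run_pipeline <- function(config, subcommand = c("all", "simulate",
                                                "engulfment", "puncta",
                                                "ephys", "stats")) {
  subcommand <- match.arg(subcommand)
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- new_manifest(config)
  tables <- list()
  stages <- if (subcommand == "all")
    c("simulate", "engulfment", "puncta", "ephys", "stats") else subcommand
  for (st in stages) {
    res <- tryCatch(
      collect_warnings(run_one_stage(st, config, outdir)),
      error = function(e)
        stop(sprintf("stage '%s' failed: %s", st, conditionMessage(e)),
             call. = FALSE))
    manifest$warnings <- c(manifest$warnings, res$warnings)
    if (!is.null(res$value$table)) {
      tables[[st]] <- res$value$table
      manifest$stages[[st]] <- list(rows = nrow(res$value$table))
    } else {
      manifest$stages[[st]] <- list(rows = res$value$rows %||% 0L)
    }
  }
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  write_report(tables, manifest, outdir)
  invisible(manifest)
}

run_one_stage <- function(stage, config, outdir) {
  sim_dir <- file.path(outdir, "sim")
  switch(stage,
    simulate = {
      idx <- run_stage_simulate(config, outdir)
      utils::write.csv(idx$volumes, file.path(sim_dir, "volumes_index.csv"),
                       row.names = FALSE)
      utils::write.csv(idx$cells, file.path(sim_dir, "cells_index.csv"),
                       row.names = FALSE)
      list(rows = nrow(idx$volumes) + nrow(idx$cells))
    },
    engulfment = {
      idx <- utils::read.csv(file.path(sim_dir, "volumes_index.csv"),
                             stringsAsFactors = FALSE)
      vols <- lapply(idx$path, read_volume)
      bq <- batch_quantify(vols, idx[c("animal", "section")],
                           thresholds = config$imaging$thresholds)
      utils::write.csv(bq$animals, file.path(outdir, "engulfment_animals.csv"),
                       row.names = FALSE)
      list(table = bq$sections)
    },
    puncta = {
      v <- read_volume(file.path(sim_dir, "puncta.tif"))
      thr <- config$imaging$thresholds
      if (!identical(thr, "otsu")) thr <- as.numeric(thr[[1]])
      pr <- quantify_puncta(v, channel = 1L, threshold = thr,
                            min_voxels = config$imaging$min_voxels)
      list(table = as.data.frame(pr))
    },
    ephys = {
      idx <- utils::read.csv(file.path(sim_dir, "cells_index.csv"),
                             stringsAsFactors = FALSE)
      recs <- lapply(idx$path, read_spike_recording)
      cl <- classify_cohort(recs, boundary = config$ephys$boundary,
                            rate_criterion = config$ephys$rate_criterion)
      tab <- cl$cells
      tab$boundary_used <- cl$boundary
      tab$boundary_mode <- cl$boundary_mode
      list(table = tab)
    },
    stats = {
      groups <- read_cohort_csv(file.path(sim_dir, "cohort.csv"))
      if (length(groups) != 2L) stop("cohort table must have 2 groups")
      es <- effect_size(groups[[1]], groups[[2]],
                        n_boot = config$stats$n_boot,
                        n_perm = config$stats$n_perm,
                        alpha = config$stats$alpha,
                        seed = stage_seed(config, "stats"),
                        name = paste(names(groups)[2], "vs", names(groups)[1]))
      list(table = as.data.frame(es))
    },
    stop("unknown stage: ", stage))
}
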