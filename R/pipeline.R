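## Pipeline orchestration: one seeded, deterministic run through
## generate -> cluster -> modes/displace -> PCA/DCCM -> geometry ->
## contacts, with per-stage CSV outputs, a JSON manifest and a run log.

#' Pipeline configuration
#'
#' Collects every stage parameter in one validated object. Stage RNG
#' streams are derived from the single global `seed` (stage k uses
#' `seed + k`); no stage reads OS entropy.
#'
#' @param out_dir report directory.
#' @param seed global integer seed.
#' @param stages character vector of stages to run, in fixed order.
#' @param solenoid a [solenoid_spec()].
#' @param motion a [motion_spec()].
#' @param n_runs independent trajectories to generate.
#' @param d_cutoff clustering RMSD cutoff (A).
#' @param n_modes internal modes to compute (default 87).
#' @param displace_range,displace_step MRMS grid (A), defaults 3.0 / 0.1.
#' @param displace_modes mode numbers to displace (default 7:9).
#' @param enm an [enm_params()].
#' @param criteria an [interaction_criteria()].
#' @param contact_frames frames in the complex ensemble.
#' @return object of class `PipelineConfig`.
#' @export
pipeline_config <- function(out_dir = "armflex_report", seed = 1L,
                            stages = c("generate", "cluster", "modes",
                                       "pca", "dccm", "geometry",
                                       "contacts"),
                            solenoid = solenoid_spec(),
                            motion = motion_spec(),
                            n_runs = 3L, d_cutoff = 2.5, n_modes = 87L,
                            displace_range = 3.0, displace_step = 0.1,
                            displace_modes = 7:9,
                            enm = enm_params(),
                            criteria = interaction_criteria(),
                            contact_frames = 60L) {
  if (d_cutoff <= 0) stop("d_cutoff must be > 0")
  if (n_modes < 1L) stop("n_modes must be >= 1")
  if (displace_step <= 0 || displace_step > displace_range)
    stop("displace_step must be in (0, displace_range]")
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Read a pipeline configuration from JSON
#'
#' Scalar fields of the JSON object override the defaults of
#' [pipeline_config()]; nested objects `solenoid`, `motion`, `enm` and
#' `criteria` override the corresponding constructor arguments.
#'
#' @param path JSON file.
#' @return a `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  scalars <- intersect(names(j), c("out_dir", "seed", "stages", "n_runs",
                                   "d_cutoff", "n_modes", "displace_range",
                                   "displace_step", "displace_modes",
                                   "contact_frames"))
  args[scalars] <- j[scalars]
  if (!is.null(j$solenoid)) args$solenoid <- do.call(solenoid_spec, j$solenoid)
  if (!is.null(j$motion)) args$motion <- do.call(motion_spec, j$motion)
  if (!is.null(j$enm)) args$enm <- do.call(enm_params, j$enm)
  if (!is.null(j$criteria)) args$criteria <- do.call(interaction_criteria,
                                                    j$criteria)
  do.call(pipeline_config, args)
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in fixed order on the synthetic
#' fixture set, writing per-stage CSVs, a JSON manifest (seed, parameter
#' echo, outputs) and a run log under `config$out_dir`. Deterministic
#' given the seed; a stage failure aborts with the stage named, keeping
#' partial outputs.
#'
#' @param config a [pipeline_config()].
#' @return the report directory path, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  cat("", file = logf)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
  }
  outputs <- character(0)
  emit <- function(df, name) {
    p <- file.path(config$out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    outputs <<- c(outputs, name)
    p
  }
  stage <- function(name, fun) {
    if (!(name %in% config$stages)) return(NULL)
    say("stage ", name, " start")
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say("stage ", name, " done")
    res
  }

  sol <- build_solenoid(config$solenoid)
  anchors <- default_anchors(sol$structure, sol$annotation)
  runs <- NULL; cx <- NULL

  stage("generate", function() {
    fx <- write_fixture_set(config$out_dir, spec = config$solenoid,
                            motion = config$motion, n_runs = config$n_runs,
                            n_contact_frames = config$contact_frames)
    runs <<- fx$runs; cx <<- fx$complex
    outputs <<- c(outputs, "solenoid.pdb", "complex.pdb",
                  "ground_truth.json")
    TRUE
  })
  if (is.null(runs)) {
    runs <- lapply(seq_len(config$n_runs), function(k) {
      mk <- config$motion; mk$seed <- config$motion$seed + k - 1L
      simulate_trajectory(sol$structure, sol$annotation, mk,
                          source_id = paste0("run", k))
    })
  }

  stage("cluster", function() {
    cp <- cluster_params(d_cutoff = config$d_cutoff,
                         selection = atom_selection(atoms = "CA"),
                         seed = config$seed + 1L)
    cl <- lz_cluster(runs, cp)
    conv <- convergence_table(cl)
    emit(cl$references, "cluster_references.csv")
    emit(data.frame(frame = seq_along(cl$assignment),
                    source = cl$frame_sources,
                    reference = cl$assignment), "cluster_assignment.csv")
    emit(data.frame(source = rownames(conv$table), conv$table,
                    check.names = FALSE), "cluster_frequencies.csv")
    say("cluster: ", nrow(cl$references), " references, spread ",
        signif(conv$spread, 3))
    for (i in seq_len(nrow(cl$references)))
      write_pdb(cl$structures[[i]],
                file.path(config$out_dir, sprintf("reference_%02d.pdb", i)))
    cl
  })

  modes <- stage("modes", function() {
    H <- build_hessian(sol$structure, config$enm)
    ms <- compute_modes(H, n_requested = config$n_modes)
    emit(summary(ms), "modes_summary.csv")
    emap <- restraint_energy_map(sol$structure, ms,
                                 mode_ids = config$displace_modes,
                                 max_range = config$displace_range,
                                 step = config$displace_step,
                                 params = config$enm)
    emit(data.frame(mode = rownames(emap), emap, check.names = FALSE),
         "restraint_energy_map.csv")
    for (k in config$displace_modes) {
      ds <- displace_along_mode(sol$structure, ms, k,
                                config$displace_range, config$displace_step,
                                hessian = H)
      write_pdb(as_trajectory(ds),
                file.path(config$out_dir,
                          sprintf("mode_%02d_displacement.pdb", k)))
    }
    ms
  })

  stage("pca", function() {
    merged <- merge_ensemble(runs, source_id = "md_ensemble")
    pca <- compute_pca(merged, atom_selection(atoms = "CA"),
                       n_components = 10L)
    emit(data.frame(pc = pca$mode_id, variance = pca$eigenvalues,
                    var_explained = pca$var_explained), "pca_summary.csv")
    if (!is.null(modes)) {
      internal <- config$displace_modes
      ov <- outer(internal, 1:3, Vectorize(function(m, p)
        mode_overlap(modes$vectors[, m], pca$vectors[, p])))
      dimnames(ov) <- list(paste0("mode", internal), paste0("PC", 1:3))
      emit(data.frame(mode = rownames(ov), ov, check.names = FALSE),
           "nm_pc_overlap.csv")
    }
    pca
  })

  stage("dccm", function() {
    merged <- merge_ensemble(runs, source_id = "md_ensemble")
    map <- dccm(merged, atom_selection(atoms = "CA"))
    write_dccm_csv(map, file.path(config$out_dir, "dccm_md.csv"))
    outputs <<- c(outputs, "dccm_md.csv")
    map
  })

  stage("geometry", function() {
    gs <- do.call(rbind, lapply(runs, function(tr) {
      g <- geometry_series(tr, anchors, sol$annotation)
      g$source <- tr$source_id
      g
    }))
    emit(gs, "geometry_series.csv")
    gs
  })

  stage("contacts", function() {
    if (is.null(cx))
      cx <<- build_complex(sol$structure, sol$annotation,
                           n_frames = config$contact_frames,
                           seed = config$seed + 2L)
    ens <- simulate_complex_trajectory(cx$complex, cx$schedule)
    rep <- occupancy_report(ens, atom_selection(chain = "A"),
                            atom_selection(chain = "B"), config$criteria)
    emit(rep$records, "contacts_all.csv")
    emit(rep$filtered, "contacts_filtered.csv")
    rep
  })

  manifest <- list(
    package = "armflex",
    version = as.character(utils::packageVersion("armflex")),
    seed = config$seed,
    stages = config$stages,
    parameters = list(
      d_cutoff = config$d_cutoff, n_modes = config$n_modes,
      displace_range = config$displace_range,
      displace_step = config$displace_step,
      enm_cutoff = config$enm$cutoff,
      criteria = unclass(config$criteria),
      motion = unclass(config$motion)[c("bend_amplitude", "twist_amplitude",
                                        "period", "noise_sd", "n_frames")]),
    outputs = unique(outputs))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline complete")
  invisible(config$out_dir)
}

#' Command-line entry point
#'
#' Subcommands: `run` (full pipeline), `generate`, `cluster`, `modes`,
#' `pca`, `dccm`, `geometry`, `contacts` (single stage). Options:
#' `--config file.json`, `--out dir`, `--seed N`. Installed as
#' `system.file("cli", "armflex.R", package = "armflex")`.
#'
#' @param args character vector, default the command line.
#' @return exit status 0 on success, invisibly.
#' @export
armflex_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L) {
    cat("usage: armflex.R <run|generate|cluster|modes|pca|dccm|geometry|",
        "contacts> [--config cfg.json] [--out dir] [--seed N]\n", sep = "")
    return(invisible(1L))
  }
  cmd <- args[1]; rest <- args[-1]
  opt <- list(config = NULL, out = "armflex_report", seed = 1L)
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!key %in% names(opt)) stop("unknown option: ", rest[i])
    opt[[key]] <- rest[i + 1L]
    i <- i + 2L
  }
  cfg <- if (!is.null(opt$config)) read_pipeline_config(opt$config)
         else pipeline_config()
  cfg$out_dir <- opt$out
  cfg$seed <- as.integer(opt$seed)
  cfg$stages <- if (cmd == "run") c("generate", "cluster", "modes", "pca",
                                    "dccm", "geometry", "contacts")
                else cmd
  run_pipeline(cfg)
  invisible(0L)
}
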