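.config_error <- function(...) {
  stop(structure(class = c("membind_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Assemble a pipeline run configuration
#'
#' Each system is either synthetic (a [synthetic_params()] object, or a list
#' of arguments for it) or file-based (\code{topology} and \code{trajectory}
#' paths). One global seed is split deterministically across synthetic
#' systems (system i runs at \code{seed + 1000 * i}).
#'
#' @param systems Named list: names are system labels, values as above.
#' @param outdir Output directory, created if missing.
#' @param classifier A [classifier_params()] object.
#' @param thermo A [thermo_params()] object.
#' @param seed Global integer seed.
#' @param deltag_table Optional path to a (peptide, guest, membrane, deltaG)
#'   table; when present the labelling regression stage runs.
#' @param native_guest,labelled_guest Guest labels for the regression stage.
#' @param z_residue Peptide residue id for the insertion-depth series;
#'   defaults to the first peptide residue.
#' @return An object of class \code{RunConfig}.
#' @export
run_config <- function(systems, outdir,
                       classifier = classifier_params(),
                       thermo = thermo_params(),
                       seed = 1L,
                       deltag_table = NULL,
                       native_guest = "W", labelled_guest = "WB",
                       z_residue = NULL) {
  if (!length(systems) || is.null(names(systems)) ||
      any(!nzchar(names(systems)))) {
    .config_error("systems must be a non-empty named list")
  }
  for (lab in names(systems)) {
    s <- systems[[lab]]
    synthetic <- inherits(s, "SyntheticParams") ||
      (is.list(s) && is.null(s$topology))
    file_based <- is.list(s) && !is.null(s$topology)
    if (synthetic == file_based) {
      .config_error("system '", lab, "': supply exactly one of ",
                    "SyntheticParams or topology/trajectory paths")
    }
  }
  structure(list(systems = systems, outdir = outdir,
                 classifier = classifier, thermo = thermo,
                 seed = as.integer(seed), deltag_table = deltag_table,
                 native_guest = native_guest,
                 labelled_guest = labelled_guest,
                 z_residue = z_residue),
            class = "RunConfig")
}

.digest_files <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(setNames(unname(tools::md5sum(paths)), basename(paths)))
}

.run_one_system <- function(label, spec, config, sysdir) {
  dir.create(sysdir, recursive = TRUE, showWarnings = FALSE)
  inputs <- character(0)
  if (inherits(spec, "SyntheticParams") ||
      (is.list(spec) && is.null(spec$topology))) {
    if (!inherits(spec, "SyntheticParams")) {
      spec <- do.call(synthetic_params, spec)
    }
    i <- match(label, names(config$systems))
    spec$seed <- config$seed + 1000L * i
    truth <- sample_state_path(spec)
    sys <- emit_trajectory(spec, truth)
    topo_path <- file.path(sysdir, "system.gro")
    traj_path <- file.path(sysdir, "trajectory.pdb")
    write_gro(sys$topology, sys$trajectory$coords[, , 1],
              sys$trajectory$box[1, ], topo_path,
              title = paste("membind synthetic system", label))
    write_pdb_traj(sys$topology, sys$trajectory, traj_path)
    write_ground_truth(truth, spec, file.path(sysdir, "ground_truth.tsv"))
    topology <- sys$topology
    trajectory <- sys$trajectory
  } else {
    if (!file.exists(spec$topology %||% "")) {
      stop("system '", label, "': missing topology ", spec$topology)
    }
    if (!is.null(spec$trajectory) && !file.exists(spec$trajectory)) {
      stop("system '", label, "': missing trajectory ", spec$trajectory)
    }
    inputs <- c(spec$topology, spec$trajectory)
    loaded <- load_system(spec$topology, spec$trajectory,
                          frame_interval = spec$frame_interval %||% 0.1)
    topology <- loaded$topology
    trajectory <- loaded$trajectory
  }

  series <- contact_series(trajectory, topology, config$classifier)
  track <- segment_states(series, config$classifier,
                          trajectory$frame_interval)
  write_table(state_records(series, track),
              file.path(sysdir, "states.tsv"))
  res_min <- as.data.frame(t(series$residue_min))
  names(res_min) <- paste0("res", rownames(series$residue_min))
  write_table(cbind(data.frame(frame = seq_len(series$n_frames)), res_min),
              file.path(sysdir, "residue_min_dist.tsv"))

  summary_row <- summarize_binding(track, label, config$thermo)
  counts <- contact_counts(trajectory, topology, config$classifier)
  write_table(counts$per_residue, file.path(sysdir, "contacts_residue.tsv"))
  if (nrow(counts$per_species)) {
    write_table(counts$per_species, file.path(sysdir, "contacts_species.tsv"))
  }
  zres <- config$z_residue %||% topology$peptide_residues[1]
  zp <- z_position(trajectory, topology, zres)
  write_table(data.frame(frame = seq_along(zp$values),
                         z_position = zp$values),
              file.path(sysdir, "z_position.tsv"))

  list(summary = summary_row,
       inputs = .digest_files(inputs),
       outputs = .digest_files(list.files(sysdir, full.names = TRUE)),
       bound_fraction_summary = bound_fraction_distribution(series, track))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' simulate/load -> classify -> thermo -> contacts (-> labelling regression),
#' writing all stage outputs plus a machine-readable manifest
#' (\code{manifest.json}) with per-file content digests. Identical config and
#' seed give identical outputs.
#'
#' @param config A [run_config()] object.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "membind",
    version = as.character(packageVersion("membind")),
    seed = config$seed,
    classifier = unclass(config$classifier),
    thermo = unclass(config$thermo),
    systems = list()
  )
  summaries <- list()
  for (label in names(config$systems)) {
    res <- tryCatch(
      .run_one_system(label, config$systems[[label]], config,
                      file.path(config$outdir, label)),
      error = function(e) {
        stop("pipeline stage failed for system '", label, "': ",
             conditionMessage(e), call. = FALSE)
      })
    summaries[[label]] <- res$summary
    manifest$systems[[label]] <- list(status = "ok", inputs = res$inputs,
                                      outputs = res$outputs)
  }
  summary_df <- do.call(rbind, summaries)
  write_table(summary_df, file.path(config$outdir, "binding_summary.tsv"))

  if (!is.null(config$deltag_table)) {
    tab <- read_deltag_table(config$deltag_table)
    pairs <- pair_deltag(tab, config$native_guest, config$labelled_guest)
    fit <- ols_fit(pairs)
    headline <- ddg_headline(fit, pairs)
    ddg <- list(regression = fit[c("slope", "intercept", "r_squared",
                                   "slope_ci_halfwidth",
                                   "intercept_ci_halfwidth", "n")],
                headline = headline)
    jsonlite::write_json(ddg, file.path(config$outdir, "ddg.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$systems[["ddg"]] <- list(
      status = "ok",
      inputs = .digest_files(config$deltag_table),
      outputs = .digest_files(file.path(config$outdir, "ddg.json")))
  }
  manifest$outputs <- .digest_files(file.path(config$outdir,
                                              "binding_summary.tsv"))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Parse a flat key-value pipeline configuration file
#'
#' Lines are \code{key = value}; \code{[system LABEL]} opens a synthetic
#' system block whose keys are [synthetic_params()] arguments (or
#' \code{topology}/\code{trajectory} paths for a file-based system). Keys
#' before the first block configure the run itself (\code{outdir},
#' \code{seed}, \code{cutoff}, \code{min_fraction}, \code{persistence},
#' \code{temperature}, \code{mode}, \code{deltag_table}). Blank lines and
#' \code{#} comments are ignored.
#'
#' @param path Config file.
#' @return A [run_config()] object.
#' @export
parse_run_config <- function(path) {
  if (!file.exists(path)) .config_error("no such config file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  global <- list()
  systems <- list()
  current <- NULL
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\[system +([^]]+)\\]$", ln))[[1]]
    if (length(m) == 2) {
      current <- trimws(m[2])
      systems[[current]] <- list()
      next
    }
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(kv) != 3) .config_error("cannot parse config line: ", ln)
    key <- trimws(kv[2]); val <- trimws(kv[3])
    num <- suppressWarnings(as.numeric(val))
    parsed <- if (!is.na(num)) num else val
    if (is.null(current)) global[[key]] <- parsed
    else systems[[current]][[key]] <- parsed
  }
  if (!length(systems)) .config_error("config defines no [system ...] block")
  cp <- classifier_params(
    contact_cutoff = global$cutoff %||% 3.5,
    min_bound_fraction = global$min_fraction %||% 0.30,
    persistence_frames = global$persistence %||% 50L,
    use_pbc = !isTRUE(global$no_pbc == 1)
  )
  tp <- thermo_params(temperature = global$temperature %||% 333,
                      gas_constant_mode = global$mode %||% "paper_literal")
  run_config(systems = systems,
             outdir = global$outdir %||% "membind_out",
             classifier = cp, thermo = tp,
             seed = global$seed %||% 1L,
             deltag_table = global$deltag_table)
}
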