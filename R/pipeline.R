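known_config_keys <- list(
  top = c("seed", "output_dir", "log_level", "physchem", "trajectory",
          "trace"),
  physchem = c("enabled", "fasta", "sequences", "c_term_amidated", "delta"),
  trajectory = c("enabled", "topology", "frames", "format", "synthetic",
                 "frame_range", "angle_type", "reference_atom",
                 "contact_cutoff", "min_contacts", "persistence"),
  trace = c("enabled", "path", "format", "synthetic", "bin_width",
            "max_levels", "method", "conductivity", "pore_length",
            "pore_model"))

check_keys <- function(x, what) {
  bad <- setdiff(names(x), known_config_keys[[what]])
  if (length(bad))
    stop("unknown config key(s) in ", what, ": ", paste(bad, collapse = ", "))
  x
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages over a configuration list (or JSON file):
#' sequence physico-chemistry, trajectory analyses (flexibility, depth,
#' aggregation) on read or synthetic trajectories, and channel-trace
#' analysis on read or synthetic traces. Every stage writes a delimited
#' table under `output_dir` and the run ends with a JSON summary echoing
#' every tunable parameter (full provenance). Re-running with an identical
#' config reproduces identical outputs.
#'
#' @param config A named list, or path to a JSON config file. Top-level
#'   keys: `seed`, `output_dir`, `log_level`, and per-stage blocks
#'   `physchem` (`fasta` or named `sequences`, `c_term_amidated`, `delta`),
#'   `trajectory` (`topology`/`frames`/`format` or `synthetic` = arguments
#'   for [trajectory_spec()]; analysis parameters `frame_range`,
#'   `angle_type`, `reference_atom`, `contact_cutoff`, `min_contacts`,
#'   `persistence`) and `trace` (`path`/`format` or `synthetic` =
#'   arguments for [trace_spec()]; `bin_width`, `max_levels`, `method`,
#'   `conductivity`, `pore_length`, `pore_model`). Unknown keys are
#'   rejected by name.
#' @return Invisibly, the summary list (also written as
#'   `summary.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  check_keys(config, "top")
  out_dir <- if (is.null(config$output_dir)) "." else config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  log_level <- if (is.null(config$log_level)) "info" else config$log_level
  logmsg <- function(...) if (log_level != "quiet")
    message(format(Sys.time(), "%H:%M:%S "), sprintf(...))
  summary <- list(seed = seed, stages = list())

  pc <- config$physchem
  if (!is.null(pc) && !isFALSE(pc$enabled)) {
    check_keys(pc, "physchem")
    delta <- if (is.null(pc$delta)) 100 else pc$delta
    amid <- if (is.null(pc$c_term_amidated)) TRUE else pc$c_term_amidated
    tab <- if (!is.null(pc$fasta)) {
      if (!file.exists(pc$fasta)) stop("missing input: ", pc$fasta)
      physchem_report(pc$fasta, c_term_amidated = amid, delta = delta)
    } else if (!is.null(pc$sequences)) {
      do.call(rbind, lapply(names(pc$sequences), function(id)
        physchem_profile(peptide_sequence(pc$sequences[[id]], id = id,
                                          c_term_amidated = amid),
                         delta = delta)))
    } else stop("physchem stage needs 'fasta' or 'sequences'")
    f <- file.path(out_dir, "physchem.tsv")
    utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    logmsg("physchem: %d sequence(s) -> %s", nrow(tab), f)
    summary$stages$physchem <- list(params = list(delta = delta,
                                                  c_term_amidated = amid),
                                    table = tab)
  }

  tc <- config$trajectory
  if (!is.null(tc) && !isFALSE(tc$enabled)) {
    check_keys(tc, "trajectory")
    if (!is.null(tc$synthetic)) {
      sp <- do.call(trajectory_spec,
                    c(tc$synthetic,
                      if (is.null(tc$synthetic$seed)) list(seed = seed)))
      traj <- generate_helix_trajectory(sp)$trajectory
    } else {
      if (!file.exists(tc$frames)) stop("missing input: ", tc$frames)
      traj <- read_trajectory(tc$topology, tc$frames, tc$format)
    }
    fr <- tc$frame_range
    ang <- if (is.null(tc$angle_type)) "psi" else tc$angle_type
    refa <- if (is.null(tc$reference_atom)) "CA" else tc$reference_atom
    cut <- if (is.null(tc$contact_cutoff)) 7 else tc$contact_cutoff
    mc <- if (is.null(tc$min_contacts)) 1 else tc$min_contacts
    pers <- if (is.null(tc$persistence)) 10 else tc$persistence
    flex <- flexibility_profile(traj, ang, frame_range = fr)
    utils::write.table(flex, file.path(out_dir, "flexibility.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dep <- residue_depth_profile(traj, reference_atom = refa,
                                 frame_range = fr)
    utils::write.table(dep, file.path(out_dir, "depth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    hm <- time_average_heatmap(traj, frame_range = fr)
    utils::write.table(round(unclass(hm), 3),
                       file.path(out_dir, "heatmap.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    pops <- oligomer_populations(traj, cut, mc, pers, frame_range = fr)
    utils::write.table(pops$per_frame,
                       file.path(out_dir, "oligomer_populations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    med <- mediating_residues(hm, cut)
    logmsg("trajectory: %d frames analysed", length(traj$frames))
    summary$stages$trajectory <- list(
      params = list(angle_type = ang, reference_atom = refa,
                    contact_cutoff = cut, min_contacts = mc,
                    persistence = pers,
                    synthetic = tc$synthetic),
      n_frames = length(traj$frames),
      flexibility = flex, depth = dep,
      oligomer_time_average = as.list(pops$time_average),
      mediating_residues = med)
  }

  trc <- config$trace
  if (!is.null(trc) && !isFALSE(trc$enabled)) {
    check_keys(trc, "trace")
    if (!is.null(trc$synthetic)) {
      sp <- do.call(trace_spec,
                    c(trc$synthetic,
                      if (is.null(trc$synthetic$seed)) list(seed = seed)))
      trace <- generate_channel_trace(sp)$trace
    } else {
      if (!file.exists(trc$path)) stop("missing input: ", trc$path)
      fmt <- if (is.null(trc$format)) "delimited" else trc$format
      trace <- read_current_trace(trc$path, fmt)
    }
    bw <- if (is.null(trc$bin_width)) 0.05 else trc$bin_width
    ml <- if (is.null(trc$max_levels)) 5 else trc$max_levels
    meth <- if (is.null(trc$method)) "histogram" else trc$method
    kap <- if (is.null(trc$conductivity)) 3.5 else trc$conductivity
    pl <- if (is.null(trc$pore_length)) 4 else trc$pore_length
    pm <- if (is.null(trc$pore_model)) "cylinder" else trc$pore_model
    cs <- channel_summary(trace, ml, meth, bw, kap, pl, pm)
    utils::write.table(as.data.frame(cs),
                       file.path(out_dir, "channel_levels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(cs)) {
      ev <- idealize(trace, cs)
      utils::write.table(ev, file.path(out_dir, "events.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    lat <- latency(trace, cs)
    logmsg("trace: %d level(s), latency %s s", nrow(cs),
           format(as.numeric(lat)))
    summary$stages$trace <- list(
      params = list(bin_width = bw, max_levels = ml, method = meth,
                    conductivity = kap, pore_length = pl, pore_model = pm,
                    synthetic = trc$synthetic),
      levels = as.data.frame(cs),
      baseline = attr(cs, "baseline"),
      latency_s = as.numeric(lat))
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       force = TRUE)
  invisible(summary)
}
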