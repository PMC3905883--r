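## End-to-end orchestration: simulate (or ingest) -> truncate at escape ->
## reconstruct FES -> basins / states -> minimum-energy-path profile ->
## per-state structure tables, behind one configuration object, with a JSON
## run report and a log.

#' Build and validate a pipeline run configuration
#'
#' Exactly one of `synthetic` (generate a toy-landscape metadynamics run)
#' or `input` (paths to existing HILLS / COLVAR / topology / trajectory
#' files) must be present.
#'
#' @param config named list, or path to a YAML file holding one.  Fields:
#'   `seed`; `synthetic` (`barrier`, optional `depths`, `n_steps`, `dt`,
#'   `friction`, `temperature`, optional `meta` overrides, `mock_structure`);
#'   `input` (`hills`, `colvar`, optional `topology`, `trajectory`,
#'   `states`); `grid_n`; `stop_distance` (nm); `state_cutoff` (kJ/mol);
#'   `hbond` (`dist_cutoff`, `angle_cutoff`); `cluster_cutoff` (nm);
#'   `outdir`.
#' @return Validated configuration (class `run_config`).
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  has_syn <- !is.null(config$synthetic)
  has_inp <- !is.null(config$input)
  if (has_syn == has_inp)
    stop("exactly one of 'synthetic' or 'input' must be present")
  defaults <- list(seed = 1L, grid_n = 500L, stop_distance = 4.0,
                   state_cutoff = 20, cluster_cutoff = 0.1,
                   hbond = list(dist_cutoff = 0.35, angle_cutoff = 30),
                   outdir = "metafes_run")
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (config$stop_distance <= 0) stop("'stop_distance' must be > 0")
  if (config$state_cutoff <= 0) stop("'state_cutoff' must be > 0")
  if (config$cluster_cutoff <= 0) stop("'cluster_cutoff' must be > 0")
  if (has_syn) {
    syn_defaults <- list(barrier = 20, n_steps = 4e6, dt = 0.002,
                         friction = 20, temperature = 100,
                         mass = c(5, 1e-4), mock_structure = TRUE)
    for (nm in names(syn_defaults))
      if (is.null(config$synthetic[[nm]]))
        config$synthetic[[nm]] <- syn_defaults[[nm]]
  }
  class(config) <- c("run_config", "list")
  config
}

.plog <- function(logfile, fmt, ...) {
  line <- sprintf("[metafes %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...))
  message(line)
  cat(line, "\n", file = logfile, append = TRUE)
}

#' Run the full unbinding-analysis pipeline
#'
#' Executes the stages in order (simulate or ingest, escape truncation,
#' FES reconstruction, basin and state assignment, minimum-energy-path
#' profile, structure tables), writes every table under the configured
#' output directory and returns (and writes) a JSON run report.  Reruns
#' with the same configuration and seed are bit-identical.
#'
#' @param config a [run_config()] (or list / YAML path accepted by it).
#' @return The run report (list), invisibly; written as `report.json`.
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "run.log")
  cat("", file = logfile)
  report <- list(package = "metafes",
                 version = as.character(utils::packageVersion("metafes")),
                 seed = config$seed, stages = list(), files = list())
  t0 <- Sys.time()

  ## stage 1: simulate or ingest -----------------------------------------
  topo <- NULL; mock <- NULL
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    .plog(logfile, "stage simulate: toy landscape, barrier %g kJ/mol",
          syn$barrier)
    pot <- make_unbinding_landscape(depths = syn$depths,
                                    barrier_BTs = syn$barrier)
    meta_args <- syn$meta
    if (is.null(meta_args))
      meta_args <- list(height = 1.0, widths = c(0.05, 50), pace = 0.5)
    params <- do.call(meta_params, meta_args)
    run <- run_metadynamics(pot, params, dt = syn$dt,
                            friction = syn$friction,
                            temperature = syn$temperature,
                            n_steps = syn$n_steps, seed = config$seed,
                            x0 = pot$minima$B$cv, mass = syn$mass)
    hills <- run$hills
    colvar <- run$colvar
    .plog(logfile, "stage simulate: deposited %d hills, recorded %d frames",
          nrow(hills), nrow(colvar))
    report$stages$simulate <- list(potential = pot$name,
                                   n_hills = nrow(hills),
                                   n_frames = nrow(colvar),
                                   mode = params$mode)
  } else {
    inp <- config$input
    .plog(logfile, "stage ingest: %s", inp$hills)
    hills <- read_hills(inp$hills)
    colvar <- read_colvar(inp$colvar)
    names(colvar)[-1L] <- paste0("cv_", seq_len(ncol(colvar) - 1L))
    if (!is.null(inp$topology)) topo <- read_topology_pdb(inp$topology)
    report$stages$ingest <- list(n_hills = nrow(hills),
                                 n_frames = nrow(colvar))
  }
  write_hills(hills, file.path(outdir, "hills.dat"))
  write_colvar(colvar, file.path(outdir, "colvar.dat"))
  report$files$hills <- "hills.dat"
  report$files$colvar <- "colvar.dat"

  ## stage 2: escape truncation ------------------------------------------
  hills_kept <- truncate_at_escape(colvar, hills, config$stop_distance)
  .plog(logfile, "stage truncate: %d of %d hills before the %g nm escape",
        nrow(hills_kept), nrow(hills), config$stop_distance)
  report$stages$truncate <- list(threshold_nm = config$stop_distance,
                                 hills_kept = nrow(hills_kept))
  if (nrow(hills_kept) == 0L)
    stop("stage truncate: no hills before the escape threshold")

  ## stage 3: FES reconstruction -----------------------------------------
  d <- .hills_dim(hills_kept)
  spec <- grid_spec_for_hills(hills_kept, n_points = config$grid_n)
  mode <- if (all(hills_kept$biasf > 1)) "well_tempered" else "standard"
  fes <- reconstruct_fes(hills_kept, spec, mode = mode)
  write_fes(fes, file.path(outdir, "fes.tsv"))
  report$files$fes <- "fes.tsv"
  .plog(logfile, "stage fes: %s grid, range %.2f kJ/mol",
        paste(spec$n_points, collapse = "x"), max(fes$values))
  report$stages$fes <- list(grid = spec$n_points, mode = mode,
                            range_kjmol = max(fes$values))

  ## stage 4: basins and states ------------------------------------------
  ## minima counting and labelling work on the surface smoothed at the
  ## hill-width resolution, with shallow deposition-noise dips merged into
  ## their significant parent basins
  sig1 <- .hills_sigmas(hills_kept, d)[1L, ]
  fes_s <- fes_smooth(fes, sig1)
  minima_raw <- suppressWarnings(find_minima(fes_s))
  minima <- significant_minima(fes_s)
  if (nrow(minima) == 0L) stop("stage landscape: no significant minima")
  basins <- merge_basins(fes_s, suppressWarnings(basin_assign(fes_s, minima_raw)),
                         minima)
  states <- assign_frames(colvar, fes_s, basins, cutoff = config$state_cutoff)
  write.table(states, file.path(outdir, "states.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  report$files$states <- "states.tsv"
  counts <- table(states$state, useNA = "no")
  .plog(logfile, "stage landscape: %d minima (%s); assigned frames: %s",
        nrow(minima), paste(minima$label, collapse = ", "),
        paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  report$stages$landscape <- list(
    n_minima = nrow(minima),
    n_minima_raw = nrow(minima_raw),
    minima = minima[, c("label", "cv1",
                        if (d == 2L) "cv2" else NULL, "energy")],
    state_counts = as.list(setNames(as.integer(counts), names(counts))),
    cutoff_kjmol = config$state_cutoff)

  ## stage 5: minimum-energy path ----------------------------------------
  if (nrow(minima) >= 2L) {
    mep <- minimum_energy_path(fes_s, basins, "B", "I")
    prof <- profile_along_path(mep)
    write.table(mep$path[, c("s", "cv1",
                             if (d == 2L) "cv2" else NULL, "energy")],
                file.path(outdir, "mep_profile.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$files$mep_profile <- "mep_profile.tsv"
    .plog(logfile, "stage mep: dG*(B->Ts) = %.2f kJ/mol at s = %.3f",
          mep$activation, mep$path$s[mep$saddle_index])
    report$stages$mep <- list(activation_kjmol = mep$activation,
                              saddle_energy_kjmol = mep$saddle_energy,
                              saddle_s = mep$path$s[mep$saddle_index])
  }

  ## stage 6: structure tables -------------------------------------------
  do_mock <- !is.null(config$synthetic) && isTRUE(config$synthetic$mock_structure)
  if (do_mock) {
    ## mock complex whose state sequence mirrors the assigned states
    ## (capped per state to keep the run light)
    tab <- table(states$state, useNA = "no")
    fps <- pmin(as.integer(tab), 2000L)
    names(fps) <- names(tab)
    fps <- fps[fps > 0L]
    if (length(fps) > 0L) {
      mspec <- default_mock_spec(states = names(fps),
                                 seed = config$seed + 1L,
                                 frames_per_state = fps)
      mock <- generate_mock_trajectory(mspec)
      topo <- mock$topology
    }
  }
  if (!is.null(mock) || (!is.null(topo) && !is.null(config$input$trajectory))) {
    if (is.null(mock)) {
      xyz <- read_xyz_trajectory(config$input$trajectory)
      traj_frames <- xyz$frames
      st <- read.table(config$input$states, sep = "\t", header = TRUE)
      frame_states <- as.character(st$state)
    } else {
      traj_frames <- mock$frames
      frame_states <- mock$states
    }
    crit <- hbond_criteria(config$hbond$dist_cutoff,
                           config$hbond$angle_cutoff)
    hb <- hbond_percentages(traj_frames, topo, frame_states, crit)
    write.table(hb, file.path(outdir, "hbonds_by_state.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$files$hbonds <- "hbonds_by_state.tsv"

    base_sel <- which(topo$group == "base")
    rmsf_tab <- do.call(rbind, lapply(unique(frame_states), function(s) {
      sel <- which(frame_states == s)
      if (length(sel) < 2L) return(NULL)
      r <- rmsf(traj_frames[sel], topo, selection = base_sel)
      cbind(state = s, r)
    }))
    write.table(rmsf_tab, file.path(outdir, "rmsf_by_state.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$files$rmsf <- "rmsf_by_state.tsv"

    lig_sel <- which(topo$group == "ligand")
    for (s in unique(frame_states)) {
      sel <- which(frame_states == s)
      sel <- sel[seq_len(min(length(sel), 200L))]  # clustering is O(n^2)
      cl <- gromos_cluster(traj_frames[sel], selection = lig_sel,
                           masses = topo$mass,
                           cutoff = config$cluster_cutoff)
      cl_tab <- data.frame(
        cluster = seq_along(cl$clusters),
        size = lengths(cl$clusters),
        representative_frame = sel[cl$representative],
        members = vapply(cl$clusters, function(m)
          paste(sel[m], collapse = ","), character(1L)))
      fn <- sprintf("clusters_%s.tsv", s)
      write.table(cl_tab, file.path(outdir, fn), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      report$files[[paste0("clusters_", s)]] <- fn
    }

    nw <- nick_width_by_state(traj_frames, topo, frame_states)
    write.table(nw, file.path(outdir, "nickwidth_by_state.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$files$nickwidth <- "nickwidth_by_state.tsv"
    .plog(logfile, "stage structure: %d H-bond rows, %d states",
          nrow(hb), length(unique(frame_states)))
    report$stages$structure <- list(
      n_hbond_rows = nrow(hb),
      states = unique(frame_states))
  }

  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report$files$report <- "report.json"
  .plog(logfile, "pipeline complete in %.1f s", report$elapsed_s)
  invisible(report)
}
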