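#' @title Configuration-driven orchestration
#' @description A YAML run configuration names constructs (label, topology,
#'   replicate trajectories) and the analyses to run with their parameters;
#'   [run_analyses()] executes every enabled analysis over every construct,
#'   writes per-replicate artifacts (CSV/JSON/DX) plus replicate summaries,
#'   and returns a structured report. Failure of one construct is recorded
#'   and does not abort the others.
#' @name pipeline
NULL

default_analysis_params <- function() {
  list(
    flux = list(stride_ps = 10, valve_selection = VALVE_SELECTION,
                density_dims = c(4, 4, 6), flux_dims = c(2, 2, 4),
                reanchor = TRUE),
    density = list(voxel_edge = 0.1, valve_selection = VALVE_SELECTION,
                   density_dims = c(4, 4, 6), flux_dims = c(2, 2, 4)),
    displacement = list(voxel_edge = 0.1, dt_ps = 10,
                        valve_selection = VALVE_SELECTION,
                        density_dims = c(4, 4, 6), flux_dims = c(2, 2, 4)),
    geometry = list(pairs = list("585:CD-426:CZ"), stride_ns = 1,
                    bin_width = 0.05),
    rmsf = list(fit_selection = NULL, target_selection = "protein and name CA"),
    sasa = list(cavity_residues = UPPER_CAVITY_RESIDUES,
                class_filter = "hydrophobic", probe = 0.14,
                stride_ps = 10, window_ps = 1000)
  )
}

#' Validate a YAML run configuration
#'
#' All validation problems are collected and reported together. Referenced
#' topology and trajectory files must exist and parse; the equilibration
#' span must be shorter than every trajectory. Analysis parameter blocks
#' are filled with defaults (flux stride 10 ps, equilibration 25 ns, etc.).
#'
#' @param path YAML configuration file
#' @return a validated config list (class `vw_config`) with `constructs`,
#'   `analyses`, `equilibration_ns`, `output_dir`, `seed`
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("malformed YAML in ", path, ": ",
                                           conditionMessage(e)))
  errors <- character(0)
  note <- function(msg) errors <<- c(errors, msg)

  if (is.null(cfg$constructs) || length(cfg$constructs) == 0L) {
    note("config must declare at least one construct")
    cfg$constructs <- list()
  }
  cfg$equilibration_ns <- cfg$equilibration_ns %||% 25
  cfg$output_dir <- cfg$output_dir %||% "valvewatch_out"
  cfg$seed <- cfg$seed %||% 1L
  if (cfg$equilibration_ns < 0) note("equilibration_ns must be >= 0")

  for (label in names(cfg$constructs)) {
    con <- cfg$constructs[[label]]
    if (is.null(con$topology)) {
      note(paste0("construct '", label, "': no topology given"))
      next
    }
    if (!file.exists(con$topology)) {
      note(paste0("construct '", label, "': topology not found: ",
                  con$topology))
      next
    }
    trjs <- unlist(con$trajectories)
    if (length(trjs) == 0L) {
      note(paste0("construct '", label, "': no trajectories given"))
      next
    }
    topo <- tryCatch(load_structure(con$topology)$topology,
                     error = function(e) {
                       note(paste0("construct '", label, "': ",
                                   conditionMessage(e)))
                       NULL
                     })
    for (trj in trjs) {
      if (!file.exists(trj)) {
        note(paste0("construct '", label, "': trajectory not found: ", trj))
        next
      }
      if (is.null(topo)) next
      span <- tryCatch({
        t <- load_trajectory(topo, trj, spacing_ps = con$spacing_ps)
        time_span_ps(t)
      }, error = function(e) {
        note(paste0("construct '", label, "': ", conditionMessage(e)))
        NA_real_
      })
      if (!is.na(span) && cfg$equilibration_ns * 1000 >= span) {
        note(paste0("construct '", label, "': equilibration ",
                    cfg$equilibration_ns, " ns is not shorter than the ",
                    span / 1000, " ns trajectory ", trj))
      }
    }
  }

  defaults <- default_analysis_params()
  analyses <- cfg$analyses %||% list()
  unknown <- setdiff(names(analyses), names(defaults))
  if (length(unknown) > 0L) {
    note(paste0("unknown analysis block(s): ", paste(unknown, collapse = ", ")))
  }
  for (a in intersect(names(analyses), names(defaults))) {
    merged <- defaults[[a]]
    user <- analyses[[a]]
    if (is.null(user)) user <- list()
    for (k in names(user)) merged[[k]] <- user[[k]]
    analyses[[a]] <- merged
  }
  cfg$analyses <- analyses

  if (length(errors) > 0L) {
    stop("configuration is invalid:\n  - ",
         paste(errors, collapse = "\n  - "))
  }
  structure(cfg, class = c("vw_config", "list"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_replicates <- function(construct_cfg, equilibration_ns) {
  topo <- load_structure(construct_cfg$topology)$topology
  lapply(unlist(construct_cfg$trajectories), function(trj) {
    t <- load_trajectory(topo, trj, spacing_ps = construct_cfg$spacing_ps)
    trim_equilibration(t, equilibration_ns)
  })
}

write_csv_plain <- function(df, path) {
  utils::write.csv(format(df, digits = 10, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the configured analyses
#'
#' @param config a `vw_config` from [validate_config()] (or a path to a YAML
#'   file, which is validated first)
#' @return report list: per construct a list of per-analysis summaries, a
#'   `manifest` of written files, `errors` (per-construct failure messages,
#'   empty on full success) and `provenance` (package version, config hash,
#'   seed)
#' @export
run_analyses <- function(config) {
  if (is.character(config)) {
    config_path <- config
    config <- validate_config(config)
  } else {
    config_path <- attr(config, "path")
  }
  stopifnot(inherits(config, "vw_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  results <- list()
  errors <- list()
  emit <- function(path) manifest <<- c(manifest, path)

  for (label in names(config$constructs)) {
    res <- tryCatch(
      run_construct(label, config$constructs[[label]], config, emit),
      error = function(e) {
        errors[[label]] <<- conditionMessage(e)
        NULL
      })
    if (!is.null(res)) results[[label]] <- res
  }

  cfg_hash <- if (!is.null(config_path) && file.exists(config_path)) {
    unname(tools::md5sum(config_path))
  } else NA_character_
  list(constructs = results, manifest = manifest, errors = errors,
       provenance = list(
         package = "valvewatch",
         version = as.character(utils::packageVersion("valvewatch")),
         config_hash = cfg_hash,
         seed = config$seed))
}

run_construct <- function(label, con_cfg, config, emit) {
  reps <- load_replicates(con_cfg, config$equilibration_ns)
  topo <- reps[[1L]]$topology
  out <- list()
  odir <- file.path(config$output_dir, gsub("[^A-Za-z0-9._-]", "_", label))
  dir.create(odir, recursive = TRUE, showWarnings = FALSE)
  an <- config$analyses

  if ("flux" %in% names(an)) {
    p <- an$flux
    sel <- select_atoms(topo, p$valve_selection)
    recs <- lapply(reps, function(t) {
      boxes <- anchor_boxes(get_frame(t, 1L), sel, p$density_dims,
                            p$flux_dims)
      count_crossings(t, boxes, stride_ps = p$stride_ps,
                      reanchor = p$reanchor)
    })
    for (i in seq_along(recs)) {
      emit(write_csv_plain(recs[[i]]$cumulative,
                           file.path(odir, sprintf("flux_rep%d.csv", i))))
    }
    summ <- if (length(recs) >= 2L) flux_summary(recs) else
      list(mean = recs[[1L]]$n_events, sem = NULL, n = 1L,
           counts = recs[[1L]]$n_events)
    jsonlite::write_json(summ, file.path(odir, "flux_summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    emit(file.path(odir, "flux_summary.json"))
    out$flux <- summ
  }

  if ("density" %in% names(an)) {
    p <- an$density
    sel <- select_atoms(topo, p$valve_selection)
    grids <- lapply(reps, function(t) {
      boxes <- anchor_boxes(get_frame(t, 1L), sel, p$density_dims,
                            p$flux_dims)
      density_grid(t, boxes, voxel_edge = p$voxel_edge)
    })
    avg <- average_grids(grids)
    emit(write_dx(avg, file.path(odir, "density_mean.dx")))
    out$density <- list(mean_in_box = sum(avg$values) * avg$voxel_edge^3,
                        n_frames = avg$n_frames)
  }

  if ("displacement" %in% names(an)) {
    p <- an$displacement
    sel <- select_atoms(topo, p$valve_selection)
    grids <- lapply(reps, function(t) {
      boxes <- anchor_boxes(get_frame(t, 1L), sel, p$density_dims,
                            p$flux_dims)
      displacement_grid(t, boxes, voxel_edge = p$voxel_edge,
                        dt_ps = p$dt_ps)
    })
    avg <- average_grids(grids)
    emit(write_dx(avg, file.path(odir, "displacement_mean.dx")))
    out$displacement <- list(
      mean_displacement_nm = mean(avg$values, na.rm = TRUE),
      n_frames = avg$n_frames)
  }

  if ("geometry" %in% names(an)) {
    p <- an$geometry
    geo <- list()
    for (spec in p$pairs) {
      series <- list()
      for (ri in seq_along(reps)) {
        halves <- distance_series(reps[[ri]], spec,
                                  stride_ns = p$stride_ns,
                                  construct = label)
        for (h in halves) {
          h$replicate <- ri
          series[[length(series) + 1L]] <- h
        }
      }
      pooled <- do.call(rbind, series)
      fname <- file.path(odir, paste0("distance_",
                                      gsub("[^A-Za-z0-9]", "_", spec),
                                      ".csv"))
      emit(write_csv_plain(pooled, fname))
      geo[[spec]] <- c(boxplot_stats(pooled$distance_nm),
                       list(distribution = distance_probability(
                         series, bin_width = p$bin_width)[c("mids", "prob")]))
    }
    jsonlite::write_json(geo, file.path(odir, "geometry_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    emit(file.path(odir, "geometry_summary.json"))
    out$geometry <- geo
  }

  if ("rmsf" %in% names(an)) {
    p <- an$rmsf
    fit <- if (is.null(p$fit_selection)) NULL else
      select_atoms(topo, p$fit_selection)
    target <- select_atoms(topo, p$target_selection)
    profiles <- lapply(reps, rmsf_profile, fit_selection = fit,
                       target_selection = target)
    avg <- rmsf_average(profiles)
    emit(write_csv_plain(avg, file.path(odir, "rmsf_mean.csv")))
    out$rmsf <- list(mean_rmsf_nm = mean(avg$rmsf_nm),
                     max_rmsf_nm = max(avg$rmsf_nm), n = length(profiles))
  }

  if ("sasa" %in% names(an)) {
    p <- an$sasa
    series <- lapply(reps, function(t) {
      sasa_series(t, cavity_residues = unlist(p$cavity_residues),
                  class_filter = p$class_filter, probe = p$probe,
                  stride_ps = p$stride_ps, window_ps = p$window_ps)
    })
    for (i in seq_along(series)) {
      df <- data.frame(time_ps = series[[i]]$times_ps,
                       sasa_nm2 = series[[i]]$raw_nm2,
                       smoothed_nm2 = series[[i]]$smoothed_nm2)
      emit(write_csv_plain(df, file.path(odir, sprintf("sasa_rep%d.csv", i))))
    }
    means <- vapply(series, function(s) mean(s$raw_nm2), numeric(1))
    out$sasa <- list(mean_nm2 = mean(means),
                     sem_nm2 = if (length(means) >= 2L)
                       stats::sd(means) / sqrt(length(means)) else NULL,
                     n = length(means))
  }

  out
}
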