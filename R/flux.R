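#' @title Valve-anchored compartment boxes and water flux counting
#' @description The analysis volume is anchored on the hydrophobic valve
#'   (by default the Calpha centroid of residues 554 and 555 of both
#'   chains): a 4 x 4 x 6 nm density box surrounds the valve, and a
#'   2 x 2 x 4 nm flux box, split at the valve plane into an upper and a
#'   central 2 x 2 x 2 nm sub-box, is used to count water molecules
#'   exchanged between the cavities in consecutive analyzed frames
#'   (default stride 10 ps).
#' @name valve-flux
NULL

#' Default valve anchor selection expression
#' @export
VALVE_SELECTION <- "resid 554 555 and name CA"

#' Anchor the analysis boxes on the valve
#'
#' @param frame a `vw_frame`
#' @param valve_selection a `vw_selection` marking the valve atoms
#' @param density_dims density box edge lengths (nm), default 4 x 4 x 6
#' @param flux_dims full flux box edge lengths (nm), default 2 x 2 x 4;
#'   split at the valve plane into two sub-boxes stacked along `axis`
#' @param axis membrane normal: 1, 2 or 3 (x, y, z); default 3
#' @return object of class `vw_boxes` with the valve centroid as `center`;
#'   the valve plane is the axial coordinate of the centroid.
#' @export
anchor_boxes <- function(frame, valve_selection,
                         density_dims = c(4, 4, 6),
                         flux_dims = c(2, 2, 4), axis = 3L) {
  stopifnot(inherits(frame, "vw_frame"))
  if (!inherits(valve_selection, "vw_selection") ||
      length(valve_selection$indices) == 0L) {
    stop("valve selection is empty")
  }
  if (length(valve_selection$indices) == 1L) {
    warning("valve anchor selection contains a single atom")
  }
  if (any(density_dims <= 0) || any(flux_dims <= 0)) {
    stop("box dimensions must be strictly positive")
  }
  if (any(flux_dims > density_dims)) {
    stop("flux box must nest inside the density box")
  }
  if (!axis %in% 1:3) stop("axis must be 1, 2 or 3")
  center <- colMeans(selection_xyz(frame, valve_selection))
  structure(list(center = center, density_dims = as.numeric(density_dims),
                 flux_dims = as.numeric(flux_dims), axis = as.integer(axis),
                 valve_selection = valve_selection),
            class = "vw_boxes")
}

#' @export
print.vw_boxes <- function(x, ...) {
  cat(sprintf(
    "<vw_boxes> center (%.3f, %.3f, %.3f) nm, density %gx%gx%g, flux %gx%gx%g, axis %d\n",
    x$center[1L], x$center[2L], x$center[3L],
    x$density_dims[1L], x$density_dims[2L], x$density_dims[3L],
    x$flux_dims[1L], x$flux_dims[2L], x$flux_dims[3L], x$axis))
  invisible(x)
}

#' Classify waters into upper / central / outside compartments
#'
#' Membership is evaluated on the minimum-image displacement from the box
#' centre, so wrapped coordinates are handled. The two flux sub-boxes share
#' the valve plane; bins are half-open (axial coordinate exactly on the
#' valve plane counts as upper) so the partition is exhaustive and
#' exclusive.
#'
#' @param frame a `vw_frame`
#' @param boxes a `vw_boxes`
#' @param water_selection a `vw_selection` of water positions (one site per
#'   molecule, conventionally the oxygen)
#' @return character vector (`"upper"`, `"central"`, `"outside"`), one label
#'   per selected water
#' @export
classify_waters <- function(frame, boxes, water_selection) {
  pos <- selection_xyz(frame, water_selection)
  d <- minimum_image_displacement(matrix(boxes$center, nrow(pos), 3L,
                                         byrow = TRUE), pos, frame$box)
  ax <- boxes$axis
  lat <- setdiff(1:3, ax)
  half_lat1 <- boxes$flux_dims[lat[1L]] / 2
  half_lat2 <- boxes$flux_dims[lat[2L]] / 2
  half_ax <- boxes$flux_dims[ax] / 2
  inside_lat <- d[, lat[1L]] >= -half_lat1 & d[, lat[1L]] < half_lat1 &
                d[, lat[2L]] >= -half_lat2 & d[, lat[2L]] < half_lat2
  labels <- rep("outside", nrow(pos))
  labels[inside_lat & d[, ax] >= 0 & d[, ax] < half_ax] <- "upper"
  labels[inside_lat & d[, ax] >= -half_ax & d[, ax] < 0] <- "central"
  labels
}

#' Count water crossings through the valve
#'
#' For each pair of consecutive analyzed frames (separated by `stride_ps`),
#' a water contributes one crossing event iff it is labelled `upper` at one
#' frame and `central` at the other; passages via `outside` contribute
#' nothing. Both directions are summed in the total; directional tallies and
#' the number of distinct water molecules involved are retained.
#'
#' @param traj a `vw_trajectory` (trim equilibration first)
#' @param boxes a `vw_boxes` from [anchor_boxes()]
#' @param water_selection a `vw_selection`; default selects water residues
#' @param stride_ps analysis stride (ps); must be a multiple of the frame
#'   spacing
#' @param reanchor re-anchor the boxes on the valve selection at every
#'   analyzed frame (default `TRUE`; the protein drifts); `FALSE` keeps the
#'   boxes fixed where first anchored
#' @return object of class `vw_flux_record`: `events` data.frame (`time`,
#'   `frame`, `water`, `atom`, `direction` in `{"up","down"}` where up means
#'   central to upper), `cumulative` data.frame (`time`, `count`),
#'   `n_events`, `n_up`, `n_down`, `n_unique_waters`, `stride_ps`,
#'   `window_ps`
#' @export
count_crossings <- function(traj, boxes, water_selection = NULL,
                            stride_ps = 10, reanchor = TRUE) {
  stopifnot(inherits(traj, "vw_trajectory"), inherits(boxes, "vw_boxes"))
  if (is.null(water_selection)) {
    water_selection <- select_atoms(traj$topology, "water")
  }
  spacing <- traj$spacing
  k <- stride_ps / spacing
  if (abs(k - round(k)) > 1e-9 || k < 1) {
    stop("stride ", stride_ps, " ps is not a multiple of the frame spacing (",
         spacing, " ps)")
  }
  k <- as.integer(round(k))
  frames <- seq(1L, traj$n_frames, by = k)
  if (length(frames) < 2L) stop("fewer than two analyzed frames")

  widx <- water_selection$indices
  n_w <- length(widx)
  prev_labels <- NULL
  ev_time <- numeric(0); ev_frame <- integer(0); ev_water <- integer(0)
  ev_dir <- character(0)
  cum_time <- numeric(0); cum_count <- integer(0)
  total <- 0L
  b <- boxes
  for (fi in frames) {
    fr <- get_frame(traj, fi)
    if (reanchor) {
      b <- anchor_boxes(fr, boxes$valve_selection, boxes$density_dims,
                        boxes$flux_dims, boxes$axis)
    }
    labels <- classify_waters(fr, b, water_selection)
    if (!is.null(prev_labels)) {
      up <- which(prev_labels == "central" & labels == "upper")
      down <- which(prev_labels == "upper" & labels == "central")
      n_new <- length(up) + length(down)
      if (n_new > 0L) {
        ev_time <- c(ev_time, rep(fr$time, n_new))
        ev_frame <- c(ev_frame, rep(fi, n_new))
        ev_water <- c(ev_water, up, down)
        ev_dir <- c(ev_dir, rep("up", length(up)), rep("down", length(down)))
      }
      total <- total + n_new
      cum_time <- c(cum_time, fr$time)
      cum_count <- c(cum_count, total)
    }
    prev_labels <- labels
  }
  events <- data.frame(time = ev_time, frame = ev_frame, water = ev_water,
                       atom = widx[ev_water], direction = ev_dir,
                       stringsAsFactors = FALSE)
  structure(list(
    events = events,
    cumulative = data.frame(time = cum_time, count = cum_count),
    n_events = total,
    n_up = sum(ev_dir == "up"),
    n_down = sum(ev_dir == "down"),
    n_unique_waters = length(unique(ev_water)),
    stride_ps = stride_ps,
    window_ps = traj$times[frames[length(frames)]] - traj$times[frames[1L]],
    n_waters = n_w
  ), class = "vw_flux_record")
}

#' @export
print.vw_flux_record <- function(x, ...) {
  cat("<vw_flux_record> ", x$n_events, " crossing events (",
      x$n_up, " up / ", x$n_down, " down, ", x$n_unique_waters,
      " distinct waters) over ", x$window_ps / 1000, " ns at ",
      x$stride_ps, " ps stride\n", sep = "")
  invisible(x)
}

#' Replicate summary of flux records
#'
#' @param records list of `vw_flux_record` from independent replicates with
#'   equal analysis windows
#' @param window_tol relative tolerance on window equality
#' @return list with `mean`, `sem` (n-1 denominator), `n`, `counts`
#'   (per-replicate event totals)
#' @export
flux_summary <- function(records, window_tol = 1e-6) {
  if (!is.list(records) || length(records) < 2L) {
    stop("at least two replicates are required (SEM undefined for one)")
  }
  windows <- vapply(records, function(r) r$window_ps, numeric(1))
  if (diff(range(windows)) > window_tol * max(windows)) {
    stop("replicate analysis windows differ: ",
         paste(signif(windows / 1000, 6), collapse = ", "), " ns")
  }
  counts <- vapply(records, function(r) r$n_events, numeric(1))
  list(mean = mean(counts),
       sem = stats::sd(counts) / sqrt(length(counts)),
       n = length(counts),
       counts = counts)
}
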