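#' Trajectory ensemble container
#'
#' An ensemble of single-molecule membrane-binding trajectories sampled at a
#' common frame interval, the universal input of the kinetic estimators.
#' It bundles a long-format table of observed track points with per-molecule
#' metadata (censoring flags and, for simulated data, the ground truth).
#'
#' @param tracks data.frame with columns `molecule_id`, `cell_id`, `frame`
#'   (0-based within the track), `t_s` (seconds since the molecule was first
#'   observed), `x_um`, `y_um`, and optionally `state` (true binding state,
#'   simulated data only).
#' @param molecules data.frame with one row per molecule: `molecule_id`,
#'   `cell_id`, `censored_start` (molecule already present at movie start),
#'   `censored_end` (still present at movie end), `n_frames`, and optionally
#'   `loss_cause` (`"unbind"`, `"bleach"` or `"censored"`) and
#'   `true_duration` (seconds from membrane association to loss).
#' @param frame_interval frame interval in seconds.
#' @param condition_label free-text label of the experimental condition.
#' @param n_cells number of cells contributing trajectories.
#'
#' @return An object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(tracks, molecules, frame_interval,
                                condition_label = "", n_cells = 1L) {
  stopifnot(is.data.frame(tracks), is.data.frame(molecules))
  req <- c("molecule_id", "cell_id", "frame", "t_s", "x_um", "y_um")
  miss <- setdiff(req, names(tracks))
  if (length(miss) > 0)
    stop("tracks is missing columns: ", paste(miss, collapse = ", "))
  req_m <- c("molecule_id", "censored_start", "censored_end")
  miss <- setdiff(req_m, names(molecules))
  if (length(miss) > 0)
    stop("molecules is missing columns: ", paste(miss, collapse = ", "))
  if (!is.numeric(frame_interval) || length(frame_interval) != 1 ||
      frame_interval <= 0)
    stop("frame_interval must be a single positive number")
  # track times must sit on the frame grid
  off_grid <- abs(tracks$t_s - round(tracks$t_s / frame_interval) * frame_interval)
  if (any(off_grid > 1e-9))
    stop("track times are not integer multiples of frame_interval")
  structure(
    list(tracks = tracks, molecules = molecules,
         frame_interval = frame_interval,
         condition_label = condition_label, n_cells = as.integer(n_cells)),
    class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  n_cens <- sum(x$molecules$censored_start | x$molecules$censored_end)
  cat(sprintf(
    "<trajectory_ensemble> %d molecules (%d censored), %d cells, dt = %.4g s%s\n",
    nrow(x$molecules), n_cens, x$n_cells, x$frame_interval,
    if (nzchar(x$condition_label)) paste0(" [", x$condition_label, "]") else ""))
  invisible(x)
}

#' Drop censored trajectories
#'
#' Removes trajectories flagged as present at movie start or end, following
#' the single-molecule tracking convention that only fully observed binding
#' events enter the lifetime and diffusion statistics.
#'
#' @param ensemble a [trajectory_ensemble].
#' @return A `trajectory_ensemble` containing only uncensored molecules.
#' @export
drop_censored <- function(ensemble) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  keep <- !(ensemble$molecules$censored_start | ensemble$molecules$censored_end)
  ids <- ensemble$molecules$molecule_id[keep]
  out <- ensemble
  out$molecules <- ensemble$molecules[keep, , drop = FALSE]
  out$tracks <- ensemble$tracks[ensemble$tracks$molecule_id %in% ids, , drop = FALSE]
  out
}

# number of observed frames per molecule, aligned with ensemble$molecules rows
frames_per_molecule <- function(ensemble) {
  tab <- table(ensemble$tracks$molecule_id)
  as.integer(tab[as.character(ensemble$molecules$molecule_id)])
}
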