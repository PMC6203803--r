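#' Write a trajectory ensemble to TSV
#'
#' Writes the observed track table (with units embedded in the column
#' names) and, when ground truth is present, a sidecar TSV carrying the
#' per-frame true state and noiseless positions.
#'
#' @param ensemble a [trajectory_ensemble].
#' @param path output TSV path.
#' @param ground_truth_path optional sidecar TSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(ensemble, path, ground_truth_path = NULL) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  tr <- ensemble$tracks
  mol <- ensemble$molecules
  cs <- mol$censored_start[match(tr$molecule_id, mol$molecule_id)]
  ce <- mol$censored_end[match(tr$molecule_id, mol$molecule_id)]
  out <- data.frame(molecule_id = tr$molecule_id, cell_id = tr$cell_id,
                    frame = tr$frame, t_s = tr$t_s,
                    x_um = tr$x_um, y_um = tr$y_um,
                    censored_start = as.integer(cs),
                    censored_end = as.integer(ce))
  data.table::fwrite(out, path, sep = "\t")
  if (!is.null(ground_truth_path) && !is.null(tr$state)) {
    gt <- data.frame(
      molecule_id = tr$molecule_id, frame = tr$frame, state = tr$state,
      x_true_um = tr$x_true_um, y_true_um = tr$y_true_um,
      loss_cause = mol$loss_cause[match(tr$molecule_id, mol$molecule_id)],
      true_duration = mol$true_duration[match(tr$molecule_id, mol$molecule_id)])
    data.table::fwrite(gt, ground_truth_path, sep = "\t")
  }
  invisible(path)
}

#' Read a trajectory ensemble from TSV
#'
#' Streaming-friendly reader for the tab-separated trajectory schema
#' (`molecule_id, cell_id, frame, t_s, x_um, y_um, censored_start,
#' censored_end`). Molecules with duplicate frames or gaps in their frame
#' sequence are rejected individually; the rejections are collected into an
#' error report attached as attribute `rejected` (with reasons), and a
#' warning summarizes them.
#'
#' @param path TSV path.
#' @param condition_label,n_cells ensemble metadata (n_cells defaults to
#'   the number of distinct cell ids).
#' @return A [trajectory_ensemble].
#' @export
read_trajectories <- function(path, condition_label = "", n_cells = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- as.data.frame(data.table::fread(path, sep = "\t"))
  req <- c("molecule_id", "cell_id", "frame", "t_s", "x_um", "y_um",
           "censored_start", "censored_end")
  miss <- setdiff(req, names(tr))
  if (length(miss) > 0)
    stop("missing columns: ", paste(miss, collapse = ", "))
  tr <- tr[order(tr$molecule_id, tr$frame), ]
  # frame interval from the most common positive time step
  dts <- diff(tr$t_s)
  same <- tr$molecule_id[-1L] == tr$molecule_id[-nrow(tr)]
  dts <- dts[same & dts > 0]
  if (length(dts) == 0) stop("cannot infer frame interval: no within-track steps")
  dt <- stats::median(dts)

  rejected <- data.frame(molecule_id = integer(0), reason = character(0),
                         line = integer(0))
  ok_ids <- integer(0)
  for (id in unique(tr$molecule_id)) {
    rows <- which(tr$molecule_id == id)
    fr <- tr$frame[rows]
    if (anyDuplicated(fr)) {
      rejected <- rbind(rejected, data.frame(
        molecule_id = id, reason = "duplicate (molecule, frame) key",
        line = rows[which(duplicated(fr))[1]] + 1L))
    } else if (length(fr) > 1 && any(diff(fr) != 1L)) {
      rejected <- rbind(rejected, data.frame(
        molecule_id = id, reason = "gap in frame sequence",
        line = rows[which(diff(fr) != 1L)[1] + 1L] + 1L))
    } else if (length(fr) > 1 &&
               any(abs(diff(tr$t_s[rows]) - dt) > 1e-6 * dt + 1e-9)) {
      rejected <- rbind(rejected, data.frame(
        molecule_id = id, reason = "non-uniform frame spacing",
        line = rows[which(abs(diff(tr$t_s[rows]) - dt) > 1e-6 * dt + 1e-9)[1] + 1L] + 1L))
    } else {
      ok_ids <- c(ok_ids, id)
    }
  }
  if (nrow(rejected) > 0)
    warning(nrow(rejected), " molecule(s) rejected while reading ", path,
            " (see attr(., 'rejected'))")
  tr <- tr[tr$molecule_id %in% ok_ids, , drop = FALSE]
  if (nrow(tr) == 0) stop("no valid molecules in ", path)
  first <- !duplicated(tr$molecule_id)
  mol <- data.frame(molecule_id = tr$molecule_id[first],
                    cell_id = tr$cell_id[first],
                    censored_start = as.logical(tr$censored_start[first]),
                    censored_end = as.logical(tr$censored_end[first]))
  if (is.null(n_cells)) n_cells <- length(unique(mol$cell_id))
  keep_cols <- intersect(c("molecule_id", "cell_id", "frame", "t_s",
                           "x_um", "y_um", "state", "x_true_um", "y_true_um"),
                         names(tr))
  out <- trajectory_ensemble(tr[, keep_cols], mol, dt,
                             condition_label = condition_label,
                             n_cells = n_cells)
  attr(out, "rejected") <- rejected
  out
}

#' Write / read a kymograph as per-channel CSV matrices
#'
#' One CSV per channel: first column `angle_deg` (rows are angles in
#' degrees in [0, 360)), remaining columns the frame times, headed
#' `t_<seconds>`.
#'
#' @param kym a [kymograph].
#' @param prefix output path prefix; files are `<prefix>_<channel>.csv`.
#' @return Named character vector of written paths, invisibly.
#' @export
write_kymograph <- function(kym, prefix) {
  stopifnot(inherits(kym, "kymograph"))
  paths <- character(0)
  for (nm in names(kym$channels)) {
    df <- data.frame(angle_deg = kym$angles, kym$channels[[nm]])
    names(df)[-1] <- paste0("t_", format(kym$times, trim = TRUE))
    p <- paste0(prefix, "_", nm, ".csv")
    utils::write.csv(df, p, row.names = FALSE)
    paths[nm] <- p
  }
  invisible(paths)
}

#' @rdname write_kymograph
#' @param paths named character vector of per-channel CSV paths.
#' @export
read_kymograph <- function(paths) {
  channels <- list()
  angles <- NULL; times <- NULL
  for (nm in names(paths)) {
    df <- utils::read.csv(paths[[nm]], check.names = FALSE)
    angles <- df$angle_deg
    times <- as.numeric(sub("^t_", "", names(df)[-1]))
    channels[[nm]] <- as.matrix(df[, -1, drop = FALSE])
    dimnames(channels[[nm]]) <- NULL
  }
  kymograph(angles, times, channels)
}

#' Write a survival curve as two-column CSV
#'
#' Columns `t_s, fraction_bound`; `n0` and the frame interval travel in a
#' leading comment line so the curve round-trips.
#'
#' @param curve a [build_survival()] curve.
#' @param path output CSV path.
#' @export
write_survival_csv <- function(curve, path) {
  stopifnot(inherits(curve, "survival_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n0=%d frame_interval=%.12g", curve$n0,
                     curve$frame_interval), con)
  utils::write.csv(data.frame(t_s = curve$times,
                              fraction_bound = curve$fraction_bound),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_csv
#' @export
read_survival_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  n0 <- as.integer(sub(".*n0=(\\d+).*", "\\1", hdr))
  dt <- as.numeric(sub(".*frame_interval=([0-9.eE+-]+).*", "\\1", hdr))
  df <- utils::read.csv(path, comment.char = "#")
  structure(list(times = df$t_s, fraction_bound = df$fraction_bound,
                 n0 = n0, frame_interval = dt),
            class = "survival_curve")
}

#' Read a migration track TSV
#'
#' Columns `t_s, x_um, y_um`; an optional leading comment line
#' `# source_x_um=<x> source_y_um=<y>` carries the attractant source.
#'
#' @param path TSV path.
#' @return A [migration_track].
#' @export
read_migration_track <- function(path) {
  hdr <- readLines(path, n = 1L)
  src <- NULL
  if (startsWith(hdr, "#")) {
    sx <- suppressWarnings(as.numeric(sub(".*source_x_um=([0-9.eE+-]+).*", "\\1", hdr)))
    sy <- suppressWarnings(as.numeric(sub(".*source_y_um=([0-9.eE+-]+).*", "\\1", hdr)))
    if (is.finite(sx) && is.finite(sy)) src <- c(sx, sy)
  }
  df <- utils::read.delim(path, comment.char = "#")
  dts <- diff(df$t_s)
  if (length(dts) > 0 && max(abs(dts - dts[1])) > 1e-9)
    stop("non-uniform sampling in migration track")
  migration_track(cbind(df$x_um, df$y_um),
                  dt = if (length(dts) > 0) dts[1] else 5,
                  source_position = src)
}

#' @rdname read_migration_track
#' @param track a [migration_track].
#' @export
write_migration_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(track$source_position))
    writeLines(sprintf("# source_x_um=%.12g source_y_um=%.12g",
                       track$source_position[1], track$source_position[2]), con)
  df <- data.frame(t_s = (seq_len(nrow(track$positions)) - 1L) * track$dt,
                   x_um = track$positions[, 1], y_um = track$positions[, 2])
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# polynomial rolling hash of a deparsed object, for embedding a config
# fingerprint in result files without a digest dependency
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Write an analysis result as JSON
#'
#' Serializes a fit or summary to JSON with the configuration fingerprint
#' and seed embedded, so every stochastic output is re-derivable.
#'
#' @param result list-like result object.
#' @param path output JSON path.
#' @param config parameters that produced the result (hashed and embedded).
#' @param seed seed that produced the result.
#' @export
write_result_json <- function(result, path, config = NULL, seed = NULL) {
  payload <- unclass(result)
  payload$meta <- list(config_hash = config_hash(config), seed = seed,
                       package_version = as.character(utils::packageVersion("smkinetics")))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

# allowed per-stage configuration keys
.config_schema <- list(
  simulate = c("n_states", "diffusion", "dissoc_rate", "transition_rates",
               "bleach_rate", "loc_error", "frame_interval", "movie_duration",
               "n_molecules", "arrival_rate", "burn_in", "init_state_probs",
               "field_size", "n_cells", "seed"),
  dissociation = c("J", "bleach_rate", "t_max", "n_starts", "seed"),
  diffusion = c("J_max", "loc_error", "n_starts", "seed"),
  transitions = c("fixed_D", "loc_error", "min_count", "t_max",
                  "survival_weight", "bleach_rate", "seed"),
  kymograph = c("channel", "align_channel", "measure_channel", "prominence"),
  migration = c("source_x_um", "source_y_um"),
  scatter = c("bins", "k", "covariance", "x_range", "y_range"))

#' Read and validate a run configuration
#'
#' YAML configuration with one block per pipeline stage; unknown stages or
#' keys are rejected with an error naming them. Every stage with a random
#' operation gets a `seed` (defaulted to 1 and echoed in the returned
#' config when absent).
#'
#' @param path YAML path.
#' @return Validated named list of stage parameter blocks, with attribute
#'   `hash`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a mapping of stage blocks")
  unknown <- setdiff(names(cfg), c(names(.config_schema), "format_version"))
  if (length(unknown) > 0)
    stop("unknown config stage(s): ", paste(unknown, collapse = ", "))
  for (stage in intersect(names(cfg), names(.config_schema))) {
    bad <- setdiff(names(cfg[[stage]]), .config_schema[[stage]])
    if (length(bad) > 0)
      stop("unknown key(s) in stage '", stage, "': ",
           paste(bad, collapse = ", "))
    if ("seed" %in% .config_schema[[stage]] && is.null(cfg[[stage]]$seed))
      cfg[[stage]]$seed <- 1L
  }
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}
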