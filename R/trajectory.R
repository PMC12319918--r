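#' Probe trajectory through the voxel grid
#'
#' A linear probe trajectory is a line through the Doppler voxel grid
#' parameterized by its tip voxel (the deepest point), a dimensionless slope
#' (lateral column offset per depth step), and the number N of 100-um depth
#' bins. Bins are ordered tip-first: bin k (0-based) sits at row
#' `tip_row - k`, column `round(tip_col + k * slope)` (half-up rounding),
#' so the trajectory ascends from the tip towards the brain surface.
#'
#' @param tip_col,tip_row Integer voxel coordinates of the tip
#'   (column = lateral x, row = depth y; 1-based).
#' @param slope Lateral offset (columns) per one-row step upward.
#' @param n_bins Number of depth bins N along the trajectory (e.g. 30 for a
#'   collicular insertion, 25 for thalamic/cortical ones).
#' @return An object of class `probe_trajectory`.
#' @export
probe_trajectory <- function(tip_col, tip_row, slope = 0, n_bins = 30) {
  stopifnot(
    length(tip_col) == 1, length(tip_row) == 1,
    is.numeric(slope), n_bins >= 1
  )
  structure(
    list(
      tip_col = as.integer(round(tip_col)),
      tip_row = as.integer(round(tip_row)),
      slope = as.numeric(slope), n_bins = as.integer(n_bins)
    ),
    class = "probe_trajectory"
  )
}

#' @export
print.probe_trajectory <- function(x, ...) {
  cat(sprintf(
    "<probe_trajectory> tip (col %d, row %d), slope %.3f, %d bins\n",
    x$tip_col, x$tip_row, x$slope, x$n_bins
  ))
  invisible(x)
}

# deterministic half-up rounding (base round() ties to even)
round_half_up <- function(x) floor(x + 0.5)

#' Voxel coordinates along a trajectory
#'
#' @param traj A [probe_trajectory()].
#' @param grid_dim Optional `c(n_rows, n_cols)`; if given, coordinates are
#'   validated to lie inside the grid (error otherwise).
#' @return A tibble with one row per bin (tip first): `bin` (1-based),
#'   `row`, `col`.
#' @export
#' @examples
#' trajectory_voxels(probe_trajectory(10, 50, slope = 0.5, n_bins = 5))
trajectory_voxels <- function(traj, grid_dim = NULL) {
  stopifnot(inherits(traj, "probe_trajectory"))
  k <- seq_len(traj$n_bins) - 1L
  out <- tibble::tibble(
    bin = k + 1L,
    row = traj$tip_row - k,
    col = as.integer(round_half_up(traj$tip_col + k * traj$slope))
  )
  if (!is.null(grid_dim)) {
    bad <- out$row < 1 | out$row > grid_dim[1] |
      out$col < 1 | out$col > grid_dim[2]
    if (any(bad)) {
      stop(sprintf(
        "trajectory exits the %d x %d grid at bin(s) %s",
        grid_dim[1], grid_dim[2],
        paste(utils::head(out$bin[bad], 3), collapse = ", ")
      ), call. = FALSE)
    }
  }
  out
}

#' Reposition the tip along a trajectory
#'
#' For recordings crossing two structures on one insertion (e.g. a
#' cortical segment above a collicular one), the upper structure is
#' analyzed with an artificial tip placed past the end of the lower one:
#' the line is unchanged, bin 1 moves `offset_bins` steps up it.
#'
#' @param traj A [probe_trajectory()].
#' @param offset_bins How many bins to move the tip up the trajectory.
#' @param n_bins Bin count of the derived trajectory (default: the
#'   remaining bins, `traj$n_bins - offset_bins`).
#' @return A new `probe_trajectory` on the same line.
#' @export
offset_tip <- function(traj, offset_bins, n_bins = NULL) {
  stopifnot(inherits(traj, "probe_trajectory"), offset_bins >= 0)
  if (is.null(n_bins)) n_bins <- traj$n_bins - offset_bins
  stopifnot(n_bins >= 1)
  probe_trajectory(
    round_half_up(traj$tip_col + offset_bins * traj$slope),
    traj$tip_row - offset_bins,
    traj$slope, n_bins
  )
}

#' Construct a validated trajectory inside a grid
#'
#' Convenience constructor that errors if any of the `n_bins` voxels falls
#' outside the grid.
#'
#' @param grid_dim `c(n_rows, n_cols)` of the voxel grid.
#' @param tip `c(col, row)` tip voxel coordinates.
#' @param slope Lateral offset per depth step.
#' @param n_bins Number of depth bins.
#' @return A `probe_trajectory`.
#' @export
gen_trajectory <- function(grid_dim, tip, slope = 0, n_bins = 30) {
  traj <- probe_trajectory(tip[1], tip[2], slope, n_bins)
  trajectory_voxels(traj, grid_dim) # validates
  traj
}
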