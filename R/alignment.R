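#' Monte-Carlo trajectory candidates
#'
#' Perturbs an initial trajectory estimate: tip shifts `(d_col, d_row)` are
#' uniform integers in `[-max_shift, max_shift]`, the slope perturbation is
#' uniform real in `[-slope_jitter, slope_jitter]`. Candidates whose voxels
#' leave the grid are rejected and resampled. The unperturbed initial
#' trajectory is always injected as candidate 1 (so the selected score can
#' never fall below the initial's).
#'
#' @param initial A [probe_trajectory()] (the B-mode-derived estimate).
#' @param grid_dim `c(n_rows, n_cols)` of the voxel grid.
#' @param n Number of candidates (default 10000).
#' @param max_shift Maximum tip shift in voxels (default 5).
#' @param slope_jitter Half-range of the slope perturbation (default 0.2).
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return A tibble: `candidate`, `d_col`, `d_row`, `d_slope`, `tip_col`,
#'   `tip_row`, `slope`.
#' @export
sample_candidates <- function(initial, grid_dim, n = 10000,
                              max_shift = 5, slope_jitter = 0.2,
                              seed = NULL) {
  stopifnot(inherits(initial, "probe_trajectory"), n >= 1)
  trajectory_voxels(initial, grid_dim) # initial must itself be valid
  draw <- function() {
    k <- seq_len(initial$n_bins) - 1L
    got <- list()
    have <- 0L
    tries <- 0L
    while (have < n - 1L) {
      m <- max(2L * (n - 1L - have), 100L)
      dc <- sample(seq(-max_shift, max_shift), m, replace = TRUE)
      dr <- sample(seq(-max_shift, max_shift), m, replace = TRUE)
      ds <- stats::runif(m, -slope_jitter, slope_jitter)
      tip_c <- initial$tip_col + dc
      tip_r <- initial$tip_row + dr
      sl <- initial$slope + ds
      # vectorized in-grid check over all bins
      rows_ok <- tip_r <= grid_dim[1] &
        tip_r - (initial$n_bins - 1L) >= 1
      cols <- round_half_up(outer(k, sl) + rep(tip_c, each = length(k)))
      cols_ok <- colSums(cols >= 1 & cols <= grid_dim[2]) == length(k)
      ok <- rows_ok & cols_ok
      if (any(ok)) {
        got[[length(got) + 1L]] <- tibble::tibble(
          d_col = dc[ok], d_row = dr[ok], d_slope = ds[ok]
        )
        have <- have + sum(ok)
      }
      tries <- tries + 1L
      if (tries > 1000L) {
        stop("could not sample valid candidates near this initial trajectory",
          call. = FALSE
        )
      }
    }
    utils::head(dplyr::bind_rows(got), n - 1L)
  }
  perturbed <- if (n > 1) {
    if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  } else {
    tibble::tibble(
      d_col = integer(0), d_row = integer(0),
      d_slope = numeric(0)
    )
  }
  out <- dplyr::bind_rows(
    tibble::tibble(d_col = 0L, d_row = 0L, d_slope = 0),
    perturbed
  )
  dplyr::mutate(out,
    candidate = dplyr::row_number(),
    tip_col = initial$tip_col + .data$d_col,
    tip_row = initial$tip_row + .data$d_row,
    slope = initial$slope + .data$d_slope,
    .before = 1
  )
}

#' Align the probe trajectory to the Doppler grid
#'
#' Scores every candidate trajectory by the Pearson correlation between the
#' trial-averaged percent-change Doppler values extracted along it and the
#' first N spike-rate depth bins from the tip (both at the highest-SNR
#' contrast), and returns the maximizer. Ties and the degenerate
#' uniform-field case resolve to the lowest candidate index.
#'
#' @param session A `fus_session`.
#' @param initial Initial [probe_trajectory()] estimate.
#' @param n_candidates Number of Monte-Carlo candidates (default 10000).
#' @param seed Seed for candidate sampling.
#' @param contrast Contrast condition used for the traces (default: the
#'   highest present).
#' @param arrangement `"concat"` correlates the full bin-by-frame
#'   concatenation; `"binmean"` correlates per-bin time means.
#' @param max_shift,slope_jitter Passed to [sample_candidates()].
#' @return An object of class `probe_alignment`: list with `trajectory`
#'   (best candidate), `score`, `candidates` (tibble with scores),
#'   `arrangement`, `contrast`.
#' @export
align_probe <- function(session, initial, n_candidates = 10000, seed = 1,
                        contrast = NULL,
                        arrangement = c("concat", "binmean"),
                        max_shift = 5, slope_jitter = 0.2) {
  arrangement <- match.arg(arrangement)
  tl <- session$timeline
  gd <- dim(session$mask)
  if (is.null(contrast)) contrast <- max(session$trials$contrast)
  N <- initial$n_bins

  # trial-averaged percent-change movie at the chosen contrast
  dmean <- delta_movie_average(session, contrast)[[1]]
  dim(dmean) <- c(gd[1] * gd[2], tl$n_frames)

  # trial-averaged per-bin percent spike-rate change, first N bins
  ids <- session$trials$trial[session$trials$contrast == contrast]
  S <- matrix(0, N, tl$n_frames)
  for (i in ids) {
    S <- S + delta_rows(
      session$spikes[seq_len(N), , i, drop = FALSE][, , 1] / tl$frame_s,
      tl$baseline_frames
    )
  }
  S <- S / length(ids)

  cand <- sample_candidates(initial, gd,
    n = n_candidates,
    max_shift = max_shift, slope_jitter = slope_jitter, seed = seed
  )
  if (nrow(cand) == 0) stop("all candidates invalid", call. = FALSE)

  k <- seq_len(N) - 1L
  if (arrangement == "concat") {
    y <- as.vector(S)
  } else {
    y <- rowMeans(S)
  }
  ny <- length(y)
  sy <- sum(y)
  syy <- sum(y^2)
  vy <- syy - sy^2 / ny

  scores <- numeric(nrow(cand))
  chunks <- split(seq_len(nrow(cand)), ceiling(seq_len(nrow(cand)) / 500))
  for (ch in chunks) {
    rows <- outer(-k, cand$tip_row[ch], "+")
    cols <- round_half_up(outer(k, cand$slope[ch]) +
      rep(cand$tip_col[ch], each = N))
    lin <- (cols - 1L) * gd[1] + rows # [bin, candidate]
    A <- dmean[as.vector(lin), , drop = FALSE] # (N*nch) x frames
    grp <- rep(seq_along(ch), each = N)
    if (arrangement == "concat") {
      sx <- rowsum(rowSums(A), grp)
      sxx <- rowsum(rowSums(A^2), grp)
      sxy <- rowsum(rowSums(A * S[rep(seq_len(N), length(ch)), ]), grp)
    } else {
      xb <- rowMeans(A)
      sx <- rowsum(xb, grp)
      sxx <- rowsum(xb^2, grp)
      sxy <- rowsum(xb * rep(y, length(ch)), grp)
    }
    vx <- sxx - sx^2 / ny
    scores[ch] <- (sxy - sx * sy / ny) / sqrt(vx * vy)
  }
  cand$score <- as.vector(scores)

  if (!any(is.finite(cand$score))) {
    warning("correlation undefined for every candidate (degenerate field); ",
      "returning the initial trajectory",
      call. = FALSE
    )
    best <- 1L
  } else {
    best <- which.max(cand$score) # first maximum on exact ties
  }
  structure(
    list(
      trajectory = probe_trajectory(
        cand$tip_col[best], cand$tip_row[best], cand$slope[best], N
      ),
      score = cand$score[best],
      candidates = cand, arrangement = arrangement, contrast = contrast
    ),
    class = "probe_alignment"
  )
}

#' @export
print.probe_alignment <- function(x, ...) {
  cat(sprintf(
    "<probe_alignment> %d candidates at %g%% contrast; best r = %.4f\n",
    nrow(x$candidates), x$contrast, x$score
  ))
  print(x$trajectory)
  invisible(x)
}

#' Trajectory-based region averaging
#'
#' For the Doppler signal, averages all voxels lying within a lateral band
#' of `band` voxels on each side of the trajectory and inside the region of
#' interest; for spikes, averages the trajectory depth bins inside the
#' region. Each trial's raw trace is averaged spatially first, converted to
#' percent change against its own baseline, then (unless `per_trial`)
#' averaged across the trials of each contrast -- one trace per contrast.
#'
#' @param session A `fus_session`.
#' @param trajectory A [probe_trajectory()] (typically the aligned one).
#' @param signal `"doppler"` or `"spikes"`.
#' @param region_id Region label (default 1).
#' @param band Lateral half-width in voxels (default 3, i.e. a 7-voxel-wide
#'   strip for a vertical trajectory).
#' @param contrasts Contrasts to extract (default all).
#' @param per_trial If `TRUE` return per-trial traces instead of
#'   trial-averaged ones.
#' @param value `"delta"` (percent change per trial, the default) or
#'   `"raw"` (plain spatial average: intensity, or spikes/s).
#' @return A tibble with `contrast`, `frame`, `time_s` (relative to trial
#'   start), `value` (% change), plus `trial` when `per_trial = TRUE` and
#'   `n_trials` otherwise. Trials with an invalid (zero) baseline are
#'   dropped from averages with a warning.
#' @export
region_average <- function(session, trajectory = NULL,
                           signal = c("doppler", "spikes"),
                           region_id = 1L, band = 3, contrasts = NULL,
                           per_trial = FALSE, value = c("delta", "raw")) {
  signal <- match.arg(signal)
  value <- match.arg(value)
  if (is.null(trajectory)) trajectory <- session$trajectory
  tl <- session$timeline
  gd <- dim(session$mask)
  tv <- trajectory_voxels(trajectory, gd)
  if (is.null(contrasts)) contrasts <- sort(unique(session$trials$contrast))

  if (signal == "doppler") {
    vox <- integer(0)
    for (b in seq_len(nrow(tv))) {
      cc <- (tv$col[b] - band):(tv$col[b] + band)
      cc <- cc[cc >= 1 & cc <= gd[2]]
      cc <- cc[session$mask[tv$row[b], cc] == region_id]
      vox <- c(vox, (cc - 1L) * gd[1] + tv$row[b])
    }
    vox <- unique(vox)
    if (length(vox) == 0) {
      stop("trajectory band does not intersect the region", call. = FALSE)
    }
    nT <- dim(session$doppler)[4]
    stride <- gd[1] * gd[2]
    idx <- as.vector(outer(vox, (seq_len(tl$n_frames * nT) - 1L) * stride,
      "+"
    ))
    vals <- session$doppler[idx]
    dim(vals) <- c(length(vox), tl$n_frames, nT)
    raw <- colMeans(vals) # frame x trial
  } else {
    in_reg <- tv$bin[session$mask[cbind(tv$row, tv$col)] == region_id]
    in_reg <- in_reg[in_reg <= dim(session$spikes)[1]]
    if (length(in_reg) == 0) {
      stop("no trajectory bin inside the region", call. = FALSE)
    }
    raw <- colMeans(
      session$spikes[in_reg, , , drop = FALSE] / tl$frame_s
    ) # frame x trial
  }

  deltas <- if (value == "delta") {
    delta_rows(t(raw), tl$baseline_frames) # trial x frame
  } else {
    t(raw)
  }
  out <- tibble::as_tibble(expand.grid(
    frame = seq_len(tl$n_frames), trial = seq_len(ncol(raw))
  ))
  out$value <- as.vector(t(deltas))
  out <- dplyr::inner_join(out, session$trials, by = "trial")
  out <- dplyr::filter(out, .data$contrast %in% contrasts)
  out$time_s <- (out$frame - 1) * tl$frame_s

  if (per_trial) {
    return(dplyr::select(
      out, "trial", "contrast", "frame", "time_s", "value"
    ))
  }
  bad <- unique(out$trial[is.na(out$value)])
  if (length(bad) > 0) {
    warning(sprintf(
      "dropping %d trial(s) with invalid baseline", length(bad)
    ), call. = FALSE)
    out <- dplyr::filter(out, !.data$trial %in% bad)
  }
  dplyr::summarise(
    dplyr::group_by(out, .data$contrast, .data$frame, .data$time_s),
    value = mean(.data$value), n_trials = dplyr::n(), .groups = "drop"
  )
}
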