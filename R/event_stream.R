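# Discretization of principal-component shape trajectories into unit-step
# integer states, and extraction of simple / time-correlated event rates.

#' Calibrate the substep discretization for a set of PC trajectories
#'
#' Changes in component 2 are rescaled by `sigma1/sigma2` (ratio of pooled
#' per-frame increment standard deviations) so both components take unit
#' steps at a similar time resolution. Each frame interval is then divided
#' into `k` substeps with linear interpolation of the PC values; `k` is the
#' smallest value on `ladder` for which no substep changes any discretized
#' component by more than one unit.
#'
#' @param trajectories a data.frame with columns `cell_id`, `frame`, `pc1`,
#'   `pc2` (and optionally `time_s`), or a list of such data.frames.
#' @param unit shape-space distance per integer step (after PC2 rescaling).
#' @param ladder candidate substep counts, scanned in increasing order.
#' @param frame_interval_s seconds between frames.
#' @param n_offset baseline added to the rounded values so states stay
#'   positive. If `NULL`, the smallest value of at least 30 that keeps
#'   every state at 1 or above across the dataset is used.
#' @return object of class `disc_config`: list with `substeps_per_frame`,
#'   `dt` (= `frame_interval_s / substeps_per_frame`), `pc2_scale`, `unit`,
#'   `n_offset`, `frame_interval_s`.
#' @export
#' @examples
#' tr <- data.frame(cell_id = 1, frame = 1:10, pc1 = cumsum(rnorm(10)),
#'                  pc2 = cumsum(rnorm(10)) / 2)
#' calibrate_substeps(tr, unit = 1)
calibrate_substeps <- function(trajectories, unit,
                               ladder = c(1L, 2L, 4L, 8L, 16L, 32L),
                               frame_interval_s = 3,
                               n_offset = NULL) {
  stopifnot(unit > 0)
  trajectories <- as_trajectory_list(trajectories)
  d1 <- unlist(lapply(trajectories, function(tr) diff(tr$pc1)))
  d2 <- unlist(lapply(trajectories, function(tr) diff(tr$pc2)))
  if (!length(d1)) stop("need at least one trajectory with >= 2 frames")
  s2 <- sd(d2)
  pc2_scale <- if (is.na(s2) || s2 == 0) 1 else sd(d1) / s2

  max_jump_at <- function(k) {
    mins <- Inf; maxj <- 0
    for (tr in trajectories) {
      v1 <- interp_substeps(tr$pc1, k)
      v2 <- interp_substeps(tr$pc2 * pc2_scale, k)
      n1 <- round(v1 / unit); n2 <- round(v2 / unit)
      if (length(n1) > 1) maxj <- max(maxj, abs(diff(n1)), abs(diff(n2)))
      mins <- min(mins, n1, n2)
    }
    list(max_jump = maxj, min_state = mins)
  }
  chosen <- NULL
  for (k in sort(as.integer(ladder))) {
    res <- max_jump_at(k)
    if (res$max_jump <= 1) { chosen <- k; break }
  }
  if (is.null(chosen)) {
    stop("no substep count on the ladder bounds per-substep changes by 1; ",
         "max observed jump at k = ", max(ladder), " is ",
         max_jump_at(max(ladder))$max_jump)
  }
  if (is.null(n_offset)) n_offset <- max(30L, 1L - res$min_state)
  structure(list(substeps_per_frame = chosen,
                 dt = frame_interval_s / chosen,
                 pc2_scale = pc2_scale, unit = unit,
                 n_offset = as.integer(n_offset),
                 frame_interval_s = frame_interval_s),
            class = "disc_config")
}

#' @export
print.disc_config <- function(x, ...) {
  cat(sprintf(paste0("discretization: k = %d substeps/frame, dt = %.4g s, ",
                     "pc2 scale = %.4g, unit = %.4g, offset = %d\n"),
              x$substeps_per_frame, x$dt, x$pc2_scale, x$unit, x$n_offset))
  invisible(x)
}

# linear interpolation of per-frame values onto k substeps per interval,
# including both endpoints once
interp_substeps <- function(v, k) {
  if (length(v) < 2 || k == 1) return(v)
  n <- length(v)
  tout <- seq(1, n, by = 1 / k)
  approx(seq_len(n), v, xout = tout)$y
}

#' Discretize a PC trajectory into integer particle-number states
#'
#' Applies the PC2 rescaling, interpolates each frame interval into
#' `config$substeps_per_frame` linear substeps, rounds to the nearest
#' multiple of `config$unit` and adds `config$n_offset`.
#'
#' @param trajectory data.frame with columns `cell_id`, `frame`, `pc1`,
#'   `pc2`.
#' @param config a `disc_config` from [calibrate_substeps].
#' @return object of class `discrete_trajectory`: list with `states`
#'   (integer matrix, columns N1 and N2, one row per substep), `dt`,
#'   `cell_id`, and `rel_fluctuation` (sigma_x / mean(N_x) per component).
#' @export
discretize <- function(trajectory, config) {
  stopifnot(inherits(config, "disc_config"))
  k <- config$substeps_per_frame
  v1 <- interp_substeps(trajectory$pc1, k)
  v2 <- interp_substeps(trajectory$pc2 * config$pc2_scale, k)
  N <- cbind(N1 = as.integer(round(v1 / config$unit)) + config$n_offset,
             N2 = as.integer(round(v2 / config$unit)) + config$n_offset)
  if (any(N < 1)) {
    stop("discretized state below 1; increase n_offset (need at least ",
         config$n_offset + 1L - min(N), ")")
  }
  jumps <- if (nrow(N) > 1) max(abs(diff(N[, 1])), abs(diff(N[, 2]))) else 0
  if (jumps > 1) {
    stop("per-substep change greater than 1 (", jumps,
         "); recalibrate with more substeps")
  }
  structure(list(states = N, dt = config$dt,
                 cell_id = trajectory$cell_id[1],
                 rel_fluctuation = apply(N, 2, function(x) sd(x) / mean(x))),
            class = "discrete_trajectory")
}

#' Extract the per-substep event stream from a discrete trajectory
#'
#' Each substep transition is classified, per component, as an increase
#' (+1), a decrease (-1) or no change (0), giving one of the 9 joint
#' macroscopic cases.
#'
#' @param discrete a `discrete_trajectory` (or a 2-column integer state
#'   matrix).
#' @return object of class `event_stream`: integer matrix (columns `e1`,
#'   `e2`, values -1/0/1, one row per transition) with attributes `dt` and
#'   `cell_id`.
#' @export
extract_events <- function(discrete) {
  states <- if (inherits(discrete, "discrete_trajectory")) discrete$states
            else as.matrix(discrete)
  dt <- if (inherits(discrete, "discrete_trajectory")) discrete$dt else NA
  if (nrow(states) < 2) {
    ev <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("e1", "e2")))
  } else {
    ev <- cbind(e1 = diff(states[, 1]), e2 = diff(states[, 2]))
    if (any(abs(ev) > 1)) {
      stop("event stream contains |change| > 1; calibration violated")
    }
  }
  structure(ev, dt = dt,
            cell_id = if (inherits(discrete, "discrete_trajectory"))
              discrete$cell_id else NA,
            mean_N = colMeans(states),
            class = c("event_stream", class(ev)))
}

# 4x4 ordered adjacent-pair count matrix of a stream (rows: event at t,
# cols: event at t + dt), in simple-event index order 1p,1m,2p,2m
mc_ordered_pair_counts <- function(events) {
  n <- nrow(events)
  if (n < 2) return(matrix(0, 4, 4,
                           dimnames = list(MC_SIMPLE_KEYS, MC_SIMPLE_KEYS)))
  M <- mc_event_indicators(events) * 1
  O <- crossprod(M[1:(n - 1), , drop = FALSE], M[2:n, , drop = FALSE])
  dimnames(O) <- list(MC_SIMPLE_KEYS, MC_SIMPLE_KEYS)
  O
}

# pool a 4x4 ordered count matrix into the 10 canonical correlated keys
mc_pool_pairs <- function(O) {
  out <- setNames(numeric(10), MC_CORR_KEYS)
  for (a in 1:4) for (b in 1:4) {
    key <- MC_PAIR_KEY[a, b]
    out[key] <- out[key] + O[a, b]
  }
  out
}

#' Compute simple and time-correlated event rates from an event stream
#'
#' Simple rates are per-substep probabilities of each of the four events.
#' Correlated rates count, per adjacent 2-substep window, every ordered pair
#' of non-null events (one at t, one at t + dt; all four cross pairs within
#' a window are counted), pooled over the two orders of each
#' order-reversal-symmetric key and divided by the number of windows. The
#' last substep contributes to simple rates but opens no window.
#'
#' @param stream an `event_stream`, or a list of event streams (pooled:
#'   counts and windows are summed across streams; windows never span
#'   stream boundaries).
#' @param mean_N mean particle numbers; defaults to the streams'
#'   `mean_N` attribute (averaged over streams weighted by length).
#' @return an [observable_set].
#' @export
compute_observables <- function(stream, mean_N = NULL) {
  streams <- if (inherits(stream, "event_stream")) list(stream) else stream
  lens <- vapply(streams, nrow, 0L)
  if (sum(lens) < 2) stop("need at least 2 substeps of events")
  simple_counts <- setNames(numeric(4), MC_SIMPLE_KEYS)
  pair_counts <- setNames(numeric(10), MC_CORR_KEYS)
  windows <- 0L
  if (is.null(mean_N)) {
    mN <- vapply(streams, function(s) {
      m <- attr(s, "mean_N"); if (is.null(m)) c(NA_real_, NA_real_) else m
    }, numeric(2))
    mean_N <- if (anyNA(mN)) c(NA_real_, NA_real_)
              else drop(mN %*% (lens / sum(lens)))
  }
  for (s in streams) {
    simple_counts <- simple_counts + colSums(mc_event_indicators(s))
    pair_counts <- pair_counts + mc_pool_pairs(mc_ordered_pair_counts(s))
    windows <- windows + max(nrow(s) - 1L, 0L)
  }
  observable_set(simple = simple_counts / sum(lens),
                 correlated = if (windows > 0) pair_counts / windows
                              else pair_counts,
                 mean_N = mean_N, n_substeps = sum(lens))
}

# accept one data.frame with cell_id column or a list of data.frames
as_trajectory_list <- function(trajectories) {
  if (is.data.frame(trajectories)) {
    split(trajectories, trajectories$cell_id)
  } else {
    trajectories
  }
}

#' Run discretization and event extraction over a set of trajectories
#'
#' Convenience wrapper: calibrates once over all trajectories, then
#' discretizes each and extracts its event stream.
#'
#' @inheritParams calibrate_substeps
#' @param config optional pre-computed `disc_config` (frozen calibration).
#' @return list with `config`, `discrete` (list of `discrete_trajectory`)
#'   and `streams` (list of `event_stream`).
#' @export
trajectories_to_events <- function(trajectories, unit, config = NULL,
                                   frame_interval_s = 3, ...) {
  trajectories <- as_trajectory_list(trajectories)
  if (is.null(config)) {
    config <- calibrate_substeps(trajectories, unit = unit,
                                 frame_interval_s = frame_interval_s, ...)
  }
  discrete <- lapply(trajectories, discretize, config = config)
  streams <- lapply(discrete, extract_events)
  list(config = config, discrete = discrete, streams = streams)
}
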