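# Synthetic inputs for every pipeline level: ground-truth multiplier presets,
# PC trajectories produced by the package's own simulator (for
# parameter-recovery tests), an independent AR(1) generator (for
# model-misspecification tests), rasterized blob movies (for end-to-end
# image tests), and labeled two-condition datasets.

#' Ground-truth multiplier presets
#'
#' `"wt_like"` emulates untreated amoeboid cells: suppressed direction
#' reversals within each component (negative `l11pm`, `l22pm`:
#' persistence) and enhanced cross-component anticorrelation (positive
#' `l12pm`, `l12mp`: an increase in one component tends to neighbor a
#' decrease in the other, as in pseudopod splitting). `"treated_like"` has
#' the same basic rates but all couplings near zero (drug-treated-like loss
#' of persistence). `"wt_nocross"` keeps the within-component persistence of
#' `"wt_like"` but zeroes the cross-component couplings — with matched
#' marginal state distributions this is the "same shapes, different
#' behavior" scenario.
#'
#' Basic rates default to a 15% chance of an increase per substep and a
#' matching total decay rate at the baseline state N = 30 (gamma_minus =
#' 0.15 / 30 per particle), so the components are stationary around the
#' baseline.
#'
#' @param name preset name.
#' @param N baseline particle numbers.
#' @return a [maxcal_multipliers] object.
#' @export
preset_multipliers <- function(name = c("wt_like", "treated_like",
                                        "wt_nocross"),
                               N = c(30L, 30L)) {
  name <- match.arg(name)
  simple <- c(l1p = log(0.15), l1m = log(0.15 / N[1]),
              l2p = log(0.15), l2m = log(0.15 / N[2]))
  corr <- switch(name,
    wt_like = c(l11pp = 0.3, l11pm = -1.2, l11mm = 0.3,
                l22pp = 0.3, l22pm = -1.2, l22mm = 0.3,
                l12pp = -0.4, l12pm = 0.9, l12mp = 0.9, l12mm = -0.4),
    treated_like = setNames(numeric(10), paste0("l", MC_CORR_KEYS)),
    wt_nocross = c(l11pp = 0.3, l11pm = -1.2, l11mm = 0.3,
                   l22pp = 0.3, l22pm = -1.2, l22mm = 0.3,
                   l12pp = 0, l12pm = 0, l12mp = 0, l12mm = 0))
  maxcal_multipliers(c(simple, corr), N = N)
}

#' Generate synthetic PC trajectories with known ground truth
#'
#' Discrete states are produced by [simulate_maxcal] at the chosen
#' ground-truth multipliers, mapped to continuous PC values
#' (`(N - n_offset) * unit` plus Gaussian observation noise), divided by
#' `sigma_ratio` for component 2 (so the generated data show the realistic
#' PC1 > PC2 variance ordering the discretization must undo), and
#' downsampled to frame resolution.
#'
#' @param n_cells number of cells.
#' @param n_frames frames per cell.
#' @param frame_interval_s seconds per frame.
#' @param substeps_per_frame substeps simulated per frame interval.
#' @param unit shape-space distance per integer step.
#' @param n_offset baseline particle number.
#' @param sigma_ratio scale factor between the two PCs (sigma1 / sigma2).
#' @param dynamics preset name or a [maxcal_multipliers] object.
#' @param noise_sd observation noise on PC1 (PC2 noise is scaled down by
#'   `sigma_ratio`), in units of `unit`.
#' @param seed integer seed (mandatory for reproducibility).
#' @return list with `trajectories` (data.frame: `cell_id`, `frame`,
#'   `time_s`, `pc1`, `pc2`), `truth` (the generating multiplier set),
#'   `states` (the underlying `trajectory_ensemble`) and the generator
#'   settings.
#' @export
generate_pc_trajectories <- function(n_cells = 50, n_frames = 200,
                                     frame_interval_s = 3,
                                     substeps_per_frame = 16, unit = 1,
                                     n_offset = 30L, sigma_ratio = 2,
                                     dynamics = "wt_like", noise_sd = 0.05,
                                     seed = 1L) {
  truth <- if (inherits(dynamics, "maxcal_multipliers")) dynamics
           else preset_multipliers(dynamics, N = c(n_offset, n_offset))
  n_sub <- (n_frames - 1) * substeps_per_frame + 1
  ens <- simulate_maxcal(truth, sim_config(
    n_cells = n_cells, n_substeps = n_sub,
    dt = frame_interval_s / substeps_per_frame,
    initial_N = c(n_offset, n_offset), seed = seed, mode = "correlated"))
  idx <- seq(1, n_sub, by = substeps_per_frame)
  trajs <- do.call(rbind, lapply(seq_len(n_cells), function(cell) {
    N <- ens$trajectories[[cell]][idx, , drop = FALSE]
    data.frame(cell_id = cell, frame = seq_len(n_frames),
               time_s = (seq_len(n_frames) - 1) * frame_interval_s,
               pc1 = (N[, 1] - n_offset) * unit +
                 rnorm(n_frames, sd = noise_sd * unit),
               pc2 = ((N[, 2] - n_offset) * unit +
                        rnorm(n_frames, sd = noise_sd * unit)) / sigma_ratio)
  }))
  list(trajectories = trajs, truth = truth, states = ens,
       settings = list(n_cells = n_cells, n_frames = n_frames,
                       frame_interval_s = frame_interval_s,
                       substeps_per_frame = substeps_per_frame, unit = unit,
                       n_offset = n_offset, sigma_ratio = sigma_ratio,
                       noise_sd = noise_sd, seed = seed))
}

#' Independent AR(1) trajectory generator
#'
#' Mean-reverting vector-autoregressive PC trajectories with tunable
#' cross-component coupling, generated without reference to the
#' maximum-caliber model. Used to test the pipeline on data the model did
#' not itself produce.
#'
#' @param n_cells,n_frames,frame_interval_s as in
#'   [generate_pc_trajectories].
#' @param phi autoregressive coefficient (|phi| < 1 for stationarity).
#' @param cross coupling of each component to the other's previous value;
#'   negative values give single-cell anticorrelation.
#' @param sd_noise innovation standard deviation.
#' @param sigma_ratio scale factor applied to component 2.
#' @param seed integer seed.
#' @return data.frame with `cell_id`, `frame`, `time_s`, `pc1`, `pc2`.
#' @export
generate_ar1_trajectories <- function(n_cells = 50, n_frames = 200,
                                      frame_interval_s = 3, phi = 0.9,
                                      cross = -0.05, sd_noise = 1,
                                      sigma_ratio = 2, seed = 1L) {
  set.seed(seed)
  A <- matrix(c(phi, cross, cross, phi), 2, 2)
  do.call(rbind, lapply(seq_len(n_cells), function(cell) {
    X <- matrix(0, n_frames, 2)
    for (t in 2:n_frames) {
      X[t, ] <- A %*% X[t - 1, ] + rnorm(2, sd = sd_noise)
    }
    data.frame(cell_id = cell, frame = seq_len(n_frames),
               time_s = (seq_len(n_frames) - 1) * frame_interval_s,
               pc1 = X[, 1], pc2 = X[, 2] / sigma_ratio)
  }))
}

#' Generate a synthetic binary blob movie
#'
#' Each frame is the filled region of the parametric outline
#' `r(theta, t) = base_radius * (1 + e(t) cos(2 theta) + l(t) cos(3 theta))`
#' rasterized on an `img_size` square grid. The elongation `e` and lobe
#' (splitting) amplitude `l` are driven by the two components of the chosen
#' dynamics (standardized states scaled by the amplitudes), so the movie's
#' shape variation carries the same temporal signature as the discrete
#' model.
#'
#' @param n_frames frames to generate.
#' @param base_radius blob radius in pixels.
#' @param elongation_amplitude,lobe_amplitude scale of the two shape modes;
#'   combinations that would make the radius non-positive raise an error.
#' @param img_size image side in pixels.
#' @param dynamics preset name or [maxcal_multipliers].
#' @param substeps_per_frame substeps of the driving dynamics per frame.
#' @param seed integer seed.
#' @return list with `frames` (list of logical matrices), `e`, `l` (the
#'   per-frame amplitudes), and `truth`.
#' @export
generate_blob_movie <- function(n_frames = 60, base_radius = 18,
                                elongation_amplitude = 0.22,
                                lobe_amplitude = 0.12, img_size = 96,
                                dynamics = "wt_like",
                                substeps_per_frame = 16, seed = 1L) {
  stopifnot(elongation_amplitude >= 0, lobe_amplitude >= 0)
  gen <- generate_pc_trajectories(
    n_cells = 1, n_frames = n_frames, substeps_per_frame = substeps_per_frame,
    dynamics = dynamics, noise_sd = 0, seed = seed)
  z1 <- gen$trajectories$pc1
  z2 <- gen$trajectories$pc2
  scl <- function(v) if (sd(v) > 0) (v - mean(v)) / (3 * sd(v)) else v * 0
  e <- elongation_amplitude * scl(z1) * 3 / 2
  l <- lobe_amplitude * scl(z2) * 3 / 2
  if (any(1 - abs(e) - abs(l) <= 0)) {
    stop("amplitudes make the radius non-positive; reduce them")
  }
  ctr <- (img_size + 1) / 2
  gx <- matrix(seq_len(img_size), img_size, img_size) - ctr
  gy <- t(gx)
  theta <- atan2(gy, gx)
  rr <- sqrt(gx^2 + gy^2)
  frames <- lapply(seq_len(n_frames), function(t) {
    rmax <- base_radius * (1 + e[t] * cos(2 * theta) + l[t] * cos(3 * theta))
    rr <= rmax
  })
  list(frames = frames, e = e, l = l, truth = gen$truth)
}

#' Labeled two-condition dataset for classification tests
#'
#' Generates PC trajectories for two conditions and assigns cells to folds
#' round-robin. With presets differing only in their couplings the marginal
#' shape distributions match while the dynamics differ — the scenario where
#' shape-based classification is near chance but behavioral signatures
#' separate the conditions.
#'
#' @param preset_a,preset_b preset names or [maxcal_multipliers] objects.
#' @param n_cells_each cells per condition.
#' @param n_frames frames per cell.
#' @param n_folds folds for cross-validation (assigned per cell).
#' @param seed integer seed.
#' @param ... passed to [generate_pc_trajectories].
#' @return list with `trajectories` (data.frame with `condition` column;
#'   `cell_id` is unique across conditions), `cells` (data.frame `cell_id`,
#'   `condition`, `fold`), `truth_a`, `truth_b`.
#' @export
make_two_condition_dataset <- function(preset_a = "wt_like",
                                       preset_b = "wt_nocross",
                                       n_cells_each = 30, n_frames = 200,
                                       n_folds = 3, seed = 1L, ...) {
  ga <- generate_pc_trajectories(n_cells = n_cells_each, n_frames = n_frames,
                                 dynamics = preset_a, seed = seed, ...)
  gb <- generate_pc_trajectories(n_cells = n_cells_each, n_frames = n_frames,
                                 dynamics = preset_b, seed = seed + 1L, ...)
  ta <- ga$trajectories; ta$condition <- "a"
  tb <- gb$trajectories; tb$condition <- "b"
  tb$cell_id <- tb$cell_id + n_cells_each
  cells <- data.frame(cell_id = seq_len(2 * n_cells_each),
                      condition = rep(c("a", "b"), each = n_cells_each))
  cells$fold <- ((cells$cell_id - 1L) %% n_folds) + 1L
  list(trajectories = rbind(ta, tb), cells = cells,
       truth_a = ga$truth, truth_b = gb$truth,
       states_a = ga$states, states_b = gb$states)
}
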