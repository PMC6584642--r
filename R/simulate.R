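# Trajectory simulators: sequential sampling from the fitted maximum-caliber
# model (with or without the adjacent-step couplings), and continuous-time
# Gillespie simulations of the matching birth-death system, Markovian or with
# nine memory states.

# joint event grid shared by the samplers: 9 cases, component order (e1, e2)
MC_JOINT_EVENTS <- as.matrix(expand.grid(e1 = c(-1L, 0L, 1L),
                                         e2 = c(-1L, 0L, 1L)))

# simple-event indices (1..4) contained in joint event j, as a list
mc_joint_members <- function() {
  lapply(seq_len(nrow(MC_JOINT_EVENTS)), function(j) {
    e <- MC_JOINT_EVENTS[j, ]
    c(if (e[1] == 1L) 1L else if (e[1] == -1L) 2L,
      if (e[2] == 1L) 3L else if (e[2] == -1L) 4L)
  })
}

# 9x9 base weight matrix: entry [s, e] = product of simple gammas of the
# events in e times coupling gammas for every (member of s, member of e)
# ordered pair; row 10 is the unconditional (first-substep) weight.
mc_weight_matrix <- function(multipliers, correlated = TRUE) {
  g <- multiplier_gammas(multipliers)
  members <- mc_joint_members()
  W <- matrix(0, 10, 9)
  for (e in 1:9) {
    base <- prod(g[paste0("l", MC_SIMPLE_KEYS)][members[[e]]],
                 na.rm = FALSE)
    if (length(members[[e]]) == 0) base <- 1
    for (s in 1:9) {
      cp <- 1
      if (correlated) {
        for (a in members[[s]]) for (b in members[[e]]) {
          cp <- cp * g[[paste0("l", MC_PAIR_KEY[a, b])]]
        }
      }
      W[s, e] <- base * cp
    }
    W[10, e] <- base
  }
  W
}

#' Simulation configuration
#'
#' @param n_cells number of independent trajectories.
#' @param n_substeps substeps per trajectory (>= 2).
#' @param dt substep duration in seconds.
#' @param initial_N starting particle-number pair.
#' @param seed integer seed; recorded in the output.
#' @param mode one of `"correlated"`, `"uncorrelated"`, `"markov_gillespie"`,
#'   `"memory_gillespie"`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 1, n_substeps = 1000, dt = 0.1875,
                       initial_N = c(30L, 30L), seed = 1L,
                       mode = "correlated") {
  stopifnot(n_substeps >= 2)
  structure(list(n_cells = n_cells, n_substeps = n_substeps, dt = dt,
                 initial_N = as.integer(initial_N), seed = as.integer(seed),
                 mode = mode),
            class = "sim_config")
}

#' Simulate discrete shape-change trajectories from a multiplier set
#'
#' Sequential lag-1 conditional sampling: the probability of joint event e at
#' a substep, given the previous substep's joint event e', is proportional to
#' `multiplicity(e, N) * prod(simple gammas of e) * prod(coupling gammas
#' (member of e' -> member of e))`. In `"uncorrelated"` mode (and for the
#' first substep) all couplings are treated as 1. A decrease of a component
#' at state N has multiplicity N; at N = 1 decreases are disallowed so
#' states stay >= 1.
#'
#' @param multipliers a [maxcal_multipliers] object.
#' @param config a [sim_config] with mode `"correlated"` or
#'   `"uncorrelated"`.
#' @return object of class `trajectory_ensemble`: list with `trajectories`
#'   (list of integer state matrices, columns N1, N2), `dt`, `seed`, `mode`.
#' @export
simulate_maxcal <- function(multipliers, config) {
  stopifnot(inherits(config, "sim_config"),
            config$mode %in% c("correlated", "uncorrelated"))
  set.seed(config$seed)
  W <- mc_weight_matrix(multipliers, correlated = config$mode == "correlated")
  dec1 <- which(MC_JOINT_EVENTS[, 1] == -1L)
  dec2 <- which(MC_JOINT_EVENTS[, 2] == -1L)
  E1 <- MC_JOINT_EVENTS[, 1]; E2 <- MC_JOINT_EVENTS[, 2]
  n <- config$n_substeps
  trajs <- vector("list", config$n_cells)
  for (cell in seq_len(config$n_cells)) {
    N1 <- integer(n); N2 <- integer(n)
    N1[1] <- config$initial_N[1]; N2[1] <- config$initial_N[2]
    prev <- 10L  # unconditional row for the first substep
    u <- runif(n)
    for (t in 2:n) {
      w <- W[prev, ]
      n1 <- N1[t - 1L]; n2 <- N2[t - 1L]
      w[dec1] <- w[dec1] * if (n1 > 1L) n1 else 0
      w[dec2] <- w[dec2] * if (n2 > 1L) n2 else 0
      cw <- cumsum(w)
      j <- which.max(cw >= u[t] * cw[9L])
      N1[t] <- n1 + E1[j]
      N2[t] <- n2 + E2[j]
      prev <- j
    }
    trajs[[cell]] <- cbind(N1 = N1, N2 = N2)
  }
  structure(list(trajectories = trajs, dt = config$dt, seed = config$seed,
                 mode = config$mode),
            class = "trajectory_ensemble")
}

#' Event streams of a trajectory ensemble
#'
#' @param ensemble a `trajectory_ensemble`.
#' @return list of [extract_events] streams, one per trajectory.
#' @export
ensemble_events <- function(ensemble) {
  lapply(seq_along(ensemble$trajectories), function(i) {
    ev <- extract_events(ensemble$trajectories[[i]])
    attr(ev, "dt") <- ensemble$dt
    attr(ev, "cell_id") <- i
    ev
  })
}

#' Co-occurrence matrix of adjacent-step events, scaled by naive rates
#'
#' Entry (a, b) is the frequency of the ordered adjacent pair (event a at t,
#' event b at t + dt), pooled symmetrically over the two orders, divided by
#' the product of the marginal rates of a and b. Independent events give a
#' matrix of ones; values above (below) 1 mark pairs that co-occur more
#' (less) often than chance.
#'
#' @param streams an `event_stream` or list of event streams.
#' @return symmetric 4x4 matrix (rows/cols `1p`,`1m`,`2p`,`2m`); entries
#'   with a zero marginal rate are `NA`.
#' @export
cooccurrence_matrix <- function(streams) {
  if (inherits(streams, "event_stream")) streams <- list(streams)
  lens <- vapply(streams, nrow, 0L)
  if (!length(lens) || max(lens) < 2) {
    stop("need at least one stream with >= 2 substeps")
  }
  O <- matrix(0, 4, 4); counts <- setNames(numeric(4), MC_SIMPLE_KEYS)
  windows <- 0L
  for (s in streams) {
    O <- O + mc_ordered_pair_counts(s)
    counts <- counts + colSums(mc_event_indicators(s))
    windows <- windows + max(nrow(s) - 1L, 0L)
  }
  marg <- counts / sum(lens)
  R <- matrix(NA_real_, 4, 4, dimnames = list(MC_SIMPLE_KEYS, MC_SIMPLE_KEYS))
  for (a in 1:4) for (b in 1:4) {
    if (marg[a] > 0 && marg[b] > 0) {
      obs <- if (a == b) O[a, a] / windows
             else (O[a, b] + O[b, a]) / (2 * windows)
      R[a, b] <- obs / (marg[a] * marg[b])
    }
  }
  R
}

# ---- Gillespie ------------------------------------------------------------

# one continuous-time birth-death segment over duration `len`, starting at
# state N (pair), with rates list(k1p, k1m, k2p, k2m); death propensity is
# k_m * N per component. Returns final state and per-component net change,
# plus the count of events per component (to warn about double events).
gillespie_segment <- function(N, rates, len) {
  t <- 0
  nev <- c(0L, 0L)
  repeat {
    a <- c(rates$k1p, rates$k1m * (N[1] - 1 >= 1) * N[1],
           rates$k2p, rates$k2m * (N[2] - 1 >= 1) * N[2])
    a0 <- sum(a)
    if (a0 <= 0) break
    t <- t + rexp(1, a0)
    if (t >= len) break
    j <- which.max(cumsum(a) >= runif(1) * a0)
    if (j == 1L) N[1] <- N[1] + 1L else if (j == 2L) N[1] <- N[1] - 1L
    else if (j == 3L) N[2] <- N[2] + 1L else N[2] <- N[2] - 1L
    nev[(j + 1L) %/% 2L] <- nev[(j + 1L) %/% 2L] + 1L
  }
  list(N = N, nev = nev)
}

#' Markovian Gillespie simulation of the birth-death shape model
#'
#' Continuous-time simulation in which each component gains particles at a
#' constant rate and loses them at a rate proportional to its current count
#' (first-order decay, the virtual force pulling the system back toward its
#' mean `k_plus / k_minus`). Event times are binned to the substep grid for
#' comparison with the discrete models.
#'
#' @param rates list with `k1p`, `k1m`, `k2p`, `k2m`: birth rates (events
#'   per second) and per-particle death rates (per second per particle).
#' @param config a [sim_config] (mode `"markov_gillespie"`).
#' @return a `trajectory_ensemble` of states sampled at substep boundaries.
#'   If any substep bin receives two events in one component a warning is
#'   issued (the discretized stream then under-reports events).
#' @export
gillespie_markov <- function(rates, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (all(unlist(rates[c("k1p", "k1m", "k2p", "k2m")]) <= 0)) {
    warning("all propensities are zero; trajectories are frozen")
  }
  n <- config$n_substeps
  doubled <- 0L
  trajs <- lapply(seq_len(config$n_cells), function(cell) {
    N <- matrix(0L, n, 2, dimnames = list(NULL, c("N1", "N2")))
    N[1, ] <- config$initial_N
    for (t in 2:n) {
      seg <- gillespie_segment(N[t - 1, ], rates, config$dt)
      if (any(seg$nev > 1)) doubled <<- doubled + 1L
      N[t, ] <- seg$N
    }
    N
  })
  if (doubled > 0) {
    warning(doubled, " substep bins received more than one event in a ",
            "component; consider a smaller dt")
  }
  structure(list(trajectories = trajs, dt = config$dt, seed = config$seed,
                 mode = "markov_gillespie"),
            class = "trajectory_ensemble")
}

#' Nine-memory-state (non-Markovian) Gillespie simulation
#'
#' As [gillespie_markov], but the propensity set in force during a substep
#' depends on the joint event (one of the 9 macroscopic cases) observed in
#' the previous substep; the first substep uses the unconditional set. With
#' all nine sets identical the model reduces exactly to the Markovian one.
#'
#' @param rate_sets list with `base` (unconditional rates list, used for the
#'   first substep and as the `"0,0"` state if unnamed entries are missing)
#'   and `sets`: a list of 9 rates lists indexed by the previous joint event,
#'   in the order of rows of `MC_JOINT_EVENTS` (e1 = -1,0,1 varying fastest).
#'   See [memory_rates_from_multipliers].
#' @param config a [sim_config] (mode `"memory_gillespie"`).
#' @return a `trajectory_ensemble`.
#' @export
gillespie_memory <- function(rate_sets, config) {
  stopifnot(inherits(config, "sim_config"), length(rate_sets$sets) == 9)
  set.seed(config$seed)
  n <- config$n_substeps
  doubled <- 0L
  trajs <- lapply(seq_len(config$n_cells), function(cell) {
    N <- matrix(0L, n, 2, dimnames = list(NULL, c("N1", "N2")))
    N[1, ] <- config$initial_N
    state <- 0L  # 0 = no previous event: unconditional rates
    for (t in 2:n) {
      rates <- if (state == 0L) rate_sets$base else rate_sets$sets[[state]]
      seg <- gillespie_segment(N[t - 1, ], rates, config$dt)
      if (any(seg$nev > 1)) doubled <<- doubled + 1L
      N[t, ] <- seg$N
      de <- sign(N[t, ] - N[t - 1, ])
      state <- which(MC_JOINT_EVENTS[, 1] == de[1] &
                       MC_JOINT_EVENTS[, 2] == de[2])
    }
    N
  })
  if (doubled > 0) {
    warning(doubled, " substep bins received more than one event in a ",
            "component; consider a smaller dt")
  }
  structure(list(trajectories = trajs, dt = config$dt, seed = config$seed,
                 mode = "memory_gillespie"),
            class = "trajectory_ensemble")
}

#' Build memory-conditioned Gillespie propensities from a multiplier set
#'
#' Maps gamma rate factors to propensities via `rate = gamma / dt`, and
#' multiplies each event's rate by the coupling gammas linking it to the
#' members of the previous joint event. Decrease gammas are already
#' per-particle in the discrete model (the N-fold path multiplicity supplies
#' the factor of N), so the per-particle death propensity is simply
#' `gamma_m / dt` and the total decay propensity `k_m * N` matches the
#' discrete rate `gamma_m * N / dt`.
#'
#' @param multipliers a [maxcal_multipliers].
#' @param dt substep duration in seconds.
#' @return list with `base` and `sets` suitable for [gillespie_memory]; the
#'   `base` set alone parameterizes [gillespie_markov].
#' @export
memory_rates_from_multipliers <- function(multipliers, dt) {
  g <- multiplier_gammas(multipliers)
  base <- list(k1p = g[["l1p"]] / dt,
               k1m = g[["l1m"]] / dt,
               k2p = g[["l2p"]] / dt,
               k2m = g[["l2m"]] / dt)
  members <- mc_joint_members()
  rate_names <- c("k1p", "k1m", "k2p", "k2m")  # aligned with 1p,1m,2p,2m
  sets <- lapply(1:9, function(s) {
    r <- base
    for (b in 1:4) {
      for (a in members[[s]]) {
        r[[rate_names[b]]] <- r[[rate_names[b]]] *
          g[[paste0("l", MC_PAIR_KEY[a, b])]]
      }
    }
    r
  })
  list(base = base, sets = sets)
}

#' Per-cell correlation between the two shape components
#'
#' Pearson correlation of N1 and N2 within each trajectory. The
#' population-level PCA construction makes the components uncorrelated
#' across cells; persistent single-cell anticorrelation is therefore a
#' dynamical signature, visible only at this per-cell level.
#'
#' @param ensemble a `trajectory_ensemble` (each trajectory >= 10 substeps).
#' @return numeric vector of per-cell correlations; trajectories where
#'   either component is constant are excluded (their count is reported in
#'   attribute `"n_excluded"`).
#' @export
percell_correlation <- function(ensemble) {
  if (!length(ensemble$trajectories)) stop("empty ensemble")
  r <- vapply(ensemble$trajectories, function(N) {
    if (nrow(N) < 10) return(NA_real_)
    if (sd(N[, 1]) == 0 || sd(N[, 2]) == 0) return(NA_real_)
    cor(N[, 1], N[, 2])
  }, 0)
  structure(r[!is.na(r)], n_excluded = sum(is.na(r)))
}
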