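# Sequential maximum-caliber sampler and Gillespie simulators.

test_that("the sampler is reproducible and respects state bounds", {
  m <- preset_multipliers("wt_like")
  cfg <- sim_config(n_cells = 3, n_substeps = 500, seed = 99)
  a <- simulate_maxcal(m, cfg)
  b <- simulate_maxcal(m, cfg)
  expect_identical(a$trajectories, b$trajectories)
  expect_length(a$trajectories, 3)
  allN <- do.call(rbind, a$trajectories)
  expect_true(all(allN >= 1))
  expect_true(all(vapply(a$trajectories, function(N) {
    all(abs(diff(N[, 1])) <= 1) && all(abs(diff(N[, 2])) <= 1)
  }, TRUE)))
  c2 <- simulate_maxcal(m, sim_config(n_cells = 3, n_substeps = 500,
                                      seed = 100))
  expect_false(identical(a$trajectories, c2$trajectories))
})

test_that("sampler one-step law matches the normalized path weights", {
  # without couplings the one-substep law per component is
  # P(+1) = gamma_p / (gamma_p + 1 + N gamma_m), and at the stationary
  # mean N = gamma_p / gamma_m the increase and decrease rates balance
  m <- maxcal_multipliers(c(l1p = log(0.3), l1m = log(0.3 / 40),
                            l2p = log(0.2), l2m = log(0.2 / 40)))
  cfg <- sim_config(n_cells = 1, n_substeps = 2e5, initial_N = c(40L, 40L),
                    seed = 101, mode = "uncorrelated")
  ens <- simulate_maxcal(m, cfg)
  ev <- ensemble_events(ens)[[1]]
  obs <- compute_observables(ev)
  p1 <- 0.3 / (0.3 + 1 + 40 * 0.3 / 40)   # 0.1875
  p2 <- 0.2 / (0.2 + 1 + 40 * 0.2 / 40)   # ~0.1429
  expect_equal(unname(obs$simple["1p"]), p1, tolerance = 0.05)
  expect_equal(unname(obs$simple["1m"]), unname(obs$simple["1p"]),
               tolerance = 0.05)
  expect_equal(unname(obs$simple["2p"]), p2, tolerance = 0.05)
})

test_that("uncorrelated mode yields a co-occurrence matrix near one", {
  m <- preset_multipliers("treated_like")
  ens <- simulate_maxcal(m, sim_config(n_cells = 4, n_substeps = 5e4,
                                       seed = 102, mode = "uncorrelated"))
  R <- cooccurrence_matrix(ensemble_events(ens))
  expect_true(all(abs(R - 1) < 0.2))
})

test_that("couplings shape the co-occurrence matrix as designed", {
  # wt_like enhances (1+,2-) and (1-,2+) and suppresses (1+,2+), (1-,2-)
  m <- preset_multipliers("wt_like")
  ens <- simulate_maxcal(m, sim_config(n_cells = 4, n_substeps = 5e4,
                                       seed = 103))
  R <- cooccurrence_matrix(ensemble_events(ens))
  expect_gt(R["1p", "2m"], 1.3)
  expect_gt(R["1m", "2p"], 1.3)
  expect_lt(R["1p", "2p"], 0.8)
  expect_lt(R["1m", "2m"], 0.8)
})

test_that("cross-couplings induce per-cell anticorrelation of the components", {
  m <- preset_multipliers("wt_like")
  ens <- simulate_maxcal(m, sim_config(n_cells = 40, n_substeps = 4000,
                                       seed = 104))
  r <- percell_correlation(ens)
  expect_lt(median(r), -0.05)
  mu <- preset_multipliers("treated_like")
  ensu <- simulate_maxcal(mu, sim_config(n_cells = 40, n_substeps = 4000,
                                         seed = 104, mode = "uncorrelated"))
  ru <- percell_correlation(ensu)
  expect_lt(abs(median(ru)), 0.15)
})

test_that("round trip: simulate from fitted multipliers, refit, recover", {
  truth <- preset_multipliers("wt_like")
  ens <- simulate_maxcal(truth, sim_config(n_cells = 2, n_substeps = 1e5,
                                           seed = 105))
  fit <- infer_multipliers(compute_observables(ensemble_events(ens)))
  expect_true(attr(fit, "converged"))
  expect_lt(max(abs(as.numeric(fit) - as.numeric(truth))), 0.1)
})

test_that("markov gillespie relaxes to the birth-death stationary mean", {
  rates <- list(k1p = 1.2, k1m = 1.2 / 30, k2p = 1.2, k2m = 1.2 / 30)
  cfg <- sim_config(n_cells = 2, n_substeps = 2e4, dt = 0.1875,
                    initial_N = c(30L, 30L), seed = 106,
                    mode = "markov_gillespie")
  ens <- gillespie_markov(rates, cfg)
  allN <- do.call(rbind, ens$trajectories)
  expect_equal(mean(allN[, 1]), 30, tolerance = 0.15 * 30)
  expect_true(all(allN >= 1))
})

test_that("markov gillespie produces no adjacent-step memory", {
  rates <- list(k1p = 0.8, k1m = 0.8 / 30, k2p = 0.8, k2m = 0.8 / 30)
  ens <- gillespie_markov(rates, sim_config(n_cells = 40, n_substeps = 3000,
                                            dt = 0.1875, seed = 107,
                                            mode = "markov_gillespie"))
  r <- percell_correlation(ens)
  expect_lt(abs(median(r)), 0.1)
})

test_that("memory gillespie with identical sets reduces to markov exactly", {
  rates <- list(k1p = 0.9, k1m = 0.9 / 25, k2p = 0.7, k2m = 0.7 / 25)
  cfg <- sim_config(n_cells = 2, n_substeps = 800, dt = 0.1875,
                    initial_N = c(25L, 25L), seed = 108,
                    mode = "memory_gillespie")
  mem <- gillespie_memory(list(base = rates, sets = rep(list(rates), 9)), cfg)
  cfg$mode <- "markov_gillespie"
  mk <- gillespie_markov(rates, cfg)
  expect_identical(mem$trajectories, mk$trajectories)
})

test_that("memory-conditioned rates implement the multiplier couplings", {
  m <- preset_multipliers("wt_like")
  rs <- memory_rates_from_multipliers(m, dt = 0.1875)
  expect_length(rs$sets, 9)
  g <- multiplier_gammas(m)
  expect_equal(rs$base$k1p, g[["l1p"]] / 0.1875)
  # state 9 of the joint grid is (e1 = +1, e2 = +1): the next 2- rate picks
  # up the coupling gammas for (1+,2-) and (2+,2-)
  expect_equal(rs$sets[[9]]$k2m,
               rs$base$k2m * g[["l12pm"]] * g[["l22pm"]])
  # the null state (e1 = 0, e2 = 0) is row 5: rates stay unconditional
  expect_equal(rs$sets[[5]], rs$base)
})

test_that("memory gillespie driven by wt couplings shows anticorrelation", {
  m <- preset_multipliers("wt_like")
  rs <- memory_rates_from_multipliers(m, dt = 0.1875)
  ens <- gillespie_memory(rs, sim_config(n_cells = 40, n_substeps = 3000,
                                         dt = 0.1875, seed = 109,
                                         mode = "memory_gillespie"))
  expect_lt(median(percell_correlation(ens)), -0.05)
})

test_that("simulator guards reject degenerate configurations", {
  expect_error(sim_config(n_substeps = 1), "n_substeps")
  m <- preset_multipliers("wt_like")
  expect_error(simulate_maxcal(m, sim_config(mode = "markov_gillespie")))
  expect_warning(
    gillespie_markov(list(k1p = 0, k1m = 0, k2p = 0, k2m = 0),
                     sim_config(n_cells = 1, n_substeps = 5, seed = 1,
                                mode = "markov_gillespie")),
    "frozen")
})
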