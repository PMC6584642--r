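# Partition function, enumeration, predicted observables and inference.

test_that("microtrajectory counts follow the combinatorial formulas", {
  # one substep: (N1 + 2)(N2 + 2), decay from N in N ways
  for (N1 in c(1, 3, 7)) for (N2 in c(1, 4)) {
    p1 <- enumerate_paths(N1, N2, horizon = 1)
    expect_equal(attr(p1, "n_paths"), (N1 + 2) * (N2 + 2))
    expect_lte(nrow(p1), 9)
  }
  # two substeps: (N1^2 + 3 N1 + 5)(N2^2 + 3 N2 + 5)
  for (N1 in 1:6) for (N2 in c(1, 2, 5)) {
    p2 <- enumerate_paths(N1, N2, horizon = 2)
    expect_equal(attr(p2, "n_paths"),
                 (N1^2 + 3 * N1 + 5) * (N2^2 + 3 * N2 + 5))
  }
  expect_error(enumerate_paths(2, 2, horizon = 3), "horizon")
})

test_that("closed-form one-component Q matches brute-force enumeration", {
  set.seed(41)
  for (N in c(1, 2, 5, 12)) {
    for (rep in 1:5) {
      g <- exp(runif(5, log(0.5), log(2)))
      names(g) <- c("p", "m", "pp", "pm", "mm")
      # silence component 2 in the oracle: gamma -> 0 keeps only its
      # double-null path, contributing a factor of 1
      lam <- setNames(rep(-600, 14), names(random_lambda()))
      lam[c("l1p", "l1m", "l11pp", "l11pm", "l11mm")] <-
        log(g[c("p", "m", "pp", "pm", "mm")])
      lam[paste0("l", c("22pp", "22pm", "22mm",
                        "12pp", "12pm", "12mp", "12mm"))] <- 0
      expect_equal(partition_function_1c(g, N)$Q, oracle_Q(lam, N, 1),
                   tolerance = 1e-12)
    }
  }
  # unit gammas count the paths
  expect_equal(partition_function_1c(
    c(p = 1, m = 1, pp = 1, pm = 1, mm = 1), 2)$Q, 15)
  expect_error(partition_function_1c(
    c(p = -1, m = 1, pp = 1, pm = 1, mm = 1), 2), "positive")
})

test_that("gamma-plus -> 0 limit of the closed form is the algebraic limit", {
  g <- c(p = 1e-300, m = 0.8, pp = 1.4, pm = 0.6, mm = 1.1)
  N <- 4
  expected <- N * g[["m"]] * (1 + (N - 1) * g[["m"]] * g[["mm"]]) +
    1 + N * g[["m"]]
  expect_equal(partition_function_1c(g, N)$Q, expected, tolerance = 1e-12)
})

test_that("two-component Q matches the independent path oracle", {
  set.seed(42)
  for (rep in 1:10) {
    lam <- random_lambda()
    N1 <- sample(1:8, 1); N2 <- sample(1:8, 1)
    expect_equal(partition_function_2c(lam, N1, N2)$Q,
                 oracle_Q(lam, N1, N2), tolerance = 1e-12)
  }
})

test_that("Q factorizes when the cross-component couplings are 1", {
  set.seed(43)
  lam <- random_lambda()
  lam[c("l12pp", "l12pm", "l12mp", "l12mm")] <- 0
  g <- exp(lam)
  q1 <- partition_function_1c(c(p = g[["l1p"]], m = g[["l1m"]],
                                pp = g[["l11pp"]], pm = g[["l11pm"]],
                                mm = g[["l11mm"]]), 5)$Q
  q2 <- partition_function_1c(c(p = g[["l2p"]], m = g[["l2m"]],
                                pp = g[["l22pp"]], pm = g[["l22pm"]],
                                mm = g[["l22mm"]]), 3)$Q
  expect_equal(partition_function_2c(lam, 5, 3)$Q, q1 * q2,
               tolerance = 1e-12)
  # unit weights count all joint paths
  expect_equal(partition_function_2c(maxcal_multipliers(), 2, 2)$Q, 225)
})

test_that("a single enhanced coupling adds exactly the oracle excess", {
  # gamma_12pm = 2, everything else 1, N1 = N2 = 2: the excess over the
  # 225 paths is sum over paths of mult * (2^c - 1), c = (1+,2-)-pair count
  lam <- setNames(numeric(14), names(random_lambda()))
  lam["l12pm"] <- log(2)
  excess <- sum(vapply(oracle_paths(2, 2), function(p) {
    p$mult * (2^p$counts[["l12pm"]] - 1)
  }, 0))
  expect_gt(excess, 0)
  expect_equal(partition_function_2c(lam, 2, 2)$Q, 225 + excess,
               tolerance = 1e-12)
})

test_that("predicted observables equal finite differences of log Q", {
  set.seed(44)
  for (rep in 1:5) {
    lam <- random_lambda()
    N1 <- sample(2:9, 1); N2 <- sample(2:9, 1)
    wm <- attr(predicted_observables(lam, N1, N2), "window_means")
    h <- 1e-6
    fd <- vapply(seq_along(lam), function(i) {
      lp <- lam; lm <- lam
      lp[i] <- lp[i] + h; lm[i] <- lm[i] - h
      (log(partition_function_2c(lp, N1, N2)$Q) -
         log(partition_function_2c(lm, N1, N2)$Q)) / (2 * h)
    }, 0)
    expect_lt(max(abs(wm - fd)), 1e-6)
  }
})

test_that("unit-weight predicted pair rates match the path-count fraction", {
  # one ++ path of weight 1 in component 1 out of 15, times any of the
  # N2 = 1 component-2 paths: <S11pp> = 1/15 per window
  obs <- predicted_observables(maxcal_multipliers(), 2, 1)
  expect_equal(unname(obs$correlated["11pp"]), 1 / 15, tolerance = 1e-12)
})

test_that("decay rates scale with N through the path multiplicities", {
  # symmetric gammas: decreases still outnumber increases N-fold
  lam <- setNames(numeric(14), names(random_lambda()))
  for (N in c(2, 6, 12)) {
    obs <- predicted_observables(lam, N, N)
    expect_gt(obs$simple[["1m"]], obs$simple[["1p"]])
    expect_equal(obs$simple[["1m"]] / obs$simple[["1p"]], N,
                 tolerance = 0.25 * N)  # multiplicity-driven, order N
  }
})

test_that("path probabilities are normalized", {
  set.seed(45)
  p <- path_probabilities(random_lambda(), 4, 7)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p >= 0))
})

test_that("inference inverts prediction on the feasible set", {
  truth <- preset_multipliers("wt_like")
  obs <- predicted_observables(truth, 30, 30)
  fit <- infer_multipliers(obs)
  expect_true(attr(fit, "converged"))
  expect_lt(max(abs(as.numeric(fit) - as.numeric(truth))), 1e-6)
  # also from a generic random multiplier set
  set.seed(46)
  lam <- random_lambda(0.4)
  fit2 <- infer_multipliers(predicted_observables(lam, 8, 5))
  expect_lt(max(abs(as.numeric(fit2) - as.numeric(lam))), 1e-6)
})

test_that("zero observed rates pin the multiplier at the floor", {
  truth <- preset_multipliers("treated_like")
  obs <- predicted_observables(truth, 30, 30)
  obs$correlated["12pp"] <- 0
  expect_warning(fit <- infer_multipliers(obs), "pinned")
  expect_equal(unname(fit["l12pp"]), -20)
})

test_that("an uncoupled event stream yields near-zero correlated multipliers", {
  truth <- preset_multipliers("treated_like")
  ens <- simulate_maxcal(truth, sim_config(n_cells = 1, n_substeps = 2e5,
                                           seed = 47))
  fit <- infer_multipliers(compute_observables(ensemble_events(ens)))
  corr <- as.numeric(fit)[5:14]
  expect_lt(max(abs(corr)), 0.15)
})

test_that("multiplier containers convert and report consistently", {
  m <- preset_multipliers("wt_like")
  expect_equal(unname(multiplier_gammas(m)), unname(exp(as.numeric(m))))
  expect_equal(unname(multiplier_log10(m)),
               unname(as.numeric(m) / log(10)))
  expect_error(maxcal_multipliers(c(bogus = 1)), "unknown multiplier")
})
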