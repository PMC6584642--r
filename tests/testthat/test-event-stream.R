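# Calibration, discretization, event extraction and observable rates.

test_that("substep calibration halves jumps until unit steps", {
  # pc1 jumps by 3.2 units between frames: k = 4 gives per-substep change
  # 0.8 < 1.5, so rounding moves the state by at most 1
  tr <- data.frame(cell_id = 1, frame = 1:6,
                   pc1 = seq(0, by = 3.2, length.out = 6),
                   pc2 = rep(0, 6))
  cfg <- calibrate_substeps(tr, unit = 1)
  expect_equal(cfg$substeps_per_frame, 4L)
  expect_equal(cfg$dt, 3 / 4)
  # default imaging cadence 3 s at k = 16 gives dt = 0.1875 s
  expect_equal(3 / 16, 0.1875)
})

test_that("pc2 rescaling equalizes per-frame increment scales", {
  set.seed(11)
  tr <- data.frame(cell_id = 1, frame = 1:400,
                   pc1 = cumsum(rnorm(400, sd = 1)),
                   pc2 = cumsum(rnorm(400, sd = 0.5)))
  cfg <- calibrate_substeps(tr, unit = 1)
  d1 <- diff(tr$pc1); d2 <- diff(tr$pc2)
  expect_equal(cfg$pc2_scale, sd(d1) / sd(d2))
  expect_equal(sd(d2 * cfg$pc2_scale), sd(d1))
})

test_that("a monotone ramp discretizes to the expected event pattern", {
  # pc1 rises 5 units over 8 substeps of one frame: round() lands on each
  # integer once, giving 5 increases and 3 null substeps (in some order)
  tr <- data.frame(cell_id = "c1", frame = 1:2, pc1 = c(0, 5), pc2 = c(0, 0))
  cfg <- calibrate_substeps(tr, unit = 1, ladder = 8L, n_offset = 30L)
  d <- discretize(tr, cfg)
  expect_s3_class(d, "discrete_trajectory")
  expect_equal(nrow(d$states), 9L)
  expect_equal(unname(d$states[1, "N1"]), 30L)
  expect_equal(unname(d$states[9, "N1"]), 35L)
  ev <- extract_events(d)
  expect_equal(sum(ev[, "e1"] == 1L), 5L)
  expect_equal(sum(ev[, "e1"] == 0L), 3L)
  expect_true(all(ev[, "e2"] == 0L))
  expect_equal(attr(ev, "cell_id"), "c1")
  expect_equal(attr(ev, "dt"), 3 / 8)
})

test_that("discretization refuses states below 1 and jumps above 1", {
  tr <- data.frame(cell_id = 1, frame = 1:3, pc1 = c(0, 1, 2), pc2 = 0)
  cfg <- calibrate_substeps(tr, unit = 1, ladder = 2L, n_offset = 30L)
  bad <- data.frame(cell_id = 1, frame = 1:3, pc1 = c(0, -40, -80), pc2 = 0)
  expect_error(discretize(bad, cfg), "")
  jumpy <- data.frame(cell_id = 1, frame = 1:3, pc1 = c(0, 10, 20), pc2 = 0)
  expect_error(discretize(jumpy, cfg), "")
  expect_error(extract_events(cbind(N1 = c(1L, 4L), N2 = c(1L, 1L))),
               "calibration")
})

test_that("event extraction covers all nine joint cases", {
  N1 <- cumsum(c(5L, 1L, 0L, -1L, 0L, 1L, -1L, 0L, 1L, -1L))
  N2 <- cumsum(c(5L, 1L, -1L, 0L, 1L, 0L, 1L, 0L, -1L, -1L))
  ev <- stream_from_states(N1, N2)
  joint <- paste(ev[, 1], ev[, 2])
  expect_equal(length(unique(joint)), 9L)
  expect_true(all(ev %in% -1:1))
})

test_that("simple rates are event frequencies per substep", {
  # 12 substeps: four 1p, two 1m, three 2m, rest null
  e1 <- c(1, 1, 0, -1, 1, 0, 0, -1, 1, 0, 0, 0)
  e2 <- c(0, -1, 0, 0, -1, 0, 0, 0, 0, -1, 0, 0)
  obs <- compute_observables(stream_from_events(e1, e2), mean_N = c(30, 30))
  expect_equal(unname(obs$simple["1p"]), 4 / 12)
  expect_equal(unname(obs$simple["1m"]), 2 / 12)
  expect_equal(unname(obs$simple["2p"]), 0)
  expect_equal(unname(obs$simple["2m"]), 3 / 12)
})

test_that("correlated rates pool ordered pairs per 2-substep window", {
  # strictly alternating (+,0), (-,0): every one of the 9 windows holds one
  # ordered 1p/1m pair -> 11pm rate 1; no same-sign component-1 pairs
  e1 <- rep(c(1, -1), 5)
  obs <- compute_observables(stream_from_events(e1), mean_N = c(30, 30))
  expect_equal(unname(obs$correlated["11pm"]), 1)
  expect_equal(unname(obs$correlated["11pp"]), 0)
  expect_equal(unname(obs$correlated["11mm"]), 0)
  # two consecutive full events (1-,2+) then (1-,2+) in one window:
  # 11mm = 1, 22pp = 1, and both cross orders of (1-,2+) -> 12mp = 2
  obs2 <- compute_observables(stream_from_events(c(-1, -1), c(1, 1)),
                              mean_N = c(30, 30))
  expect_equal(unname(obs2$correlated["11mm"]), 1)
  expect_equal(unname(obs2$correlated["22pp"]), 1)
  expect_equal(unname(obs2$correlated["12mp"]), 2)
  expect_equal(unname(obs2$correlated["12pm"]), 0)
})

test_that("order-reversal symmetry is built into the pooling", {
  a <- compute_observables(stream_from_events(c(1, 0), c(0, -1)),
                           mean_N = c(30, 30))  # 1+ then 2-
  b <- compute_observables(stream_from_events(c(0, 1), c(-1, 0)),
                           mean_N = c(30, 30))  # 2- then 1+
  expect_equal(a$correlated, b$correlated)
  expect_equal(unname(a$correlated["12pm"]), 1)
})

test_that("pooling across streams never opens a window at a boundary", {
  s1 <- stream_from_events(c(1), c(0))
  s2 <- stream_from_events(c(-1), c(0))
  obs <- compute_observables(list(s1, s2), mean_N = c(30, 30))
  # one event each, zero windows: correlated counts must all be 0
  expect_true(all(obs$correlated == 0))
  expect_equal(unname(obs$simple["1p"]), 0.5)
  joined <- compute_observables(stream_from_events(c(1, -1)),
                                mean_N = c(30, 30))
  expect_equal(unname(joined$correlated["11pm"]), 1)  # contrast
})

test_that("pooled observables equal weighted per-stream recombination", {
  set.seed(12)
  streams <- lapply(1:3, function(i) {
    stream_from_events(sample(-1:1, 40, replace = TRUE),
                       sample(-1:1, 40, replace = TRUE))
  })
  pooled <- compute_observables(streams, mean_N = c(30, 30))
  # recombine by hand: counts weighted by substeps / windows
  simple <- Reduce(`+`, lapply(streams, function(s)
    compute_observables(s, mean_N = c(30, 30))$simple * nrow(s))) / 120
  corr <- Reduce(`+`, lapply(streams, function(s)
    compute_observables(s, mean_N = c(30, 30))$correlated * (nrow(s) - 1))) /
    (3 * 39)
  expect_equal(pooled$simple, simple)
  expect_equal(pooled$correlated, corr)
  expect_equal(pooled$n_substeps, 120L)
})

test_that("trajectories_to_events runs the full discretization pipeline", {
  set.seed(13)
  tr <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(cell_id = i, frame = 1:50,
               pc1 = cumsum(rnorm(50, sd = 0.4)),
               pc2 = cumsum(rnorm(50, sd = 0.2)))
  }))
  res <- trajectories_to_events(tr, unit = 0.3)
  expect_length(res$streams, 3)
  expect_s3_class(res$config, "disc_config")
  n_sub <- (50 - 1) * res$config$substeps_per_frame + 1
  expect_equal(nrow(res$discrete[[1]]$states), n_sub)
  expect_equal(nrow(res$streams[[2]]), n_sub - 1)
  # frozen config reproduces the same streams
  res2 <- trajectories_to_events(tr, unit = 0.3, config = res$config)
  expect_equal(res2$streams, res$streams)
})
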