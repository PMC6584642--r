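# Independent oracles, kept deliberately naive: explicit nested loops and a
# literal pair-name table, sharing no code with the package internals.

# canonical correlated-observable name for the ordered pair of simple events
# (a at t, b at t+dt); a, b are strings "1p","1m","2p","2m"
oracle_pair_name <- local({
  tab <- c(
    "1p.1p" = "11pp", "1p.1m" = "11pm", "1m.1p" = "11pm", "1m.1m" = "11mm",
    "2p.2p" = "22pp", "2p.2m" = "22pm", "2m.2p" = "22pm", "2m.2m" = "22mm",
    "1p.2p" = "12pp", "2p.1p" = "12pp",
    "1p.2m" = "12pm", "2m.1p" = "12pm",
    "1m.2p" = "12mp", "2p.1m" = "12mp",
    "1m.2m" = "12mm", "2m.1m" = "12mm")
  function(a, b) unname(tab[paste(a, b, sep = ".")])
})

# brute-force list of all 2-substep paths with multiplicities and per-path
# observable counts; lambda is the named 14-vector
oracle_paths <- function(N1, N2) {
  ev_name <- function(e, comp) {
    if (e == 1) paste0(comp, "p") else if (e == -1) paste0(comp, "m") else NULL
  }
  out <- list()
  for (e11 in -1:1) for (e12 in -1:1) for (e21 in -1:1) for (e22 in -1:1) {
    mult <- (if (e11 == -1) N1 else 1) * (if (e12 == -1) N2 else 1) *
      (if (e21 == -1) N1 + e11 else 1) * (if (e22 == -1) N2 + e12 else 1)
    counts <- setNames(numeric(14), paste0("l", c(
      "1p", "1m", "2p", "2m",
      "11pp", "11pm", "11mm", "22pp", "22pm", "22mm",
      "12pp", "12pm", "12mp", "12mm")))
    step1 <- c(ev_name(e11, 1), ev_name(e12, 2))
    step2 <- c(ev_name(e21, 1), ev_name(e22, 2))
    for (a in c(step1, step2)) counts[paste0("l", a)] <-
        counts[paste0("l", a)] + 1
    for (a in step1) for (b in step2) {
      nm <- paste0("l", oracle_pair_name(a, b))
      counts[nm] <- counts[nm] + 1
    }
    out[[length(out) + 1]] <- list(mult = mult, counts = counts)
  }
  out
}

oracle_Q <- function(lambda, N1, N2) {
  sum(vapply(oracle_paths(N1, N2), function(p) {
    p$mult * exp(sum(lambda[names(p$counts)] * p$counts))
  }, 0))
}

# random full multiplier vector with moderate values
random_lambda <- function(scale = 0.5) {
  setNames(runif(14, -scale, scale), paste0("l", c(
    "1p", "1m", "2p", "2m",
    "11pp", "11pm", "11mm", "22pp", "22pm", "22mm",
    "12pp", "12pm", "12mp", "12mm")))
}

# dense analytic contour of r(theta) = base * (1 + a2 cos 2t + b3 sin 3t)
smooth_blob_contour <- function(n = 2000, base = 10, a2 = 0.3, b3 = 0.2) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- base * (1 + a2 * cos(2 * t) + b3 * sin(3 * t))
  cbind(x = r * cos(t), y = r * sin(t))
}

# event-stream object from an integer state matrix
stream_from_states <- function(N1, N2) {
  extract_events(cbind(N1 = as.integer(N1), N2 = as.integer(N2)))
}

# event-stream object directly from event columns in -1/0/1
stream_from_events <- function(e1, e2 = rep(0L, length(e1))) {
  structure(cbind(e1 = as.integer(e1), e2 = as.integer(e2)),
            class = c("event_stream", "matrix"))
}
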