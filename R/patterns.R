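# Long-horizon behavioral statistics: sliding-window pattern probabilities,
# run-length distributions, and Jensen-Shannon model-vs-data comparison.

# indicator vector of one event type ("1p","1m","2p","2m") in a stream
mc_type_indicator <- function(stream, event_type) {
  event_type <- match.arg(event_type, MC_SIMPLE_KEYS)
  comp <- MC_EV_COMP[match(event_type, MC_SIMPLE_KEYS)]
  sgn <- if (MC_EV_SIGN[match(event_type, MC_SIMPLE_KEYS)] == "p") 1L else -1L
  stream[, comp] == sgn
}

#' Probability of "N transitions in T time-steps" patterns
#'
#' Fraction of windows of `t_window` consecutive substeps containing at
#' least (default) or exactly `n_events` events of one type. Windows are
#' sliding by default; windows never span stream boundaries.
#'
#' @param stream an `event_stream` or list of event streams (pooled).
#' @param event_type one of `"1p"`, `"1m"`, `"2p"`, `"2m"`.
#' @param n_events pattern size N (1 <= N <= T).
#' @param t_window window length T in substeps.
#' @param windows `"sliding"` (every start position) or `"disjoint"`
#'   (non-overlapping windows).
#' @param count `"at_least"` (>= N events, the default) or `"exactly"`.
#' @return probability in `[0, 1]`.
#' @export
pattern_probability <- function(stream, event_type, n_events, t_window,
                                windows = c("sliding", "disjoint"),
                                count = c("at_least", "exactly")) {
  windows <- match.arg(windows); count <- match.arg(count)
  stopifnot(n_events >= 1, n_events <= t_window)
  streams <- if (inherits(stream, "event_stream")) list(stream) else stream
  hits <- 0; total <- 0
  for (s in streams) {
    n <- nrow(s)
    if (n < t_window) {
      stop("stream of length ", n, " shorter than window T = ", t_window)
    }
    v <- mc_type_indicator(s, event_type)
    cs <- c(0, cumsum(v))
    starts <- if (windows == "sliding") seq_len(n - t_window + 1)
              else seq(1, n - t_window + 1, by = t_window)
    wc <- cs[starts + t_window] - cs[starts]
    hits <- hits + if (count == "at_least") sum(wc >= n_events)
                   else sum(wc == n_events)
    total <- total + length(starts)
  }
  hits / total
}

#' Run-length distribution of a single transition type
#'
#' Probability of observing a maximal run of exactly r consecutive
#' occurrences of one event type, over all maximal runs, plus the survival
#' form P(run >= r).
#'
#' @inheritParams pattern_probability
#' @return data.frame with columns `length`, `p_exact`, `p_at_least`;
#'   empty (with a warning) if the event never occurs.
#' @export
run_length_distribution <- function(stream, event_type) {
  streams <- if (inherits(stream, "event_stream")) list(stream) else stream
  lens <- unlist(lapply(streams, function(s) {
    if (!nrow(s)) return(integer(0))
    r <- rle(mc_type_indicator(s, event_type))
    r$lengths[r$values]
  }))
  if (!length(lens)) {
    warning("event type never occurs; empty run-length distribution")
    return(data.frame(length = integer(0), p_exact = numeric(0),
                      p_at_least = numeric(0)))
  }
  tab <- tabulate(lens)
  p <- tab / sum(tab)
  data.frame(length = seq_along(p), p_exact = p,
             p_at_least = rev(cumsum(rev(p))))
}

#' Jensen-Shannon divergence between two discrete distributions
#'
#' `JSD(p, q) = KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2`, base-2
#' logarithms, so the value lies in `[0, 1]`.
#'
#' @param p,q non-negative vectors on the same support; renormalized (with a
#'   warning if the sum deviates from 1 by more than 1e-6).
#' @return divergence in `[0, 1]`.
#' @export
#' @examples
#' jensen_shannon(c(1, 0), c(0, 1))  # maximal, 1
jensen_shannon <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must share a support")
  if (any(p < 0) || any(q < 0)) stop("negative probabilities")
  if (sum(p) == 0 || sum(q) == 0) stop("zero-mass distribution")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    warning("renormalizing input distributions")
  }
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  kl(p, m) / 2 + kl(q, m) / 2
}

#' Default pattern grid
#'
#' Patterns of the form "N transitions in T time-steps" with T from 10 to 20
#' and N from T - 8 to T, for each of the four transition types.
#'
#' @param t_range window lengths T.
#' @param n_back how far N runs below T (N in `[T - n_back, T]`).
#' @return data.frame with columns `event_type`, `n_events`, `t_window`.
#' @export
pattern_grid <- function(t_range = 10:20, n_back = 8) {
  g <- do.call(rbind, lapply(t_range, function(t) {
    data.frame(n_events = max(t - n_back, 1):t, t_window = t)
  }))
  out <- do.call(rbind, lapply(MC_SIMPLE_KEYS, function(ty) {
    cbind(event_type = ty, g)
  }))
  rownames(out) <- NULL
  out
}

#' Compare pattern statistics of data against correlated and uncorrelated
#' models
#'
#' Evaluates the pattern grid on the data stream(s) and on event streams of
#' the two model ensembles, and summarizes each model's agreement with the
#' data by the Jensen-Shannon divergence between the normalized
#' pattern-probability vectors.
#'
#' @param data_stream an `event_stream` or list of streams.
#' @param correlated_ensemble,uncorrelated_ensemble `trajectory_ensemble`s
#'   (e.g. from [simulate_maxcal] in the two modes).
#' @param grid pattern grid, see [pattern_grid].
#' @param ... passed to [pattern_probability].
#' @return list with `table` (per-pattern probabilities: `p_data`, `p_corr`,
#'   `p_uncorr`) and `jsd` (named pair `correlated`, `uncorrelated`).
#' @export
compare_models <- function(data_stream, correlated_ensemble,
                           uncorrelated_ensemble, grid = pattern_grid(),
                           ...) {
  sc <- ensemble_events(correlated_ensemble)
  su <- ensemble_events(uncorrelated_ensemble)
  probs <- function(streams) {
    vapply(seq_len(nrow(grid)), function(i) {
      pattern_probability(streams, grid$event_type[i], grid$n_events[i],
                          grid$t_window[i], ...)
    }, 0)
  }
  tab <- cbind(grid,
               p_data = probs(data_stream),
               p_corr = probs(sc),
               p_uncorr = probs(su))
  norm <- function(x) if (sum(x) > 0) x / sum(x) else x
  pd <- tab$p_data; pc <- tab$p_corr; pu <- tab$p_uncorr
  if (sum(pd) == 0) stop("no patterns observed in the data stream")
  jsd <- c(correlated = jensen_shannon(norm(pd), norm(pc)),
           uncorrelated = jensen_shannon(norm(pd), norm(pu)))
  list(table = tab, jsd = jsd)
}
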