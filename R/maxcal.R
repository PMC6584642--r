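# Maximum-caliber core: microtrajectory enumeration over a 2-substep window,
# the dynamical partition function, predicted observables, and inference of
# the Lagrange multipliers from observed rates.
#
# Model: each shape component behaves like a particle number N. In one
# substep it may gain a particle (one way), lose a particle (first-order
# decay: N distinguishable ways) or stay. A path over two substeps is
# weighted by exp(sum_n lambda_n S_n) where the S_n count, per window, the
# simple events (0..2 each) and the canonical adjacent-step event pairs.

# ---- enumeration ----------------------------------------------------------

# all 81 joint 2-substep paths for fixed starting state (N1, N2):
# multiplicity vector and the 14-column count matrix S.
mc_path_table <- function(N1, N2) {
  ev <- c(-1L, 0L, 1L)
  g <- expand.grid(e11 = ev, e12 = ev, e21 = ev, e22 = ev,
                   KEEP.OUT.ATTRS = FALSE)
  n <- nrow(g)
  mult1 <- function(e, N) ifelse(e == -1L, N, 1)
  mult <- mult1(g$e11, N1) * mult1(g$e12, N2) *
    mult1(g$e21, N1 + g$e11) * mult1(g$e22, N2 + g$e12)

  S <- matrix(0, n, length(MC_MULTIPLIER_NAMES),
              dimnames = list(NULL, MC_MULTIPLIER_NAMES))
  S[, "l1p"] <- (g$e11 == 1L) + (g$e21 == 1L)
  S[, "l1m"] <- (g$e11 == -1L) + (g$e21 == -1L)
  S[, "l2p"] <- (g$e12 == 1L) + (g$e22 == 1L)
  S[, "l2m"] <- (g$e12 == -1L) + (g$e22 == -1L)

  # simple-event index (1..4) of each component's step event, NA if null
  idx <- function(e, comp) ifelse(e == 1L, 2L * (comp - 1L) + 1L,
                           ifelse(e == -1L, 2L * comp, NA_integer_))
  s1 <- cbind(idx(g$e11, 1L), idx(g$e12, 2L))  # events at t
  s2 <- cbind(idx(g$e21, 1L), idx(g$e22, 2L))  # events at t + dt
  for (i in 1:2) for (j in 1:2) {
    a <- s1[, i]; b <- s2[, j]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) {
      keys <- paste0("l", MC_PAIR_KEY[cbind(a[ok], b[ok])])
      rows <- which(ok)
      for (r in seq_along(rows)) S[rows[r], keys[r]] <- S[rows[r], keys[r]] + 1
    }
  }
  list(paths = g, mult = mult, S = S)
}

#' Enumerate microtrajectories of the two-component birth-death model
#'
#' Lists every microscopic path over one or two substeps starting from state
#' `(N1, N2)`. An increase of a component is a single microscopic event; a
#' decrease from state N is realizable in N distinguishable ways
#' (first-order decay), tracked in the `multiplicity` column. Over one
#' substep the total count is `(N1 + 2) * (N2 + 2)`; over two substeps it is
#' `(N1^2 + 3 N1 + 5) * (N2^2 + 3 N2 + 5)`.
#'
#' @param N1,N2 starting particle numbers of the two components (>= 1).
#' @param horizon number of substeps, 1 or 2.
#' @return data.frame with integer event columns in -1/0/1 (`step1_c1`,
#'   `step1_c2`, and for horizon 2 `step2_c1`, `step2_c2`) and
#'   `multiplicity`. Paths with zero multiplicity (a decay that no particle
#'   can realize) are dropped. Attribute `"n_paths"` holds the
#'   multiplicity-weighted path count.
#' @export
#' @examples
#' nrow(enumerate_paths(3, 1, horizon = 1))      # macroscopic cases
#' attr(enumerate_paths(2, 3, horizon = 2), "n_paths")  # 15 * 23
enumerate_paths <- function(N1, N2, horizon = 2) {
  stopifnot(N1 >= 1, N2 >= 1)
  if (!horizon %in% c(1, 2)) stop("horizon must be 1 or 2")
  ev <- c(-1L, 0L, 1L)
  if (horizon == 1) {
    g <- expand.grid(step1_c1 = ev, step1_c2 = ev, KEEP.OUT.ATTRS = FALSE)
    g$multiplicity <- ifelse(g$step1_c1 == -1L, N1, 1) *
      ifelse(g$step1_c2 == -1L, N2, 1)
  } else {
    tab <- mc_path_table(N1, N2)
    g <- data.frame(step1_c1 = tab$paths$e11, step1_c2 = tab$paths$e12,
                    step2_c1 = tab$paths$e21, step2_c2 = tab$paths$e22,
                    multiplicity = tab$mult)
  }
  g <- g[g$multiplicity > 0, , drop = FALSE]
  rownames(g) <- NULL
  attr(g, "n_paths") <- sum(g$multiplicity)
  g
}

# ---- partition functions --------------------------------------------------

#' One-component partition function over a 2-substep window (closed form)
#'
#' Closed-form dynamical partition function for a single shape component at
#' particle number N, with rate factors gamma = exp(lambda) for the five
#' one-component observables: increase (`p`), decrease (`m`), and the
#' adjacent-step couplings `pp`, `pm` (= `mp`) and `mm`:
#' \deqn{Q_N = \gamma^+[\gamma^+\gamma^{++} + 1 + (N+1)\gamma^-\gamma^{+-}]
#'       + N\gamma^-[\gamma^+\gamma^{+-} + 1 + (N-1)\gamma^-\gamma^{--}]
#'       + \gamma^+ + 1 + N\gamma^-.}
#' With all gammas equal to 1 this counts the `N^2 + 3N + 5` paths.
#'
#' @param gammas named numeric with entries `p`, `m`, `pp`, `pm`, `mm`, all
#'   positive.
#' @param N particle number, >= 1.
#' @return list with `Q` and `dlogQ`, the per-observable derivatives
#'   d log Q / d lambda (expected event counts per window).
#' @export
#' @examples
#' partition_function_1c(c(p = 1, m = 1, pp = 1, pm = 1, mm = 1), N = 2)$Q  # 15
partition_function_1c <- function(gammas, N) {
  need <- c("p", "m", "pp", "pm", "mm")
  stopifnot(all(need %in% names(gammas)), N >= 1)
  if (any(gammas[need] <= 0)) stop("all gammas must be positive")
  gp <- gammas[["p"]]; gm <- gammas[["m"]]
  gpp <- gammas[["pp"]]; gpm <- gammas[["pm"]]; gmm <- gammas[["mm"]]
  Q <- gp * (gp * gpp + 1 + (N + 1) * gm * gpm) +
    N * gm * (gp * gpm + 1 + (N - 1) * gm * gmm) +
    gp + 1 + N * gm
  # gamma dQ/dgamma / Q, written out from the closed form
  dp <- gp * (2 * gp * gpp + 2 + (2 * N + 1) * gm * gpm)
  dm <- gm * ((2 * N + 1) * gp * gpm + 2 * N + 2 * N * (N - 1) * gm * gmm)
  dpp <- gp * gp * gpp
  dpm <- (2 * N + 1) * gp * gm * gpm
  dmm <- N * (N - 1) * gm * gm * gmm
  list(Q = Q,
       dlogQ = c(p = dp, m = dm, pp = dpp, pm = dpm, mm = dmm) / Q)
}

#' Two-component partition function over a 2-substep window (enumeration)
#'
#' Evaluates the dynamical partition function of the full two-component
#' model, including the four cross-component couplings, by summing
#' `multiplicity * exp(sum_n lambda_n S_n)` over all enumerated paths. With
#' all cross-couplings at 1 it factorizes into the product of the two
#' one-component closed forms.
#'
#' @param multipliers a [maxcal_multipliers] object or named numeric vector
#'   of the 14 lambda values (natural-log scale).
#' @param N1,N2 starting particle numbers (>= 1).
#' @return list with `Q` and `dlogQ`, the named 14-vector of expected event
#'   (pair) counts per 2-substep window, d log Q / d lambda.
#' @export
partition_function_2c <- function(multipliers, N1, N2) {
  lambda <- as_lambda_vector(multipliers)
  stopifnot(N1 >= 1, N2 >= 1)
  tab <- mc_path_table(N1, N2)
  w <- tab$mult * exp(drop(tab$S %*% lambda))
  Q <- sum(w)
  dlogQ <- drop(crossprod(tab$S, w)) / Q
  list(Q = Q, dlogQ = dlogQ)
}

# coerce multiplier input to the canonical named 14-vector of lambdas
as_lambda_vector <- function(multipliers) {
  lambda <- unclass(multipliers)
  if (is.null(names(lambda)) && length(lambda) == 14) {
    names(lambda) <- MC_MULTIPLIER_NAMES
  }
  missing <- setdiff(MC_MULTIPLIER_NAMES, names(lambda))
  if (length(missing)) {
    stop("missing multipliers: ", paste(missing, collapse = ", "))
  }
  lambda[MC_MULTIPLIER_NAMES]
}

#' Construct a multiplier set
#'
#' @param lambda named numeric vector of the 14 Lagrange multipliers
#'   (natural-log scale; names `l1p`, `l1m`, `l2p`, `l2m` plus the 10
#'   correlated keys such as `l11pm`, `l12mp`). Missing names default to 0.
#' @param N particle-number pair at which the set was (or is to be) evaluated.
#' @return object of class `maxcal_multipliers`: the named lambda vector
#'   with attribute `N`. `exp(lambda)` are the gamma rate factors.
#' @export
#' @examples
#' m <- maxcal_multipliers(c(l1p = -1.9, l1m = -5.3, l2p = -1.9, l2m = -5.3))
#' multiplier_gammas(m)[1:4]
maxcal_multipliers <- function(lambda = NULL, N = c(30L, 30L)) {
  full <- setNames(numeric(14), MC_MULTIPLIER_NAMES)
  if (!is.null(lambda)) {
    bad <- setdiff(names(lambda), MC_MULTIPLIER_NAMES)
    if (length(bad)) stop("unknown multiplier names: ",
                          paste(bad, collapse = ", "))
    full[names(lambda)] <- lambda
  }
  structure(full, N = as.integer(round(N)), class = "maxcal_multipliers")
}

#' @rdname maxcal_multipliers
#' @param x a `maxcal_multipliers` object.
#' @export
multiplier_gammas <- function(x) exp(as_lambda_vector(x))

#' @export
print.maxcal_multipliers <- function(x, ...) {
  cat("maxcal multiplier set (lambda, natural log scale)\n")
  cat("  N =", paste(attr(x, "N"), collapse = ", "))
  if (!is.null(attr(x, "converged")))
    cat(";  converged:", attr(x, "converged"),
        " max residual:", format(attr(x, "max_residual"), digits = 3))
  cat("\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Report multipliers on the display scale log10(gamma)
#'
#' @param x a `maxcal_multipliers` object.
#' @return named numeric, `lambda / log(10)`.
#' @export
multiplier_log10 <- function(x) as_lambda_vector(x) / log(10)

# ---- observables ----------------------------------------------------------

#' Construct an observable set
#'
#' Simple rates are events per substep (in `[0, 1]`); correlated rates are
#' pooled adjacent-substep pair counts per 2-substep window (same-component
#' pairs at most 1, cross-component pairs at most 2 per window).
#'
#' @param simple named numeric of length 4 (`1p`,`1m`,`2p`,`2m`).
#' @param correlated named numeric of length 10 (canonical keys).
#' @param mean_N numeric pair, mean particle numbers.
#' @param n_substeps number of substeps the rates were estimated from.
#' @return object of class `observable_set`.
#' @export
observable_set <- function(simple, correlated, mean_N,
                           n_substeps = NA_integer_) {
  stopifnot(all(MC_SIMPLE_KEYS %in% names(simple)),
            all(MC_CORR_KEYS %in% names(correlated)))
  structure(list(simple = simple[MC_SIMPLE_KEYS],
                 correlated = correlated[MC_CORR_KEYS],
                 mean_N = mean_N, n_substeps = n_substeps),
            class = "observable_set")
}

#' @export
print.observable_set <- function(x, ...) {
  cat("observable set (", x$n_substeps, "substeps; mean N =",
      paste(round(x$mean_N, 2), collapse = ", "), ")\n")
  cat("simple rates per substep:\n"); print(round(x$simple, 5))
  cat("correlated rates per window:\n"); print(round(x$correlated, 5))
  invisible(x)
}

#' Model-predicted observables at a given multiplier set
#'
#' Expected simple rates (per substep) and correlated pair rates (per
#' 2-substep window) under the maximum-caliber path distribution at fixed
#' starting state, computed as gamma_n dQ/dgamma_n / Q from the path
#' enumeration. The full 14-vector of per-window means d log Q / d lambda is
#' attached as attribute `"window_means"` (simple entries there count both
#' substeps of the window, i.e. twice the per-substep rate).
#'
#' @inheritParams partition_function_2c
#' @return an [observable_set].
#' @export
predicted_observables <- function(multipliers, N1, N2) {
  pf <- partition_function_2c(multipliers, N1, N2)
  wm <- pf$dlogQ
  simple <- setNames(wm[paste0("l", MC_SIMPLE_KEYS)] / 2, MC_SIMPLE_KEYS)
  correlated <- setNames(wm[paste0("l", MC_CORR_KEYS)], MC_CORR_KEYS)
  out <- observable_set(simple, correlated, mean_N = c(N1, N2))
  attr(out, "window_means") <- wm
  attr(out, "Q") <- pf$Q
  out
}

# ---- inference ------------------------------------------------------------

#' Infer Lagrange multipliers from observed event rates
#'
#' Solves the moment-matching conditions `d log Q / d lambda_n = <S_n>` at
#' fixed particle numbers `N = round(mean_N)` by a damped Newton iteration.
#' The exact Jacobian is the covariance matrix of the path counts under the
#' current model. This is equivalent to maximum-likelihood fitting of the
#' exponential-family path distribution.
#'
#' Observables with observed rate 0 are infeasible for a finite multiplier;
#' their lambda is pinned at `lambda_floor` with a warning and excluded from
#' the root-finding.
#'
#' @param observed an [observable_set] (e.g. from [compute_observables]).
#' @param N optional integer pair overriding `round(observed$mean_N)`.
#' @param lambda_floor value assigned to multipliers of zero-rate
#'   observables.
#' @param tol convergence tolerance on the maximum absolute residual between
#'   predicted and observed rates.
#' @param max_iter maximum Newton iterations.
#' @return a [maxcal_multipliers] object with attributes `converged`,
#'   `max_residual`, `iterations` and `N`.
#' @export
infer_multipliers <- function(observed, N = NULL, lambda_floor = -20,
                              tol = 1e-8, max_iter = 200) {
  stopifnot(inherits(observed, "observable_set"))
  if (is.null(N)) N <- round(observed$mean_N)
  N <- as.integer(N)
  stopifnot(length(N) == 2, all(N >= 1))

  # per-window targets: simple events appear twice per 2-substep window
  target <- c(2 * observed$simple, observed$correlated)
  names(target) <- MC_MULTIPLIER_NAMES

  lambda <- setNames(numeric(14), MC_MULTIPLIER_NAMES)
  pinned <- target <= 0
  if (any(pinned)) {
    warning("observables with zero rate pinned at lambda_floor: ",
            paste(names(target)[pinned], collapse = ", "))
    lambda[pinned] <- lambda_floor
  }
  free <- !pinned
  # start near the uncorrelated solution: rate ~ gamma (increase) or
  # N * gamma (decrease), couplings 0
  start <- c(log(pmax(observed$simple, 1e-12)) -
               log(c(1, N[1], 1, N[2])), numeric(10))
  lambda[free] <- start[free]

  tab <- mc_path_table(N[1], N[2])
  S <- tab$S; mult <- tab$mult
  residual_at <- function(l) {
    w <- mult * exp(drop(S %*% l))
    Q <- sum(w)
    pred <- drop(crossprod(S, w)) / Q
    list(pred = pred, w = w, Q = Q, resid = target - pred)
  }

  st <- residual_at(lambda)
  it <- 0L
  while (max(abs(st$resid[free])) >= tol && it < max_iter) {
    it <- it + 1L
    # Jacobian d pred / d lambda = covariance of counts under the model
    p <- st$w / st$Q
    M <- S * p
    J <- crossprod(S, M) - tcrossprod(st$pred)
    Jf <- J[free, free, drop = FALSE]
    ridge <- 1e-12 * (1 + mean(diag(Jf)))
    step <- tryCatch(
      solve(Jf + diag(ridge, nrow(Jf)), st$resid[free]),
      error = function(e) stop("singular Jacobian during inference: ",
                               conditionMessage(e)))
    alpha <- 1
    repeat {
      cand <- lambda
      cand[free] <- lambda[free] + alpha * step
      st2 <- residual_at(cand)
      if (max(abs(st2$resid[free])) < max(abs(st$resid[free])) ||
          alpha < 1e-8) break
      alpha <- alpha / 2
    }
    lambda <- cand
    st <- st2
  }
  converged <- max(abs(st$resid[free])) < tol
  if (!converged) {
    warning("inference did not converge after ", it,
            " iterations; max residual ",
            format(max(abs(st$resid[free])), digits = 4))
  }
  out <- maxcal_multipliers(lambda, N = N)
  attr(out, "converged") <- converged
  attr(out, "max_residual") <- max(abs(st$resid[free]))
  attr(out, "iterations") <- it
  out
}

#' Path probabilities of the maximum-caliber model
#'
#' Normalized probability of every enumerated 2-substep path,
#' `p_j = multiplicity_j exp(sum_n lambda_n S_nj) / Q`.
#'
#' @inheritParams partition_function_2c
#' @return numeric vector summing to 1, aligned with the rows of
#'   `enumerate_paths(N1, N2, horizon = 2)` before zero-multiplicity paths
#'   are dropped (zero-multiplicity paths get probability 0).
#' @export
path_probabilities <- function(multipliers, N1, N2) {
  lambda <- as_lambda_vector(multipliers)
  tab <- mc_path_table(N1, N2)
  w <- tab$mult * exp(drop(tab$S %*% lambda))
  w / sum(w)
}
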