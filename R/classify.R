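# Behavioral-signature classification: bootstrap multiplier distributions
# per condition, Kolmogorov-Smirnov comparison, discriminative-multiplier
# selection, and group-voted kNN classification with cell-disjoint folds.

#' Bootstrap multiplier estimates for one condition
#'
#' Each replicate draws `ceiling(frac * n_cells)` cells with replacement,
#' pools their event streams, computes observables, and infers a multiplier
#' set. Replicates where inference fails are dropped (their count is
#' reported in attribute `"n_failed"`).
#'
#' @param trajectories list of `discrete_trajectory` objects (one per cell),
#'   or a `trajectory_ensemble`.
#' @param n_boot number of bootstrap replicates.
#' @param frac fraction of cells per replicate.
#' @param seed integer seed.
#' @param condition label stored with the result.
#' @return object of class `bootstrap_set`: list with `lambda` (matrix
#'   n_boot x 14), `condition`, `n_boot`, `frac`, `seed`.
#' @export
bootstrap_multipliers <- function(trajectories, n_boot = 100, frac = 0.2,
                                  seed = 1L, condition = "condition") {
  if (inherits(trajectories, "trajectory_ensemble")) {
    dt <- trajectories$dt
    trajectories <- lapply(trajectories$trajectories, function(N) {
      structure(list(states = N, dt = dt, cell_id = NA),
                class = "discrete_trajectory")
    })
  }
  n_cells <- length(trajectories)
  if (n_cells < 5) stop("need at least 5 cells to bootstrap")
  stopifnot(n_boot >= 1)
  set.seed(seed)
  streams <- lapply(trajectories, extract_events)
  m <- ceiling(frac * n_cells)
  draws <- matrix(sample.int(n_cells, n_boot * m, replace = TRUE),
                  nrow = n_boot)
  reps <- vector("list", n_boot)
  failed <- 0L
  for (b in seq_len(n_boot)) {
    obs <- compute_observables(streams[draws[b, ]])
    fit <- tryCatch(suppressWarnings(infer_multipliers(obs)),
                    error = function(e) NULL)
    if (is.null(fit) || !isTRUE(attr(fit, "converged"))) {
      failed <- failed + 1L
    } else {
      reps[[b]] <- as_lambda_vector(fit)
    }
  }
  reps <- reps[!vapply(reps, is.null, TRUE)]
  if (!length(reps)) stop("all bootstrap replicates failed inference")
  if (failed > 0) {
    warning(failed, " of ", n_boot, " bootstrap replicates dropped ",
            "(inference failure)")
  }
  structure(list(lambda = do.call(rbind, reps), condition = condition,
                 n_boot = n_boot, frac = frac, seed = seed),
            class = "bootstrap_set", n_failed = failed)
}

#' Kolmogorov-Smirnov comparison of two bootstrap multiplier distributions
#'
#' Two-sample KS test per multiplier.
#'
#' @param a,b `bootstrap_set` objects with >= 10 replicates each.
#' @param alpha significance level for the decision flag.
#' @return data.frame with one row per multiplier: `multiplier`,
#'   `statistic`, `p_value`, `significant`.
#' @export
compare_distributions <- function(a, b, alpha = 0.001) {
  stopifnot(inherits(a, "bootstrap_set"), inherits(b, "bootstrap_set"),
            nrow(a$lambda) >= 10, nrow(b$lambda) >= 10)
  res <- lapply(MC_MULTIPLIER_NAMES, function(nm) {
    ks <- suppressWarnings(ks.test(a$lambda[, nm], b$lambda[, nm]))
    data.frame(multiplier = nm, statistic = unname(ks$statistic),
               p_value = ks$p.value, significant = ks$p.value < alpha)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Select the multipliers that best separate two training conditions
#'
#' Separation score per multiplier: absolute difference of bootstrap means
#' divided by the pooled bootstrap standard deviation
#' `sqrt((var_a + var_b) / 2)`. Ties are broken by the fixed multiplier name
#' order. Apply to training folds only.
#'
#' @param train_a,train_b `bootstrap_set` objects from the training cells.
#' @param n_select number of multipliers to return (<= 14).
#' @return character vector of multiplier names, best first, with the scores
#'   as attribute `"score"`.
#' @export
select_discriminative_multipliers <- function(train_a, train_b,
                                              n_select = 2) {
  if (n_select > length(MC_MULTIPLIER_NAMES)) {
    stop("n_select exceeds the number of multipliers")
  }
  ma <- colMeans(train_a$lambda); mb <- colMeans(train_b$lambda)
  va <- apply(train_a$lambda, 2, var); vb <- apply(train_b$lambda, 2, var)
  pooled <- sqrt((va + vb) / 2)
  score <- abs(ma - mb) / pooled
  score[pooled == 0 & abs(ma - mb) == 0] <- 0
  score[pooled == 0 & abs(ma - mb) > 0] <- Inf
  if (all(score[is.finite(score)] == 0) && !any(is.infinite(score))) {
    warning("conditions are indistinguishable; selection is degenerate")
  }
  ord <- order(-score, match(names(score), MC_MULTIPLIER_NAMES))
  sel <- names(score)[ord][seq_len(n_select)]
  attr(sel, "score") <- score[sel]
  sel
}

# plain kNN with Euclidean distance; returns predicted label and the mean
# distance to the k nearest neighbors
knn_predict <- function(train_x, train_y, x, k) {
  d <- sqrt(colSums((t(train_x) - x)^2))
  nn <- order(d)[seq_len(k)]
  votes <- table(train_y[nn])
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1) {
    # tie between labels: pick the label with smaller mean neighbor distance
    md <- vapply(top, function(l) mean(d[nn][train_y[nn] == l]), 0)
    top <- top[which.min(md)]
  }
  list(label = top, mean_dist = mean(d[nn]))
}

#' Group-voted k-nearest-neighbor classification
#'
#' Draws `n_repeats` test samples of one (known) condition, classifies each
#' by kNN in the training features, and assigns the group the majority
#' label; vote ties are broken in favor of the label whose voting samples
#' had the smaller mean neighbor distance. Accuracy is estimated over
#' `n_trials` random groups per condition and per `n_repeats` value.
#'
#' @param train_x numeric matrix of training features (rows = samples).
#' @param train_y training labels (two classes).
#' @param test_x,test_y test features and labels; must come from cells/days
#'   disjoint from the training data.
#' @param k number of neighbors (must not exceed the training size).
#' @param n_repeats vector of group sizes.
#' @param n_trials voted groups drawn per condition and group size.
#' @param standardize center/scale features by training statistics before
#'   computing distances.
#' @param seed integer seed.
#' @return object of class `classification_result`: data.frame with columns
#'   `n_repeats`, `accuracy`.
#' @export
knn_vote_classify <- function(train_x, train_y, test_x, test_y, k = 5,
                              n_repeats = c(1, 3, 5, 9, 15), n_trials = 100,
                              standardize = TRUE, seed = 1L) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  if (k > nrow(train_x)) stop("k exceeds the training-set size")
  set.seed(seed)
  if (standardize) {
    mu <- colMeans(train_x)
    sdv <- apply(train_x, 2, sd); sdv[sdv == 0] <- 1
    train_x <- sweep(sweep(train_x, 2, mu), 2, sdv, "/")
    test_x <- sweep(sweep(test_x, 2, mu), 2, sdv, "/")
  }
  train_y <- as.character(train_y); test_y <- as.character(test_y)
  classes <- unique(test_y)
  acc <- vapply(n_repeats, function(m) {
    correct <- 0L; total <- 0L
    for (cl in classes) {
      pool <- which(test_y == cl)
      for (trial in seq_len(n_trials)) {
        take <- pool[sample.int(length(pool), min(m, length(pool)),
                                replace = length(pool) < m)]
        preds <- lapply(take, function(i)
          knn_predict(train_x, train_y, test_x[i, ], k))
        labs <- vapply(preds, `[[`, "", "label")
        votes <- table(labs)
        top <- names(votes)[votes == max(votes)]
        if (length(top) > 1) {
          md <- vapply(top, function(l)
            mean(vapply(preds[labs == l], `[[`, 0, "mean_dist")), 0)
          top <- top[which.min(md)]
        }
        correct <- correct + (top == cl)
        total <- total + 1L
      }
    }
    correct / total
  }, 0)
  structure(data.frame(n_repeats = n_repeats, accuracy = acc),
            class = c("classification_result", "data.frame"), k = k)
}

#' Cross-validated group-voted kNN over cell- or day-disjoint folds
#'
#' For each fold, samples whose cell belongs to the fold form the test set
#' and all other samples the training set; no cell's samples appear on both
#' sides (asserted). Folds containing a single class are skipped with a
#' warning.
#'
#' @param features numeric matrix, one row per sample.
#' @param labels condition label per sample.
#' @param cells cell (or day) identifier per sample; fold membership is at
#'   this granularity.
#' @param folds named vector mapping each cell to a fold id (>= 2 folds),
#'   or an unnamed per-sample fold vector (`length(labels)`); in the latter
#'   case the cell-disjointness of the folds is verified and violated splits
#'   raise an error.
#' @param ... passed to [knn_vote_classify].
#' @return list with `per_fold` (list of `classification_result`) and
#'   `mean_accuracy` (data.frame `n_repeats`, `accuracy` averaged over
#'   folds).
#' @export
cross_validate <- function(features, labels, cells, folds, ...) {
  features <- as.matrix(features)
  cells <- as.character(cells)
  if (is.null(names(folds))) {
    if (length(folds) != length(cells)) {
      stop("folds must be named by cell id or given per sample")
    }
    fold_of <- folds
  } else {
    fold_of <- folds[cells]
  }
  if (length(unique(fold_of)) < 2) stop("need at least 2 folds")
  results <- list()
  for (f in sort(unique(fold_of))) {
    test_i <- which(fold_of == f)
    train_i <- which(fold_of != f)
    if (length(intersect(cells[test_i], cells[train_i]))) {
      stop("train/test leakage: a cell appears in both splits")
    }
    if (length(unique(labels[test_i])) < 2 ||
        length(unique(labels[train_i])) < 2) {
      warning("fold ", f, " has a single class; skipped")
      next
    }
    results[[as.character(f)]] <- knn_vote_classify(
      features[train_i, , drop = FALSE], labels[train_i],
      features[test_i, , drop = FALSE], labels[test_i], ...)
  }
  if (!length(results)) stop("no usable folds")
  accs <- do.call(rbind, lapply(results, function(r) r$accuracy))
  list(per_fold = results,
       mean_accuracy = data.frame(n_repeats = results[[1]]$n_repeats,
                                  accuracy = colMeans(accs)))
}
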