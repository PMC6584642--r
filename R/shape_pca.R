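# Principal-component shape space over Fourier power spectra.

#' Fit the PCA shape space over a set of power spectra
#'
#' PCA on the covariance of the spectra (no per-feature standardization: all
#' 64 powers share units). Component signs follow a fixed convention — the
#' entry of largest magnitude in each component is positive — so repeated
#' fits and bootstrap comparisons are stable.
#'
#' @param spectra numeric matrix, one spectrum per row (>= 2 rows).
#' @param n_components maximum number of components to retain.
#' @return object of class `shape_space`: list with `mean`, `components`
#'   (orthonormal columns), `sdev`, `explained_fraction`.
#' @export
fit_shape_pca <- function(spectra, n_components = 3) {
  spectra <- as.matrix(spectra)
  if (nrow(spectra) < 2) stop("need at least 2 spectra")
  pc <- prcomp(spectra, center = TRUE, scale. = FALSE)
  keep <- pc$sdev > 1e-12 * max(pc$sdev, 1)
  if (!any(keep)) {
    warning("spectra have zero variance; no components")
    rot <- pc$rotation[, 0, drop = FALSE]
    sdev <- numeric(0)
  } else {
    n_keep <- min(n_components, sum(keep))
    if (n_keep < n_components) {
      warning("rank-deficient input: returning ", n_keep, " components")
    }
    rot <- pc$rotation[, seq_len(n_keep), drop = FALSE]
    sdev <- pc$sdev[seq_len(n_keep)]
    for (j in seq_len(ncol(rot))) {
      i <- which.max(abs(rot[, j]))
      if (rot[i, j] < 0) rot[, j] <- -rot[, j]
    }
  }
  total_var <- sum(pc$sdev^2)
  structure(list(mean = pc$center, components = rot, sdev = sdev,
                 explained_fraction = if (total_var > 0) sdev^2 / total_var
                                      else numeric(0)),
            class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  cat("shape space:", ncol(x$components), "components over",
      length(x$mean), "spectral features\n")
  if (length(x$explained_fraction)) {
    cat("explained variance fractions:",
        paste(round(x$explained_fraction, 3), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Project spectra into the shape space
#'
#' Scores are `(spectrum - mean) %*% component`. A model fitted on one
#' dataset may be applied to another (frozen basis), e.g. to place treated
#' and control cells in one shape space.
#'
#' @param spectra numeric matrix of spectra (rows) or a single spectrum.
#' @param model a `shape_space`.
#' @param n_components how many leading components to return.
#' @return numeric matrix of scores (columns `pc1`, `pc2`, ...).
#' @export
project_spectra <- function(spectra, model, n_components = 2) {
  stopifnot(inherits(model, "shape_space"))
  if (is.null(dim(spectra))) spectra <- matrix(spectra, nrow = 1)
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != length(model$mean)) {
    stop("spectrum length ", ncol(spectra), " does not match the model (",
         length(model$mean), ")")
  }
  if (n_components > ncol(model$components)) {
    stop("model holds only ", ncol(model$components), " components")
  }
  sc <- sweep(spectra, 2, model$mean) %*%
    model$components[, seq_len(n_components), drop = FALSE]
  colnames(sc) <- paste0("pc", seq_len(n_components))
  sc
}

#' Cumulative explained-variance table
#'
#' @param model a `shape_space`.
#' @return data.frame with `component`, `fraction`, `cumulative`.
#' @export
variance_report <- function(model) {
  stopifnot(inherits(model, "shape_space"))
  f <- model$explained_fraction
  data.frame(component = seq_along(f), fraction = f, cumulative = cumsum(f))
}

#' Build PC trajectories from per-frame spectra of tracked cells
#'
#' @param spectra matrix of spectra, one row per frame.
#' @param cell_id,frame vectors aligned with the rows.
#' @param model a fitted `shape_space`.
#' @param frame_interval_s seconds between frames.
#' @return data.frame with `cell_id`, `frame`, `time_s`, `pc1`, `pc2`
#'   (ordered by cell then frame).
#' @export
spectra_to_trajectories <- function(spectra, cell_id, frame, model,
                                    frame_interval_s = 3) {
  sc <- project_spectra(spectra, model, n_components = 2)
  out <- data.frame(cell_id = cell_id, frame = frame,
                    time_s = (frame - min(frame)) * frame_interval_s,
                    pc1 = sc[, 1], pc2 = sc[, 2])
  out[order(out$cell_id, out$frame), ]
}

#' Save / load a shape-space model as JSON
#'
#' @param model a `shape_space`.
#' @param path file path.
#' @return `read_shape_space` returns the restored `shape_space`.
#' @export
write_shape_space <- function(model, path) {
  jsonlite::write_json(list(mean = model$mean,
                            components = model$components,
                            sdev = model$sdev,
                            explained_fraction = model$explained_fraction),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_shape_space
#' @export
read_shape_space <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = as.numeric(o$mean),
                 components = as.matrix(o$components),
                 sdev = as.numeric(o$sdev),
                 explained_fraction = as.numeric(o$explained_fraction)),
            class = "shape_space")
}
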