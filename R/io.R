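# File formats: CSV for spectra, contours, trajectories and event streams;
# JSON for observable sets and multiplier sets; TIFF/PNG mask movies via the
# optional tiff/png packages.

#' Read and write PC trajectories (CSV: cell_id, frame, time_s, pc1, pc2)
#'
#' @param trajectories data.frame of trajectories.
#' @param path file path.
#' @export
write_trajectories <- function(trajectories, path) {
  write.csv(trajectories, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  tr <- read.csv(path)
  need <- c("cell_id", "frame", "pc1", "pc2")
  if (!all(need %in% names(tr))) {
    stop("trajectory CSV must have columns ", paste(need, collapse = ", "))
  }
  tr
}

#' Read pre-extracted contours (CSV: cell_id, frame, vertex_index, x, y)
#'
#' @param path file path.
#' @return nested list: per cell, per frame, a two-column coordinate matrix.
#' @export
read_contours <- function(path) {
  d <- read.csv(path)
  need <- c("cell_id", "frame", "vertex_index", "x", "y")
  if (!all(need %in% names(d))) {
    stop("contour CSV must have columns ", paste(need, collapse = ", "))
  }
  lapply(split(d, d$cell_id), function(dc) {
    lapply(split(dc, dc$frame), function(df) {
      df <- df[order(df$vertex_index), ]
      as.matrix(df[, c("x", "y")])
    })
  })
}

#' Write spectra (CSV: cell_id, frame, p0..p63)
#'
#' @param spectra matrix of spectra (64 columns).
#' @param cell_id,frame vectors aligned with rows.
#' @param path file path.
#' @export
write_spectra <- function(spectra, cell_id, frame, path) {
  d <- data.frame(cell_id = cell_id, frame = frame)
  sp <- as.data.frame(as.matrix(spectra))
  names(sp) <- paste0("p", seq_len(ncol(sp)) - 1)
  write.csv(cbind(d, sp), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  d <- read.csv(path)
  pcols <- grep("^p[0-9]+$", names(d))
  list(spectra = as.matrix(d[, pcols]), cell_id = d$cell_id,
       frame = d$frame)
}

#' Write / read an event stream collection (CSV: cell_id, substep, e1, e2)
#'
#' Events are stored as "+", "0", "-".
#'
#' @param streams list of `event_stream` objects.
#' @param path file path.
#' @export
write_event_streams <- function(streams, path) {
  sym <- c(`-1` = "-", `0` = "0", `1` = "+")
  rows <- lapply(seq_along(streams), function(i) {
    s <- streams[[i]]
    id <- attr(s, "cell_id"); if (is.null(id) || is.na(id)) id <- i
    data.frame(cell_id = id, substep = seq_len(nrow(s)),
               e1 = sym[as.character(s[, 1])],
               e2 = sym[as.character(s[, 2])])
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_streams
#' @export
read_event_streams <- function(path) {
  d <- read.csv(path, colClasses = c(e1 = "character", e2 = "character"))
  num <- c(`-` = -1L, `0` = 0L, `+` = 1L)
  lapply(split(d, d$cell_id), function(dc) {
    dc <- dc[order(dc$substep), ]
    structure(cbind(e1 = num[dc$e1], e2 = num[dc$e2]),
              cell_id = dc$cell_id[1], class = c("event_stream", "matrix"))
  })
}

#' Write / read an observable set as JSON
#'
#' @param observed an [observable_set].
#' @param path file path.
#' @export
write_observables <- function(observed, path) {
  jsonlite::write_json(list(simple = as.list(observed$simple),
                            correlated = as.list(observed$correlated),
                            mean_N = observed$mean_N,
                            n_substeps = observed$n_substeps),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_observables
#' @export
read_observables <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(o$simple) || is.null(o$correlated)) {
    stop("malformed observable-set JSON: ", path)
  }
  observable_set(unlist(o$simple), unlist(o$correlated),
                 mean_N = as.numeric(o$mean_N),
                 n_substeps = o$n_substeps)
}

#' Write / read a multiplier set as JSON
#'
#' @param multipliers a [maxcal_multipliers].
#' @param path file path.
#' @export
write_multipliers <- function(multipliers, path) {
  jsonlite::write_json(list(lambda = as.list(as_lambda_vector(multipliers)),
                            N = attr(multipliers, "N"),
                            converged = attr(multipliers, "converged"),
                            max_residual = attr(multipliers, "max_residual")),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_multipliers
#' @export
read_multipliers <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(o$lambda)) stop("malformed multiplier JSON: ", path)
  m <- maxcal_multipliers(unlist(o$lambda),
                          N = if (is.null(o$N)) c(30L, 30L) else o$N)
  attr(m, "converged") <- o$converged
  attr(m, "max_residual") <- o$max_residual
  m
}

#' Write a trajectory ensemble (CSV: cell_id, substep, N1, N2)
#'
#' The seed and mode are recorded in comment lines at the top of the file.
#'
#' @param ensemble a `trajectory_ensemble`.
#' @param path file path.
#' @export
write_ensemble <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# seed: ", ensemble$seed),
               paste0("# mode: ", ensemble$mode),
               paste0("# dt: ", ensemble$dt)), con)
  d <- do.call(rbind, lapply(seq_along(ensemble$trajectories), function(i) {
    N <- ensemble$trajectories[[i]]
    data.frame(cell_id = i, substep = seq_len(nrow(N)),
               N1 = N[, 1], N2 = N[, 2])
  }))
  write.csv(d, con, row.names = FALSE)
  invisible(path)
}

#' Read a mask movie from a multi-page TIFF or a directory of PNG frames
#'
#' Requires the optional `tiff` / `png` packages.
#'
#' @param path TIFF file or directory of PNG files (sorted by name).
#' @return list of grayscale matrices.
#' @export
read_mask_stack <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop("no PNG frames in ", path)
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG frames requires the 'png' package")
    }
    lapply(files, function(f) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 3) img <- img[, , 1]
      img
    })
  } else {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF stacks requires the 'tiff' package")
    }
    frames <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(frames)) frames <- list(frames)
    lapply(frames, function(img) {
      if (length(dim(img)) == 3) img[, , 1] else img
    })
  }
}
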