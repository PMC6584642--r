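# Conversion of grayscale frames / binary masks into rotation- and
# flip-invariant Fourier power-spectrum shape descriptors:
# mask -> centroid-referenced contour -> 64 equal-arc-length complex points
# -> FFT power spectrum.

#' Extract a single-cell binary mask from a grayscale frame
#'
#' Thresholds the frame (Otsu's method by default), applies binary closing
#' and hole filling, and keeps the largest connected foreground component.
#' Frames that produce no foreground are rejected with a diagnostic rather
#' than an error, so a movie run can continue past bad frames.
#'
#' @param image_frame numeric matrix of intensities in `[0, 1]` (values
#'   outside are rescaled).
#' @param threshold intensity threshold; `NULL` uses Otsu's method.
#' @param closing_radius radius of the disc brush for binary closing
#'   (0 disables).
#' @param min_area reject masks smaller than this many pixels.
#' @param invert set `TRUE` when cells are darker than the background.
#' @return list of class `mask_frame` with `mask` (logical matrix), `ok`
#'   (logical), and `reason` (`NA` or the rejection diagnostic).
#' @export
extract_mask <- function(image_frame, threshold = NULL, closing_radius = 2,
                         min_area = 9, invert = FALSE) {
  img <- as.matrix(image_frame)
  if (length(unique(as.vector(img))) < 2) {
    return(structure(list(mask = NULL, ok = FALSE,
                          reason = "frame has a single intensity level"),
                     class = "mask_frame"))
  }
  rng <- range(img)
  img <- (img - rng[1]) / diff(rng)
  if (invert) img <- 1 - img
  if (is.null(threshold)) threshold <- EBImage::otsu(EBImage::Image(img))
  bw <- EBImage::Image(img > threshold)
  if (closing_radius > 0) {
    brush <- EBImage::makeBrush(2 * closing_radius + 1, shape = "disc")
    bw <- EBImage::closing(bw, brush)
  }
  bw <- EBImage::fillHull(bw)
  lab <- EBImage::bwlabel(bw)
  sizes <- tabulate(as.integer(EBImage::imageData(lab)))
  if (!length(sizes) || max(sizes) < min_area) {
    return(structure(list(mask = NULL, ok = FALSE,
                          reason = "empty or sub-minimal mask after preprocessing"),
                     class = "mask_frame"))
  }
  keep <- which.max(sizes)
  mask <- EBImage::imageData(lab) == keep
  structure(list(mask = mask, ok = TRUE, reason = NA_character_),
            class = "mask_frame")
}

#' Trace the centroid-referenced boundary of a binary mask
#'
#' Returns the ordered closed boundary of the (single) foreground component,
#' traversed counter-clockwise, starting at the boundary pixel with maximal
#' x (ties: maximal y), with the boundary centroid subtracted. The power
#' spectrum downstream removes any residual dependence on these
#' conventions; fixing them makes runs deterministic.
#'
#' @param mask logical matrix (or a `mask_frame`).
#' @return numeric matrix with columns `x`, `y` (class `cell_contour`), mean
#'   approximately (0, 0).
#' @export
trace_contour <- function(mask) {
  if (inherits(mask, "mask_frame")) {
    if (!isTRUE(mask$ok)) stop("cannot trace a rejected frame: ", mask$reason)
    mask <- mask$mask
  }
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  if (!length(oc)) stop("mask has no traceable boundary")
  pts <- oc[[which.max(vapply(oc, nrow, 0L))]] * 1.0
  if (nrow(pts) < 3) stop("boundary thinner than one pixel; frame rejected")
  colnames(pts) <- c("x", "y")
  # counter-clockwise orientation by signed area
  n <- nrow(pts); nxt <- c(2:n, 1)
  area2 <- sum(pts[, 1] * pts[nxt, 2] - pts[nxt, 1] * pts[, 2])
  if (area2 < 0) pts <- pts[n:1, , drop = FALSE]
  # canonical start: maximal x, ties by maximal y
  start <- which(pts[, 1] == max(pts[, 1]))
  start <- start[which.max(pts[start, 2])]
  if (start > 1) pts <- pts[c(start:n, 1:(start - 1)), , drop = FALSE]
  pts <- sweep(pts, 2, colMeans(pts))
  structure(pts, class = c("cell_contour", class(pts)))
}

#' Resample a contour to 64 points equally spaced in arc length
#'
#' Piecewise-linear interpolation along the closed boundary; the 64 samples
#' start at the contour's first vertex and are spaced `perimeter / 64`
#' apart. Points are encoded as complex numbers x + iy and re-centered so
#' they sum to zero.
#'
#' @param contour numeric matrix with columns x, y (>= 3 points).
#' @param n number of samples (64 for the standard descriptor).
#' @return complex vector of length `n` (class `complex_boundary`).
#' @export
resample_to_64 <- function(contour, n = 64) {
  pts <- unclass(contour)
  if (nrow(pts) < 3) stop("contour needs at least 3 points")
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L <= 0) stop("zero-perimeter contour")
  target <- (seq_len(n) - 1) / n * L
  x <- approx(s, closed[, 1], xout = target)$y
  y <- approx(s, closed[, 2], xout = target)$y
  z <- complex(real = x, imaginary = y)
  z <- z - mean(z)
  structure(z, class = "complex_boundary")
}

#' Fourier power spectrum of a complex boundary
#'
#' FFT of the 64 complex boundary points, returned as the 64 non-negative
#' powers `P(f) = |s(f)|^2`. Rotating the cell multiplies every coefficient
#' by a unit phase, and cyclic shifts of the starting point only add a
#' phase ramp, so the power spectrum is invariant to both. Traversal
#' orientation is canonicalized internally (reversed if the 64-gon is
#' clockwise), which makes the spectrum exactly invariant under mirror
#' flips as well.
#'
#' @param boundary complex vector of length 64 (a `complex_boundary`).
#' @param normalize divide by total power for a scale-invariant descriptor
#'   (off by default: spectra retain cell-size information).
#' @return numeric vector of 64 non-negative values (class
#'   `shape_spectrum`).
#' @export
power_spectrum <- function(boundary, normalize = FALSE) {
  z <- unclass(boundary)
  if (length(z) != 64) stop("boundary must have exactly 64 points")
  n <- length(z); nxt <- c(2:n, 1)
  area2 <- sum(Re(z) * Im(z[nxt]) - Re(z[nxt]) * Im(z))
  if (area2 < 0) z <- rev(z)
  p <- Mod(fft(z))^2
  if (normalize) {
    tot <- sum(p)
    if (tot > 0) p <- p / tot
  }
  structure(p, class = "shape_spectrum")
}

#' Reconstruct boundary points from a truncated Fourier expansion
#'
#' Inverse transform keeping the `n_components` largest-frequency-magnitude
#' coefficients closest to zero frequency (i.e. the lowest harmonics). With
#' all 64 components the original points are recovered to machine
#' precision; reconstruction error decreases monotonically as components
#' are added.
#'
#' @param boundary complex vector of length 64.
#' @param n_components number of Fourier components to keep (1..64).
#' @return complex vector of 64 reconstructed points.
#' @export
reconstruct_boundary <- function(boundary, n_components = 64) {
  z <- unclass(boundary)
  stopifnot(length(z) == 64, n_components >= 1, n_components <= 64)
  co <- fft(z)
  # frequency order 0, 1, -1, 2, -2, ... for truncation
  freqs <- c(0:31, -32:-1)
  keep_order <- order(abs(freqs), -sign(freqs))
  keep <- keep_order[seq_len(n_components)]
  co[setdiff(seq_along(co), keep)] <- 0
  fft(co, inverse = TRUE) / length(co)
}

#' Full descriptor pipeline for one mask
#'
#' @param mask logical matrix or `mask_frame`.
#' @param normalize passed to [power_spectrum].
#' @return a `shape_spectrum`, or `NULL` (with the diagnostic as a message)
#'   if the frame was rejected.
#' @export
mask_to_spectrum <- function(mask, normalize = FALSE) {
  if (inherits(mask, "mask_frame") && !isTRUE(mask$ok)) {
    message("frame rejected: ", mask$reason)
    return(NULL)
  }
  power_spectrum(resample_to_64(trace_contour(mask)), normalize = normalize)
}

#' Spectra for a whole mask movie, with overlap screening
#'
#' Applies [extract_mask] and the descriptor pipeline to each frame of a
#' grayscale movie. Rejected frames are skipped and reported.
#'
#' @param frames list of grayscale matrices.
#' @param ... passed to [extract_mask].
#' @return matrix of spectra (rows = retained frames, 64 columns) with
#'   attribute `"frame_index"` giving the source frame of each row and
#'   `"rejected"` the indices of rejected frames.
#' @export
movie_to_spectra <- function(frames, ...) {
  specs <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    mf <- extract_mask(frames[[i]], ...)
    if (isTRUE(mf$ok)) specs[[i]] <- as.numeric(mask_to_spectrum(mf))
  }
  ok <- !vapply(specs, is.null, TRUE)
  out <- do.call(rbind, specs[ok])
  attr(out, "frame_index") <- which(ok)
  attr(out, "rejected") <- which(!ok)
  out
}
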