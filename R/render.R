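#' Render fluorescent spots into a synthetic camera stack
#'
#' Draws each emitter as an integrated 2-D Gaussian point-spread function on
#' the camera pixel grid (160 nm/pixel by default), applies Poisson shot
#' noise plus Gaussian read noise, and returns the stack together with the
#' ground-truth table mapping emitters to frames.
#'
#' @param positions Data frame with columns `frame` (0-based), `id`, `x`,
#'   `y` (nm). One row per emitter per frame.
#' @param fov Field of view in pixels, `c(nx, ny)`.
#' @param pixel_nm Pixel size, nm.
#' @param psf_sd Point-spread-function standard deviation, nm.
#' @param photons Expected photons per emitter per frame.
#' @param background Expected background photons per pixel.
#' @param read_noise Gaussian read noise (counts rms).
#' @param seed Integer seed (NULL = use current RNG state).
#' @return Object of class `fg_stack`: `stack` (array ny x nx x nframes),
#'   `truth`, `pixel_nm`, `psf_sd`.
#' @export
render_frames <- function(positions, fov = c(96, 96), pixel_nm = 160,
                          psf_sd = 120, photons = 2000, background = 5,
                          read_noise = 2, seed = NULL) {
  stopifnot(all(c("frame", "id", "x", "y") %in% names(positions)))
  if (!is.null(seed)) set.seed(seed)
  nx <- fov[1]; ny <- fov[2]
  frames <- sort(unique(positions$frame))
  nf <- length(frames)
  stack <- array(0, dim = c(ny, nx, nf))
  s_px <- psf_sd / pixel_nm
  out_of_field <- FALSE
  for (fi in seq_len(nf)) {
    img <- matrix(background, ny, nx)
    p <- positions[positions$frame == frames[fi], , drop = FALSE]
    if (photons > 0 && nrow(p)) {
      for (k in seq_len(nrow(p))) {
        cx <- p$x[k] / pixel_nm; cy <- p$y[k] / pixel_nm
        if (cx < 0 || cx > nx || cy < 0 || cy > ny) {
          out_of_field <- TRUE
          cx <- min(max(cx, 0), nx); cy <- min(max(cy, 0), ny)
        }
        r <- ceiling(4 * s_px)
        xs <- max(1, floor(cx) - r):min(nx, ceiling(cx) + r)
        ys <- max(1, floor(cy) - r):min(ny, ceiling(cy) + r)
        # integrated Gaussian over pixel areas (pixel i covers [i-1, i])
        gx <- stats::pnorm(xs, cx, s_px) - stats::pnorm(xs - 1, cx, s_px)
        gy <- stats::pnorm(ys, cy, s_px) - stats::pnorm(ys - 1, cy, s_px)
        img[ys, xs] <- img[ys, xs] + photons * outer(gy, gx)
      }
    }
    noisy <- stats::rpois(length(img), img) +
      stats::rnorm(length(img), 0, read_noise)
    stack[, , fi] <- matrix(noisy, ny, nx)
  }
  if (out_of_field) warning("some emitter positions fell outside the field and were clipped")
  structure(list(stack = stack, truth = positions, pixel_nm = pixel_nm,
                 psf_sd = psf_sd, frames = frames), class = "fg_stack")
}

#' Render a textured gliding microtubule stack
#'
#' Renders the microtubule channel: a line of emitters with a fixed axial
#' intensity texture rigidly translating at the given velocity. The texture
#' provides the kymograph features whose slopes encode the velocity.
#'
#' @param length_um Microtubule length, um.
#' @param velocity Gliding speed, nm/s; either a single value or a per-frame
#'   vector.
#' @param n_frames Number of frames.
#' @param frame_interval Frame interval, s.
#' @param y_nm Lateral position of the (horizontal) microtubule, nm.
#' @param x0_nm Initial position of the trailing end, nm.
#' @param fov,pixel_nm,psf_sd,photons,background,read_noise,seed As in
#'   [render_frames()]; `photons` scales the per-segment intensity.
#' @param texture_cv Coefficient of variation of the axial texture.
#' @return An `fg_stack`; `truth` holds the trailing-end position per frame,
#'   and the rigid texture is stored as attribute `texture`.
#' @export
render_microtubule <- function(length_um = 6, velocity = 800, n_frames = 50,
                               frame_interval = 0.2, y_nm = NULL, x0_nm = 500,
                               fov = c(96, 32), pixel_nm = 160, psf_sd = 120,
                               photons = 400, background = 5, read_noise = 2,
                               texture_cv = 0.5, seed = 1) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(y_nm)) y_nm <- fov[2] * pixel_nm / 2
  v <- rep_len(velocity, n_frames)
  Xs <- x0_nm + c(0, cumsum(v[-n_frames]) * frame_interval)
  seg <- 80  # emitter spacing along the lattice, nm
  s_axis <- seq(0, length_um * 1000, by = seg)
  texture <- pmax(stats::rnorm(length(s_axis), 1, texture_cv), 0.05)
  nx <- fov[1]; ny <- fov[2]
  stack <- array(0, dim = c(ny, nx, n_frames))
  s_px <- psf_sd / pixel_nm
  r <- ceiling(4 * s_px)
  cy <- y_nm / pixel_nm
  ys <- max(1, floor(cy) - r):min(ny, ceiling(cy) + r)
  gy <- stats::pnorm(ys, cy, s_px) - stats::pnorm(ys - 1, cy, s_px)
  for (fi in seq_len(n_frames)) {
    img <- matrix(background, ny, nx)
    cxs <- (Xs[fi] + s_axis) / pixel_nm
    keep <- cxs > -r & cxs < nx + r
    for (k in which(keep)) {
      cx <- cxs[k]
      xs <- max(1, floor(cx) - r):min(nx, ceiling(cx) + r)
      gx <- stats::pnorm(xs, cx, s_px) - stats::pnorm(xs - 1, cx, s_px)
      img[ys, xs] <- img[ys, xs] + photons * texture[k] * outer(gy, gx)
    }
    noisy <- stats::rpois(length(img), img) +
      stats::rnorm(length(img), 0, read_noise)
    stack[, , fi] <- matrix(noisy, ny, nx)
  }
  truth <- data.frame(frame = seq_len(n_frames) - 1L,
                      time = (seq_len(n_frames) - 1L) * frame_interval,
                      position = Xs, velocity = v)
  out <- structure(list(stack = stack, truth = truth, pixel_nm = pixel_nm,
                        psf_sd = psf_sd, frames = truth$frame,
                        y_nm = y_nm), class = "fg_stack")
  attr(out, "texture") <- texture
  out
}

#' Write an image stack as multi-page TIFF
#'
#' @param stack 3-D array (or `fg_stack`).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  if (inherits(stack, "fg_stack")) stack <- stack$stack
  mx <- max(stack, 1)
  imgs <- lapply(seq_len(dim(stack)[3]),
                 function(i) pmin(pmax(stack[, , i] / mx, 0), 1))
  tiff::writeTIFF(imgs, path, bits.per.sample = 16)
  invisible(path)
}
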