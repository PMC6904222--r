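#' Laplacian-of-Gaussian spot detection
#'
#' Detects diffraction-limited spots as local maxima of the (negated)
#' Laplacian-of-Gaussian response, with the kernel scale set by the expected
#' blob diameter (sigma = d / 2 sqrt 2). Maxima closer than one blob
#' diameter are suppressed, keeping the stronger response.
#'
#' @param frame 2-D image matrix (rows = y, columns = x).
#' @param blob_diameter Expected spot diameter, pixels.
#' @param threshold Minimum LoG response; NULL chooses a threshold
#'   automatically (Otsu on the positive responses).
#' @return Data frame with `x`, `y` (pixel units, pixel centers at i - 0.5)
#'   and `response`, ordered by decreasing response.
#' @export
detect_spots <- function(frame, blob_diameter = 4, threshold = NULL) {
  stopifnot(is.matrix(frame))
  sigma <- blob_diameter / (2 * sqrt(2))
  resp <- -log_filter(frame, sigma)
  ny <- nrow(frame); nx <- ncol(frame)
  if (is.null(threshold)) {
    pos <- resp[resp > 0]
    if (!length(pos)) return(data.frame(x = numeric(0), y = numeric(0),
                                        response = numeric(0)))
    threshold <- otsu_threshold(pos)
  }
  # 8-neighbourhood local maxima above threshold (exclude 1-px border)
  cand <- which(resp >= threshold, arr.ind = TRUE)
  cand <- cand[cand[, 1] > 1 & cand[, 1] < ny & cand[, 2] > 1 & cand[, 2] < nx, ,
               drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    nb <- resp[(r - 1):(r + 1), (c - 1):(c + 1)]
    keep[i] <- resp[r, c] >= max(nb)
  }
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(data.frame(x = numeric(0), y = numeric(0),
                                     response = numeric(0)))
  det <- data.frame(x = cand[, 2] - 0.5, y = cand[, 1] - 0.5,
                    response = resp[cand])
  det <- det[order(-det$response), ]
  # non-overlap suppression within one blob diameter
  sel <- rep(TRUE, nrow(det))
  for (i in seq_len(nrow(det))) {
    if (!sel[i]) next
    if (i < nrow(det)) {
      j <- (i + 1):nrow(det)
      dd <- sqrt((det$x[j] - det$x[i])^2 + (det$y[j] - det$y[i])^2)
      sel[j][dd < blob_diameter] <- FALSE
    }
  }
  out <- det[sel, ]
  rownames(out) <- NULL
  out
}

# LoG response by FFT convolution with a discrete LoG kernel
log_filter <- function(img, sigma) {
  r <- max(ceiling(4 * sigma), 2)
  xs <- -r:r
  g <- exp(-xs^2 / (2 * sigma^2))
  k <- outer(g, g)
  rr <- outer(xs^2, xs^2, "+")
  k <- k * (rr - 2 * sigma^2) / sigma^4
  k <- k / sum(abs(k))
  k <- k - mean(k)  # zero-sum: flat regions give zero response
  conv2_fft(img, k)
}

conv2_fft <- function(img, kernel) {
  ny <- nrow(img); nx <- ncol(img)
  kr <- nrow(kernel); kc <- ncol(kernel)
  py <- ny + kr - 1; px <- nx + kc - 1
  A <- matrix(0, py, px); A[1:ny, 1:nx] <- img
  K <- matrix(0, py, px); K[1:kr, 1:kc] <- kernel
  full <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / (py * px)
  oy <- (kr - 1) %/% 2; ox <- (kc - 1) %/% 2
  full[(1 + oy):(ny + oy), (1 + ox):(nx + ox)]
}

otsu_threshold <- function(x, nbins = 256) {
  h <- graphics::hist(x, breaks = nbins, plot = FALSE)
  w <- h$counts / sum(h$counts)
  m <- h$mids
  best <- -Inf; thr <- m[1]
  cw <- cumsum(w); cm <- cumsum(w * m)
  mt <- cm[length(cm)]
  for (i in seq_along(m)[-length(m)]) {
    w0 <- cw[i]; w1 <- 1 - w0
    if (w0 < 1e-9 || w1 < 1e-9) next
    m0 <- cm[i] / w0; m1 <- (mt - cm[i]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; thr <- h$breaks[i + 1] }
  }
  thr
}

#' Sub-pixel localization by 2-D Gaussian least squares
#'
#' Refines detections to sub-pixel accuracy by fitting an integrated 2-D
#' Gaussian (amplitude, center, width, offset) in a window around each spot,
#' in the FIONA spirit. Non-converging fits are dropped (recorded in the
#' `dropped` attribute).
#'
#' @param frame 2-D image matrix.
#' @param spots Detections from [detect_spots()] (`x`, `y` in pixels).
#' @param window Fit window half-size, pixels.
#' @param pixel_nm Pixel size, nm.
#' @return Data frame with `x`, `y` (nm), `sigma` (nm), `amplitude`,
#'   `precision` (nm, from the fit covariance).
#' @export
localize_subpixel <- function(frame, spots, window = 3, pixel_nm = 160) {
  ny <- nrow(frame); nx <- ncol(frame)
  res <- list(); dropped <- 0L
  for (i in seq_len(nrow(spots))) {
    cx <- spots$x[i]; cy <- spots$y[i]
    xs <- max(1, round(cx + 0.5) - window):min(nx, round(cx + 0.5) + window)
    ys <- max(1, round(cy + 0.5) - window):min(ny, round(cy + 0.5) + window)
    z <- frame[ys, xs]
    grid <- expand.grid(py = ys - 0.5, px = xs - 0.5)
    zz <- as.vector(z)
    p0 <- c(off = min(zz), amp = max(zz) - min(zz), x0 = cx, y0 = cy, s = 1)
    fit <- try(minpack.lm::nls.lm(
      par = p0,
      lower = c(-Inf, 0, min(xs) - 1, min(ys) - 1, 0.3),
      upper = c(Inf, Inf, max(xs), max(ys), window + 1),
      fn = function(p) {
        zz - (p[1] + p[2] * exp(-((grid$px - p[3])^2 + (grid$py - p[4])^2) /
                                  (2 * p[5]^2)))
      }), silent = TRUE)
    if (inherits(fit, "try-error") || fit$info == 0) { dropped <- dropped + 1L; next }
    p <- stats::coef(fit)
    prec <- tryCatch({
      v <- diag(stats::vcov(fit))
      sqrt(mean(v[c("x0", "y0")])) * pixel_nm
    }, error = function(e) NA_real_)
    res[[length(res) + 1L]] <- data.frame(
      x = p[["x0"]] * pixel_nm, y = p[["y0"]] * pixel_nm,
      sigma = p[["s"]] * pixel_nm, amplitude = p[["amp"]], precision = prec)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(x = numeric(0), y = numeric(0), sigma = numeric(0),
               amplitude = numeric(0), precision = numeric(0))
  attr(out, "dropped") <- dropped
  out
}

#' Detect and localize spots across a whole stack
#'
#' @param stack An `fg_stack` or 3-D array.
#' @param blob_diameter,threshold Passed to [detect_spots()].
#' @param pixel_nm Pixel size, nm (taken from the stack if available).
#' @return Data frame with `frame`, `x`, `y` (nm) for all localized spots.
#' @export
track_stack_spots <- function(stack, blob_diameter = 4, threshold = NULL,
                              pixel_nm = NULL) {
  if (inherits(stack, "fg_stack")) {
    if (is.null(pixel_nm)) pixel_nm <- stack$pixel_nm
    stack <- stack$stack
  }
  if (is.null(pixel_nm)) pixel_nm <- 160
  out <- list()
  for (fi in seq_len(dim(stack)[3])) {
    fr <- stack[, , fi]
    det <- detect_spots(fr, blob_diameter, threshold)
    if (!nrow(det)) next
    loc <- localize_subpixel(fr, det, pixel_nm = pixel_nm)
    if (nrow(loc)) {
      loc$frame <- fi - 1L
      out[[length(out) + 1L]] <- loc
    }
  }
  if (!length(out)) return(data.frame(frame = integer(0), x = numeric(0),
                                      y = numeric(0)))
  do.call(rbind, out)
}

# Linear assignment by shortest augmenting paths with potentials
# (Jonker-Volgenant style Hungarian, O(n^2 m)). cost must have nrow <= ncol;
# returns the assigned column for each row.
lap_solve <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  INF <- 1e18
  u <- numeric(n); v <- numeric(m + 1)
  p <- integer(m + 1)    # p[j]: row assigned to column j-1 (j = 1 is virtual)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in 2:(m + 1)) {
        if (used[j]) next
        cur <- cost[i0, j - 1] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(m + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]; p[j0] <- p[j1]; j0 <- j1
      if (j0 == 1L) break
    }
  }
  ans <- integer(n)
  for (j in 2:(m + 1)) if (p[j] > 0L) ans[p[j]] <- j - 1L
  ans
}

# Assignment with rejection: pairs costlier than `max_cost` stay unmatched.
# Pads the cost matrix with per-row dummy columns at max_cost.
lap_match <- function(cost, max_cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0 || m == 0) return(integer(n))
  big <- max_cost * 1.0000001
  padded <- cbind(pmin(cost, big * 2), matrix(big, n, n))
  a <- lap_solve(padded)
  a[a > m] <- 0L
  a[a > 0L & cost[cbind(which(a > 0L), a[a > 0L])] > max_cost] <- 0L
  a
}

#' Link per-frame spots into tracks with gap closing
#'
#' Two-pass tracker in the Simple LAP spirit: (1) frame-to-frame linking by
#' optimal linear assignment on squared distance with a maximum link
#' distance; (2) track-segment stitching, matching segment ends to later
#' segment starts within a maximum frame gap and gap-closing distance, again
#' by linear assignment.
#'
#' @param spots Data frame with `frame` (integer) and `x`, `y` (nm).
#' @param max_link Maximum frame-to-frame link distance, pixels.
#' @param max_gap_close Maximum gap-closing distance, pixels.
#' @param max_gap Maximum frame gap bridged when stitching, frames.
#' @param pixel_nm Pixel size used to convert the pixel-unit limits, nm.
#' @return Data frame `track`, `frame`, `x`, `y`, ordered by track and
#'   frame. Unlinked spots become singleton tracks.
#' @export
link_tracks <- function(spots, max_link = 4, max_gap_close = 4, max_gap = 20,
                        pixel_nm = 160) {
  stopifnot(all(c("frame", "x", "y") %in% names(spots)))
  if (!nrow(spots)) {
    return(data.frame(track = integer(0), frame = integer(0),
                      x = numeric(0), y = numeric(0)))
  }
  max_link_nm <- max_link * pixel_nm
  max_close_nm <- max_gap_close * pixel_nm
  spots <- spots[order(spots$frame), , drop = FALSE]
  spots$track <- NA_integer_
  frames <- sort(unique(spots$frame))
  next_id <- 0L
  prev_idx <- integer(0)  # row indices of the previous frame's spots
  prev_frame <- NA_integer_
  for (f in frames) {
    cur_idx <- which(spots$frame == f)
    if (!is.na(prev_frame) && f - prev_frame != 1L) prev_idx <- integer(0)
    prev_frame <- f
    if (length(prev_idx) && length(cur_idx)) {
      cost <- outer(seq_along(prev_idx), seq_along(cur_idx),
                    function(i, j) (spots$x[prev_idx[i]] - spots$x[cur_idx[j]])^2 +
                                   (spots$y[prev_idx[i]] - spots$y[cur_idx[j]])^2)
      if (length(prev_idx) <= length(cur_idx)) {
        a <- lap_match(cost, max_link_nm^2)
        for (i in seq_along(a)) if (a[i] > 0L) {
          spots$track[cur_idx[a[i]]] <- spots$track[prev_idx[i]]
        }
      } else {
        a <- lap_match(t(cost), max_link_nm^2)
        for (j in seq_along(a)) if (a[j] > 0L) {
          spots$track[cur_idx[j]] <- spots$track[prev_idx[a[j]]]
        }
      }
    }
    new <- cur_idx[is.na(spots$track[cur_idx])]
    if (length(new)) {
      spots$track[new] <- next_id + seq_along(new)
      next_id <- next_id + length(new)
    }
    prev_idx <- cur_idx
  }
  spots$track <- as.integer(spots$track)
  # segment stitching across gaps
  segs <- do.call(rbind, lapply(split(seq_len(nrow(spots)), spots$track),
    function(ii) {
      ii <- ii[order(spots$frame[ii])]
      data.frame(track = spots$track[ii[1]],
                 f0 = spots$frame[ii[1]], f1 = spots$frame[ii[length(ii)]],
                 x0 = spots$x[ii[1]], y0 = spots$y[ii[1]],
                 x1 = spots$x[ii[length(ii)]], y1 = spots$y[ii[length(ii)]])
    }))
  repeat {
    merged <- FALSE
    segs <- segs[order(segs$f0), ]
    for (i in seq_len(nrow(segs))) {
      cand <- which(segs$f0 > segs$f1[i] & segs$f0 - segs$f1[i] <= max_gap)
      if (!length(cand)) next
      dd <- sqrt((segs$x0[cand] - segs$x1[i])^2 + (segs$y0[cand] - segs$y1[i])^2)
      keep <- dd <= max_close_nm
      cand <- cand[keep]; dd <- dd[keep]
      if (!length(cand)) next
      j <- cand[which.min(dd)]
      spots$track[spots$track == segs$track[j]] <- segs$track[i]
      segs$f1[i] <- segs$f1[j]; segs$x1[i] <- segs$x1[j]; segs$y1[i] <- segs$y1[j]
      segs <- segs[-j, ]
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  spots$track <- as.integer(factor(spots$track))
  out <- spots[order(spots$track, spots$frame),
               c("track", "frame", "x", "y",
                 setdiff(names(spots), c("track", "frame", "x", "y")))]
  rownames(out) <- NULL
  out
}
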