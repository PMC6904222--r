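#' Microtubule backbone polyline
#'
#' Piecewise-linear backbone of a (possibly bent) microtubule with an
#' arc-length parameterization and a gliding orientation.
#'
#' @param vertices Two-column matrix (x, y in nm), at least 2 rows, ordered
#'   along the gliding direction.
#' @return Object of class `backbone_polyline` with cumulative arc lengths.
#' @export
backbone_polyline <- function(vertices) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 2)
  seglen <- sqrt(rowSums(diff(vertices)^2))
  if (any(seglen <= 0)) stop("backbone vertices must be distinct")
  structure(list(vertices = vertices,
                 arc = c(0, cumsum(seglen)),
                 length = sum(seglen)), class = "backbone_polyline")
}

#' @export
print.backbone_polyline <- function(x, ...) {
  cat(sprintf("backbone polyline: %d vertices, %.0f nm arc length\n",
              nrow(x$vertices), x$length))
  invisible(x)
}

# point on the backbone at arc position s (nm), plus unit tangent and normal
backbone_point <- function(bb, s) {
  s <- pmin(pmax(s, 0), bb$length)
  i <- findInterval(s, bb$arc, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1), nrow(bb$vertices) - 1)
  t0 <- bb$arc[i]
  d <- bb$vertices[i + 1, , drop = FALSE] - bb$vertices[i, , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  tang <- d / len
  pt <- bb$vertices[i, , drop = FALSE] + tang * (s - t0)
  list(point = pt, tangent = tang, normal = cbind(-tang[, 2], tang[, 1]))
}

#' Project a 2-D track onto the microtubule axis
#'
#' Maps each track point to the nearest point on the backbone polyline and
#' reports its arc-length coordinate (so bent microtubules contribute arc
#' length, not chord length). Points farther than `capture` from the
#' backbone are flagged off-axis.
#'
#' @param track Data frame with `x`, `y` (nm); other columns are preserved.
#' @param backbone A [backbone_polyline()].
#' @param capture Maximum perpendicular distance, nm.
#' @return The track with added `onaxis` (arc length, nm), `offaxis`
#'   (signed perpendicular distance, nm) and `flagged`.
#' @export
project_onaxis <- function(track, backbone, capture = 800) {
  V <- backbone$vertices
  n <- nrow(V)
  px <- track$x; py <- track$y
  best_d2 <- rep(Inf, length(px)); best_s <- rep(NA_real_, length(px))
  best_off <- rep(NA_real_, length(px))
  for (i in seq_len(n - 1)) {
    ax <- V[i, 1]; ay <- V[i, 2]
    bx <- V[i + 1, 1]; by <- V[i + 1, 2]
    dx <- bx - ax; dy <- by - ay
    L2 <- dx^2 + dy^2
    t <- ((px - ax) * dx + (py - ay) * dy) / L2
    t <- pmin(pmax(t, 0), 1)
    qx <- ax + t * dx; qy <- ay + t * dy
    d2 <- (px - qx)^2 + (py - qy)^2
    upd <- d2 < best_d2
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      best_s[upd] <- backbone$arc[i] + t[upd] * sqrt(L2)
      # signed perpendicular offset (left of the gliding direction positive)
      cross <- dx * (py - qy) - dy * (px - qx)
      best_off[upd] <- cross[upd] / sqrt(L2)
    }
  }
  track$onaxis <- best_s
  track$offaxis <- best_off
  track$flagged <- sqrt(best_d2) > capture
  track
}

#' Build a kymograph along a backbone
#'
#' Samples the image intensity along the backbone arc at one-pixel spacing,
#' averaged across `linewidth` perpendicular offsets, for every frame.
#'
#' @param stack An `fg_stack` or 3-D array (ny x nx x frames).
#' @param backbone A [backbone_polyline()].
#' @param linewidth Perpendicular averaging width, pixels.
#' @param pixel_nm Pixel size, nm.
#' @param frame_interval Frame interval, s.
#' @return Object of class `fg_kymograph`: `intensity` (arc x time matrix),
#'   `space_step` (nm), `time_step` (s).
#' @export
build_kymograph <- function(stack, backbone, linewidth = 3, pixel_nm = NULL,
                            frame_interval = 0.2) {
  if (inherits(stack, "fg_stack")) {
    if (is.null(pixel_nm)) pixel_nm <- stack$pixel_nm
    stack <- stack$stack
  }
  if (is.null(pixel_nm)) pixel_nm <- 160
  if (length(dim(stack)) != 3 || dim(stack)[3] < 1) stop("empty image stack")
  ny <- dim(stack)[1]; nx <- dim(stack)[2]; nf <- dim(stack)[3]
  s <- seq(0, backbone$length, by = pixel_nm)
  bp <- backbone_point(backbone, s)
  offs <- (seq_len(linewidth) - (linewidth + 1) / 2) * pixel_nm
  # sample positions (px units, pixel centers at i - 0.5)
  sample_xy <- lapply(offs, function(o) {
    cbind(bp$point[, 1] + o * bp$normal[, 1],
          bp$point[, 2] + o * bp$normal[, 2]) / pixel_nm
  })
  inside <- Reduce(`&`, lapply(sample_xy, function(m) {
    m[, 1] >= 0.5 & m[, 1] <= nx - 0.5 & m[, 2] >= 0.5 & m[, 2] <= ny - 0.5
  }))
  if (!any(inside)) stop("backbone lies outside the image")
  K <- matrix(NA_real_, length(s), nf)
  for (fi in seq_len(nf)) {
    img <- stack[, , fi]
    acc <- numeric(length(s))
    for (m in sample_xy) {
      acc <- acc + bilinear(img, m[, 1], m[, 2])
    }
    K[, fi] <- acc / linewidth
  }
  K[!inside, ] <- NA
  structure(list(intensity = K, space_step = pixel_nm,
                 time_step = frame_interval, arc = s),
            class = "fg_kymograph")
}

# bilinear interpolation; coordinates in pixel units, centers at i - 0.5
bilinear <- function(img, x, y) {
  ny <- nrow(img); nx <- ncol(img)
  fx <- pmin(pmax(x - 0.5, 0), nx - 1.0001)
  fy <- pmin(pmax(y - 0.5, 0), ny - 1.0001)
  ix <- floor(fx); iy <- floor(fy)
  tx <- fx - ix; ty <- fy - iy
  i00 <- cbind(iy + 1, ix + 1); i01 <- cbind(iy + 1, pmin(ix + 2, nx))
  i10 <- cbind(pmin(iy + 2, ny), ix + 1); i11 <- cbind(pmin(iy + 2, ny), pmin(ix + 2, nx))
  img[i00] * (1 - tx) * (1 - ty) + img[i01] * tx * (1 - ty) +
    img[i10] * (1 - tx) * ty + img[i11] * tx * ty
}

#' Microtubule velocity from kymograph edges
#'
#' Detects intensity edges in every kymograph time column as local maxima of
#' the spatial gradient magnitude above an automatic (Otsu) threshold, links
#' edges across frames by nearest-neighbour continuity, converts each edge
#' trace to a velocity by a smoothed derivative, and averages across edges
#' per frame. Frames without edges are interpolated.
#'
#' @param kym An [build_kymograph()] result.
#' @param max_jump Largest per-frame edge displacement considered the same
#'   edge, nm.
#' @param min_len Minimum edge-trace length (frames) used for velocity.
#' @param window Savitzky-Golay window (frames).
#' @return Data frame with `time`, `velocity` (nm/s) and `n_edges`; frames
#'   where no edge was tracked carry `n_edges = 0` and interpolated
#'   velocity. Attribute `flag` is `"no-edges"` when nothing was tracked.
#' @export
kymograph_velocity <- function(kym, max_jump = 400, min_len = 5, window = 7) {
  K <- kym$intensity
  nf <- ncol(K)
  if (nf < 2) stop("kymograph needs at least 2 time samples")
  ds <- kym$space_step
  grad <- apply(K, 2, function(col) {
    g <- c(NA, diff(col)) / ds
    g
  })
  gm <- abs(grad)
  thr <- otsu_threshold(gm[is.finite(gm)])
  # per-frame edge positions (sub-pixel by parabolic refinement)
  edges <- vector("list", nf)
  for (fi in seq_len(nf)) {
    g <- gm[, fi]
    idx <- which(!is.na(g) & g >= thr)
    idx <- idx[idx > 2 & idx < length(g) - 1]
    idx <- idx[g[idx] >= g[idx - 1] & g[idx] >= g[idx + 1]]
    if (!length(idx)) { edges[[fi]] <- numeric(0); next }
    pos <- vapply(idx, function(i) {
      a <- g[i - 1]; b <- g[i]; c <- g[i + 1]
      den <- a - 2 * b + c
      d <- if (is.finite(den) && den != 0) 0.5 * (a - c) / den else 0
      (i - 1 + max(min(d, 0.5), -0.5)) * ds
    }, numeric(1))
    edges[[fi]] <- pos
  }
  # link edges into traces
  traces <- list()   # each: list(frames, pos)
  active <- list()
  for (fi in seq_len(nf)) {
    pos <- edges[[fi]]
    taken <- rep(FALSE, length(pos))
    if (length(active)) {
      keep <- logical(length(active))
      for (ai in seq_along(active)) {
        tr <- active[[ai]]
        last <- tr$pos[length(tr$pos)]
        if (length(pos)) {
          dd <- abs(pos - last)
          j <- which.min(ifelse(taken, Inf, dd))
          if (length(j) && !taken[j] && dd[j] <= max_jump) {
            tr$frames <- c(tr$frames, fi); tr$pos <- c(tr$pos, pos[j])
            active[[ai]] <- tr; taken[j] <- TRUE; keep[ai] <- TRUE
            next
          }
        }
        traces[[length(traces) + 1L]] <- tr
      }
      active <- active[keep]
    }
    for (j in which(!taken)) {
      active[[length(active) + 1L]] <- list(frames = fi, pos = pos[j])
    }
  }
  traces <- c(traces, active)
  traces <- traces[vapply(traces, function(t) length(t$frames), 1L) >= min_len]
  vsum <- numeric(nf); vn <- integer(nf)
  for (tr in traces) {
    v <- sg_derivative(tr$pos, kym$time_step, min(window, length(tr$pos)))
    ok <- is.finite(v)
    vsum[tr$frames[ok]] <- vsum[tr$frames[ok]] + v[ok]
    vn[tr$frames[ok]] <- vn[tr$frames[ok]] + 1L
  }
  vel <- ifelse(vn > 0, vsum / pmax(vn, 1), NA_real_)
  out <- data.frame(time = (seq_len(nf) - 1) * kym$time_step,
                    velocity = vel, n_edges = vn)
  if (all(is.na(vel))) {
    attr(out, "flag") <- "no-edges"
    return(out)
  }
  out$velocity <- stats::approx(out$time[is.finite(vel)], vel[is.finite(vel)],
                                xout = out$time, rule = 2)$y
  out
}
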