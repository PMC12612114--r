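# Droplet re-centering: synthetic trap-image rendering, Sobel edge maps, a
# gradient-directed circular Hough transform, and the XY stage correction.
# Images are plain integer matrices (rows = y, cols = x) with 8-bit values;
# pixel (1,1) is the top-left corner.

#' Render a synthetic droplet-trap image
#'
#' Draws the dark circular trap ring on a bright background as a radial
#' Gaussian trough. Defocus widens the ring profile (lowering edge gradients,
#' as a blurred trap would) and additive Gaussian pixel noise is applied
#' before quantization to 8 bits. Deterministic under `seed`.
#'
#' @param center_px numeric `(cx, cy)` ring center in pixel coordinates.
#' @param radius_px ring radius in pixels.
#' @param ring_contrast trough depth in grey levels (0-255 scale).
#' @param defocus_um absolute defocus in micrometres; widens the ring.
#' @param noise_sd Gaussian noise standard deviation in grey levels.
#' @param seed integer seed for the noise, or `NULL`.
#' @param width,height frame size in pixels (camera default 640 x 480).
#' @param background background grey level.
#' @return integer matrix `height x width` with values in 0..255.
#' @export
render_trap_image <- function(center_px = c(320, 240), radius_px = 170,
                              ring_contrast = 120, defocus_um = 0,
                              noise_sd = 2, seed = NULL,
                              width = 640L, height = 480L,
                              background = 200) {
  cx <- center_px[1]; cy <- center_px[2]
  stopifnot_scalar_num(radius_px, "radius_px", positive = TRUE)
  if (cx - radius_px < 1 || cx + radius_px > width ||
      cy - radius_px < 1 || cy + radius_px > height)
    stop("ring does not fit inside the frame", call. = FALSE)
  ring_w <- 2 + 1.2 * abs(defocus_um)   # ring half-width grows with defocus
  xs <- matrix(seq_len(width), nrow = height, ncol = width, byrow = TRUE)
  ys <- matrix(seq_len(height), nrow = height, ncol = width)
  rho <- sqrt((xs - cx)^2 + (ys - cy)^2)
  img <- background - ring_contrast * exp(-((rho - radius_px)^2) /
                                            (2 * ring_w^2))
  img <- with_seed(seed, {
    if (noise_sd > 0)
      img <- img + stats::rnorm(length(img), sd = noise_sd)
    img
  })
  img <- round(img)
  img[img < 0] <- 0
  img[img > 255] <- 255
  storage.mode(img) <- "integer"
  img
}

# Sobel gradients of a numeric image matrix; returns gx, gy, magnitude.
sobel_gradients <- function(img) {
  img <- matrix(as.numeric(img), nrow = nrow(img))
  h <- nrow(img); w <- ncol(img)
  pad <- function(m) m[c(1, seq_len(h), h), c(1, seq_len(w), w)]
  p <- pad(img)
  ix <- function(dr, dc) p[seq_len(h) + 1 + dr, seq_len(w) + 1 + dc]
  gx <- (ix(-1, 1) + 2 * ix(0, 1) + ix(1, 1)) -
        (ix(-1, -1) + 2 * ix(0, -1) + ix(1, -1))
  gy <- (ix(1, -1) + 2 * ix(1, 0) + ix(1, 1)) -
        (ix(-1, -1) + 2 * ix(-1, 0) + ix(-1, 1))
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

#' Detect the circular droplet trap by Hough transform
#'
#' Two-stage gradient-directed circular Hough transform. A Sobel edge map is
#' thresholded; each edge pixel casts center votes along its gradient
#' direction (both polarities) at every candidate radius, all into one 2-D
#' center accumulator, so the true center collects votes from the whole ring
#' regardless of radius. The accumulator peak (ties broken in raster order
#' by `which.max`) fixes the coarse center; the radius is the modal 1 px
#' distance bin from that center to the edge pixels; and center and radius
#' are then refined to sub-pixel by an algebraic (Kasa) least-squares circle
#' fit on the edge pixels within 4 px of the Hough circle.
#'
#' @param image 2-D numeric/integer image matrix (rows = y).
#' @param radius_px_range numeric `(min, max)` candidate radii in pixels.
#' @param accumulator_threshold minimum center-accumulator peak, as a
#'   fraction of the number of edge pixels; below it the image is declared
#'   trap-free.
#' @param edge_quantile quantile of gradient magnitude above which a pixel is
#'   treated as an edge.
#' @return list of class `circle_fit` with `cx_px`, `cy_px`, `radius_px`,
#'   `vote_strength`.
#' @export
hough_center <- function(image, radius_px_range = c(150, 190),
                         accumulator_threshold = 0.03,
                         edge_quantile = 0.98) {
  if (!is.matrix(image) || length(image) == 0)
    stop("image must be a nonempty matrix", call. = FALSE)
  h <- nrow(image); w <- ncol(image)
  radii <- seq(floor(radius_px_range[1]), ceiling(radius_px_range[2]))
  if (max(radii) > min(h, w))
    stop("radius range exceeds image size", call. = FALSE)
  g <- sobel_gradients(image)
  # strong-edge threshold: the stated quantile, but never below a fixed
  # fraction of the maximum gradient, so weak noise texture is not promoted
  # to edges in nearly-clean images
  thr <- max(stats::quantile(g$mag, edge_quantile), 0.3 * max(g$mag))
  if (thr <= 0) stop("no trap found: image has no edges", call. = FALSE)
  edge <- which(g$mag >= thr & g$mag > 0)
  if (length(edge) == 0)
    stop("no trap found: image has no edges", call. = FALSE)
  ey <- (edge - 1) %% h + 1
  ex <- (edge - 1) %/% h + 1
  ux <- g$gx[edge] / g$mag[edge]
  uy <- g$gy[edge] / g$mag[edge]
  vote <- function(rset) {
    acc <- integer(h * w)
    for (r in rset) {
      for (s in c(-1, 1)) {
        cxv <- round(ex + s * r * ux)
        cyv <- round(ey + s * r * uy)
        ok <- cxv >= 1 & cxv <= w & cyv >= 1 & cyv <= h
        if (!any(ok)) next
        acc <- acc + tabulate((cxv[ok] - 1L) * h + cyv[ok], nbins = h * w)
      }
    }
    acc
  }
  peak_of <- function(acc) {
    best <- which.max(acc)
    list(cx = (best - 1L) %/% h + 1L, cy = (best - 1L) %% h + 1L,
         votes = acc[best])
  }
  # pass 1: coarse center over the whole radius range
  p1 <- peak_of(vote(radii))
  if (p1$votes < accumulator_threshold * length(edge))
    stop("no trap found: accumulator peak below threshold", call. = FALSE)
  # radius: modal 1 px distance bin from the coarse center to edge pixels
  d <- sqrt((ex - p1$cx)^2 + (ey - p1$cy)^2)
  d <- d[d >= min(radii) - 0.5 & d <= max(radii) + 0.5]
  r_best <- if (length(d)) radii[which.max(tabulate(
    findInterval(d, radii - 0.5), nbins = length(radii)))]
  else radii[1]
  votes <- p1$votes
  # sub-pixel refinement: algebraic (Kasa) circle fit on the edge pixels in
  # a narrow distance band around the Hough solution, iterated once
  cx_ref <- p1$cx; cy_ref <- p1$cy; r_ref <- r_best
  for (pass in 1:8) {
    dd <- sqrt((ex - cx_ref)^2 + (ey - cy_ref)^2)
    band <- abs(dd - r_ref) <= 4
    if (sum(band) < 10) break
    cx_prev <- cx_ref; cy_prev <- cy_ref
    bx <- ex[band]; by <- ey[band]
    wt <- sqrt(g$mag[edge][band])   # damp weak (noise) edges
    A <- cbind(2 * bx, 2 * by, 1) * wt
    bvec <- (bx^2 + by^2) * wt
    sol <- tryCatch(qr.solve(A, bvec), error = function(e) NULL)
    if (is.null(sol)) break
    cx_ref <- sol[1]; cy_ref <- sol[2]
    r_ref <- sqrt(max(0, sol[3] + sol[1]^2 + sol[2]^2))
    if (abs(cx_ref - cx_prev) < 0.01 && abs(cy_ref - cy_prev) < 0.01) break
  }
  structure(list(cx_px = cx_ref, cy_px = cy_ref, radius_px = r_ref,
                 vote_strength = votes),
            class = "circle_fit")
}

#' XY stage correction from a detected circle
#'
#' The correction to apply to the stage so the detected trap center returns
#' to its expected position: `expected - detected`.
#'
#' @param fit a `circle_fit` from [hough_center()].
#' @param expected_center_px numeric `(cx, cy)` expected center.
#' @return numeric `(dx_px, dy_px)`.
#' @export
stage_correction <- function(fit, expected_center_px = c(320, 240)) {
  if (!inherits(fit, "circle_fit"))
    stop("'fit' must be a circle_fit", call. = FALSE)
  c(dx_px = expected_center_px[1] - fit$cx_px,
    dy_px = expected_center_px[2] - fit$cy_px)
}
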