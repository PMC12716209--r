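#' Specify a rendered synthetic microscopy scene
#'
#' Geometry and noise model for [render_scene()]: nuclei are axis-aligned
#' ellipses with per-nucleus radius jitter inside `nucleus_radius_range`,
#' placed by rejection sampling so that no two nuclei overlap and centers are
#' at least `min_center_distance` apart. Channels are filled at each cell's
#' truth-table intensity over a constant background, then independent
#' Gaussian read noise of SD `noise_sd` is added per pixel.
#'
#' @param image_shape `c(rows, cols)` in pixels.
#' @param nucleus_radius_range `c(min, max)` semi-axis length in pixels
#'   (>= 3).
#' @param min_center_distance minimum Euclidean distance between nucleus
#'   centers (pixels, >= 0). Non-overlap is enforced in addition.
#' @param background_level constant background intensity.
#' @param noise_sd per-pixel Gaussian noise SD (0 disables noise).
#' @param channels ordered channel names; each must be a column of the truth
#'   table passed to [render_scene()].
#' @param border_margin extra clearance (pixels) between any nucleus edge and
#'   the image border, so blurring during segmentation does not push nuclei
#'   into the border-drop rule.
#' @param max_attempts rejection-sampling attempts per nucleus before a
#'   capacity error is raised.
#' @param seed RNG seed for [render_scene()].
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(image_shape = c(384L, 384L),
                       nucleus_radius_range = c(8, 12),
                       min_center_distance = 28,
                       background_level = 10,
                       noise_sd = 2,
                       channels = c("lamin_a", "lamin_b1"),
                       border_margin = 8,
                       max_attempts = 5000L,
                       seed = NULL) {
  if (length(image_shape) != 2L || any(image_shape < 16)) {
    stop_param("image_shape must be two dimensions of at least 16 px")
  }
  if (length(nucleus_radius_range) != 2L || nucleus_radius_range[1] < 3 ||
      diff(nucleus_radius_range) < 0) {
    stop_param("nucleus_radius_range must be increasing with minimum radius >= 3 px")
  }
  if (min_center_distance < 0) stop_param("min_center_distance must be >= 0")
  if (noise_sd < 0) stop_param("noise_sd must be >= 0")
  if (length(channels) < 1) stop_param("at least one channel is required")
  structure(
    list(
      image_shape = as.integer(image_shape),
      nucleus_radius_range = nucleus_radius_range,
      min_center_distance = min_center_distance,
      background_level = background_level,
      noise_sd = noise_sd,
      channels = channels,
      border_margin = border_margin,
      max_attempts = as.integer(max_attempts),
      seed = seed
    ),
    class = "scene_spec"
  )
}

#' Render a truth table into a multi-channel image with a label mask
#'
#' One ellipse per truth-table row, filled at the row's per-channel intensity;
#' label `k` in the mask marks the pixels of the `k`-th truth row. Rendering
#' is deterministic under a fixed `scene$seed`. Noise-free renders reproduce
#' the truth intensities exactly as per-nucleus means over mask pixels.
#'
#' @param truth a truth table; must contain every `scene$channels` column.
#' @param scene a [scene_spec()].
#' @return an object of class `synthetic_scene`: a list with
#'   `image` (array `rows x cols x channels`, channel names in
#'   `dimnames(image)[[3]]`), `mask` (integer matrix, 0 = background), and
#'   `truth` (the input truth with placement columns `center_row`,
#'   `center_col`, `radius_row`, `radius_col`, `area_px` appended).
#' @examples
#' tt <- simulate_population(population_spec(10, seed = 1))
#' sc <- render_scene(tt, scene_spec(image_shape = c(128, 128), seed = 2))
#' max(sc$mask)  # 10
#' @export
render_scene <- function(truth, scene = scene_spec()) {
  if (!inherits(scene, "scene_spec")) stop_param("scene must be a scene_spec()")
  if (nrow(truth) > 0) .check_truth(truth)
  miss <- setdiff(scene$channels, names(truth))
  if (nrow(truth) > 0 && length(miss)) {
    stop_input("truth table lacks channel column(s): %s", toString(miss))
  }
  nr <- scene$image_shape[1]
  nc <- scene$image_shape[2]
  n <- nrow(truth)
  rmin <- scene$nucleus_radius_range[1]
  rmax <- scene$nucleus_radius_range[2]
  margin <- rmax + scene$border_margin
  if (nr - 2 * margin < 1 || nc - 2 * margin < 1) {
    stop_capacity("image_shape %dx%d too small for nucleus_radius_range + border_margin",
                  nr, nc)
  }

  with_seed(scene$seed, {
    centers <- matrix(NA_real_, n, 2)
    radii <- matrix(NA_real_, n, 2)
    for (k in seq_len(n)) {
      placed <- FALSE
      for (att in seq_len(scene$max_attempts)) {
        ry <- stats::runif(1, rmin, rmax)
        rx <- stats::runif(1, rmin, rmax)
        cy <- stats::runif(1, margin, nr - margin)
        cx <- stats::runif(1, margin, nc - margin)
        ok <- TRUE
        if (k > 1) {
          prev <- seq_len(k - 1)
          dd <- sqrt((centers[prev, 1] - cy)^2 + (centers[prev, 2] - cx)^2)
          # forbid overlap (sum of larger semi-axes + 1 px guard) and
          # enforce the stated center spacing
          lim <- pmax(scene$min_center_distance,
                      pmax(radii[prev, 1], radii[prev, 2]) + max(ry, rx) + 1)
          ok <- all(dd >= lim)
        }
        if (ok) {
          centers[k, ] <- c(cy, cx)
          radii[k, ] <- c(ry, rx)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop_capacity(
          paste0("could not place nucleus %d of %d after %d attempts; ",
                 "limiting parameters: image_shape / min_center_distance / ",
                 "nucleus_radius_range"),
          k, n, scene$max_attempts
        )
      }
    }

    mask <- matrix(0L, nr, nc)
    row_ix <- matrix(seq_len(nr), nr, nc)
    col_ix <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    pix <- vector("list", n)
    for (k in seq_len(n)) {
      # bounding-box fill: pixel centers inside the ellipse
      r0 <- max(1L, floor(centers[k, 1] - radii[k, 1]))
      r1 <- min(nr, ceiling(centers[k, 1] + radii[k, 1]))
      c0 <- max(1L, floor(centers[k, 2] - radii[k, 2]))
      c1 <- min(nc, ceiling(centers[k, 2] + radii[k, 2]))
      rr <- row_ix[r0:r1, c0:c1]
      cc <- col_ix[r0:r1, c0:c1]
      inside <- ((rr - centers[k, 1]) / radii[k, 1])^2 +
        ((cc - centers[k, 2]) / radii[k, 2])^2 <= 1
      ii <- cbind(rr[inside], cc[inside])
      mask[ii] <- k
      pix[[k]] <- ii
    }

    image <- array(scene$background_level,
                   dim = c(nr, nc, length(scene$channels)),
                   dimnames = list(NULL, NULL, scene$channels))
    for (ci in seq_along(scene$channels)) {
      ch <- scene$channels[ci]
      plane <- matrix(scene$background_level, nr, nc)
      for (k in seq_len(n)) plane[pix[[k]]] <- truth[[ch]][k]
      if (scene$noise_sd > 0) {
        plane <- plane + matrix(rnorm(nr * nc, 0, scene$noise_sd), nr, nc)
      }
      image[, , ci] <- plane
    }

    truth_out <- truth
    if (n > 0) {
      truth_out$center_row <- centers[, 1]
      truth_out$center_col <- centers[, 2]
      truth_out$radius_row <- radii[, 1]
      truth_out$radius_col <- radii[, 2]
      truth_out$area_px <- vapply(pix, nrow, integer(1))
    }
    structure(
      list(image = image, mask = mask, truth = truth_out, spec = scene),
      class = "synthetic_scene"
    )
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %d x %d px, %d channel(s) [%s], %d nuclei\n",
    nrow(x$mask), ncol(x$mask), dim(x$image)[3],
    toString(dimnames(x$image)[[3]]), max(x$mask)
  ))
  invisible(x)
}
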