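#' Segmentation parameters
#'
#' Parameters of the nucleus-detection pipeline (see [segment_nuclei()]).
#' None of the numeric defaults is a measured constant; they are calibrated
#' for nuclei of roughly 8--12 px radius and are meant to be overridden per
#' dataset.
#'
#' @param blur_sigma Gaussian blur SD (px) applied before thresholding.
#' @param log_sigma Laplacian-of-Gaussian scale (px) for seed detection;
#'   approximately the expected nucleus radius.
#' @param min_seed_distance minimum distance between seeds (px, >= 1).
#' @param min_area,max_area area filter bounds (px^2), applied after the
#'   watershed.
#' @param border_policy `"drop"` removes nuclei touching the image border,
#'   `"keep"` retains them.
#' @param min_separation empty-foreground guard: minimum two-class separation
#'   index (gap between foreground and background means over the pooled
#'   within-class SD of the blurred image) for the Li threshold to count as
#'   having found foreground. Blurred pure Gaussian noise scores about 2.6
#'   regardless of its scale; images with genuine nuclei score well above 5.
#'   Below the guard, zero nuclei are reported instead of noise partitions.
#' @return an object of class `segmentation_config`.
#' @export
segmentation_config <- function(blur_sigma = 2,
                                log_sigma = 8,
                                min_seed_distance = 10,
                                min_area = 50,
                                max_area = 10000,
                                border_policy = c("drop", "keep"),
                                min_separation = 4) {
  border_policy <- match.arg(border_policy)
  if (blur_sigma <= 0 || log_sigma <= 0) stop_param("sigmas must be > 0")
  if (min_seed_distance < 1) stop_param("min_seed_distance must be >= 1")
  if (min_area >= max_area) stop_param("min_area must be < max_area")
  if (min_separation < 0) stop_param("min_separation must be >= 0")
  structure(
    list(
      blur_sigma = blur_sigma, log_sigma = log_sigma,
      min_seed_distance = min_seed_distance,
      min_area = min_area, max_area = max_area,
      border_policy = border_policy,
      min_separation = min_separation
    ),
    class = "segmentation_config"
  )
}

# Li foreground of the blurred image plus the separation index used by the
# empty-foreground guard.
.foreground <- function(blurred, config) {
  thr <- li_threshold(blurred)
  fg <- blurred > thr
  sep <- if (any(fg) && any(!fg)) {
    pooled <- (var(blurred[fg]) * sum(fg) + var(blurred[!fg]) * sum(!fg)) /
      length(blurred)
    (mean(blurred[fg]) - mean(blurred[!fg])) / sqrt(pooled)
  } else {
    0
  }
  list(fg = fg & (sep >= config$min_separation), thr = thr, separation = sep)
}

#' Detect nucleus seeds
#'
#' Seeds are local maxima of the Laplacian-of-Gaussian blob response
#' ([log_response()] at `config$log_sigma`) restricted to the Li-threshold
#' foreground of the blurred image, suppressed to a minimum mutual distance
#' of `config$min_seed_distance`. Ties in response are broken by
#' (row, col) lexicographic order, so the result is deterministic.
#'
#' @param image single-channel numeric matrix (the lamin A channel).
#' @param config a [segmentation_config()].
#' @return integer-valued `k x 2` matrix of seed (row, col) positions,
#'   possibly with zero rows.
#' @export
detect_seeds <- function(image, config = segmentation_config()) {
  blurred <- gaussian_blur(image, config$blur_sigma)
  fgr <- .foreground(blurred, config)
  if (!any(fgr$fg)) {
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  }
  resp <- log_response(image, config$log_sigma)
  find_local_maxima(resp, fgr$fg, config$min_seed_distance)
}

#' Segment nuclei on the lamin A channel
#'
#' Pipeline: Gaussian blur (`blur_sigma`) -> Li threshold on the blurred
#' image -> Laplacian-of-Gaussian seed detection ([detect_seeds()]) ->
#' seeded watershed on the inverted blurred image restricted to the
#' foreground mask -> area filter -> border policy. Labels are relabeled
#' contiguously `1..K` in seed order. The whole pipeline is deterministic,
#' and invariant to positive rescaling of the input (the Li threshold scales
#' with the image).
#'
#' @inheritParams detect_seeds
#' @return integer label matrix (`0` = background) with attributes
#'   `seeds` (seed coordinates retained after filtering), `threshold`
#'   (the Li threshold used) and `config`.
#' @export
segment_nuclei <- function(image, config = segmentation_config()) {
  blurred <- gaussian_blur(image, config$blur_sigma)
  fgr <- .foreground(blurred, config)  # propagates degenerate-input error
  thr <- fgr$thr
  fg <- fgr$fg
  empty <- function() {
    lab <- matrix(0L, nrow(image), ncol(image))
    attr(lab, "seeds") <- matrix(numeric(0), 0, 2)
    attr(lab, "threshold") <- thr
    attr(lab, "config") <- config
    lab
  }
  if (!any(fg)) return(empty())

  resp <- log_response(image, config$log_sigma)
  seeds <- find_local_maxima(resp, fg, config$min_seed_distance)
  if (!nrow(seeds)) return(empty())

  seed_img <- matrix(0L, nrow(image), ncol(image))
  seed_img[seeds] <- seq_len(nrow(seeds))
  lab <- .ws_flood(-blurred, seed_img, fg)

  k <- nrow(seeds)
  areas <- tabulate(lab, nbins = k)
  keep <- areas >= config$min_area & areas <= config$max_area
  if (config$border_policy == "drop") {
    border <- unique(c(
      lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]
    ))
    keep[border[border > 0]] <- FALSE
  }
  # relabel contiguously in seed order
  remap <- integer(k)
  remap[keep] <- seq_len(sum(keep))
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  out[nz] <- remap[lab[nz]]
  attr(out, "seeds") <- seeds[keep, , drop = FALSE]
  attr(out, "threshold") <- thr
  attr(out, "config") <- config
  out
}

#' Measure per-nucleus mean intensities
#'
#' One record per label: per-channel mean intensity over the label's pixels,
#' pixel-count area and centroid, in stable (ascending label) order.
#'
#' @param mask integer label matrix (e.g. from [segment_nuclei()] or a
#'   [render_scene()] ground-truth mask).
#' @param channels named list of numeric matrices, or a 3-D array with
#'   channel names in `dimnames(...)[[3]]`; every channel must match the
#'   mask's shape.
#' @param metadata optional named list of identifiers (`fov_id`, `condition`,
#'   `well`, `timepoint_h`) copied into every record.
#' @return a `data.frame` of cell records: `cell_id`, `label`, `fov_id`,
#'   `condition`, `well`, `timepoint_h`, `area_px`, `centroid_row`,
#'   `centroid_col`, and one mean-intensity column per channel (named as the
#'   channel).
#' @export
measure_rois <- function(mask, channels, metadata = list()) {
  if (is.array(channels) && length(dim(channels)) == 3L) {
    nm <- dimnames(channels)[[3]] %||% paste0("ch", seq_len(dim(channels)[3]))
    channels <- setNames(
      lapply(seq_len(dim(channels)[3]), function(i) channels[, , i]),
      nm
    )
  }
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop_input("channels must be a named list of matrices or a named 3-D array")
  }
  for (ch in names(channels)) {
    if (!identical(dim(channels[[ch]]), dim(mask))) {
      stop_input("channel '%s' does not match the mask shape", ch)
    }
  }
  k <- max(mask, 0L)
  fov <- metadata$fov_id %||% "fov1"
  if (k == 0L) {
    out <- data.frame(
      cell_id = character(0), label = integer(0), fov_id = character(0),
      condition = character(0), well = character(0), timepoint_h = numeric(0),
      area_px = integer(0), centroid_row = numeric(0), centroid_col = numeric(0)
    )
    for (ch in names(channels)) out[[ch]] <- numeric(0)
    return(out)
  }
  nz <- which(mask > 0)
  lab <- mask[nz]
  areas <- tabulate(lab, nbins = k)
  if (any(areas == 0)) stop_input("mask labels must be contiguous 1..K")
  rows <- ((nz - 1L) %% nrow(mask)) + 1L
  cols <- ((nz - 1L) %/% nrow(mask)) + 1L
  out <- data.frame(
    cell_id = sprintf("%s_roi%04d", fov, seq_len(k)),
    label = seq_len(k),
    fov_id = fov,
    condition = metadata$condition %||% NA_character_,
    well = metadata$well %||% NA_character_,
    timepoint_h = metadata$timepoint_h %||% NA_real_,
    area_px = areas,
    centroid_row = as.numeric(rowsum(rows, lab)) / areas,
    centroid_col = as.numeric(rowsum(cols, lab)) / areas,
    stringsAsFactors = FALSE
  )
  for (ch in names(channels)) {
    out[[ch]] <- as.numeric(rowsum(channels[[ch]][nz], lab)) / areas
  }
  out
}

#' Segment a rendered scene and measure all channels
#'
#' Convenience wrapper: segments the `lamin_a` channel of a
#' [render_scene()] output (or any channel named in `segment_on`) and
#' measures every channel over the resulting labels.
#'
#' @param scene a `synthetic_scene` (or a list with `image` as a named 3-D
#'   array).
#' @param config a [segmentation_config()].
#' @param segment_on channel used for segmentation (default `"lamin_a"`).
#' @param metadata passed to [measure_rois()].
#' @return list with `mask` (the label matrix) and `cells` (cell records).
#' @export
segment_scene <- function(scene, config = segmentation_config(),
                          segment_on = "lamin_a", metadata = list()) {
  chans <- dimnames(scene$image)[[3]]
  if (!segment_on %in% chans) {
    stop_input("segmentation channel '%s' not present in scene", segment_on)
  }
  mask <- segment_nuclei(scene$image[, , segment_on], config)
  cells <- measure_rois(mask, scene$image, metadata)
  list(mask = mask, cells = cells)
}
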