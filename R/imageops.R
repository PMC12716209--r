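# Low-level image operations used by the segmentation pipeline. Images are
# numeric matrices indexed (row, col), 1-based as everywhere in R. Borders are
# handled by edge replication.

gaussian_kernel <- function(sigma) {
  if (sigma <= 0) stop_param("sigma must be > 0")
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable 1-D convolution along rows then columns with replicate padding.
conv_sep <- function(x, k) {
  r <- (length(k) - 1L) / 2L
  nr <- nrow(x)
  nc <- ncol(x)
  xp <- x[c(rep(1L, r), seq_len(nr), rep(nr, r)), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_along(k)) {
    out <- out + k[i] * xp[i:(i + nr - 1L), , drop = FALSE]
  }
  xp <- out[, c(rep(1L, r), seq_len(nc), rep(nc, r)), drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_along(k)) {
    out <- out + k[i] * xp[, i:(i + nc - 1L), drop = FALSE]
  }
  out
}

#' Gaussian blur
#'
#' Separable Gaussian smoothing with kernel radius `ceiling(3 * sigma)` and
#' replicate border padding.
#'
#' @param image numeric matrix.
#' @param sigma Gaussian SD in pixels (> 0).
#' @return blurred matrix of the same shape.
#' @export
gaussian_blur <- function(image, sigma) {
  if (!is.matrix(image)) stop_input("image must be a matrix")
  conv_sep(image, gaussian_kernel(sigma))
}

# 4-neighbour discrete Laplacian with replicate padding.
laplacian <- function(x) {
  nr <- nrow(x)
  nc <- ncol(x)
  up <- x[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  dn <- x[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  lf <- x[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  rt <- x[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  up + dn + lf + rt - 4 * x
}

#' Laplacian-of-Gaussian blob response
#'
#' Gaussian blur at scale `sigma` followed by the discrete Laplacian, negated
#' so that bright blobs of radius about `sigma * sqrt(2)` produce positive
#' peaks at their centers.
#'
#' @inheritParams gaussian_blur
#' @return response matrix; maxima mark bright blob centers.
#' @export
log_response <- function(image, sigma) {
  -laplacian(gaussian_blur(image, sigma))
}

#' Li minimum cross-entropy threshold
#'
#' Iterative scheme: with the image shifted to a zero minimum, start from the
#' mean and update `t <- (mu_bg - mu_fg) / (log(mu_bg) - log(mu_fg))`, where
#' `mu_bg` / `mu_fg` are the means of pixels below / above the current
#' threshold, until the change drops below `tol`. The returned threshold is on
#' the original intensity scale.
#'
#' @param image numeric matrix (or vector) of pixel values; must contain at
#'   least two distinct values.
#' @param tol convergence tolerance on the threshold.
#' @param max_iter iteration cap.
#' @return scalar threshold, strictly between `min(image)` and `max(image)`.
#' @export
li_threshold <- function(image, tol = 1e-8, max_iter = 1000L) {
  v <- as.numeric(image)
  if (!length(v) || anyNA(v)) stop_input("image must be numeric without NA")
  lo <- min(v)
  hi <- max(v)
  if (hi - lo == 0) stop_degenerate("constant image: threshold undefined")
  v <- v - lo  # Li's update needs non-negative values
  t_cur <- mean(v)
  for (i in seq_len(max_iter)) {
    bg <- v[v <= t_cur]
    fg <- v[v > t_cur]
    if (!length(fg) || !length(bg)) break
    mu_bg <- mean(bg)
    mu_fg <- mean(fg)
    t_new <- if (mu_bg > 0) {
      (mu_bg - mu_fg) / (log(mu_bg) - log(mu_fg))
    } else {
      mu_fg / exp(1)  # limit of the update as mu_bg -> 0
    }
    if (abs(t_new - t_cur) < tol) {
      t_cur <- t_new
      break
    }
    t_cur <- t_new
  }
  t_cur + lo
}

# Local maxima of `response` within `mask`, separated by >= min_distance
# (Euclidean). Candidates are 8-neighbourhood maxima; greedy suppression in
# decreasing response order, ties broken by (row, col) lexicographic order.
# Returns a k x 2 matrix of (row, col).
find_local_maxima <- function(response, mask, min_distance) {
  nr <- nrow(response)
  nc <- ncol(response)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- response
  nmax <- matrix(-Inf, nr, nc)
  for (di in -1:1) {
    for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      nmax <- pmax(nmax, pad[(2:(nr + 1L)) + di, (2:(nc + 1L)) + dj])
    }
  }
  cand <- which(mask & response >= nmax, arr.ind = TRUE)
  if (!nrow(cand)) return(cand)
  vals <- response[cand]
  ord <- order(-vals, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  sel <- matrix(numeric(0), 0, 2)
  d2 <- min_distance^2
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (!nrow(sel) ||
        all((sel[, 1] - p[1])^2 + (sel[, 2] - p[2])^2 >= d2)) {
      sel <- rbind(sel, p)
    }
  }
  dimnames(sel) <- list(NULL, c("row", "col"))
  sel
}
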