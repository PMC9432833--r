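# Simplified soma segmentation: a temporal-activity feature image, blob
# detection (Laplacian of Gaussian), adaptive thresholding, and SNR-based
# candidate filtering.

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

# separable convolution with replicate padding
blur2d <- function(img, sigma) {
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  pad <- function(m, n) rbind(m[rep(1, n), , drop = FALSE], m,
                              m[rep(nrow(m), n), , drop = FALSE])
  conv_cols <- function(m) {
    p <- pad(m, r)
    out <- stats::filter(p, k, method = "convolution", sides = 2)
    out[(r + 1):(r + nrow(m)), , drop = FALSE]
  }
  t(conv_cols(t(conv_cols(img))))
}

laplacian4 <- function(img) {
  H <- nrow(img); W <- ncol(img)
  up <- img[c(1, seq_len(H - 1)), ]; dn <- img[c(seq_len(H - 1) + 1, H), ]
  lf <- img[, c(1, seq_len(W - 1))]; rt <- img[, c(seq_len(W - 1) + 1, W)]
  up + dn + lf + rt - 4 * img
}

local_maxima <- function(img) {
  H <- nrow(img); W <- ncol(img)
  ok <- matrix(TRUE, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    sh <- img[pmin(pmax(seq_len(H) + dr, 1), H),
              pmin(pmax(seq_len(W) + dc, 1), W)]
    ok <- ok & (img >= sh)
  }
  ok
}

# 4-connected components over a logical mask; returns integer label matrix
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  fg <- which(mask)
  for (start in fg) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      r <- (p - 1L) %% H + 1L; c <- (p - 1L) %/% H + 1L
      for (q in c(if (r > 1) p - 1L, if (r < H) p + 1L,
                  if (c > 1) p - H, if (c < W) p + H)) {
        if (mask[q] && lab[q] == 0L) { lab[q] <- cur; stack <- c(stack, q) }
      }
    }
  }
  lab
}

#' Segment active somata from a fluorescence video
#'
#' Builds a per-pixel temporal activity score (mean squared positive z-score
#' over time, which amplifies transient-active pixels over static
#' background), finds blob-scale seeds with a Laplacian-of-Gaussian detector,
#' thresholds the feature image adaptively, and keeps connected components
#' that contain a seed, fall in the allowed area range, and whose mean trace
#' passes a transient-SNR test. Somata are returned in deterministic
#' row-major centroid order.
#'
#' @param video registered H x W x T array.
#' @param snr_min minimum trace SNR, `(peak - median) / noise` with a
#'   difference-based robust noise estimate (default 3).
#' @param area_range_px allowed soma area in px (default c(10, 200)).
#' @param sigma_px LoG blob scale, px (default 3, soma-sized).
#' @param threshold_k adaptive threshold: median + k * MAD of the feature
#'   image (default 3).
#' @param px_size_um microns per pixel for the returned [roi_set()].
#' @return a [roi_set()] (possibly with zero somata).
#' @export
segment_somata <- function(video, snr_min = 3, area_range_px = c(10, 200),
                           sigma_px = 3, threshold_k = 3,
                           px_size_um = 420 / 512) {
  dims <- dim(video)
  H <- dims[1]; W <- dims[2]; nt <- dims[3]
  v <- video; dim(v) <- c(H * W, nt)
  mu <- rowMeans(v)
  sdv <- sqrt(pmax(rowMeans(v^2) - mu^2, 0))
  sdv[sdv == 0] <- Inf
  z <- (v - mu) / sdv
  z[z < 0] <- 0
  feature <- matrix(rowMeans(z^2), H, W)
  rm(z)

  fs <- blur2d(feature, 1)
  resp <- -laplacian4(blur2d(fs, sigma_px)) * sigma_px^2
  thr_seed <- stats::median(resp) + 3 * stats::mad(resp)
  seeds <- local_maxima(resp) & resp > thr_seed
  mask <- fs > stats::median(fs) + threshold_k * stats::mad(fs)
  lab <- label_components(mask)

  keep <- integer(0)
  if (max(lab) > 0) {
    for (l in seq_len(max(lab))) {
      px <- which(lab == l)
      if (length(px) < area_range_px[1] || length(px) > area_range_px[2]) next
      if (!any(seeds[px])) next
      tr <- colMeans(v[px, , drop = FALSE])
      noise <- stats::mad(diff(tr)) / sqrt(2)
      if (noise == 0) noise <- .Machine$double.eps
      if ((max(tr) - stats::median(tr)) / noise < snr_min) next
      keep <- c(keep, l)
    }
  }
  masks <- lapply(keep, function(l) which(lab == l))
  if (length(masks)) {
    cent <- t(vapply(masks, function(px)
      c(mean((px - 1L) %% H + 1L), mean((px - 1L) %/% H + 1L)), numeric(2)))
    masks <- masks[order(round(cent[, 1]), cent[, 2])]
  }
  if (!length(masks)) {
    out <- list(masks = list(), rings = list(),
                centroids = matrix(numeric(0), 0, 2), dim = c(H, W),
                px_size_um = px_size_um)
    class(out) <- "roi_set"
    return(out)
  }
  roi_set(masks, dim = c(H, W), px_size_um = px_size_um)
}
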