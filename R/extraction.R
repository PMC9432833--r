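# Calcium signal extraction: annular ring subtraction (ARS) and neuron
# matching across sessions.
#
# The ARS chain, per neuron:
#   F_ROI = F_raw - F_b          (background-subtracted soma trace)
#   F_con = F_ring - F_b         (z-axis contamination from the annulus)
#   F_sig = F_ROI - alpha * F_con  (alpha = 1 by default)
#   dF/F  = F_sig / F_0,  F_0 = mean(F_ROI)
#
# Note the as-written formula has baseline near 1 ("ratio" convention); the
# conventional variant (F_sig - F_0)/F_0 with baseline near 0 is available as
# convention = "relative".

#' dF/F matrix container
#'
#' @param C neurons x frames numeric matrix.
#' @param timestamps frame times in seconds.
#' @param neuron_ids optional ids (default 1..n).
#' @return a `dff_matrix` list.
#' @export
dff_matrix <- function(C, timestamps, neuron_ids = NULL) {
  C <- as.matrix(C)
  stopifnot(ncol(C) == length(timestamps), all(is.finite(C)))
  out <- list(C = C, timestamps = as.numeric(timestamps),
              neuron_ids = neuron_ids %||% seq_len(nrow(C)))
  class(out) <- "dff_matrix"
  out
}

#' @export
print.dff_matrix <- function(x, ...) {
  cat("dff_matrix:", nrow(x$C), "neurons x", ncol(x$C), "frames (",
      round(diff(range(x$timestamps)), 1), "s )\n")
  invisible(x)
}

#' Per-frame background baseline
#'
#' `F_b(t)` is the minimum pixel intensity of frame `t` (the concatenated
#' frame minima of the stack). `per_frame = FALSE` collapses to the single
#' global minimum, the alternative reading.
#'
#' @param video H x W x T array.
#' @param per_frame logical, default TRUE.
#' @return numeric vector of length T (or length 1).
#' @export
background_trace <- function(video, per_frame = TRUE) {
  stopifnot(length(dim(video)) == 3)
  if (!per_frame) return(min(video))
  nt <- dim(video)[3]
  npx <- prod(dim(video)[1:2])
  dim(video) <- c(npx, nt)
  vapply(seq_len(nt), function(t) min(video[, t]), numeric(1))
}

#' Annular ring around a soma
#'
#' Pixels whose Euclidean distance to the nearest soma pixel lies in
#' `(gap, gap + width]`, excluding pixels belonging to any soma in
#' `all_somata` and clipped to the frame.
#'
#' @param soma linear pixel indices (column-major) of the soma.
#' @param gap,width annulus geometry in px (defaults 2 and 4).
#' @param all_somata list of all soma pixel sets (for exclusion).
#' @param dim frame size `c(H, W)`.
#' @return linear pixel indices of the ring; error if empty after exclusion.
#' @export
make_ring <- function(soma, gap = 2, width = 4, all_somata = list(soma), dim) {
  stopifnot(gap >= 1, width >= 1)
  H <- dim[1]; W <- dim[2]
  sr <- (soma - 1L) %% H + 1L
  sc <- (soma - 1L) %/% H + 1L
  rmax <- gap + width
  r0 <- max(1L, min(sr) - ceiling(rmax)); r1 <- min(H, max(sr) + ceiling(rmax))
  c0 <- max(1L, min(sc) - ceiling(rmax)); c1 <- min(W, max(sc) + ceiling(rmax))
  g <- expand.grid(r = r0:r1, c = c0:c1)
  # distance to nearest soma pixel
  dmin <- sqrt(outer(g$r, sr, "-")^2 + outer(g$c, sc, "-")^2)
  dmin <- apply(dmin, 1, min)
  sel <- dmin > gap & dmin <= gap + width
  ring <- g$r[sel] + (g$c[sel] - 1L) * H
  ring <- setdiff(ring, unlist(all_somata))
  if (!length(ring)) stop("empty ring after exclusions")
  sort(ring)
}

#' ROI set container
#'
#' @param masks list of per-neuron soma linear pixel index vectors.
#' @param dim frame size `c(H, W)` in px.
#' @param px_size_um microns per pixel (default 420/512, the FOV pitch).
#' @param gap,width ring geometry passed to [make_ring()].
#' @return a `roi_set`: masks, rings, centroids (px), `px_size_um`.
#' @export
roi_set <- function(masks, dim, px_size_um = 420 / 512, gap = 2, width = 4) {
  H <- dim[1]
  centroids <- t(vapply(masks, function(px)
    c(mean((px - 1L) %% H + 1L), mean((px - 1L) %/% H + 1L)), numeric(2)))
  rings <- lapply(masks, make_ring, gap = gap, width = width,
                  all_somata = masks, dim = dim)
  out <- list(masks = masks, rings = rings, centroids = centroids, dim = dim,
              px_size_um = px_size_um)
  class(out) <- "roi_set"
  out
}

#' @export
print.roi_set <- function(x, ...) {
  cat("roi_set:", length(x$masks), "somata in a", x$dim[1], "x", x$dim[2],
      "px frame\n")
  invisible(x)
}

#' Mean soma / ring / background traces for every ROI
#'
#' @param video H x W x T array.
#' @param rois a [roi_set()].
#' @param per_frame_background passed to [background_trace()].
#' @return list of per-neuron `trace_bundle`s (`F_raw`, `F_ring`, `F_b`).
#' @export
extract_traces <- function(video, rois, per_frame_background = TRUE) {
  nt <- dim(video)[3]
  npx <- prod(dim(video)[1:2])
  dim(video) <- c(npx, nt)
  fb <- if (per_frame_background)
    vapply(seq_len(nt), function(t) min(video[, t]), numeric(1))
  else rep(min(video), nt)
  lapply(seq_along(rois$masks), function(i) {
    list(F_raw = colMeans(video[rois$masks[[i]], , drop = FALSE]),
         F_ring = colMeans(video[rois$rings[[i]], , drop = FALSE]),
         F_b = fb)
  })
}

#' Annular-ring-subtracted dF/F of one trace bundle
#'
#' @param bundle list with `F_raw`, `F_ring`, `F_b` (equal lengths).
#' @param alpha contamination degree (default 1).
#' @param convention `"ratio"` (`F_sig / F_0`, as written, baseline ~1) or
#'   `"relative"` (`(F_sig - F_0) / F_0`, baseline ~0).
#' @param neuron id used in error messages.
#' @return numeric dF/F trace.
#' @export
ars_dff <- function(bundle, alpha = 1, convention = c("ratio", "relative"),
                    neuron = NA) {
  convention <- match.arg(convention)
  stopifnot(length(bundle$F_raw) == length(bundle$F_ring))
  f_roi <- bundle$F_raw - bundle$F_b
  f_con <- bundle$F_ring - bundle$F_b
  f_sig <- f_roi - alpha * f_con
  f0 <- mean(f_roi)
  if (f0 == 0) stop("F_0 = 0 for neuron ", neuron, "; cannot normalize")
  if (convention == "ratio") f_sig / f0 else (f_sig - f0) / f0
}

#' Extract a dF/F matrix from a video
#'
#' Convenience wrapper: [extract_traces()] then [ars_dff()] per neuron.
#'
#' @inheritParams extract_traces
#' @inheritParams ars_dff
#' @param timestamps frame times; default frame index / 9.76.
#' @return a [dff_matrix()].
#' @export
video_to_dff <- function(video, rois, alpha = 1,
                         convention = c("ratio", "relative"),
                         timestamps = NULL, per_frame_background = TRUE) {
  convention <- match.arg(convention)
  bundles <- extract_traces(video, rois, per_frame_background)
  C <- t(vapply(seq_along(bundles), function(i)
    ars_dff(bundles[[i]], alpha, convention, neuron = i),
    numeric(dim(video)[3])))
  dff_matrix(C, timestamps %||% (seq_len(dim(video)[3]) - 1) / 9.76)
}

#' Match neurons across sessions
#'
#' Greedy one-to-one matching, smallest centroid distance first; a pair is
#' admissible iff (after mapping B into A's frame with `displacement`) the
#' centroid distance is below `max_dist_um` and the mask overlap (Jaccard,
#' intersection over union) exceeds `min_overlap`.
#'
#' @param roisA,roisB [roi_set()]s from the two sessions.
#' @param displacement length-2 `c(dr, dc)` in px mapping B into A's frame.
#' @param max_dist_um centroid rule, microns (default 3).
#' @param min_overlap overlap rule (default 0.75).
#' @return data.frame (a, b, dist_um, overlap); zero rows if nothing matches.
#' @export
match_across_days <- function(roisA, roisB, displacement = c(0, 0),
                              max_dist_um = 3, min_overlap = 0.75) {
  H <- roisA$dim[1]
  shift_px <- round(displacement)
  shifted <- lapply(roisB$masks, function(px) {
    r <- (px - 1L) %% H + 1L + shift_px[1]
    c <- (px - 1L) %/% H + 1L + shift_px[2]
    ok <- r >= 1 & r <= H & c >= 1 & c <= roisA$dim[2]
    r[ok] + (c[ok] - 1L) * H
  })
  centB <- sweep(roisB$centroids, 2, displacement, "+")
  cand <- list()
  for (a in seq_along(roisA$masks)) for (b in seq_along(roisB$masks)) {
    d_um <- sqrt(sum((roisA$centroids[a, ] - centB[b, ])^2)) * roisA$px_size_um
    if (d_um >= max_dist_um) next
    ov <- length(intersect(roisA$masks[[a]], shifted[[b]])) /
      length(union(roisA$masks[[a]], shifted[[b]]))
    if (ov > min_overlap)
      cand[[length(cand) + 1L]] <- data.frame(a = a, b = b, dist_um = d_um,
                                              overlap = ov)
  }
  if (!length(cand))
    return(data.frame(a = integer(), b = integer(), dist_um = numeric(),
                      overlap = numeric()))
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$dist_um), ]
  used_a <- logical(length(roisA$masks)); used_b <- logical(length(roisB$masks))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!used_a[cand$a[i]] && !used_b[cand$b[i]]) {
      keep[i] <- TRUE; used_a[cand$a[i]] <- TRUE; used_b[cand$b[i]] <- TRUE
    }
  }
  out <- cand[keep, ]
  rownames(out) <- NULL
  out
}
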