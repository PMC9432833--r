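# State-spliced pairwise correlation networks and signed weighted clustering
# coefficients.
#
# The signed clustering coefficient splits the correlation matrix into its
# positive part W+ = max(W, 0) and negative part W- = max(-W, 0) (diagonals
# zeroed) and applies, per split, the Zhang-Horvath weighted clustering
# coefficient on cube-rooted weights:
#
#   C_u = sum_{v,w} (w_uv w_vw w_wu)^(1/3)
#         / [ (sum_v w_uv^(1/3))^2 - sum_v w_uv^(2/3) ]
#
# On binary graphs this reduces to the ordinary unweighted clustering
# coefficient; scaling all weights by lambda scales every coefficient by
# lambda^(1/3). An Onnela-style variant is selectable.

#' Splice a dF/F matrix by state
#'
#' Keeps the columns (frames) where `B_state == 1`, concatenated in time
#' order.
#'
#' @param C neurons x frames matrix.
#' @param B_state binary state vector.
#' @return neurons x (active frames) matrix; error below 3 frames.
#' @export
splice_by_state <- function(C, B_state) {
  stopifnot(ncol(C) == length(B_state))
  if (sum(B_state) < 3) stop("state has fewer than 3 frames")
  C[, B_state == 1, drop = FALSE]
}

#' Pairwise Pearson correlation network
#'
#' @param spliced neurons x frames matrix (>= 3 frames).
#' @return symmetric correlation matrix with unit diagonal; rows/columns of
#'   zero-variance neurons are NA and their indices are attached as
#'   attribute `"flagged"`.
#' @export
correlation_network <- function(spliced) {
  stopifnot(ncol(spliced) >= 3)
  v <- apply(spliced, 1, stats::sd)
  flagged <- which(v == 0)
  W <- suppressWarnings(stats::cor(t(spliced)))
  W[flagged, ] <- NA_real_; W[, flagged] <- NA_real_
  diag(W) <- 1
  attr(W, "flagged") <- flagged
  W
}

zh_clustering <- function(A) {
  # A: nonnegative weights, zero diagonal, already cube-rooted
  num <- diag(A %*% A %*% A)
  s1 <- rowSums(A); s2 <- rowSums(A^2)
  den <- s1^2 - s2
  out <- ifelse(den > 0, num / den, 0)
  attr(out, "isolated") <- which(den <= 0)
  out
}

onnela_clustering <- function(A) {
  # A: nonnegative weights in [0,1], zero diagonal (normalize by max first)
  mx <- max(A)
  if (mx > 0) A <- A / mx
  Ah <- A^(1 / 3)
  num <- diag(Ah %*% Ah %*% Ah)
  k <- rowSums(A > 0)
  den <- k * (k - 1)
  ifelse(den > 0, num / den, 0)
}

#' Signed weighted clustering coefficients
#'
#' @param W symmetric correlation matrix (unit diagonal allowed; the
#'   diagonal is removed before computing). NAs are treated as absent edges.
#' @param method `"zhang"` (default, Zhang-Horvath on cube-rooted weights)
#'   or `"onnela"`.
#' @return list: `C_pos`, `C_neg` (per node, in `[0, 1]`), `mean_pos`,
#'   `mean_neg`, `method`. Isolated nodes get coefficient 0 and are flagged
#'   in `isolated_pos` / `isolated_neg`.
#' @export
signed_clustering <- function(W, method = c("zhang", "onnela")) {
  method <- match.arg(method)
  stopifnot(isSymmetric(unname(W)) || max(abs(W - t(W)), na.rm = TRUE) < 1e-12)
  W[is.na(W)] <- 0
  diag(W) <- 0
  Wp <- pmax(W, 0); Wn <- pmax(-W, 0)
  if (method == "zhang") {
    cp <- zh_clustering(Wp^(1 / 3))
    cn <- zh_clustering(Wn^(1 / 3))
  } else {
    cp <- onnela_clustering(Wp)
    cn <- onnela_clustering(Wn)
  }
  list(C_pos = as.numeric(cp), C_neg = as.numeric(cn),
       mean_pos = mean(cp), mean_neg = mean(cn),
       isolated_pos = attr(cp, "isolated") %||% integer(0),
       isolated_neg = attr(cn, "isolated") %||% integer(0),
       method = method)
}

#' State-spliced signed network of a session
#'
#' @param dff a [dff_matrix()].
#' @param B_state binary state vector (e.g. [social_vector()]).
#' @param method passed to [signed_clustering()].
#' @return list with `W` and the [signed_clustering()] output.
#' @export
state_network <- function(dff, B_state, method = "zhang") {
  W <- correlation_network(splice_by_state(dff$C, B_state))
  c(list(W = W), signed_clustering(W, method))
}
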