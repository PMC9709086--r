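#' Block-matching collaborative filtering of an interferogram
#'
#' Patch-grouping transform-domain denoiser in the block-matching 3-D
#' family: for each reference patch, similar patches are collected from a
#' local search window, stacked into a 3-D group, transformed (2-D DCT per
#' patch, 1-D orthogonal transform along the group), hard-thresholded at
#' \code{lambda * noise_sigma}, inverse-transformed and aggregated back with
#' sparsity-adaptive weights.  One-stage (hard-thresholding) variant.
#'
#' \code{noise_sigma = 0} returns the input unchanged, bit for bit.
#'
#' @param frame intensity image (matrix), counts
#' @param noise_sigma noise standard deviation, counts
#' @param patch patch side, pixels
#' @param stride reference-patch stride, pixels
#' @param search half-width of the block-matching search window, pixels
#' @param max_group maximum patches per group
#' @param lambda hard-threshold multiplier
#' @return denoised image, same dimensions
#' @export
denoise_frame <- function(frame, noise_sigma, patch = 8, stride = 4,
                          search = 12, max_group = 16, lambda = 2.7) {
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  if (noise_sigma == 0) return(frame)
  d <- dim(frame)
  if (any(d < patch)) stop("image smaller than the patch size")
  P <- patch
  # orthonormal DCT-II matrix for patches
  D <- dct_matrix(P)
  K2 <- kronecker(D, D) # 2-D DCT on vectorized patches
  ys <- unique(c(seq(1, d[1] - P + 1, by = stride), d[1] - P + 1))
  xs <- unique(c(seq(1, d[2] - P + 1, by = stride), d[2] - P + 1))
  # all candidate patch top-left corners = same lattice (search among them)
  corners <- expand.grid(y = ys, x = xs)
  np <- nrow(corners)
  pmat <- matrix(0, P * P, np)
  for (i in seq_len(np)) {
    pmat[, i] <- frame[corners$y[i]:(corners$y[i] + P - 1),
                       corners$x[i]:(corners$x[i] + P - 1)]
  }
  pdct <- K2 %*% pmat
  acc <- matrix(0, d[1], d[2])
  wgt <- matrix(0, d[1], d[2])
  thr <- lambda * noise_sigma
  for (i in seq_len(np)) {
    cy <- corners$y[i]; cx <- corners$x[i]
    cand <- which(abs(corners$y - cy) <= search & abs(corners$x - cx) <= search)
    dist <- colSums((pdct[, cand, drop = FALSE] - pdct[, i])^2) / (P * P)
    ord <- order(dist)
    g <- cand[ord[seq_len(min(max_group, length(ord)))]]
    G <- pdct[, g, drop = FALSE]
    ng <- length(g)
    if (ng > 1) {
      Dg <- dct_matrix(ng)
      S <- G %*% t(Dg)       # 1-D transform along the group dimension
      keep <- abs(S) >= thr
      keep[1, 1] <- TRUE     # always keep the group DC term
      S[!keep] <- 0
      nret <- sum(keep)
      G <- S %*% Dg
    } else {
      keep <- abs(G) >= thr
      keep[1] <- TRUE
      G[!keep] <- 0
      nret <- sum(keep)
    }
    w <- 1 / max(1, nret)
    back <- crossprod(K2, G) # inverse 2-D DCT (orthonormal)
    for (m in seq_len(ng)) {
      yy <- corners$y[g[m]]:(corners$y[g[m]] + P - 1)
      xx <- corners$x[g[m]]:(corners$x[g[m]] + P - 1)
      acc[yy, xx] <- acc[yy, xx] + w * matrix(back[, m], P, P)
      wgt[yy, xx] <- wgt[yy, xx] + w
    }
  }
  out <- frame
  covered <- wgt > 0
  out[covered] <- acc[covered] / wgt[covered]
  out
}
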