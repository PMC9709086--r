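#' @keywords internal
.dct_cache <- new.env(parent = emptyenv())

# orthonormal DCT-II matrix of size n (inverse = transpose)
dct_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.dct_cache[[key]])) return(.dct_cache[[key]])
  k <- 0:(n - 1)
  M <- sqrt(2 / n) * cos(pi * outer(k, 2 * k + 1) / (2 * n))
  M[1, ] <- M[1, ] / sqrt(2)
  .dct_cache[[key]] <- M
  M
}

dct2d <- function(x) {
  Dr <- dct_matrix(nrow(x)); Dc <- dct_matrix(ncol(x))
  Dr %*% x %*% t(Dc)
}

idct2d <- function(x) {
  Dr <- dct_matrix(nrow(x)); Dc <- dct_matrix(ncol(x))
  t(Dr) %*% x %*% Dc
}

#' Wrap phase into the principal interval
#'
#' @param phi phase values, rad
#' @return values wrapped into \code{(-pi, pi]}
#' @export
wrap_phase <- function(phi) {
  w <- phi - 2 * pi * round(phi / (2 * pi))
  w[w <= -pi] <- pi
  w
}

# wrapped forward differences along rows/cols, zero-padded at the far edge
wrapped_grads <- function(phi) {
  d <- dim(phi)
  gx <- matrix(0, d[1], d[2])
  gy <- matrix(0, d[1], d[2])
  gx[, -d[2]] <- wrap_phase(phi[, -1, drop = FALSE] -
                              phi[, -d[2], drop = FALSE])
  gy[-d[1], ] <- wrap_phase(phi[-1, , drop = FALSE] -
                              phi[-d[1], , drop = FALSE])
  list(gx = gx, gy = gy)
}

# divergence of a (gy, gx) field with Neumann conventions
div_grads <- function(gy, gx) {
  d <- dim(gx)
  rho <- gx - cbind(0, gx[, -d[2], drop = FALSE]) +
    gy - rbind(0, gy[-d[1], , drop = FALSE])
  rho
}

# unweighted least-squares Poisson solve with Neumann BC via DCT
poisson_dct_solve <- function(rho) {
  d <- dim(rho)
  R <- dct2d(rho)
  ly <- 2 * cos(pi * (0:(d[1] - 1)) / d[1]) - 2
  lx <- 2 * cos(pi * (0:(d[2] - 1)) / d[2]) - 2
  L <- outer(ly, rep(1, d[2])) + outer(rep(1, d[1]), lx)
  L[1, 1] <- 1 # zero-mean mode
  R <- R / L
  R[1, 1] <- 0
  idct2d(R)
}

#' Two-dimensional least-squares phase unwrapping (DCT-Poisson / PCG)
#'
#' Unweighted case: the wrapped phase gradients are integrated in the
#' least-squares sense by solving the discrete Poisson equation with Neumann
#' boundary conditions — forward DCT, spectral division, inverse DCT.  When
#' per-pixel quality weights below 1 are present, the weighted least-squares
#' normal equations are solved by conjugate gradients preconditioned with
#' the unweighted DCT solver (tolerance \code{tol} on the relative residual,
#' iteration cap \code{max_iter}).
#'
#' The least-squares solution is made congruent to the input (output =
#' wrapped input + exact multiples of 2*pi per pixel), so wrapping the
#' output reproduces the input everywhere.  The remaining additive constant
#' (a 2*pi multiple) is fixed by a zero-median background rule: the median
#' over \code{background} (default: the two-pixel image border, which in
#' this imaging geometry holds medium-only pixels) is brought as close to
#' zero as congruence allows.
#'
#' @param wrapped a \code{wrapped_phase} (or a bare phase matrix)
#' @param weights optional per-pixel weights in \code{[0, 1]}; defaults to
#'   the quality layer when a \code{wrapped_phase} is given, else unweighted
#' @param background logical mask of background (lowest-thickness) pixels
#'   used to anchor the constant; default: two-pixel border
#' @param tol relative residual tolerance of the PCG iteration
#' @param max_iter PCG iteration cap
#' @return an \code{unwrapped_phase}: \code{phase} (rad), \code{residual}
#'   (final solver residual norm), \code{iterations}
#' @export
unwrap_phase <- function(wrapped, weights = NULL, background = NULL,
                         tol = 1e-8, max_iter = 500) {
  if (inherits(wrapped, "wrapped_phase")) {
    phi <- wrapped$phase
    if (is.null(weights)) weights <- wrapped$quality
  } else {
    phi <- wrapped
  }
  if (any(!is.finite(phi))) stop("phase values must be finite")
  d <- dim(phi)
  g <- wrapped_grads(phi)
  use_weights <- !is.null(weights) && any(weights < 1 - 1e-12)
  if (!use_weights) {
    rho <- div_grads(g$gy, g$gx)
    sol <- poisson_dct_solve(rho)
    res <- 0; iters <- 0L
  } else {
    W <- pmin(pmax(weights, 0), 1)
    # gradient weights: minimum of the two pixel weights
    wx <- matrix(0, d[1], d[2])
    wy <- matrix(0, d[1], d[2])
    wx[, -d[2]] <- pmin(W[, -d[2], drop = FALSE], W[, -1, drop = FALSE])^2
    wy[-d[1], ] <- pmin(W[-d[1], , drop = FALSE], W[-1, , drop = FALSE])^2
    apply_Q <- function(x) {
      gg <- list(
        gx = cbind(x[, -1, drop = FALSE] - x[, -d[2], drop = FALSE], 0) * wx,
        gy = rbind(x[-1, , drop = FALSE] - x[-d[1], , drop = FALSE], 0) * wy)
      div_grads(gg$gy, gg$gx)
    }
    c_rhs <- div_grads(g$gy * wy, g$gx * wx)
    x <- matrix(0, d[1], d[2])
    r <- c_rhs
    rhs_norm <- sqrt(sum(c_rhs^2))
    if (rhs_norm == 0) rhs_norm <- 1
    z <- poisson_dct_solve(r)
    p <- z
    rz <- sum(r * z)
    iters <- 0L
    res <- sqrt(sum(r^2)) / rhs_norm
    while (res > tol && iters < max_iter) {
      Qp <- apply_Q(p)
      alpha <- rz / sum(p * Qp)
      x <- x + alpha * p
      r <- r - alpha * Qp
      res <- sqrt(sum(r^2)) / rhs_norm
      if (res <= tol) { iters <- iters + 1L; break }
      z <- poisson_dct_solve(r)
      rz_new <- sum(r * z)
      beta <- rz_new / rz
      rz <- rz_new
      p <- z + beta * p
      iters <- iters + 1L
    }
    if (res > tol) {
      stop(sprintf(
        "phase unwrapping PCG did not converge: residual %.3g after %d iterations",
        res, iters))
    }
    sol <- x
  }
  # congruence: keep the wrapped values, adopt the solver's 2*pi offsets
  out <- phi + 2 * pi * round((sol - phi) / (2 * pi))
  if (is.null(background)) {
    bg <- matrix(FALSE, d[1], d[2])
    bg[c(1:2, d[1] - 1, d[1]), ] <- TRUE
    bg[, c(1:2, d[2] - 1, d[2])] <- TRUE
    background <- bg
  }
  k0 <- round(stats::median(out[background]) / (2 * pi))
  out <- out - 2 * pi * k0
  res_obj <- list(phase = out, residual = res, iterations = iters)
  class(res_obj) <- "unwrapped_phase"
  res_obj
}

#' @export
print.unwrapped_phase <- function(x, ...) {
  cat(sprintf("<unwrapped_phase> %d x %d px  range [%.3f, %.3f] rad (residual %.2g)\n",
              nrow(x$phase), ncol(x$phase), min(x$phase), max(x$phase),
              x$residual))
  invisible(x)
}
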