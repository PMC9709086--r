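#' Stroboscopic binning of a stack
#'
#' Re-orders the acquisition into vibration-phase bins: bin \code{j}
#' (1-based) collects, from each step \code{k}, frame
#' \code{(j - 1 + s_k) mod F + 1}, so each bin holds \code{n_steps}
#' interferograms of the same vibration phase at successive reference phases
#' \code{theta_k}.  Bin \code{j} is annotated with the nominal phase
#' \code{psi_j = 2*pi*(j - 1)/F}.
#'
#' @param stack an \code{interferogram_stack}
#' @param shifts per-step cyclic shifts (e.g. from
#'   \code{\link{match_step_offset}}); default all zero
#' @return a \code{bin_set}: \code{bins} is a list of \code{F} arrays
#'   \code{[rows, cols, step]}, plus \code{psi}, \code{theta} and metadata
#' @export
bin_frames <- function(stack, shifts = NULL) {
  validate_stack(stack)
  K <- stack$plan$n_steps
  Fn <- stack$plan$frames_per_step
  if (is.null(shifts)) shifts <- rep(0L, K)
  if (is.list(shifts)) shifts <- shifts$shifts
  if (length(shifts) != K) stop("need one shift per step")
  d <- dim(stack$frames[[1]])[1:2]
  bins <- vector("list", Fn)
  for (j in seq_len(Fn)) {
    arr <- array(0, c(d[1], d[2], K))
    for (k in seq_len(K)) {
      src <- (j - 1 + shifts[k]) %% Fn + 1
      arr[, , k] <- stack$frames[[k]][, , src]
    }
    bins[[j]] <- arr
  }
  out <- list(bins = bins, psi = 2 * pi * (seq_len(Fn) - 1) / Fn,
              theta = stack$theta, shifts = as.integer(shifts),
              optics = stack$optics, n_sample = stack$n_sample,
              n_medium = stack$n_medium, pixel_pitch = stack$pixel_pitch)
  class(out) <- "bin_set"
  out
}

#' @export
print.bin_set <- function(x, ...) {
  d <- dim(x$bins[[1]])
  cat(sprintf("<bin_set> %d bins x %d frames of %d x %d px\n",
              length(x$bins), d[3], d[1], d[2]))
  invisible(x)
}

#' Undo the binning permutation
#'
#' Restores the per-step frame arrays from a \code{bin_set} (the inverse of
#' \code{\link{bin_frames}} for the same shifts); useful to verify that
#' binning is a pure permutation of the acquired frames.
#'
#' @param binset a \code{bin_set}
#' @return list over steps of \code{[rows, cols, frame]} arrays
#' @export
unbin_frames <- function(binset) {
  Fn <- length(binset$bins)
  K <- dim(binset$bins[[1]])[3]
  d <- dim(binset$bins[[1]])[1:2]
  frames <- lapply(seq_len(K), function(k) array(0, c(d[1], d[2], Fn)))
  for (j in seq_len(Fn)) {
    for (k in seq_len(K)) {
      src <- (j - 1 + binset$shifts[k]) %% Fn + 1
      frames[[k]][, , src] <- binset$bins[[j]][, , k]
    }
  }
  frames
}
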