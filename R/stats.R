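#' Coefficient of determination between observed and calculated vectors
#'
#' \deqn{R^2 = 1 - \frac{\sum_i (y_{i,obs} - y_{i,calc})^2}
#'                     {\sum_i (y_{i,obs} - \bar y)^2},\qquad
#'       \bar y = N^{-1}\sum_i y_{i,obs}.}
#' The statistic is not symmetric in its arguments: the first argument is
#' the observation being evaluated, the second the comparator.  \code{R^2 =
#' 1} iff the vectors are identical; values can be negative for poor
#' matches.
#'
#' @param observed numeric vector (must not be constant)
#' @param calculated numeric vector of the same length
#' @return a \code{comparison_result}: \code{r_squared}, \code{n},
#'   \code{y_bar}
#' @examples
#' r_squared(c(1, 2, 3), c(1.1, 1.9, 3.0))$r_squared # 0.99
#' @export
r_squared <- function(observed, calculated) {
  if (length(observed) != length(calculated)) {
    stop("observed and calculated must have equal length")
  }
  if (length(observed) < 2) stop("need at least 2 values")
  y_bar <- mean(observed)
  den <- sum((observed - y_bar)^2)
  if (den == 0) stop("observed vector is constant: zero denominator")
  r2 <- 1 - sum((observed - calculated)^2) / den
  out <- list(r_squared = r2, n = length(observed), y_bar = y_bar)
  class(out) <- "comparison_result"
  out
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> R^2 = %.4f (n = %d)\n", x$r_squared, x$n))
  invisible(x)
}

#' Shared histogram binning rule for a set of stiffness maps
#'
#' Freedman-Diaconis width computed on the pooled masked values of all maps
#' being compared, with shared edges spanning the pooled range, so any two
#' histograms of one study are comparable bin by bin.
#'
#' @param maps list of \code{stiffness_map} (or numeric vectors)
#' @param n_bins optional explicit override of the number of bins
#' @return a \code{binning_rule}: \code{edges} (Pa), \code{n_bins},
#'   \code{fingerprint} (a short hash of the edges)
#' @export
binning_rule <- function(maps, n_bins = NULL) {
  vals <- unlist(lapply(maps, map_values))
  if (!length(vals)) stop("no values to bin")
  rng <- range(vals)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5) * max(abs(rng[1]), 1)
  if (is.null(n_bins)) {
    iqr <- stats::IQR(vals)
    width <- if (iqr > 0) 2 * iqr / length(vals)^(1 / 3) else diff(rng) / 30
    n_bins <- max(5L, min(200L, ceiling(diff(rng) / width)))
  }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  out <- list(edges = edges, n_bins = n_bins,
              fingerprint = sprintf("fd-%d-%.6g-%.6g", n_bins, rng[1], rng[2]))
  class(out) <- "binning_rule"
  out
}

map_values <- function(m) {
  if (inherits(m, "stiffness_map")) m$E[m$mask]
  else if (inherits(m, "stiffness_histogram")) stop("already a histogram")
  else as.numeric(m[is.finite(m)])
}

#' Histogram of a stiffness map under a shared binning rule
#'
#' @param map a \code{stiffness_map} (masked pixels are binned) or a numeric
#'   vector
#' @param rule a \code{\link{binning_rule}}; values outside the rule's range
#'   are clamped into the edge bins so counts are conserved
#' @param normalize return frequencies summing to 1 (default) instead of
#'   counts
#' @param id source object identifier
#' @return a \code{stiffness_histogram}: \code{edges}, \code{frequencies},
#'   \code{counts}, \code{n}, \code{id}, \code{fingerprint}
#' @export
stiffness_histogram <- function(map, rule, normalize = TRUE, id = NA) {
  vals <- map_values(map)
  if (!length(vals)) stop("empty mask: nothing to histogram")
  edges <- rule$edges
  vals <- pmin(pmax(vals, edges[1]), edges[length(edges)])
  cts <- graphics::hist(vals, breaks = edges, plot = FALSE)$counts
  out <- list(edges = edges, counts = cts,
              frequencies = cts / sum(cts),
              n = length(vals), id = id, fingerprint = rule$fingerprint,
              normalized = normalize)
  class(out) <- "stiffness_histogram"
  out
}

hist_vector <- function(h) {
  if (isTRUE(h$normalized)) h$frequencies else h$counts
}

#' Pairwise coefficient-of-determination matrix between two histogram sets
#'
#' Evaluates \code{\link{r_squared}} for every (observed, calculated) pair
#' with the observed slot taken from \code{set_a}.  Both sets must share one
#' binning rule.
#'
#' @param set_a,set_b lists of \code{stiffness_histogram} built with the
#'   same \code{\link{binning_rule}}
#' @return a \code{pairwise_r2} object: \code{matrix}
#'   (\code{|set_a| x |set_b|}), \code{mean}, \code{sd}, \code{n_values}
#' @export
pairwise_r2 <- function(set_a, set_b) {
  fp <- unique(c(vapply(set_a, `[[`, character(1), "fingerprint"),
                 vapply(set_b, `[[`, character(1), "fingerprint")))
  if (length(fp) != 1) {
    stop("histograms were built with different binning rules: ",
         paste(fp, collapse = " vs "))
  }
  M <- matrix(NA_real_, length(set_a), length(set_b))
  for (i in seq_along(set_a)) {
    ya <- hist_vector(set_a[[i]])
    for (j in seq_along(set_b)) {
      M[i, j] <- r_squared(ya, hist_vector(set_b[[j]]))$r_squared
    }
  }
  out <- list(matrix = M, mean = mean(M), sd = stats::sd(as.vector(M)),
              n_values = length(M))
  class(out) <- "pairwise_r2"
  out
}

#' @export
print.pairwise_r2 <- function(x, ...) {
  cat(sprintf("<pairwise_r2> %d x %d  R^2 = %.2f +/- %.2f (%d values)\n",
              nrow(x$matrix), ncol(x$matrix), x$mean, x$sd, x$n_values))
  invisible(x)
}

#' Per-group mean/SD summaries of ensembles
#'
#' Summarizes per-object mean stiffness (and mean thickness when available)
#' for each named group: the ensemble-level mean and standard deviation of
#' the per-object means.
#'
#' @param groups named list; each element is a list of \code{stiffness_map},
#'   a list of \code{sample_scene} (ground-truth summaries), or a numeric
#'   vector of per-object values
#' @return data.frame with columns \code{group}, \code{n}, \code{mean_stiffness},
#'   \code{sd_stiffness}, \code{mean_thickness}, \code{sd_thickness}
#' @export
ensemble_summary <- function(groups) {
  if (!length(groups)) stop("no groups supplied")
  rows <- lapply(names(groups), function(nm) {
    g <- groups[[nm]]
    if (!length(g)) stop("empty group '", nm, "'")
    if (is.numeric(g)) {
      es <- g; hs <- rep(NA_real_, length(g))
    } else {
      es <- vapply(g, function(obj) {
        if (inherits(obj, "stiffness_map")) obj$summary$mean
        else if (inherits(obj, "sample_scene")) mean(obj$E_true[obj$support])
        else stop("unsupported group element")
      }, numeric(1))
      hs <- vapply(g, function(obj) {
        if (inherits(obj, "sample_scene")) max(obj$h0)
        else if (inherits(obj, "stiffness_map")) NA_real_
        else NA_real_
      }, numeric(1))
    }
    data.frame(group = nm, n = length(es),
               mean_stiffness = mean(es),
               sd_stiffness = if (length(es) > 1) stats::sd(es) else 0,
               mean_thickness = mean(hs),
               sd_thickness = if (length(hs) > 1) stats::sd(hs) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
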