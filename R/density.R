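# TF binding-density profiles: peak-to-TSS offsets, Gaussian kernel density
# estimation on a fixed grid, and Kolmogorov-Smirnov comparisons of offset
# samples.

#' Signed peak offsets to the nearest TSS
#'
#' Converts each peak to its signed distance (bp) from the nearest TSS on
#' the same chromosome (peak midpoint minus TSS).  With
#' `strand_aware = TRUE` the sign is flipped for genes on the minus strand,
#' so positive always means downstream of transcription.  Nearest-TSS ties
#' are broken toward the lower coordinate.  Offsets beyond `window` are
#' discarded, and peaks on chromosomes without genes are skipped.
#'
#' @param peaks Peak data.frame.
#' @param genes Gene table (gene_id, chrom, tss, strand).
#' @param window Half-width of the retained offset range in bp
#'   (default 50000).
#' @param strand_aware Orient offsets by the strand of the nearest gene.
#' @return Numeric vector of offsets in \[-window, window\], with attributes
#'   `tf_name` and `n_discarded`.
#' @export
relative_positions <- function(peaks, genes, window = 50000,
                               strand_aware = TRUE) {
  if (nrow(genes) == 0L) stopf("'genes' must be non-empty")
  offsets <- numeric(0)
  n_skip <- 0L
  for (ch in unique(peaks$chrom)) {
    pi <- peaks$chrom == ch
    gi <- which(genes$chrom == ch)
    if (!length(gi)) {
      n_skip <- n_skip + sum(pi)
      next
    }
    ord <- gi[order(genes$tss[gi])]
    tss <- genes$tss[ord]
    strand <- genes$strand[ord]
    mid <- (peaks$start[pi] + peaks$end[pi]) / 2
    i <- findInterval(mid, tss)
    lo <- pmax(1L, i)
    hi <- pmin(length(tss), i + 1L)
    d_lo <- abs(mid - tss[lo])
    d_hi <- abs(mid - tss[hi])
    use_lo <- i >= 1L & (i >= length(tss) | d_lo <= d_hi)  # tie -> lower
    near <- ifelse(use_lo, lo, hi)
    off <- mid - tss[near]
    if (strand_aware) off <- ifelse(strand[near] == "-", -off, off)
    offsets <- c(offsets, off)
  }
  if (n_skip > 0L)
    tfd_log("relative_positions: %d peaks on chromosomes with no genes", n_skip)
  keep <- abs(offsets) <= window
  out <- offsets[keep]
  attr(out, "tf_name") <- peaks$tf_name[1] %||% NA_character_
  attr(out, "n_discarded") <- sum(!keep) + n_skip
  out
}

#' Max-normalized Gaussian kernel density profile of peak offsets
#'
#' Estimates the binding-density profile on an evenly spaced grid over
#' \[-window, window\]: raw density at x is the mean of Gaussian kernels
#' (sd = `bandwidth`) centred at the offsets, evaluated exactly; heights
#' are divided by the maximum so the profile lies in \[0, 1\] with max 1.
#'
#' @param offsets Numeric vector of signed offsets (from
#'   [relative_positions()]).
#' @param bandwidth Gaussian kernel standard deviation in bp (default 300).
#' @param grid_step Grid spacing in bp (default 100).
#' @param window Half-width of the grid in bp (default 50000).
#' @param tf_name Label carried by the profile.
#' @return Object of class `density_profile`: list with grid, heights,
#'   bandwidth, n_points_used, tf_name.
#' @export
estimate_density <- function(offsets, bandwidth = 300, grid_step = 100,
                             window = 50000, tf_name = NULL) {
  offsets <- as.numeric(offsets)
  if (length(offsets) == 0L) stopf("no peaks in window: empty offset sample")
  grid <- seq(-window, window, by = grid_step)
  n <- length(offsets)
  heights <- numeric(length(grid))
  # exact kernel sum, chunked over offsets to bound memory
  chunk <- 2000L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    heights <- heights +
      rowSums(stats::dnorm(outer(grid, offsets[s:e], "-"), sd = bandwidth))
  }
  heights <- heights / n
  heights <- heights / max(heights)
  structure(list(tf_name = tf_name %||% attr(offsets, "tf_name"),
                 grid = grid, heights = heights, bandwidth = bandwidth,
                 n_points_used = n),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("Density profile%s: %d offsets, bandwidth %g bp, grid [%g, %g] step %g\n",
              if (is.null(x$tf_name) || is.na(x$tf_name)) ""
              else paste0(" (", x$tf_name, ")"),
              x$n_points_used, x$bandwidth, min(x$grid), max(x$grid),
              x$grid[2] - x$grid[1]))
  invisible(x)
}

#' Evaluate a density profile at arbitrary positions
#'
#' Linear interpolation between grid points; zero outside the grid.
#'
#' @param profile A `density_profile`.
#' @param x Positions (bp offsets) to evaluate at.
#' @return Numeric vector of heights in \[0, 1\].
#' @export
profile_at <- function(profile, x) {
  if (length(x) == 0L) return(numeric(0))
  approx(profile$grid, profile$heights, xout = x, yleft = 0, yright = 0)$y
}

#' Two-sample Kolmogorov-Smirnov comparison of offset samples
#'
#' D is the supremum absolute difference of the two empirical CDFs; the
#' p-value uses the asymptotic KS distribution.
#'
#' @param a,b Numeric offset vectors (non-empty).
#' @return list with statistic, p_value, n1, n2.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stopf("empty offset sample")
  kt <- suppressWarnings(ks.test(as.numeric(a), as.numeric(b),
                                 exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value),
       n1 = length(a), n2 = length(b))
}

#' One-sample KS test of absolute offsets against an exponential fit
#'
#' Fits rate = 1/mean(|offset|) and tests the absolute offsets against
#' Exponential(rate).  Because the rate is estimated from the same sample
#' the test is conservative under the null.
#'
#' @param offsets Numeric offset vector (non-empty, not all zero).
#' @return list with statistic, p_value, n, rate.
#' @export
ks_vs_exponential <- function(offsets) {
  if (length(offsets) == 0L) stopf("empty offset sample")
  a <- abs(as.numeric(offsets))
  m <- mean(a)
  if (m == 0) stopf("all offsets are zero; exponential rate undefined")
  rate <- 1 / m
  kt <- suppressWarnings(ks.test(a, "pexp", rate = rate, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value),
       n = length(a), rate = rate)
}
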