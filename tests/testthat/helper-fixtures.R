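# Shared fixture builders.  Everything is generated in code; file-based
# fixtures are written to tempfiles at test time.

make_genes <- function(tss, chrom = "chr1", strand = "+", esc = NULL,
                       eb = NULL) {
  n <- length(tss)
  df <- data.frame(gene_id = sprintf("g%03d", seq_len(n)),
                   chrom = rep_len(chrom, n), tss = tss,
                   strand = rep_len(strand, n), stringsAsFactors = FALSE)
  if (!is.null(esc)) df$ESC <- esc
  if (!is.null(eb)) df$EB <- eb
  df
}

make_peaks <- function(start, end, intensity, chrom = "chr1",
                       tf_name = "TF", fdr = NA_real_,
                       fold_enrichment = NA_real_) {
  n <- length(start)
  data.frame(chrom = rep_len(chrom, n), start = start, end = end,
             intensity = intensity, fdr = rep_len(fdr, n),
             fold_enrichment = rep_len(fold_enrichment, n),
             tf_name = rep_len(tf_name, n), stringsAsFactors = FALSE)
}

make_fragments <- function(start, length = 200, chrom = "chr1") {
  data.frame(chrom = rep_len(chrom, base::length(start)), start = start,
             end = start + length, stringsAsFactors = FALSE)
}

# A constant-height profile with a single maximum at offset 0: F(0) = 1,
# F elsewhere = height.  Convenient for exact score arithmetic.
flat_profile <- function(height = 0.5, window = 50000, step = 100) {
  grid <- seq(-window, window, by = step)
  heights <- rep(height, length(grid))
  heights[grid == 0] <- 1
  structure(list(tf_name = "TF", grid = grid, heights = heights,
                 bandwidth = 300, n_points_used = 1L),
            class = "density_profile")
}

write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# Brute-force per-base coverage peak caller (oracle for call_peaks) on a
# single chromosome of bounded length.
brute_call_peaks <- function(fragments, min_height, chrom_len) {
  cov <- integer(chrom_len)
  for (i in seq_len(nrow(fragments))) {
    s <- fragments$start[i] + 1L
    e <- min(chrom_len, fragments$end[i])
    cov[s:e] <- cov[s:e] + 1L
  }
  above <- cov >= min_height
  if (!any(above)) return(data.frame(start = numeric(0), end = numeric(0),
                                     intensity = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep] - 1,
             end = ends[keep],
             intensity = vapply(keep, function(k)
               max(cov[starts[k]:ends[k]]), integer(1)))
}

# Exhaustive two-sample KS statistic: sup |ECDF_a - ECDF_b| over the pooled
# sample points.
brute_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(p) mean(a <= p) - mean(b <= p), numeric(1))))
}
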