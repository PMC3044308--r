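# Height-based peak calling from mapped tags: tag extension to virtual
# fragments, coverage pileup, Monte-Carlo FDR per chromosome, and control
# fold-enrichment filtering.

#' Extend tags to fixed-length virtual fragments
#'
#' Each uniquely mapped tag is extended to a fragment of `fragment_length`
#' bp in its strand direction: a + tag at p covers \[p, p+L), a - tag at p
#' covers \[p-L+1, p+1).  Fragments are truncated at position 0.
#'
#' @param tags data.frame with columns chrom, pos, strand
#'   (see [read_tags()]).
#' @param fragment_length Fragment length in bp (default 200).
#' @return data.frame with columns chrom, start, end (0-based half-open).
#' @export
extend_tags <- function(tags, fragment_length = 200) {
  if (fragment_length < 1) stopf("fragment_length must be >= 1")
  L <- fragment_length
  fwd <- tags$strand == "+"
  start <- ifelse(fwd, tags$pos, tags$pos - L + 1)
  end <- ifelse(fwd, tags$pos + L, tags$pos + 1)
  start <- pmax(0, start)
  data.frame(chrom = tags$chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

# Per-chromosome coverage Rle list from a fragment data.frame.
.coverage_by_chrom <- function(fragments) {
  out <- list()
  for (ch in unique(fragments$chrom)) {
    i <- fragments$chrom == ch
    ir <- IRanges::IRanges(start = fragments$start[i] + 1L,
                           end = fragments$end[i])
    out[[ch]] <- IRanges::coverage(ir)
  }
  out
}

#' Call peaks as maximal regions of coverage above a height threshold
#'
#' A peak is a maximal interval whose fragment coverage is at least
#' `min_height` everywhere; adjacent qualifying positions merge.  Peak
#' intensity is the maximum coverage inside the region.
#'
#' @param fragments Fragments from [extend_tags()].
#' @param min_height Minimum coverage height (>= 1).
#' @param tf_name Label attached to output peaks.
#' @return Peak data.frame (chrom, start, end, intensity, fdr,
#'   fold_enrichment, tf_name); fdr/fold_enrichment are `NA` until
#'   [filter_peaks()] annotates them.
#' @export
call_peaks <- function(fragments, min_height, tf_name = "TF") {
  if (min_height < 1) stopf("min_height must be >= 1")
  covs <- .coverage_by_chrom(fragments)
  res <- lapply(names(covs), function(ch) {
    v <- IRanges::slice(covs[[ch]], lower = min_height)
    if (length(v) == 0L) return(NULL)
    data.frame(chrom = ch,
               start = IRanges::start(v) - 1,
               end = IRanges::end(v),
               intensity = as.numeric(IRanges::viewMaxs(v)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(empty_peaks(tf_name))
  res$fdr <- NA_real_
  res$fold_enrichment <- NA_real_
  res$tf_name <- tf_name
  res[order(res$chrom, res$start), , drop = FALSE]
}

# Number of maximal regions with coverage >= h, for h = 1..hmax, from a
# coverage Rle.
.peak_counts_by_height <- function(cov, hmax) {
  vapply(seq_len(hmax), function(h)
    length(IRanges::slice(cov, lower = h)), integer(1))
}

#' Monte-Carlo FDR table for height-thresholded peak calling
#'
#' Repeatedly places `n_fragments` fragments uniformly at random on a
#' chromosome of `chrom_length` bp and counts, for every height threshold h,
#' the peaks called at `min_height = h`.  The mean count over iterations is
#' the expected number of false peaks at that threshold.  When
#' `observed_counts` (observed peaks at each h on the real data) is
#' supplied, FDR(h) = expected(h) / max(1, observed(h)), monotonized so it
#' never increases with h and capped at 1; otherwise the fdr column is `NA`
#' and only expected counts are reported.
#'
#' @param n_fragments Number of fragments in the real library for this
#'   chromosome.
#' @param chrom_length Chromosome length in bp.
#' @param fragment_length Fragment length in bp.
#' @param n_iterations Monte-Carlo iterations (default 100).
#' @param seed RNG seed (required: the table is a deterministic function of
#'   its inputs).
#' @param observed_counts Optional integer vector: observed peak count at
#'   height h for h = 1, 2, ... .
#' @return data.frame with columns h, expected_false, fdr and attributes
#'   n_fragments, n_iterations, seed.
#' @export
estimate_fdr_mc <- function(n_fragments, chrom_length, fragment_length = 200,
                            n_iterations = 100, seed,
                            observed_counts = NULL) {
  if (n_iterations < 1) stopf("n_iterations must be >= 1")
  if (chrom_length <= fragment_length)
    stopf("chrom_length must exceed fragment_length")
  if (n_fragments == 0) {
    tab <- data.frame(h = 1L, expected_false = 0, fdr = NA_real_)
  } else {
    counts <- with_seed(seed, {
      lapply(seq_len(n_iterations), function(i) {
        starts <- floor(runif(n_fragments, 0, chrom_length - fragment_length + 1))
        cov <- IRanges::coverage(IRanges::IRanges(start = starts + 1L,
                                                  width = fragment_length))
        hmax <- max(S4Vectors::runValue(cov))
        .peak_counts_by_height(cov, hmax)
      })
    })
    hmax <- max(vapply(counts, length, integer(1)))
    mat <- vapply(counts, function(x) c(x, rep(0L, hmax - length(x))),
                  numeric(hmax))
    expected <- if (hmax == 1L) mean(mat) else rowMeans(mat)
    tab <- data.frame(h = seq_len(hmax), expected_false = expected,
                      fdr = NA_real_)
  }
  if (!is.null(observed_counts)) {
    obs <- observed_counts[tab$h]
    obs[is.na(obs)] <- 0
    raw <- pmin(1, tab$expected_false / pmax(1, obs))
    # enforce the non-increasing-in-h property (suffix maximum)
    tab$fdr <- rev(cummax(rev(raw)))
  }
  attr(tab, "n_fragments") <- n_fragments
  attr(tab, "n_iterations") <- n_iterations
  attr(tab, "seed") <- seed
  tab
}

# Count fragments overlapping each peak region, per chromosome.
.overlap_counts <- function(peaks, fragments) {
  n <- integer(nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    fi <- fragments$chrom == ch
    if (!any(fi)) next
    pr <- IRanges::IRanges(start = peaks$start[pi] + 1L, end = peaks$end[pi])
    fr <- IRanges::IRanges(start = fragments$start[fi] + 1L,
                           end = fragments$end[fi])
    n[pi] <- IRanges::countOverlaps(pr, fr)
  }
  n
}

#' Fold enrichment of sample over control fragments in peak regions
#'
#' For each peak: (sample fragments overlapping / sample library size)
#' divided by (control fragments overlapping / control library size).  A
#' control overlap of zero receives a +1 pseudocount so enrichment stays
#' finite.
#'
#' @param peaks Peak data.frame.
#' @param sample,control Fragment data.frames (non-empty).
#' @return Numeric vector of fold enrichments, one per peak.
#' @export
fold_enrichment <- function(peaks, sample, control) {
  if (nrow(sample) == 0L || nrow(control) == 0L)
    stopf("sample and control fragment libraries must be non-empty")
  ns <- .overlap_counts(peaks, sample)
  nc <- .overlap_counts(peaks, control)
  nc[nc == 0] <- 1
  (ns / nrow(sample)) / (nc / nrow(control))
}

# Look up FDR(intensity) for peaks on one chromosome against its table.
.fdr_lookup <- function(intensity, tab, all_peak_intensities) {
  fdr <- tab$fdr
  if (all(is.na(fdr))) {
    obs <- vapply(tab$h, function(h) sum(all_peak_intensities >= h),
                  numeric(1))
    raw <- pmin(1, tab$expected_false / pmax(1, obs))
    fdr <- rev(cummax(rev(raw)))
  }
  h <- floor(intensity)
  out <- numeric(length(h))
  above <- h > max(tab$h)       # taller than anything simulated: FDR 0
  out[above] <- 0
  idx <- match(pmax(1, pmin(h[!above], max(tab$h))), tab$h)
  out[!above] <- fdr[idx]
  out
}

#' Filter peaks by Monte-Carlo FDR and control fold enrichment
#'
#' Retains peaks whose FDR at their intensity is below `fdr_max` and whose
#' fold enrichment is at least `fold_min`; survivors carry both statistics.
#' Fold enrichment is computed from `sample`/`control` fragments when given,
#' otherwise the peaks' existing fold_enrichment column is used.
#'
#' @param peaks Peak data.frame with intensities.
#' @param fdr_table A table from [estimate_fdr_mc()], or a named list of
#'   such tables keyed by chromosome.  Tables without a populated fdr column
#'   have FDR derived using the supplied peaks as the observed counts.
#' @param fdr_max Maximum FDR (exclusive; default 0.05).
#' @param fold_min Minimum fold enrichment (inclusive; default 5).
#' @param sample,control Optional fragment data.frames for
#'   [fold_enrichment()].
#' @return The surviving peaks with fdr and fold_enrichment filled in.
#' @export
filter_peaks <- function(peaks, fdr_table, fdr_max = 0.05, fold_min = 5.0,
                         sample = NULL, control = NULL) {
  if (nrow(peaks) == 0L) return(peaks)
  if (!is.null(sample) && !is.null(control))
    peaks$fold_enrichment <- fold_enrichment(peaks, sample, control)
  if (any(is.na(peaks$fold_enrichment)) && fold_min > 0)
    stopf("peaks lack fold_enrichment; supply sample and control fragments")
  get_tab <- function(ch) {
    if (is.data.frame(fdr_table)) fdr_table
    else fdr_table[[ch]] %||% stopf("no FDR table for chromosome '%s'", ch)
  }
  fdr <- numeric(nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    i <- peaks$chrom == ch
    fdr[i] <- .fdr_lookup(peaks$intensity[i], get_tab(ch),
                          peaks$intensity[i])
  }
  peaks$fdr <- fdr
  keep <- peaks$fdr < fdr_max & peaks$fold_enrichment >= fold_min
  tfd_log("filter_peaks: %d of %d retained", sum(keep), nrow(peaks))
  peaks[keep, , drop = FALSE]
}
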