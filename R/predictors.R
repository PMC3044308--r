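# Gene x variable design matrix: density-weighted and exponentially
# weighted TF binding scores, ordinal epigenetic codings, and the
# log + quantile-normalization transform.

# All (gene, peak) pairs with peak midpoint within +/- window of the TSS,
# as signed transcription-oriented offsets.
.peak_gene_pairs <- function(genes, peaks, window, strand_aware = TRUE) {
  gene_row <- integer(0); offset <- numeric(0); intensity <- numeric(0)
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    pi <- which(peaks$chrom == ch)
    if (!length(pi)) next
    mid <- (peaks$start[pi] + peaks$end[pi]) / 2
    ord <- order(mid)
    mid <- mid[ord]
    g <- peaks$intensity[pi][ord]
    lo <- findInterval(genes$tss[gi] - window, mid, left.open = TRUE) + 1L
    hi <- findInterval(genes$tss[gi] + window, mid)
    n <- pmax(0L, hi - lo + 1L)
    keep <- n > 0L
    if (!any(keep)) next
    idx <- sequence(n[keep], from = lo[keep])
    grow <- rep(gi[keep], n[keep])
    off <- mid[idx] - genes$tss[grow]
    if (strand_aware) off <- ifelse(genes$strand[grow] == "-", -off, off)
    gene_row <- c(gene_row, grow)
    offset <- c(offset, off)
    intensity <- c(intensity, g[idx])
  }
  list(gene_row = gene_row, offset = offset, intensity = intensity)
}

#' Density-based TF binding score per gene
#'
#' For one TF, each gene's score is the sum over the TF's peaks within
#' +/- `window` bp of the gene's TSS of peak intensity times the TF's
#' normalized density profile evaluated at the peak's signed offset
#' (linear interpolation between grid points).  Genes with no peaks in
#' window score 0.
#'
#' @param genes Gene table.
#' @param peaks Peak data.frame for one TF.
#' @param profile `density_profile` for the same TF.
#' @param window Scoring window half-width in bp (default 50000).
#' @param strand_aware Orient offsets by gene strand (must match how the
#'   profile was estimated).
#' @return Numeric vector of scores, one per gene row.
#' @export
density_score <- function(genes, peaks, profile, window = 50000,
                          strand_aware = TRUE) {
  out <- numeric(nrow(genes))
  if (nrow(peaks) == 0L) return(out)
  pr <- .peak_gene_pairs(genes, peaks, window, strand_aware)
  if (!length(pr$gene_row)) return(out)
  w <- pr$intensity * profile_at(profile, pr$offset)
  agg <- rowsum(w, pr$gene_row)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Exponentially weighted TF association strength per gene
#'
#' The classical TFAS baseline: sum over peaks within the window of
#' intensity times exp(-|offset| / d0).
#'
#' @param genes Gene table.
#' @param peaks Peak data.frame for one TF.
#' @param d0 Exponential decay scale in bp (default 5000).
#' @param window Scoring window half-width in bp (default 50000).
#' @return Numeric vector of scores, one per gene row.
#' @export
exponential_score <- function(genes, peaks, d0 = 5000, window = 50000) {
  if (d0 <= 0) stopf("d0 must be positive")
  out <- numeric(nrow(genes))
  if (nrow(peaks) == 0L) return(out)
  pr <- .peak_gene_pairs(genes, peaks, window, strand_aware = FALSE)
  if (!length(pr$gene_row)) return(out)
  w <- pr$intensity * exp(-abs(pr$offset) / d0)
  agg <- rowsum(w, pr$gene_row)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Ordinal coding of the promoter histone state
#'
#' none = 1, H3K27me3 = 2, bivalent = 3, H3K4me3 = 4.
#'
#' @param state Character vector over none/K27me3/bivalent/K4me3.
#' @return Numeric codes.
#' @export
encode_histone <- function(state) {
  codes <- c(none = 1, K27me3 = 2, bivalent = 3, K4me3 = 4)
  bad <- setdiff(unique(state), names(codes))
  if (length(bad)) stopf("unknown histone state: %s", paste(bad, collapse = ", "))
  unname(codes[state])
}

#' Ordinal coding of promoter DNA methylation
#'
#' Classifies via [methylation_category()] (only high-CpG promoters with
#' GC >= 0.55 and extreme mean levels are called) and codes
#' no annotation = 1, methylated = 2, unmethylated = 3.
#'
#' @param mean_level Mean methylation in \[0, 1\] or `NA`.
#' @param gc_content Promoter GC content in \[0, 1\].
#' @return Numeric codes.
#' @export
encode_methylation <- function(mean_level, gc_content) {
  .encode_methylation_category(methylation_category(mean_level, gc_content))
}

.encode_methylation_category <- function(category) {
  codes <- c(no_annotation = 1, methylated = 2, unmethylated = 3)
  bad <- setdiff(unique(category), names(codes))
  if (length(bad))
    stopf("unknown methylation category: %s", paste(bad, collapse = ", "))
  unname(codes[category])
}

#' Binary coding of CpG-island presence
#'
#' absent = 1, present = 2.
#'
#' @param present Logical vector.
#' @return Numeric codes.
#' @export
encode_cpg <- function(present) {
  ifelse(present, 2, 1)
}

#' Assemble the gene x variable design matrix
#'
#' One column of binding scores per TF (density- or exponential-weighted),
#' plus ordinal columns HistM, Methy, CpGI when epigenetic states are
#' included.
#'
#' @param genes Gene table.
#' @param peak_sets Named list of peak data.frames, one per TF; column
#'   order follows this list.
#' @param profiles Named list of `density_profile`s (required for
#'   `scoring = "density"`).
#' @param states Epigenetic state data.frame from
#'   [read_epigenetic_annotations()]; required when
#'   `include_epigenetic = TRUE`.
#' @param scoring "density" or "exponential".
#' @param include_epigenetic Add HistM/Methy/CpGI columns.
#' @param window Scoring window half-width in bp.
#' @param d0 Decay scale for exponential scoring.
#' @param strand_aware Passed to [density_score()].
#' @return Object of class `design_matrix`: list with `values` (numeric
#'   matrix, rownames = gene ids), `score_cols`, `epi_cols`,
#'   `transform_state` ("raw").
#' @export
build_design <- function(genes, peak_sets, profiles = NULL, states = NULL,
                         scoring = c("density", "exponential"),
                         include_epigenetic = FALSE, window = 50000,
                         d0 = 5000, strand_aware = TRUE) {
  scoring <- match.arg(scoring)
  tfs <- names(peak_sets)
  cols <- lapply(tfs, function(tf) {
    if (scoring == "density") {
      if (is.null(profiles[[tf]]))
        stopf("no density profile supplied for TF '%s'", tf)
      density_score(genes, peak_sets[[tf]], profiles[[tf]], window,
                    strand_aware)
    } else {
      exponential_score(genes, peak_sets[[tf]], d0, window)
    }
  })
  values <- do.call(cbind, cols)
  if (is.null(values)) values <- matrix(numeric(0), nrow = nrow(genes))
  colnames(values) <- tfs
  epi_cols <- character(0)
  if (include_epigenetic) {
    if (is.null(states)) stopf("include_epigenetic = TRUE but no states given")
    idx <- match(genes$gene_id, states$gene_id)
    if (any(is.na(idx)))
      stopf("missing epigenetic state for gene(s): %s",
            paste(head(genes$gene_id[is.na(idx)], 5), collapse = ", "))
    st <- states[idx, ]
    values <- cbind(values,
                    HistM = encode_histone(st$histone),
                    Methy = .encode_methylation_category(st$methylation),
                    CpGI = encode_cpg(st$cpg))
    epi_cols <- c("HistM", "Methy", "CpGI")
  }
  rownames(values) <- genes$gene_id
  structure(list(values = values, score_cols = tfs, epi_cols = epi_cols,
                 transform_state = "raw"),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("Design matrix (%s): %d genes x %d variables (%d TF scores, %d epigenetic)\n",
              x$transform_state, nrow(x$values), ncol(x$values),
              length(x$score_cols), length(x$epi_cols)))
  invisible(x)
}

#' @export
as.matrix.design_matrix <- function(x, ...) x$values

#' Log-transform and quantile-normalize a design matrix
#'
#' Score columns are log-transformed (natural log of value + pseudocount)
#' and then quantile-normalized across columns: each value is replaced by
#' the mean, over all normalized columns, of the column-wise sorted values
#' at its (tie-averaged) rank.  Epigenetic code columns are left as ordinal
#' codes unless `quantile_normalize_epigenetic = TRUE`.
#'
#' @param design Raw `design_matrix`.
#' @param log_pseudocount Added before the log (default 1; scores can be 0).
#' @param quantile_normalize_epigenetic Include HistM/Methy/CpGI columns in
#'   the log + quantile step.
#' @param log Apply the log step (disable for pre-transformed inputs).
#' @return The transformed `design_matrix` (`transform_state` =
#'   "transformed").
#' @export
transform_design <- function(design, log_pseudocount = 1,
                             quantile_normalize_epigenetic = FALSE,
                             log = TRUE) {
  if (design$transform_state != "raw")
    stopf("design is already transformed")
  v <- design$values
  cols <- design$score_cols
  if (quantile_normalize_epigenetic) cols <- c(cols, design$epi_cols)
  cols <- intersect(cols, colnames(v))
  if (length(cols)) {
    sub <- v[, cols, drop = FALSE]
    if (log) sub <- base::log(sub + log_pseudocount)
    if (length(cols) > 1L)
      sub <- limma::normalizeQuantiles(sub, ties = TRUE)
    v[, cols] <- as.matrix(sub)
  }
  design$values <- v
  design$transform_state <- "transformed"
  design
}
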