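# File readers/writers and the shared genomic data model.
#
# All coordinates are 0-based, half-open ([start, end)) internally, matching
# the BED convention.  Intervals that share only an endpoint do not overlap.
# Peaks, genes, tags and epigenetic states are held as plain data.frames with
# fixed column sets so they compose with base R and IRanges directly.

PEAK_COLS <- c("chrom", "start", "end", "intensity", "fdr",
               "fold_enrichment", "tf_name")
HISTONE_LEVELS <- c("none", "K27me3", "bivalent", "K4me3")
METHYLATION_LEVELS <- c("no_annotation", "methylated", "unmethylated")

# Detect and skip a single header line in a whitespace/tab-delimited file
# whose given column should be numeric in data rows.
.has_header <- function(path, numeric_col) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return(FALSE)
  fields <- strsplit(trimws(first), "[ \t]+")[[1]]
  if (length(fields) < numeric_col) return(FALSE)
  is.na(suppressWarnings(as.numeric(fields[numeric_col])))
}

.read_delim <- function(path, header) {
  read.table(path, header = header, sep = "", stringsAsFactors = FALSE,
             comment.char = "#", quote = "")
}

#' Read a BED-like peak file
#'
#' Columns: chrom, start, end, intensity, and optionally fdr and
#' fold_enrichment.  Coordinates are taken as 0-based half-open (BED
#' standard).  A header line is detected automatically.
#'
#' @param path Path to a whitespace- or tab-delimited peak file.
#' @param tf_name Label attached to every peak (the factor the peaks belong
#'   to).
#' @return A data.frame with columns chrom, start, end, intensity, fdr,
#'   fold_enrichment, tf_name; fdr and fold_enrichment are `NA` when absent
#'   from the file.
#' @export
read_peaks <- function(path, tf_name = "TF") {
  header <- .has_header(path, 2L)
  if (length(readLines(path)) <= as.integer(header))
    return(empty_peaks(tf_name))
  df <- .read_delim(path, header)
  if (ncol(df) < 4L)
    stopf("peak file '%s' needs >= 4 columns (chrom, start, end, intensity), found %d",
          path, ncol(df))
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = suppressWarnings(as.numeric(df[[2]])),
                    end = suppressWarnings(as.numeric(df[[3]])),
                    intensity = suppressWarnings(as.numeric(df[[4]])),
                    stringsAsFactors = FALSE)
  out$fdr <- if (ncol(df) >= 5L) suppressWarnings(as.numeric(df[[5]])) else NA_real_
  out$fold_enrichment <- if (ncol(df) >= 6L)
    suppressWarnings(as.numeric(df[[6]])) else NA_real_
  out$tf_name <- tf_name
  line0 <- as.integer(header)  # offset of first data row in the file
  bad <- which(is.na(out$start) | is.na(out$end) | is.na(out$intensity))
  if (length(bad))
    stopf("peak file '%s': non-numeric coordinates/intensity at line %d",
          path, bad[1] + line0)
  bad <- which(out$start >= out$end | out$start < 0)
  if (length(bad))
    stopf("peak file '%s': invalid interval (start >= end or start < 0) at line %d",
          path, bad[1] + line0)
  bad <- which(out$intensity < 0)
  if (length(bad))
    stopf("peak file '%s': negative intensity at line %d", path, bad[1] + line0)
  bad <- which(!is.na(out$fdr) & (out$fdr < 0 | out$fdr > 1))
  if (length(bad))
    stopf("peak file '%s': fdr outside [0,1] at line %d", path, bad[1] + line0)
  tfd_log("read %d peaks for %s from %s", nrow(out), tf_name, path)
  out
}

empty_peaks <- function(tf_name = "TF") {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             intensity = numeric(), fdr = numeric(),
             fold_enrichment = numeric(), tf_name = character(),
             stringsAsFactors = FALSE)
}

#' Write peaks to a BED-like file
#'
#' Inverse of [read_peaks()]: writes chrom, start, end, intensity, fdr,
#' fold_enrichment with a header line.
#'
#' @param peaks Peak data.frame as returned by [read_peaks()].
#' @param path Output path.
#' @export
write_peaks <- function(peaks, path) {
  df <- peaks[, c("chrom", "start", "end", "intensity", "fdr",
                  "fold_enrichment")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation/expression table
#'
#' Tab-delimited with header: gene_id, chrom, tss, strand, plus one RPKM
#' column per expression condition (e.g. ESC, EB).
#'
#' @param path Path to the table.
#' @return data.frame with columns gene_id, chrom, tss, strand and the
#'   condition columns.
#' @export
read_gene_table <- function(path) {
  df <- .read_delim(path, header = TRUE)
  need <- c("gene_id", "chrom", "tss", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("gene table '%s' lacks column(s): %s", path,
          paste(miss, collapse = ", "))
  df$gene_id <- as.character(df$gene_id)
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup))
    stopf("gene table '%s': duplicated gene_id(s): %s", path,
          paste(head(dup, 5), collapse = ", "))
  df$tss <- as.numeric(df$tss)
  if (any(is.na(df$tss) | df$tss < 0))
    stopf("gene table '%s': tss must be a non-negative number", path)
  if (!all(df$strand %in% c("+", "-")))
    stopf("gene table '%s': strand must be '+' or '-'", path)
  cond <- setdiff(names(df), need)
  for (cc in cond) {
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
    if (any(is.na(df[[cc]]) | df[[cc]] < 0))
      stopf("gene table '%s': RPKM column '%s' must be non-negative", path, cc)
  }
  tfd_log("read %d genes (%d condition columns) from %s", nrow(df),
          length(cond), path)
  df
}

#' Read mapped-tag positions
#'
#' Tab-delimited columns: chrom, pos (0-based 5' mapped position), strand.
#'
#' @param path Path to the tag file.
#' @return data.frame with columns chrom, pos, strand, in file order.
#' @export
read_tags <- function(path) {
  header <- .has_header(path, 2L)
  if (length(readLines(path)) <= as.integer(header))
    return(data.frame(chrom = character(), pos = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  df <- .read_delim(path, header)
  if (ncol(df) < 3L)
    stopf("tag file '%s' needs 3 columns (chrom, pos, strand)", path)
  out <- data.frame(chrom = as.character(df[[1]]),
                    pos = suppressWarnings(as.numeric(df[[2]])),
                    strand = as.character(df[[3]]),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$pos) | out$pos < 0))
    stopf("tag file '%s': pos must be a non-negative number", path)
  bad <- which(!out$strand %in% c("+", "-"))
  if (length(bad))
    stopf("tag file '%s': malformed strand '%s' at line %d", path,
          out$strand[bad[1]], bad[1] + as.integer(header))
  out
}

# Which of the 0-based half-open query intervals overlap any subject
# interval on the same chromosome.
.overlaps_any <- function(q_chrom, q_start, q_end, subj) {
  hit <- logical(length(q_chrom))
  if (is.null(subj) || nrow(subj) == 0L || length(q_chrom) == 0L) return(hit)
  for (ch in unique(q_chrom)) {
    si <- subj$chrom == ch
    if (!any(si)) next
    qi <- which(q_chrom == ch)
    qr <- IRanges::IRanges(start = q_start[qi] + 1L, end = q_end[qi])
    sr <- IRanges::IRanges(start = subj$start[si] + 1L, end = subj$end[si])
    hit[qi] <- IRanges::overlapsAny(qr, sr)
  }
  hit
}

#' Categorise promoter DNA methylation
#'
#' Only high-CpG-density promoters (GC content >= 0.55) are classified:
#' mean methylation <= 0.25 is "unmethylated", >= 0.75 is "methylated";
#' everything else (low GC, missing level, intermediate level) is
#' "no_annotation".
#'
#' @param mean_level Mean promoter methylation in \[0, 1\], or `NA`.
#' @param gc_content Promoter GC content in \[0, 1\].
#' @return Character vector over `r METHYLATION_LEVELS`.
#' @export
methylation_category <- function(mean_level, gc_content) {
  if (any(!is.na(mean_level) & (mean_level < 0 | mean_level > 1)))
    stopf("mean_level must lie in [0, 1]")
  out <- rep("no_annotation", length(mean_level))
  classify <- !is.na(mean_level) & !is.na(gc_content) & gc_content >= 0.55
  out[classify & mean_level >= 0.75] <- "methylated"
  out[classify & mean_level <= 0.25] <- "unmethylated"
  out
}

#' Assemble per-gene promoter epigenetic states
#'
#' Overlaps each gene's promoter window (TSS +/- `promoter_halfwidth`,
#' half-open) with histone-domain and CpG-island intervals and joins mean
#' promoter methylation.  Histone state is "bivalent" when both H3K4me3 and
#' H3K27me3 domains overlap the promoter, the single overlapping mark
#' otherwise, and "none" when neither does.
#'
#' @param histone_beds Named list with elements `K4me3` and `K27me3`: paths
#'   to BED files or interval data.frames (chrom, start, end).
#' @param cpg_bed CpG-island intervals, path or data.frame.
#' @param methylation_table data.frame (or path to a tab-delimited file with
#'   header) with columns gene_id, mean_level, gc_content.  May be `NULL`.
#' @param genes Gene table as from [read_gene_table()].
#' @param promoter_halfwidth Half-width of the promoter window in bp.
#' @return data.frame with columns gene_id, histone, methylation, cpg
#'   (logical: CpG island present).
#' @export
read_epigenetic_annotations <- function(histone_beds, cpg_bed = NULL,
                                        methylation_table = NULL, genes,
                                        promoter_halfwidth = 1000) {
  as_intervals <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) {
      df <- .read_delim(x, header = .has_header(x, 2L))
      x <- data.frame(chrom = as.character(df[[1]]),
                      start = as.numeric(df[[2]]), end = as.numeric(df[[3]]),
                      stringsAsFactors = FALSE)
    }
    x
  }
  p_start <- pmax(0, genes$tss - promoter_halfwidth)
  p_end <- genes$tss + promoter_halfwidth
  k4 <- .overlaps_any(genes$chrom, p_start, p_end,
                      as_intervals(histone_beds$K4me3))
  k27 <- .overlaps_any(genes$chrom, p_start, p_end,
                       as_intervals(histone_beds$K27me3))
  histone <- rep("none", nrow(genes))
  histone[k4 & !k27] <- "K4me3"
  histone[!k4 & k27] <- "K27me3"
  histone[k4 & k27] <- "bivalent"
  cpg <- .overlaps_any(genes$chrom, p_start, p_end, as_intervals(cpg_bed))
  methylation <- rep("no_annotation", nrow(genes))
  if (!is.null(methylation_table)) {
    mt <- if (is.character(methylation_table))
      .read_delim(methylation_table, header = TRUE) else methylation_table
    idx <- match(genes$gene_id, as.character(mt$gene_id))
    methylation <- methylation_category(mt$mean_level[idx],
                                        mt$gc_content[idx])
  }
  data.frame(gene_id = genes$gene_id, histone = histone,
             methylation = methylation, cpg = cpg, stringsAsFactors = FALSE)
}
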