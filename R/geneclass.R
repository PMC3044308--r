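# Gene subset construction (ESC-specific, co-bound) and the C1/C2
# classification of genes by predicted expression, with per-class
# epigenetic summaries.

#' Select condition-specific genes by fold change
#'
#' A gene is included when (up + pc) / (down + pc) is at least `fold` or at
#' most 1/`fold`; the direction (up/down) is recorded.
#'
#' @param genes Gene table with both condition columns.
#' @param cond_up,cond_down Condition column names (default ESC over EB).
#' @param fold Fold-change threshold (default 4).
#' @param pseudocount Added to both conditions before the ratio.
#' @return data.frame with columns gene_id, direction ("up"/"down").
#' @export
select_esc_specific <- function(genes, cond_up = "ESC", cond_down = "EB",
                                fold = 4.0, pseudocount = 0.01) {
  for (cc in c(cond_up, cond_down))
    if (is.null(genes[[cc]])) stopf("gene table lacks condition '%s'", cc)
  ratio <- (genes[[cond_up]] + pseudocount) / (genes[[cond_down]] + pseudocount)
  up <- ratio >= fold
  down <- ratio <= 1 / fold
  out <- data.frame(gene_id = genes$gene_id[up | down],
                    direction = ifelse(up[up | down], "up", "down"),
                    stringsAsFactors = FALSE)
  attr(out, "fold") <- fold
  out
}

#' Genes co-bound by a TF pair
#'
#' A gene belongs to the subset when at least one peak of each factor has
#' its midpoint within +/- `window` bp of the gene's TSS.
#'
#' @param genes Gene table.
#' @param peaks_a,peaks_b Peak data.frames of the two factors.
#' @param window Half-width in bp (default 50000, the scoring window).
#' @return Character vector of gene ids.
#' @export
cobound_subset <- function(genes, peaks_a, peaks_b, window = 50000) {
  bound_by <- function(peaks) {
    hit <- logical(nrow(genes))
    pr <- .peak_gene_pairs(genes, peaks, window, strand_aware = FALSE)
    hit[unique(pr$gene_row)] <- TRUE
    hit
  }
  genes$gene_id[bound_by(peaks_a) & bound_by(peaks_b)]
}

#' Classify genes into C1/C2 by predicted expression
#'
#' C1: predicted expression at least `threshold_rpkm` (on the RPKM scale);
#' C2: the rest.  Predictions must be on the same log scale as
#' [log_expression()] (default log10 with pseudocount 0.01, so the cut sits
#' essentially at zero on the log axis).
#'
#' @param predicted Predicted log expression per gene.
#' @param threshold_rpkm Classification threshold in RPKM (default 1).
#' @param pseudocount,base Must match the expression transform.
#' @return Character vector of "C1"/"C2" labels (names preserved).
#' @export
classify_c1_c2 <- function(predicted, threshold_rpkm = 1.0,
                           pseudocount = 0.01, base = 10) {
  cut <- base::log(threshold_rpkm + pseudocount, base = base)
  out <- ifelse(predicted >= cut, "C1", "C2")
  names(out) <- names(predicted)
  out
}

#' Epigenetic category frequencies for a gene subset
#'
#' Counts and proportions of each histone category, methylation category
#' and CpG-island presence among the subset's genes.
#'
#' @param gene_ids Character vector of gene ids (a subset).
#' @param states Epigenetic state data.frame
#'   (see [read_epigenetic_annotations()]).
#' @return data.frame with columns annotation, category, count, proportion;
#'   proportions sum to 1 within each annotation type.
#' @export
epigenetic_summary <- function(gene_ids, states) {
  idx <- match(gene_ids, states$gene_id)
  if (any(is.na(idx)))
    stopf("missing epigenetic state for gene(s): %s",
          paste(head(gene_ids[is.na(idx)], 5), collapse = ", "))
  st <- states[idx, ]
  one <- function(values, levels, annotation) {
    counts <- table(factor(values, levels = levels))
    data.frame(annotation = annotation, category = names(counts),
               count = as.integer(counts),
               proportion = as.integer(counts) / length(values),
               stringsAsFactors = FALSE)
  }
  rbind(one(st$histone, HISTONE_LEVELS, "histone"),
        one(st$methylation, METHYLATION_LEVELS, "methylation"),
        one(ifelse(st$cpg, "present", "absent"), c("absent", "present"),
            "cpg"))
}
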