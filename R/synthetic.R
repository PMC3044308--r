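# Fully synthetic study generator: genome, genes, peaks with planted
# density profiles, epigenetic states, tags for the peak caller, and
# expression with planted coefficients and interaction effects.  Every
# generator is a pure function of (config, seed).

CORE_TFS <- c("Oct4", "Sox2", "Nanog", "Klf4", "Esrrb", "Tcfcp2l1", "Zfx",
              "Stat3", "Smad1", "cMyc", "nMyc")

# Per-TF offset-profile specs for the default scenario: a cycle of
# TSS-proximal and shifted Gaussian mixtures so profiles differ across TFs.
.default_profiles <- function(tfs) {
  base <- list(
    list(type = "gaussian_mixture", means = 0, sds = 2000, weights = 1),
    list(type = "gaussian_mixture", means = c(-5000, 1000),
         sds = c(2500, 1200), weights = c(0.4, 0.6)),
    list(type = "gaussian_mixture", means = c(-1500, 8000),
         sds = c(1000, 3000), weights = c(0.7, 0.3)),
    list(type = "gaussian_mixture", means = c(0, -12000),
         sds = c(1500, 4000), weights = c(0.6, 0.4)))
  setNames(base[(seq_along(tfs) - 1) %% length(base) + 1], tfs)
}

#' Simulation configuration
#'
#' Assembles the parameter set describing one synthetic study.  Defaults
#' describe the reference conditions used throughout the package's tests:
#' 2000 genes on three chromosomes, 11 TFs with 800 peaks each, log-normal
#' peak intensities, positive planted coefficients, epigenetic effects, and
#' noise calibrated to a planted R2 of 0.6.
#'
#' @param n_genes Number of genes (default 2000).
#' @param tfs Character vector of TF names (default the 11 core factors).
#' @param preset "default" (mixed Gaussian profiles; expression planted on
#'   density scores), "density-wins" (bimodal profiles at +/-10 kb),
#'   "exponential-null" (exponential offset profiles; expression planted on
#'   exponential scores).
#' @param n_peaks Peaks per TF (default 800).
#' @param coefficients Named planted coefficients, one per TF (on the
#'   transformed-score scale).
#' @param alpha,beta,gamma Planted coefficients of the histone,
#'   methylation and CpG codes.
#' @param intercept Planted intercept of log10 expression.
#' @param target_r2 Planted proportion of variance explained (noise sd is
#'   derived from the realized signal variance); ignored when `noise_sd`
#'   is given.
#' @param noise_sd Optional explicit residual sd on the log10 scale.
#' @param interactions List of planted interaction effects, each
#'   `list(members = c(...), effect = <number>)` over transformed columns.
#' @param include_epigenetic Plant and use HistM/Methy/CpGI effects.
#' @param ... Overrides for the remaining fields (window, bandwidth,
#'   grid_step, tss_spacing, peak_width, d0, intensity_meanlog,
#'   intensity_sdlog, epi_probs, expr_pseudocount, expr_base,
#'   chrom_lengths).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, tfs = CORE_TFS,
                       preset = c("default", "density-wins",
                                  "exponential-null"),
                       n_peaks = 800, coefficients = NULL, alpha = 0.30,
                       beta = 0.20, gamma = 0.15, intercept = 1.0,
                       target_r2 = 0.6, noise_sd = NULL,
                       interactions = list(), include_epigenetic = TRUE,
                       ...) {
  preset <- match.arg(preset)
  profiles <- switch(preset,
    "default" = .default_profiles(tfs),
    "density-wins" = setNames(rep(list(
      list(type = "gaussian_mixture", means = c(-10000, 10000),
           sds = c(1500, 1500), weights = c(0.5, 0.5))), length(tfs)), tfs),
    "exponential-null" = setNames(rep(list(
      list(type = "exponential", d0 = 5000)), length(tfs)), tfs))
  if (is.null(coefficients)) {
    vals <- seq(0.50, 0.05, length.out = length(tfs))
    coefficients <- setNames(vals, tfs)
  }
  cfg <- list(
    n_genes = n_genes, tfs = tfs, preset = preset, profiles = profiles,
    n_peaks = n_peaks, coefficients = coefficients, alpha = alpha,
    beta = beta, gamma = gamma, intercept = intercept,
    target_r2 = target_r2, noise_sd = noise_sd, interactions = interactions,
    include_epigenetic = include_epigenetic,
    truth_scoring = if (preset == "exponential-null") "exponential"
                    else "density",
    window = 50000, bandwidth = 300, grid_step = 100, d0 = 5000,
    tss_spacing = 20000, peak_width = 200,
    intensity_meanlog = 2, intensity_sdlog = 0.5,
    epi_probs = list(
      histone = c(none = 0.30, K27me3 = 0.15, bivalent = 0.15, K4me3 = 0.40),
      methylation = c(no_annotation = 0.40, methylated = 0.30,
                      unmethylated = 0.30),
      cpg = c(absent = 0.40, present = 0.60)),
    expr_pseudocount = 0.01, expr_base = 10,
    chrom_lengths = NULL)
  cfg <- modifyList(cfg, list(...))
  if (is.null(cfg$chrom_lengths)) {
    per <- max(150000, ceiling(cfg$n_genes * 37500 / 3))
    cfg$chrom_lengths <- setNames(rep(per, 3), paste0("chr", 1:3))
  }
  for (p in cfg$epi_probs)
    if (abs(sum(p) - 1) > 1e-8) stopf("epigenetic probabilities must sum to 1")
  if (any(cfg$chrom_lengths <= 100000))
    stopf("chromosome lengths must exceed 100 kb")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a gene annotation table
#'
#' TSSs are placed uniformly at random per chromosome subject to a minimum
#' pairwise spacing (default 20 kb) so nearest-TSS assignment is
#' unambiguous for most peaks; strands are random 50/50.
#'
#' @param config `sim_config`.
#' @param seed RNG seed.
#' @return Gene table (gene_id, chrom, tss, strand).
#' @export
simulate_genome <- function(config, seed) {
  L <- config$chrom_lengths
  n <- config$n_genes
  spacing <- config$tss_spacing
  # apportion genes to chromosomes by length (largest remainder)
  quota <- n * L / sum(L)
  n_per <- floor(quota)
  rem <- n - sum(n_per)
  if (rem > 0) {
    ord <- order(quota - n_per, decreasing = TRUE)
    n_per[ord[seq_len(rem)]] <- n_per[ord[seq_len(rem)]] + 1L
  }
  if (any(n_per * spacing > L - spacing))
    stopf("genes do not fit at %d bp spacing", spacing)
  with_seed(seed, {
    rows <- lapply(seq_along(L), function(i) {
      k <- n_per[i]
      if (k == 0) return(NULL)
      slack <- L[i] - k * spacing
      tss <- sort(runif(k, 0, slack)) + spacing * (seq_len(k) - 1) + spacing / 2
      data.frame(chrom = names(L)[i], tss = floor(tss),
                 strand = sample(c("+", "-"), k, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- data.frame(gene_id = sprintf("g%05d", seq_len(nrow(out))),
                      out, stringsAsFactors = FALSE)
    out[, c("gene_id", "chrom", "tss", "strand")]
  })
}

# Draw n offsets from a per-TF profile spec, truncated to +/- window.
.draw_offsets <- function(spec, n, window) {
  draw <- function(k) {
    if (spec$type == "exponential") {
      sample(c(-1, 1), k, replace = TRUE) * rexp(k, rate = 1 / spec$d0)
    } else {
      comp <- sample.int(length(spec$weights), k, replace = TRUE,
                         prob = spec$weights)
      rnorm(k, mean = spec$means[comp], sd = spec$sds[comp])
    }
  }
  out <- draw(n)
  bad <- abs(out) > window
  while (any(bad)) {
    out[bad] <- draw(sum(bad))
    bad <- abs(out) > window
  }
  out
}

#' Simulate per-TF peak sets with planted offset profiles
#'
#' Each peak is anchored to a random gene at an offset drawn from the TF's
#' profile spec (truncated to the window), oriented by the gene's strand,
#' with log-normal intensity, and materialized as a `peak_width` interval
#' centred on the resulting position.
#'
#' @param config `sim_config`.
#' @param genes Gene table from [simulate_genome()].
#' @param seed RNG seed.
#' @return Named list of peak data.frames, one per TF; each carries the
#'   planted offsets as attribute `true_offsets`.
#' @export
simulate_peaks <- function(config, genes, seed) {
  with_seed(seed, {
    out <- lapply(config$tfs, function(tf) {
      n <- config$n_peaks
      anchor <- sample.int(nrow(genes), n, replace = TRUE)
      off <- .draw_offsets(config$profiles[[tf]], n, config$window)
      pos <- ifelse(genes$strand[anchor] == "+",
                    genes$tss[anchor] + off, genes$tss[anchor] - off)
      start <- pmax(0, round(pos) - config$peak_width / 2)
      pk <- data.frame(chrom = genes$chrom[anchor], start = start,
                       end = start + config$peak_width,
                       intensity = rlnorm(n, config$intensity_meanlog,
                                          config$intensity_sdlog),
                       fdr = NA_real_, fold_enrichment = NA_real_,
                       tf_name = tf, stringsAsFactors = FALSE)
      pk <- pk[order(pk$chrom, pk$start), ]
      attr(pk, "true_offsets") <- off
      pk
    })
    setNames(out, config$tfs)
  })
}

#' Simulate per-gene epigenetic states
#'
#' Categories drawn independently per gene from the configured
#' probabilities.
#'
#' @param config `sim_config`.
#' @param genes Gene table.
#' @param seed RNG seed.
#' @return State data.frame (gene_id, histone, methylation, cpg).
#' @export
simulate_epigenetic_states <- function(config, genes, seed) {
  p <- config$epi_probs
  with_seed(seed, {
    n <- nrow(genes)
    data.frame(
      gene_id = genes$gene_id,
      histone = sample(names(p$histone), n, replace = TRUE,
                       prob = p$histone),
      methylation = sample(names(p$methylation), n, replace = TRUE,
                           prob = p$methylation),
      cpg = sample(c(FALSE, TRUE), n, replace = TRUE,
                   prob = p$cpg[c("absent", "present")]),
      stringsAsFactors = FALSE)
  })
}

#' Simulate expression with planted coefficients
#'
#' Log10 expression = intercept + sum of planted coefficients times the
#' design columns + planted interaction effects + Gaussian noise; RPKM =
#' base^value - pseudocount, clipped at 0.  The design passed in should be
#' the transformed design the model will later be fitted on, so that the
#' planted coefficients are recoverable.  The second condition (EB) uses an
#' independently scrambled coefficient vector so fold-change subsets are
#' non-trivial.
#'
#' @param config `sim_config`.
#' @param design Transformed `design_matrix` (or matrix) whose columns
#'   match the configured coefficient names.
#' @param seed RNG seed.
#' @return data.frame (gene_id, ESC, EB) with attribute `truth`: list with
#'   coefficients, intercept, noise_sd, y_log (noise-free ESC signal),
#'   y_esc (noisy log expression before the RPKM clip).
#' @export
simulate_expression <- function(config, design, seed) {
  X <- .design_values(design)
  coefs <- config$coefficients
  if (config$include_epigenetic)
    coefs <- c(coefs, HistM = config$alpha, Methy = config$beta,
               CpGI = config$gamma)
  miss <- setdiff(names(coefs), colnames(X))
  if (length(miss))
    stopf("design lacks column(s) for planted coefficients: %s",
          paste(miss, collapse = ", "))
  signal <- drop(X[, names(coefs), drop = FALSE] %*% coefs)
  for (ia in config$interactions) {
    col <- X[, ia$members[1]]
    for (w in ia$members[-1]) col <- col * X[, w]
    signal <- signal + ia$effect * col
  }
  noise_sd <- config$noise_sd
  if (is.null(noise_sd)) {
    r2 <- config$target_r2
    noise_sd <- sqrt(var(signal) * (1 - r2) / r2)
  }
  with_seed(seed, {
    y_esc <- config$intercept + signal + rnorm(length(signal), 0, noise_sd)
    scramble <- sample(coefs) * sample(c(-1, 1), length(coefs),
                                       replace = TRUE)
    names(scramble) <- names(coefs)
    sig_eb <- drop(X[, names(coefs), drop = FALSE] %*% scramble)
    y_eb <- config$intercept + sig_eb + rnorm(length(signal), 0, noise_sd)
    to_rpkm <- function(v)
      pmax(0, config$expr_base^v - config$expr_pseudocount)
    out <- data.frame(gene_id = rownames(X) %||% seq_along(signal),
                      ESC = to_rpkm(y_esc), EB = to_rpkm(y_eb),
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- list(coefficients = coefs,
                               intercept = config$intercept,
                               noise_sd = noise_sd,
                               y_log = config$intercept + signal,
                               y_esc = y_esc)
    out
  })
}

#' Simulate mapped tags with planted enriched loci
#'
#' Background tags are uniform over the chromosome; each planted locus
#' receives Gaussian-positioned tags so that the tag density over the locus
#' footprint (fragment length + 4 placement sd) is `enrichment` times the
#' background tag density -- the same ratio the downstream fold-enrichment
#' filter measures.  The control library is background-only at matched
#' size.
#'
#' @param chrom_length Chromosome length in bp.
#' @param n_background Background tag count.
#' @param planted_loci Numeric vector of locus centres (bp), or NULL.
#' @param enrichment Coverage enrichment of each locus over background.
#' @param locus_sd Gaussian sd of planted tag placement (bp).
#' @param fragment_length Fragment length used downstream (bp).
#' @param seed RNG seed.
#' @param chrom Chromosome name.
#' @return list with `tags`, `control` (tag data.frames) and
#'   `n_per_locus`.
#' @export
simulate_tags <- function(chrom_length = 1e6, n_background = 5000,
                          planted_loci = NULL, enrichment = 20,
                          locus_sd = 50, fragment_length = 200, seed,
                          chrom = "chr1") {
  footprint <- fragment_length + 4 * locus_sd
  bg_in_footprint <- n_background * (footprint + fragment_length) /
    chrom_length
  n_locus <- if (length(planted_loci))
    round(enrichment * bg_in_footprint) else 0L
  with_seed(seed, {
    mk_bg <- function(n) data.frame(
      chrom = chrom, pos = floor(runif(n, 0, chrom_length)),
      strand = sample(c("+", "-"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    tags <- mk_bg(n_background)
    for (locus in planted_loci) {
      strand <- sample(c("+", "-"), n_locus, replace = TRUE)
      centre <- rnorm(n_locus, locus, locus_sd)
      # place the 5' end so the extended fragment is centred on the locus
      pos <- ifelse(strand == "+", centre - fragment_length / 2,
                    centre + fragment_length / 2 - 1)
      pos <- pmax(0, pmin(chrom_length - 1, floor(pos)))
      tags <- rbind(tags, data.frame(chrom = chrom, pos = pos,
                                     strand = strand,
                                     stringsAsFactors = FALSE))
    }
    control <- mk_bg(nrow(tags))
    list(tags = tags, control = control, n_per_locus = n_locus)
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper chaining the generators: genome, peaks, epigenetic
#' states, density profiles estimated from the simulated peaks, raw and
#' transformed design matrices under both scoring methods, and expression
#' with coefficients planted on the transformed design of the preset's
#' true scoring method.
#'
#' @param n_genes Number of genes.
#' @param seed RNG seed (sub-seeds for each stage are derived from it).
#' @param preset Scenario preset, see [sim_config()].
#' @param config Optional ready-made `sim_config` (overrides `n_genes` and
#'   `preset`).
#' @param ... Passed to [sim_config()].
#' @return list with config, genes, peak_sets, states, profiles,
#'   design_density, design_exponential (both transformed), design (the
#'   truth-bearing one), expr, y (log10 ESC expression), truth.
#' @export
simulate_study <- function(n_genes = 2000, seed = 1, preset = "default",
                           config = NULL, ...) {
  cfg <- config %||% sim_config(n_genes = n_genes, preset = preset, ...)
  genes <- simulate_genome(cfg, derive_seed(seed, 1))
  peak_sets <- simulate_peaks(cfg, genes, derive_seed(seed, 2))
  states <- if (cfg$include_epigenetic)
    simulate_epigenetic_states(cfg, genes, derive_seed(seed, 3)) else NULL
  profiles <- lapply(peak_sets, function(pk) {
    off <- relative_positions(pk, genes, window = cfg$window)
    estimate_density(off, bandwidth = cfg$bandwidth,
                     grid_step = cfg$grid_step, window = cfg$window,
                     tf_name = pk$tf_name[1])
  })
  design_density <- transform_design(build_design(
    genes, peak_sets, profiles, states, scoring = "density",
    include_epigenetic = cfg$include_epigenetic, window = cfg$window))
  design_exponential <- transform_design(build_design(
    genes, peak_sets, NULL, states, scoring = "exponential",
    include_epigenetic = cfg$include_epigenetic, window = cfg$window,
    d0 = cfg$d0))
  design <- if (cfg$truth_scoring == "density") design_density
            else design_exponential
  expr <- simulate_expression(cfg, design, derive_seed(seed, 4))
  genes$ESC <- expr$ESC
  genes$EB <- expr$EB
  y <- log_expression(expr$ESC, cfg$expr_pseudocount, cfg$expr_base)
  list(config = cfg, genes = genes, peak_sets = peak_sets, states = states,
       profiles = profiles, design_density = design_density,
       design_exponential = design_exponential, design = design,
       expr = expr, y = y, truth = attr(expr, "truth"), seed = seed)
}
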