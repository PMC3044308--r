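# End-to-end workflows: prediction (profiles -> design -> regression ->
# C1/C2 classes) and interaction discovery (co-bound subsets -> saturated
# model -> greedy selection -> network), with a run manifest capturing
# config, seeds, digests and runtimes.

.load_config <- function(config) {
  if (is.character(config)) {
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yml", "yaml")) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stopf("reading YAML configs requires the yaml package")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$seed)) stopf("config must set a seed")
  config
}

# Gather inputs either from the synthetic generator or from files.
.load_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% config$seed
    do.call(simulate_study, sim_args)
  } else {
    for (key in c("genes", "peaks"))
      if (is.null(config[[key]])) stopf("config must name '%s' input", key)
    if (!all(file.exists(unlist(config$peaks))))
      stopf("missing peak file(s): %s",
            paste(unlist(config$peaks)[!file.exists(unlist(config$peaks))],
                  collapse = ", "))
    if (!file.exists(config$genes)) stopf("missing input file: %s",
                                          config$genes)
    genes <- read_gene_table(config$genes)
    peak_sets <- lapply(names(config$peaks), function(tf)
      read_peaks(config$peaks[[tf]], tf))
    names(peak_sets) <- names(config$peaks)
    states <- if (!is.null(config$states)) {
      st <- read.table(config$states, header = TRUE,
                       stringsAsFactors = FALSE)
      st$cpg <- as.logical(st$cpg)
      st
    } else NULL
    list(genes = genes, peak_sets = peak_sets, states = states,
         config = NULL)
  }
}

.manifest <- function(config, outputs, timings) {
  list(config = config,
       package_version = as.character(utils::packageVersion("tfdensity")),
       seed = config$seed,
       runtimes_sec = timings,
       outputs = lapply(outputs, function(p)
         list(path = p, md5 = unname(tools::md5sum(p)))))
}

.write_profiles <- function(profiles, path) {
  long <- do.call(rbind, lapply(names(profiles), function(tf)
    data.frame(tf = tf, grid = profiles[[tf]]$grid,
               height = profiles[[tf]]$heights)))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the expression-prediction workflow
#'
#' Estimates per-TF density profiles, builds and transforms the design
#' matrix under the requested scoring method(s), fits the regression with
#' repeated 10-fold CV (optionally AIC-stepwise reduced), classifies genes
#' into C1/C2 by predicted expression, and writes profiles, design, fit
#' summary, labels and a run manifest to `config$outdir`.
#'
#' @param config A list, or path to a YAML/JSON file, with elements:
#'   `seed` (required); either `simulate` (arguments to
#'   [simulate_study()]) or `genes`/`peaks`/`states` input paths;
#'   optionally `scoring` ("density", "exponential" or "both"),
#'   `condition` (default "ESC"), `stepwise`, `n_folds`, `n_runs`,
#'   `outdir`.
#' @return list with fits (per scoring), labels, manifest.
#' @export
run_predict_workflow <- function(config) {
  config <- .load_config(config)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage) {
    now <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(now - t0, 3)
    t0 <<- now
  }
  inp <- .load_inputs(config)
  tick("inputs")
  scoring <- config$scoring %||% "density"
  methods <- if (identical(scoring, "both")) c("density", "exponential")
             else scoring
  condition <- config$condition %||% "ESC"
  if (is.null(inp$genes[[condition]]))
    stopf("gene table lacks expression condition '%s'", condition)
  y <- log_expression(inp$genes[[condition]])
  include_epi <- !is.null(inp$states)

  if (is.null(inp$profiles) && "density" %in% methods) {
    inp$profiles <- lapply(inp$peak_sets, function(pk) {
      estimate_density(relative_positions(pk, inp$genes),
                       tf_name = pk$tf_name[1])
    })
  }
  tick("profiles")

  designs <- list()
  if ("density" %in% methods)
    designs$density <- inp$design_density %||% transform_design(build_design(
      inp$genes, inp$peak_sets, inp$profiles, inp$states,
      scoring = "density", include_epigenetic = include_epi))
  if ("exponential" %in% methods)
    designs$exponential <- inp$design_exponential %||%
      transform_design(build_design(
        inp$genes, inp$peak_sets, NULL, inp$states,
        scoring = "exponential", include_epigenetic = include_epi))
  tick("design")

  fits <- lapply(designs, function(d)
    expr_regression(d, y, n_folds = config$n_folds %||% 10,
                    n_runs = config$n_runs %||% 10, seed = config$seed,
                    stepwise = isTRUE(config$stepwise)))
  tick("fit")

  primary <- fits[[1]]
  labels <- classify_c1_c2(setNames(predict(primary), inp$genes$gene_id))
  tick("classify")

  outputs <- list()
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    od <- function(f) file.path(config$outdir, f)
    if (!is.null(inp$profiles))
      outputs$profiles <- .write_profiles(inp$profiles, od("profiles.tsv"))
    fit_json <- lapply(fits, function(f) list(
      coefficients = as.list(coef(f)), aic = f$fit$aic,
      cv_r = f$cv$cv_r, cv_r2 = f$cv$cv_r2,
      variables = f$variables))
    jsonlite::write_json(fit_json, od("fit.json"), auto_unbox = TRUE,
                         digits = NA)
    outputs$fit <- od("fit.json")
    write.table(data.frame(gene_id = names(labels), class = labels),
                od("labels.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    outputs$labels <- od("labels.tsv")
  }
  manifest <- .manifest(config, outputs, timings)
  if (!is.null(config$outdir)) {
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  tfd_log("predict workflow: %d genes, %d TFs, methods: %s",
          nrow(inp$genes), length(inp$peak_sets),
          paste(methods, collapse = "+"))
  invisible(list(fits = fits, labels = labels, manifest = manifest,
                 inputs = inp))
}

#' Run the interaction-discovery workflow
#'
#' For each requested TF pair: selects the ESC-specific genes co-bound by
#' the pair, builds the transformed design on that subset, screens all
#' pairwise and triplewise interaction terms by sequential ANOVA, greedily
#' assembles the best cross-validated model, and exports the interaction
#' network.  Pairs with too few co-bound genes are recorded as skipped.
#'
#' @param config As for [run_predict_workflow()], plus optionally `pairs`
#'   (list of 2-vectors of TF names; default all pairs), `alpha` (screen
#'   threshold, default 0.05), `min_genes` (default 50), `fold`
#'   (ESC-specific fold change, default 4).
#' @return list with per-pair results, a summary data.frame (CV-R2 with
#'   and without interactions), and the manifest.
#' @export
run_interaction_workflow <- function(config) {
  config <- .load_config(config)
  inp <- .load_inputs(config)
  tfs <- names(inp$peak_sets)
  pairs <- config$pairs %||% combn(tfs, 2, simplify = FALSE)
  alpha <- config$alpha %||% 0.05
  min_genes <- config$min_genes %||% 50
  condition <- config$condition %||% "ESC"
  esc <- select_esc_specific(inp$genes, fold = config$fold %||% 4)
  include_epi <- !is.null(inp$states)

  if (is.null(inp$profiles)) {
    inp$profiles <- lapply(inp$peak_sets, function(pk)
      estimate_density(relative_positions(pk, inp$genes),
                       tf_name = pk$tf_name[1]))
  }

  results <- list()
  summary_rows <- list()
  for (pair in pairs) {
    key <- paste(pair, collapse = ":")
    ids <- intersect(esc$gene_id,
                     cobound_subset(inp$genes, inp$peak_sets[[pair[1]]],
                                    inp$peak_sets[[pair[2]]]))
    if (length(ids) < min_genes) {
      results[[key]] <- list(skipped = TRUE, n_genes = length(ids))
      next
    }
    sub <- inp$genes[inp$genes$gene_id %in% ids, ]
    y <- log_expression(sub[[condition]])
    design <- transform_design(build_design(
      sub, inp$peak_sets, inp$profiles, inp$states, scoring = "density",
      include_epigenetic = include_epi))
    terms <- enumerate_terms(colnames(design$values))
    sat <- build_saturated_matrix(design, terms)
    screened <- anova_screen(sat, y)
    sel <- suppressWarnings(greedy_select(screened, design, y,
                                          alpha = alpha,
                                          cv_seed = config$seed))
    main_cv <- suppressWarnings(
      cross_validate(design, y, seed = config$seed))
    network <- terms_to_network(sel$terms)
    results[[key]] <- list(skipped = FALSE, n_genes = length(ids),
                           selection = sel, network = network,
                           main_cv_r2 = main_cv$cv_r2)
    summary_rows[[key]] <- data.frame(
      pair = key, n_genes = length(ids), cv_r2_main = main_cv$cv_r2,
      cv_r2_interactions = sel$cv_r2,
      n_terms = length(sel$terms), stringsAsFactors = FALSE)
  }
  summary <- if (length(summary_rows)) do.call(rbind, summary_rows)
             else data.frame()
  outputs <- list()
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    for (key in names(results)) {
      if (isTRUE(results[[key]]$skipped)) next
      safe <- gsub(":", "_", key)
      mj <- file.path(config$outdir, paste0("model_", safe, ".json"))
      sel <- results[[key]]$selection
      jsonlite::write_json(list(pair = key, terms = sel$terms,
                                cv_r2 = sel$cv_r2,
                                main_cv_r2 = results[[key]]$main_cv_r2),
                           mj, auto_unbox = TRUE, digits = NA)
      nt <- file.path(config$outdir, paste0("network_", safe, ".tsv"))
      write.table(results[[key]]$network, nt, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      outputs[[paste0("model_", safe)]] <- mj
      outputs[[paste0("network_", safe)]] <- nt
    }
    sp <- file.path(config$outdir, "summary.tsv")
    write.table(summary, sp, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs$summary <- sp
  }
  manifest <- .manifest(config, outputs, list())
  if (!is.null(config$outdir))
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(list(results = results, summary = summary, manifest = manifest))
}
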