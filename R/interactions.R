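# Higher-order interaction search: enumerate the saturated main + pairwise
# + triplewise model, screen terms by sequential ANOVA F-tests, greedily
# assemble the best cross-validated model, and export the interaction
# network.

#' Enumerate main, pairwise and triplewise terms
#'
#' All order-1 terms in input order, then all C(m,2) order-2 and C(m,3)
#' order-3 products in lexicographic order of member indices.  Term labels
#' join members with ":".
#'
#' @param main_variables Ordered character vector of variable names.
#' @return data.frame with columns term, order.
#' @export
enumerate_terms <- function(main_variables) {
  m <- length(main_variables)
  if (m < 1) stopf("need at least one variable")
  terms <- data.frame(term = main_variables, order = 1L,
                      stringsAsFactors = FALSE)
  for (ord in 2:3) {
    if (m < ord) next
    combos <- combn(main_variables, ord,
                    FUN = function(v) paste(v, collapse = ":"))
    terms <- rbind(terms, data.frame(term = combos, order = ord,
                                     stringsAsFactors = FALSE))
  }
  terms
}

#' Split term labels into their member variables
#'
#' @param term Character vector of term labels ("A", "A:B", "A:B:C").
#' @return list of character vectors of member names.
#' @export
term_members <- function(term) strsplit(term, ":", fixed = TRUE)

#' Build the saturated interaction design matrix
#'
#' One column per term: interaction columns are elementwise products of the
#' member variables' (transformed) columns.
#'
#' @param design Transformed `design_matrix` or numeric matrix.
#' @param terms data.frame from [enumerate_terms()] or a character vector
#'   of term labels.
#' @return Numeric matrix with one column per term.
#' @export
build_saturated_matrix <- function(design, terms) {
  X <- .design_values(design)
  labels <- if (is.data.frame(terms)) terms$term else terms
  members <- term_members(labels)
  unknown <- setdiff(unique(unlist(members)), colnames(X))
  if (length(unknown))
    stopf("unknown variable(s) in terms: %s", paste(unknown, collapse = ", "))
  out <- vapply(members, function(v) {
    col <- X[, v[1]]
    for (w in v[-1]) col <- col * X[, w]
    col
  }, numeric(nrow(X)))
  colnames(out) <- labels
  rownames(out) <- rownames(X)
  out
}

#' Screen saturated-model terms by sequential ANOVA F-tests
#'
#' Fits the saturated model and performs sequential (type-I) ANOVA in the
#' enumerated term order: each term's F statistic compares the residual sum
#' of squares before and after adding its column, against the final model's
#' residual mean square.  Columns aliased in the saturated fit get `NA`
#' p-values and are excluded downstream.
#'
#' @param saturated Matrix from [build_saturated_matrix()].
#' @param y Response vector.
#' @return data.frame with columns term, order, p_value, sorted as
#'   enumerated.
#' @export
anova_screen <- function(saturated, y) {
  nm <- .sanitize_names(colnames(saturated))
  df <- as.data.frame(saturated)
  colnames(df) <- nm
  df$.y <- y
  fit <- lm(.y ~ ., data = df)
  if (fit$df.residual <= 0)
    stopf("zero residual degrees of freedom; use fewer terms or more genes")
  av <- anova(fit)
  rows <- rownames(av)
  idx <- match(nm, rows)
  p <- av[["Pr(>F)"]][idx]
  dfs <- av[["Df"]][idx]
  p[!is.na(dfs) & dfs == 0] <- NA  # aliased: no df spent
  p[is.na(idx)] <- NA
  data.frame(term = colnames(saturated),
             order = lengths(term_members(colnames(saturated))),
             p_value = p, stringsAsFactors = FALSE)
}

# CV-R2 of a candidate term set (empty set = intercept-only = 0).
.cv_r2_of <- function(terms, design, y, n_folds, n_runs, cv_seed) {
  if (!length(terms)) return(0)
  M <- build_saturated_matrix(design, terms)
  suppressWarnings(cross_validate(M, y, n_folds, n_runs, cv_seed)$cv_r2)
}

#' Greedily assemble the best cross-validated interaction model
#'
#' Candidates are the screened terms with p below `alpha`, in increasing
#' p-value order.  Starting from the empty model, each candidate is
#' tentatively added and kept only if CV-R2 improves by more than
#' `min_gain`; after every kept addition each current member is tentatively
#' removed (most recent first) and the removal kept under the same rule.
#' One ordered pass; all CV evaluations share `cv_seed`.
#'
#' Because the candidates were screened on the same data the CV reuses, a
#' pure-noise term that passed the screen at level `alpha` shows an
#' apparent held-out gain of up to about chi-square(1 - alpha, 1)/n purely
#' from that selection; the default `min_gain` is exactly this
#' selection-bias allowance, so retained terms must beat what post-hoc
#' selection alone would produce.  Set `min_gain = 0` for the plain
#' strict-improvement rule.
#'
#' @param screened data.frame from [anova_screen()].
#' @param design Transformed `design_matrix` or numeric matrix of main
#'   effects.
#' @param y Response vector.
#' @param alpha Screen significance threshold (default 0.05).
#' @param cv_seed Seed shared by every CV evaluation.
#' @param n_folds,n_runs Cross-validation settings.
#' @param min_gain Minimum CV-R2 improvement to accept a move; default
#'   `qchisq(1 - alpha, 1) / length(y)`.
#' @return list with `terms` (selected labels), `cv_r2`, `cv`
#'   (`cv_result` of the final model, NULL if empty), `fit` (`ols_fit` on
#'   the selected columns, NULL if empty), `n_candidates`.
#' @export
greedy_select <- function(screened, design, y, alpha = 0.05, cv_seed = 1,
                          n_folds = 10, n_runs = 10, min_gain = NULL) {
  if (is.null(min_gain)) min_gain <- stats::qchisq(1 - alpha, 1) / length(y)
  cand <- screened[!is.na(screened$p_value) & screened$p_value < alpha, ]
  cand <- cand[order(cand$p_value), ]
  if (nrow(cand) == 0L) {
    warning("no term passes the screen; returning intercept-only model",
            call. = FALSE)
    return(list(terms = character(0), cv_r2 = 0, cv = NULL, fit = NULL,
                n_candidates = 0L))
  }
  model <- character(0)
  best <- 0
  for (term in cand$term) {
    trial <- .cv_r2_of(c(model, term), design, y, n_folds, n_runs, cv_seed)
    if (trial > best + min_gain) {
      model <- c(model, term)
      best <- trial
      # removal sweep, most recent first
      for (member in rev(model)) {
        reduced <- setdiff(model, member)
        r2 <- .cv_r2_of(reduced, design, y, n_folds, n_runs, cv_seed)
        if (r2 > best + min_gain) {
          model <- reduced
          best <- r2
        }
      }
    }
  }
  fit <- NULL
  cvres <- NULL
  if (length(model)) {
    M <- build_saturated_matrix(design, model)
    fit <- fit_ols(M, y)
    cvres <- suppressWarnings(cross_validate(M, y, n_folds, n_runs, cv_seed))
  }
  list(terms = model, cv_r2 = best, cv = cvres, fit = fit,
       n_candidates = nrow(cand))
}

#' Interaction network from selected terms
#'
#' Nodes are TFs, the epigenetic effects, and one target-gene-set node.  A
#' triplewise term A:B:C yields edges A-B, A-C, B-C plus an edge from each
#' non-epigenetic member to the target node; a pairwise term with no
#' epigenetic member yields the pair edge plus both member-target edges; a
#' pairwise term with an epigenetic member yields only the pair edge (the
#' partner is not linked to the target by that term); a main-effect term
#' yields a member-target edge.  Duplicate edges accumulate multiplicity.
#'
#' @param selected Character vector of term labels.
#' @param epigenetic_names Names treated as epigenetic effects.
#' @param target Name of the target-gene-set node.
#' @return data.frame with columns node_a, node_b, multiplicity; no
#'   self-edges.
#' @export
terms_to_network <- function(selected,
                             epigenetic_names = c("HistM", "Methy", "CpGI"),
                             target = "__geneset__") {
  edges <- character(0)
  add_edge <- function(a, b) {
    if (a == b) return()
    pair <- sort(c(a, b), method = "radix")  # locale-independent order
    edges[[length(edges) + 1]] <<- paste(pair[1], pair[2], sep = "\t")
  }
  for (members in term_members(selected)) {
    ord <- length(members)
    epi <- members %in% epigenetic_names
    if (ord == 1L) {
      add_edge(members, target)
    } else if (ord == 2L) {
      add_edge(members[1], members[2])
      if (!any(epi)) {
        add_edge(members[1], target)
        add_edge(members[2], target)
      }
    } else {
      pairs <- combn(members, 2)
      for (j in seq_len(ncol(pairs))) add_edge(pairs[1, j], pairs[2, j])
      for (m in members[!epi]) add_edge(m, target)
    }
  }
  if (!length(edges))
    return(data.frame(node_a = character(0), node_b = character(0),
                      multiplicity = integer(0), stringsAsFactors = FALSE))
  tab <- table(unlist(edges))
  parts <- strsplit(names(tab), "\t", fixed = TRUE)
  out <- data.frame(node_a = vapply(parts, `[`, "", 1),
                    node_b = vapply(parts, `[`, "", 2),
                    multiplicity = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(out$node_a, out$node_b, method = "radix"), , drop = FALSE]
}
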