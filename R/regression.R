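# Multivariate linear regression of log expression on TF binding scores
# and epigenetic codes, with repeated 10-fold cross-validation and AIC
# stepwise reduction.  The user-facing entry point is expr_regression(),
# which returns a classed fit; fit_ols/cross_validate/stepwise_select are
# the underlying operations.

# Accept a design_matrix or a plain numeric matrix.
.design_values <- function(design) {
  if (inherits(design, "design_matrix")) design$values
  else as.matrix(design)
}

# lm wants syntactic names; keep a map back to the originals.
.sanitize_names <- function(nm) {
  out <- make.names(nm, unique = TRUE)
  names(out) <- nm
  out
}

#' Log-transform expression values
#'
#' log(y + pseudocount) in the requested base.  The default pseudocount
#' 0.01 with base 10 puts 1 RPKM at (approximately) zero on the log axis,
#' which the C1/C2 classification threshold relies on.
#'
#' @param y Non-negative RPKM values.
#' @param pseudocount Positive value added before the log (default 0.01).
#' @param base Logarithm base, 10 or exp(1).
#' @return Transformed values.
#' @export
log_expression <- function(y, pseudocount = 0.01, base = 10) {
  if (pseudocount <= 0) stopf("pseudocount must be positive")
  if (any(y < 0)) stopf("expression values must be non-negative")
  base::log(y + pseudocount, base = base)
}

#' Ordinary least-squares fit of the expression model
#'
#' Fits y = intercept + sum_j w_j x_j + e by OLS.  Perfectly collinear
#' (aliased) columns are dropped and reported.  AIC is the Gaussian
#' profile-likelihood form n*log(rss/n) + 2*(k+1).
#'
#' @param design Transformed `design_matrix` or numeric matrix.
#' @param y Response vector (log expression).
#' @return Object of class `ols_fit`: coefficients, intercept, residuals,
#'   fitted, rss, aic, n, k, dropped (aliased column names), se
#'   (coefficient standard errors), lm (the underlying [stats::lm] fit).
#' @export
fit_ols <- function(design, y) {
  X <- .design_values(design)
  if (length(y) != nrow(X)) stopf("length(y) != nrow(design)")
  if (anyNA(X) || anyNA(y)) stopf("missing values are not allowed")
  nm <- .sanitize_names(colnames(X))
  df <- as.data.frame(X)
  colnames(df) <- nm
  df$.y <- y
  fit <- lm(.y ~ ., data = df)
  .as_ols_fit(fit, nm)
}

.as_ols_fit <- function(fit, name_map) {
  cf <- coef(fit)
  aliased <- names(cf)[is.na(cf)]
  cf_ok <- cf[!is.na(cf)]
  n <- length(residuals(fit))
  k <- length(cf_ok) - 1L
  if (n <= k + 1L) stopf("too few observations for %d terms", k)
  rss <- sum(residuals(fit)^2)
  back <- setNames(names(name_map), name_map)  # sanitized -> original
  rename <- function(v) {
    hit <- v %in% names(back)
    v[hit] <- back[v[hit]]
    v
  }
  se <- sqrt(diag(suppressWarnings(vcov(fit))))  # zero-residual fits warn
  names(cf_ok) <- rename(names(cf_ok))
  names(se) <- rename(names(se))
  structure(list(intercept = unname(cf_ok["(Intercept)"]),
                 coefficients = cf_ok[-1],
                 se = se,
                 residuals = unname(residuals(fit)),
                 fitted = unname(fitted(fit)),
                 rss = rss,
                 aic = n * base::log(rss / n) + 2 * (k + 1),
                 n = n, k = k,
                 dropped = rename(aliased),
                 name_map = name_map,
                 lm = fit),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit: n = %d, %d terms%s, rss = %.4g, AIC = %.2f\n",
              x$n, x$k,
              if (length(x$dropped))
                sprintf(" (%d aliased dropped)", length(x$dropped)) else "",
              x$rss, x$aic))
  invisible(x)
}

#' @export
coef.ols_fit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
predict.ols_fit <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  X <- .design_values(newdata)
  beta <- object$coefficients
  miss <- setdiff(names(beta), colnames(X))
  if (length(miss)) stopf("newdata lacks column(s): %s",
                          paste(miss, collapse = ", "))
  drop(X[, names(beta), drop = FALSE] %*% beta) + object$intercept
}

#' Repeated k-fold cross-validation of the expression model
#'
#' Per run, genes are randomly partitioned into `n_folds` folds; held-out
#' predictions are pooled across folds and the run's r is their Pearson
#' correlation with the observed values.  CV-R is the mean r over runs and
#' CV-R2 the mean squared r.  A run with constant held-out predictions
#' records r = 0 with a warning.
#'
#' @param design Transformed `design_matrix` or numeric matrix.
#' @param y Response vector.
#' @param n_folds Folds per run (default 10).
#' @param n_runs Independent runs (default 10).
#' @param seed RNG seed; identical seeds give identical folds.
#' @return Object of class `cv_result`: cv_r, cv_r2, per_run (r per run),
#'   n_folds, n_runs, seed.
#' @export
cross_validate <- function(design, y, n_folds = 10, n_runs = 10, seed = 1) {
  X <- .design_values(design)
  n <- length(y)
  if (n < 2 * n_folds) stopf("need n >= 2 * n_folds observations")
  Xi <- cbind(1, X)
  per_run <- with_seed(seed, vapply(seq_len(n_runs), function(run) {
    ord <- sample.int(n)
    sizes <- rep(n %/% n_folds, n_folds)
    extra <- n %% n_folds
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    fold <- integer(n)
    fold[ord] <- rep(seq_len(n_folds), times = sizes)
    pred <- numeric(n)
    for (f in seq_len(n_folds)) {
      test <- fold == f
      fit <- lm.fit(Xi[!test, , drop = FALSE], y[!test])
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      pred[test] <- Xi[test, , drop = FALSE] %*% beta
    }
    if (sd(pred) == 0 || sd(y) == 0) {
      warning("constant held-out predictions; recording r = 0",
              call. = FALSE)
      0
    } else cor(pred, y)
  }, numeric(1)))
  structure(list(cv_r = mean(per_run), cv_r2 = mean(per_run^2),
                 per_run = per_run, n_folds = n_folds, n_runs = n_runs,
                 seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d x %d-fold CV: CV-R = %.4f, CV-R2 = %.4f\n",
              x$n_runs, x$n_folds, x$cv_r, x$cv_r2))
  invisible(x)
}

#' AIC stepwise reduction of the main-effects model
#'
#' Starting from the full main-effects model, repeatedly applies the
#' single variable addition or removal that most decreases AIC (both
#' directions) and stops when no move improves it; this is the classical
#' backward-and-forward stepAIC procedure.
#'
#' @param design Transformed `design_matrix` or numeric matrix.
#' @param y Response vector.
#' @param direction Passed to [stats::step()] (default "both").
#' @return list with `fit` (`ols_fit` of the reduced model) and `retained`
#'   (original column names kept).
#' @export
stepwise_select <- function(design, y, direction = "both") {
  X <- .design_values(design)
  nm <- .sanitize_names(colnames(X))
  df <- as.data.frame(X)
  colnames(df) <- nm
  df$.y <- y
  full <- lm(.y ~ ., data = df)
  red <- step(full, direction = direction, trace = 0,
              scope = list(lower = .y ~ 1, upper = stats::formula(full)))
  kept_sane <- attr(stats::terms(red), "term.labels")
  back <- setNames(names(nm), nm)
  list(fit = .as_ols_fit(red, nm[nm %in% kept_sane]),
       retained = unname(back[kept_sane]))
}

#' Fit the density-based expression regression model
#'
#' The package's central fitting function: takes a design matrix of TF
#' binding scores (plus optional epigenetic codes) and log expression,
#' applies the log + quantile-normalization transform when given a raw
#' design, fits OLS, optionally reduces the model by AIC stepwise
#' selection, and evaluates repeated 10-fold cross-validation.
#'
#' @param design `design_matrix` (raw designs are transformed with default
#'   settings) or numeric matrix of ready-to-fit predictors.
#' @param y Log expression (see [log_expression()]).
#' @param cv Run cross-validation (default TRUE).
#' @param n_folds,n_runs,seed Cross-validation settings.
#' @param stepwise Reduce the model by AIC stepwise selection first.
#' @return Object of class `expr_regression` with print, summary, coef,
#'   predict, residuals, plot and simulate methods.
#' @examples
#' sim <- simulate_study(n_genes = 300, seed = 1)
#' fit <- expr_regression(sim$design, sim$y, seed = 1)
#' fit
#' @export
expr_regression <- function(design, y, cv = TRUE, n_folds = 10, n_runs = 10,
                            seed = 1, stepwise = FALSE) {
  cl <- match.call()
  if (inherits(design, "design_matrix") && design$transform_state == "raw")
    design <- transform_design(design)
  X <- .design_values(design)
  sw <- NULL
  if (stepwise) {
    sw <- stepwise_select(X, y)
    fit <- sw$fit
    Xcv <- X[, sw$retained, drop = FALSE]
  } else {
    fit <- fit_ols(X, y)
    Xcv <- X
  }
  cvres <- if (cv) cross_validate(Xcv, y, n_folds, n_runs, seed) else NULL
  structure(list(call = cl, fit = fit, cv = cvres, stepwise = sw,
                 variables = colnames(Xcv), y = y, n = length(y),
                 design = X),
            class = "expr_regression")
}

#' @export
print.expr_regression <- function(x, ...) {
  cat("Density-based expression regression\n")
  cat(sprintf("  n = %d genes, %d variables%s\n", x$n, length(x$variables),
              if (!is.null(x$stepwise)) " (after stepwise reduction)" else ""))
  r2 <- 1 - x$fit$rss / sum((x$y - mean(x$y))^2)
  cat(sprintf("  in-sample R2 = %.4f, AIC = %.2f\n", r2, x$fit$aic))
  if (!is.null(x$cv))
    cat(sprintf("  CV-R = %.4f, CV-R2 = %.4f (%d x %d-fold)\n",
                x$cv$cv_r, x$cv$cv_r2, x$cv$n_runs, x$cv$n_folds))
  invisible(x)
}

#' @export
summary.expr_regression <- function(object, ...) {
  out <- list(coefficients = coef(object$fit), se = object$fit$se,
              cv = object$cv, aic = object$fit$aic, n = object$n,
              retained = object$variables, dropped = object$fit$dropped)
  class(out) <- "summary.expr_regression"
  out
}

#' @export
print.summary.expr_regression <- function(x, ...) {
  cat("Coefficients:\n")
  print(round(x$coefficients, 4))
  if (!is.null(x$cv)) print(x$cv)
  cat(sprintf("AIC = %.2f, n = %d\n", x$aic, x$n))
  invisible(x)
}

#' @export
coef.expr_regression <- function(object, ...) coef(object$fit)

#' @export
residuals.expr_regression <- function(object, ...) object$fit$residuals

#' @export
predict.expr_regression <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fit$fitted)
  predict(object$fit, newdata)
}

#' @export
plot.expr_regression <- function(x, ...) {
  plot(x$fit$fitted, x$y, xlab = "predicted log expression",
       ylab = "observed log expression", pch = 20,
       col = grDevices::adjustcolor("steelblue", 0.5), ...)
  graphics::abline(0, 1, col = "grey40", lty = 2)
  invisible(x)
}

#' @export
simulate.expr_regression <- function(object, nsim = 1, seed = NULL, ...) {
  sigma <- sqrt(object$fit$rss / (object$n - object$fit$k - 1))
  draw <- function() object$fit$fitted + rnorm(object$n, 0, sigma)
  out <- if (is.null(seed)) replicate(nsim, draw())
         else with_seed(seed, replicate(nsim, draw()))
  as.data.frame(out)
}
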