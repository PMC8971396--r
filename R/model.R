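# Model construction: multiple logistic regression over the screened
# candidate flags with backward elimination (Wald tests) after a
# collinearity pass, presented in the classic R modelling idiom.

# variance inflation factor of each column of a 0/1 design matrix:
# 1 / (1 - R^2) from regressing it on the remaining columns
design_vif <- function(X) {
  if (ncol(X) < 2L) return(stats::setNames(rep(1, ncol(X)), colnames(X)))
  vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    1 / max(1 - r2, 1e-12)
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(colnames(X))
}

#' Fit the additive evidence model by backward elimination
#'
#' Fits a multiple logistic regression of the binary CNS-outcome label on a
#' set of binary candidate metrics, then prunes it: first any metric whose
#' variance inflation factor exceeds `vif_limit` (highest first, recomputed
#' each round), then iteratively the metric with the largest Wald p-value
#' at or above `alpha`, refitting after every removal. Metrics that
#' separate the outcome perfectly are dropped with reason `"separation"`.
#' Every retained coefficient is Wald-significant at `alpha`.
#'
#' @param formula Model formula, e.g. `cns ~ de_novo + index + ccr99 +
#'   gtex + gnomad_lof`. The response must be logical or 0/1.
#' @param data data.frame of labeled genes; rows with NA in the response or
#'   any candidate are dropped (complete-case fitting).
#' @param alpha Wald retention level, default 0.05.
#' @param vif_limit Collinearity bound, default 5.
#' @return Object of class `neuroscore_model`: `retained`, `dropped`
#'   (data.frame name/reason), `fit` (the final [stats::glm()] object, or
#'   NULL when nothing survives), `coefficients` table with log-odds, SE,
#'   Wald statistic, p, OR and CI, `baseline_odds` (exponentiated
#'   intercept), `alpha`, `vif_limit`, `n`.
#' @seealso [screen_metrics()] for the univariate pre-screen.
#' @export
neuroscore_model <- function(formula, data, alpha = 0.05, vif_limit = 5) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (is.logical(y)) y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("response must be binary (logical or 0/1)")
  terms0 <- attr(stats::terms(mf), "term.labels")
  if (!length(terms0)) stop("at least one candidate metric is required")
  X <- stats::model.matrix(stats::reformulate(terms0), mf)[, -1, drop = FALSE]
  mode(X) <- "numeric"
  colnames(X) <- terms0[match(colnames(X), colnames(X))] # 0/1 predictors: 1:1

  dropped <- data.frame(name = character(0), reason = character(0))
  drop_metric <- function(nm, why) {
    dropped <<- rbind(dropped, data.frame(name = nm, reason = why))
    X <<- X[, setdiff(colnames(X), nm), drop = FALSE]
  }

  # degenerate predictors can't enter
  for (nm in colnames(X)) if (stats::var(X[, nm]) == 0)
    drop_metric(nm, "degenerate")

  # collinearity pass
  repeat {
    if (ncol(X) < 2L) break
    v <- design_vif(X)
    if (max(v) <= vif_limit) break
    drop_metric(names(which.max(v)), "collinearity")
  }

  # backward elimination on Wald p-values
  fit <- NULL
  repeat {
    if (ncol(X) == 0L) { fit <- NULL; break }
    df <- data.frame(y = y, X, check.names = FALSE)
    fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
    cf <- summary(fit)$coefficients
    rows <- rownames(cf)[-1]
    # perfect separation shows as exploding SE
    sep <- rows[cf[-1, "Std. Error"] > 50]
    if (length(sep)) { drop_metric(sub("^`|`$", "", sep[1]), "separation"); next }
    pvals <- cf[-1, "Pr(>|z|)"]
    if (!length(pvals) || max(pvals) < alpha) break
    worst <- rows[which.max(pvals)]
    drop_metric(sub("^`|`$", "", worst), "elimination")
  }

  coefs <- NULL
  baseline_odds <- NA_real_
  if (!is.null(fit)) {
    cf <- summary(fit)$coefficients
    baseline_odds <- exp(cf["(Intercept)", "Estimate"])
    z <- stats::qnorm(0.975)
    est <- cf[-1, , drop = FALSE]
    coefs <- data.frame(
      metric = sub("^`|`$", "", rownames(est)),
      estimate = est[, "Estimate"], se = est[, "Std. Error"],
      wald_z = est[, "z value"], p = est[, "Pr(>|z|)"],
      or = exp(est[, "Estimate"]),
      ci_low = exp(est[, "Estimate"] - z * est[, "Std. Error"]),
      ci_high = exp(est[, "Estimate"] + z * est[, "Std. Error"]),
      row.names = NULL)
  }

  structure(list(
    retained = if (is.null(coefs)) character(0) else coefs$metric,
    dropped = dropped, fit = fit, coefficients = coefs,
    baseline_odds = baseline_odds, alpha = alpha, vif_limit = vif_limit,
    n = length(y), call = match.call()
  ), class = "neuroscore_model")
}

#' @export
print.neuroscore_model <- function(x, ...) {
  cat("Additive evidence model (logistic, backward elimination)\n")
  cat("  n =", x$n, " retained:", length(x$retained), " dropped:",
      nrow(x$dropped), "\n")
  if (!is.null(x$coefficients)) {
    tab <- x$coefficients
    cat(sprintf("  %-12s OR %6s  [%s, %s]  p\n", "metric", "", "lo", "hi"))
    for (i in seq_len(nrow(tab)))
      cat(sprintf("  %-12s %6.2f  [%5.2f, %5.2f]  %.2g\n", tab$metric[i],
                  tab$or[i], tab$ci_low[i], tab$ci_high[i], tab$p[i]))
  } else cat("  (no metric retained)\n")
  invisible(x)
}

#' @export
summary.neuroscore_model <- function(object, ...) {
  out <- list(model = object,
              glm_summary = if (!is.null(object$fit)) summary(object$fit))
  class(out) <- "summary.neuroscore_model"
  out
}

#' @export
print.summary.neuroscore_model <- function(x, ...) {
  print(x$model)
  if (!is.null(x$model$dropped) && nrow(x$model$dropped)) {
    cat("Dropped:\n")
    print(x$model$dropped, row.names = FALSE)
  }
  cat(sprintf("Baseline odds (intercept): %.4g\n", x$model$baseline_odds))
  invisible(x)
}

#' @export
coef.neuroscore_model <- function(object, ...) {
  if (is.null(object$coefficients)) return(numeric(0))
  stats::setNames(object$coefficients$estimate, object$coefficients$metric)
}

#' Predict CNS-association probabilities from a fitted evidence model
#'
#' @param object A [neuroscore_model()] fit.
#' @param newdata data.frame carrying the retained metric columns.
#' @param type `"response"` (probability, default) or `"link"` (log-odds).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.neuroscore_model <- function(object, newdata,
                                     type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(object$fit)) stop("model retained no metrics; nothing to predict")
  nd <- newdata[, object$retained, drop = FALSE]
  nd[] <- lapply(nd, as.numeric)
  stats::predict(object$fit, newdata = nd, type = type)
}
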