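#' Small-sample corrected Akaike Information Criterion
#'
#' Least-squares deviance form:
#' \deqn{AICc = n \log(RSS/n) + 2k + 2k(k+1)/(n-k-1)}
#' where \code{k} counts the explanatory variables under the convention of
#' the route being scored (families plus intercept for the linear route;
#' observed motif count for clustering-level selection; family count for
#' clustering family selection). No additive constant and no extra variance
#' parameter enter \code{k}, so values are comparable across routes as long
#' as one convention is used throughout.
#'
#' @param rss residual sum of squares (>= 0; a zero RSS gives \code{-Inf}).
#' @param n number of observations.
#' @param k variable count entering the penalty; requires \code{n - k - 1 > 0}.
#' @return the AICc value.
#' @examples
#' aicc(5, 20, 3)  # -20.2259
#' @export
aicc <- function(rss, n, k) {
  if (rss < 0) stop("rss must be non-negative", call. = FALSE)
  if (n - k - 1 <= 0)
    stop(sprintf("AICc correction undefined: n - k - 1 = %d <= 0", n - k - 1),
         call. = FALSE)
  if (rss == 0) return(-Inf)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

new_model_fit <- function(route, fitted, y, k, n, p = NULL,
                          coefficients = NULL, kept_families = NULL,
                          f_ratio = NA_real_, reported_df = NA_integer_,
                          residual_df = NA_integer_, extra = list()) {
  tss <- sum((y - mean(y))^2)
  rss <- sum((y - fitted)^2)
  # at the paper's limiting design (p = n - 2) the small-sample correction
  # diverges; the fit is recorded with AICc = +Inf and selection moves on
  aicc_val <- if (n - k - 1 > 0) aicc(rss, n, k) else Inf
  fit <- c(list(route = route, fitted = fitted, coefficients = coefficients,
                kept_families = kept_families,
                r2 = 1 - rss / tss, rss = rss, tss = tss,
                f_ratio = f_ratio, aicc = aicc_val, k = k, n = n,
                reported_df = reported_df, residual_df = residual_df),
           extra)
  class(fit) <- "model_fit"
  fit
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s model fit: n = %d, k = %d\n",
              ifelse(x$route == "linear", "Multi-linear", "Functional-clustering"),
              x$n, x$k))
  cat(sprintf("  R2 = %.4f  F = %.2f  AICc = %.2f\n", x$r2, x$f_ratio, x$aicc))
  if (!is.null(x$kept_families))
    cat(sprintf("  families: %d kept\n", length(x$kept_families)))
  invisible(x)
}

#' Ordinary least squares of a property on family relative abundances
#'
#' The multi-linear composition-effect route: the property is modelled as an
#' intercept plus a linear combination of the columns of \code{X} (family
#' relative abundances), without interactions. Requires \code{n > p + 1}
#' observations so the residual degrees of freedom are positive.
#'
#' @param X numeric matrix, samples x predictors.
#' @param y a \code{\link{property_vector}} or numeric vector, same length
#'   as \code{nrow(X)}.
#' @return a \code{model_fit} with route \code{"linear"}: coefficients
#'   (intercept first), fitted values, \code{r2},
#'   \code{f_ratio = (SSreg/p)/(RSS/(n-p-1))}, \code{aicc} with
#'   \code{k = p + 1}, and residual df.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("X and y differ in length", call. = FALSE)
  if (n <= p + 1)
    stop(sprintf(
      "insufficient degrees of freedom: need n > p + 1 but n = %d, p = %d",
      n, p), call. = FALSE)
  if (stats::var(y) == 0)
    stop("property is constant across samples: nothing to explain",
         call. = FALSE)
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  fitted <- fit$fitted.values
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  f_ratio <- ((tss - rss) / p) / (rss / (n - p - 1))
  new_model_fit("linear", fitted, y, k = p + 1L, n = n,
                coefficients = fit$coefficients,
                kept_families = colnames(X),
                f_ratio = f_ratio,
                residual_df = n - p - 1L,
                reported_df = n - p - 1L)
}

new_selection_trace <- function(steps, final, initial_families) {
  structure(list(steps = steps, final = final,
                 initial_families = initial_families),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("Backward selection: %d of %d families removed\n",
              sum(x$steps$accepted), length(x$initial_families)))
  print(x$final)
  invisible(x)
}

empty_steps <- function() {
  data.frame(removed = character(), reason = character(),
             aicc_before = numeric(), aicc_after = numeric(),
             kept_count = integer(), accepted = logical(),
             stringsAsFactors = FALSE)
}

#' Backward stepwise family selection for the multi-linear route
#'
#' Starting from the full model, each remaining family is tentatively
#' removed in turn and the model's AICc recomputed; the removal giving the
#' lowest AICc is accepted if it strictly improves on the current AICc,
#' and the loop repeats until no removal improves. Ties are broken by
#' family input order, so the procedure is deterministic.
#'
#' When the initial predictor count violates \code{n > p + 1}, the
#' lowest-abundance families (smallest column sums of \code{X}) are dropped
#' first until \code{p = n - 2}; these drops are recorded in the trace with
#' reason \code{"df_constraint"} and the full initial family set is kept as
#' the selection universe.
#'
#' @param X samples x families matrix of relative abundances.
#' @param y property vector.
#' @return a \code{selection_trace}: \code{steps} (one row per accepted
#'   removal plus the stopping check), \code{final} (the reduced
#'   \code{model_fit}, with \code{reported_df = p_initial - m_kept - 1}) and
#'   \code{initial_families}.
#' @export
backward_select_linear <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  n <- nrow(X)
  initial_families <- colnames(X)
  p_initial <- length(initial_families)
  steps <- empty_steps()
  keep <- initial_families
  if (n <= p_initial + 1) {
    n_drop <- p_initial - (n - 2L)
    drop <- colnames(X)[order(colSums(X), seq_len(ncol(X)),
                              method = "radix")][seq_len(n_drop)]
    for (d in drop)
      steps[nrow(steps) + 1L, ] <- list(d, "df_constraint", NA_real_,
                                        NA_real_, p_initial - match(d, drop),
                                        TRUE)
    keep <- setdiff(keep, drop)
  }
  cur <- fit_ols(X[, keep, drop = FALSE], y)
  repeat {
    if (length(keep) == 1L) break
    cand_aicc <- vapply(keep, function(fam) {
      Xr <- X[, setdiff(keep, fam), drop = FALSE]
      f <- stats::lm.fit(cbind(1, Xr), y)
      aicc(sum(f$residuals^2), n, ncol(Xr) + 1L)
    }, 0)
    best <- which.min(cand_aicc)  # first index on ties = input order
    if (cand_aicc[best] < cur$aicc) {
      steps[nrow(steps) + 1L, ] <- list(keep[best], "aicc", cur$aicc,
                                        cand_aicc[best], length(keep) - 1L,
                                        TRUE)
      keep <- keep[-best]
      cur <- fit_ols(X[, keep, drop = FALSE], y)
    } else {
      steps[nrow(steps) + 1L, ] <- list(keep[best], "stop", cur$aicc,
                                        cand_aicc[best], length(keep), FALSE)
      break
    }
  }
  cur$reported_df <- p_initial - length(keep) - 1L
  new_selection_trace(steps, cur, initial_families)
}

#' Exhaustive best-subset AICc search (test oracle)
#'
#' Enumerates all 2^p - 1 non-empty predictor subsets and returns the one
#' with minimal AICc. Intended as an independent bound for the greedy
#' backward selection on small problems.
#'
#' @param X samples x predictors matrix (\code{ncol(X) <= 15} enforced).
#' @param y property vector.
#' @return list with \code{families}, \code{aicc}.
#' @export
best_subset_aicc <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  p <- ncol(X)
  if (p > 15) stop("exhaustive search limited to p <= 15", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(p))
  n <- nrow(X)
  best <- list(families = character(), aicc = Inf)
  for (mask in seq_len(2^p - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    f <- stats::lm.fit(cbind(1, X[, sel, drop = FALSE]), y)
    a <- aicc(sum(f$residuals^2), n, length(sel) + 1L)
    if (a < best$aicc) best <- list(families = colnames(X)[sel], aicc = a)
  }
  best
}
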