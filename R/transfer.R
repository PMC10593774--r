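#' Instance-weighted transfer regression (TrAdaBoostR2)
#'
#' Learns the mapping from concatenated raw modality features to the first
#' embedding score with elastic-net base learners inside a reverse-boosting
#' transfer procedure: source and target samples are pooled, and at each
#' round poorly predicted source instances lose weight while poorly
#' predicted target instances gain weight, shifting the fit toward the
#' target domain. Prediction is the weighted median of the estimators kept
#' from the last half of the rounds.
#'
#' @name transfer
NULL

#' Elastic-net hyperparameters
#'
#' @param l1_ratio mixing between L1 and L2 penalties in `[0, 1]`
#'   (default 0.5, equal balance).
#' @param penalty_strength overall penalty weight (default 1.0).
#' @param fit_intercept fit an unpenalized intercept (default `TRUE`).
#' @export
elastic_net_params <- function(l1_ratio = 0.5, penalty_strength = 1.0,
                               fit_intercept = TRUE) {
  if (l1_ratio < 0 || l1_ratio > 1) stop("l1_ratio must lie in [0, 1]")
  if (penalty_strength < 0) stop("penalty_strength must be nonnegative")
  structure(list(l1_ratio = l1_ratio, penalty_strength = penalty_strength,
                 fit_intercept = isTRUE(fit_intercept)),
            class = "elastic_net_params")
}

#' Transfer-boosting hyperparameters
#'
#' @param n_boost number of boosting rounds `N` (default 10); estimators
#'   from the last `ceiling(N / 2)` rounds are kept for prediction.
#' @param loss adjusted-error loss: `"linear"` (default), `"square"` or
#'   `"exponential"`.
#' @param seed integer seed (reserved for the optional resampling mode; the
#'   default analytic-weight fit is deterministic).
#' @export
transfer_params <- function(n_boost = 10L, loss = c("linear", "square",
                                                    "exponential"),
                            seed = 1L) {
  n_boost <- as.integer(n_boost)
  if (n_boost < 2L) stop("n_boost must be >= 2")
  structure(list(n_boost = n_boost, loss = match.arg(loss),
                 seed = as.integer(seed)),
            class = "transfer_params")
}

#' Weighted elastic-net fit
#'
#' Minimizes the weighted elastic-net objective
#' `(1/2n) sum_i w_i (y_i - b0 - x_i' b)^2 +
#'  penalty * (l1_ratio * |b|_1 + (1 - l1_ratio)/2 * |b|_2^2)`
#' with observation weights rescaled to sum to `n` (the convention of the
#' standard solvers). Uses glmnet at the single requested penalty; a zero
#' penalty is solved exactly by weighted least squares.
#'
#' @param X n x p numeric matrix.
#' @param y numeric response vector.
#' @param sample_weights nonnegative weights with positive sum (default
#'   uniform).
#' @param params an [elastic_net_params()] object.
#' @return list with `coef` (length p) and `intercept`.
#' @export
fit_elastic_net <- function(X, y, sample_weights = NULL,
                            params = elastic_net_params()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (ncol(X) == 0L) stop("no feature columns")
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("non-finite inputs")
  if (is.null(sample_weights)) sample_weights <- rep(1, n)
  if (any(sample_weights < 0) || sum(sample_weights) <= 0)
    stop("sample weights must be nonnegative with positive sum")
  w <- sample_weights * n / sum(sample_weights)

  if (stats::sd(y) == 0) {
    return(list(coef = rep(0, ncol(X)), intercept = y[1L]))
  }
  if (params$penalty_strength == 0) {
    Xd <- if (params$fit_intercept) cbind(1, X) else X
    fit <- stats::lm.wfit(Xd, y, w)
    b <- fit$coefficients
    b[is.na(b)] <- 0
    if (params$fit_intercept)
      return(list(coef = unname(b[-1L]), intercept = unname(b[1L])))
    return(list(coef = unname(b), intercept = 0))
  }
  fit <- glmnet::glmnet(X, y, weights = w, alpha = params$l1_ratio,
                        lambda = params$penalty_strength,
                        standardize = FALSE,
                        intercept = params$fit_intercept,
                        thresh = 1e-10)
  list(coef = as.numeric(fit$beta[, 1L]),
       intercept = as.numeric(fit$a0[1L]))
}

.linear_predict <- function(est, X) as.numeric(X %*% est$coef) + est$intercept

# loss-specific adjusted errors in [0, 1]
.adjusted_error <- function(abs_err, loss) {
  emax <- max(abs_err)
  if (emax == 0) return(rep(0, length(abs_err)))
  switch(loss,
         linear = abs_err / emax,
         square = (abs_err / emax) ^ 2,
         exponential = 1 - exp(-abs_err / emax))
}

#' One reverse-boosting weight update
#'
#' Given current instance weights and a round's absolute prediction errors,
#' computes the adjusted errors, the target error rate `eps_t`, the target
#' confidence `beta_t = eps_t / (1 - eps_t)`, and updates source weights by
#' `beta_S^{e_i}` (decay) and target weights by `beta_t^{-e_i}` (growth),
#' renormalizing to the probability simplex. When `eps_t >= 0.5` the round's
#' estimator gets zero confidence (`beta_t` capped at 1) but boosting
#' continues.
#'
#' @param weights current weight vector over the pooled sample (sums to 1).
#' @param is_source logical vector marking source instances.
#' @param abs_err absolute prediction errors `|yhat - y|` for the round.
#' @param beta_source fixed source decay `1 / (1 + sqrt(2 ln n_S / N))`.
#' @param loss adjusted-error loss name.
#' @return list with updated `weights`, the round's `beta_t`, `eps_t`, the
#'   adjusted errors `e`, and `perfect` (`TRUE` when all errors were zero,
#'   signalling early termination).
#' @export
boost_round <- function(weights, is_source, abs_err, beta_source,
                        loss = "linear") {
  stopifnot(length(weights) == length(abs_err),
            length(is_source) == length(abs_err))
  e <- .adjusted_error(abs_err, loss)
  if (all(e == 0)) {
    return(list(weights = weights, beta_t = 1e-12, eps_t = 0, e = e,
                perfect = TRUE))
  }
  wt <- weights[!is_source]
  eps_t <- sum(wt * e[!is_source]) / sum(wt)
  beta_t <- if (eps_t >= 0.5) 1 else max(eps_t / (1 - eps_t), 1e-12)
  w <- weights
  w[is_source] <- w[is_source] * beta_source ^ e[is_source]
  w[!is_source] <- w[!is_source] * beta_t ^ (-e[!is_source])
  w <- w / sum(w)
  list(weights = w, beta_t = beta_t, eps_t = eps_t, e = e, perfect = FALSE)
}

#' Fit a domain-adapted regression model (TrAdaBoostR2)
#'
#' Pools source and target samples with uniform initial weights, runs
#' `n_boost` rounds of weighted elastic-net fitting followed by a
#' reverse-boosting weight update, and keeps the estimators of the last
#' `ceiling(N / 2)` rounds with confidence weights `ln(1 / beta_t)`.
#' Features are standardized with statistics of the pooled training set;
#' prediction applies the same statistics.
#'
#' @param X_source,y_source source-domain features and responses (the
#'   source may be empty, in which case the procedure reduces to boosting
#'   on the target alone).
#' @param X_target,y_target target-domain adaptation features and responses
#'   (`n >= 2`).
#' @param en an [elastic_net_params()] object.
#' @param tp a [transfer_params()] object.
#' @return object of class `tradaboost_model` with the frozen estimators,
#'   their confidence weights, the standardization statistics and the
#'   feature column order.
#' @export
tradaboost_fit <- function(X_source, y_source, X_target, y_target,
                           en = elastic_net_params(),
                           tp = transfer_params()) {
  X_source <- as.matrix(X_source)
  X_target <- as.matrix(X_target)
  if (nrow(X_source) > 0L && ncol(X_source) != ncol(X_target))
    stop("feature mismatch: source has ", ncol(X_source),
         " columns, target has ", ncol(X_target))
  if (nrow(X_source) > 0L && !is.null(colnames(X_source)) &&
      !is.null(colnames(X_target)) &&
      !identical(colnames(X_source), colnames(X_target)))
    stop("feature columns differ: ",
         paste(setdiff(colnames(X_source), colnames(X_target)),
               collapse = ", "))
  if (nrow(X_target) < 2L) stop("need at least 2 target instances")
  N <- tp$n_boost

  X <- rbind(X_source, X_target)
  y <- c(y_source, y_target)
  n_S <- nrow(X_source)
  is_source <- c(rep(TRUE, n_S), rep(FALSE, nrow(X_target)))
  Xs <- standardize_features(X)
  stats_ <- list(center = attr(Xs, "center"), scale = attr(Xs, "scale"))

  beta_source <- if (n_S > 0L) 1 / (1 + sqrt(2 * log(n_S) / N)) else 1
  w <- rep(1 / nrow(X), nrow(X))
  estimators <- vector("list", N)
  beta_t <- rep(NA_real_, N)
  n_rounds <- N
  for (t in seq_len(N)) {
    est <- fit_elastic_net(Xs, y, sample_weights = w, params = en)
    estimators[[t]] <- est
    upd <- boost_round(w, is_source, abs(.linear_predict(est, Xs) - y),
                       beta_source, loss = tp$loss)
    beta_t[t] <- upd$beta_t
    w <- upd$weights
    if (upd$perfect) { n_rounds <- t; break }
  }
  keep <- seq.int(max(1L, n_rounds - ceiling(N / 2) + 1L), n_rounds)
  est_w <- log(1 / beta_t[keep])
  if (all(est_w == 0)) est_w <- rep(1, length(keep))   # no confident round
  structure(list(estimators = estimators[keep],
                 estimator_weights = est_w,
                 beta_t = beta_t[seq_len(n_rounds)],
                 beta_source = beta_source,
                 center = stats_$center, scale = stats_$scale,
                 columns = colnames(X_target),
                 params = list(elastic_net = en, transfer = tp)),
            class = "tradaboost_model")
}

#' Weighted median of estimator predictions
#'
#' @param preds numeric vector of one subject's predictions, one per
#'   estimator.
#' @param weights nonnegative estimator confidence weights.
#' @return the first prediction, in ascending order, whose cumulative
#'   weight reaches half the total.
#' @export
weighted_median <- function(preds, weights) {
  o <- order(preds)
  cw <- cumsum(weights[o])
  preds[o][which(cw >= sum(weights) / 2)[1L]]
}

#' Predict embedding scores from a domain-adapted model
#'
#' @param object a `tradaboost_model`.
#' @param newdata n x p matrix with the training feature columns.
#' @param ... unused.
#' @return numeric vector of predicted first-embedding scores.
#' @export
predict.tradaboost_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$columns) && !is.null(colnames(X))) {
    if (!identical(colnames(X), object$columns)) {
      missing_ <- setdiff(object$columns, colnames(X))
      if (length(missing_))
        stop("missing feature column(s): ", paste(missing_, collapse = ", "))
      X <- X[, object$columns, drop = FALSE]
    }
  } else if (ncol(X) != length(object$center)) {
    stop("newdata has ", ncol(X), " columns; model expects ",
         length(object$center))
  }
  Xs <- standardize_features(X, stats = list(center = object$center,
                                             scale = object$scale))
  P <- vapply(object$estimators, function(est) .linear_predict(est, Xs),
              numeric(nrow(X)))
  P <- matrix(P, nrow = nrow(X))
  apply(P, 1L, weighted_median, weights = object$estimator_weights)
}

#' @rdname predict.tradaboost_model
#' @param model a `tradaboost_model`.
#' @param X_new feature matrix.
#' @export
tradaboost_predict <- function(model, X_new) predict(model, X_new)
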