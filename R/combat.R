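#' Parametric empirical-Bayes batch harmonization (ComBat)
#'
#' Removes additive (location) and multiplicative (scale) batch effects --
#' scanner or site differences -- from a subjects x features table. Batch
#' location and scale parameters are estimated per feature and shrunk toward
#' their batch-level means with the parametric empirical-Bayes model of
#' Johnson et al. (normal prior on locations, inverse-gamma prior on
#' variances, moment-matched hyperpriors, iterative conditional updates).
#' The fit/apply split allows a model estimated on one partition to be
#' applied to another with the same batches.
#'
#' @name combat
NULL

# moment-matched inverse-gamma hyperpriors for the batch variances
.aprior <- function(delta_hat) {
  m <- mean(delta_hat); s2 <- stats::var(delta_hat)
  (2 * s2 + m ^ 2) / s2
}
.bprior <- function(delta_hat) {
  m <- mean(delta_hat); s2 <- stats::var(delta_hat)
  (m * s2 + m ^ 3) / s2
}

# iterative conditional posterior updates for one batch (vectors over features)
.eb_solve <- function(z_bar, delta_hat, n_b, gamma_bar, tau2, a, b,
                      conv = 1e-6) {
  g_old <- z_bar
  d_old <- delta_hat
  repeat {
    g_new <- (n_b * tau2 * z_bar + d_old * gamma_bar) / (n_b * tau2 + d_old)
    sum2 <- delta_hat * (n_b - 1) + n_b * (z_bar - g_new) ^ 2
    d_new <- (0.5 * sum2 + b) / (n_b / 2 + a - 1)
    change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                  abs(d_new - d_old) / d_old)
    g_old <- g_new
    d_old <- d_new
    if (change < conv) break
  }
  list(gamma_star = g_new, delta_star = d_new)
}

#' Fit a ComBat harmonization model
#'
#' @param values subjects x features numeric matrix.
#' @param batches factor or character vector of batch (site/scanner) labels,
#'   one per subject; every batch needs at least 2 subjects and there must
#'   be at least 2 batches.
#' @return object of class `combat_model` carrying pooled per-feature
#'   mean/variance and EB-shrunk per-batch location (`gamma_star`) and
#'   variance (`delta_star`) parameters.
#' @export
combat_fit <- function(values, batches) {
  X <- as.matrix(values)
  batches <- as.character(batches)
  if (length(batches) != nrow(X)) stop("one batch label per subject required")
  tab <- table(batches)
  if (length(tab) < 2L) stop("need at least 2 batches")
  if (any(tab < 2L))
    stop("batch(es) with < 2 subjects: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  zv <- apply(X, 2L, stats::var) == 0
  if (any(zv))
    stop("zero-variance feature(s): ",
         paste(colnames(X)[zv], collapse = ", "))

  levels_b <- sort(names(tab))
  n <- nrow(X)
  n_b <- as.numeric(tab[levels_b])
  # per-batch means, and the grand mean as their sample-size-weighted average
  bmeans <- t(vapply(levels_b, function(b) colMeans(X[batches == b, , drop = FALSE]),
                     numeric(ncol(X))))
  grand <- colSums(bmeans * n_b) / n
  resid <- X - bmeans[match(batches, levels_b), , drop = FALSE]
  var_pooled <- colSums(resid ^ 2) / n
  sd_pooled <- sqrt(var_pooled)

  Z <- sweep(sweep(X, 2L, grand), 2L, sd_pooled, "/")
  gamma_hat <- t(vapply(levels_b, function(b) colMeans(Z[batches == b, , drop = FALSE]),
                        numeric(ncol(X))))
  delta_hat <- t(vapply(levels_b, function(b) apply(Z[batches == b, , drop = FALSE], 2L, stats::var),
                        numeric(ncol(X))))

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (i in seq_along(levels_b)) {
    sol <- .eb_solve(gamma_hat[i, ], delta_hat[i, ], n_b[i],
                     gamma_bar = mean(gamma_hat[i, ]),
                     tau2 = stats::var(gamma_hat[i, ]),
                     a = .aprior(delta_hat[i, ]), b = .bprior(delta_hat[i, ]))
    gamma_star[i, ] <- sol$gamma_star
    delta_star[i, ] <- sol$delta_star
  }
  structure(list(batch_levels = levels_b,
                 grand_mean = grand,
                 var_pooled = var_pooled,
                 gamma_star = gamma_star,
                 delta_star = delta_star,
                 features = colnames(X)),
            class = "combat_model")
}

#' Apply a fitted ComBat model
#'
#' Adjusted value = `sd_pooled * (standardized - gamma_star) /
#' sqrt(delta_star) + grand_mean`, per the fitted batch of each subject.
#'
#' @param values subjects x features matrix with the same feature columns
#'   the model was fitted on.
#' @param model a `combat_model` from [combat_fit()].
#' @param batches batch label per subject; all labels must have been seen at
#'   fit time.
#' @return harmonized matrix of the same shape, ids and column order.
#' @export
combat_apply <- function(values, model, batches) {
  X <- as.matrix(values)
  batches <- as.character(batches)
  if (length(batches) != nrow(X)) stop("one batch label per subject required")
  unseen <- setdiff(unique(batches), model$batch_levels)
  if (length(unseen))
    stop("batch label(s) not seen at fit: ", paste(unseen, collapse = ", "))
  if (!is.null(model$features) && !is.null(colnames(X)) &&
      !identical(colnames(X), model$features))
    stop("feature columns differ from the fitted model")
  sd_pooled <- sqrt(model$var_pooled)
  Z <- sweep(sweep(X, 2L, model$grand_mean), 2L, sd_pooled, "/")
  idx <- match(batches, model$batch_levels)
  Zadj <- (Z - model$gamma_star[idx, , drop = FALSE]) /
    sqrt(model$delta_star[idx, , drop = FALSE])
  out <- sweep(sweep(Zadj, 2L, sd_pooled, "*"), 2L, model$grand_mean, "+")
  dimnames(out) <- dimnames(X)
  out
}

#' Harmonize a modality table in one step
#'
#' Fits and applies ComBat on the same partition (the mode used per
#' timepoint and per train/test split).
#'
#' @inheritParams combat_fit
#' @export
combat_harmonize <- function(values, batches) {
  combat_apply(values, combat_fit(values, batches), batches)
}
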