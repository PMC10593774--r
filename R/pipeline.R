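#' End-to-end pipeline
#'
#' Orchestrates the full workflow: build the source reference space (SNF +
#' diffusion map embedding), embed the target adaptation subset and align
#' it to the source convention, fit the domain-adapted transfer model,
#' predict embedding scores for unseen target subjects (per timepoint),
#' derive change scores, optionally compare against an independently
#' embedded ground truth, and fit association models.
#'
#' @name pipeline
NULL

#' Fuse modalities and embed in one step
#'
#' @param modalities named list of subjects x features matrices over the
#'   same subjects in the same order.
#' @param snf an [snf_params()] object.
#' @param embed an [embedding_params()] object.
#' @return list with the fused network (`fused`) and the
#'   `embedding_result` (`embedding`).
#' @export
fuse_and_embed <- function(modalities, snf = snf_params(),
                           embed = embedding_params()) {
  affinities <- lapply(modalities, modality_affinity, params = snf)
  fused <- snf_fuse(affinities, snf)
  list(fused = fused, embedding = diffusion_map_embed(fused, embed))
}

#' Align an embedding score vector to a reference cohort's convention
#'
#' Cross-cohort score vectors come from different fused networks, so the
#' leading eigenvalue -- and with it the `lambda / (1 - lambda)` score
#' scale -- is cohort-specific. Subject-matched Procrustes does not apply
#' across disjoint cohorts; instead the deterministic skewness sign
#' convention makes directions comparable and this helper matches the
#' spread to the reference (scores are unitless).
#'
#' @param scores numeric score vector to align.
#' @param reference numeric score vector of the reference cohort.
#' @return rescaled `scores` with `sd` equal to the reference's.
#' @export
align_embedding_scale <- function(scores, reference) {
  s <- stats::sd(scores)
  if (s == 0) stop("degenerate score vector")
  as.numeric(scores) * stats::sd(reference) / s
}

.cfg_get <- function(config, ...) {
  out <- config
  for (k in c(...)) {
    if (is.null(out)) return(NULL)
    out <- out[[k]]
  }
  out
}

.params_from_config <- function(config) {
  list(
    snf = snf_params(
      K = .cfg_get(config, "snf", "K") %||% 30L,
      mu = .cfg_get(config, "snf", "mu") %||% 0.8,
      T = .cfg_get(config, "snf", "T") %||% 20L,
      standardize = .cfg_get(config, "snf", "standardize") %||% TRUE),
    embed = embedding_params(
      n_components = .cfg_get(config, "embed", "n_components") %||% 5L,
      t = .cfg_get(config, "embed", "t") %||% 0,
      alpha = .cfg_get(config, "embed", "alpha") %||% 0.5),
    en = elastic_net_params(
      l1_ratio = .cfg_get(config, "elastic_net", "l1_ratio") %||% 0.5,
      penalty_strength = .cfg_get(config, "elastic_net", "alpha") %||% 1.0),
    tp = transfer_params(
      n_boost = .cfg_get(config, "transfer", "n_boost") %||% 10L,
      loss = .cfg_get(config, "transfer", "loss") %||% "linear",
      seed = .cfg_get(config, "seed") %||% 1L))
}

.read_modality_set <- function(paths) {
  mods <- lapply(paths, read_feature_table)
  ids <- rownames(mods[[1L]])
  for (X in mods)
    if (!identical(rownames(X), ids))
      stop("subject ids differ across modality files")
  if (is.null(names(mods)) || any(names(mods) == ""))
    names(mods) <- sprintf("modality_%d", seq_along(mods))
  mods
}

.maybe_harmonize <- function(mods, config, phen, stage, log) {
  if (!isTRUE(.cfg_get(config, "combat", "enabled"))) return(mods)
  batch_col <- .cfg_get(config, "combat", "batch_column") %||% "site"
  if (is.null(phen)) stop("combat enabled but no phenotype table given")
  lapply(mods, function(X) {
    batches <- phen[[batch_col]][match(rownames(X), phen$subject_id)]
    if (anyNA(batches)) stop(stage, ": missing ", batch_col,
                             " for some subjects")
    if (length(unique(batches)) < 2L) return(X)
    combat_harmonize(X, batches)
  })
}

.stage <- function(log_lines, msg) {
  c(log_lines, msg)
}

#' Run the full pipeline from a configuration list
#'
#' @param config nested list as produced by [read_config()]: input paths
#'   (`paths$source`, `paths$target_adapt`, `paths$target_test`, optional
#'   `paths$target_test_followup`, optional `paths$phenotypes`), module
#'   parameter blocks and `output_dir`. Each modality-set entry is a named
#'   list/vector of per-modality file paths. When `paths$target_adapt` is
#'   absent the model falls back to a plain (non-adapted) elastic net
#'   trained on the source, with a logged warning.
#' @return invisibly, a list with the key artifacts (`model`,
#'   `predictions`, `delta`, `comparison`, `associations`) -- all also
#'   written under `output_dir`.
#' @export
run_pipeline <- function(config) {
  outdir <- .cfg_get(config, "output_dir") %||% "fusemap_output"
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  prm <- .params_from_config(config)
  log_lines <- character()
  t0 <- proc.time()[["elapsed"]]
  phen <- NULL
  if (!is.null(.cfg_get(config, "paths", "phenotypes")))
    phen <- utils::read.csv(.cfg_get(config, "paths", "phenotypes"),
                            stringsAsFactors = FALSE)

  elapsed <- function() sprintf("%.1fs", proc.time()[["elapsed"]] - t0)

  # -- stage 1: source reference space ------------------------------------
  src_mods <- .read_modality_set(.cfg_get(config, "paths", "source"))
  src_mods <- .maybe_harmonize(src_mods, config, phen, "source", log_lines)
  src <- fuse_and_embed(src_mods, prm$snf, prm$embed)
  y_src <- src$embedding$scores[, 1L]
  X_src <- concat_modalities(src_mods)
  log_lines <- .stage(log_lines,
                      sprintf("stage=source n=%d p=%d elapsed=%s",
                              nrow(X_src), ncol(X_src), elapsed()))
  write_similarity_matrix(src$fused, file.path(outdir, "source_fused.csv"))
  write_embedding(src$embedding, file.path(outdir, "source_embedding.csv"))

  # -- stage 2/3: adaptation subset + transfer fit ------------------------
  adapt_paths <- .cfg_get(config, "paths", "target_adapt")
  if (is.null(adapt_paths)) {
    warning("no target_adapt block: falling back to a non-adapted ",
            "elastic net trained on the source")
    log_lines <- .stage(log_lines, "stage=fit mode=elastic_net_fallback")
    est <- fit_elastic_net(standardize_features(X_src), y_src,
                           params = prm$en)
    model <- structure(list(estimators = list(est),
                            estimator_weights = 1,
                            beta_t = NA_real_, beta_source = NA_real_,
                            center = attr(standardize_features(X_src),
                                          "center"),
                            scale = attr(standardize_features(X_src),
                                         "scale"),
                            columns = colnames(X_src)),
                       class = "tradaboost_model")
  } else {
    ad_mods <- .read_modality_set(adapt_paths)
    ad_mods <- .maybe_harmonize(ad_mods, config, phen, "target_adapt",
                                log_lines)
    ad <- fuse_and_embed(ad_mods, prm$snf, prm$embed)
    y_ad <- align_embedding_scale(ad$embedding$scores[, 1L], y_src)
    X_ad <- concat_modalities(ad_mods)
    if (!identical(colnames(X_ad), colnames(X_src)))
      stop("feature columns differ between source and target_adapt")
    model <- tradaboost_fit(X_src, y_src, X_ad, y_ad,
                            en = prm$en, tp = prm$tp)
    log_lines <- .stage(log_lines,
                        sprintf("stage=fit mode=tradaboost n_source=%d n_target=%d elapsed=%s",
                                nrow(X_src), nrow(X_ad), elapsed()))
  }
  write_model(model, file.path(outdir, "model.json"))

  # -- stage 4: predict unseen target subjects ----------------------------
  test_paths <- .cfg_get(config, "paths", "target_test")
  result <- list(model = model)
  if (!is.null(test_paths)) {
    test_mods <- .read_modality_set(test_paths)
    test_mods <- .maybe_harmonize(test_mods, config, phen, "target_test",
                                  log_lines)
    X_test <- concat_modalities(test_mods)
    pred <- predict(model, X_test)
    preds <- data.frame(subject_id = rownames(X_test),
                        timepoint = "baseline",
                        predicted_embedding = pred,
                        stringsAsFactors = FALSE)

    fup_paths <- .cfg_get(config, "paths", "target_test_followup")
    if (!is.null(fup_paths)) {
      fup_mods <- .read_modality_set(fup_paths)
      fup_mods <- .maybe_harmonize(fup_mods, config, phen,
                                   "target_test_followup", log_lines)
      X_fup <- concat_modalities(fup_mods)
      pred_f <- predict(model, X_fup)
      preds <- rbind(preds,
                     data.frame(subject_id = rownames(X_fup),
                                timepoint = "followup",
                                predicted_embedding = pred_f,
                                stringsAsFactors = FALSE))
      common <- intersect(rownames(X_test), rownames(X_fup))
      delta <- data.frame(
        subject_id = common,
        delta_embedding = pred_f[match(common, rownames(X_fup))] -
          pred[match(common, rownames(X_test))],
        stringsAsFactors = FALSE)
      utils::write.csv(delta, file.path(outdir, "delta_scores.csv"),
                       row.names = FALSE)
      result$delta <- delta
    }
    utils::write.csv(preds, file.path(outdir, "predicted_scores.csv"),
                     row.names = FALSE)
    result$predictions <- preds
    log_lines <- .stage(log_lines,
                        sprintf("stage=predict n=%d elapsed=%s",
                                nrow(preds), elapsed()))

    # -- stage 6: optional ground-truth comparison ------------------------
    if (isTRUE(.cfg_get(config, "evaluate", "ground_truth"))) {
      gt <- fuse_and_embed(test_mods, prm$snf, prm$embed)
      truth <- gt$embedding$scores[, 1L]
      aligned <- procrustes_align(matrix(pred), matrix(truth), scale = TRUE)
      cmp <- compare_embeddings(aligned, truth)
      jsonlite::write_json(unclass(cmp),
                           file.path(outdir, "comparison.json"),
                           auto_unbox = TRUE, digits = NA)
      result$comparison <- cmp
      log_lines <- .stage(log_lines,
                          sprintf("stage=evaluate r=%.4f elapsed=%s",
                                  cmp$pearson_r, elapsed()))
    }
  }

  # -- stage 7: associations ---------------------------------------------
  assoc_cfg <- .cfg_get(config, "associate")
  if (!is.null(assoc_cfg) && !is.null(phen) && !is.null(result$predictions)) {
    phen_sc <- score_phenotypes(phen)
    dat <- merge(result$predictions, phen_sc,
                 by = c("subject_id", "timepoint"))
    assoc <- run_associations(dat, assoc_cfg$models,
                              alpha_family = assoc_cfg$alpha_family %||% 0.05)
    utils::write.csv(assoc, file.path(outdir, "associations.csv"),
                     row.names = FALSE)
    result$associations <- assoc
    log_lines <- .stage(log_lines,
                        sprintf("stage=associate n_models=%d elapsed=%s",
                                nrow(assoc), elapsed()))
  }

  log_lines <- c(sprintf("seed=%d", .cfg_get(config, "seed") %||% 1L),
                 log_lines)
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  yaml::write_yaml(config, file.path(outdir, "config_used.yaml"))
  invisible(result)
}
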