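#' Synthetic developmental cohorts with planted latent structure
#'
#' Generates source/target cohorts that emulate the statistical assumptions
#' of the fusion framework: each subject carries a latent maturation score
#' `z` increasing with age (with a sex-specific intercept), regional
#' features of each modality load on `z` through a modality-specific link
#' (linear for the first, saturating for the second, so modalities carry
#' shared plus complementary signal) plus a sex gradient, site
#' location/scale effects and Gaussian noise. PDS items are ordinalized
#' monotone functions of `z` with logistic reporter noise, and diagnosis
#' counts follow a count distribution whose rate grows with the deviation
#' of `z` from its age/sex expectation.
#'
#' @name synthetic_cohort
NULL

# deterministic integer sub-seed per named generation block, so that toggling
# one block never perturbs the draws of another
.substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1000003
  as.integer((as.numeric(seed) %% 65536 * 32003 + h) %% 2147483629)
}

#' Generator configuration
#'
#' @param n_subjects cohort size (>= 4).
#' @param n_features_per_modality regional features per modality (default
#'   34, bilaterally averaged cortical regions).
#' @param n_modalities number of modalities (default 2, e.g. volume and
#'   surface area).
#' @param n_sites number of acquisition sites.
#' @param sex_ratio fraction of females.
#' @param age_range min/max age in years.
#' @param latent_loading_scale SD of the per-feature loadings on `z`.
#' @param noise_sd SD of the per-feature Gaussian noise.
#' @param site_offset_sd SD of additive per-site, per-feature offsets.
#' @param site_scale_sd SD of per-site log scale factors.
#' @param sex_gradient_strength magnitude of the additive sex pattern.
#' @param pds_coupling slope of the PDS items' latent propensity on
#'   standardized `z`.
#' @param diagnosis_coupling slope of the diagnosis rate on the absolute
#'   deviation of `z` from its age/sex expectation (females only by
#'   default, mirroring the female-specific clinical effect).
#' @param diagnosis_female_only restrict the diagnosis coupling to females.
#' @param clinical clinical-cohort flavor: diagnosis counts truncated to
#'   `[1, 10]`.
#' @param seed integer seed; identical seed + config give a bit-identical
#'   cohort.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_subjects,
                             n_features_per_modality = 34L,
                             n_modalities = 2L,
                             n_sites = 1L,
                             sex_ratio = 0.5,
                             age_range = c(8, 21),
                             latent_loading_scale = 1,
                             noise_sd = 0.5,
                             site_offset_sd = 0,
                             site_scale_sd = 0,
                             sex_gradient_strength = 0.5,
                             pds_coupling = 1,
                             diagnosis_coupling = 0,
                             diagnosis_female_only = TRUE,
                             clinical = FALSE,
                             seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_features_per_modality = as.integer(n_features_per_modality),
              n_modalities = as.integer(n_modalities),
              n_sites = as.integer(n_sites),
              sex_ratio = sex_ratio,
              age_range = as.numeric(age_range),
              latent_loading_scale = latent_loading_scale,
              noise_sd = noise_sd,
              site_offset_sd = site_offset_sd,
              site_scale_sd = site_scale_sd,
              sex_gradient_strength = sex_gradient_strength,
              pds_coupling = pds_coupling,
              diagnosis_coupling = diagnosis_coupling,
              diagnosis_female_only = isTRUE(diagnosis_female_only),
              clinical = isTRUE(clinical),
              seed = as.integer(seed))
  if (cfg$n_subjects < 4L) stop("n_subjects must be >= 4")
  if (cfg$n_modalities < 1L) stop("n_modalities must be >= 1")
  if (cfg$n_sites < 1L) stop("n_sites must be >= 1")
  if (sex_ratio < 0 || sex_ratio > 1) stop("sex_ratio must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(cfg$age_range) != 2L || diff(cfg$age_range) <= 0)
    stop("age_range must be (min, max) with max > min")
  if (latent_loading_scale == 0 &&
      (pds_coupling != 0 || diagnosis_coupling != 0))
    stop("latent_loading_scale = 0 with nonzero coupling leaves the ",
         "planted signal unidentifiable")
  structure(cfg, class = "generator_config")
}

# cohort-level structural parameters shared across timepoints
.draw_structure <- function(cfg) {
  p <- cfg$n_features_per_modality
  set.seed(.substream_seed(cfg$seed, "loadings"))
  loadings <- lapply(seq_len(cfg$n_modalities),
                     function(m) stats::rnorm(p) * cfg$latent_loading_scale)
  sex_pattern <- lapply(seq_len(cfg$n_modalities),
                        function(m) stats::rnorm(p))
  set.seed(.substream_seed(cfg$seed, "sites"))
  site_offset <- matrix(stats::rnorm(cfg$n_sites * p, 0, cfg$site_offset_sd),
                        cfg$n_sites, p)
  site_logscale <- stats::rnorm(cfg$n_sites, 0, cfg$site_scale_sd)
  list(loadings = loadings, sex_pattern = sex_pattern,
       site_offset = site_offset, site_logscale = site_logscale)
}

# modality link functions: shared (linear) plus complementary (saturating)
.modality_link <- function(z, m) {
  if (m %% 2L == 1L) z else 4 * tanh(z / 4)
}

.gen_features <- function(cfg, struct, z, sex_sign, site_idx, noise_stream) {
  n <- length(z)
  p <- cfg$n_features_per_modality
  set.seed(.substream_seed(cfg$seed, noise_stream))
  out <- vector("list", cfg$n_modalities)
  for (m in seq_len(cfg$n_modalities)) {
    signal <- outer(.modality_link(z, m), struct$loadings[[m]]) +
      cfg$sex_gradient_strength * outer(sex_sign, struct$sex_pattern[[m]])
    noise <- matrix(stats::rnorm(n * p, 0, cfg$noise_sd), n, p)
    X <- (signal + noise) * exp(struct$site_logscale[site_idx]) +
      struct$site_offset[site_idx, , drop = FALSE]
    colnames(X) <- sprintf("region_%02d", seq_len(p))
    out[[m]] <- X
  }
  names(out) <- sprintf("modality_%d", seq_len(cfg$n_modalities))
  out
}

# ordinal PDS items from standardized z: fixed thresholds on a logistic-noise
# latent propensity; menarche is a single higher threshold. The center/scale
# of the standardization must be shared across visits so that latent growth
# moves the items (defaults: this visit's own moments).
.gen_pds <- function(cfg, z, sex, stream, center = mean(z), scale = stats::sd(z)) {
  n <- length(z)
  zs <- (z - center) / scale
  set.seed(.substream_seed(cfg$seed, stream))
  thr <- c(-0.8, 0.2, 1.2)
  items <- matrix(NA_real_, n, 5L,
                  dimnames = list(NULL, sprintf("pds_%d", 1:5)))
  for (j in 1:5) {
    latent <- cfg$pds_coupling * zs + stats::rlogis(n, 0, 0.55)
    items[, j] <- findInterval(latent, thr) + 1
  }
  menarche_latent <- cfg$pds_coupling * zs + stats::rlogis(n, 0, 0.55)
  menarche <- ifelse(sex == "female", menarche_latent > 0.9, NA)
  items[sex == "female", "pds_5"] <- NA  # facial-hair item is male-specific
  list(items = items, menarche = menarche)
}

.gen_diagnoses <- function(cfg, z, age, sex, stream) {
  set.seed(.substream_seed(cfg$seed, stream))
  fml <- if (length(unique(sex)) > 1L) z ~ age + sex else z ~ age
  resid <- stats::residuals(stats::lm(fml, data = data.frame(z, age, sex)))
  dev <- abs(resid)
  coupled <- if (cfg$diagnosis_female_only) sex == "female"
             else rep(TRUE, length(z))
  lambda <- ifelse(coupled, 2 + cfg$diagnosis_coupling * dev, 2)
  if (cfg$clinical) {
    # zero-truncated Poisson via inverse CDF, capped at 10
    u <- stats::runif(length(z), stats::ppois(0, lambda), 1)
    counts <- pmin(stats::qpois(u, lambda), 10L)
  } else {
    counts <- stats::rpois(length(z), lambda)
  }
  cbcl <- round(pmax(0, 25 + 10 * cfg$diagnosis_coupling * dev * coupled +
                       stats::rnorm(length(z), 0, 5)), 1)
  list(counts = as.integer(counts), cbcl = cbcl)
}

.assemble_phenotypes <- function(ids, sex, age, site, timepoint, pds, dx) {
  data.frame(subject_id = ids, sex = sex, age = age, site = site,
             timepoint = timepoint,
             as.data.frame(pds$items),
             menarche = pds$menarche,
             diagnosis_count = dx$counts,
             cbcl_total = dx$cbcl,
             stringsAsFactors = FALSE)
}

#' Generate a single-visit synthetic cohort
#'
#' @param config a [generator_config()].
#' @return object of class `synthetic_cohort` with elements `modalities`
#'   (list: timepoint -> list: modality -> subjects x features matrix),
#'   `phenotypes` (long data frame, one row per subject and timepoint),
#'   `latent` (planted truth: `z` and the sex-gradient offset per subject
#'   and timepoint) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  n <- cfg$n_subjects
  ids <- sprintf("sub-%05d", seq_len(n))

  set.seed(.substream_seed(cfg$seed, "demographics"))
  sex <- ifelse(stats::runif(n) < cfg$sex_ratio, "female", "male")
  site <- sprintf("site_%d", sample.int(cfg$n_sites, n, replace = TRUE))
  age <- stats::runif(n, cfg$age_range[1L], cfg$age_range[2L])

  set.seed(.substream_seed(cfg$seed, "latent"))
  slope <- 3 / diff(cfg$age_range)
  z <- slope * (age - cfg$age_range[1L]) + 0.5 * (sex == "female") +
    stats::rnorm(n)

  struct <- .draw_structure(cfg)
  sex_sign <- ifelse(sex == "female", 0.5, -0.5)
  site_idx <- as.integer(sub("site_", "", site))
  mods <- .gen_features(cfg, struct, z, sex_sign, site_idx, "noise_single")
  mods <- lapply(mods, function(X) { rownames(X) <- ids; X })

  pds <- .gen_pds(cfg, z, sex, "pds_single")
  dx <- .gen_diagnoses(cfg, z, age, sex, "diagnosis_single")
  phen <- .assemble_phenotypes(ids, sex, age, site, "single", pds, dx)

  structure(list(modalities = list(single = mods),
                 phenotypes = phen,
                 latent = data.frame(subject_id = ids, timepoint = "single",
                                     z = z,
                                     sex_offset = cfg$sex_gradient_strength *
                                       sex_sign,
                                     stringsAsFactors = FALSE),
                 config = cfg),
            class = "synthetic_cohort")
}

#' Generate a two-visit longitudinal cohort
#'
#' Baseline and follow-up visits for the same subjects: loadings, site
#' assignment and sex patterns are held fixed across timepoints, the
#' latent maturation advances by a sex-specific mean increment, and
#' feature/reporter noise is drawn fresh per visit. The change in PDS thus
#' correlates with the latent increment by construction.
#'
#' @param config a [generator_config()].
#' @param delta_z_by_sex named numeric vector `c(female = ..., male = ...)`
#'   of mean latent increments between visits; the default advances
#'   females more than males, mirroring faster female pubertal maturation
#'   over a two-year follow-up window.
#' @param delta_age_mean mean inter-visit interval in years.
#' @return a `synthetic_cohort` with timepoints `baseline` and `followup`.
#' @export
generate_longitudinal_pair <- function(config,
                                       delta_z_by_sex = c(female = 1.0,
                                                          male = 0.5),
                                       delta_age_mean = 2) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  n <- cfg$n_subjects
  ids <- sprintf("sub-%05d", seq_len(n))

  set.seed(.substream_seed(cfg$seed, "demographics"))
  sex <- ifelse(stats::runif(n) < cfg$sex_ratio, "female", "male")
  site <- sprintf("site_%d", sample.int(cfg$n_sites, n, replace = TRUE))
  age <- stats::runif(n, cfg$age_range[1L], cfg$age_range[2L])

  set.seed(.substream_seed(cfg$seed, "latent"))
  slope <- 3 / diff(cfg$age_range)
  z1 <- slope * (age - cfg$age_range[1L]) + 0.5 * (sex == "female") +
    stats::rnorm(n)
  z2 <- z1 + unname(delta_z_by_sex[sex])

  set.seed(.substream_seed(cfg$seed, "followup_age"))
  age2 <- age + delta_age_mean + stats::runif(n, -0.2, 0.2)

  struct <- .draw_structure(cfg)
  sex_sign <- ifelse(sex == "female", 0.5, -0.5)
  site_idx <- as.integer(sub("site_", "", site))

  mods1 <- .gen_features(cfg, struct, z1, sex_sign, site_idx,
                         "noise_baseline")
  mods2 <- .gen_features(cfg, struct, z2, sex_sign, site_idx,
                         "noise_followup")
  mods1 <- lapply(mods1, function(X) { rownames(X) <- ids; X })
  mods2 <- lapply(mods2, function(X) { rownames(X) <- ids; X })

  zc <- mean(c(z1, z2))
  zsd <- stats::sd(c(z1, z2))
  pds1 <- .gen_pds(cfg, z1, sex, "pds_baseline", center = zc, scale = zsd)
  pds2 <- .gen_pds(cfg, z2, sex, "pds_followup", center = zc, scale = zsd)
  dx1 <- .gen_diagnoses(cfg, z1, age, sex, "diagnosis_baseline")
  dx2 <- .gen_diagnoses(cfg, z2, age2, sex, "diagnosis_followup")

  phen <- rbind(
    .assemble_phenotypes(ids, sex, age, site, "baseline", pds1, dx1),
    .assemble_phenotypes(ids, sex, age2, site, "followup", pds2, dx2))

  latent <- rbind(
    data.frame(subject_id = ids, timepoint = "baseline", z = z1,
               sex_offset = cfg$sex_gradient_strength * sex_sign,
               stringsAsFactors = FALSE),
    data.frame(subject_id = ids, timepoint = "followup", z = z2,
               sex_offset = cfg$sex_gradient_strength * sex_sign,
               stringsAsFactors = FALSE))

  structure(list(modalities = list(baseline = mods1, followup = mods2),
                 phenotypes = phen, latent = latent, config = cfg),
            class = "synthetic_cohort")
}

#' Concatenate a cohort's modality tables
#'
#' Column-binds the modality matrices of one timepoint into the wide
#' feature matrix fed to the transfer regressor (columns prefixed with the
#' modality name).
#'
#' @param cohort a `synthetic_cohort`, or a plain named list of modality
#'   matrices.
#' @param timepoint which visit to use (defaults to the first present).
#' @return subjects x (sum of features) matrix.
#' @export
concat_modalities <- function(cohort, timepoint = NULL) {
  mods <- if (inherits(cohort, "synthetic_cohort")) {
    tp <- timepoint %||% names(cohort$modalities)[1L]
    cohort$modalities[[tp]]
  } else cohort
  pieces <- lapply(names(mods), function(nm) {
    X <- mods[[nm]]
    colnames(X) <- paste(nm, colnames(X), sep = ".")
    X
  })
  do.call(cbind, pieces)
}

#' Write a synthetic cohort to disk
#'
#' One wide CSV per timepoint and modality (`subject_id` + feature
#' columns), a phenotype CSV, and a JSON sidecar carrying the full
#' configuration and the planted latent truth.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (tp in names(cohort$modalities)) {
    for (mod in names(cohort$modalities[[tp]])) {
      p <- file.path(dir, sprintf("features_%s_%s.csv", tp, mod))
      write_feature_table(cohort$modalities[[tp]][[mod]], p)
      paths <- c(paths, p)
    }
  }
  pp <- file.path(dir, "phenotypes.csv")
  utils::write.csv(cohort$phenotypes, pp, row.names = FALSE)
  sidecar <- file.path(dir, "cohort.json")
  jsonlite::write_json(list(config = unclass(cohort$config),
                            latent = cohort$latent),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, pp, sidecar))
}
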