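test_that("identical config and seed give a bit-identical cohort", {
  cfg <- generator_config(n_subjects = 100, seed = 7)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  lcfg <- generator_config(n_subjects = 50, seed = 7)
  expect_identical(generate_longitudinal_pair(lcfg),
                   generate_longitudinal_pair(lcfg))
})

test_that("different seeds give different cohorts", {
  a <- generate_cohort(generator_config(n_subjects = 20, seed = 1))
  b <- generate_cohort(generator_config(n_subjects = 20, seed = 2))
  expect_false(identical(a$modalities$single$modality_1,
                         b$modalities$single$modality_1))
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(n_subjects = 3), "n_subjects")
  expect_error(generator_config(10, n_modalities = 0), "n_modalities")
  expect_error(generator_config(10, sex_ratio = 1.5), "sex_ratio")
  expect_error(generator_config(10, noise_sd = -1), "noise_sd")
  expect_error(generator_config(10, latent_loading_scale = 0,
                                pds_coupling = 1), "unidentifiable")
  expect_error(generator_config(10, age_range = c(12, 10)), "age_range")
})

test_that("noise-free single-site cohort puts z on the first principal axis", {
  cfg <- generator_config(n_subjects = 60, noise_sd = 0, n_sites = 1,
                          sex_gradient_strength = 0, pds_coupling = 0,
                          seed = 5)
  co <- generate_cohort(cfg)
  pc1 <- prcomp(co$modalities$single$modality_1)$x[, 1]
  expect_equal(abs(cor(pc1, co$latent$z)), 1, tolerance = 1e-8)
})

test_that("PDS mean tracks the planted latent at the default coupling", {
  co <- generate_cohort(generator_config(n_subjects = 600, seed = 3))
  ph <- score_phenotypes(co$phenotypes)
  expect_gt(abs(cor(co$latent$z, ph$pds_mean, use = "complete.obs")), 0.6)
  # rank coupling is positive whenever pds_coupling > 0
  for (s in 1:3) {
    co2 <- generate_cohort(generator_config(n_subjects = 300, seed = s,
                                            pds_coupling = 0.5))
    ph2 <- score_phenotypes(co2$phenotypes)
    expect_gt(cor(co2$latent$z, ph2$pds_mean, use = "complete.obs",
                  method = "spearman"), 0)
  }
})

test_that("site offsets produce detectable site differences in raw features", {
  co <- generate_cohort(generator_config(n_subjects = 300, n_sites = 3,
                                         site_offset_sd = 0.5, seed = 11))
  X <- co$modalities$single$modality_1
  site <- co$phenotypes$site
  p_vals <- apply(X[, 1:10], 2L,
                  function(col) anova(lm(col ~ site))$`Pr(>F)`[1])
  expect_lt(min(p_vals), 0.01)
})

test_that("modality tables and phenotypes share subject ids in order", {
  co <- generate_cohort(generator_config(n_subjects = 40, seed = 9))
  ids <- co$phenotypes$subject_id
  for (m in co$modalities$single) expect_identical(rownames(m), ids)
  expect_identical(co$latent$subject_id, ids)
})

test_that("zero latent increment and zero noise give identical visits", {
  cfg <- generator_config(n_subjects = 30, noise_sd = 0, seed = 2)
  co <- generate_longitudinal_pair(cfg, delta_z_by_sex = c(female = 0,
                                                           male = 0))
  expect_equal(co$modalities$baseline$modality_1,
               co$modalities$followup$modality_1, tolerance = 0)
})

test_that("sex-specific latent increments order the PDS change scores", {
  co <- generate_longitudinal_pair(generator_config(n_subjects = 400,
                                                    seed = 3))
  ph <- score_phenotypes(co$phenotypes)
  d <- delta_scores(ph)
  base <- ph[ph$timepoint == "baseline", ]
  sex <- base$sex[match(d$subject_id, base$subject_id)]
  expect_gt(mean(d$delta_pds[sex == "female"], na.rm = TRUE),
            mean(d$delta_pds[sex == "male"], na.rm = TRUE))
  expect_true(all(ph$age[ph$timepoint == "followup"] >
                    ph$age[ph$timepoint == "baseline"]))
  expect_equal(nrow(co$latent), 2 * 400)
})

test_that("clinical flavor keeps diagnosis counts in the 1-10 range", {
  co <- generate_cohort(generator_config(n_subjects = 300, seed = 2,
                                         clinical = TRUE,
                                         diagnosis_coupling = 1))
  dx <- co$phenotypes$diagnosis_count
  expect_true(all(dx >= 1 & dx <= 10))
  # coupling raises counts for females (the coupled stratum) with deviant z
  expect_true(mean(dx[co$phenotypes$sex == "female"]) > 0)
})

test_that("female item sets exclude the male-specific item and include menarche", {
  co <- generate_cohort(generator_config(n_subjects = 50, seed = 4))
  ph <- co$phenotypes
  expect_true(all(is.na(ph$pds_5[ph$sex == "female"])))
  expect_true(all(!is.na(ph$pds_5[ph$sex == "male"])))
  expect_true(all(is.na(ph$menarche[ph$sex == "male"])))
  expect_true(all(!is.na(ph$menarche[ph$sex == "female"])))
  sc <- score_phenotypes(ph)
  expect_true(all(sc$pds_mean >= 1 & sc$pds_mean <= 4))
})

test_that("cohorts round-trip through the CSV/JSON writers", {
  co <- generate_cohort(generator_config(n_subjects = 12, seed = 6))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  X <- read_feature_table(file.path(dir, "features_single_modality_1.csv"))
  expect_equal(X, co$modalities$single$modality_1, tolerance = 1e-12)
  side <- jsonlite::read_json(file.path(dir, "cohort.json"),
                              simplifyVector = TRUE)
  expect_equal(side$config$seed, 6)
  expect_equal(side$latent$z, co$latent$z, tolerance = 1e-12)
})
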