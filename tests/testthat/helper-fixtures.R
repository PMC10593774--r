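make_pipeline_fixture <- function(dir, n_src = 40, n_tgt = 40, seed = 1) {
  src <- generate_cohort(generator_config(n_subjects = n_src, seed = seed,
                                          age_range = c(8, 21)))
  tgt <- generate_longitudinal_pair(
    generator_config(n_subjects = n_tgt, seed = seed + 1,
                     age_range = c(9, 11)))
  write_cohort(src, file.path(dir, "src"))
  write_cohort(tgt, file.path(dir, "tgt"))
  half <- seq_len(n_tgt / 2)
  adapt_dir <- file.path(dir, "adapt")
  test_dir <- file.path(dir, "test")
  dir.create(adapt_dir); dir.create(test_dir)
  for (m in names(tgt$modalities$baseline)) {
    write_feature_table(tgt$modalities$baseline[[m]][half, ],
                        file.path(adapt_dir, paste0(m, ".csv")))
    write_feature_table(tgt$modalities$baseline[[m]][-half, ],
                        file.path(test_dir, paste0(m, "_base.csv")))
    write_feature_table(tgt$modalities$followup[[m]][-half, ],
                        file.path(test_dir, paste0(m, "_fup.csv")))
  }
  ph <- score_phenotypes(tgt$phenotypes)
  write.csv(ph, file.path(dir, "phenotypes.csv"), row.names = FALSE)
  list(
    seed = seed,
    output_dir = file.path(dir, "out"),
    snf = list(K = 10, T = 10),
    embed = list(n_components = 3),
    paths = list(
      source = as.list(file.path(dir, "src",
                                 paste0("features_single_",
                                        names(src$modalities$single),
                                        ".csv"))),
      target_adapt = as.list(file.path(adapt_dir,
                                       paste0(names(tgt$modalities$baseline),
                                              ".csv"))),
      target_test = as.list(file.path(test_dir,
                                      paste0(names(tgt$modalities$baseline),
                                             "_base.csv"))),
      target_test_followup = as.list(file.path(test_dir,
                                               paste0(names(tgt$modalities$baseline),
                                                      "_fup.csv"))),
      phenotypes = file.path(dir, "phenotypes.csv")),
    evaluate = list(ground_truth = TRUE))
}
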