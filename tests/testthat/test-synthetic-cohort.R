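test_that("config invariants are validated field by field", {
  expect_error(cohort_config(n_completers = 14, n_ogtt_pre = 13),
               "n_completers")
  expect_error(cohort_config(subject_sd = 0), "subject_sd")
  expect_error(cohort_config(timepoints = c(30, 60)), "timepoints")
  expect_error(cohort_config(class_mix = c(lipid_suppressed = 1)), "class_mix")
  expect_error(cohort_config(n_planted = 400), "n_planted")
  expect_error(cohort_config(missing_frac = 1.2), "missing_frac")
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- cohort_config(n_metabolites = 12, n_planted = 3, seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$panel, b$panel)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  expect_identical(generate_glucose_insulin(cfg), generate_glucose_insulin(cfg))
})

test_that("design structure matches the nested cohort flow", {
  cfg <- cohort_config(n_metabolites = 8, n_planted = 2, missing_frac = 0, seed = 2)
  cc <- generate_cohort(cfg)
  df <- as.data.frame(cc$panel)
  per_met <- table(df$metabolite_id)
  # 13 OGTT subjects x 5 draws + 2 fasting-only subjects + 12 completers x 5
  expect_true(all(per_met == 13 * 5 + 2 + 12 * 5))
  post_sub <- unique(df$subject_id[df$phase == "post"])
  expect_length(post_sub, 12)
  pre_t <- df[df$phase == "pre" & df$time_min > 0, ]
  expect_length(unique(pre_t$subject_id), 13)
  expect_true(all(post_sub %in% unique(pre_t$subject_id)))
  expect_false(anyNA(df$intensity))
  expect_true(all(df$intensity > 0))
})

test_that("missingness is applied at the configured rate and only then", {
  cfg <- cohort_config(n_metabolites = 40, n_planted = 5, missing_frac = 0.1, seed = 3)
  df <- as.data.frame(generate_cohort(cfg)$panel)
  expect_gt(mean(is.na(df$intensity)), 0.07)
  expect_lt(mean(is.na(df$intensity)), 0.13)
})

test_that("planted fasting responders shift by the configured standardized effect", {
  effects <- sapply(1:30, function(s) {
    cfg <- cohort_config(n_metabolites = 40, n_planted = 10,
                         channel_mix = c(fasting = 1, auc = 0, both = 0),
                         effect_size_fasting = 3, missing_frac = 0, seed = s)
    cc <- generate_cohort(cfg)
    df <- as.data.frame(cc$panel)
    unit <- sqrt(cfg$subject_sd^2 + cfg$residual_sd^2)
    planted <- cc$truth[cc$truth$channel == "fasting", ]
    per_met <- mapply(function(m, d) {
      v <- df[df$metabolite_id == m, ]
      d * (mean(log(v$intensity[v$phase == "post"])) -
             mean(log(v$intensity[v$phase == "pre"]))) / unit
    }, planted$metabolite_id, planted$direction)
    mean(per_met)
  })
  expect_lt(abs(mean(effects) - 3), 0.2)
})

test_that("inert metabolites match the configured log-scale dispersion", {
  sds <- sapply(1:30, function(s) {
    cfg <- cohort_config(n_metabolites = 10, n_planted = 0,
                         class_mix = c(lipid_suppressed = 0, carb_raised = 0,
                                       late_rise_xeno = 0, fasting_shifted = 0,
                                       inert = 1),
                         missing_frac = 0, seed = s)
    df <- as.data.frame(generate_cohort(cfg)$panel)
    mean(tapply(log(df$intensity), df$metabolite_id, sd))
  })
  unit <- sqrt(0.4^2 + 0.3^2)
  se <- sd(sds) / sqrt(length(sds))
  expect_lt(abs(mean(sds) - unit), 3 * se + 0.02)
})

test_that("glucose/insulin generator improves insulin sensitivity post-intervention", {
  deltas <- sapply(1:50, function(s) {
    ci <- cohort_indices(generate_glucose_insulin(cohort_config(seed = s)))
    m <- tapply(ci$indices$matsuda, ci$indices$phase, mean)
    m["post"] - m["pre"]
  })
  expect_gte(sum(deltas > 0), 49)

  rec <- generate_glucose_insulin(cohort_config(seed = 1))
  expect_true(all(rec$glucose_mgdl >= 40))
  expect_true(all(rec$insulin_uUml > 0))
  ins <- cohort_indices(rec)$indices
  expect_lt(mean(ins$fasting_insulin[ins$phase == "post"]),
            mean(ins$fasting_insulin[ins$phase == "pre"]))
})

test_that("zero subject SD and no improvement give identical pre/post series", {
  cfg <- cohort_config(gi_subject_sd = 0, insulin_improvement = 1,
                       glucose_improvement = 1, seed = 8)
  ci <- cohort_indices(generate_glucose_insulin(cfg))$indices
  pre <- ci[ci$phase == "pre", ]
  post <- ci[ci$phase == "post", ]
  common <- intersect(pre$subject_id, post$subject_id)
  expect_equal(pre$matsuda[match(common, pre$subject_id)],
               post$matsuda[match(common, post$subject_id)])
})

test_that("fingerprint generator separates clusters and is deterministic", {
  ids <- paste0("m", 1:12)
  one <- generate_fingerprints(ids, n_bits = 64, n_clusters = 1, noise = 0,
                               seed = 2)
  sim <- ogttmetab:::tanimoto_matrix(one)
  expect_true(all(sim == 1))

  two <- generate_fingerprints(ids, n_bits = 128, n_clusters = 2, noise = 0.02,
                               seed = 3)
  net <- build_network(two, threshold = 0.7)
  expect_gte(nrow(attr(net, "components")), 2)

  expect_identical(generate_fingerprints(ids, 64, 3, seed = 7),
                   generate_fingerprints(ids, 64, 3, seed = 7))
  expect_error(generate_fingerprints(ids, 64, n_clusters = 13, seed = 1),
               "n_clusters")
})
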