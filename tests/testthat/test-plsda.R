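test_that("NIPALS scores are orthogonal and predictions reconstruct from parts", {
  set.seed(1)
  for (k in 1:5) {
    x <- matrix(rnorm(20 * 15), 20, 15)
    y <- rep(c("pre", "post"), 10)
    m <- plsda(x, y, ncomp = 4, fold_weights = FALSE)
    G <- crossprod(m$scores)
    expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
    expect_true(all(abs(colSums(m$weights^2) - 1) < 1e-10))
    # score-space prediction == coefficient prediction
    score_pred <- drop(m$scores %*% m$y_loadings) + m$y_mean
    coef_pred <- predict(m, x)
    expect_equal(score_pred, unname(coef_pred), tolerance = 1e-10)
  }
})

test_that("a single perfectly informative feature gives an exact rank-1 fit", {
  y <- rep(c("pre", "post"), c(6, 6))
  x <- matrix(as.numeric(y == "post"), ncol = 1)
  m <- plsda(x, y, ncomp = 1, fold_weights = FALSE)
  fitted <- predict(m, x)
  r2 <- 1 - sum((m$y01 - fitted)^2) / sum((m$y01 - mean(m$y01))^2)
  expect_equal(r2, 1, tolerance = 1e-12)
})

test_that("univariate PLS equals the least-squares line", {
  set.seed(3)
  x <- matrix(rnorm(30), ncol = 1)
  y <- 2 + 0.8 * x[, 1] + rnorm(30, sd = 0.2)
  m <- plsda(x, y, ncomp = 1, fold_weights = FALSE)
  ols <- lm(y ~ x)
  expect_equal(unname(predict(m, x)), unname(fitted(ols)), tolerance = 1e-10)
})

test_that("pure-noise models have no predictive value", {
  q2 <- sapply(1:30, function(s) {
    set.seed(s)
    x <- matrix(rnorm(27 * 50), 27, 50)
    y <- sample(rep(c("pre", "post"), c(14, 13)))
    loo_q2(x, y, max_comp = 1)$q2[1]
  })
  expect_lt(mean(q2), 0)
  expect_gte(mean(q2 <= 0), 0.7)
  expect_true(all(q2 < 1))
})

test_that("informative data yield high Q2 and LV1 oriented toward the positive class", {
  d <- make_two_class(p = 40, planted = 15, effect = 3, seed = 5)
  q <- loo_q2(d$x, d$y, max_comp = 3)
  expect_gt(max(q$q2), 0.9)
  m <- plsda(d$x, d$y)
  expect_gt(mean(m$scores[d$y == "post", 1]), mean(m$scores[d$y == "pre", 1]))
})

test_that("jackknife weight selection recovers signal and stays calibrated on noise", {
  d <- make_two_class(p = 50, planted = 1, effect = 4, seed = 7)
  m <- plsda(d$x, d$y)
  sel <- select_features(m)
  expect_true(sel$selected[sel$feature_id == d$planted])

  frac <- sapply(1:10, function(s) {
    dn <- make_two_class(p = 50, planted = 0, seed = 100 + s)
    mean(select_features(plsda(dn$x, dn$y, ncomp = 1))$selected)
  })
  expect_lte(mean(frac), 0.10)
})

test_that("constant fold weights at the group mean are never selected", {
  d <- make_two_class(p = 20, planted = 3, effect = 2, seed = 9)
  m <- plsda(d$x, d$y)
  sel0 <- select_features(m)
  j <- which(sel0$sign_group == "positive")[1]
  gmean <- sel0$group_mean[j]
  m$fold_weights[, j] <- gmean
  sel <- select_features(m)
  expect_false(sel$selected[j])
  expect_true(is.na(sel$t[j]))
})

test_that("AUROC counts pairs with half credit for ties", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(c(0.6, 0.3, 0.4, 0.7), c(1, 1, 0, 0)), 0.25)
  expect_equal(auroc(rep(0.5, 8), rep(c(0, 1), 4)), 0.5)
  set.seed(4)
  sc <- rnorm(40)
  lb <- rep(c(0, 1), 20)
  expect_equal(auroc(sc, lb),
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                              direction = "<"))))
  expect_error(auroc(1:3, c(1, 1, 1)), "class")
})

test_that("performance distributions do the bookkeeping and calibrate the null", {
  d <- make_two_class(n1 = 14, n2 = 13, p = 30, planted = 10, effect = 2.5,
                      seed = 11)
  pr <- performance_distributions(d$x, d$y, n_splits = 25, seed = 21)
  expect_equal(nrow(pr$observed), 25)
  expect_equal(nrow(pr$null), 25)
  expect_gt(median(pr$observed$auroc), 0.9)
  expect_lt(pr$p$auroc, 0.2)
  expect_true(all(unlist(pr$p) > 0 & unlist(pr$p) <= 1))
  expect_lt(abs(mean(pr$null$auroc) - 0.5), 0.1)
})

test_that("combined model categorizes features and flags add-backs", {
  set.seed(23)
  n <- 27
  y <- rep(c("pre", "post"), c(14, 13))
  strong <- function(p, eff) {
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("M%02d", seq_len(p))))
    x[y == "post", 1:3] <- x[y == "post", 1:3] + eff
    x
  }
  fx <- strong(10, 3)
  ax <- strong(10, 3)
  mf <- plsda(fx, y)
  ma <- plsda(ax, y)
  sf <- suppressWarnings(select_features(mf))  # tiny panels can leave a
  sa <- suppressWarnings(select_features(ma))  # one-feature sign group
  expect_true(any(sf$selected) && any(sa$selected))
  cm <- combined_model(fx, sf, ax, sa, clinical_x = NULL, y = y)
  expect_true(all(cm$table$in_final == (cm$table$selected_refit |
                                          cm$table$added_back)))
  both_ids <- intersect(sf$feature_id[sf$selected], sa$feature_id[sa$selected])
  if (length(both_ids)) {
    expect_true(all(cm$table$category[cm$table$metabolite_id %in% both_ids]
                    == "both"))
  }
  # force an add-back: inject a pure-noise feature into the fasting selection
  sf2 <- sf
  noise_id <- sf$feature_id[!sf$selected][1]
  sf2$selected[sf2$feature_id == noise_id] <- TRUE
  cm2 <- combined_model(fx, sf2, ax, sa, clinical_x = NULL, y = y)
  row <- cm2$table[cm2$table$feature_id == paste0("fasting:", noise_id), ]
  if (!row$selected_refit) {
    expect_true(row$added_back && row$in_final)
  }
})

test_that("OGTT time model orients loadings by response archetype", {
  cfg <- cohort_config(seed = 3, n_metabolites = 100, n_planted = 0,
                       missing_frac = 0)
  cc <- generate_cohort(cfg)
  tm <- ogtt_time_model(sum_normalize(cc$panel))
  sc <- tm$scores
  expect_gt(cor(sc$lv1, sc$time_min), 0.5)
  ld <- tm$loadings
  carb <- intersect(names(ld),
                    cc$truth$metabolite_id[cc$truth$archetype == "carb_raised"])
  lip <- intersect(names(ld),
                   cc$truth$metabolite_id[cc$truth$archetype == "lipid_suppressed"])
  xeno <- intersect(names(ld),
                    cc$truth$metabolite_id[cc$truth$archetype == "late_rise_xeno"])
  expect_gte(mean(ld[carb] > 0), 0.7)
  expect_gte(mean(ld[lip] < 0), 0.9)
  expect_gte(mean(ld[xeno] > 0), 0.9)
  # late-OGTT score centroids converge: 90 vs 120 closer than 0 vs 90
  cen <- tapply(sc$lv1, sc$time_min, mean)
  expect_lt(abs(cen["90"] - cen["120"]), abs(cen["0"] - cen["90"]))
})

test_that("shuffled time labels destroy the time model's predictivity", {
  nonpos <- sapply(1:10, function(s) {
    set.seed(s)
    x <- matrix(rnorm(27 * 40), 27, 40)
    yt <- sample(rep(c(0, 30, 60, 90, 120), length.out = 27))
    loo_q2(x, yt, max_comp = 1)$q2[1] <= 0
  })
  expect_gte(mean(nonpos), 0.7)
})
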