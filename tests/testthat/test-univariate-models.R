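sim_unbalanced <- function(seed, beta = 0, n_pre = 15, n_post = 12,
                           sb = 1.2, se = 0.7) {
  set.seed(seed)
  subs <- sprintf("S%02d", seq_len(n_pre))
  id <- c(subs, subs[seq_len(n_post)])
  ph <- rep(c("pre", "post"), c(n_pre, n_post))
  b <- rnorm(n_pre, sd = sb)
  names(b) <- subs
  y <- beta * (ph == "post") + b[id] + rnorm(length(id), sd = se)
  data.frame(y = y, phase = ph, subject = id, stringsAsFactors = FALSE)
}

test_that("REML fit matches lme4 on unbalanced pre/post designs", {
  for (s in 1:5) {
    d <- sim_unbalanced(s, beta = 0.5)
    fit <- fit_random_intercept(d$y, d$phase, d$subject)
    m <- lme4::lmer(y ~ ph + (1 | subject),
                    data = transform(d, ph = factor(phase, c("pre", "post"))),
                    REML = TRUE)
    expect_equal(fit$beta, unname(lme4::fixef(m)[2]), tolerance = 1e-6)
    expect_equal(fit$se, sqrt(as.matrix(vcov(m))[2, 2]), tolerance = 1e-6)
    vc <- as.data.frame(lme4::VarCorr(m))
    expect_equal(fit$sigma2_b, vc$vcov[1], tolerance = 1e-5)
    expect_equal(fit$sigma2_e, vc$vcov[2], tolerance = 1e-5)
  }
})

test_that("balanced complete-pair designs reduce to the paired t-test", {
  for (s in 1:100) {
    set.seed(s)
    n <- 10
    subs <- sprintf("S%02d", 1:n)
    b <- rnorm(n, sd = 2)
    pre <- b + rnorm(n, sd = 0.6)
    post <- 0.3 + b + rnorm(n, sd = 0.6)
    fit <- fit_random_intercept(c(pre, post),
                                rep(c("pre", "post"), each = n),
                                rep(subs, 2))
    pt <- paired_t(pre, post)
    if (!fit$boundary) {
      expect_equal(fit$p, pt$p, tolerance = 1e-3)
      expect_equal(fit$t, pt$t, tolerance = 1e-3)
    }
  }
})

test_that("REML profile attains its optimum over a wide ratio grid", {
  d <- sim_unbalanced(7, beta = 0.3)
  fit <- fit_random_intercept(d$y, d$phase, d$subject)
  at_opt <- fit$objective(fit$theta)
  grid <- 10^seq(-6, 6, length.out = 21)
  expect_true(all(fit$objective(fit$theta) <=
                    vapply(grid, fit$objective, numeric(1)) + 1e-6))
  expect_lte(at_opt, fit$objective(0) + 1e-6)
})

test_that("mixed-model type-I error is nominal under the null", {
  ps <- unlist(lapply(1:40, function(s) {
    sapply(1:10, function(k) {
      d <- sim_unbalanced(s * 1000 + k, beta = 0)
      fit_random_intercept(d$y, d$phase, d$subject)$p
    })
  }))
  rate <- mean(ps < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("degenerate responses are handled at the boundary", {
  y <- rep(5, 24)
  fit <- fit_random_intercept(y, rep(c("pre", "post"), each = 12),
                              rep(sprintf("S%02d", 1:12), 2))
  expect_equal(fit$beta, 0)
  expect_equal(fit$p, 1)
})

test_that("paired t matches hand computation and flags degeneracies", {
  pt <- paired_t(c(0, 0, 0), c(1, 2, 3))
  expect_equal(pt$t, 3.464, tolerance = 1e-3)
  expect_equal(round(pt$p, 4), 0.0742)

  same <- paired_t(c(4, 5, 6), c(4, 5, 6))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  deg <- paired_t(c(0, 0, 0), c(1, 1, 1))
  expect_true(deg$degenerate)
})

test_that("fold changes reproduce printed-table arithmetic", {
  expect_equal(round(fold_change(804, 480), 2), 0.60)
  expect_equal(round(fold_change(5040, 3400), 2), 0.67)
  expect_equal(fold_change(7, 7), 1.0)
  expect_error(fold_change(0, 5), "positive")
})

test_that("BH step-up matches the brute-force oracle and hand example", {
  out <- bh_fdr(c(0.001, 0.013, 0.04, 0.8))
  expect_equal(out$reject, c(TRUE, TRUE, FALSE, FALSE))

  all1 <- bh_fdr(rep(1, 6))
  expect_true(all(all1$q == 1) && !any(all1$reject))

  set.seed(13)
  for (k in 1:20) {
    p <- runif(sample(3:12, 1))^sample(1:3, 1)
    q <- bh_fdr(p)$q
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-15))
  }
})

test_that("univariate table recovers planted fasting responders", {
  sens <- sapply(1:3, function(s) {
    cfg <- cohort_config(seed = s, n_metabolites = 60, n_planted = 10,
                         channel_mix = c(fasting = 1, auc = 0, both = 0))
    cc <- generate_cohort(cfg)
    pan <- sum_normalize(presence_filter(cc$panel))
    ut <- univariate_table(pan, "fasting")
    planted <- cc$truth$metabolite_id[cc$truth$channel == "fasting"]
    mean(ut$raw_significant[ut$metabolite_id %in% planted])
  })
  expect_gte(mean(sens), 0.8)
})

test_that("univariate table covers every retained metabolite with q >= p", {
  cfg <- cohort_config(seed = 17, n_metabolites = 25, n_planted = 0)
  pan <- sum_normalize(presence_filter(generate_cohort(cfg)$panel))
  ut <- univariate_table(pan, "fasting")
  expect_equal(nrow(ut), length(unique(pan$metabolite_id)))
  ok <- !is.na(ut$p)
  expect_true(all(ut$q[ok] >= ut$p[ok] - 1e-15))
  expect_true(all(ut$q[ok] <= 1))
  expect_true(all(ut$fold[ok] > 0))
})
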