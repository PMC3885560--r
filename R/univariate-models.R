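#' Random-intercept mixed model for pre/post intervention contrasts
#'
#' Fits `y = mu + beta * phase + b_subject + e`, `b ~ N(0, sb^2)`,
#' `e ~ N(0, se^2)`, by REML. The single variance ratio
#' `theta = sb^2 / se^2` is profiled out by one-dimensional optimization of
#' the REML criterion on the log scale (the boundary `theta = 0` is allowed
#' and reported); for fixed `theta` the GLS solution is closed-form via
#' block inversion per subject, so the fit handles the unbalanced 15-pre /
#' 12-post design directly. Inference on the phase effect uses a Wald t with
#' residual (containment) degrees of freedom `N - n_subjects - 1`.
#'
#' On balanced complete-pair data with the variance ratio off its boundary,
#' the phase t-statistic reduces exactly to the paired t-test.
#'
#' @param y numeric response (normally transform-to-normality output).
#' @param phase character/factor with levels pre, post (effect = post - pre).
#' @param subject subject identifiers.
#' @return list: `beta`, `se`, `t`, `p`, `df`, `mu`, `sigma2_e`, `sigma2_b`,
#'   `theta` (variance ratio), `boundary` (TRUE when theta pinned at 0), and
#'   `objective` (the -2 REML profile criterion as a function of theta, for
#'   diagnostics).
#' @export
fit_random_intercept <- function(y, phase, subject) {
  ok <- is.finite(y)
  y <- y[ok]
  phase <- as.character(phase)[ok]
  subject <- as.character(subject)[ok]
  y_shift <- mean(y)
  y <- y - y_shift  # quadratic forms cancel catastrophically off-center
  if (!all(phase %in% c("pre", "post"))) {
    stop("phase must be 'pre' or 'post'", call. = FALSE)
  }
  x <- as.numeric(phase == "post")
  f <- factor(subject)
  n_subj <- nlevels(f)
  if (n_subj < 3) stop("need >= 3 subjects", call. = FALSE)
  both <- sum(tapply(x, f, function(v) length(unique(v))) == 2)
  if (both < 2) stop("need >= 2 subjects observed in both phases", call. = FALSE)
  N <- length(y)
  groups <- split(seq_len(N), f)

  # -2 * REML profile criterion at variance ratio theta, plus GLS pieces
  gls_at <- function(theta) {
    A <- matrix(0, 2, 2)
    b <- c(0, 0)
    yVy <- 0
    logdetV <- 0
    for (idx in groups) {
      ni <- length(idx)
      Xi <- cbind(1, x[idx])
      yi <- y[idx]
      w <- theta / (1 + ni * theta)
      XtX <- crossprod(Xi)
      Xty <- crossprod(Xi, yi)
      sx <- colSums(Xi)
      sy <- sum(yi)
      A <- A + XtX - w * tcrossprod(sx)
      b <- b + Xty - w * sx * sy
      yVy <- yVy + sum(yi^2) - w * sy^2
      logdetV <- logdetV + log1p(ni * theta)
    }
    beta <- solve(A, b)
    Q <- max(yVy - sum(beta * b), 0)
    list(A = A, beta = beta, Q = Q, logdetV = logdetV)
  }
  objective <- function(theta) {
    g <- gls_at(theta)
    s2 <- g$Q / (N - 2)
    if (s2 <= 0) s2 <- .Machine$double.xmin
    (N - 2) * log(s2) + g$logdetV + determinant(g$A, logarithm = TRUE)$modulus[1]
  }

  opt <- stats::optimize(function(lt) objective(exp(lt)),
                         interval = c(-15, 15), tol = 1e-8)
  theta <- exp(opt$minimum)
  if (objective(0) <= opt$objective) theta <- 0
  boundary <- theta < 1e-8

  g <- gls_at(theta)
  s2e <- g$Q / (N - 2)
  Ainv <- solve(g$A)
  se <- sqrt(max(s2e * Ainv[2, 2], 0))
  beta <- g$beta[2]
  df <- N - n_subj - 1
  if (se == 0) {
    # all-residual-zero degeneracy: no evidence against 0 only if beta is 0
    tt <- if (abs(beta) < 1e-12) 0 else sign(beta) * Inf
  } else {
    tt <- beta / se
  }
  p <- 2 * stats::pt(-abs(tt), df = df)
  list(beta = beta, se = se, t = tt, p = p, df = df, mu = g$beta[1] + y_shift,
       sigma2_e = s2e, sigma2_b = theta * s2e, theta = theta,
       boundary = boundary, objective = objective)
}

#' Paired t-test on completer pre/post values
#'
#' Standard two-sided paired t (df = n - 1). Zero-variance differences with
#' a nonzero mean are flagged degenerate (the statistic is unbounded);
#' identical pre and post give t = 0, p = 1.
#'
#' @param pre,post numeric vectors paired by subject.
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre/post must pair up", call. = FALSE)
  d <- post - pre
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 3) stop("need >= 3 complete pairs", call. = FALSE)
  s <- sd1(d)
  if (s == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, p = 1, df = n - 1, degenerate = FALSE))
    }
    return(list(t = NA_real_, p = NA_real_, df = n - 1, degenerate = TRUE))
  }
  tt <- mean(d) / (s / sqrt(n))
  list(t = tt, p = 2 * stats::pt(-abs(tt), df = n - 1), df = n - 1,
       degenerate = FALSE)
}

#' Fold change of post- over pre-intervention group means
#'
#' Raw-scale ratio `post_mean / pre_mean` of (normalized) group means; the
#' transformed scale is used for testing only, never for the printed fold.
#'
#' @param pre_mean,post_mean group means on the raw normalized scale.
#' @export
fold_change <- function(pre_mean, post_mean) {
  if (!is.finite(pre_mean) || pre_mean <= 0) {
    stop("pre_mean must be positive for a fold change", call. = FALSE)
  }
  post_mean / pre_mean
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up q-values (`q_i = min_{j >= i} m * p_(j) / j`, clipped at 1) with
#' rejection at `q <= q_max`.
#'
#' @param pvalues numeric p-values in `[0, 1]`.
#' @param q_max FDR level (default 0.05).
#' @return list `q` (adjusted values) and `reject` (logical).
#' @export
bh_fdr <- function(pvalues, q_max = 0.05) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- stats::p.adjust(pvalues, method = "BH")
  list(q = q, reject = !is.na(q) & q <= q_max)
}

#' Per-metabolite univariate intervention table
#'
#' The machinery behind the fasting-concentration and AUC intervention
#' tables: for each metabolite, select a transform to normality, fit the
#' random-intercept model (phase fixed, subject random) on the transformed
#' values, and report raw-scale group means, fold change, mixed-model p and
#' the BH q over all metabolites. Raw-p and q-based significance are kept
#' separate: a study of this size can show metabolites at raw p < 0.05 while
#' none survive FDR control.
#'
#' @param panel preprocessed intensity panel.
#' @param endpoint `"fasting"` (time-0 normalized intensities) or `"auc"`
#'   (per-subject incremental AUCs).
#' @param q_max FDR level.
#' @return data.frame: metabolite_id, endpoint, n_pre, n_post, pre_mean,
#'   post_mean, fold, transform, lambda, beta, se, t, p, q, reject_q,
#'   raw_significant.
#' @export
univariate_table <- function(panel, endpoint = c("fasting", "auc"),
                             q_max = 0.05) {
  endpoint <- match.arg(endpoint)
  df <- as.data.frame(panel)
  if (endpoint == "fasting") {
    d0 <- df[df$time_min == 0 & !is.na(df$intensity), ]
    value_df <- data.frame(metabolite_id = d0$metabolite_id,
                           subject_id = d0$subject_id, phase = d0$phase,
                           value = d0$intensity, stringsAsFactors = FALSE)
  } else {
    sa <- cohort_aucs(panel)$subject_aucs
    value_df <- data.frame(metabolite_id = sa$metabolite_id,
                           subject_id = sa$subject_id, phase = sa$phase,
                           value = sa$auc, stringsAsFactors = FALSE)
  }
  rows <- lapply(split(value_df, value_df$metabolite_id), function(d) {
    pre <- d$value[d$phase == "pre"]
    post <- d$value[d$phase == "post"]
    out <- data.frame(metabolite_id = d$metabolite_id[1], endpoint = endpoint,
                      n_pre = length(pre), n_post = length(post),
                      pre_mean = mean(pre), post_mean = mean(post),
                      fold = NA_real_, transform = NA_character_,
                      lambda = NA_real_, beta = NA_real_, se = NA_real_,
                      t = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
    if (is.finite(out$pre_mean) && out$pre_mean > 0) {
      out$fold <- fold_change(out$pre_mean, out$post_mean)
    }
    tc <- tryCatch(select_transform(d$value), error = function(e) NULL)
    if (!is.null(tc)) {
      out$transform <- tc$family
      out$lambda <- tc$lambda
      fit <- tryCatch(
        fit_random_intercept(tc$transform(d$value), d$phase, d$subject_id),
        error = function(e) NULL)
      if (!is.null(fit)) {
        out$beta <- fit$beta
        out$se <- fit$se
        out$t <- fit$t
        out$p <- fit$p
      }
    }
    out
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  fdr <- bh_fdr(tab$p, q_max = q_max)
  tab$q <- fdr$q
  tab$reject_q <- fdr$reject
  tab$raw_significant <- !is.na(tab$p) & tab$p < 0.05
  tab
}
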