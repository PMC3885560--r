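# autoscale that tolerates features constant inside a CV fold: such a
# feature carries no information in the fold, so it is centered and given
# unit scale (scaled values 0) instead of erroring like autoscale()
fold_autoscale <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd1)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(x = sweep(sweep(x, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

# NIPALS PLS1 on an autoscaled X and centered y. Returns weights W (each
# column unit norm), scores T, X-loadings P, y-loadings q, per-component.
nipals_pls1 <- function(X, y, A) {
  n <- nrow(X)
  p <- ncol(X)
  A <- min(A, n - 1, p)
  W <- matrix(0, p, A)
  P <- matrix(0, p, A)
  Tm <- matrix(0, n, A)
  q <- numeric(A)
  Xa <- X
  ya <- y
  a_used <- 0
  for (a in seq_len(A)) {
    w <- crossprod(Xa, ya)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break  # deflated X orthogonal to y: rank exhausted
    w <- w / nw
    t <- Xa %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pl <- crossprod(Xa, t) / tt
    qa <- sum(ya * t) / tt
    W[, a] <- w
    P[, a] <- pl
    Tm[, a] <- t
    q[a] <- qa
    Xa <- Xa - tcrossprod(t, pl)
    ya <- ya - qa * t
    a_used <- a
  }
  if (a_used < A) {
    W <- W[, seq_len(a_used), drop = FALSE]
    P <- P[, seq_len(a_used), drop = FALSE]
    Tm <- Tm[, seq_len(a_used), drop = FALSE]
    q <- q[seq_len(a_used)]
  }
  list(weights = W, loadings = P, scores = Tm, y_loadings = q,
       ncomp = a_used)
}

# regression coefficients (on the autoscaled X scale) using a components
pls_coef <- function(fit, a = fit$ncomp) {
  W <- fit$weights[, seq_len(a), drop = FALSE]
  P <- fit$loadings[, seq_len(a), drop = FALSE]
  q <- fit$y_loadings[seq_len(a)]
  W %*% solve(crossprod(P, W), q)
}

code_response <- function(y) {
  if (is.numeric(y) && length(unique(y)) > 2) {
    list(y01 = as.numeric(y), classes = NULL, discriminant = FALSE)
  } else {
    f <- factor(y)
    if (nlevels(f) != 2) stop("y must have exactly two classes", call. = FALSE)
    # put 'pre' first when present so the positive class is 'post'
    if (all(c("pre", "post") %in% levels(f))) f <- factor(f, c("pre", "post"))
    list(y01 = as.numeric(f) - 1, classes = levels(f), discriminant = TRUE)
  }
}

#' Fit a PLS-DA (or PLS regression) model by NIPALS
#'
#' Autoscales `X`, codes a two-class `y` as centered 0/1 (a numeric `y` with
#' more than two distinct values is treated as a continuous response, e.g.
#' OGTT time), and runs NIPALS PLS1. The component count is chosen as the
#' maximizer of leave-one-out Q2 (autoscaling re-estimated inside every
#' fold), capped at `max_comp`; pass `ncomp` to fix it instead. Missing
#' entries are imputed with the feature's training mean (0 after
#' autoscaling) and counted in `n_imputed`. Latent variable 1 is oriented so
#' the positive class (or the response, for continuous `y`) has positive
#' score correlation.
#'
#' @param x samples x features matrix.
#' @param y class labels (two classes; `pre`/`post` order is respected) or a
#'   continuous response.
#' @param ncomp fixed number of components (optional).
#' @param max_comp cap on the LOO-selected component count.
#' @param fold_weights if TRUE (default), keep each LOO fold's component-1
#'   weight vector (sign-aligned to the full model) for jackknife feature
#'   selection.
#' @return object of class `plsda`: weights/loadings/scores/y-loadings,
#'   `q2` (per component count), `ncomp`, `coefficients`, autoscale
#'   center/scale, `fold_weights`, `feature_ids`, class coding.
#' @export
plsda <- function(x, y, ncomp = NULL, max_comp = 5, fold_weights = TRUE) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  n_imputed <- sum(is.na(x))
  if (n_imputed > 0) {
    for (j in seq_len(ncol(x))) {
      nas <- is.na(x[, j])
      if (any(nas)) x[nas, j] <- mean(x[!nas, j])
    }
  }
  cr <- code_response(y)
  n <- nrow(x)
  if (n < 3) stop("need >= 3 samples", call. = FALSE)
  sc <- autoscale(x)
  yc <- cr$y01 - mean(cr$y01)

  cap <- min(max_comp, n - 2, ncol(x))
  q2 <- loo_q2_scaled(x, cr$y01, cap)
  a_star <- ncomp %||% which.max(q2)
  a_star <- min(a_star, n - 1, ncol(x))

  fit <- nipals_pls1(sc$x, yc, a_star)
  if (fit$ncomp == 0) stop("no usable PLS component (X orthogonal to y)",
                           call. = FALSE)
  a_star <- fit$ncomp

  # orientation: LV1 score correlates positively with the response
  if (stats::cor(fit$scores[, 1], cr$y01) < 0) {
    fit$weights[, 1] <- -fit$weights[, 1]
    fit$loadings[, 1] <- -fit$loadings[, 1]
    fit$scores[, 1] <- -fit$scores[, 1]
    fit$y_loadings[1] <- -fit$y_loadings[1]
  }

  fw <- NULL
  if (fold_weights) {
    fw <- matrix(NA_real_, n, ncol(x))
    for (i in seq_len(n)) {
      sci <- fold_autoscale(x[-i, , drop = FALSE])
      yci <- cr$y01[-i] - mean(cr$y01[-i])
      fi <- nipals_pls1(sci$x, yci, 1)
      if (fi$ncomp >= 1) {
        w <- fi$weights[, 1]
        if (sum(w * fit$weights[, 1]) < 0) w <- -w  # sign-align to full model
        fw[i, ] <- w
      }
    }
    fw <- fw[stats::complete.cases(fw), , drop = FALSE]
    colnames(fw) <- colnames(x)
  }

  structure(list(
    feature_ids = colnames(x), center = sc$center, scale = sc$scale,
    weights = fit$weights, loadings = fit$loadings, scores = fit$scores,
    y_loadings = fit$y_loadings, ncomp = a_star, q2 = q2,
    coefficients = pls_coef(fit), y_mean = mean(cr$y01), y01 = cr$y01,
    classes = cr$classes, discriminant = cr$discriminant,
    fold_weights = fw, n_imputed = n_imputed), class = "plsda")
}

#' @rdname plsda
#' @param object fitted `plsda` model.
#' @param newx samples x features matrix on the raw scale (training
#'   autoscaling is applied, never the test sample's own).
#' @param ... unused.
#' @export
predict.plsda <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  if (!is.null(colnames(newx))) {
    newx <- newx[, object$feature_ids, drop = FALSE]
  } else if (ncol(newx) != length(object$feature_ids)) {
    stop("newx has no column names and its width does not match the model",
         call. = FALSE)
  }
  for (j in seq_len(ncol(newx))) {
    nas <- is.na(newx[, j])
    if (any(nas)) newx[nas, j] <- object$center[j]
  }
  xs <- sweep(sweep(newx, 2, object$center), 2, object$scale, "/")
  drop(xs %*% object$coefficients) + object$y_mean
}

# LOO PRESS path on raw x / 0-1 (or continuous) y; autoscaling re-estimated
# inside each fold
loo_q2_scaled <- function(x, y01, max_a) {
  n <- nrow(x)
  max_a <- min(max_a, n - 2, ncol(x))
  if (max_a < 1) return(NA_real_)
  press <- matrix(NA_real_, n, max_a)
  for (i in seq_len(n)) {
    sci <- fold_autoscale(x[-i, , drop = FALSE])
    yi <- y01[-i]
    fit <- nipals_pls1(sci$x, yi - mean(yi), max_a)
    if (fit$ncomp == 0) next
    xs <- (x[i, ] - sci$center) / sci$scale
    for (a in seq_len(fit$ncomp)) {
      pred <- sum(xs * pls_coef(fit, a)) + mean(yi)
      press[i, a] <- (y01[i] - pred)^2
    }
    if (fit$ncomp < max_a) {
      press[i, (fit$ncomp + 1):max_a] <- press[i, fit$ncomp]
    }
  }
  tss <- sum((y01 - mean(y01))^2)
  1 - colSums(press, na.rm = TRUE) / tss
}

#' Leave-one-out Q2 path
#'
#' `Q2(a) = 1 - PRESS(a) / TSS` with PRESS from leave-one-out refits,
#' re-estimating the autoscaling inside every fold. Q2 never exceeds 1;
#' values at or below 0 mean no predictive value.
#'
#' @param x samples x features matrix (raw scale).
#' @param y two-class labels or continuous response.
#' @param max_comp largest component count to evaluate.
#' @return list with `q2` (vector over component counts) and `best`
#'   (argmax).
#' @export
loo_q2 <- function(x, y, max_comp = 5) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need >= 3 samples", call. = FALSE)
  cr <- code_response(y)
  q2 <- loo_q2_scaled(x, cr$y01, max_comp)
  list(q2 = q2, best = which.max(q2))
}

#' Jackknife weight-based feature selection
#'
#' Features are split by the sign of their full-model LV1 weight; within
#' each sign group, each feature's leave-one-out fold weights are tested
#' against the group's mean full-model weight with a one-sample t whose
#' standard error is the jackknife estimator
#' `SE^2 = (n-1)/n * sum((w_(-i) - wbar)^2)` (leave-one-out replicates
#' underestimate sampling variance by ~1/n, so the naive SD/sqrt(n) would be
#' badly anticonservative). A feature is selected iff p < 0.05 and its mean
#' fold weight is more extreme than the group mean, away from zero.
#'
#' @param model a [plsda()] fit with `fold_weights`.
#' @param alpha selection level.
#' @return data.frame: feature_id, sign_group, mean_weight (fold mean),
#'   group_mean, t, p, selected.
#' @export
select_features <- function(model, alpha = 0.05) {
  if (is.null(model$fold_weights) || nrow(model$fold_weights) < 3) {
    stop("model has no usable fold weights (refit with fold_weights = TRUE)",
         call. = FALSE)
  }
  w1 <- model$weights[, 1]
  fw <- model$fold_weights
  n <- nrow(fw)
  out <- data.frame(feature_id = model$feature_ids,
                    sign_group = ifelse(w1 > 0, "positive",
                                        ifelse(w1 < 0, "negative", "zero")),
                    mean_weight = colMeans(fw), group_mean = NA_real_,
                    t = NA_real_, p = NA_real_, selected = FALSE,
                    stringsAsFactors = FALSE)
  for (grp in c("positive", "negative")) {
    in_grp <- out$sign_group == grp
    if (sum(in_grp) < 2) {
      if (any(in_grp)) warning("sign group '", grp,
                               "' has fewer than 2 features; skipped")
      next
    }
    gmean <- mean(w1[in_grp])
    out$group_mean[in_grp] <- gmean
    for (j in which(in_grp)) {
      v <- fw[, j]
      wbar <- mean(v)
      se <- sqrt((n - 1) / n * sum((v - wbar)^2))
      if (se == 0) next  # constant fold weights: t undefined, not selected
      tt <- (wbar - gmean) / se
      pp <- 2 * stats::pt(-abs(tt), df = n - 1)
      more_extreme <- if (grp == "positive") wbar > gmean else wbar < gmean
      out$t[j] <- tt
      out$p[j] <- pp
      out$selected[j] <- pp < alpha && more_extreme
    }
  }
  out
}

#' Area under the ROC curve by pair counting
#'
#' Mann-Whitney statistic: the fraction of (positive, negative) pairs ranked
#' concordantly, with half credit for ties. 0.5 for random scores.
#'
#' @param scores numeric classifier scores.
#' @param labels two-class labels; the second factor level (or `post` when
#'   levels are pre/post, or 1 for 0/1 coding) is the positive class.
#' @export
auroc <- function(scores, labels) {
  cr <- code_response(labels)
  if (!cr$discriminant) stop("labels must be two-class", call. = FALSE)
  pos <- cr$y01 == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)  # average ranks give the half-credit tie convention
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Resampling and permutation performance distributions
#'
#' For each of `n_splits` random stratified 2/3-1/3 train/test splits, fits
#' the model on the training split (component count by LOO within the
#' split), and records training Q2, test RMSEP and test AUROC; the null
#' repeats the identical procedure with class labels permuted independently
#' per split. Empirical p-values use the add-one rule
#' `(1 + exceedances) / (n_splits + 1)` against the observed median
#' (exceedance means null >= observed for Q2/AUROC, null <= observed for
#' RMSEP).
#'
#' @param x samples x features matrix.
#' @param y two-class labels.
#' @param n_splits number of resampling splits.
#' @param train_frac training fraction.
#' @param max_comp component cap per split.
#' @param seed RNG seed.
#' @return object of class `permutation_report`: `observed` and `null`
#'   data.frames (columns q2, rmsep, auroc) and `p` (named list).
#' @export
performance_distributions <- function(x, y, n_splits = 100, train_frac = 2 / 3,
                                      max_comp = 5, seed = NULL) {
  x <- as.matrix(x)
  cr <- code_response(y)
  if (!cr$discriminant) stop("y must be two-class", call. = FALSE)
  y01 <- cr$y01
  n <- length(y01)
  idx1 <- which(y01 == 1)
  idx0 <- which(y01 == 0)
  n1_tr <- round(length(idx1) * train_frac)
  n0_tr <- round(length(idx0) * train_frac)
  if (n1_tr < 2 || n0_tr < 2 || n1_tr >= length(idx1) || n0_tr >= length(idx0)) {
    stop("classes too small for a ", format(train_frac), " training split",
         call. = FALSE)
  }
  one_split <- function(labels, train) {
    fit <- plsda(x[train, , drop = FALSE], labels[train],
                 max_comp = max_comp, fold_weights = FALSE)
    pred <- predict.plsda(fit, x[-train, , drop = FALSE])
    list(q2 = max(fit$q2, na.rm = TRUE),
         rmsep = sqrt(mean((labels[-train] - pred)^2)),
         auroc = auroc(pred, labels[-train]))
  }
  with_seed(seed, {
    obs <- null <- matrix(NA_real_, n_splits, 3,
                          dimnames = list(NULL, c("q2", "rmsep", "auroc")))
    for (k in seq_len(n_splits)) {
      train <- c(sample(idx1, n1_tr), sample(idx0, n0_tr))
      o <- one_split(y01, train)
      obs[k, ] <- c(o$q2, o$rmsep, o$auroc)
      # permuted-label null: resample labelings until the training split
      # contains both classes (capped)
      ok <- FALSE
      for (try in 1:100) {
        yperm <- sample(y01)
        if (length(unique(yperm[train])) == 2 &&
            length(unique(yperm[-train])) == 2) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not draw a permuted labeling with both classes in ",
                    "each split", call. = FALSE)
      np <- one_split(yperm, train)
      null[k, ] <- c(np$q2, np$rmsep, np$auroc)
    }
    p <- list(
      q2 = (1 + sum(null[, "q2"] >= stats::median(obs[, "q2"]))) / (n_splits + 1),
      rmsep = (1 + sum(null[, "rmsep"] <= stats::median(obs[, "rmsep"]))) / (n_splits + 1),
      auroc = (1 + sum(null[, "auroc"] >= stats::median(obs[, "auroc"]))) / (n_splits + 1))
    structure(list(observed = as.data.frame(obs), null = as.data.frame(null),
                   p = p, n_splits = n_splits), class = "permutation_report")
  })
}

#' Combined fasting + AUC + clinical PLS-DA model with add-back
#'
#' Builds the candidate block from the features selected in the fasting
#' model, the features selected in the AUC model, and the clinical
#' insulin-sensitivity indices, refits PLS-DA on the union, re-runs the
#' jackknife weight selection, and reports the final feature table: features
#' surviving re-selection plus "add-backs" (features selected in a base
#' model but dropped on refit), each categorized as fasting-only, AUC-only,
#' both (metabolite selected in both base models) or clinical.
#'
#' @param fasting_x,auc_x samples x features matrices aligned to the same
#'   sample order (rows = subject-phase).
#' @param fasting_sel,auc_sel selection tables from [select_features()] on
#'   the base models.
#' @param clinical_x samples x clinical-index matrix (same row order), or
#'   NULL.
#' @param y class labels (phase per row).
#' @param max_comp component cap.
#' @return list: `model` (the refit [plsda()]), `selection` (re-selection
#'   table), `table` (final feature table with category and added_back).
#' @export
combined_model <- function(fasting_x, fasting_sel, auc_x, auc_sel,
                           clinical_x = NULL, y, max_comp = 5) {
  f_ids <- fasting_sel$feature_id[fasting_sel$selected]
  a_ids <- auc_sel$feature_id[auc_sel$selected]
  if (!length(f_ids) || !length(a_ids)) {
    stop("both base selections must be non-empty", call. = FALSE)
  }
  blocks <- list(fasting_x[, f_ids, drop = FALSE],
                 auc_x[, a_ids, drop = FALSE])
  names_all <- c(paste0("fasting:", f_ids), paste0("auc:", a_ids))
  if (!is.null(clinical_x)) {
    blocks <- c(blocks, list(as.matrix(clinical_x)))
    names_all <- c(names_all, paste0("clinical:", colnames(clinical_x)))
  }
  xc <- do.call(cbind, blocks)
  colnames(xc) <- names_all
  model <- plsda(xc, y, max_comp = max_comp)
  resel <- select_features(model)

  src <- sub(":.*$", "", names_all)
  met <- sub("^[^:]*:", "", names_all)
  category <- ifelse(src == "clinical", "clinical",
                     ifelse(met %in% intersect(f_ids, a_ids), "both",
                            ifelse(src == "fasting", "fasting_only",
                                   "auc_only")))
  kept <- resel$selected[match(names_all, resel$feature_id)]
  added_back <- !kept & src != "clinical"  # base-selected but dropped on refit
  tab <- data.frame(feature_id = names_all, metabolite_id = met,
                    source = src, category = category,
                    selected_refit = kept, added_back = added_back,
                    in_final = kept | added_back,
                    stringsAsFactors = FALSE)
  list(model = model, selection = resel, table = tab)
}

#' OGTT time-course PLS model on intervention-adjusted data
#'
#' Centers every metabolite within phase (removing the intervention main
#' effect, so pre/post differences do not masquerade as time structure) and
#' regresses the adjusted sample x metabolite matrix on OGTT time (minutes)
#' by PLS. LV1 is oriented so the score-time correlation is positive:
#' metabolites rising through the OGTT load positively, suppressed
#' metabolites negatively. The LV1 loadings feed the chemical-similarity
#' network; the per-sample scores grouped by timepoint draw the OGTT
#' trajectory.
#'
#' @param panel preprocessed intensity panel (all OGTT timepoints).
#' @param max_comp component cap.
#' @return list: `model` ([plsda()] fit on time), `scores` (data.frame
#'   subject_id, phase, time_min, lv1, lv2), `loadings` (named LV1 loading
#'   vector).
#' @export
ogtt_time_model <- function(panel, max_comp = 5) {
  df <- as.data.frame(panel)
  sample_key <- paste(df$subject_id, df$phase, df$time_min, sep = "\r")
  mets <- sort(unique(df$metabolite_id))
  samples <- unique(data.frame(key = sample_key, subject_id = df$subject_id,
                               phase = df$phase, time_min = df$time_min,
                               stringsAsFactors = FALSE))
  x <- matrix(NA_real_, nrow(samples), length(mets),
              dimnames = list(samples$key, mets))
  x[cbind(match(sample_key, samples$key), match(df$metabolite_id, mets))] <-
    df$intensity
  # intervention adjustment: subtract each metabolite's phase-specific mean
  for (ph in unique(samples$phase)) {
    rows <- samples$phase == ph
    x[rows, ] <- sweep(x[rows, , drop = FALSE], 2,
                       colMeans(x[rows, , drop = FALSE], na.rm = TRUE))
  }
  keep <- apply(x, 2, function(col) sum(is.finite(col)) >= 3 &&
                  sd1(col[is.finite(col)]) > 0)
  x <- x[, keep, drop = FALSE]
  model <- plsda(x, samples$time_min, max_comp = max_comp,
                 fold_weights = FALSE)
  sc <- data.frame(samples[c("subject_id", "phase", "time_min")],
                   lv1 = model$scores[, 1],
                   lv2 = if (model$ncomp >= 2) model$scores[, 2] else NA_real_,
                   stringsAsFactors = FALSE)
  list(model = model,
       scores = sc,
       loadings = stats::setNames(model$loadings[, 1], model$feature_ids))
}
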