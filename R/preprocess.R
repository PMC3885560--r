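#' Presence filter for reported metabolites
#'
#' A metabolite is reported only if it was detected (non-missing) in at least
#' `min_frac` of the samples, where a "sample" is one (subject, phase, time)
#' observation -- the per-injection reporting convention of GC-TOF practice.
#' The default 0.5 keeps metabolites present in at least 50% of samples;
#' the bound is inclusive (exactly 50% presence is retained).
#'
#' @param panel intensity panel.
#' @param min_frac minimum presence fraction in (0, 1].
#' @return Filtered panel; the dropped ids and their presence fractions are
#'   attached as attribute `"dropped"` (a data.frame).
#' @export
presence_filter <- function(panel, min_frac = 0.5) {
  min_frac <- check_fraction(min_frac, "min_frac", open_left = TRUE)
  if (nrow(panel) == 0) {
    warning("empty panel; nothing to filter")
    attr(panel, "dropped") <- data.frame(metabolite_id = character(0),
                                         presence = numeric(0))
    return(panel)
  }
  sample_key <- paste(panel$subject_id, panel$phase, panel$time_min, sep = "\r")
  n_samples <- length(unique(sample_key))
  present <- tapply(!is.na(panel$intensity), panel$metabolite_id, sum)
  presence <- as.numeric(present) / n_samples
  names(presence) <- names(present)
  keep <- names(presence)[presence >= min_frac]
  dropped <- data.frame(metabolite_id = setdiff(names(presence), keep),
                        presence = presence[setdiff(names(presence), keep)],
                        row.names = NULL, stringsAsFactors = FALSE)
  out <- panel[panel$metabolite_id %in% keep, , drop = FALSE]
  out <- intensity_panel(out, panel_schedule(panel))
  attr(out, "dropped") <- dropped
  out
}

#' Sum-intensity normalization
#'
#' Within each (subject, phase, time) sample, each reported peak height is
#' divided by the sum of that sample's reported (non-missing) intensities, so
#' values become relative abundances summing to 1 per sample. Missing values
#' stay missing.
#'
#' @param panel intensity panel.
#' @export
sum_normalize <- function(panel) {
  sample_key <- paste(panel$subject_id, panel$phase, panel$time_min, sep = "\r")
  sums <- tapply(panel$intensity, sample_key, function(v) sum(v, na.rm = TRUE))
  n_obs <- tapply(!is.na(panel$intensity), sample_key, sum)
  dead <- names(n_obs)[n_obs == 0]
  if (length(dead)) {
    stop("sample(s) with all intensities missing: ",
         paste(gsub("\r", "/", utils::head(dead, 5)), collapse = ", "),
         call. = FALSE)
  }
  panel$intensity <- panel$intensity / as.numeric(sums[sample_key])
  intensity_panel(as.data.frame(panel), panel_schedule(panel))
}

#' Anderson-Darling statistic for composite normality
#'
#' Computes the A-squared statistic against the normal family with mean and
#' SD estimated from the sample, scaled by the small-sample multiplier
#' `(1 + 4/n - 25/n^2)`; under this convention the 5% critical value is
#' 0.752. Used to score candidate transforms in [select_transform()].
#'
#' @param values numeric vector, at least 8 finite values with positive SD.
#' @return The multiplied A-squared statistic (a single number).
#' @export
anderson_darling <- function(values) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 8) stop("need at least 8 finite values", call. = FALSE)
  s <- sd1(x)
  if (!is.finite(s) || s == 0) {
    stop("constant input: normality test undefined", call. = FALSE)
  }
  z <- sort((x - mean(x)) / s)
  # guard log(0) at extreme standardized values
  p <- pmin(pmax(stats::pnorm(z), .Machine$double.xmin), 1 - 1e-16)
  i <- seq_len(n)
  a2 <- -n - mean((2 * i - 1) * (log(p) + log(1 - rev(p))))
  a2 * (1 + 4 / n - 25 / n^2)
}

transform_families <- function() {
  list(
    identity    = list(fun = identity, needs = "any", lambda = NA_real_),
    log         = list(fun = log, needs = "positive", lambda = NA_real_),
    sqrt        = list(fun = sqrt, needs = "nonnegative", lambda = NA_real_),
    `cube-root` = list(fun = function(x) sign(x) * abs(x)^(1 / 3),
                       needs = "any", lambda = NA_real_),
    square      = list(fun = function(x) x^2, needs = "any", lambda = NA_real_)
  )
}

# Power transform in the sign-adjusted form sign(lambda) * x^lambda, an
# increasing affine image of the classic Box-Cox (x^lambda - 1)/lambda.
# The Anderson-Darling score and all downstream location tests are affine
# invariant, and this form avoids the catastrophic cancellation the shifted
# version suffers when x^lambda is small against the 1/lambda constant
# (normalized abundances are ~1e-4, so x^2 sits 8 decades below 0.5).
boxcox_fun <- function(lambda) function(x) sign(lambda) * x^lambda

#' Select a transform to normality
#'
#' Evaluates a fixed candidate set -- identity, log, square root, cube root,
#' square, and Box-Cox over lambda in {-2, -1, -0.5, 0.5, 1, 2} -- and
#' returns the candidate minimizing the Anderson-Darling statistic. Log and
#' Box-Cox candidates are marked infeasible when any value is nonpositive
#' (no silent offsets: offsets change inference invisibly). Ties break toward
#' the simpler family in the order identity < log < sqrt < cube-root <
#' square < box-cox.
#'
#' @param values numeric vector to transform.
#' @param boxcox_lambdas Box-Cox exponents to try.
#' @return A list of class `transform_choice`: `family`, `lambda`,
#'   `ad_statistic`, `transform` (the function), and `candidates` (data.frame
#'   of every candidate's A-squared, `NA` where infeasible).
#' @export
select_transform <- function(values, boxcox_lambdas = c(-2, -1, -0.5, 0.5, 1, 2)) {
  x <- values[is.finite(values)]
  fams <- transform_families()
  cand <- data.frame(family = names(fams), lambda = NA_real_,
                     ad = NA_real_, stringsAsFactors = FALSE)
  for (lam in boxcox_lambdas) {
    cand <- rbind(cand, data.frame(family = "box-cox", lambda = lam, ad = NA_real_))
  }
  funs <- c(lapply(fams, `[[`, "fun"), lapply(boxcox_lambdas, boxcox_fun))
  needs <- c(vapply(fams, `[[`, "", "needs"), rep("positive", length(boxcox_lambdas)))
  for (k in seq_len(nrow(cand))) {
    ok <- switch(needs[k],
                 any = TRUE,
                 nonnegative = all(x >= 0),
                 positive = all(x > 0))
    if (!ok) next
    y <- funs[[k]](x)
    if (!all(is.finite(y)) || sd1(y) == 0) next
    cand$ad[k] <- tryCatch(anderson_darling(y), error = function(e) NA_real_)
  }
  if (all(is.na(cand$ad))) stop("no feasible transform candidate", call. = FALSE)
  best <- which(cand$ad == min(cand$ad, na.rm = TRUE))[1]  # ties: earlier = simpler
  structure(list(family = cand$family[best], lambda = cand$lambda[best],
                 ad_statistic = cand$ad[best], transform = funs[[best]],
                 candidates = cand),
            class = "transform_choice")
}

#' Autoscale a sample-by-feature matrix
#'
#' Centers each feature (column) to mean 0 and scales to sample SD 1
#' (n - 1 denominator), the standard pretreatment for PLS-DA. Centers and
#' scales are returned so held-out samples can be projected with the
#' training parameters rather than their own.
#'
#' @param x numeric matrix, samples in rows, features in columns.
#' @return list with `x` (scaled matrix), `center`, `scale`.
#' @export
autoscale <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd1)
  zero <- which(!is.finite(scl) | scl == 0)
  if (length(zero)) {
    stop("zero-variance feature(s): ",
         paste(utils::head(colnames(x)[zero] %||% zero, 5), collapse = ", "),
         call. = FALSE)
  }
  list(x = sweep(sweep(x, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

#' @rdname autoscale
#' @param scaling an object returned by [autoscale()] on the training data.
#' @export
apply_autoscale <- function(x, scaling) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, scaling$center), 2, scaling$scale, "/")
}

#' Per-metabolite transform report over a panel
#'
#' Runs [select_transform()] on each metabolite's non-missing values and
#' returns a long report (metabolite, family, lambda, A-squared).
#'
#' @param panel intensity panel (normally after [sum_normalize()]).
#' @export
transform_report <- function(panel) {
  ids <- unique(panel$metabolite_id)
  rows <- lapply(ids, function(m) {
    v <- panel$intensity[panel$metabolite_id == m]
    tc <- tryCatch(select_transform(v), error = function(e) NULL)
    if (is.null(tc)) {
      data.frame(metabolite_id = m, family = NA_character_, lambda = NA_real_,
                 ad_statistic = NA_real_, stringsAsFactors = FALSE)
    } else {
      data.frame(metabolite_id = m, family = tc$family, lambda = tc$lambda,
                 ad_statistic = tc$ad_statistic, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
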