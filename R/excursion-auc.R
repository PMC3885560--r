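#' Incremental (baseline-subtracted) area under an OGTT excursion
#'
#' Trapezoidal integral of `value(t) - value(0)` over the observed span.
#' Interior missing timepoints are bridged linearly between flanking
#' observations (which is what the trapezoid over the remaining points
#' computes); a missing terminal timepoint shortens the integration span --
#' no extrapolation. The result is signed: metabolites suppressed after the
#' glucose load have negative incremental AUC. Set `total = TRUE` for the
#' non-subtracted total AUC (sensitivity-analysis mode).
#'
#' @param times strictly increasing minutes including 0.
#' @param values intensities at `times`; `NA` = missing. The baseline (t=0)
#'   must be observed and at least 3 points overall.
#' @param total if TRUE, integrate the raw values without baseline
#'   subtraction.
#' @return signed area (peak height x minutes), with the integration span
#'   attached as attribute `"span"`.
#' @export
incremental_auc <- function(times, values, total = FALSE) {
  if (length(times) != length(values)) stop("length mismatch", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (times[1] != 0) stop("series must start at time 0", call. = FALSE)
  if (is.na(values[1])) stop("missing baseline (t = 0) value", call. = FALSE)
  obs <- !is.na(values)
  if (sum(obs) < 3) stop("need >= 3 observed timepoints including baseline",
                         call. = FALSE)
  t <- times[obs]
  v <- values[obs]
  if (!total) v <- v - v[1]
  auc <- sum(diff(t) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
  attr(auc, "span") <- c(t[1], t[length(t)])
  auc
}

#' Per-metabolite excursion AUCs with one-sample tests
#'
#' For every metabolite and phase: computes each subject's incremental AUC,
#' then the group mean +/- SEM and a two-sided one-sample t-test of the mean
#' AUC against zero (df = n - 1) -- equivalent to asking whether the 95%
#' confidence interval of the excursion overlaps zero. Subjects without a
#' usable series (missing baseline or < 3 observed points) are skipped and
#' counted.
#'
#' @param panel preprocessed intensity panel.
#' @param total passed through to [incremental_auc()].
#' @return list with `results` (metabolite x phase data.frame: n, mean_auc,
#'   sem_auc, t, p, nonzero, untestable, degenerate, n_skipped) and
#'   `subject_aucs` (long data.frame of per-subject AUCs).
#' @export
cohort_aucs <- function(panel, total = FALSE) {
  schedule <- panel_schedule(panel)
  df <- as.data.frame(panel)
  split_key <- interaction(df$metabolite_id, df$phase, drop = TRUE)
  subj_rows <- list()
  res_rows <- list()
  for (chunk in split(df, split_key)) {
    m <- chunk$metabolite_id[1]
    ph <- chunk$phase[1]
    aucs <- c()
    subs <- c()
    skipped <- 0L
    for (s in unique(chunk$subject_id)) {
      r <- chunk[chunk$subject_id == s, ]
      v <- r$intensity[match(schedule, r$time_min)]
      a <- tryCatch(incremental_auc(schedule, v, total = total),
                    error = function(e) NULL)
      if (is.null(a)) {
        skipped <- skipped + 1L
      } else {
        aucs <- c(aucs, as.numeric(a))
        subs <- c(subs, s)
      }
    }
    n <- length(aucs)
    if (n) {
      subj_rows[[length(subj_rows) + 1L]] <-
        data.frame(metabolite_id = m, phase = ph, subject_id = subs,
                   auc = aucs, stringsAsFactors = FALSE)
    }
    untestable <- n < 3
    degenerate <- !untestable && sd1(aucs) == 0
    if (untestable || degenerate) {
      tt <- pp <- NA_real_
      sem <- if (n > 1) sd1(aucs) / sqrt(n) else NA_real_
    } else {
      sem <- sd1(aucs) / sqrt(n)
      tt <- mean(aucs) / sem
      pp <- 2 * stats::pt(-abs(tt), df = n - 1)
    }
    res_rows[[length(res_rows) + 1L]] <-
      data.frame(metabolite_id = m, phase = ph, n = n,
                 mean_auc = if (n) mean(aucs) else NA_real_,
                 sem_auc = sem, t = tt, p = pp,
                 nonzero = isTRUE(pp < 0.05),
                 untestable = untestable, degenerate = degenerate,
                 n_skipped = skipped, stringsAsFactors = FALSE)
  }
  list(results = do.call(rbind, res_rows),
       subject_aucs = do.call(rbind, subj_rows))
}

#' Classify a metabolite's OGTT responsiveness across phases
#'
#' Truth table over the two phase-level "AUC differs from zero" flags:
#' `both`, `pre_only`, `post_only`, `neither`. An untestable phase counts as
#' not-nonzero and sets the `flagged` attribute.
#'
#' @param pre,post single rows of the `results` table from [cohort_aucs()]
#'   (or any lists with `nonzero` and `untestable` elements).
#' @export
classify_responsiveness <- function(pre, post) {
  flag <- isTRUE(pre$untestable) || isTRUE(post$untestable)
  a <- isTRUE(pre$nonzero) && !isTRUE(pre$untestable)
  b <- isTRUE(post$nonzero) && !isTRUE(post$untestable)
  cls <- if (a && b) "both" else if (a) "pre_only" else if (b) "post_only" else "neither"
  structure(cls, flagged = flag)
}

#' @rdname classify_responsiveness
#' @param auc_results `results` table from [cohort_aucs()] covering both
#'   phases.
#' @return data.frame metabolite_id, class, flagged.
#' @export
responsiveness_table <- function(auc_results) {
  ids <- unique(auc_results$metabolite_id)
  rows <- lapply(ids, function(m) {
    pre <- auc_results[auc_results$metabolite_id == m & auc_results$phase == "pre", ]
    post <- auc_results[auc_results$metabolite_id == m & auc_results$phase == "post", ]
    if (!nrow(pre)) pre <- data.frame(nonzero = FALSE, untestable = TRUE)
    if (!nrow(post)) post <- data.frame(nonzero = FALSE, untestable = TRUE)
    cls <- classify_responsiveness(pre, post)
    data.frame(metabolite_id = m, class = as.character(cls),
               flagged = attr(cls, "flagged"), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pre- vs post-intervention comparison of excursion AUCs
#'
#' Fits the random-intercept model (phase fixed, subject random) to the
#' per-subject AUCs of one metabolite, mirroring the univariate
#' intervention analysis but on the excursion scale.
#'
#' @param subject_aucs long data.frame (subject_id, phase, auc) for one
#'   metabolite, e.g. a slice of `subject_aucs` from [cohort_aucs()].
#' @return list with `delta` (post minus pre fixed effect), `se`, `t`, `p`,
#'   and the full mixed-model fit.
#' @export
compare_auc_phases <- function(subject_aucs) {
  fit <- fit_random_intercept(subject_aucs$auc, subject_aucs$phase,
                              subject_aucs$subject_id)
  list(delta = fit$beta, se = fit$se, t = fit$t, p = fit$p, fit = fit)
}
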