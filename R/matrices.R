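# Helpers that reshape the long panel into the sample-by-feature matrices
# the multivariate stages consume. Sample rows are subject-phase units.

#' Fasting sample-by-metabolite matrix
#'
#' One row per subject-phase, columns = metabolites, values = normalized
#' time-0 intensities (`NA` where undetected). Row names are
#' `subject_id.phase`; the subject/phase bookkeeping is attached as
#' attribute `"samples"`.
#'
#' @param panel intensity panel.
#' @export
fasting_matrix <- function(panel) {
  df <- as.data.frame(panel)
  df <- df[df$time_min == 0, ]
  cast_matrix(df$subject_id, df$phase, df$metabolite_id, df$intensity)
}

#' Per-subject AUC sample-by-metabolite matrix
#'
#' @param panel intensity panel (or pass `subject_aucs` from
#'   [cohort_aucs()] via the `subject_aucs` argument to avoid recomputing).
#' @param subject_aucs optional precomputed long AUC table.
#' @rdname fasting_matrix
#' @export
auc_matrix <- function(panel = NULL, subject_aucs = NULL) {
  sa <- subject_aucs %||% cohort_aucs(panel)$subject_aucs
  cast_matrix(sa$subject_id, sa$phase, sa$metabolite_id, sa$auc)
}

cast_matrix <- function(subject, phase, feature, value) {
  key <- paste(subject, phase, sep = ".")
  samples <- unique(data.frame(key = key, subject_id = subject, phase = phase,
                               stringsAsFactors = FALSE))
  feats <- sort(unique(feature))
  x <- matrix(NA_real_, nrow(samples), length(feats),
              dimnames = list(samples$key, feats))
  x[cbind(match(key, samples$key), match(feature, feats))] <- value
  attr(x, "samples") <- samples
  x
}

#' Clinical-index block aligned to a feature matrix
#'
#' Builds a samples x indices matrix (matsuda, quicki, fasting insulin and
#' glucose) whose rows line up with the given feature matrix's
#' subject-phase rows.
#'
#' @param indices per-subject index table from [cohort_indices()].
#' @param x a matrix from [fasting_matrix()]/[auc_matrix()] whose row order
#'   to match.
#' @export
clinical_matrix <- function(indices, x) {
  samples <- attr(x, "samples")
  idx <- indices$indices %||% indices
  m <- match(paste(samples$subject_id, samples$phase, sep = "."),
             paste(idx$subject_id, idx$phase, sep = "."))
  out <- cbind(matsuda = idx$matsuda[m], quicki = idx$quicki[m],
               fasting_insulin = idx$fasting_insulin[m],
               fasting_glucose = idx$fasting_glucose[m])
  rownames(out) <- rownames(x)
  out
}

#' Phase labels for a cast matrix
#' @param x matrix from [fasting_matrix()]/[auc_matrix()].
#' @export
matrix_phase <- function(x) attr(x, "samples")$phase

# drop features that are all-missing or constant (unusable for autoscaling)
usable_features <- function(x, min_obs = 3) {
  keep <- apply(x, 2, function(col) {
    v <- col[is.finite(col)]
    length(v) >= min_obs && sd1(v) > 0
  })
  out <- x[, keep, drop = FALSE]
  attr(out, "samples") <- attr(x, "samples")
  out
}
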