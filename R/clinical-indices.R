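#' Insulin-sensitivity indices from fasting and OGTT glucose/insulin
#'
#' `quicki()` is the Quantitative Insulin Sensitivity Check Index,
#' `1 / (log10(I0) + log10(G0))` with fasting glucose `g0` in mg/dL and
#' fasting insulin `i0` in uU/mL (base-10 logarithms; at the conventional
#' insulin-resistance derivation inputs G0 = 100 mg/dL, I0 = 15 uU/mL the
#' index is 0.315). `homa()` is the homeostasis model assessment,
#' `G0 * I0 / 405` (mg/dL convention). `matsuda()` is the composite
#' whole-body index `10000 / sqrt(G0 * I0 * Gbar * Ibar)` where `Gbar`,
#' `Ibar` are unweighted means over the full OGTT schedule (0, 30, 60, 90,
#' 120 min by default).
#'
#' @param g0,i0 fasting glucose (mg/dL) and insulin (uU/mL); positive.
#' @return a single numeric index.
#' @export
quicki <- function(g0, i0) {
  stopifnot(length(g0) == 1, length(i0) == 1)
  if (!is.finite(g0) || !is.finite(i0) || g0 <= 0 || i0 <= 0) {
    stop("g0 and i0 must be positive", call. = FALSE)
  }
  den <- log10(i0) + log10(g0)
  if (den <= 0) stop("log10(i0) + log10(g0) <= 0: non-physiological input",
                     call. = FALSE)
  1 / den
}

#' @rdname quicki
#' @export
homa <- function(g0, i0) {
  if (any(g0 <= 0) || any(i0 <= 0)) stop("g0 and i0 must be positive",
                                         call. = FALSE)
  g0 * i0 / 405
}

#' @rdname quicki
#' @param glucose,insulin OGTT series (same length as `times`), positive.
#' @param times sampling schedule in minutes; must include 0.
#' @export
matsuda <- function(glucose, insulin, times = c(0, 30, 60, 90, 120)) {
  if (length(glucose) != length(times) || length(insulin) != length(times)) {
    stop("glucose/insulin series must cover the declared schedule",
         call. = FALSE)
  }
  if (anyNA(glucose) || anyNA(insulin)) {
    miss <- times[is.na(glucose) | is.na(insulin)]
    stop("missing timepoint(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(glucose <= 0) || any(insulin <= 0)) {
    stop("glucose and insulin must be positive", call. = FALSE)
  }
  if (!0 %in% times) stop("schedule must include time 0", call. = FALSE)
  g0 <- glucose[times == 0]
  i0 <- insulin[times == 0]
  10000 / sqrt(g0 * i0 * mean(glucose) * mean(insulin))
}

#' Per-subject indices and phase summary for a cohort
#'
#' Computes Matsuda, QUICKI and HOMA for every subject-phase with a complete
#' OGTT series, then summarizes each phase as mean +/- SEM (SD/sqrt(n)) and,
#' when at least three subjects have both phases, a paired t-test on the
#' completers' Matsuda indices.
#'
#' @param records `subject_records` table.
#' @param times OGTT schedule in minutes.
#' @return list with `indices` (per subject-phase data.frame), `summary`
#'   (per phase mean/SEM for each index), and `matsuda_paired` (list with
#'   `t`, `p`, `n` or NULL when too few completers).
#' @export
cohort_indices <- function(records, times = c(0, 30, 60, 90, 120)) {
  grp <- unique(as.data.frame(records)[c("subject_id", "phase")])
  rows <- mapply(function(s, p) {
    r <- records[records$subject_id == s & records$phase == p, ]
    r <- r[order(r$time_min), ]
    if (!identical(as.numeric(r$time_min), as.numeric(times))) return(NULL)
    g <- r$glucose_mgdl
    i <- r$insulin_uUml
    data.frame(subject_id = s, phase = p,
               matsuda = matsuda(g, i, times),
               quicki = quicki(g[1], i[1]),
               homa = homa(g[1], i[1]),
               fasting_glucose = g[1], fasting_insulin = i[1],
               stringsAsFactors = FALSE)
  }, grp$subject_id, grp$phase, SIMPLIFY = FALSE)
  idx <- do.call(rbind, rows)
  rownames(idx) <- NULL

  summarize <- function(v) {
    n <- length(v)
    c(mean = mean(v), sem = if (n > 1) sd1(v) / sqrt(n) else NA_real_, n = n)
  }
  summ <- do.call(rbind, lapply(split(idx, idx$phase), function(d) {
    data.frame(phase = d$phase[1],
               index = c("matsuda", "quicki", "homa",
                         "fasting_glucose", "fasting_insulin"),
               t(vapply(d[c("matsuda", "quicki", "homa",
                            "fasting_glucose", "fasting_insulin")],
                        summarize, numeric(3))),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL

  paired <- NULL
  pre <- idx[idx$phase == "pre", ]
  post <- idx[idx$phase == "post", ]
  common <- intersect(pre$subject_id, post$subject_id)
  if (length(common) >= 3) {
    pt <- paired_t(pre$matsuda[match(common, pre$subject_id)],
                   post$matsuda[match(common, post$subject_id)])
    paired <- list(t = pt$t, p = pt$p, n = length(common))
  }
  list(indices = idx, summary = summ, matsuda_paired = paired)
}
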