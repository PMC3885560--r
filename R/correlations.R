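#' Spearman rank correlation with t-approximation p-value
#'
#' Ranks with average ties, rho as Pearson correlation of the ranks, and a
#' two-sided p from `t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2`
#' degrees of freedom. Missing values are dropped pairwise. A perfect
#' monotone relation (|rho| = 1) is reported at the machine floor rather
#' than 0.
#'
#' @param x,y numeric vectors.
#' @return list: `rho`, `p`, `n` (pairwise-complete count).
#' @export
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need >= 3 pairwise-complete observations", call. = FALSE)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stop("all-tied variable: rank correlation undefined", call. = FALSE)
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- .Machine$double.xmin
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Loading-based variable prefilter
#'
#' Retains variables whose PLS loading deviates from the mean loading by
#' strictly more than one SD of the loadings -- the usual pruning step
#' before a phenotype-metabolite cross-correlation panel, keeping only
#' variables the multivariate model leaned on.
#'
#' @param loadings named numeric vector.
#' @return character vector of retained names.
#' @export
loading_prefilter <- function(loadings) {
  if (length(loadings) < 3) stop("need >= 3 loadings", call. = FALSE)
  s <- sd1(loadings)
  if (s == 0) {
    warning("zero SD among loadings; nothing retained")
    return(character(0))
  }
  names(loadings)[abs(loadings - mean(loadings)) > s]
}

star_code <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                              ifelse(p < 0.01, "**",
                                     ifelse(p <= 0.05, "*", ""))))
}

#' Phenotype-metabolite Spearman cross-correlation panel
#'
#' All pairwise Spearman correlations among the columns of a variable
#' matrix (clinical indices plus prefiltered fasting/AUC metabolite
#' features), pairwise-complete, with the conventional star coding
#' (p <= 0.05 `*`, < 0.01 `**`, < 0.001 `***`) and an optional BH-adjusted
#' column.
#'
#' @param vars samples x variables numeric matrix (one phase).
#' @param phase label stored in the output.
#' @param min_n smallest pairwise-complete count for a reported pair.
#' @return data.frame: phase, var_a, var_b, rho, p, n, stars, q.
#' @export
ccp <- function(vars, phase = NA_character_, min_n = 3) {
  vars <- as.matrix(vars)
  nm <- colnames(vars)
  if (is.null(nm)) stop("variable matrix needs column names", call. = FALSE)
  rows <- list()
  for (i in seq_len(ncol(vars) - 1)) {
    for (j in (i + 1):ncol(vars)) {
      sp <- tryCatch(spearman(vars[, i], vars[, j]), error = function(e) NULL)
      if (is.null(sp) || sp$n < min_n) next
      rows[[length(rows) + 1L]] <-
        data.frame(phase = phase, var_a = nm[i], var_b = nm[j],
                   rho = sp$rho, p = sp$p, n = sp$n,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(phase = character(0), var_a = character(0),
                      var_b = character(0), rho = numeric(0), p = numeric(0),
                      n = integer(0), stars = character(0), q = numeric(0)))
  }
  out$stars <- star_code(out$p)
  out$q <- bh_fdr(out$p)$q
  out
}
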