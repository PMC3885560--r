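# Shared fixture builders; everything is generated in code.

# tiny long-form panel from a subject x time intensity matrix for one
# metabolite, or from a named list of such matrices
make_panel <- function(mats, phase = "pre", schedule = c(0, 30, 60, 90, 120)) {
  if (is.matrix(mats)) mats <- list(M1 = mats)
  rows <- list()
  for (m in names(mats)) {
    x <- mats[[m]]
    for (i in seq_len(nrow(x))) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = rownames(x)[i] %||% paste0("S", i), phase = phase,
        time_min = schedule[seq_len(ncol(x))], metabolite_id = m,
        intensity = as.numeric(x[i, ]), stringsAsFactors = FALSE)
    }
  }
  intensity_panel(do.call(rbind, rows), schedule)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small informative two-class matrix with planted discriminating columns
make_two_class <- function(n1 = 14, n2 = 13, p = 50, planted = 5,
                           effect = 2, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm((n1 + n2) * p), n1 + n2, p,
              dimnames = list(NULL, sprintf("F%03d", seq_len(p))))
  y <- rep(c("pre", "post"), c(n1, n2))
  if (planted > 0) {
    x[y == "post", seq_len(planted)] <- x[y == "post", seq_len(planted)] + effect
  }
  list(x = x, y = y, planted = colnames(x)[seq_len(planted)])
}

# brute-force BH step-up over all thresholds (independent of p.adjust)
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(ord == i)  # rank of p[i]
    q[i] <- min(1, min(m * p[ord][r:m] / (r:m)))
  }
  q
}

# average-rank helper written independently of base rank()
avg_rank <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  i <- 1
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[o[j + 1]] == x[o[i]]) j <- j + 1
    r[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}
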