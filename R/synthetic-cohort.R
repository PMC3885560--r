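#' Configuration of the synthetic OGTT cohort
#'
#' The generator emulates the structure of a longitudinal pre/post
#' intervention OGTT metabolomics study: 15 subjects enrolled pre-
#' intervention of whom 12 complete the post-intervention week, OGTT
#' metabolomics available for 13 subjects pre-intervention (completers are a
#' nested subset of the OGTT subjects, who are nested in the enrolled
#' subjects), ~321 detected plasma metabolites sampled at 0/30/60/90/120
#' minutes, log-normal peak heights with per-subject random intercepts,
#' archetypal OGTT response shapes, and a planted set of intervention-
#' responsive metabolites that shift between phases on the fasting level,
#' the excursion (AUC), or both.
#'
#' @param n_subjects_pre subjects enrolled pre-intervention.
#' @param n_completers subjects re-examined post-intervention
#'   (`<= n_ogtt_pre`).
#' @param n_ogtt_pre subjects with pre-intervention OGTT series
#'   (`n_completers <= n_ogtt_pre <= n_subjects_pre`); the remaining
#'   pre-intervention subjects contribute fasting (t = 0) samples only.
#' @param n_metabolites number of metabolites.
#' @param timepoints OGTT schedule, strictly increasing minutes from 0.
#' @param class_mix named fractions over the response archetypes
#'   `lipid_suppressed`, `carb_raised`, `late_rise_xeno`, `fasting_shifted`,
#'   `inert`; must sum to 1.
#' @param effect_size_fasting,effect_size_auc planted standardized shifts
#'   (units of the total log-scale SD `sqrt(subject_sd^2 + residual_sd^2)`).
#' @param n_planted number of intervention-responsive metabolites.
#' @param channel_mix named fractions over planted channels
#'   `fasting`, `auc`, `both`.
#' @param subject_sd,residual_sd log-scale dispersion of the subject random
#'   intercept and the residual.
#' @param missing_frac probability a metabolite is undetected in a sample
#'   (missing completely at random).
#' @param gi_subject_sd log-scale inter-subject SD of the glucose/insulin
#'   curves.
#' @param insulin_improvement,glucose_improvement post-intervention
#'   multipliers on the insulin and glucose curves (< 1 = improved insulin
#'   sensitivity: the cohort-mean Matsuda index rises and fasting insulin
#'   falls).
#' @param seed RNG seed.
#' @export
cohort_config <- function(n_subjects_pre = 15, n_completers = 12,
                          n_ogtt_pre = 13, n_metabolites = 321,
                          timepoints = c(0, 30, 60, 90, 120),
                          class_mix = c(lipid_suppressed = 0.25,
                                        carb_raised = 0.20,
                                        late_rise_xeno = 0.05,
                                        fasting_shifted = 0.10,
                                        inert = 0.40),
                          effect_size_fasting = 1.5, effect_size_auc = 1.5,
                          n_planted = 20,
                          channel_mix = c(fasting = 0.5, auc = 0.5, both = 0),
                          subject_sd = 0.4, residual_sd = 0.3,
                          missing_frac = 0.05,
                          gi_subject_sd = 0.15,
                          insulin_improvement = 0.70,
                          glucose_improvement = 0.97,
                          seed = 1) {
  cfg <- list(
    n_subjects_pre = check_count(n_subjects_pre, "n_subjects_pre", 3),
    n_completers = check_count(n_completers, "n_completers", 3),
    n_ogtt_pre = check_count(n_ogtt_pre, "n_ogtt_pre", 3),
    n_metabolites = check_count(n_metabolites, "n_metabolites", 1),
    timepoints = as.numeric(timepoints),
    class_mix = class_mix,
    effect_size_fasting = as.numeric(effect_size_fasting),
    effect_size_auc = as.numeric(effect_size_auc),
    n_planted = check_count(n_planted, "n_planted", 0),
    channel_mix = channel_mix,
    subject_sd = check_positive(subject_sd, "subject_sd"),
    residual_sd = check_positive(residual_sd, "residual_sd"),
    missing_frac = check_fraction(missing_frac, "missing_frac"),
    gi_subject_sd = as.numeric(gi_subject_sd),
    insulin_improvement = check_positive(insulin_improvement,
                                         "insulin_improvement"),
    glucose_improvement = check_positive(glucose_improvement,
                                         "glucose_improvement"),
    seed = seed
  )
  if (cfg$n_completers > cfg$n_ogtt_pre || cfg$n_ogtt_pre > cfg$n_subjects_pre) {
    stop("'n_completers' <= 'n_ogtt_pre' <= 'n_subjects_pre' is required",
         call. = FALSE)
  }
  tp <- cfg$timepoints
  if (length(tp) < 2 || tp[1] != 0 || any(diff(tp) <= 0)) {
    stop("'timepoints' must be strictly increasing and start at 0",
         call. = FALSE)
  }
  archetypes <- c("lipid_suppressed", "carb_raised", "late_rise_xeno",
                  "fasting_shifted", "inert")
  if (!setequal(names(cfg$class_mix), archetypes) ||
      abs(sum(cfg$class_mix) - 1) > 1e-8 || any(cfg$class_mix < 0)) {
    stop("'class_mix' must be nonnegative fractions over {",
         paste(archetypes, collapse = ", "), "} summing to 1", call. = FALSE)
  }
  if (!setequal(names(cfg$channel_mix), c("fasting", "auc", "both")) ||
      abs(sum(cfg$channel_mix) - 1) > 1e-8 || any(cfg$channel_mix < 0)) {
    stop("'channel_mix' must be nonnegative fractions over {fasting, auc, both} summing to 1",
         call. = FALSE)
  }
  if (cfg$n_planted > cfg$n_metabolites) {
    stop("'n_planted' cannot exceed 'n_metabolites'", call. = FALSE)
  }
  if (cfg$gi_subject_sd < 0) stop("'gi_subject_sd' must be >= 0", call. = FALSE)
  structure(cfg, class = "cohort_config")
}

# Piecewise-linear archetype templates on normalized time u = t / max(t),
# anchored at u = 0, .25, .5, .75, 1 (the five default OGTT draws), in units
# of one total log-scale SD.
archetype_template <- function(archetype, u) {
  anchors <- switch(archetype,
    lipid_suppressed = c(0, -0.35, -0.65, -0.88, -1),
    carb_raised      = c(0, 1, 0.85, 0.5, 0.2),
    late_rise_xeno   = c(0, 0.1, 0.35, 0.7, 1),
    fasting_shifted  = c(0, 0, 0, 0, 0),
    inert            = c(0, 0, 0, 0, 0),
    stop("unknown archetype: ", archetype, call. = FALSE))
  stats::approx(seq(0, 1, by = 0.25), anchors, xout = u)$y
}

# extra excursion bump used for planted AUC responders (same normalized grid)
auc_bump <- function(u) {
  stats::approx(seq(0, 1, by = 0.25), c(0, 0.6, 1, 0.8, 0.5), xout = u)$y
}

subject_ids <- function(n) sprintf("S%02d", seq_len(n))
metabolite_ids <- function(n) sprintf("M%03d", seq_len(n))

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws the full intensity panel (long form), the subject glucose/insulin
#' records, and the planted-truth table. Peak heights are log-normal: for
#' metabolite m, subject s, phase f, time t the log intensity is
#' `mu_m + a_m * template_m(t) + planted effects + b_{s,m} + e` with
#' `b ~ N(0, subject_sd^2)` shared across a subject's observations of one
#' metabolite and `e ~ N(0, residual_sd^2)`. Planted fasting responders
#' shift their whole post-phase profile by `effect_size_fasting` total SDs
#' (a fasting-level shift leaves the baseline-subtracted AUC untouched);
#' planted AUC responders gain an extra post-phase excursion bump of
#' amplitude `effect_size_auc` total SDs. Post-phase rows exist only for
#' completers; pre-phase rows at t > 0 only for the OGTT subjects. Identical
#' config and seed give identical output.
#'
#' @param config a [cohort_config()].
#' @return list with `panel` (intensity_panel), `records`
#'   (subject_records, from [generate_glucose_insulin()]), `truth`
#'   (data.frame metabolite_id, archetype, direction, channel; planted rows
#'   have channel != "none").
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    tp <- config$timepoints
    u <- tp / max(tp)
    subs <- subject_ids(config$n_subjects_pre)
    completers <- subs[seq_len(config$n_completers)]
    ogtt_pre <- subs[seq_len(config$n_ogtt_pre)]
    mets <- metabolite_ids(config$n_metabolites)

    # archetype assignment: deterministic counts from the mix, then shuffled
    counts <- floor(config$class_mix * config$n_metabolites)
    left <- config$n_metabolites - sum(counts)
    if (left > 0) {
      extra <- order(config$class_mix * config$n_metabolites - counts,
                     decreasing = TRUE)[seq_len(left)]
      counts[extra] <- counts[extra] + 1
    }
    archetype <- sample(rep(names(counts), counts))

    unit_sd <- sqrt(config$subject_sd^2 + config$residual_sd^2)
    mu <- stats::rnorm(config$n_metabolites, mean = log(1e4), sd = 1)
    amp <- unit_sd * stats::runif(config$n_metabolites, 0.8, 1.6)

    planted_idx <- if (config$n_planted > 0) {
      sample(config$n_metabolites, config$n_planted)
    } else integer(0)
    channel <- rep("none", config$n_metabolites)
    if (config$n_planted > 0) {
      ch_counts <- floor(config$channel_mix * config$n_planted)
      ch_left <- config$n_planted - sum(ch_counts)
      if (ch_left > 0) {
        extra <- order(config$channel_mix * config$n_planted - ch_counts,
                       decreasing = TRUE)[seq_len(ch_left)]
        ch_counts[extra] <- ch_counts[extra] + 1
      }
      channel[planted_idx] <- sample(rep(names(ch_counts), ch_counts))
    }
    direction <- rep(0L, config$n_metabolites)
    direction[planted_idx] <- sample(c(-1L, 1L), length(planted_idx),
                                     replace = TRUE)

    # design rows: pre phase for all subjects (t > 0 only for OGTT subjects),
    # post phase for completers at all timepoints
    design <- rbind(
      expand.grid(subject_id = ogtt_pre, phase = "pre", time_min = tp,
                  stringsAsFactors = FALSE),
      expand.grid(subject_id = setdiff(subs, ogtt_pre), phase = "pre",
                  time_min = 0, stringsAsFactors = FALSE),
      expand.grid(subject_id = completers, phase = "post", time_min = tp,
                  stringsAsFactors = FALSE)
    )
    design <- design[order(design$subject_id, design$phase, design$time_min), ]
    n_rows <- nrow(design)

    panel_list <- vector("list", config$n_metabolites)
    for (m in seq_len(config$n_metabolites)) {
      b <- stats::rnorm(length(subs), sd = config$subject_sd)
      names(b) <- subs
      shape <- amp[m] * archetype_template(archetype[m], u)
      names(shape) <- as.character(tp)
      log_y <- mu[m] + shape[as.character(design$time_min)] +
        b[design$subject_id] +
        stats::rnorm(n_rows, sd = config$residual_sd)
      if (channel[m] %in% c("fasting", "both")) {
        shift <- direction[m] * config$effect_size_fasting * unit_sd
        log_y <- log_y + shift * (design$phase == "post")
      }
      if (channel[m] %in% c("auc", "both")) {
        bump <- direction[m] * config$effect_size_auc * unit_sd * auc_bump(u)
        names(bump) <- as.character(tp)
        log_y <- log_y +
          bump[as.character(design$time_min)] * (design$phase == "post")
      }
      intensity <- exp(log_y)
      if (config$missing_frac > 0) {
        intensity[stats::runif(n_rows) < config$missing_frac] <- NA_real_
      }
      panel_list[[m]] <- data.frame(design, metabolite_id = mets[m],
                                    intensity = intensity,
                                    stringsAsFactors = FALSE)
    }
    panel <- intensity_panel(do.call(rbind, panel_list), schedule = tp)
    records <- generate_glucose_insulin_impl(config)
    truth <- data.frame(metabolite_id = mets, archetype = archetype,
                        direction = direction, channel = channel,
                        stringsAsFactors = FALSE)
    list(panel = panel, records = records, truth = truth)
  })
}

# glucose/insulin curve anchors (normalized-time grid), chosen so the
# cohort-mean Matsuda index sits near 2.0 pre- and 2.9 post-intervention
gi_curves <- function(u) {
  list(glucose = stats::approx(seq(0, 1, by = 0.25),
                               c(93, 155, 150, 130, 118), xout = u)$y,
       insulin = stats::approx(seq(0, 1, by = 0.25),
                               c(18.5, 155, 170, 135, 100), xout = u)$y)
}

generate_glucose_insulin_impl <- function(config) {
  tp <- config$timepoints
  curves <- gi_curves(tp / max(tp))
  subs <- subject_ids(config$n_subjects_pre)
  completers <- subs[seq_len(config$n_completers)]
  mult_g <- exp(stats::rnorm(length(subs), sd = config$gi_subject_sd * 0.5))
  mult_i <- exp(stats::rnorm(length(subs), sd = config$gi_subject_sd))
  names(mult_g) <- names(mult_i) <- subs
  rows <- list()
  for (s in subs) {
    phases <- if (s %in% completers) c("pre", "post") else "pre"
    for (ph in phases) {
      gf <- if (ph == "post") config$glucose_improvement else 1
      if_ <- if (ph == "post") config$insulin_improvement else 1
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s, phase = ph, time_min = tp,
        glucose_mgdl = pmax(curves$glucose * mult_g[s] * gf, 45),
        insulin_uUml = curves$insulin * mult_i[s] * if_,
        stringsAsFactors = FALSE)
    }
  }
  subject_records(do.call(rbind, rows))
}

#' Generate synthetic OGTT glucose/insulin series
#'
#' Per-subject glucose and insulin curves at the configured schedule, with
#' log-normal subject-level multipliers shared between phases and
#' post-intervention improvement factors applied to the post phase, so the
#' cohort-mean Matsuda index rises from pre to post and fasting insulin
#' falls. With `gi_subject_sd = 0` and both improvement factors 1, pre and
#' post series are identical per subject.
#'
#' @param config a [cohort_config()].
#' @return a `subject_records` table.
#' @export
generate_glucose_insulin <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, generate_glucose_insulin_impl(config))
}

#' Generate clustered binary fingerprints
#'
#' Draws `n_clusters` random prototype bit vectors (each bit Bernoulli 0.5)
#' and assigns metabolites round-robin; each member copies its prototype
#' with independent bit flips at rate `noise`. With few flips,
#' within-cluster Tanimoto similarities concentrate near 1 (above the usual
#' 0.7 network threshold) while between-cluster similarities sit near 1/3.
#'
#' @param ids metabolite identifiers.
#' @param n_bits fingerprint length (>= 16).
#' @param n_clusters number of chemical families (`<= length(ids)`).
#' @param noise per-bit flip probability.
#' @param seed RNG seed.
#' @return a [fingerprint_set()] with an attribute `"cluster"` giving each
#'   id's cluster.
#' @export
generate_fingerprints <- function(ids, n_bits = 256, n_clusters = 8,
                                  noise = 0.02, seed = 1) {
  n_bits <- check_count(n_bits, "n_bits", 16)
  n_clusters <- check_count(n_clusters, "n_clusters", 1)
  if (n_clusters > length(ids)) {
    stop("'n_clusters' cannot exceed the number of ids", call. = FALSE)
  }
  check_fraction(noise, "noise")
  with_seed(seed, {
    proto <- matrix(stats::rbinom(n_clusters * n_bits, 1, 0.5),
                    nrow = n_clusters)
    cluster <- rep_len(seq_len(n_clusters), length(ids))
    bits <- proto[cluster, , drop = FALSE]
    if (noise > 0) {
      flips <- matrix(stats::runif(length(bits)) < noise, nrow = nrow(bits))
      bits <- abs(bits - flips)
    }
    rownames(bits) <- ids
    out <- fingerprint_set(bits)
    attr(out, "cluster") <- stats::setNames(cluster, ids)
    out
  })
}
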