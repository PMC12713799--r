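#' Associate lexicon for indirect incorporations
#'
#' Fixed per-cue lists of semantic associates used by the synthetic
#' report generator for indirect incorporations, and by
#' [count_template_incorporations()] for human-free rating of synthetic
#' reports by exact lookup.
#'
#' @return named list of character vectors.
#' @export
associate_lexicon <- function() {
  list(Tree = c("branches", "leaves", "forest", "roots", "acorns"),
       Fork = c("spoon", "knife", "cutlery", "plate", "utensils"))
}

.distractor_pool <- c(
  "I was walking through my old neighborhood",
  "My thoughts drifted to the ocean waves",
  "I remembered a conversation with my sister",
  "There was music playing somewhere far away",
  "I kept thinking about an email I need to send",
  "A staircase seemed to go on forever",
  "I pictured the street outside my window",
  "Someone was laughing in another room",
  "I felt like I was floating above my bed",
  "I thought about what to cook tomorrow",
  "The colors around me kept changing slowly",
  "I imagined driving down a long empty road")

.direct_templates <- c(
  "I dreamed about a %s on a table",
  "A %s appeared right in front of me",
  "I kept picturing the %s again and again",
  "There was a giant %s in my mind")

.indirect_templates <- c(
  "I imagined %s all around me",
  "I thought about %s for a while",
  "Somehow %s kept showing up in the scene")

#' Default planted loading matrix
#'
#' Items are assigned to factors round-robin with a single common loading
#' value, giving a clean simple structure for recovery studies.
#'
#' @param n_items,n_factors matrix shape.
#' @param loading common loading value.
#' @return `n_items` x `n_factors` matrix.
#' @export
planted_loadings <- function(n_items = 11L, n_factors = 4L, loading = 0.7) {
  L <- matrix(0, n_items, n_factors)
  L[cbind(seq_len(n_items), rep_len(seq_len(n_factors), n_items))] <- loading
  rownames(L) <- if (n_items == 11L) probe_items() else paste0("item_", seq_len(n_items))
  L
}

.default_condition_shifts <- function() {
  # planted hypnagogia-minus-FMT shifts on the item scale
  stats::setNames(
    c(0.0375, -0.1000, 0.0625, -0.2375, 0.1250, 0.3125, 0.0500, -0.1000,
      -0.1625, 0.1750, -0.1250),
    probe_items())
}

#' Parameters of a synthetic incubation cohort
#'
#' Defaults emulate the study conditions of a two-condition
#' within-subject online cohort: 132 recruited participants of whom a
#' fraction 80/132 pass the vigilance screen; per-session cued
#' incorporation counts with Poisson means 2.85 (direct) and 1.68
#' (indirect); a 0.91 probability of at least one cued incorporation per
#' session; uncued incorporations absent by default; and probe responses
#' generated from a planted 4-factor model with small per-item condition
#' shifts.
#'
#' @param n_recruited recruited cohort size.
#' @param p_compliant probability a participant passes the vigilance
#'   screen.
#' @param lambda_direct,lambda_indirect Poisson means of cued direct and
#'   indirect incorporation counts per report (given any incorporation).
#' @param p_any probability a report contains at least one cued
#'   incorporation.
#' @param uncued_rate Poisson mean of uncued-object incorporations
#'   (default 0: exactly none).
#' @param loadings planted probe loading matrix (11 rows).
#' @param Phi factor correlation matrix.
#' @param condition_shifts named 11-vector of hypnagogia-minus-FMT item
#'   shifts on the latent scale.
#' @param person_consistency correlation of a participant's latent factor
#'   scores across their two conditions.
#' @param p_spontaneous_hyp,p_spontaneous_fmt planted probabilities of a
#'   "spontaneous" intentionality response per condition.
#' @param temporality_hyp,temporality_fmt planted temporality category
#'   probabilities (past, present, future, none) per condition.
#' @param rater2_extra Poisson mean of extra incorporations the second
#'   rater scores per report (0 = identical raters).
#' @param latency_min_s,latency_max_s latency window given to every
#'   synthetic session.
#' @return validated list of class `dc_cohort_params`.
#' @export
cohort_params <- function(n_recruited = 132L,
                          p_compliant = 80 / 132,
                          lambda_direct = 2.85,
                          lambda_indirect = 1.68,
                          p_any = 0.91,
                          uncued_rate = 0,
                          loadings = planted_loadings(),
                          Phi = diag(ncol(loadings)),
                          condition_shifts = .default_condition_shifts(),
                          person_consistency = 0.3,
                          p_spontaneous_hyp = 0.65,
                          p_spontaneous_fmt = 0.45,
                          temporality_hyp = c(past = 0.25, present = 0.25,
                                              future = 0.25, none = 0.25),
                          temporality_fmt = c(past = 0.25, present = 0.33768,
                                              future = 0.23232, none = 0.18),
                          rater2_extra = 0,
                          latency_min_s = 600,
                          latency_max_s = 900) {
  stopifnot(n_recruited >= 1,
            p_compliant >= 0, p_compliant <= 1,
            lambda_direct >= 0, lambda_indirect >= 0,
            p_any >= 0, p_any <= 1, uncued_rate >= 0,
            person_consistency >= 0, person_consistency <= 1,
            rater2_extra >= 0)
  loadings <- as.matrix(loadings)
  if (nrow(loadings) != 11L) stop("loading matrix must have 11 item rows")
  if (!isTRUE(all.equal(dim(Phi), rep(ncol(loadings), 2L)))) {
    stop("Phi must be square with one row per factor")
  }
  if (!all(probe_items() %in% names(condition_shifts))) {
    stop("condition_shifts must be named with all 11 probe items")
  }
  for (tp in list(temporality_hyp, temporality_fmt)) {
    if (!isTRUE(all.equal(sum(tp), 1)) ||
        !setequal(names(tp), c("past", "present", "future", "none"))) {
      stop("temporality probabilities must be named past/present/future/none and sum to 1")
    }
  }
  structure(as.list(environment()), class = "dc_cohort_params")
}

discretize_likert <- function(x, thresholds = c(-1.5, -0.5, 0.5, 1.5)) {
  findInterval(x, thresholds) + 1L
}

#' Generate probe responses from a planted latent-factor model
#'
#' Items are Likert discretizations (fixed thresholds at -1.5, -0.5,
#' 0.5, 1.5 on the latent scale) of `loadings %*% f + shift + e`, with
#' factor scores `f ~ N(0, Phi)` and residuals scaled so each latent
#' item has unit variance.
#'
#' @param n number of respondents (rows).
#' @param loadings items x factors loading matrix.
#' @param Phi factor correlation matrix.
#' @param shift per-item latent mean shift (default 0).
#' @param seed integer seed.
#' @param factor_scores optional pre-drawn factor score matrix (n x k);
#'   when supplied only residuals are drawn.
#' @return list `items` (data frame of Likert integers), `scores`
#'   (planted factor scores).
#' @export
generate_probe_data <- function(n, loadings = planted_loadings(),
                                Phi = diag(ncol(loadings)),
                                shift = 0, seed = 1L,
                                factor_scores = NULL) {
  loadings <- as.matrix(loadings)
  p <- nrow(loadings); k <- ncol(loadings)
  communal <- rowSums((loadings %*% Phi) * loadings)
  psi <- sqrt(pmax(1 - communal, 0.05^2))
  shift <- rep_len(shift, p)
  out <- with_local_seed(seed, {
    f <- if (is.null(factor_scores)) {
      matrix(stats::rnorm(n * k), n, k) %*% chol(Phi)
    } else {
      as.matrix(factor_scores)
    }
    e <- matrix(stats::rnorm(n * p), n, p) %*% diag(psi, p)
    latent <- f %*% t(loadings) + e + matrix(shift, n, p, byrow = TRUE)
    list(latent = latent, f = f)
  })
  items <- as.data.frame(apply(out$latent, 2L, discretize_likert))
  names(items) <- rownames(loadings)
  list(items = items, scores = out$f)
}

compose_report <- function(cue, n_direct, n_indirect, n_uncued_direct,
                           n_uncued_indirect, n_distractors) {
  lex <- associate_lexicon()
  other <- setdiff(c("Fork", "Tree"), cue)
  mk <- function(templates, word, n) {
    if (n == 0L) return(character(0))
    sprintf(templates[1 + (seq_len(n) - 1L) %% length(templates)], word)
  }
  ind_words <- function(obj, n) {
    if (n == 0L) return(character(0))
    lex[[obj]][1 + (seq_len(n) - 1L) %% length(lex[[obj]])]
  }
  sents <- c(
    mk(.direct_templates, tolower(cue), n_direct),
    mapply(function(tpl, w) sprintf(tpl, w),
           .indirect_templates[1 + (seq_len(n_indirect) - 1L) %% length(.indirect_templates)],
           ind_words(cue, n_indirect), USE.NAMES = FALSE),
    mk(.direct_templates, tolower(other), n_uncued_direct),
    mapply(function(tpl, w) sprintf(tpl, w),
           .indirect_templates[1 + (seq_len(n_uncued_indirect) - 1L) %% length(.indirect_templates)],
           ind_words(other, n_uncued_indirect), USE.NAMES = FALSE),
    .distractor_pool[1 + (seq_len(n_distractors) - 1L) %% length(.distractor_pool)])
  sents <- sample(sents)
  paste0(paste(sents, collapse = ". "), ".")
}

#' Recount template incorporations in synthetic reports
#'
#' Synthetic reports mention the cue word verbatim for direct
#' incorporations and a fixed associate word for indirect ones, so
#' planted counts can be recovered from the text by exact token lookup.
#'
#' @param reports synthetic report data frame.
#' @return data frame `participant_id`, `condition`, and token counts
#'   `direct_fork`, `indirect_fork`, `direct_tree`, `indirect_tree`.
#' @export
count_template_incorporations <- function(reports) {
  lex <- associate_lexicon()
  count_tokens <- function(text, words) {
    toks <- .tokenize(text)
    sum(toks %in% tolower(words))
  }
  data.frame(
    participant_id = reports$participant_id,
    condition = reports$condition,
    direct_fork = vapply(reports$text, count_tokens, numeric(1), "fork",
                         USE.NAMES = FALSE),
    indirect_fork = vapply(reports$text, count_tokens, numeric(1), lex$Fork,
                           USE.NAMES = FALSE),
    direct_tree = vapply(reports$text, count_tokens, numeric(1), "tree",
                         USE.NAMES = FALSE),
    indirect_tree = vapply(reports$text, count_tokens, numeric(1), lex$Tree,
                           USE.NAMES = FALSE))
}

draw_incorporation_counts <- function(n, p_any, lambda_d, lambda_i) {
  any_inc <- stats::runif(n) < p_any
  d <- integer(n); ind <- integer(n)
  for (i in which(any_inc)) {
    repeat {
      di <- stats::rpois(1, lambda_d)
      ii <- stats::rpois(1, lambda_i)
      if (di + ii >= 1L) break
    }
    d[i] <- di; ind[i] <- ii
  }
  data.frame(any = any_inc, direct = d, indirect = ind)
}

#' Generate a full synthetic cohort with known ground truth
#'
#' Produces every table the analysis modules consume: session configs
#' (condition order and cue object counterbalanced), a vigilance table
#' with planted compliance, template-based thought reports with planted
#' direct/indirect cue incorporations, two raters' annotations, probe
#' responses drawn from the planted latent-factor model, and a ground
#' truth table keyed to the emitted data.  Reports, annotations and
#' probes are emitted for the compliant (screen-passing) participants,
#' who each complete both conditions.
#'
#' @param params a [cohort_params()] object.
#' @param seed master integer seed; stream-split sub-seeds drive each
#'   data product so partial regeneration is stable.
#' @return list of class `dc_cohort` with elements `sessions`,
#'   `vigilance`, `reports`, `annotations`, `probes`, `truth`, `params`.
#' @export
generate_cohort <- function(params = cohort_params(), seed = 1L) {
  stopifnot(inherits(params, "dc_cohort_params"))
  sub <- with_local_seed(seed, sample.int(.Machine$integer.max - 1L, 6L))
  n <- params$n_recruited
  ids <- sprintf("P%03d", seq_len(n))

  # -- compliance and vigilance ------------------------------------------
  vig <- with_local_seed(sub[1], {
    compliant <- stats::runif(n) < params$p_compliant
    hyp <- ifelse(compliant,
                  sample(c("fully_asleep", "half_asleep"), n, replace = TRUE),
                  NA)
    fmt <- ifelse(compliant, "did_not_sleep", NA)
    for (i in which(!compliant)) {
      # violate (a) awake-FMT, (b) asleep-hypnagogia, or both
      mode <- sample(3L, 1L)
      hyp[i] <- if (mode %in% c(2L, 3L)) "did_not_sleep"
                else sample(c("fully_asleep", "half_asleep"), 1L)
      fmt[i] <- if (mode %in% c(1L, 3L)) sample(c("fully_asleep", "half_asleep"), 1L)
                else "did_not_sleep"
    }
    list(compliant = compliant, hyp = hyp, fmt = fmt)
  })
  vigilance <- rbind(
    data.frame(participant_id = ids, condition = "hypnagogia", level = vig$hyp),
    data.frame(participant_id = ids, condition = "fmt", level = vig$fmt))

  keep <- ids[vig$compliant]
  nk <- length(keep)
  idx <- seq_len(nk)
  # counterbalancing: alternate both the condition order and which
  # condition receives the Fork cue
  first_hyp <- idx %% 2L == 1L
  fork_in_hyp <- (idx %/% 2L) %% 2L == 0L

  sessions <- do.call(rbind, lapply(idx, function(i) {
    conds <- if (first_hyp[i]) c("hypnagogia", "fmt") else c("fmt", "hypnagogia")
    cues <- vapply(conds, function(cnd) {
      if ((cnd == "hypnagogia") == fork_in_hyp[i]) "Fork" else "Tree"
    }, character(1))
    data.frame(participant_id = keep[i], session_order = 1:2,
               condition = conds, cue_object = cues,
               latency_min_s = params$latency_min_s,
               latency_max_s = params$latency_max_s,
               dwell_s = 180, n_trials = 4L, report_s = 60, return_s = 420,
               rng_seed = seed + i)
  }))
  rownames(sessions) <- NULL

  # -- incorporations, reports, annotations ------------------------------
  inc <- with_local_seed(sub[2], {
    cued <- draw_incorporation_counts(nrow(sessions), params$p_any,
                                      params$lambda_direct,
                                      params$lambda_indirect)
    un_d <- stats::rpois(nrow(sessions), params$uncued_rate)
    un_i <- stats::rpois(nrow(sessions), params$uncued_rate)
    cbind(cued, uncued_direct = un_d, uncued_indirect = un_i)
  })

  reports <- with_local_seed(sub[3], {
    n_dis <- 2L + stats::rpois(nrow(sessions), 3)
    data.frame(
      participant_id = sessions$participant_id,
      condition = sessions$condition,
      cue_object = sessions$cue_object,
      text = vapply(seq_len(nrow(sessions)), function(i) {
        compose_report(sessions$cue_object[i], inc$direct[i], inc$indirect[i],
                       inc$uncued_direct[i], inc$uncued_indirect[i], n_dis[i])
      }, character(1)))
  })

  planted_counts <- function(i) {
    fork_cued <- sessions$cue_object[i] == "Fork"
    c(direct_fork = if (fork_cued) inc$direct[i] else inc$uncued_direct[i],
      indirect_fork = if (fork_cued) inc$indirect[i] else inc$uncued_indirect[i],
      direct_tree = if (fork_cued) inc$uncued_direct[i] else inc$direct[i],
      indirect_tree = if (fork_cued) inc$uncued_indirect[i] else inc$indirect[i])
  }
  base_counts <- t(vapply(seq_len(nrow(sessions)), planted_counts, integer(4)))
  annotations <- with_local_seed(sub[4], {
    r2 <- base_counts
    if (params$rater2_extra > 0) {
      r2 <- r2 + matrix(stats::rpois(length(r2), params$rater2_extra / 4),
                        nrow(r2))
    }
    rbind(
      data.frame(rater_id = "R1", participant_id = sessions$participant_id,
                 condition = sessions$condition,
                 cue_object = sessions$cue_object, base_counts),
      data.frame(rater_id = "R2", participant_id = sessions$participant_id,
                 condition = sessions$condition,
                 cue_object = sessions$cue_object, r2))
  })
  rownames(annotations) <- NULL

  # -- probes -------------------------------------------------------------
  k <- ncol(params$loadings)
  shifts <- params$condition_shifts[probe_items()]
  probes_parts <- with_local_seed(sub[5], {
    rho <- params$person_consistency
    z_person <- matrix(stats::rnorm(nk * k), nk, k)
    per_cond <- lapply(c(hypnagogia = 1, fmt = -1), function(sgn) {
      z_cond <- matrix(stats::rnorm(nk * k), nk, k)
      f_raw <- sqrt(rho) * z_person + sqrt(1 - rho) * z_cond
      f <- f_raw %*% chol(params$Phi)
      pd <- generate_probe_data(
        nk, params$loadings, params$Phi,
        shift = sgn * shifts / 2,
        seed = stats::runif(1, 1, .Machine$integer.max),
        factor_scores = f)
      p_sp <- if (sgn > 0) params$p_spontaneous_hyp else params$p_spontaneous_fmt
      tprob <- if (sgn > 0) params$temporality_hyp else params$temporality_fmt
      items <- pd$items
      items$intentionality <- ifelse(stats::runif(nk) < p_sp,
                                     "spontaneous", "deliberate")
      items$temporality <- sample(names(tprob), nk, replace = TRUE, prob = tprob)
      list(items = items, scores = pd$scores)
    })
    per_cond
  })
  probes <- do.call(rbind, lapply(names(probes_parts), function(cnd) {
    data.frame(participant_id = keep, condition = cnd,
               probes_parts[[cnd]]$items)
  }))
  rownames(probes) <- NULL

  truth <- data.frame(
    participant_id = sessions$participant_id,
    condition = sessions$condition,
    cue_object = sessions$cue_object,
    any_incorporation = inc$any,
    direct_cued = inc$direct,
    indirect_cued = inc$indirect,
    uncued_direct = inc$uncued_direct,
    uncued_indirect = inc$uncued_indirect)
  truth_compliance <- data.frame(participant_id = ids,
                                 compliant = vig$compliant)
  factor_scores <- lapply(probes_parts, `[[`, "scores")

  structure(list(sessions = sessions, vigilance = vigilance,
                 reports = reports, annotations = annotations,
                 probes = probes,
                 truth = list(incorporations = truth,
                              compliance = truth_compliance,
                              factor_scores = factor_scores,
                              loadings = params$loadings),
                 params = params, seed = seed),
            class = "dc_cohort")
}

#' @export
print.dc_cohort <- function(x, ...) {
  cat(sprintf("synthetic incubation cohort: %d recruited, %d compliant (seed %d)\n",
              x$params$n_recruited, sum(x$truth$compliance$compliant), x$seed))
  cat(sprintf("  %d sessions, %d reports, %d annotation rows, %d probe rows\n",
              nrow(x$sessions), nrow(x$reports), nrow(x$annotations),
              nrow(x$probes)))
  invisible(x)
}

#' Write all cohort tables to a directory
#'
#' Emits `sessions.csv`, `vigilance.csv`, `reports.csv`,
#' `annotations.csv`, `probes.csv` and `truth_incorporations.csv` /
#' `truth_compliance.csv` in the formats the analysis readers consume.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dc_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$sessions, file.path(dir, "sessions.csv"), row.names = FALSE)
  utils::write.csv(cohort$vigilance, file.path(dir, "vigilance.csv"), row.names = FALSE)
  write_reports(cohort$reports, file.path(dir, "reports.csv"))
  write_annotations(cohort$annotations, file.path(dir, "annotations.csv"))
  write_probes(cohort$probes, file.path(dir, "probes.csv"))
  utils::write.csv(cohort$truth$incorporations,
                   file.path(dir, "truth_incorporations.csv"), row.names = FALSE)
  utils::write.csv(cohort$truth$compliance,
                   file.path(dir, "truth_compliance.csv"), row.names = FALSE)
  invisible(dir)
}
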