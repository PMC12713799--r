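.annotation_cols <- c("rater_id", "participant_id", "condition", "cue_object",
                      "direct_fork", "indirect_fork", "direct_tree", "indirect_tree")

#' Read/write rater annotation tables
#'
#' One row per rater-by-participant-by-condition report, with the counts
#' of direct and indirect incorporations of each object (Fork, Tree) the
#' rater scored in that report.  A direct incorporation names the object
#' itself ("I dreamed of becoming a tree"); an indirect one evokes it
#' through an associate ("watering big plants").
#'
#' @param path CSV file path.
#' @return data frame with the annotation columns.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(.annotation_cols %in% names(ann))) {
    stop("annotation table must have columns: ",
         paste(.annotation_cols, collapse = ", "))
  }
  validate_annotations(ann)
  ann
}

#' @rdname read_annotations
#' @param annotations annotation data frame.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations[, .annotation_cols], path, row.names = FALSE)
  invisible(path)
}

validate_annotations <- function(annotations) {
  counts <- annotations[, c("direct_fork", "indirect_fork",
                            "direct_tree", "indirect_tree")]
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("incorporation counts must be non-negative integers")
  }
  key <- interaction(annotations$rater_id, annotations$participant_id,
                     annotations$condition, drop = TRUE)
  if (anyDuplicated(key)) {
    stop("duplicate rater x participant x condition annotation rows")
  }
  invisible(annotations)
}

one_rater <- function(annotations, rater = NULL) {
  raters <- sort(unique(annotations$rater_id))
  if (is.null(rater)) rater <- raters[1]
  if (!rater %in% raters) stop("no annotations for rater ", rater)
  annotations[annotations$rater_id == rater, , drop = FALSE]
}

cued_uncued <- function(annotations) {
  fork_cued <- annotations$cue_object == "Fork"
  data.frame(
    annotations,
    direct_cued = ifelse(fork_cued, annotations$direct_fork, annotations$direct_tree),
    indirect_cued = ifelse(fork_cued, annotations$indirect_fork, annotations$indirect_tree),
    direct_uncued = ifelse(fork_cued, annotations$direct_tree, annotations$direct_fork),
    indirect_uncued = ifelse(fork_cued, annotations$indirect_tree, annotations$indirect_fork))
}

#' Tally incorporation counts across a cohort
#'
#' Aggregates one rater's annotations into the cue-by-content-by-type
#' incorporation table: for each session cue (Fork, Tree), the mean and
#' SD across reports of direct and indirect incorporations of each
#' content object, labelled cued/uncued relative to that session's cue.
#'
#' @param annotations annotation data frame (see [read_annotations()]).
#' @param rater rater to tally (default: first rater id in sort order).
#' @return data frame of class `dc_incorporation_table` with columns
#'   `cue`, `content`, `type`, `relation`, `mean`, `sd`, `n`.
#' @export
tally_incorporations <- function(annotations, rater = NULL) {
  validate_annotations(annotations)
  ann <- one_rater(annotations, rater)
  grid <- expand.grid(cue = c("Fork", "Tree"), content = c("Fork", "Tree"),
                      type = c("direct", "indirect"), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sub <- ann[ann$cue_object == g$cue, , drop = FALSE]
    col <- paste0(g$type, "_", tolower(g$content))
    vals <- sub[[col]]
    data.frame(g,
               relation = ifelse(g$cue == g$content, "cued", "uncued"),
               mean = if (length(vals)) mean(vals) else NA_real_,
               sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
               n = length(vals))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("dc_incorporation_table", "data.frame")
  out
}

#' @export
print.dc_incorporation_table <- function(x, ...) {
  cat("Incorporation tally (mean count per report):\n")
  df <- as.data.frame(x)
  df$mean <- round(df$mean, 2)
  df$sd <- round(df$sd, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Proportion of participants with at least one cued incorporation
#'
#' @param annotations annotation data frame.
#' @param condition restrict to one condition (`"hypnagogia"`/`"fmt"`),
#'   or `NULL` for all sessions pooled per participant.
#' @param rater rater whose counts are used (default first).
#' @return list `k` (participants with any direct or indirect cued
#'   incorporation), `n`, `proportion`.
#' @export
any_incorporation_rate <- function(annotations, condition = NULL, rater = NULL) {
  validate_annotations(annotations)
  ann <- cued_uncued(one_rater(annotations, rater))
  if (!is.null(condition)) ann <- ann[ann$condition == condition, , drop = FALSE]
  if (nrow(ann) == 0L) stop("no annotations in scope")
  any_by_pp <- tapply(ann$direct_cued + ann$indirect_cued >= 1,
                      ann$participant_id, any)
  k <- sum(any_by_pp)
  n <- length(any_by_pp)
  list(k = as.integer(k), n = as.integer(n), proportion = k / n)
}

#' Goodness-of-fit chi-square of a rate against a chance level
#'
#' Pearson one-sample chi-square (df = 1, no continuity correction) of
#' `k` successes out of `n` against a null proportion `p0` (default 0.5,
#' the chance level used for incorporation rates).
#'
#' @param k,n successes and trials.
#' @param p0 null proportion, strictly between 0 and 1.
#' @return list `chi2`, `df`, `p`.
#' @export
chisq_vs_chance <- function(k, n, p0 = 0.5) {
  stopifnot(n > 0, k >= 0, k <= n, p0 > 0, p0 < 1)
  ht <- suppressWarnings(stats::chisq.test(c(k, n - k), p = c(p0, 1 - p0),
                                           correct = FALSE))
  list(chi2 = unname(ht$statistic), df = 1L, p = unname(ht$p.value))
}

#' Chi-square comparison of two independent proportions
#'
#' Pearson chi-square on the 2x2 table (df = 1, no continuity
#' correction), e.g. comparing the online incorporation rate with the
#' combined in-person laboratory rate.
#'
#' @param k1,n1,k2,n2 successes/trials in the two samples.
#' @return list `chi2`, `df`, `p`.
#' @export
chisq_two_proportions <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  tab <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("2x2 table has a zero margin")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = 1L, p = unname(ht$p.value))
}

#' Cohen's kappa for two categorical label vectors
#'
#' @param x,y equal-length label vectors.
#' @return chance-corrected agreement `(po - pe) / (1 - pe)`.
#' @export
cohen_kappa <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) > 0)
  levs <- sort(unique(c(as.character(x), as.character(y))))
  x <- factor(as.character(x), levels = levs)
  y <- factor(as.character(y), levels = levs)
  tab <- table(x, y) / length(x)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (pe >= 1) return(1)  # both raters constant and identical
  (po - pe) / (1 - pe)
}

#' Inter-rater agreement on incorporation counts
#'
#' Compares two raters' annotations over matched report units
#' (participant-by-condition): Pearson correlation of per-report total
#' incorporation counts, Cohen's kappa on a categorical unit rule, and a
#' paired t-test for a systematic scoring difference (df = N - 1 over
#' the N matched reports).
#'
#' @param annotations annotation data frame containing both raters.
#' @param raters length-2 vector of rater ids (default: first two in
#'   sort order).
#' @param unit_rule how each report is labelled for kappa:
#'   `"any_cued"` (default) — presence/absence of at least one cued
#'   incorporation; `"any"` — any incorporation of either object;
#'   or a function taking a cued/uncued-augmented annotation data frame
#'   and returning one label per row.
#' @return object of class `dc_agreement`: `pearson_r`, `pearson_p`,
#'   `kappa`, `t`, `df`, `t_p`, `n_units`.
#' @export
rater_agreement <- function(annotations, raters = NULL,
                            unit_rule = c("any_cued", "any")) {
  validate_annotations(annotations)
  ids <- sort(unique(annotations$rater_id))
  if (is.null(raters)) {
    if (length(ids) < 2L) stop("need annotations from two raters")
    raters <- ids[1:2]
  }
  a1 <- cued_uncued(one_rater(annotations, raters[1]))
  a2 <- cued_uncued(one_rater(annotations, raters[2]))
  key <- function(a) paste(a$participant_id, a$condition, sep = "\r")
  common <- intersect(key(a1), key(a2))
  if (length(common) < 3L) stop("fewer than 3 matched report units")
  a1 <- a1[match(common, key(a1)), ]
  a2 <- a2[match(common, key(a2)), ]
  totals <- function(a) a$direct_fork + a$indirect_fork + a$direct_tree + a$indirect_tree
  t1 <- totals(a1); t2 <- totals(a2)
  labeller <- if (is.function(unit_rule)) {
    unit_rule
  } else {
    switch(match.arg(unit_rule),
           any_cued = function(a) (a$direct_cued + a$indirect_cued) >= 1,
           any = function(a) totals(a) >= 1)
  }
  r <- stats::cor.test(t1, t2)
  d <- t1 - t2
  if (stats::sd(d) == 0) {
    tt <- list(statistic = c(t = 0), parameter = c(df = length(d) - 1),
               p.value = 1)
  } else {
    tt <- stats::t.test(t1, t2, paired = TRUE)
  }
  structure(list(pearson_r = unname(r$estimate), pearson_p = r$p.value,
                 kappa = cohen_kappa(labeller(a1), labeller(a2)),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 t_p = tt$p.value, n_units = length(common),
                 raters = raters),
            class = "dc_agreement")
}

#' @export
print.dc_agreement <- function(x, ...) {
  cat(sprintf("Inter-rater agreement over %d report units (%s vs %s):\n",
              x$n_units, x$raters[1], x$raters[2]))
  cat(sprintf("  Pearson r = %.2f (p = %.3g); Cohen's kappa = %.2f\n",
              x$pearson_r, x$pearson_p, x$kappa))
  cat(sprintf("  paired t(%d) = %.2f, p = %.3g\n", x$df, x$t, x$t_p))
  invisible(x)
}

#' Within-subject factorial ANOVA via per-participant contrasts
#'
#' For a fully within-subject design in which every factor has exactly
#' two levels, each main effect and interaction is computed from its
#' signed contrast score per participant (difference of cell means
#' between the +1 and -1 cells of the effect's sign pattern).  The F for
#' the effect is exactly the square of the paired t on that contrast,
#' with df = (1, n - 1), and partial eta squared is `F / (F + df_error)`.
#'
#' @param data long-format data frame, one row per participant x cell.
#' @param dv name of the count/score column.
#' @param id name of the participant column.
#' @param factors character vector of up to three 2-level factor columns.
#' @return data frame: `effect`, `estimate`, `F`, `df1`, `df2`, `p`,
#'   `partial_eta_sq`.
#' @export
within_subject_anova <- function(data, dv, id, factors) {
  stopifnot(all(c(dv, id, factors) %in% names(data)),
            length(factors) >= 1L, length(factors) <= 3L)
  lev <- lapply(factors, function(f) sort(unique(as.character(data[[f]]))))
  names(lev) <- factors
  if (any(lengths(lev) != 2L)) stop("every factor must have exactly 2 levels")
  ids <- unique(data[[id]])
  n_cells <- 2L^length(factors)
  cell_of <- interaction(lapply(factors, function(f) data[[f]]), drop = FALSE)
  counts <- table(data[[id]], cell_of)
  if (any(counts != 1L)) stop("each participant needs exactly one value per cell")
  # +1/-1 code per factor: second sorted level is +1
  codes <- lapply(factors, function(f) {
    ifelse(as.character(data[[f]]) == lev[[f]][2], 1, -1)
  })
  effects <- unlist(lapply(seq_along(factors), function(k) {
    utils::combn(factors, k, paste, collapse = ":", simplify = FALSE)
  }))
  rows <- lapply(effects, function(eff) {
    involved <- strsplit(eff, ":", fixed = TRUE)[[1]]
    sign <- Reduce(`*`, codes[match(involved, factors)])
    plus <- tapply(data[[dv]][sign > 0], data[[id]][sign > 0], mean)
    minus <- tapply(data[[dv]][sign < 0], data[[id]][sign < 0], mean)
    score <- plus[match(ids, names(plus))] - minus[match(ids, names(minus))]
    n <- length(score)
    m <- mean(score)
    s <- stats::sd(score)
    tval <- if (s == 0) 0 else m / (s / sqrt(n))
    Fval <- tval^2
    df2 <- n - 1L
    data.frame(effect = eff, estimate = m, F = Fval, df1 = 1L, df2 = df2,
               p = stats::pf(Fval, 1, df2, lower.tail = FALSE),
               partial_eta_sq = Fval / (Fval + df2))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation between incorporation counts and a probe item
#'
#' Pearson correlation with a two-sided (uncorrected) p-value, matching
#' participants between an incorporation-count vector and a thought-probe
#' item score vector.
#'
#' @param counts,scores equal-length numeric vectors (matched
#'   participants).
#' @return list `r`, `p`, `n`.
#' @export
corr_with_probes <- function(counts, scores) {
  stopifnot(length(counts) == length(scores))
  keep <- stats::complete.cases(counts, scores)
  counts <- counts[keep]; scores <- scores[keep]
  if (length(counts) < 3L) stop("need at least 3 matched participants")
  if (stats::sd(counts) == 0 || stats::sd(scores) == 0) {
    stop("zero variance in one of the variables")
  }
  ct <- stats::cor.test(counts, scores)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(counts))
}
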