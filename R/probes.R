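#' The 13-item thought-probe battery
#'
#' Eleven Likert items (1-5) indexing phenomenological features of
#' thought, one binary item (intentionality: deliberate vs spontaneous)
#' and one 4-category item (temporality: past / present / future / none),
#' administered once per condition.
#'
#' @return character vector of the 11 Likert item column names.
#' @export
probe_items <- function() {
  c("positive_valence", "negative_valence", "images", "words", "novelty",
    "freedom_of_flow", "topical_shifts", "meaningfulness",
    "current_concerns", "bizarreness", "emotionality")
}

.intentionality_levels <- c("deliberate", "spontaneous")
.temporality_levels <- c("past", "present", "future", "none")

#' Validate / read a thought-probe response table
#'
#' Expected columns: `participant_id`, `condition`, the 11 Likert items
#' of [probe_items()] (integers 1-5), `intentionality`
#' (deliberate/spontaneous) and `temporality` (past/present/future/none).
#'
#' @param probes probe data frame.
#' @return the validated data frame, invisibly for `validate_probes()`.
#' @export
validate_probes <- function(probes) {
  need <- c("participant_id", "condition", probe_items(),
            "intentionality", "temporality")
  if (!all(need %in% names(probes))) {
    stop("probe table must have columns: ", paste(need, collapse = ", "))
  }
  for (it in probe_items()) {
    v <- probes[[it]]
    if (any(is.na(v)) || any(!v %in% 1:5)) {
      stop("Likert item '", it, "' must contain integers 1..5")
    }
  }
  if (!all(probes$intentionality %in% .intentionality_levels)) {
    stop("intentionality must be one of: ",
         paste(.intentionality_levels, collapse = ", "))
  }
  if (!all(probes$temporality %in% .temporality_levels)) {
    stop("temporality must be one of: ",
         paste(.temporality_levels, collapse = ", "))
  }
  invisible(probes)
}

#' @rdname validate_probes
#' @param path CSV file path.
#' @export
read_probes <- function(path) {
  probes <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_probes(probes)
  probes
}

#' @rdname validate_probes
#' @export
write_probes <- function(probes, path) {
  utils::write.csv(probes, path, row.names = FALSE)
  invisible(path)
}

match_conditions <- function(probes) {
  hyp <- probes[probes$condition == "hypnagogia", ]
  fmt <- probes[probes$condition == "fmt", ]
  ids <- intersect(hyp$participant_id, fmt$participant_id)
  if (length(ids) == 0L) stop("no participants with both conditions")
  list(hyp = hyp[match(ids, hyp$participant_id), ],
       fmt = fmt[match(ids, fmt$participant_id), ],
       ids = ids)
}

#' Paired contrast of one Likert item between conditions
#'
#' Two-sided paired t-test of the hypnagogia-minus-FMT difference for one
#' item, over participants with both conditions.
#'
#' @param probes probe table containing both conditions.
#' @param item one of [probe_items()].
#' @return list `item`, `estimate` (hypnagogia - FMT mean difference),
#'   `t`, `df`, `p`.
#' @export
paired_contrast <- function(probes, item) {
  validate_probes(probes)
  stopifnot(item %in% probe_items())
  m <- match_conditions(probes)
  d <- m$hyp[[item]] - m$fmt[[item]]
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(item = item, estimate = 0, t = 0, df = length(d) - 1L, p = 1))
    }
    stop("zero-variance non-zero differences for item '", item, "'")
  }
  tt <- stats::t.test(m$hyp[[item]], m$fmt[[item]], paired = TRUE)
  list(item = item, estimate = unname(tt$estimate),
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-values controlling the false discovery rate: with raw
#' p-values sorted ascending, `adj_(k) = min_{j >= k} p_(j) * m / j`,
#' clipped at 1, mapped back to input order.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Condition contrast for the binary intentionality item
#'
#' Binomial logistic regression of intentionality (spontaneous vs
#' deliberate) on condition, assessed by a likelihood-ratio test against
#' the intercept-only model.  Complete separation is flagged and the odds
#' ratio replaced by the Haldane-Anscombe (add 0.5) table estimate.
#'
#' @param probes probe table containing both conditions.
#' @return list `chi2`, `df`, `p`, `odds_ratio` (odds of "spontaneous" in
#'   hypnagogia relative to FMT), `separation`.
#' @export
binary_item_contrast <- function(probes) {
  validate_probes(probes)
  m <- match_conditions(probes)
  dat <- rbind(m$hyp, m$fmt)
  dat$y <- as.integer(dat$intentionality == "spontaneous")
  dat$condition <- factor(dat$condition, levels = c("fmt", "hypnagogia"))
  if (length(unique(dat$y)) < 2L) stop("intentionality has no variation")
  full <- suppressWarnings(stats::glm(y ~ condition, family = stats::binomial(),
                                      data = dat))
  null <- stats::glm(y ~ 1, family = stats::binomial(), data = dat)
  chi2 <- as.numeric(2 * (stats::logLik(full) - stats::logLik(null)))
  chi2 <- max(chi2, 0)
  co <- stats::coef(full)[["conditionhypnagogia"]]
  fitted_extreme <- any(full$fitted.values > 1 - 1e-8 | full$fitted.values < 1e-8)
  separation <- !full$converged || abs(co) > 15 || fitted_extreme
  or <- exp(co)
  if (separation) {
    tab <- table(dat$condition, dat$y) + 0.5
    or <- unname((tab["hypnagogia", "1"] / tab["hypnagogia", "0"]) /
                   (tab["fmt", "1"] / tab["fmt", "0"]))
    warning("separation detected; odds ratio from Haldane-Anscombe corrected table")
  }
  list(chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, 1, lower.tail = FALSE),
       odds_ratio = unname(or), separation = separation)
}

#' Condition contrast for the 4-category temporality item
#'
#' Baseline-category multinomial logit of temporality on condition, with
#' the atemporal "none" response as the reference category.  Reports the
#' per-category relative-risk ratio (RRR) of responding in that category
#' rather than "none" for FMT relative to hypnagogia, also expressed as a
#' percent change, and a model likelihood-ratio test against the
#' intercept-only model.
#'
#' @param probes probe table containing both conditions.
#' @param reference reference temporality category (default `"none"`).
#' @return list with `rrr` (named vector), `pct_change`, `chi2`, `df`,
#'   `p`.
#' @export
multinomial_item_contrast <- function(probes, reference = "none") {
  validate_probes(probes)
  m <- match_conditions(probes)
  dat <- rbind(m$hyp, m$fmt)
  present_levels <- .temporality_levels[.temporality_levels %in% dat$temporality]
  if (!reference %in% present_levels) stop("reference category '", reference,
                                           "' is empty")
  dropped <- setdiff(.temporality_levels, present_levels)
  if (length(dropped)) {
    warning("empty temporality categories dropped: ",
            paste(dropped, collapse = ", "))
  }
  dat$temporality <- factor(dat$temporality,
                            levels = c(reference, setdiff(present_levels, reference)))
  dat$condition <- factor(dat$condition, levels = c("hypnagogia", "fmt"))
  full <- nnet::multinom(temporality ~ condition, data = dat, trace = FALSE)
  null <- nnet::multinom(temporality ~ 1, data = dat, trace = FALSE)
  chi2 <- max(0, as.numeric(null$deviance - full$deviance))
  df <- length(stats::coef(full)) - length(stats::coef(null))
  co <- stats::coef(full)
  if (is.null(dim(co))) co <- matrix(co, nrow = 1,
                                     dimnames = list(levels(dat$temporality)[2],
                                                     names(co)))
  rrr <- exp(co[, "conditionfmt"])
  list(rrr = rrr, pct_change = 100 * (rrr - 1),
       chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Full item-level contrast table with BH correction
#'
#' Runs the 11 paired t-tests plus the intentionality (binomial logistic)
#' and temporality (multinomial logistic) model contrasts, then applies
#' the Benjamini-Hochberg correction across all 13 p-values as one
#' family.
#'
#' @param probes probe table containing both conditions.
#' @return data frame of class `dc_contrast_table`: `item`, `estimate`
#'   (hypnagogia - FMT; `NA` for the categorical items), `raw_p`, `bh_p`,
#'   ordered by ascending raw p.
#' @export
probe_contrasts <- function(probes) {
  cont <- lapply(probe_items(), function(it) {
    r <- paired_contrast(probes, it)
    data.frame(item = it, estimate = r$estimate, raw_p = r$p)
  })
  b <- binary_item_contrast(probes)
  mm <- multinomial_item_contrast(probes)
  out <- rbind(do.call(rbind, cont),
               data.frame(item = "intentionality", estimate = NA_real_,
                          raw_p = b$p),
               data.frame(item = "temporality", estimate = NA_real_,
                          raw_p = mm$p))
  out$bh_p <- bh_adjust(out$raw_p)
  out <- out[order(out$raw_p), ]
  rownames(out) <- NULL
  class(out) <- c("dc_contrast_table", "data.frame")
  out
}

#' @export
print.dc_contrast_table <- function(x, ...) {
  cat("Hypnagogia vs FMT item-level contrasts (BH-corrected family of",
      nrow(x), "tests):\n")
  df <- as.data.frame(x)
  df$estimate <- round(df$estimate, 4)
  df$raw_p <- signif(df$raw_p, 3)
  df$bh_p <- signif(df$bh_p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
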