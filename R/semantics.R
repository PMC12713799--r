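#' Prompt centrality of a report
#'
#' The mean cosine similarity between each sentence of a report and the
#' cued object's bare lowercase word (e.g. "fork").  Reports should be
#' prompt-word filtered first (see [filter_prompt_words()]) so literal cue
#' mentions cannot inflate the score.
#'
#' @param sentences character vector of (filtered) sentences.
#' @param cue_word the cue as a single word; lowercased before embedding.
#' @param embedder a `dc_embedder` (default [hash_embedder()]).
#' @return mean similarity in `[-1, 1]`, or `NA_real_` for an empty
#'   sentence set.
#' @export
prompt_centrality <- function(sentences, cue_word, embedder = hash_embedder()) {
  stopifnot(inherits(embedder, "dc_embedder"), is.character(cue_word),
            length(cue_word) == 1L)
  if (length(sentences) == 0L) return(NA_real_)
  cue_vec <- drop(embed_sentences(embedder, tolower(cue_word)))
  mat <- embed_sentences(embedder, sentences)
  mean(apply(mat, 1L, cosine_similarity, v = cue_vec))
}

#' Temporal coherence of a report
#'
#' The mean cosine similarity between consecutive sentence embeddings
#' (sentence 1 with 2, 2 with 3, ...), a width-2 stride-1 sliding window
#' over the report.  Defined only for reports with at least two
#' sentences; otherwise the value is missing (`NA`), not an error.
#'
#' @inheritParams prompt_centrality
#' @return mean consecutive-pair similarity in `[-1, 1]`, or `NA_real_`
#'   when fewer than two sentences are present.
#' @export
temporal_coherence <- function(sentences, embedder = hash_embedder()) {
  stopifnot(inherits(embedder, "dc_embedder"))
  n <- length(sentences)
  if (n < 2L) return(NA_real_)
  mat <- embed_sentences(embedder, sentences)
  mean(vapply(seq_len(n - 1L),
              function(i) cosine_similarity(mat[i, ], mat[i + 1L, ]),
              numeric(1)))
}

#' Semantic scores for a table of reports
#'
#' Runs the full per-report semantic pipeline: sentence segmentation,
#' prompt-word filtering, prompt centrality against the session's cue
#' word, and temporal coherence.
#'
#' @param reports data frame with `participant_id`, `condition`,
#'   `cue_object`, `text` (see [read_reports()]).
#' @param embedder a `dc_embedder`.
#' @param filter_prompt remove cue words before scoring (default `TRUE`,
#'   applied to centrality and coherence alike).
#' @return tidy data frame: `participant_id`, `condition`, `cue_object`,
#'   `n_sentences`, `prompt_centrality`, `temporal_coherence`.
#' @export
semantic_scores <- function(reports, embedder = hash_embedder(),
                            filter_prompt = TRUE) {
  need <- c("participant_id", "condition", "cue_object", "text")
  stopifnot(all(need %in% names(reports)))
  rows <- lapply(seq_len(nrow(reports)), function(i) {
    sents <- segment_sentences(reports$text[i])
    if (filter_prompt) {
      sents <- filter_prompt_words(sents, reports$cue_object[i])
    }
    data.frame(participant_id = reports$participant_id[i],
               condition = reports$condition[i],
               cue_object = reports$cue_object[i],
               n_sentences = length(sents),
               prompt_centrality = prompt_centrality(
                 sents, tolower(reports$cue_object[i]), embedder),
               temporal_coherence = temporal_coherence(sents, embedder))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit a random-intercept linear mixed model
#'
#' Fits `outcome ~ fixed terms + (1 | group)` by maximum likelihood
#' (`REML = FALSE`, so nested fixed-effect fits are comparable by
#' likelihood ratio).  This is the model family used to relate prompt
#' centrality, temporal coherence, condition and incorporation counts,
#' with a random intercept absorbing stable participant differences.
#'
#' @param formula fixed-effects formula, e.g.
#'   `prompt_centrality ~ direct_incorporations`.
#' @param data model data frame.
#' @param group name of the grouping column (default `"participant_id"`).
#' @return object of class `dc_mixed`: the `lme4` fit plus extracted
#'   fixed effects (`beta`), standard errors (`se`), random-intercept
#'   standard deviation (`sigma_u`), residual sd (`sigma`), `logLik` and
#'   parameter count `n_par`.
#' @export
fit_random_intercept <- function(formula, data, group = "participant_id") {
  stopifnot(inherits(formula, "formula"), group %in% names(data))
  if (length(unique(data[[group]])) < 2L) stop("need at least 2 groups")
  yname <- all.vars(formula)[1]
  keep <- stats::complete.cases(data[, unique(c(all.vars(formula), group)), drop = FALSE])
  data <- data[keep, , drop = FALSE]
  if (stats::var(data[[yname]]) == 0) stop("outcome is constant")
  full <- stats::as.formula(paste(deparse(formula), "+ (1 |", group, ")"))
  fit <- lme4::lmer(full, data = data, REML = FALSE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  ll <- stats::logLik(fit)
  structure(list(fit = fit,
                 beta = lme4::fixef(fit),
                 se = sqrt(diag(as.matrix(stats::vcov(fit)))),
                 sigma_u = vc$sdcor[vc$grp == group][1],
                 sigma = stats::sigma(fit),
                 logLik = as.numeric(ll),
                 n_par = attr(ll, "df"),
                 n_obs = nrow(data),
                 formula = formula, group = group),
            class = "dc_mixed")
}

#' @export
print.dc_mixed <- function(x, ...) {
  cat("random-intercept mixed model (ML):",
      deparse(x$formula), "+ (1 |", x$group, ")\n")
  est <- cbind(estimate = x$beta, se = x$se)
  print(round(est, 4))
  cat(sprintf("random-intercept sd %.4f, residual sd %.4f, logLik %.2f (%d par, %d obs)\n",
              x$sigma_u, x$sigma, x$logLik, x$n_par, x$n_obs))
  invisible(x)
}

#' Likelihood ratio test between nested mixed-model fits
#'
#' The significance of each effect is assessed by comparing the full
#' model against the model with that effect removed:
#' `chi2 = 2 (logLik_full - logLik_reduced)` on `df` equal to the
#' parameter-count difference.  Both fits must be maximum likelihood
#' (as produced by [fit_random_intercept()]).
#'
#' @param full,reduced `dc_mixed` fits, `reduced` nested in `full`.
#' @param tol tolerance for a negative chi-square before it is treated as
#'   a fit failure.
#' @return list `chi2`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, reduced, tol = 1e-6) {
  stopifnot(inherits(full, "dc_mixed"), inherits(reduced, "dc_mixed"))
  df <- full$n_par - reduced$n_par
  if (df < 1L) stop("'reduced' must have fewer parameters than 'full'")
  chi2 <- 2 * (full$logLik - reduced$logLik)
  if (chi2 < -tol) {
    stop("full model has lower likelihood than reduced model: fit failure")
  }
  chi2 <- max(chi2, 0)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}
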