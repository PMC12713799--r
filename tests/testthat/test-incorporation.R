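test_that("tally computes cued/uncued cell means across participants", {
  ann <- make_annotations(direct_cued = c(2, 4), indirect_cued = c(1, 1))
  tab <- tally_incorporations(ann)
  cued_direct <- tab[tab$cue == "Tree" & tab$content == "Tree" &
                       tab$type == "direct", ]
  expect_equal(cued_direct$mean, 3.0)
  expect_equal(cued_direct$relation, "cued")
  uncued <- tab[tab$relation == "uncued" & tab$n > 0, ]
  expect_true(all(uncued$mean == 0))

  dup <- rbind(ann, ann[1, ])
  expect_error(tally_incorporations(dup), "duplicate")
  bad <- ann; bad$direct_tree[1] <- -1
  expect_error(tally_incorporations(bad), "non-negative")
})

test_that("tally recovers a planted Poisson rate within sampling error", {
  set.seed(12)
  ann <- make_annotations(direct_cued = rpois(80, 3), indirect_cued = rpois(80, 1))
  tab <- tally_incorporations(ann)
  cell <- tab[tab$cue == "Tree" & tab$content == "Tree" & tab$type == "direct", ]
  expect_lt(abs(cell$mean - 3), 0.6)
})

test_that("any-incorporation rate counts participants, not reports", {
  ann <- make_annotations(direct_cued = c(0, 2, 0, 1), indirect_cued = c(0, 0, 1, 0))
  r <- any_incorporation_rate(ann, condition = "hypnagogia")
  expect_equal(r$k, 3L)
  expect_equal(r$n, 4L)
  expect_equal(r$proportion, 0.75)

  zero <- make_annotations(direct_cued = rep(0, 5), indirect_cued = rep(0, 5))
  expect_equal(any_incorporation_rate(zero)$proportion, 0)
  expect_error(any_incorporation_rate(ann, condition = "fmt"), "no annotations")

  set.seed(13)
  big <- make_annotations(direct_cued = rbinom(500, 1, 0.9),
                          indirect_cued = 0)
  expect_lt(abs(any_incorporation_rate(big)$proportion - 0.9), 0.03)
})

test_that("chi-square statistics agree with the cell-by-cell oracle", {
  expect_equal(chisq_vs_chance(40, 80, 0.5)$chi2, 0)
  set.seed(14)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.05, 0.95)
    expect_equal(chisq_vs_chance(k, n, p0)$chi2, chi2_gof_oracle(k, n, p0))
    n2 <- sample(10:200, 1)
    k1 <- sample(1:(n - 1), 1)
    k2 <- sample(1:(n2 - 1), 1)
    expect_equal(chisq_two_proportions(k1, n, k2, n2)$chi2,
                 chi2_2x2_oracle(k1, n, k2, n2))
  }
  expect_equal(chisq_two_proportions(10, 20, 10, 20)$chi2, 0)
  expect_equal(chisq_two_proportions(10, 20, 0, 20)$chi2,
               chi2_2x2_oracle(10, 20, 0, 20))
  expect_error(chisq_two_proportions(0, 20, 0, 20), "zero margin")
  expect_error(chisq_vs_chance(5, 10, 0), "p0")
})

test_that("Cohen's kappa matches its closed form and invariances", {
  # fixed 2x2 agreement table a=50, b=10, c=10, d=10
  x <- rep(c(1, 1, 0, 0), c(50, 10, 10, 10))
  y <- rep(c(1, 0, 1, 0), c(50, 10, 10, 10))
  po <- (50 + 10) / 80
  pe <- (60 / 80) * (60 / 80) + (20 / 80) * (20 / 80)
  expect_equal(cohen_kappa(x, y), (po - pe) / (1 - pe))
  expect_equal(cohen_kappa(x, x), 1)
  # simultaneous label swap leaves kappa unchanged
  expect_equal(cohen_kappa(1 - x, 1 - y), cohen_kappa(x, y))
  if (requireNamespace("e1071", quietly = TRUE)) {
    expect_equal(cohen_kappa(x, y),
                 e1071::classAgreement(table(x, y))$kappa)
  }
  # independent labels: permutation of one rater hovers near zero
  set.seed(15)
  a <- rbinom(2000, 1, 0.5)
  expect_lt(abs(cohen_kappa(a, sample(a))), 0.05)
})

test_that("rater agreement compares matched report units", {
  set.seed(16)
  counts <- rpois(40, 2)
  r1 <- make_annotations(counts, rpois(40, 1), rater = "R1")
  r2 <- r1; r2$rater_id <- "R2"
  ag <- rater_agreement(rbind(r1, r2))
  expect_equal(ag$pearson_r, 1)
  expect_equal(ag$kappa, 1)
  expect_equal(ag$t, 0)
  expect_equal(ag$df, 39)

  # a systematically higher second rater yields a negative paired t and
  # imperfect kappa once presence/absence labels start to differ
  sparse <- make_annotations(rbinom(40, 1, 0.4), integer(40), rater = "R1")
  r2b <- sparse
  r2b$rater_id <- "R2"
  r2b$direct_tree <- as.integer(r2b$direct_tree + rbinom(40, 1, 0.5))
  ag2 <- rater_agreement(rbind(sparse, r2b))
  expect_lt(ag2$t, 0)
  expect_lt(ag2$kappa, 1)

  few <- rbind(r1[1:2, ], r2[1:2, ])
  expect_error(rater_agreement(few), "fewer than 3")
})

test_that("within-subject ANOVA equals paired-t-squared for every effect", {
  set.seed(17)
  n <- 30
  grid <- expand.grid(participant = sprintf("P%02d", seq_len(n)),
                      cue = c("Fork", "Tree"),
                      content = c("Fork", "Tree"),
                      type = c("direct", "indirect"),
                      stringsAsFactors = FALSE)
  grid$count <- rpois(nrow(grid), 2) +
    2 * (grid$cue == grid$content) * (grid$type == "direct")
  res <- within_subject_anova(grid, "count", "participant",
                              c("cue", "content", "type"))
  expect_equal(nrow(res), 7L)  # 3 mains + 3 two-way + 1 three-way
  for (eff in res$effect) {
    involved <- strsplit(eff, ":")[[1]]
    sign <- Reduce(`*`, lapply(involved, function(f) {
      ifelse(grid[[f]] == sort(unique(grid[[f]]))[2], 1, -1)
    }))
    score <- tapply(grid$count[sign > 0], grid$participant[sign > 0], mean) -
      tapply(grid$count[sign < 0], grid$participant[sign < 0], mean)
    tt <- t.test(score)
    expect_equal(res$F[res$effect == eff], unname(tt$statistic)^2,
                 tolerance = 1e-10)
    expect_equal(res$p[res$effect == eff], tt$p.value, tolerance = 1e-10)
    expect_equal(res$partial_eta_sq[res$effect == eff],
                 unname(tt$statistic)^2 / (unname(tt$statistic)^2 + n - 1))
  }

  # all-zero contrasts give F = 0
  flat <- expand.grid(participant = sprintf("P%02d", seq_len(n)),
                      cue = c("Fork", "Tree"),
                      content = c("Fork", "Tree"), stringsAsFactors = FALSE)
  flat$count <- 5
  res0 <- within_subject_anova(flat, "count", "participant",
                               c("cue", "content"))
  expect_true(all(res0$F == 0))

  expect_error(within_subject_anova(grid[-1, ], "count", "participant",
                                    c("cue", "content", "type")),
               "exactly one value")
})

test_that("a planted cue-by-content interaction is detected with high power", {
  set.seed(18)
  n <- 80
  hits <- replicate(200, {
    grid <- expand.grid(participant = seq_len(n),
                        cue = c("Fork", "Tree"),
                        content = c("Fork", "Tree"), stringsAsFactors = FALSE)
    # per-participant interaction contrast score distributed N(1, 1): d = 1
    score <- rnorm(n, mean = 1, sd = 1)
    grid$count <- ifelse(grid$cue == grid$content, 1, -1) *
      score[grid$participant] / 2 + rnorm(nrow(grid), sd = 0.1)
    res <- within_subject_anova(grid, "count", "participant", c("cue", "content"))
    res$p[res$effect == "cue:content"] < 0.001
  })
  expect_gte(mean(hits), 0.95)
})

test_that("incorporation-probe correlations behave at the boundaries", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(corr_with_probes(x, x)$r, 1)
  expect_error(corr_with_probes(x, rep(2, 5)), "zero variance")
  expect_error(corr_with_probes(x[1:2], x[1:2]), "at least 3")
  set.seed(19)
  null_r <- replicate(2000, corr_with_probes(rnorm(80), rnorm(80))$r)
  expect_equal(mean(abs(null_r) < 0.22), 0.95, tolerance = 0.02)
})

test_that("annotation tables round-trip through CSV", {
  ann <- make_annotations(direct_cued = c(2, 0), indirect_cued = c(1, 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, f)
  expect_identical(read_annotations(f), ann)
})
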