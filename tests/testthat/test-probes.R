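test_that("paired contrasts are symmetric and handle identical responses", {
  items <- random_likert(30, seed = 41)
  same <- make_probes(items, items)
  r <- paired_contrast(same, "novelty")
  expect_equal(r$estimate, 0)
  expect_equal(r$p, 1)

  shifted <- items
  shifted[, 6] <- pmin(items[, 6] + rbinom(30, 1, 0.6), 5)
  probes <- make_probes(shifted, items)
  a <- paired_contrast(probes, "freedom_of_flow")
  # swapping condition labels negates the estimate, p unchanged
  swapped <- probes
  swapped$condition <- ifelse(probes$condition == "fmt", "hypnagogia", "fmt")
  b <- paired_contrast(swapped, "freedom_of_flow")
  expect_equal(b$estimate, -a$estimate)
  expect_equal(b$p, a$p)
  expect_gt(a$estimate, 0)
})

test_that("a planted shift on one item is detected in most cohorts", {
  set.seed(42)
  hits <- replicate(100, {
    n <- 80
    hyp <- random_likert(n, seed = sample.int(1e6, 1))
    fmt <- hyp
    # shift roughly +0.31 on the 1-5 scale with difference sd near 1.2
    bump <- rbinom(n, 2, 0.4) - rbinom(n, 2, 0.25)
    hyp[, 6] <- pmin(pmax(hyp[, 6] + bump, 1), 5)
    paired_contrast(make_probes(hyp, fmt), "freedom_of_flow")$p < 0.05
  })
  expect_gt(mean(hits), 0.5)
})

test_that("BH adjustment equals the min-over-tail oracle", {
  expect_equal(bh_adjust(0.37), 0.37)  # m = 1: adjusted equals raw
  expect_error(bh_adjust(c(0.2, 1.3)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.2, -0.1)), "\\[0, 1\\]")
  set.seed(43)
  for (i in 1:200) {
    p <- runif(sample(1:25, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("binary intentionality contrast: LRT and closed-form odds ratio", {
  items <- random_likert(160, seed = 44)
  ident <- make_probes(items, items,
                       hyp_int = rep(c("spontaneous", "deliberate"), 80),
                       fmt_int = rep(c("spontaneous", "deliberate"), 80))
  r0 <- binary_item_contrast(ident)
  expect_lt(r0$chi2, 1e-8)
  expect_equal(r0$odds_ratio, 1, tolerance = 1e-4)

  # planted 2x2 table: hypnagogia 30 spontaneous / 50 deliberate,
  # FMT 50 spontaneous / 30 deliberate -> OR = (30*30)/(50*50) = 0.36
  tab <- make_probes(random_likert(80, seed = 45), random_likert(80, seed = 46),
                     hyp_int = rep(c("spontaneous", "deliberate"), c(30, 50)),
                     fmt_int = rep(c("spontaneous", "deliberate"), c(50, 30)))
  r <- binary_item_contrast(tab)
  expect_equal(r$odds_ratio, 0.36, tolerance = 1e-6)
  expect_false(r$separation)
  expect_lt(r$p, 0.05)

  sep <- make_probes(random_likert(20, seed = 47), random_likert(20, seed = 48),
                     hyp_int = rep("spontaneous", 20),
                     fmt_int = rep("deliberate", 20))
  expect_warning(rs <- binary_item_contrast(sep), "separation")
  expect_true(rs$separation)
  expect_true(is.finite(rs$odds_ratio))
})

test_that("a planted intentionality log-odds shift of 1 is reliably detected", {
  set.seed(49)
  hits <- replicate(100, {
    n <- 80
    p_hyp <- plogis(0.5)   # log-odds +0.5
    p_fmt <- plogis(-0.5)  # log-odds -0.5 -> difference 1.0
    tab <- make_probes(
      random_likert(n, seed = sample.int(1e6, 1)),
      random_likert(n, seed = sample.int(1e6, 1)),
      hyp_int = ifelse(runif(n) < p_hyp, "spontaneous", "deliberate"),
      fmt_int = ifelse(runif(n) < p_fmt, "spontaneous", "deliberate"))
    binary_item_contrast(tab)$p < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("multinomial temporality contrast reports RRRs against 'none'", {
  items <- random_likert(200, seed = 50)
  temp <- rep(c("past", "present", "future", "none"), 50)
  same <- make_probes(items, items, hyp_temp = temp, fmt_temp = temp)
  r0 <- multinomial_item_contrast(same)
  expect_true(all(abs(r0$rrr - 1) < 1e-4))
  expect_true(all(abs(r0$pct_change) < 0.05))

  # duplicating every observation tenfold leaves the RRRs unchanged
  idx <- rep(seq_len(nrow(same)), 10)
  big <- same[idx, ]
  big$participant_id <- paste0(big$participant_id, "_", rep(1:10, each = nrow(same)))
  r10 <- multinomial_item_contrast(big)
  expect_equal(r10$rrr, r0$rrr, tolerance = 1e-3)

  dropped <- make_probes(items, items,
                         hyp_temp = rep(c("past", "present", "none"),
                                        length.out = 200),
                         fmt_temp = rep(c("past", "present", "none"),
                                        length.out = 200))
  expect_warning(multinomial_item_contrast(dropped), "future")
  none_empty <- make_probes(items, items,
                            hyp_temp = rep("past", 200),
                            fmt_temp = rep("present", 200))
  expect_error(multinomial_item_contrast(none_empty), "reference")
})

test_that("a planted present-vs-none relative risk ratio is recovered", {
  set.seed(51)
  n <- 4000
  p_hyp <- c(past = 0.25, present = 0.25, future = 0.25, none = 0.25)
  p_fmt <- c(past = 0.25, present = 0.33768, future = 0.23232, none = 0.18)
  tab <- make_probes(random_likert(n, seed = 52), random_likert(n, seed = 53),
                     hyp_temp = sample(names(p_hyp), n, TRUE, p_hyp),
                     fmt_temp = sample(names(p_fmt), n, TRUE, p_fmt))
  r <- multinomial_item_contrast(tab)
  planted <- (0.33768 / 0.18) / (0.25 / 0.25)  # 1.876
  expect_equal(unname(r$rrr["present"]), planted, tolerance = 0.1)
})

test_that("the full 13-item contrast table is one BH family", {
  set.seed(54)
  probes <- make_probes(random_likert(60, seed = 55), random_likert(60, seed = 56))
  ct <- probe_contrasts(probes)
  expect_equal(nrow(ct), 13L)
  expect_setequal(ct$item, c(probe_items(), "intentionality", "temporality"))
  expect_true(all(ct$bh_p >= ct$raw_p - 1e-15))
  expect_true(all(ct$bh_p <= 1))
  expect_equal(ct$bh_p, bh_oracle(ct$raw_p))
  expect_true(all(is.na(ct$estimate[ct$item %in% c("intentionality", "temporality")])))
  expect_false(is.unsorted(ct$raw_p))
})

test_that("probe tables validate and round-trip", {
  probes <- make_probes(random_likert(10, seed = 57), random_likert(10, seed = 58))
  f <- withr::local_tempfile(fileext = ".csv")
  write_probes(probes, f)
  expect_identical(read_probes(f), probes)
  bad <- probes; bad$novelty[1] <- 6
  expect_error(validate_probes(bad), "1..5")
  bad2 <- probes; bad2$temporality[2] <- "later"
  expect_error(validate_probes(bad2), "temporality")
})
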