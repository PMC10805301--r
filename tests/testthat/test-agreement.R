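tab <- fixture_concordance()

test_that("percent agreement counts concordant pairs", {
  pa <- percent_agreement(tab)
  expect_equal(pa$n_agree, 139L)
  expect_equal(pa$proportion, 139 / 160)
  expect_equal(percent_agreement(
    pairs_from_counts(avoid = c(0, 0, 5)))$proportion, 1)
  expect_equal(percent_agreement(
    pairs_from_counts(avoid = c(0, 1, 1)))$proportion, 0.5)
  expect_error(percent_agreement(tab, classes = character(0)),
               class = "edacr_empty_input")
})

test_that("pooled-marginal kappa reproduces the study estimates", {
  expect_equal(round(pooled_kappa(tab)$kappa, 2), 0.69)
  expect_equal(round(pooled_kappa(
    tab, classes = c("avoidable", "not_avoidable"))$kappa, 2), 0.84)
  expect_equal(round(per_class_kappa(tab, "avoidable")$kappa, 2), 0.66)
  expect_equal(round(per_class_kappa(tab, "not_avoidable")$kappa, 2), 0.69)
  k <- pooled_kappa(tab)
  expect_true(k$ci_low <= k$kappa && k$kappa <= k$ci_high)
  expect_true(k$kappa <= k$po)
})

test_that("perfect agreement with a mixed marginal gives kappa 1", {
  k <- pooled_kappa(pairs_from_counts(avoid = c(3, 0, 7)))
  expect_equal(k$kappa, 1)
  expect_equal(k$po, 1)
})

test_that("kappa is undefined when every rating is identical", {
  expect_error(pooled_kappa(pairs_from_counts(avoid = c(0, 0, 4))),
               class = "edacr_kappa_undefined")
  # a single concordant pair can never have chance agreement below 1
  expect_error(pooled_kappa(pairs_from_counts(not_av = c(1, 0, 0))),
               class = "edacr_kappa_undefined")
})

test_that("kappa is invariant to swapping the anonymous rating slots", {
  pairs <- fixture_pairs()
  set.seed(9)
  for (i in 1:20) {
    flip <- runif(nrow(pairs)) < 0.5
    swapped <- pairs
    swapped$rating_a[flip] <- pairs$rating_b[flip]
    swapped$rating_b[flip] <- pairs$rating_a[flip]
    expect_equal(pooled_kappa(swapped)$kappa, pooled_kappa(pairs)$kappa)
  }
})

test_that("independent ratings at matched marginals give kappa near zero", {
  set.seed(31)
  n <- 10000
  p <- tibble::tibble(
    visit_id = as.character(seq_len(n)),
    edac_class = "avoidable",
    rating_a = runif(n) < 0.6, rating_b = runif(n) < 0.6)
  expect_lt(abs(pooled_kappa(p)$kappa), 0.03)
})

test_that("pooled kappa equals classical Cohen kappa under symmetric attribution", {
  # even attribution of discordant pairs -> identical 2x2 marginals
  counts <- c(both_ed = 10, discordant = 8, both_subacute = 22)
  tab2x2 <- rbind(c(counts[["both_subacute"]], 4), c(4, counts[["both_ed"]]))
  pairs <- pairs_from_counts(avoid = c(10, 8, 22))
  expect_equal(pooled_kappa(pairs)$kappa, cohen_kappa_2x2(tab2x2))
  skip_if_not_installed("e1071")
  expect_equal(cohen_kappa_2x2(tab2x2),
               e1071::classAgreement(tab2x2)$kappa)
})

test_that("attribution of discordant pairs moves kappa only within a narrow band", {
  rng <- kappa_attribution_range(tab)
  expect_equal(nrow(rng), 22) # 21 discordant pairs overall
  expect_true(all(round(rng$kappa, 2) == 0.69))
  for (cl in c("avoidable", "not_avoidable")) {
    r <- kappa_attribution_range(tab, classes = cl)
    expect_true(diff(range(r$kappa)) < 0.02)
  }
  # the published per-class values sit inside the attribution envelopes
  r_not <- kappa_attribution_range(tab, classes = "not_avoidable")
  expect_true(any(round(r_not$kappa, 2) == 0.70))
  r_pot <- kappa_attribution_range(tab, classes = "potentially_avoidable")
  expect_true(any(round(r_pot$kappa, 2) %in% c(0.24, 0.25)))
})

test_that("interpretation bands follow the Landis-Koch cut points", {
  expect_equal(kappa_interpretation(0.69), "substantial agreement")
  expect_equal(kappa_interpretation(0.84), "almost perfect agreement")
  expect_equal(kappa_interpretation(0), "slight agreement")
  expect_equal(kappa_interpretation(c(-0.1, 0.20, 0.21, 0.60, 0.61, 1)),
               c("poor agreement", "slight agreement", "fair agreement",
                 "moderate agreement", "substantial agreement",
                 "almost perfect agreement"))
})

test_that("confidence summaries pool both slots with sample SD", {
  p <- pairs_from_counts(avoid = c(0, 0, 2))
  p$confidence_a <- c(5L, 3L)
  p$confidence_b <- c(5L, 5L)
  s <- confidence_summary(p)
  expect_equal(s$mean, 4.5)
  expect_equal(s$sd, sd(c(5, 3, 5, 5)))
  p2 <- p
  p2$confidence_a <- c(5L, 5L); p2$confidence_b <- c(5L, 5L)
  expect_equal(confidence_summary(p2)$sd, 0)
  # {3, 5} -> mean 4
  p3 <- pairs_from_counts(avoid = c(0, 0, 1))
  p3$confidence_a <- 3L; p3$confidence_b <- 5L
  expect_equal(confidence_summary(p3)$mean, 4)
  expect_error(confidence_summary(fixture_pairs()),
               class = "edacr_empty_input") # fixture carries no scores
})

test_that("confidence summaries recover generator moments", {
  v <- generate_visits(n_per_class = c(avoidable = 2000,
                                       potentially_avoidable = 0,
                                       not_avoidable = 0), seed = 5)
  j <- generate_judgements(v, seed = 6)
  s <- confidence_summary(j)
  # clipping to 1..5 shifts the mean slightly below the 4.2 target
  expect_lt(abs(s$mean - 4.2), 0.1)
  expect_lt(abs(s$sd - 0.9), 0.15)
})

test_that("bootstrap intervals behave on degenerate and fixture data", {
  conc <- pairs_from_counts(avoid = c(4, 0, 6))
  b <- bootstrap_ci(conc, "percent_agreement", reps = 300, seed = 1)
  expect_equal(c(b$ci_low, b$ci_high), c(1, 1))
  fx <- fixture_pairs()
  bk <- bootstrap_ci(fx, "kappa", reps = 400, seed = 2)
  expect_true(bk$ci_low <= bk$point && bk$point <= bk$ci_high)
  bk2 <- bootstrap_ci(fx, "kappa", reps = 400, seed = 2)
  expect_equal(bk, bk2)
  expect_error(bootstrap_ci(fx, "kappa", reps = 50), class = "edacr_invalid_spec")
})

test_that("bootstrap interval width shrinks roughly as 1/sqrt(n)", {
  make <- function(n) pairs_from_counts(not_av = c(3, 1, 1) * n,
                                        avoid = c(1, 1, 3) * n)
  w <- vapply(c(4, 16), function(n) {
    b <- bootstrap_ci(make(n), "kappa", reps = 400, seed = 3)
    b$ci_high - b$ci_low
  }, numeric(1))
  expect_lt(w[2] / w[1], 0.75) # quadrupling n should roughly halve the width
})
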