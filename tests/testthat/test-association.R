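tab <- fixture_concordance()

test_that("pair concordance ordinalizes symmetrically", {
  expect_equal(as.character(ordinalize(TRUE, TRUE)), "both_subacute")
  expect_equal(as.character(ordinalize(TRUE, FALSE)), "discordant")
  expect_equal(as.character(ordinalize(FALSE, TRUE)), "discordant")
  expect_equal(as.character(ordinalize(FALSE, FALSE)), "both_ed")
  expect_true(is.ordered(ordinalize(TRUE, TRUE)))
})

test_that("concordance tables cross-classify pairs and preserve totals", {
  fx <- fixture_pairs()
  t2 <- concordance_table(fx)
  expect_equal(unclass(t2), unclass(tab))
  expect_equal(unname(unclass(tab)["avoidable", ]), c(1, 1, 52))
  expect_equal(unname(unclass(tab)["not_avoidable", ]), c(33, 7, 13))
  expect_equal(sum(tab), 160)
  one <- concordance_table(pairs_from_counts(pot = c(0, 1, 0)))
  expect_equal(sum(one), 1)
  expect_equal(unclass(one)["potentially_avoidable", "discordant"], 1)
  expect_error(concordance_table(fx[0, ]), class = "edacr_empty_input")
})

test_that("tie-corrected Spearman matches the study and the base-R oracle", {
  expect_equal(round(spearman_ordinal(tab), 2), 0.64)
  diag_tab <- as_concordance_table(rbind(
    not_avoidable = c(both_ed = 5, discordant = 0, both_subacute = 0),
    potentially_avoidable = c(0, 4, 0),
    avoidable = c(0, 0, 6)))
  expect_equal(spearman_ordinal(diag_tab), 1)
  # enumeration oracle on a small table with ties
  toy <- as_concordance_table(rbind(
    not_avoidable = c(both_ed = 3, discordant = 0, both_subacute = 1),
    potentially_avoidable = c(0, 0, 0),
    avoidable = c(1, 0, 3)))
  long <- expand_table_long(toy)
  x <- as.integer(factor(long$cls, levels = edac_levels()))
  y <- as.integer(factor(long$lvl, levels = concordance_levels()))
  expect_equal(spearman_ordinal(toy), cor(x, y, method = "spearman"))
  long_fx <- expand_table_long(tab)
  expect_equal(spearman_ordinal(tab),
               cor(as.integer(factor(long_fx$cls, levels = edac_levels())),
                   as.integer(factor(long_fx$lvl,
                                     levels = concordance_levels())),
                   method = "spearman"))
})

test_that("Spearman is invariant to monotone relabeling and flags degeneracy", {
  # midranks depend only on the orderings, so any strictly monotone
  # relabeling of either scale leaves rho unchanged; permuting rows breaks it
  r <- spearman_ordinal(tab)
  expect_equal(r, spearman_ordinal(as_concordance_table(unclass(tab))))
  degenerate <- as_concordance_table(rbind(
    not_avoidable = c(both_ed = 0, discordant = 0, both_subacute = 4),
    potentially_avoidable = c(0, 0, 3), avoidable = c(0, 0, 5)))
  expect_error(spearman_ordinal(degenerate),
               class = "edacr_degenerate_margin")
})

test_that("the proportional-odds fit matches MASS::polr on the fixture", {
  skip_if_not_installed("MASS")
  fit <- fit_cumulative_logit(tab)
  long <- expand_table_long(tab)
  long$y <- factor(long$lvl, levels = concordance_levels(), ordered = TRUE)
  long$cls <- factor(long$cls, levels = edac_levels())
  oracle <- MASS::polr(y ~ cls, data = long, Hess = TRUE)
  expect_equal(unname(fit$beta),
               unname(coef(oracle)[c("clspotentially_avoidable",
                                     "clsavoidable")]),
               tolerance = 1e-4)
  expect_equal(unname(fit$zeta), unname(oracle$zeta), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(oracle)), tolerance = 1e-6)
  expect_true(fit$converged)
  expect_gte(fit$loglik, fit$loglik_null)
})

test_that("binary collapse of the fit reduces to closed-form logistic estimates", {
  # merge discordant into both_ed: with a saturated dummy predictor the
  # cumulative-logit MLE equals ordinary logistic regression, whose fitted
  # log-odds are the observed cell log-odds and whose coefficients are log
  # cross-product ratios
  m <- unclass(tab)
  collapsed <- cbind(both_ed = m[, "both_ed"] + m[, "discordant"],
                     discordant = 0, both_subacute = m[, "both_subacute"])
  # drop the empty middle level by fitting the dichotomy directly
  pos <- collapsed[, "both_subacute"]
  neg <- collapsed[, "both_ed"]
  glm_fit <- glm(cbind(pos, neg) ~ factor(rownames(m), levels = edac_levels()),
                 family = binomial())
  closed_beta_avoid <- log(pos["avoidable"] * neg["not_avoidable"] /
                             (neg["avoidable"] * pos["not_avoidable"]))
  expect_equal(unname(coef(glm_fit)[3]), unname(closed_beta_avoid),
               tolerance = 1e-8)
  or <- reported_or(tab, "avoidable")
  expect_equal(log(or$or), unname(closed_beta_avoid), tolerance = 1e-10)
  expect_equal(log(or$or), unname(coef(glm_fit)[3]), tolerance = 1e-6)
})

test_that("an intercept-only fit returns the observed cumulative logits", {
  single <- as_concordance_table(rbind(
    not_avoidable = c(both_ed = 12, discordant = 5, both_subacute = 23),
    potentially_avoidable = c(1, 1, 1), avoidable = c(1, 1, 1)))
  # with each non-referent row flat, check the threshold start logic on the
  # referent-dominated table via the closed form for one class alone:
  counts <- c(12, 5, 23)
  n <- sum(counts)
  expected <- qlogis(cumsum(counts)[1:2] / n)
  # fit a table whose three rows are identical: betas ~ 0 and thresholds at
  # the pooled cumulative logits
  flat <- as_concordance_table(rbind(
    not_avoidable = c(both_ed = 12, discordant = 5, both_subacute = 23),
    potentially_avoidable = c(12, 5, 23), avoidable = c(12, 5, 23)))
  fit <- fit_cumulative_logit(flat)
  expect_equal(unname(fit$beta), c(0, 0), tolerance = 1e-6)
  expect_equal(unname(fit$zeta), unname(expected), tolerance = 1e-6)
})

test_that("separation is flagged with a warning", {
  sep <- as_concordance_table(rbind(
    not_avoidable = c(both_ed = 10, discordant = 5, both_subacute = 5),
    potentially_avoidable = c(2, 3, 5),
    avoidable = c(0, 0, 30)))
  expect_warning(try(fit_cumulative_logit(sep, max_iter = 40), silent = TRUE),
                 class = "edacr_separation")
})

test_that("dichotomized odds ratios reproduce the published table exactly", {
  a <- reported_or(tab, "avoidable")
  expect_equal(round(a$or, 1), 80.0)
  expect_equal(round(a$ci_low, 1), 17.1)
  expect_equal(round(a$ci_high, 1), 374.9)
  p <- reported_or(tab, "potentially_avoidable")
  expect_equal(round(p$or, 1), 7.1)
  expect_equal(round(p$ci_low, 1), 3.0)
  expect_equal(round(p$ci_high, 1), 16.8)
  expect_equal(reported_or(tab, "not_avoidable")$or, 1)
})

test_that("zero cells error unless the continuity correction is requested", {
  z <- as_concordance_table(rbind(
    not_avoidable = c(both_ed = 10, discordant = 0, both_subacute = 5),
    potentially_avoidable = c(1, 1, 1),
    avoidable = c(0, 0, 12)))
  expect_error(reported_or(z, "avoidable"), class = "edacr_zero_cell")
  corrected <- reported_or(z, "avoidable", continuity = TRUE)
  expect_equal(unname(corrected$or), (12.5 * 10.5) / (0.5 * 5.5))
})

test_that("the ordinal concordance index matches the study and survival::concordance", {
  expect_equal(round(ordinal_cindex(tab), 2), 0.84)
  perfect <- as_concordance_table(rbind(
    not_avoidable = c(both_ed = 5, discordant = 0, both_subacute = 0),
    potentially_avoidable = c(0, 4, 0),
    avoidable = c(0, 0, 6)))
  expect_equal(ordinal_cindex(perfect), 1)
  expect_equal(ordinal_cindex(tab, scores = c(avoidable = 1,
                                              potentially_avoidable = 1,
                                              not_avoidable = 1)), 0.5)
  # antisymmetry under score reversal
  rev_scores <- c(not_avoidable = 2, potentially_avoidable = 1, avoidable = 0)
  expect_equal(ordinal_cindex(tab, rev_scores), 1 - ordinal_cindex(tab))
  expect_error(ordinal_cindex(as_concordance_table(rbind(
    not_avoidable = c(both_ed = 0, discordant = 0, both_subacute = 3),
    potentially_avoidable = c(0, 0, 3), avoidable = c(0, 0, 3)))),
    class = "edacr_degenerate_margin")
  skip_if_not_installed("survival")
  long <- expand_table_long(tab)
  y <- as.integer(factor(long$lvl, levels = concordance_levels()))
  s <- c(not_avoidable = 0, potentially_avoidable = 1, avoidable = 2)[long$cls]
  oracle <- survival::concordance(y ~ s)$concordance
  expect_equal(ordinal_cindex(tab), unname(oracle), tolerance = 1e-10)
})
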