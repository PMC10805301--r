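#' Observed percent agreement between the paired raters
#'
#' @param x Judgement pairs (tibble with `rating_a`, `rating_b`,
#'   `edac_class`) or a `concordance_table`.
#' @param classes Optional subset of [edac_levels()] to restrict to.
#' @return List with `proportion`, `n_agree`, `n_pairs`.
#' @export
#' @examples
#' percent_agreement(fixture_concordance())
percent_agreement <- function(x, classes = NULL) {
  cnt <- concordance_counts(x, classes)
  n <- sum(cnt)
  if (n == 0) {
    abort("No judgement pairs in the requested subset.",
          class = "edacr_empty_input")
  }
  agree <- cnt[["both_ed"]] + cnt[["both_subacute"]]
  list(proportion = agree / n, n_agree = as.integer(agree),
       n_pairs = as.integer(n))
}

# Vectorized pooled-marginal kappa from concordance counts. Returns po, p
# (pooled subacute marginal), pe, kappa, se (Fleiss-Cohen-Everitt asymptotic
# SE evaluated on the slot-symmetrized 2x2 table). kappa is NA where pe == 1.
kappa_from_counts <- function(both_subacute, discordant, both_ed) {
  n <- both_subacute + discordant + both_ed
  po <- (both_subacute + both_ed) / n
  p <- (2 * both_subacute + discordant) / (2 * n)
  pe <- p^2 + (1 - p)^2
  kap <- ifelse(pe < 1, (po - pe) / (1 - pe), NA_real_)
  # symmetrized cell probabilities (common marginal p in both slots)
  p11 <- both_subacute / n
  p00 <- both_ed / n
  pd2 <- discordant / (2 * n)
  a_term <- p11 * ((1 - pe) - 2 * p * (1 - po))^2 +
    p00 * ((1 - pe) - 2 * (1 - p) * (1 - po))^2
  b_term <- (1 - po)^2 * (2 * pd2) # off-diagonal margin sums are exactly 1
  c_term <- (po * pe - 2 * pe + po)^2
  v <- (a_term + b_term - c_term) / (n * (1 - pe)^4)
  se <- ifelse(pe < 1 & v > 0, sqrt(v), ifelse(pe < 1, 0, NA_real_))
  list(n = n, po = po, p = p, pe = pe, kappa = kap, se = se)
}

new_agreement_result <- function(k, method, conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    po = k$po, pe = k$pe, kappa = k$kappa, se = k$se,
    ci_low = max(-1, k$kappa - z * k$se), ci_high = min(1, k$kappa + z * k$se),
    n_pairs = as.integer(k$n), method = method, conf_level = conf_level
  ), class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "Chance-corrected agreement (%s, n = %d pairs)\n  po = %.4f, pe = %.4f\n  kappa = %.4f (%.0f%% CI %.4f-%.4f)\n  %s\n",
    x$method, x$n_pairs, x$po, x$pe, x$kappa, 100 * x$conf_level,
    x$ci_low, x$ci_high, kappa_interpretation(x$kappa)))
  invisible(x)
}

#' Pooled-marginal Cohen's kappa
#'
#' Chance-corrected agreement of the two anonymous rating slots. Because the
#' study randomized and anonymized which physician filled which slot, the
#' chance-agreement term uses a single marginal pooled across both slots
#' (`p = ` total subacute ratings `/ 2n`), making the estimator exactly
#' symmetric in the slot labels; on data with symmetric per-rater marginals it
#' coincides with classical two-rater Cohen's kappa. The 95% interval is the
#' asymptotic large-sample (Fleiss--Cohen--Everitt) interval; see
#' [bootstrap_ci()] for a resampling alternative.
#'
#' @inheritParams percent_agreement
#' @param conf_level Confidence level for the asymptotic interval.
#' @return An `agreement_result`: list with `po`, `pe`, `kappa`, `se`,
#'   `ci_low`, `ci_high`, `n_pairs`, `method`.
#' @export
#' @examples
#' pooled_kappa(fixture_concordance())
pooled_kappa <- function(x, classes = NULL, conf_level = 0.95) {
  cnt <- concordance_counts(x, classes)
  if (sum(cnt) == 0) {
    abort("No judgement pairs in the requested subset.",
          class = "edacr_empty_input")
  }
  k <- kappa_from_counts(cnt[["both_subacute"]], cnt[["discordant"]],
                         cnt[["both_ed"]])
  if (is.na(k$kappa)) {
    abort(paste0("Kappa is undefined: all ", 2 * k$n, " ratings are ",
                 "identical, so chance agreement is 1."),
          class = "edacr_kappa_undefined")
  }
  new_agreement_result(k, "pooled", conf_level)
}

#' @rdname pooled_kappa
#' @param class A single class label; the kappa of that class's subset.
#' @export
per_class_kappa <- function(x, class, conf_level = 0.95) {
  stopifnot(length(class) == 1)
  pooled_kappa(x, classes = class, conf_level = conf_level)
}

#' Classical two-rater Cohen's kappa from an attributed 2x2 table
#'
#' For data where each slot is a fixed rater, computes kappa with separate
#' row/column marginals. Used mainly by [kappa_attribution_range()].
#'
#' @param tab 2x2 numeric matrix of counts, rows = rater A (subacute, ed),
#'   columns = rater B (subacute, ed).
#' @return Kappa value (scalar), `NA` if chance agreement is 1.
#' @export
cohen_kappa_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Kappa under every attribution of the discordant pairs to raters
#'
#' The study's anonymized data fix how many pairs were discordant but not
#' which rater judged "subacute" in each. Enumerates all `d + 1` splits of the
#' `d` discordant pairs and returns the classical Cohen's kappa each implies,
#' quantifying how much the anonymization can matter.
#'
#' @inheritParams percent_agreement
#' @return Tibble with `n_a_subacute` (discordant pairs attributed as slot-A
#'   subacute) and `kappa`.
#' @export
kappa_attribution_range <- function(x, classes = NULL) {
  cnt <- concordance_counts(x, classes)
  d <- cnt[["discordant"]]
  ks <- vapply(0:d, function(a) {
    cohen_kappa_2x2(rbind(c(cnt[["both_subacute"]], a),
                          c(d - a, cnt[["both_ed"]])))
  }, numeric(1))
  tibble(n_a_subacute = 0:d, kappa = ks)
}

#' Landis--Koch interpretation bands for kappa
#'
#' @param kappa Numeric vector of kappa values (each <= 1).
#' @return Character vector of band labels ("poor agreement", "slight
#'   agreement", "fair agreement", "moderate agreement", "substantial
#'   agreement", "almost perfect agreement").
#' @export
#' @examples
#' kappa_interpretation(c(0.69, 0.84, 0.25))
kappa_interpretation <- function(kappa) {
  stopifnot(all(kappa <= 1 + 1e-12, na.rm = TRUE))
  cut_pts <- c(-Inf, -1e-12, 0.20, 0.40, 0.60, 0.80, 1 + 1e-12)
  labs <- c("poor agreement", "slight agreement", "fair agreement",
            "moderate agreement", "substantial agreement",
            "almost perfect agreement")
  # band edges belong to the lower band (0.60 "moderate", 0.80
  # "substantial"), except 0, which opens the slight band
  as.character(cut(kappa, breaks = cut_pts, labels = labs, right = TRUE,
                   include.lowest = TRUE))
}

#' Mean and SD of rater confidence scores
#'
#' Confidence (1 = not confident .. 5 = very confident) is pooled over both
#' rating slots; the SD uses the sample (n - 1) denominator.
#'
#' @param pairs Judgement pairs with `confidence_a`, `confidence_b` (and
#'   `edac_class` when `by_class`).
#' @param by_class Also summarise per avoidability class?
#' @return Tibble with `class` (`"all"` plus the classes when requested),
#'   `mean`, `sd`, `n_scores`.
#' @export
confidence_summary <- function(pairs, by_class = FALSE) {
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0) {
    abort("No judgement pairs supplied.", class = "edacr_empty_input")
  }
  stopifnot(all(c("confidence_a", "confidence_b") %in% names(pairs)))
  pool <- function(df) {
    v <- c(df$confidence_a, df$confidence_b)
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      abort("All confidence scores are missing.", class = "edacr_empty_input")
    }
    stopifnot(all(v %in% 1:5))
    tibble(mean = mean(v), sd = sd(v), n_scores = length(v))
  }
  out <- cbind(tibble(class = "all"), pool(pairs))
  if (by_class) {
    cls <- edac_factor(pairs$edac_class)
    per <- lapply(edac_levels(), function(cl) {
      sub <- pairs[cls == cl, , drop = FALSE]
      if (nrow(sub) == 0) return(NULL)
      cbind(tibble(class = cl), pool(sub))
    })
    out <- bind_rows(c(list(out), per))
  }
  as_tibble(out)
}

#' Percentile bootstrap interval for an agreement statistic
#'
#' Resamples visits (pairs) with replacement. Replicates on which the
#' statistic is undefined (e.g. kappa when a resample has identical ratings
#' throughout) are dropped and counted.
#'
#' @param pairs Judgement pairs tibble.
#' @param statistic `"kappa"`, `"percent_agreement"`, or a function of a
#'   pairs tibble returning a scalar.
#' @param reps Number of bootstrap replicates (>= 200).
#' @param seed Integer seed for reproducibility.
#' @param conf_level Interval level.
#' @return List with `ci_low`, `ci_high`, `point`, `reps_used`, `n_dropped`.
#' @export
bootstrap_ci <- function(pairs, statistic = "kappa", reps = 1000, seed = NULL,
                         conf_level = 0.95) {
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0) {
    abort("No judgement pairs supplied.", class = "edacr_empty_input")
  }
  if (reps < 200) {
    abort("`reps` must be at least 200.", class = "edacr_invalid_spec")
  }
  stat_fun <- if (is.function(statistic)) {
    statistic
  } else {
    switch(match.arg(statistic, c("kappa", "percent_agreement")),
           kappa = function(p) pooled_kappa(p)$kappa,
           percent_agreement = function(p) percent_agreement(p)$proportion)
  }
  point <- stat_fun(pairs)
  vals <- with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      idx <- sample.int(nrow(pairs), replace = TRUE)
      tryCatch(stat_fun(pairs[idx, , drop = FALSE]),
               edacr_kappa_undefined = function(e) NA_real_)
    }, numeric(1))
  })
  dropped <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  if (dropped > 0) {
    message(dropped, " bootstrap replicate(s) dropped (statistic undefined).")
  }
  alpha <- 1 - conf_level
  qs <- quantile(vals, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
  list(ci_low = qs[1], ci_high = qs[2], point = point,
       reps_used = length(vals), n_dropped = dropped)
}
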