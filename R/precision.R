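precision_scenarios <- function() {
  c("exclude_potential", "potential_as_avoidable", "potential_as_not_avoidable")
}

#' Rating-level 2x2 table under a middle-class regrouping scenario
#'
#' The precision analyses score every individual judgement (two per visit,
#' 320 for the 160-visit study) against the classifier's grouping: each pair
#' contributes two rating rows (a both-subacute pair two "subacute" ratings, a
#' discordant pair one of each, and so on). The potentially-avoidable class is
#' excluded, merged into the avoidable (positive) group, or merged into the
#' not-avoidable (negative) group according to `scenario`.
#'
#' @param x Judgement pairs or a `concordance_table`.
#' @param scenario One of `"exclude_potential"`, `"potential_as_avoidable"`,
#'   `"potential_as_not_avoidable"`.
#' @return A `rating_table`: 2x2 matrix, rows `positive`/`negative`
#'   (classifier group), columns `subacute`/`ed` (judgement), with the
#'   scenario and total rating count attached.
#' @export
#' @examples
#' rating_table(fixture_concordance(), "exclude_potential")
rating_table <- function(x, scenario = precision_scenarios()) {
  scenario <- match.arg(scenario)
  tab <- if (inherits(x, "concordance_table")) x else concordance_table(x)
  m <- unclass(tab)
  sub_ratings <- 2 * m[, "both_subacute"] + m[, "discordant"]
  ed_ratings <- 2 * m[, "both_ed"] + m[, "discordant"]
  pos_classes <- switch(scenario,
    exclude_potential = "avoidable",
    potential_as_avoidable = c("avoidable", "potentially_avoidable"),
    potential_as_not_avoidable = "avoidable")
  neg_classes <- switch(scenario,
    exclude_potential = "not_avoidable",
    potential_as_avoidable = "not_avoidable",
    potential_as_not_avoidable = c("not_avoidable", "potentially_avoidable"))
  out <- rbind(
    positive = c(subacute = sum(sub_ratings[pos_classes]),
                 ed = sum(ed_ratings[pos_classes])),
    negative = c(subacute = sum(sub_ratings[neg_classes]),
                 ed = sum(ed_ratings[neg_classes])))
  if (sum(out) == 0) {
    abort("No ratings remain after applying the scenario.",
          class = "edacr_empty_input")
  }
  structure(out, scenario = scenario, n_ratings = sum(out),
            class = c("rating_table", "matrix", "array"))
}

#' @export
print.rating_table <- function(x, ...) {
  cat("Rating-level table (scenario: ", attr(x, "scenario"), ", ",
      attr(x, "n_ratings"), " ratings)\n", sep = "")
  print(unclass(x))
  invisible(x)
}

cp_interval <- function(successes, total, conf_level = 0.95) {
  ci <- binom.test(successes, total, conf.level = conf_level)$conf.int
  c(ci[1], ci[2])
}

#' Accuracy, sensitivity and specificity of the classifier vs judgements
#'
#' Proportions are at the rating level with exact (Clopper--Pearson) 95%
#' intervals. The primary orientation matches the validation study's
#' convention, recovered from its printed tables: accuracy counts a rating as
#' correct when a positive-group visit was judged subacute-suitable or a
#' negative-group visit was judged ED-appropriate; "sensitivity" conditions on
#' the negative group (fraction judged ED-appropriate) and "specificity" on
#' the positive group (fraction judged subacute-suitable). Because that
#' labeling is the reverse of the textbook one (which would condition
#' sensitivity on the positive group), both orientations are returned,
#' explicitly labeled.
#'
#' @param table A `rating_table`.
#' @param conf_level Interval level for the exact binomial CIs.
#' @return A `precision_result`: list with `scenario`, `primary` and
#'   `alternate` tibbles (`statistic`, `estimate`, `ci_low`, `ci_high`,
#'   `numerator`, `denominator`), and `n_ratings`.
#' @export
precision_stats <- function(table, conf_level = 0.95) {
  stopifnot(inherits(table, "rating_table"))
  m <- unclass(table)
  pos_tot <- sum(m["positive", ])
  neg_tot <- sum(m["negative", ])
  tot <- pos_tot + neg_tot
  if (pos_tot == 0 || neg_tot == 0) {
    abort(paste0("Zero denominator for ",
                 if (pos_tot == 0) "specificity (no positive-group ratings)"
                 else "sensitivity (no negative-group ratings)", "."),
          class = "edacr_zero_denominator")
  }
  row_of <- function(stat, num, den) {
    ci <- cp_interval(num, den, conf_level)
    tibble(statistic = stat, estimate = num / den,
           ci_low = ci[1], ci_high = ci[2],
           numerator = as.integer(num), denominator = as.integer(den))
  }
  correct <- m["positive", "subacute"] + m["negative", "ed"]
  primary <- bind_rows(
    row_of("accuracy", correct, tot),
    row_of("sensitivity", m["negative", "ed"], neg_tot),
    row_of("specificity", m["positive", "subacute"], pos_tot))
  alternate <- bind_rows(
    row_of("accuracy", correct, tot),
    row_of("sensitivity", m["positive", "subacute"], pos_tot),
    row_of("specificity", m["negative", "ed"], neg_tot))
  structure(list(scenario = attr(table, "scenario"), primary = primary,
                 alternate = alternate, n_ratings = tot),
            class = "precision_result")
}

#' @export
print.precision_result <- function(x, ...) {
  cat("Precision (scenario: ", x$scenario, ", ", x$n_ratings,
      " ratings; primary orientation)\n", sep = "")
  print(x$primary)
  invisible(x)
}

#' Compare precision across the three middle-class scenarios
#'
#' Runs [precision_stats()] under all three regroupings and reports each
#' statistic's change, in percentage points, relative to the
#' exclude-the-middle-class baseline.
#'
#' @inheritParams rating_table
#' @param conf_level Interval level.
#' @return List with `results` (tibble: scenario x statistic, primary
#'   orientation) and `deltas` (tibble of percentage-point changes vs the
#'   `exclude_potential` baseline).
#' @export
#' @examples
#' scenario_compare(fixture_concordance())$deltas
scenario_compare <- function(x, conf_level = 0.95) {
  tab <- if (inherits(x, "concordance_table")) x else concordance_table(x)
  res <- lapply(precision_scenarios(), function(sc) {
    pr <- precision_stats(rating_table(tab, sc), conf_level)
    mutate(pr$primary, scenario = sc, .before = 1)
  })
  results <- bind_rows(res)
  base <- results[results$scenario == "exclude_potential", ]
  deltas <- bind_rows(lapply(precision_scenarios()[-1], function(sc) {
    cur <- results[results$scenario == sc, ]
    tibble(scenario = sc, statistic = cur$statistic,
           delta_points = 100 * (cur$estimate - base$estimate))
  }))
  list(results = results, deltas = deltas)
}
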