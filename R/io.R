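canonical_names <- function(x) {
  x <- tolower(trimws(x))
  gsub("[^a-z0-9]+", "_", x)
}

#' Read and write visit tables
#'
#' Comma-separated, UTF-8, header required. Header names are canonicalized
#' (case, surrounding whitespace and punctuation are ignored). Booleans are
#' accepted as true/false (also t/f, yes/no, 1/0) and written as true/false.
#' All validation problems are collected and reported together with row
#' numbers.
#'
#' @param path File path.
#' @return `read_visits()`: a validated tibble of visit records.
#' @export
read_visits <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(df) <- canonical_names(names(df))
  df <- validate_visits(df, where = "data")
  if (anyDuplicated(df$visit_id)) {
    abort(paste0("Duplicate visit_id(s): ",
                 paste(unique(df$visit_id[duplicated(df$visit_id)]),
                       collapse = ", ")),
          class = "edacr_duplicate_visit")
  }
  df$visit_id <- as.character(df$visit_id)
  if ("edac_class" %in% names(df)) df$edac_class <- edac_factor(df$edac_class)
  df
}

#' @rdname read_visits
#' @param visits Tibble of visit records.
#' @export
write_visits <- function(visits, path) {
  visits <- as_tibble(visits)
  out <- mutate(visits, dplyr::across(dplyr::where(is.logical),
                                      ~ ifelse(.x, "true", "false")))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write judgement tables
#'
#' The on-disk judgement format is rating-level: one row per rating with
#' columns `rater_id`, `visit_id`, `judgement` (`subacute` or `ed`) and
#' `confidence` (1--5). Reading pairs the two ratings of each visit (slots
#' ordered by rater id for determinism) and fails, naming the visits, if any
#' visit has other than exactly two ratings.
#'
#' @param path File path.
#' @param visits Optional classified visit tibble (with `edac_class`); when
#'   given, the class is joined onto the pairs.
#' @return `read_judgements()`: tibble of pairs with `visit_id`, `rater_a`,
#'   `rater_b`, `rating_a`, `rating_b`, `confidence_a`, `confidence_b` (and
#'   `edac_class` when `visits` is supplied).
#' @export
read_judgements <- function(path, visits = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(df) <- canonical_names(names(df))
  need <- c("rater_id", "visit_id", "judgement", "confidence")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing judgement column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "edacr_invalid_judgement")
  }
  j <- tolower(trimws(as.character(df$judgement)))
  bad <- which(!(j %in% c("subacute", "ed")))
  if (length(bad) > 0) {
    abort(paste0("`judgement` must be subacute or ed (rows ",
                 paste(head(bad, 10), collapse = ", "), ")."),
          class = "edacr_invalid_judgement")
  }
  conf <- df$confidence
  bad_conf <- which(!is.na(conf) & !(conf %in% 1:5))
  if (length(bad_conf) > 0) {
    abort(paste0("`confidence` must be in 1..5 (rows ",
                 paste(head(bad_conf, 10), collapse = ", "), ")."),
          class = "edacr_invalid_judgement")
  }
  df$visit_id <- as.character(df$visit_id)
  counts <- table(df$visit_id)
  off <- names(counts)[counts != 2]
  if (length(off) > 0) {
    abort(paste0("Each visit needs exactly two ratings; offending visit(s): ",
                 paste0(head(off, 10), " (", counts[head(off, 10)], ")",
                        collapse = ", "), "."),
          class = "edacr_pairing_error")
  }
  df <- arrange(df, .data$visit_id, .data$rater_id)
  a <- df[seq(1, nrow(df), by = 2), ]
  b <- df[seq(2, nrow(df), by = 2), ]
  if (any(a$rater_id == b$rater_id)) {
    abort(paste0("Visit(s) rated twice by the same rater: ",
                 paste(head(a$visit_id[a$rater_id == b$rater_id], 10),
                       collapse = ", ")),
          class = "edacr_pairing_error")
  }
  pairs <- tibble(
    visit_id = a$visit_id,
    rater_a = as.character(a$rater_id), rater_b = as.character(b$rater_id),
    rating_a = tolower(trimws(a$judgement)) == "subacute",
    rating_b = tolower(trimws(b$judgement)) == "subacute",
    confidence_a = as.integer(a$confidence),
    confidence_b = as.integer(b$confidence))
  if (!is.null(visits)) {
    visits <- as_tibble(visits)
    stopifnot(all(c("visit_id", "edac_class") %in% names(visits)))
    pairs <- left_join(pairs,
                       select(mutate(visits,
                                     visit_id = as.character(.data$visit_id)),
                              "visit_id", "edac_class"),
                       by = "visit_id")
    if (anyNA(pairs$edac_class)) {
      abort("Some judged visits are absent from the visit table.",
            class = "edacr_pairing_error")
    }
  }
  pairs
}

#' @rdname read_judgements
#' @param pairs Tibble of judgement pairs (as produced by
#'   [generate_judgements()] or [read_judgements()]). Rater ids default to
#'   `"A"`/`"B"` when absent.
#' @export
write_judgements <- function(pairs, path) {
  pairs <- as_tibble(pairs)
  long <- bind_rows(
    tibble(rater_id = if ("rater_a" %in% names(pairs)) pairs$rater_a else "A",
           visit_id = pairs$visit_id,
           judgement = ifelse(pairs$rating_a, "subacute", "ed"),
           confidence = pairs$confidence_a),
    tibble(rater_id = if ("rater_b" %in% names(pairs)) pairs$rater_b else "B",
           visit_id = pairs$visit_id,
           judgement = ifelse(pairs$rating_b, "subacute", "ed"),
           confidence = pairs$confidence_b))
  long <- arrange(long, .data$visit_id, .data$rater_id)
  readr::write_csv(long, path, progress = FALSE)
  invisible(path)
}

#' Run the complete validity analysis
#'
#' Reproduces the study's analytic sequence on a set of dual-rated classified
#' visits: cohort descriptives, the agreement block (percent agreement,
#' pooled-marginal kappa with interpretation, overall, for the
#' avoidable-and-not-avoidable subset and per class, plus confidence
#' summaries when scores are present), the association block (tie-corrected
#' Spearman, proportional-odds fit, dichotomized odds ratios, concordance
#' index) and the precision block (all three middle-class scenarios, both
#' orientation labelings). Any stage failure aborts with the stage name;
#' completed blocks are attached to the error condition.
#'
#' @param pairs Judgement pairs with `edac_class` (e.g. from
#'   [read_judgements()] with `visits`, or [generate_judgements()]).
#'   Alternatively supply `table`.
#' @param table A `concordance_table` (used when `pairs` is `NULL`;
#'   confidence summaries are then unavailable).
#' @param seed Integer recorded in the provenance block (the analysis itself
#'   is deterministic; the seed documents upstream generation).
#' @return An `edac_study_report` list with elements `meta`, `descriptives`,
#'   `agreement`, `association`, `precision`.
#' @export
#' @examples
#' rep <- run_full_study(table = fixture_concordance())
#' rep$agreement$overall$kappa
run_full_study <- function(pairs = NULL, table = NULL, seed = NULL) {
  if (is.null(pairs) && is.null(table)) {
    abort("Supply `pairs` or `table`.", class = "edacr_invalid_config")
  }
  done <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Stage `", name, "` failed: ", conditionMessage(e)),
            class = "edacr_stage_error", partial = done, parent = e)
    })
  }
  tab <- stage("tabulate", {
    if (is.null(table)) concordance_table(pairs) else table
  })
  done$descriptives <- stage("descriptives", {
    m <- unclass(tab)
    list(n_visits = sum(m), n_ratings = 2 * sum(m),
         per_class = rowSums(m)[rev(edac_levels())],
         concordance = m)
  })
  done$agreement <- stage("agreement", {
    blocks <- list(
      overall = pooled_kappa(tab),
      avoidable_and_not = pooled_kappa(
        tab, classes = c("avoidable", "not_avoidable")),
      avoidable = per_class_kappa(tab, "avoidable"),
      potentially_avoidable = per_class_kappa(tab, "potentially_avoidable"),
      not_avoidable = per_class_kappa(tab, "not_avoidable"))
    out <- lapply(blocks, function(b) {
      list(n_pairs = b$n_pairs, po = b$po, kappa = b$kappa,
           ci_low = b$ci_low, ci_high = b$ci_high,
           interpretation = kappa_interpretation(b$kappa))
    })
    out$percent_agreement <- percent_agreement(tab)
    if (!is.null(pairs) && !all(is.na(pairs$confidence_a))) {
      out$confidence <- confidence_summary(pairs, by_class = TRUE)
    }
    out
  })
  done$association <- stage("association", {
    fit <- fit_cumulative_logit(tab)
    list(
      spearman = spearman_ordinal(tab),
      ordinal_fit = list(zeta = fit$zeta, beta = fit$beta, or = fit$or,
                         loglik = fit$loglik, iterations = fit$iterations),
      reported_or = lapply(
        setNames(c("avoidable", "potentially_avoidable"),
                 c("avoidable", "potentially_avoidable")),
        function(cl) reported_or(tab, cl)[c("or", "ci_low", "ci_high",
                                            "p_value")]),
      cindex = ordinal_cindex(tab))
  })
  done$precision <- stage("precision", {
    comp <- scenario_compare(tab)
    alt <- lapply(setNames(precision_scenarios(), precision_scenarios()),
                  function(sc) precision_stats(rating_table(tab, sc))$alternate)
    list(results = comp$results, deltas = comp$deltas, alternate = alt)
  })
  meta <- list(package = "edacr",
               version = as.character(utils::packageVersion("edacr")),
               seed = seed,
               input_hash = hash(unclass(tab)),
               timestamp = format(Sys.time(), tz = "UTC"))
  structure(c(list(meta = meta), done), class = "edac_study_report")
}

#' @export
print.edac_study_report <- function(x, ...) {
  cat("Avoidability validity study report\n")
  cat(sprintf("  %d visits (%d ratings); per class: %s\n",
              x$descriptives$n_visits, x$descriptives$n_ratings,
              paste(names(x$descriptives$per_class),
                    x$descriptives$per_class, sep = "=", collapse = ", ")))
  ov <- x$agreement$overall
  cat(sprintf("  agreement: %.1f%%; kappa %.2f (%.2f-%.2f), %s\n",
              100 * x$agreement$percent_agreement$proportion, ov$kappa,
              ov$ci_low, ov$ci_high, ov$interpretation))
  cat(sprintf("  association: Spearman %.2f; OR(avoidable) %.1f; C %.2f\n",
              x$association$spearman, x$association$reported_or$avoidable$or,
              x$association$cindex))
  acc <- x$precision$results
  cat(sprintf("  precision (middle class excluded): accuracy %.1f%%\n",
              100 * acc$estimate[acc$scenario == "exclude_potential" &
                                   acc$statistic == "accuracy"]))
  invisible(x)
}

#' Write a study report to disk
#'
#' @param report An `edac_study_report`.
#' @param path Output file.
#' @param format `"json"` (structured, schema version 1) or `"markdown"`
#'   (human-readable summary tables).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "markdown")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "edac_study_report"))
  if (format == "json") {
    payload <- c(list(schema = "edacr-report/1"), unclass(report))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 10,
                         na = "null", force = TRUE)
  } else {
    lines <- c(
      "# Avoidability validity study report", "",
      sprintf("- Visits: %d (%d ratings)", report$descriptives$n_visits,
              report$descriptives$n_ratings),
      sprintf("- Percent agreement: %.1f%%",
              100 * report$agreement$percent_agreement$proportion),
      sprintf("- Pooled kappa: %.2f (%s)", report$agreement$overall$kappa,
              report$agreement$overall$interpretation),
      sprintf("- Spearman: %.2f | OR avoidable: %.1f | C: %.2f",
              report$association$spearman,
              report$association$reported_or$avoidable$or,
              report$association$cindex))
    writeLines(lines, path)
  }
  invisible(path)
}
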