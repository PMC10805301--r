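#' Intervention-code registries
#'
#' The avoidability rule's fourth criterion asks whether the main physician
#' intervention recorded for the visit is one that subacute primary care could
#' deliver. The reference list of such CCI (Canadian Classification of Health
#' Interventions) codes is site configuration, not code: supply it as a
#' character vector or a one-code-per-line text file. Codes are canonicalized
#' (trimmed, upper-cased) before any membership test.
#'
#' @param codes Character vector of intervention codes.
#' @return A `code_registry`: canonicalized, de-duplicated character vector.
#' @export
#' @examples
#' reg <- code_registry(c(" 1.an.09 ", "2.GY.70"))
#' reg
code_registry <- function(codes) {
  if (length(codes) == 0) {
    abort("A code registry must contain at least one code.",
          class = "edacr_empty_registry")
  }
  codes <- canonicalize_code(as.character(codes))
  codes <- unique(codes[nzchar(codes)])
  if (length(codes) == 0) {
    abort("A code registry must contain at least one non-blank code.",
          class = "edacr_empty_registry")
  }
  structure(codes, class = c("code_registry", "character"))
}

canonicalize_code <- function(x) toupper(trimws(x))

#' @rdname code_registry
#' @param path Path to a plain-text file, one code per line; blank lines and
#'   lines starting with `#` are ignored.
#' @export
read_code_registry <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  code_registry(lines)
}

#' Synthetic default intervention-code registry
#'
#' The consensus list of subacute-manageable intervention codes used by the
#' original validation study is not public. This registry is a clearly
#' synthetic stand-in (CCI-style strings) so that examples, tests and the
#' cohort generator run self-contained; real analyses should load the local
#' site list with [read_code_registry()].
#'
#' @return A [code_registry()].
#' @export
default_registry <- function() {
  code_registry(c(
    "1.AN.09", "1.SZ.35", "2.GY.70", "2.OD.71", "3.IP.10",
    "1.YV.55", "2.ZZ.02", "1.WL.03", "3.AN.40", "1.JE.50",
    "2.HZ.13", "1.OT.52"
  ))
}

required_visit_fields <- function() {
  c("visit_id", "age", "ctas", "specialist_consult", "main_intervention",
    "outcome")
}

outcome_levels <- function() c("discharged", "admission", "other")

# Validate the five criterion fields of one or more visits; `where` labels the
# offending rows in messages. Mirrors the study's chart-exclusion rule: a
# visit missing any required variable is an error, never silently classified.
validate_visits <- function(visits, where = "visit") {
  visits <- as_tibble(visits)
  missing_cols <- setdiff(required_visit_fields(), names(visits))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required visit field(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "edacr_invalid_visit")
  }
  problems <- character()
  bad <- function(field, rows, why) {
    if (length(rows) > 0) {
      problems <<- c(problems, paste0(
        "field `", field, "` ", why, " (", where, " row",
        if (length(rows) > 1) "s" else "", " ",
        paste(head(rows, 10), collapse = ", "),
        if (length(rows) > 10) ", ..." else "", ")"))
    }
  }
  age <- visits$age
  bad("age", which(is.na(age)), "is missing")
  bad("age", which(!is.na(age) & (age < 0 | age != floor(age))),
      "must be a non-negative integer")
  ctas <- visits$ctas
  bad("ctas", which(is.na(ctas)), "is missing")
  bad("ctas", which(!is.na(ctas) & !(ctas %in% 1:5)), "must be in 1..5")
  sc <- visits$specialist_consult
  if (!is.logical(sc)) {
    sc <- parse_boolean(sc)
    visits$specialist_consult <- sc
  }
  bad("specialist_consult", which(is.na(sc)), "is missing or not true/false")
  mi <- visits$main_intervention
  bad("main_intervention", which(is.na(mi) | !nzchar(trimws(as.character(mi)))),
      "is missing")
  oc <- as.character(visits$outcome)
  bad("outcome", which(is.na(oc) | !(oc %in% outcome_levels())),
      paste0("must be one of ", paste(outcome_levels(), collapse = "/")))
  if (length(problems) > 0) {
    abort(paste0("Invalid visit record(s):\n  - ",
                 paste(problems, collapse = "\n  - ")),
          class = "edacr_invalid_visit")
  }
  visits$outcome <- oc
  visits
}

parse_boolean <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "yes", "1")] <- TRUE
  out[x %in% c("false", "f", "no", "0")] <- FALSE
  out
}

# vectorized rule core; inputs assumed validated
edac_rule <- function(age, ctas, specialist_consult, main_intervention,
                      outcome, registry) {
  code_ok <- canonicalize_code(main_intervention) %in% registry
  base <- age >= 18 & age <= 70 & !specialist_consult & code_ok &
    outcome == "discharged"
  cls <- rep("not_avoidable", length(age))
  cls[base & ctas %in% c(4, 5)] <- "avoidable"
  cls[base & ctas == 3] <- "potentially_avoidable"
  edac_factor(cls)
}

#' Classify a single ED visit
#'
#' Applies the avoidability decision table. A visit is `avoidable` when all
#' five criteria hold: age 18--70 (inclusive), triage acuity CTAS 4 or 5, no
#' specialist consultation in the ED, main physician intervention on the
#' subacute-manageable registry, and discharge from the ED.
#' `potentially_avoidable` is the same conjunction with CTAS 3. Every other
#' visit is `not_avoidable`.
#'
#' @param visit A named list or one-row data frame with at least the fields
#'   `visit_id`, `age`, `ctas`, `specialist_consult`, `main_intervention`,
#'   `outcome` (`discharged`/`admission`/`other`).
#' @param registry A [code_registry()].
#' @return A single value of the ordered avoidability factor.
#' @export
#' @examples
#' reg <- default_registry()
#' classify_visit(list(visit_id = "v1", age = 25, ctas = 5,
#'                     specialist_consult = FALSE,
#'                     main_intervention = "1.AN.09",
#'                     outcome = "discharged"), reg)
classify_visit <- function(visit, registry) {
  stopifnot(inherits(registry, "code_registry"))
  visit <- as_tibble(as.list(visit)[required_visit_fields()[
    required_visit_fields() %in% names(visit)]])
  visit <- validate_visits(visit)
  edac_rule(visit$age, visit$ctas, visit$specialist_consult,
            visit$main_intervention, visit$outcome, registry)
}

#' Classify a cohort of ED visits
#'
#' @param visits Data frame of visit records (see [classify_visit()] for the
#'   required fields); `visit_id` must be unique.
#' @param registry A [code_registry()].
#' @return A list with `classes`, a tibble of `visit_id` and `edac_class`
#'   (ordered factor), and `tally`, a named integer vector of per-class counts
#'   in `avoidable`, `potentially_avoidable`, `not_avoidable` order.
#' @export
classify_cohort <- function(visits, registry) {
  stopifnot(inherits(registry, "code_registry"))
  visits <- as_tibble(visits)
  if (nrow(visits) == 0) {
    empty <- tibble(visit_id = character(), edac_class = edac_factor(character()))
    return(list(classes = empty,
                tally = setNames(integer(3), rev(edac_levels()))))
  }
  visits <- validate_visits(visits)
  ids <- as.character(visits$visit_id)
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate visit_id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "edacr_duplicate_visit")
  }
  cls <- edac_rule(visits$age, visits$ctas, visits$specialist_consult,
                   visits$main_intervention, visits$outcome, registry)
  tal <- table(factor(cls, levels = rev(edac_levels())))
  list(classes = tibble(visit_id = ids, edac_class = cls),
       tally = setNames(as.integer(tal), names(tal)))
}
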