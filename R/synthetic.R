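#' Default per-class attribute marginals for the cohort generator
#'
#' Frequencies of the descriptive characteristics of the 160-visit validation
#' cohort, per avoidability class: sex, age band, mode of arrival, triage
#' acuity, day of week, time-in-ED band, most responsible provider and visit
#' outcome. These counts are the generator's default sampling weights;
#' attributes are drawn independently within class (the published cohort
#' gives marginals only), except where the class definition constrains them
#' (triage, consult, intervention code, outcome, and the 18--70 age range of
#' the avoidable/potentially-avoidable classes).
#'
#' @return Named list of per-class lists of named count vectors.
#' @export
default_marginals <- function() {
  list(
    avoidable = list(
      sex = c(male = 26, female = 28),
      age_band = c(`18-40` = 31, `41-60` = 18, `61-105` = 5),
      arrival_mode = c(`walk-in` = 47, ambulance = 7),
      ctas = c(`4` = 38, `5` = 16),
      day_of_week = c(monday = 7, tuesday = 6, wednesday = 11, thursday = 8,
                      friday = 5, saturday = 9, sunday = 8),
      ed_band = c(`under_30` = 0, `31-60` = 2, `61-120` = 8, `121-180` = 16,
                  `181-240` = 11, `over_241` = 15),
      provider_service = c(emergency_medicine = 54),
      outcome = c(discharged = 54)
    ),
    potentially_avoidable = list(
      sex = c(male = 25, female = 28),
      age_band = c(`18-40` = 31, `41-60` = 22, `61-105` = 0),
      arrival_mode = c(`walk-in` = 36, ambulance = 17),
      ctas = c(`3` = 53),
      day_of_week = c(monday = 7, tuesday = 9, wednesday = 6, thursday = 6,
                      friday = 7, saturday = 6, sunday = 12),
      ed_band = c(`under_30` = 1, `31-60` = 3, `61-120` = 8, `121-180` = 10,
                  `181-240` = 6, `over_241` = 24),
      provider_service = c(emergency_medicine = 53),
      outcome = c(discharged = 53)
    ),
    not_avoidable = list(
      sex = c(male = 26, female = 27),
      age_band = c(`18-40` = 15, `41-60` = 5, `61-105` = 33),
      arrival_mode = c(`walk-in` = 26, ambulance = 27),
      ctas = c(`1` = 2, `2` = 23, `3` = 24, `4` = 3, `5` = 1),
      day_of_week = c(monday = 11, tuesday = 8, wednesday = 11, thursday = 6,
                      friday = 6, saturday = 5, sunday = 6),
      ed_band = c(`under_30` = 0, `31-60` = 0, `61-120` = 2, `121-180` = 3,
                  `181-240` = 1, `over_241` = 47),
      provider_service = c(emergency_medicine = 22, psychiatry = 10,
                           internal_medicine = 9, nephrology = 2,
                           cardiology = 2, general_surgery = 3, other = 5),
      outcome = c(discharged = 20, admission = 27, other = 6)
    )
  )
}

ed_band_bounds <- function() {
  list(`under_30` = c(5, 30), `31-60` = c(31, 60), `61-120` = c(61, 120),
       `121-180` = c(121, 180), `181-240` = c(181, 240),
       `over_241` = c(241, 1440))
}

sample_weighted <- function(n, weights) {
  weights <- weights[weights > 0]
  if (length(weights) == 1) return(rep(names(weights), n))
  sample(names(weights), n, replace = TRUE, prob = weights)
}

validate_marginals <- function(marginals) {
  for (cl in edac_levels()) {
    m <- marginals[[cl]]
    if (is.null(m)) {
      abort(paste0("Marginals missing for class ", cl, "."),
            class = "edacr_invalid_config")
    }
    for (attr_name in names(m)) {
      w <- m[[attr_name]]
      if (any(w < 0) || sum(w) <= 0) {
        abort(paste0("Marginal `", attr_name, "` for class ", cl,
                     " must be non-negative with positive total."),
              class = "edacr_invalid_config")
      }
    }
    if (cl != "not_avoidable") {
      allowed_ctas <- if (cl == "avoidable") c("4", "5") else "3"
      if (any(m$ctas[setdiff(names(m$ctas), allowed_ctas)] > 0)) {
        abort(paste0("Class ", cl, " admits CTAS ",
                     paste(allowed_ctas, collapse = "/"),
                     " only; the supplied marginal puts mass elsewhere."),
              class = "edacr_invalid_config")
      }
      if (any(m$outcome[setdiff(names(m$outcome), "discharged")] > 0)) {
        abort(paste0("Class ", cl, " visits must be discharged."),
              class = "edacr_invalid_config")
      }
    }
  }
  invisible(marginals)
}

#' Generate a synthetic classified ED-visit cohort
#'
#' Draws visits class by class from the per-class attribute marginals
#' (defaults: the validation cohort's descriptive frequencies, see
#' [default_marginals()]), then enforces class consistency: avoidable and
#' potentially-avoidable visits get ages truncated to 18--70, no specialist
#' consult, a registry intervention code and discharge; not-avoidable visits
#' that would satisfy the avoidable conjunction are repaired by assigning an
#' off-registry intervention code. Every generated visit therefore classifies
#' to its intended class, which the generator asserts on each run.
#'
#' @param n_per_class Named integer vector of visits per class (names in
#'   [edac_levels()]); default 54/53/53 in avoidable/potentially/not order.
#' @param marginals Per-class attribute marginals, as [default_marginals()].
#' @param registry A [code_registry()] of subacute-manageable codes.
#' @param p_consult_not_avoidable Probability a not-avoidable visit records a
#'   specialist consult (the published cohort does not report this marginal).
#' @param seed Integer seed.
#' @return Tibble of visit records with the five criterion fields, the
#'   descriptor fields, and the intended `edac_class`.
#' @export
#' @examples
#' v <- generate_visits(seed = 7)
#' table(v$edac_class)
generate_visits <- function(n_per_class = c(avoidable = 54,
                                            potentially_avoidable = 53,
                                            not_avoidable = 53),
                            marginals = default_marginals(),
                            registry = default_registry(),
                            p_consult_not_avoidable = 0.5,
                            seed = NULL) {
  stopifnot(all(names(n_per_class) %in% edac_levels()),
            all(n_per_class >= 0))
  validate_marginals(marginals)
  stopifnot(inherits(registry, "code_registry"))
  off_registry <- "9.ZZ.99" # sentinel outside any canonical registry
  stopifnot(!(off_registry %in% registry))
  bounds <- ed_band_bounds()
  with_seed(seed, {
    out <- lapply(edac_levels(), function(cl) {
      k <- if (cl %in% names(n_per_class)) n_per_class[[cl]] else 0L
      if (k == 0) return(NULL)
      m <- marginals[[cl]]
      band <- sample_weighted(k, m$age_band)
      age_lo <- c(`18-40` = 18, `41-60` = 41, `61-105` = 61)[band]
      age_hi <- c(`18-40` = 40, `41-60` = 60, `61-105` = 105)[band]
      if (cl != "not_avoidable") age_hi <- pmin(age_hi, 70)
      age <- age_lo + floor(runif(k) * (age_hi - age_lo + 1))
      ctas <- as.integer(sample_weighted(k, m$ctas))
      ed_band <- sample_weighted(k, m$ed_band)
      lo <- vapply(bounds[ed_band], `[`, numeric(1), 1)
      hi <- vapply(bounds[ed_band], `[`, numeric(1), 2)
      ed_minutes <- round(lo + runif(k) * (hi - lo))
      if (cl == "not_avoidable") {
        consult <- runif(k) < p_consult_not_avoidable
        code <- ifelse(runif(k) < 0.5, sample(registry, k, replace = TRUE),
                       off_registry)
        outcome <- sample_weighted(k, m$outcome)
        # repair: any draw that satisfies the avoidable/potentially
        # conjunction is forced off-registry, which breaks the conjunction
        violates <- age >= 18 & age <= 70 & ctas %in% 3:5 & !consult &
          code %in% registry & outcome == "discharged"
        code[violates] <- off_registry
      } else {
        consult <- rep(FALSE, k)
        code <- sample(registry, k, replace = TRUE)
        outcome <- rep("discharged", k)
      }
      tibble(
        edac_class = cl, age = as.integer(age), ctas = ctas,
        specialist_consult = consult, main_intervention = code,
        outcome = outcome, sex = sample_weighted(k, m$sex),
        arrival_mode = sample_weighted(k, m$arrival_mode),
        day_of_week = sample_weighted(k, m$day_of_week),
        ed_minutes = ed_minutes,
        provider_service = sample_weighted(k, m$provider_service))
    })
    visits <- bind_rows(out)
    visits <- mutate(visits,
                     visit_id = sprintf("SV%04d", seq_len(nrow(visits))),
                     edac_class = edac_factor(.data$edac_class),
                     .before = 1)
    got <- edac_rule(visits$age, visits$ctas, visits$specialist_consult,
                     visits$main_intervention, visits$outcome, registry)
    if (!all(got == visits$edac_class)) {
      abort("Internal error: a generated visit does not classify to its intended class.",
            class = "edacr_generator_inconsistent")
    }
    visits
  })
}

#' Generate paired blinded judgements for a classified cohort
#'
#' Each visit carries a latent suitability state drawn with the per-class
#' probability `p_subacute`; the two independent ratings flip that state with
#' probability `rater_error` each. Confidence scores are integers drawn
#' around the per-class mean and clipped to 1--5. Defaults reproduce the
#' validation fixture in expectation: `p_subacute` matches its per-class
#' rating margins and `rater_error = 0.07` matches its overall discordance
#' rate (2e(1-e) = 21/160).
#'
#' @param visits Tibble with `visit_id` and `edac_class`.
#' @param p_subacute Named per-class latent suitability probabilities.
#' @param rater_error Per-rating flip probability (< 0.5).
#' @param confidence_mean Named per-class mean confidence.
#' @param confidence_sd Confidence SD before rounding/clipping.
#' @param seed Integer seed.
#' @return Tibble of judgement pairs: `visit_id`, `edac_class`, `rating_a`,
#'   `rating_b`, `confidence_a`, `confidence_b`.
#' @export
generate_judgements <- function(visits,
                                p_subacute = c(avoidable = 0.97,
                                               potentially_avoidable = 0.82,
                                               not_avoidable = 0.31),
                                rater_error = 0.07,
                                confidence_mean = c(avoidable = 4.2,
                                                    potentially_avoidable = 3.9,
                                                    not_avoidable = 4.4),
                                confidence_sd = 0.9,
                                seed = NULL) {
  visits <- as_tibble(visits)
  stopifnot(all(c("visit_id", "edac_class") %in% names(visits)))
  if (!(rater_error >= 0 && rater_error < 0.5)) {
    abort("`rater_error` must lie in [0, 0.5).", class = "edacr_invalid_spec")
  }
  if (any(p_subacute < 0 | p_subacute > 1)) {
    abort("`p_subacute` entries must lie in [0, 1].",
          class = "edacr_invalid_spec")
  }
  cls <- as.character(edac_factor(visits$edac_class))
  stopifnot(all(cls %in% names(p_subacute)),
            all(cls %in% names(confidence_mean)))
  n <- nrow(visits)
  with_seed(seed, {
    latent <- unname(runif(n) < p_subacute[cls])
    flip_a <- runif(n) < rater_error
    flip_b <- runif(n) < rater_error
    conf <- function() {
      unname(pmin(pmax(round(rnorm(n, confidence_mean[cls], confidence_sd)),
                       1L), 5L))
    }
    tibble(visit_id = as.character(visits$visit_id),
           edac_class = edac_factor(cls),
           rating_a = xor(latent, flip_a),
           rating_b = xor(latent, flip_b),
           confidence_a = as.integer(conf()),
           confidence_b = as.integer(conf()))
  })
}

#' Recover the judgement-model parameters from observed pairs
#'
#' Method-of-moments inversion of the latent-state flip model: the pooled
#' discordant fraction identifies the rater error via `d = 2e(1-e)` (smaller
#' root), and each class's both-subacute fraction then identifies its latent
#' suitability probability via `f = p(1-e)^2 + (1-p)e^2`.
#'
#' @param pairs Judgement pairs with `edac_class`, `rating_a`, `rating_b`.
#' @return List with `p_subacute` (named, clipped to `[0, 1]`), `rater_error`,
#'   and `n_pairs`.
#' @export
recover_parameters <- function(pairs) {
  pairs <- as_tibble(pairs)
  tab <- concordance_table(pairs)
  m <- unclass(tab)
  present <- rowSums(m) > 0
  if (sum(present) < 2) {
    abort("Parameter recovery needs pairs from at least two classes.",
          class = "edacr_nonidentifiable")
  }
  n <- sum(m)
  d <- sum(m[, "discordant"]) / n
  if (d > 0.5) {
    abort("Discordance above 0.5 is outside the model (rater_error < 0.5).",
          class = "edacr_nonidentifiable")
  }
  e <- (1 - sqrt(1 - 2 * d)) / 2
  denom <- 1 - 2 * e # (1-e)^2 - e^2
  p_hat <- vapply(edac_levels(), function(cl) {
    if (!present[cl]) return(NA_real_)
    f_bs <- m[cl, "both_subacute"] / sum(m[cl, ])
    min(max((f_bs - e^2) / denom, 0), 1)
  }, numeric(1))
  list(p_subacute = p_hat, rater_error = e, n_pairs = as.integer(n))
}
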