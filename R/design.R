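#' Equal-quantity stratified sample of classified visits
#'
#' Samples uniformly without replacement within each class cluster,
#' allocating `total_n` as evenly as possible over the three clusters; when
#' `total_n` is not divisible by 3 the remainder goes to clusters in fixed
#' order avoidable, potentially avoidable, not avoidable (so 160 visits yield
#' cluster sizes 54/53/53).
#'
#' @param labeled_visits Tibble with `visit_id` and `edac_class`.
#' @param total_n Total number of visits to draw.
#' @param seed Integer seed for reproducibility.
#' @return Tibble of sampled `visit_id`, `edac_class`.
#' @export
stratified_sample <- function(labeled_visits, total_n, seed = NULL) {
  lv <- as_tibble(labeled_visits)
  stopifnot(all(c("visit_id", "edac_class") %in% names(lv)),
            total_n >= 1)
  cls <- edac_factor(lv$edac_class)
  order_pref <- c("avoidable", "potentially_avoidable", "not_avoidable")
  base <- total_n %/% 3
  quota <- setNames(rep(base, 3), order_pref)
  rem <- total_n - 3 * base
  if (rem > 0) quota[order_pref[seq_len(rem)]] <- base + 1
  avail <- table(factor(cls, levels = order_pref))
  short <- names(quota)[as.integer(avail[names(quota)]) < quota]
  if (length(short) > 0) {
    abort(paste0("Cluster(s) too small for the requested sample: ",
                 paste0(short, " (need ", quota[short], ", have ",
                        as.integer(avail[short]), ")", collapse = "; ")),
          class = "edacr_insufficient_cluster")
  }
  with_seed(seed, {
    picks <- lapply(order_pref, function(cl) {
      ids <- as.character(lv$visit_id[cls == cl])
      sample(ids, quota[[cl]])
    })
    tibble(visit_id = unlist(picks),
           edac_class = edac_factor(rep(order_pref, quota[order_pref])))
  })
}

# split `demand` into `k` integer parts as evenly as possible, larger parts
# first positions of `order`
even_split <- function(demand, k, order = seq_len(k)) {
  base <- demand %/% k
  parts <- rep(base, k)
  extra <- demand - base * k
  if (extra > 0) parts[order[seq_len(extra)]] <- base + 1
  parts
}

#' Blinded dual-rater assignment plan
#'
#' Assigns every sampled visit to exactly two distinct raters. First-round
#' raters each receive `batch_size` visits with the per-cluster composition
#' given (e.g. 7/7/6), the cluster carrying the smaller share rotating across
#' raters so aggregate per-cluster workloads stay balanced; second-round
#' batches absorb the remaining demand as evenly as possible. Within each
#' cluster the two rating slots of each visit are placed by a randomized
#' largest-remaining-capacity rule with whole-cluster retries as backtracking,
#' which terminates for any feasible instance of the study's dimensions. The
#' returned plan deliberately carries no class column, preserving rater
#' blinding; keep the class map separately.
#'
#' @param sample Tibble with `visit_id` and `edac_class` (e.g. from
#'   [stratified_sample()]).
#' @param raters_round1,raters_round2 Character vectors of rater ids; a rater
#'   may appear in both rounds but never rates the same visit twice.
#' @param batch_size Ratings per rater batch.
#' @param composition Integer vector (one entry per class, summing to
#'   `batch_size`) giving the first-round per-cluster batch make-up, rotated
#'   across raters; `NULL` derives balanced compositions automatically.
#' @param seed Integer seed.
#' @param max_tries Whole-cluster retries before giving up.
#' @return An `assignment_plan`: tibble with `rater_id`, `visit_id`, `round`.
#' @export
build_assignment <- function(sample, raters_round1, raters_round2 = character(),
                             batch_size, composition = NULL, seed = NULL,
                             max_tries = 50) {
  sample <- as_tibble(sample)
  stopifnot(all(c("visit_id", "edac_class") %in% names(sample)))
  n <- nrow(sample)
  r1 <- as.character(raters_round1)
  r2 <- as.character(raters_round2)
  if (n >= 1 && (length(r1) + length(r2)) < 2) {
    abort("At least two raters are required so each visit gets two distinct raters.",
          class = "edacr_infeasible")
  }
  supply <- (length(r1) + length(r2)) * batch_size
  if (supply != 2 * n) {
    abort(sprintf(
      "Rating capacity (%d batches x %d = %d) must equal twice the sample size (%d); deficit %d.",
      length(r1) + length(r2), batch_size, supply, 2 * n, 2 * n - supply),
      class = "edacr_infeasible")
  }
  cls <- edac_factor(sample$edac_class)
  clusters <- edac_levels()[edac_levels() %in% as.character(unique(cls))]
  sizes <- setNames(as.integer(table(factor(cls, levels = clusters))), clusters)

  batches <- tibble(rater_id = c(r1, r2),
                    round = rep(c(1L, 2L), c(length(r1), length(r2))))
  nb <- nrow(batches)
  quota <- matrix(0L, nrow = nb, ncol = length(clusters),
                  dimnames = list(NULL, clusters))
  demand <- 2L * sizes
  if (!is.null(composition)) {
    if (length(composition) != length(clusters) ||
        sum(composition) != batch_size) {
      abort("`composition` must have one entry per cluster present and sum to `batch_size`.",
            class = "edacr_infeasible")
    }
    for (i in seq_along(r1)) {
      rot <- ((seq_along(clusters) - 1 + (i - 1)) %% length(clusters)) + 1
      quota[i, ] <- composition[rot]
    }
  } else {
    # balanced first-round compositions proportional to demand
    for (i in seq_along(r1)) {
      rem <- pmax(demand - colSums(quota[seq_len(i - 1), , drop = FALSE]), 0L)
      row <- even_split(batch_size, length(clusters),
                        order(rem, decreasing = TRUE))
      # cap by remaining demand, reallocate any excess
      row <- pmin(row, rem)
      while (sum(row) < batch_size) {
        slack <- which(row < rem)
        if (length(slack) == 0) {
          abort("First-round batches exceed total rating demand.",
                class = "edacr_infeasible")
        }
        j <- slack[which.max(rem[slack] - row[slack])]
        row[j] <- row[j] + 1L
      }
      quota[i, ] <- row
    }
  }
  used1 <- colSums(quota[seq_along(r1), , drop = FALSE])
  left <- demand - used1
  if (any(left < 0)) {
    abort(paste0("First-round composition over-allocates cluster(s): ",
                 paste(clusters[left < 0], collapse = ", ")),
          class = "edacr_infeasible")
  }
  if (length(r2) > 0) {
    i2 <- length(r1) + seq_along(r2)
    for (cl in clusters) {
      quota[i2, cl] <- even_split(left[[cl]], length(r2))
    }
    # repair row sums to batch_size by moving single units between rows
    # (keeps cluster totals fixed)
    repeat {
      rs <- rowSums(quota[i2, , drop = FALSE])
      over <- which(rs > batch_size)
      under <- which(rs < batch_size)
      if (length(over) == 0 && length(under) == 0) break
      o <- i2[over[1]]; u <- i2[under[1]]
      cl <- which(quota[o, ] > 0 & quota[u, ] < sizes)[1]
      if (is.na(cl)) {
        abort("Could not balance second-round batches.",
              class = "edacr_infeasible")
      }
      quota[o, cl] <- quota[o, cl] - 1L
      quota[u, cl] <- quota[u, cl] + 1L
    }
  } else if (any(left != 0)) {
    abort("First-round batches do not cover the rating demand and no second-round raters were given.",
          class = "edacr_infeasible")
  }
  if (any(quota > matrix(sizes, nb, length(clusters), byrow = TRUE))) {
    abort("A rater's per-cluster quota exceeds the cluster size, so distinct visits cannot fill it.",
          class = "edacr_infeasible")
  }

  with_seed(seed, {
    assign_cluster <- function(cl) {
      ids <- as.character(sample$visit_id[cls == cl])
      q <- quota[, cl]
      raters <- batches$rater_id
      for (try in seq_len(max_tries)) {
        cap <- tapply(q, raters, sum) # capacity per distinct rater id
        rem_batch <- q
        out <- vector("list", length(ids))
        ok <- TRUE
        for (v in sample(seq_along(ids))) {
          elig <- names(cap)[cap > 0]
          if (length(elig) < 2) { ok <- FALSE; break }
          # two distinct raters with largest remaining capacity, random ties
          pick <- elig[order(-cap[elig], runif(length(elig)))][1:2]
          rows <- integer(2)
          for (k in 1:2) {
            cand <- which(raters == pick[k] & rem_batch > 0)
            rows[k] <- cand[order(batches$round[cand])][1] # round 1 first
            rem_batch[rows[k]] <- rem_batch[rows[k]] - 1L
            cap[pick[k]] <- cap[pick[k]] - 1L
          }
          out[[v]] <- tibble(rater_id = pick, visit_id = ids[v],
                             round = batches$round[rows])
        }
        if (ok && all(rem_batch == 0)) return(bind_rows(out))
      }
      abort(paste0("Could not realize a feasible assignment for cluster ", cl,
                   " in ", max_tries, " attempts."),
            class = "edacr_infeasible")
    }
    plan <- bind_rows(lapply(clusters, assign_cluster))
    plan <- arrange(plan, .data$rater_id, .data$round, .data$visit_id)
    structure(plan, class = c("assignment_plan", class(plan)),
              composition = quota)
  })
}

#' Simulation-based power for a kappa criterion
#'
#' Monte-Carlo power of the two-sided asymptotic z-test of the pooled-marginal
#' kappa against `kappa_null`, when data arise from paired binary ratings with
#' the given marginal prevalence and true agreement `kappa_alt`. Pairs are
#' generated from the common-correlation 2x2 construction: both-subacute with
#' probability `p^2 + kappa p(1-p)`, discordant `2 p (1-p) (1-kappa)`, both-ED
#' the rest. Replicates with undefined kappa are dropped (counted).
#'
#' @param kappa_null Agreement under the null hypothesis (`0 <= kappa_null`).
#' @param kappa_alt True (alternative) agreement (`> kappa_null`, unless
#'   calibrating at the null).
#' @param prevalence Marginal probability a single rating is
#'   subacute-suitable.
#' @param n_visits Number of dual-rated visits per replicate.
#' @param alpha Two-sided significance level.
#' @param reps Monte-Carlo replicates.
#' @param seed Integer seed.
#' @return List with `power`, `mc_se`, `reps_used`, `n_degenerate`.
#' @export
#' @examples
#' simulate_power(0.4, 0.69, prevalence = 0.7, n_visits = 160,
#'                reps = 500, seed = 1)
simulate_power <- function(kappa_null, kappa_alt, prevalence, n_visits,
                           alpha = 0.05, reps = 2000, seed = NULL) {
  if (!(kappa_null >= 0 && kappa_null <= 1 && kappa_alt >= 0 &&
        kappa_alt <= 1 && kappa_alt >= kappa_null)) {
    abort("Require 0 <= kappa_null <= kappa_alt <= 1.",
          class = "edacr_invalid_spec")
  }
  if (!(prevalence > 0 && prevalence < 1)) {
    abort("`prevalence` must lie strictly in (0, 1).",
          class = "edacr_invalid_spec")
  }
  if (!(alpha > 0 && alpha < 1)) {
    abort("`alpha` must lie strictly in (0, 1).", class = "edacr_invalid_spec")
  }
  stopifnot(n_visits >= 2, reps >= 1)
  p <- prevalence
  p_bs <- p^2 + kappa_alt * p * (1 - p)
  p_dc <- 2 * p * (1 - p) * (1 - kappa_alt)
  p_be <- 1 - p_bs - p_dc
  with_seed(seed, {
    draws <- rmultinom(reps, n_visits, c(p_bs, p_dc, p_be))
    k <- kappa_from_counts(draws[1, ], draws[2, ], draws[3, ])
    zcrit <- qnorm(1 - alpha / 2)
    z <- (k$kappa - kappa_null) / k$se
    reject <- abs(z) > zcrit
    used <- sum(!is.na(reject))
    pw <- mean(reject, na.rm = TRUE)
    list(power = pw, mc_se = sqrt(pw * (1 - pw) / used),
         reps_used = used, n_degenerate = reps - used)
  })
}
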