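#' Tie-corrected Spearman correlation between class and concordance
#'
#' Pearson correlation of midranks of the two ordinal scales (avoidability
#' class, ranked not < potentially < avoidable, against pair concordance,
#' both-ED < discordant < both-subacute), computed from the 3x3 count table
#' with weighted formulas (no expansion to rows). This is exactly the
#' tie-corrected Spearman rho of the underlying visit-level data.
#'
#' @param table A `concordance_table`.
#' @return Scalar correlation coefficient.
#' @export
#' @examples
#' spearman_ordinal(fixture_concordance())
spearman_ordinal <- function(table) {
  stopifnot(inherits(table, "concordance_table"))
  m <- unclass(table)
  n <- sum(m)
  if (n < 2) {
    abort("At least two pairs are needed for a correlation.",
          class = "edacr_empty_input")
  }
  midranks <- function(counts) {
    cum <- cumsum(counts)
    cum - counts + (counts + 1) / 2
  }
  rr <- midranks(rowSums(m)) # class midranks, rows already in ordinal order
  rc <- midranks(colSums(m))
  w <- m / n
  mx <- sum(rowSums(w) * rr)
  my <- sum(colSums(w) * rc)
  vx <- sum(rowSums(w) * (rr - mx)^2)
  vy <- sum(colSums(w) * (rc - my)^2)
  if (vx <= 0 || vy <= 0) {
    abort("Correlation undefined: one margin is concentrated in a single level.",
          class = "edacr_degenerate_margin")
  }
  cxy <- sum(w * outer(rr - mx, rc - my))
  cxy / sqrt(vx * vy)
}

# negative log-likelihood pieces for the proportional-odds model on a 3-level
# outcome with the avoidability class as a dummy-coded predictor.
# Parameterization (as in polr): logit P(Y <= j | class c) = zeta_j - eta_c,
# eta = 0 for the referent (not avoidable) class.
po_probs <- function(zeta, eta) {
  g1 <- plogis(zeta[1] - eta)
  g2 <- plogis(zeta[2] - eta)
  cbind(g1, g2 - g1, 1 - g2)
}

po_loglik <- function(par, counts) {
  zeta <- par[1:2]
  if (zeta[1] >= zeta[2]) return(-Inf)
  eta <- c(0, par[3], par[4])
  pr <- po_probs(zeta, eta)
  if (any(pr <= 0)) return(-Inf)
  sum(counts * log(pr))
}

po_gradient <- function(par, counts) {
  zeta <- par[1:2]
  eta <- c(0, par[3], par[4])
  pr <- po_probs(zeta, eta)
  f1 <- dlogis(zeta[1] - eta)
  f2 <- dlogis(zeta[2] - eta)
  r0 <- counts[, 1] / pr[, 1]
  r1 <- counts[, 2] / pr[, 2]
  r2 <- counts[, 3] / pr[, 3]
  dz1 <- sum(f1 * (r0 - r1))
  dz2 <- sum(f2 * (r1 - r2))
  dbeta <- -(f1 * (r0 - r1) + f2 * (r1 - r2))
  c(dz1, dz2, dbeta[2], dbeta[3])
}

#' Proportional-odds (cumulative logit) fit of concordance on class
#'
#' Maximum-likelihood fit of the three-level ordinal concordance outcome on
#' dummy-coded avoidability class (referent: not avoidable) by damped Newton
#' iteration: full Newton steps with step-halving so the log-likelihood never
#' decreases, converging when the gradient max-norm drops below `tol`.
#' Positive coefficients mean higher odds of the both-subacute end of the
#' scale. Odds ratios are `exp(beta)` with Wald intervals from the inverse
#' observed information; the concordance index is Harrell's C of the fitted
#' class scores against the outcome.
#'
#' @param table A `concordance_table`.
#' @param tol Convergence tolerance on the gradient max-norm.
#' @param max_iter Maximum Newton iterations.
#' @return An `ordinal_fit`: list with `zeta` (two thresholds), `beta` (named
#'   coefficients), `vcov`, `or` (tibble of class, odds ratio, Wald CI,
#'   p-value), `cindex`, `loglik`, `loglik_null`, `iterations`, `converged`,
#'   `trace`.
#' @export
#' @examples
#' fit <- fit_cumulative_logit(fixture_concordance())
#' fit$or
fit_cumulative_logit <- function(table, tol = 1e-8, max_iter = 100) {
  stopifnot(inherits(table, "concordance_table"))
  counts <- unclass(table)
  if (any(rowSums(counts) == 0)) {
    abort("Every class row must contain at least one pair.",
          class = "edacr_empty_input")
  }
  if (sum(colSums(counts) > 0) < 2) {
    abort("The outcome must take at least two observed levels.",
          class = "edacr_degenerate_margin")
  }
  # separation: a non-referent row with all mass at one extreme level drives
  # its coefficient to +/- infinity
  extreme <- rowSums(counts[, c(1, 3)] == rowSums(counts)) > 0
  if (any(extreme)) {
    warn(paste0("Class row(s) ", paste(rownames(counts)[extreme],
                                       collapse = ", "),
                " are entirely at one extreme outcome level; estimates are ",
                "quasi-separated and variances inflated."),
         class = "edacr_separation")
  }
  # start: thresholds at pooled cumulative logits, coefficients at zero
  tot <- colSums(counts)
  cum <- cumsum(tot) / sum(tot)
  zeta0 <- qlogis(pmin(pmax(cum[1:2], 1e-6), 1 - 1e-6))
  if (zeta0[1] >= zeta0[2]) zeta0 <- c(zeta0[1], zeta0[1] + 0.5)
  par <- c(zeta0, 0, 0)
  ll <- po_loglik(par, counts)
  trace <- tibble(iteration = 0L, loglik = ll, grad_norm = NA_real_)
  converged <- FALSE
  iter <- 0L
  num_hessian <- function(p) {
    h <- 1e-5
    H <- matrix(0, 4, 4)
    for (j in 1:4) {
      e <- rep(0, 4); e[j] <- h
      H[, j] <- (po_gradient(p + e, counts) - po_gradient(p - e, counts)) /
        (2 * h)
    }
    (H + t(H)) / 2
  }
  for (iter in seq_len(max_iter)) {
    g <- po_gradient(par, counts)
    gn <- max(abs(g))
    trace <- bind_rows(trace, tibble(iteration = iter, loglik = ll,
                                     grad_norm = gn))
    if (gn < tol) { converged <- TRUE; break }
    H <- num_hessian(par)
    step <- tryCatch(solve(H, g), error = function(e) g / max(1, gn))
    # Newton direction for a maximum is -solve(H, g); damp until no decrease
    lambda <- 1
    repeat {
      cand <- par - lambda * step
      llc <- po_loglik(cand, counts)
      if (is.finite(llc) && llc >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) {
        abort("Newton iteration failed to find an ascent step.",
              class = "edacr_nonconvergence",
              trace_tbl = trace)
      }
    }
    par <- cand
    ll <- llc
  }
  if (!converged) {
    abort(paste0("Cumulative-logit fit did not converge in ", max_iter,
                 " iterations (gradient max-norm ",
                 format(max(abs(po_gradient(par, counts)))), ")."),
          class = "edacr_nonconvergence", trace_tbl = trace)
  }
  H <- num_hessian(par)
  vc <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, 4, 4))
  pn <- c("zeta_1", "zeta_2", "beta_potentially_avoidable", "beta_avoidable")
  dimnames(vc) <- list(pn, pn)
  beta <- setNames(par[3:4], pn[3:4])
  se <- sqrt(diag(vc)[3:4])
  z <- qnorm(0.975)
  or_tbl <- tibble(
    class = c("avoidable", "potentially_avoidable", "not_avoidable"),
    or = c(exp(beta[2]), exp(beta[1]), 1),
    ci_low = c(exp(beta[2] - z * se[2]), exp(beta[1] - z * se[1]), NA),
    ci_high = c(exp(beta[2] + z * se[2]), exp(beta[1] + z * se[1]), NA),
    p_value = c(2 * pnorm(-abs(beta[2] / se[2])),
                2 * pnorm(-abs(beta[1] / se[1])), NA))
  scores <- setNames(c(0, beta[1], beta[2]), edac_levels())
  null_ll <- po_loglik(c(zeta0, 0, 0), counts)
  # intercept-only MLE: thresholds at pooled cumulative logits exactly
  structure(list(
    zeta = setNames(par[1:2], pn[1:2]), beta = beta, vcov = vc,
    or = or_tbl, cindex = ordinal_cindex(table, scores),
    loglik = ll, loglik_null = null_ll,
    iterations = iter, converged = converged, trace = trace
  ), class = "ordinal_fit")
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat(sprintf(
    "Proportional-odds fit (converged in %d iterations, logLik %.3f)\n",
    x$iterations, x$loglik))
  cat(sprintf("  thresholds: zeta_1 = %.3f, zeta_2 = %.3f\n",
              x$zeta[1], x$zeta[2]))
  print(x$or)
  cat(sprintf("  concordance index (Harrell's C): %.3f\n", x$cindex))
  invisible(x)
}

#' Dichotomized odds ratio of both-subacute concordance
#'
#' Collapses the concordance outcome to both-subacute vs the rest and reports
#' the cross-product odds ratio of the given class row against the
#' not-avoidable referent row, with the Wald interval
#' `exp(log OR +/- 1.96 sqrt(sum 1/cell))`. This closed form is the quantity
#' the validation study's headline odds ratios correspond to digit-for-digit;
#' [fit_cumulative_logit()] gives the genuinely ordinal alternative.
#'
#' @param table A `concordance_table`.
#' @param class Class to compare against the referent (`"not_avoidable"`
#'   returns the referent's OR of 1 by definition).
#' @param continuity Add 0.5 to every cell (use when a cell is zero).
#' @param conf_level Interval level.
#' @return List with `or`, `ci_low`, `ci_high`, `p_value`, `cells`.
#' @export
#' @examples
#' reported_or(fixture_concordance(), "avoidable")
reported_or <- function(table, class, continuity = FALSE, conf_level = 0.95) {
  stopifnot(inherits(table, "concordance_table"))
  class <- match.arg(class, edac_levels())
  if (class == "not_avoidable") {
    return(list(or = 1, ci_low = NA_real_, ci_high = NA_real_,
                p_value = NA_real_, cells = NULL))
  }
  m <- unclass(table)
  pos <- function(row) m[row, "both_subacute"]
  neg <- function(row) m[row, "both_ed"] + m[row, "discordant"]
  cells <- c(a = pos(class), b = neg(class),
             c = pos("not_avoidable"), d = neg("not_avoidable"))
  if (any(cells == 0)) {
    if (!continuity) {
      abort(paste0("Zero cell in the dichotomized 2x2 table; re-run with ",
                   "`continuity = TRUE` to add 0.5 to every cell."),
            class = "edacr_zero_cell")
    }
    cells <- cells + 0.5
  }
  lor <- log(cells[["a"]]) - log(cells[["b"]]) -
    log(cells[["c"]]) + log(cells[["d"]])
  se <- sqrt(sum(1 / cells))
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(or = exp(lor), ci_low = exp(lor - z * se), ci_high = exp(lor + z * se),
       p_value = 2 * pnorm(-abs(lor / se)), cells = cells)
}

#' Harrell's concordance index over the ordinal outcome
#'
#' Over all pairs of visits with different concordance levels, the fraction
#' in which the visit with the higher outcome level also carries the higher
#' class score, counting score ties as one half. With scores respecting the
#' class order this is the ordinal analogue of the model AUC.
#'
#' @param table A `concordance_table`.
#' @param scores Named numeric risk score per class (names = [edac_levels()]);
#'   defaults to the class ranks 0, 1, 2.
#' @return Scalar C in `[0, 1]`.
#' @export
#' @examples
#' ordinal_cindex(fixture_concordance())
ordinal_cindex <- function(table, scores = NULL) {
  stopifnot(inherits(table, "concordance_table"))
  scores <- scores %||% setNames(c(0, 1, 2), edac_levels())
  stopifnot(all(edac_levels() %in% names(scores)))
  s <- as.numeric(scores[edac_levels()])
  m <- unclass(table)[edac_levels(), , drop = FALSE]
  num <- 0
  den <- 0
  for (j1 in 1:2) for (j2 in (j1 + 1):3) {
    # visit i at lower level j1, visit j at higher level j2
    for (c1 in 1:3) for (c2 in 1:3) {
      w <- m[c1, j1] * m[c2, j2]
      if (w == 0) next
      den <- den + w
      if (s[c2] > s[c1]) num <- num + w
      else if (s[c2] == s[c1]) num <- num + w / 2
    }
  }
  if (den == 0) {
    abort("No informative pairs: all visits share one concordance level.",
          class = "edacr_degenerate_margin")
  }
  num / den
}
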