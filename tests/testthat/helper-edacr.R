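# shared fixtures built in code

reg <- default_registry()

# a visit satisfying every avoidable conjunct
avoidable_visit <- function(...) {
  modifyList(list(visit_id = "v1", age = 25, ctas = 5,
                  specialist_consult = FALSE,
                  main_intervention = "1.AN.09", outcome = "discharged"),
             list(...))
}

# random valid visit records spanning the whole input space
random_visits <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(
    visit_id = sprintf("r%04d", seq_len(n)),
    age = sample(0:100, n, replace = TRUE),
    ctas = sample(1:5, n, replace = TRUE),
    specialist_consult = sample(c(TRUE, FALSE), n, replace = TRUE),
    main_intervention = sample(c(as.character(reg), "9.ZZ.99", "8.AA.00"),
                               n, replace = TRUE),
    outcome = sample(c("discharged", "admission", "other"), n, replace = TRUE)
  )
}

# pairs tibble with given per-class concordance counts
pairs_from_counts <- function(not_av = c(0, 0, 0), pot = c(0, 0, 0),
                              avoid = c(0, 0, 0)) {
  mat <- rbind(not_avoidable = not_av, potentially_avoidable = pot,
               avoidable = avoid)
  colnames(mat) <- concordance_levels()
  fixture_pairs(as_concordance_table(mat[edac_levels(), ]))
}

expand_table_long <- function(tab) {
  m <- unclass(tab)
  data.frame(
    cls = rep(rep(rownames(m), each = ncol(m)), as.vector(t(m))),
    lvl = rep(rep(colnames(m), nrow(m)), as.vector(t(m))))
}
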