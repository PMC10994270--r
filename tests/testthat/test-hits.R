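# score table builder: list(compound = list(SC1 = c(`100` = .., `300` = ..)))
score_table <- function(spec_list) {
  rows <- list()
  for (cpd in names(spec_list)) for (sc in names(spec_list[[cpd]])) {
    v <- spec_list[[cpd]][[sc]]
    rows[[length(rows) + 1]] <- data.frame(
      compound_id = cpd, subclone_id = sc,
      concentration_nM = as.numeric(names(v)), score = as.numeric(v))
  }
  do.call(rbind, rows)
}

test_that("the replication rule calls hits above a strict threshold", {
  sc <- score_table(list(CPDX = list(SC1 = c(`300` = 0.62),
                                     SC2 = c(`300` = 0.58),
                                     SC3 = c(`300` = 0.51))))
  for (mode in c("any_conc", "same_conc")) {
    h <- call_hits(sc, mode = mode, subclones = c("SC1", "SC2", "SC3"))
    expect_true(h$hit[h$compound_id == "CPDX"])
  }
  # a sub-clone maximum of exactly tau is never a hit (strict >)
  sc2 <- score_table(list(CPDY = list(SC1 = c(`300` = 0.62),
                                      SC2 = c(`300` = 0.505),
                                      SC3 = c(`300` = 0.51))))
  h2 <- call_hits(sc2, subclones = c("SC1", "SC2", "SC3"))
  expect_false(any(h2$hit))
  # one sub-clone below threshold at every concentration blocks the hit
  sc3 <- score_table(list(CPDZ = list(
    SC1 = c(`100` = 0.6, `300` = 0.6, `1000` = 0.6),
    SC2 = c(`100` = 0.6, `300` = 0.6, `1000` = 0.6),
    SC3 = c(`100` = 0.40, `300` = 0.40, `1000` = 0.40))))
  expect_false(any(call_hits(sc3, subclones = paste0("SC", 1:3))$hit))
})

test_that("replication modes differ when sub-clones respond at different doses", {
  sc <- score_table(list(CPDA = list(SC1 = c(`100` = 0.6, `300` = 0.2),
                                     SC2 = c(`100` = 0.2, `300` = 0.6))))
  expect_true(call_hits(sc, mode = "any_conc", subclones = c("SC1", "SC2"))$hit)
  expect_false(call_hits(sc, mode = "same_conc", subclones = c("SC1", "SC2"))$hit)
})

test_that("missing cells count as non-exceeding", {
  sc <- score_table(list(CPDB = list(SC1 = c(`300` = 0.9),
                                     SC2 = c(`300` = 0.9))))
  expect_false(call_hits(sc, subclones = c("SC1", "SC2", "SC3"))$hit)
})

test_that("threshold sanity and monotonicity properties hold", {
  expect_error(call_hits(score_table(list(A = list(SC1 = c(`1` = .5)))),
                         tau = 1.2), "\\(0, 1\\)")
  set.seed(15)
  sc <- do.call(rbind, lapply(sprintf("C%02d", 1:25), function(cpd)
    data.frame(compound_id = cpd,
               subclone_id = rep(c("SC1", "SC2", "SC3"), each = 3),
               concentration_nM = rep(c(100, 300, 1000), 3),
               score = runif(9))))
  taus <- seq(0.1, 0.9, by = 0.1)
  prev <- NULL
  for (tau in taus) {
    h <- call_hits(sc, tau = tau, subclones = paste0("SC", 1:3))
    hits <- h$compound_id[h$hit]
    if (!is.null(prev)) expect_true(all(hits %in% prev))
    prev <- hits
    # same_conc hits are a subset of any_conc hits
    h2 <- call_hits(sc, tau = tau, mode = "same_conc",
                    subclones = paste0("SC", 1:3))
    expect_true(all(h2$compound_id[h2$hit] %in% hits))
    # a score exactly at tau never drives a hit
    sc_eq <- sc; sc_eq$score <- tau
    expect_false(any(call_hits(sc_eq, tau = tau,
                               subclones = paste0("SC", 1:3))$hit))
  }
})

test_that("salt forms collapse 16 compound hits to 14 unique drugs", {
  man <- default_library_manifest()
  # the manifest's two salt pairs: CPD002/CPD003 and CPD005/CPD006
  hit_ids <- c("CPD002", "CPD003", "CPD005", "CPD006", sprintf("CPD%03d", 10:21))
  sc <- do.call(rbind, lapply(hit_ids, function(cpd)
    data.frame(compound_id = cpd, subclone_id = paste0("SC", 1:3),
               concentration_nM = 300, score = 0.8)))
  h <- call_hits(sc, subclones = paste0("SC", 1:3))
  expect_equal(sum(h$hit), 16)
  col <- collapse_salt_forms(h, man)
  expect_equal(col$n_compound_hits, 16)
  expect_equal(col$n_drug_hits, 14)
  expect_true(all(c("drug_002", "drug_005") %in% col$drugs$parent_drug))
  expect_equal(sort(col$drugs$n_forms, decreasing = TRUE)[1:2], c(2, 2))
})

test_that("collapse keeps the best score and demands manifest coverage", {
  man <- default_library_manifest(10)
  sc <- score_table(list(CPD002 = list(SC1 = c(`300` = 0.7)),
                         CPD003 = list(SC1 = c(`300` = 0.9))))
  h <- call_hits(sc, subclones = "SC1")
  col <- collapse_salt_forms(h, man)
  expect_equal(col$n_drug_hits, 1)
  expect_equal(col$drugs$best_score, 0.9)
  # a hit not present in the manifest is an explicit error
  sc2 <- score_table(list(NOPE = list(SC1 = c(`300` = 0.9))))
  expect_error(collapse_salt_forms(call_hits(sc2, subclones = "SC1"), man),
               "NOPE")
  # a manifest without salt forms maps identically
  man2 <- man; man2$parent_drug <- man2$compound_id; man2$is_salt_form <- FALSE
  col2 <- collapse_salt_forms(h, man2)
  expect_equal(col2$n_drug_hits, col2$n_compound_hits)
})

test_that("mechanism summaries count drugs per class", {
  drugs <- data.frame(parent_drug = c("a", "b", "c"),
                      mechanism_class = c("A", "A", "B"),
                      n_forms = 1, best_score = c(0.8, 0.6, 0.9))
  s <- summarize_by_mechanism(drugs)
  expect_equal(s$n_drugs[s$mechanism_class == "A"], 2)
  expect_equal(s$n_drugs[s$mechanism_class == "B"], 1)
  expect_equal(s$max_score[s$mechanism_class == "A"], 0.8)
  drugs$mechanism_class[3] <- NA
  expect_true("unannotated" %in% summarize_by_mechanism(drugs)$mechanism_class)
  empty <- summarize_by_mechanism(drugs[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("hit recovery scores against ground truth", {
  truth <- list(compound_id = sprintf("C%02d", 1:10),
                true_hit = c(rep(TRUE, 4), rep(FALSE, 6)))
  hits <- data.frame(compound_id = sprintf("C%02d", 1:10),
                     hit = c(TRUE, TRUE, TRUE, FALSE, TRUE, rep(FALSE, 5)))
  r <- hit_recovery(hits, truth)
  expect_equal(r$recovered, 3)
  expect_equal(r$missed, 1)
  expect_equal(r$false_positives, 1)
  expect_equal(r$sensitivity, 0.75)
  expect_equal(r$specificity, 5 / 6)
})
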