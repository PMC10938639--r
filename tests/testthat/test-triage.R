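test_that("percent change is positive for stronger-than-reference binders", {
  expect_equal(percent_change(-11, -10), 10)
  expect_equal(percent_change(-9, -10), -10)
  expect_equal(percent_change(-10, -10), 0)
  expect_equal(percent_change(-11, -10, negate = TRUE), -10)
  expect_error(percent_change(-11, 0), "zero reference")
})

test_that("the average percent change is the plain arithmetic mean", {
  expect_equal(average_percent_change(10, -10), 0)
  expect_equal(average_percent_change(5, 5), 5)
  expect_equal(average_percent_change(0, -20), -10)
})

test_that("strength classes follow the printed boundaries", {
  expect_equal(classify_strength(5), "strong")
  expect_equal(classify_strength(-5), "moderate")
  expect_equal(classify_strength(0), "moderate")   # strict > 0 for strong
  expect_equal(classify_strength(-10), "weak")     # <= -10 is weak
  expect_equal(classify_strength(-10 + 1e-9), "moderate")
})

test_that("strength classes partition the real line", {
  set.seed(1)
  x <- c(stats::runif(500, -50, 50), 0, -10, 10, -1e-12)
  cls <- classify_strength(x)
  expect_true(all(cls %in% c("strong", "moderate", "weak")))
  expect_equal(cls == "strong", x > 0)
  expect_equal(cls == "weak", x <= -10)
})

test_that("the shortlist bound sits 10% off the best reference", {
  expect_true(shortlist_scores(-11, -60, best_dock = -12, best_dg = -60))
  expect_false(shortlist_scores(-10, -60, best_dock = -12, best_dg = -60))
  # equality with the bound and with the best reference itself both pass
  expect_true(shortlist_scores(-10.8, -54, best_dock = -12, best_dg = -60))
  expect_true(shortlist_scores(-12, -60, best_dock = -12, best_dg = -60))
  # conjunction: one passing metric is not enough
  expect_false(shortlist_scores(-12, -40, best_dock = -12, best_dg = -60))
  expect_error(shortlist_scores(-11, -60, best_dock = 2, best_dg = -60),
               "negative")
})

test_that("consensus calls gate shortlisted chemicals through the labels", {
  expect_equal(consensus_call(TRUE, "antagonist", "AR"), "active_antagonist")
  expect_equal(consensus_call(TRUE, "agonist", "ERA"), "active_agonist")
  expect_equal(consensus_call(TRUE, "agonist_antagonist", "PR"),
               "active_ago_ant")
  expect_equal(consensus_call(TRUE, "active", "RXRA"), "active")
  expect_equal(consensus_call(TRUE, "inactive", "ERA"), "inactive")
  expect_equal(consensus_call(FALSE, "agonist", "AR"), "inactive")
  # docking-only receptors: shortlisting alone decides
  expect_equal(consensus_call(TRUE, NA_character_, "PPARA"), "active")
  expect_equal(consensus_call(FALSE, NA_character_, "MR"), "inactive")
  expect_error(consensus_call(TRUE, "agonist", "PPARA"), "without models")
  expect_error(consensus_call(TRUE, NA_character_, "AR"), "missing")
})

test_that("improving a score never demotes a chemical", {
  rank <- c(not_shortlisted = 0, weak = 1, moderate = 2, strong = 3)
  stats <- data.frame(receptor = "AR", n_ref = 3, mean_dock = -10,
                      best_dock = -11, mean_dg = -50, best_dg = -55)
  set.seed(2)
  base <- data.frame(
    chemical_id = sprintf("c%03d", 1:200), receptor = "AR",
    dock_score = stats::runif(200, -14, -6),
    dg_bind = stats::runif(200, -70, -30)
  )
  ml <- data.frame(chemical_id = base$chemical_id, receptor = "AR",
                   label = "agonist", in_domain = TRUE)
  before <- triage_calls(base, stats, ml)
  for (delta in c(0.5, 2)) {
    better <- transform(base, dock_score = dock_score - delta,
                        dg_bind = dg_bind - delta)
    after <- triage_calls(better, stats, ml)
    expect_true(all(after$shortlisted >= before$shortlisted))
    expect_true(all(rank[after$strength] >= rank[before$strength]))
  }
})

test_that("triage is invariant to rescaling all scores by a positive factor", {
  fx <- small_scores()
  calls <- triage_calls(fx$candidates, fx$stats, fx$ml)
  for (k in c(2, 0.5)) {
    cand2 <- transform(fx$candidates, dock_score = dock_score * k,
                       dg_bind = dg_bind * k)
    refs2 <- transform(fx$references, dock_score = dock_score * k,
                       dg_bind = dg_bind * k)
    calls2 <- triage_calls(cand2, compute_reference_stats(refs2), fx$ml)
    expect_equal(calls2$pc_dock, calls$pc_dock)
    expect_equal(calls2$avg_pc, calls$avg_pc)
    expect_equal(calls2$shortlisted, calls$shortlisted)
    expect_equal(calls2$strength, calls$strength)
    expect_equal(calls2$final_call, calls$final_call)
  }
})

test_that("triage recovers the generator's planted strata exactly", {
  fx <- small_scores()
  calls <- triage_calls(fx$candidates, fx$stats, fx$ml)
  key <- function(d) paste(d$chemical_id, d$receptor)
  tr <- fx$truth[match(key(calls), key(fx$truth)), ]
  expect_equal(calls$shortlisted, tr$expect_shortlisted)
  expect_equal(calls$strength, tr$expect_strength)
  # the planted stratum is recoverable from the percent-change statistic
  expect_equal(classify_strength(calls$avg_pc) == "weak",
               tr$stratum == "weak")
  expect_equal(calls$final_call != "inactive", tr$expect_active)
})

test_that("summaries partition the actives and handle empty inputs", {
  fx <- small_scores()
  calls <- triage_calls(fx$candidates, fx$stats, fx$ml)
  s <- summarize_counts(calls)
  expect_equal(
    s$by_receptor$n_total_active,
    s$by_receptor$n_ago_ant + s$by_receptor$n_antagonist +
      s$by_receptor$n_agonist + s$by_receptor$n_active
  )
  expect_equal(sum(s$strength$n), sum(s$by_receptor$n_total_active))
  expect_setequal(s$strength$strength, c("strong", "moderate", "weak"))

  none <- summarize_counts(calls[0, ])
  expect_equal(nrow(none$by_receptor), 0L)
  expect_equal(sum(none$strength$n), 0L)

  quiet <- transform(calls, final_call = "inactive")
  s0 <- summarize_counts(quiet)
  expect_true(all(s0$by_receptor$n_total_active == 0L))
})
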