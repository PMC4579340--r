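# Presence calls, sequence-fate resolution, expression outcomes and the
# lineage deletion-bias statistics.

test_that("presence calls combine the two alignment sources correctly", {
  cfg <- classifier_config()
  cases <- list(
    list(dual_status("p", "mouse", "GAPPED", "UNMAPPED"), "ABSENT"),
    list(dual_status("p", "mouse", "ALIGNED", "GAPPED",
                     target = target_iv(), msa_fraction = 0.9),
         "CONFLICT"),
    list(rbind(status_row("p", "mouse", "msa", "ALIGNED", target_iv(),
                          0.9),
               status_row("p", "mouse", "pairwise", "MULTI")),
         "PRESENT_MULTI"),
    list(dual_status("p", "mouse", "ALIGNED", "ALIGNED",
                     target = target_iv(), msa_fraction = 0.95,
                     pw_fraction = 0.8),
         "PRESENT_UNIQUE"),
    # sub-threshold aligned fraction counts as absent
    list(dual_status("p", "mouse", "ALIGNED", "UNMAPPED",
                     target = target_iv(), msa_fraction = 0.2),
         "ABSENT")
  )
  for (case in cases) {
    expect_equal(presence_call(case[[1]], cfg), case[[2]])
  }
  # missing source row is treated as unmapped
  one <- status_row("p", "mouse", "msa", "ALIGNED", target_iv(), 0.9)
  expect_equal(presence_call(one, cfg), "CONFLICT")
})

test_that("raising the absence threshold never turns ABSENT into PRESENT", {
  set.seed(21)
  for (i in 1:50) {
    frac <- runif(2)
    st <- sample(c("ALIGNED", "GAPPED", "UNMAPPED"), 2, replace = TRUE)
    rows <- rbind(
      status_row("p", "mouse", "msa", st[1],
                 if (st[1] == "ALIGNED") target_iv(), frac[1]),
      status_row("p", "mouse", "pairwise", st[2],
                 if (st[2] == "ALIGNED") target_iv(), frac[2])
    )
    thresholds <- sort(runif(2))
    lo <- presence_call(rows, classifier_config(
      absence_max_aligned_fraction = thresholds[1]))
    hi <- presence_call(rows, classifier_config(
      absence_max_aligned_fraction = thresholds[2]))
    if (lo == "ABSENT") expect_true(hi %in% c("ABSENT", "CONFLICT"))
    if (hi == "PRESENT_UNIQUE") expect_true(lo %in% c("PRESENT_UNIQUE",
                                                      "CONFLICT"))
  }
})

test_that("sequence fate follows the outgroup-resolution rules", {
  cfg <- classifier_config()
  og <- function(...) {
    setNames(c(...), c("dog", "horse", "cow", "pig"))
  }
  all_absent <- og("ABSENT", "ABSENT", "ABSENT", "ABSENT")
  # absent everywhere -> insertion in the focal lineage
  r <- classify_sequence_fate("ABSENT", all_absent, cfg)
  expect_equal(r$sequence_fate, "INSERTED")
  expect_equal(r$lineage_of_event, "focal")
  # one outgroup retains the sequence -> deletion in the opposing lineage
  r <- classify_sequence_fate(
    "ABSENT", og("ABSENT", "PRESENT_UNIQUE", "ABSENT", "ABSENT"), cfg)
  expect_equal(r$sequence_fate, "DELETED_IN_OPPOSING")
  expect_equal(r$lineage_of_event, "opposing")
  # uniquely present in the opposing species -> aligned
  r <- classify_sequence_fate("PRESENT_UNIQUE", all_absent, cfg)
  expect_equal(r$sequence_fate, "ALIGNED")
  # conflicts and multi-locus projections stay unclassified
  expect_equal(classify_sequence_fate("CONFLICT", all_absent,
                                      cfg)$sequence_fate, "UNCLASSIFIED")
  expect_equal(classify_sequence_fate("PRESENT_MULTI", all_absent,
                                      cfg)$sequence_fate, "UNCLASSIFIED")
  # deletion support resting only on a multi-locus outgroup alignment
  expect_equal(classify_sequence_fate(
    "ABSENT", og("PRESENT_MULTI", "ABSENT", "ABSENT", "ABSENT"),
    cfg)$sequence_fate, "UNCLASSIFIED")
  # missing outgroup call is an error
  expect_error(classify_sequence_fate("ABSENT", all_absent[1:3], cfg),
               "missing outgroup")
})

test_that("expression outcomes follow the threshold rules", {
  cfg <- classifier_config()
  focal <- list(max_tpm = 100, biased_tissues = "tA,tB")
  expect_equal(classify_expression_outcome(focal, silent_profile(), cfg),
               "NO_ACTIVITY")
  expect_equal(classify_expression_outcome(
    focal, list(max_tpm = 5, biased_tissues = "tA,tB"), cfg),
    "DIMINISHED")                                  # 5/100 < 0.1
  expect_equal(classify_expression_outcome(
    focal, list(max_tpm = 80, biased_tissues = "tA,tB"), cfg),
    "MATCHED")                                     # Jaccard 1
  expect_equal(classify_expression_outcome(
    focal, list(max_tpm = 80, biased_tissues = "tC"), cfg),
    "DIVERGENT")                                   # Jaccard 0
  # both bias sets empty count as matched
  expect_equal(classify_expression_outcome(
    list(max_tpm = 10, biased_tissues = ""),
    list(max_tpm = 9, biased_tissues = ""), cfg), "MATCHED")
  expect_error(classify_expression_outcome(focal, NULL, cfg), "required")
})

test_that("noise-free simulation is recovered exactly and labels map 1:1", {
  cfg <- noise_free_config(seed = 101L, n = 300L)
  ds <- simulate_dataset(cfg)
  cls <- classify_dataset(ds)
  sp <- cfg$species
  for (si in 1:2) {
    me <- sp[si]
    other <- sp[3 - si]
    oc <- cls$outcomes_by_species[[me]]
    ev <- ds$truth$event[ds$promoters[[me]]$truth_row]
    expected <- expected_sequence_fate(ev, me, other)
    expect_equal(oc$sequence_fate, expected)
    # expression labels with a wide decision margin map deterministically
    expect_true(all(oc$expression_outcome[
      ev == paste0("expression_lost_in_", other)] == "NO_ACTIVITY"))
    expect_true(all(oc$expression_outcome[
      ev == paste0("diminished_in_", other)] == "DIMINISHED"))
    # conserved promoters are never called silent or diminished
    cons <- ev == "ancestral_conserved"
    expect_false(any(oc$expression_outcome[cons] %in%
                       c("NO_ACTIVITY", "DIMINISHED")))
    expect_gt(mean(oc$expression_outcome[cons] == "MATCHED"), 0.95)
  }
  # every promoter receives exactly one fate
  expect_false(any(is.na(cls$outcomes$sequence_fate)))
  # noise-free lineage table equals the truth-derived table
  truth_tab <- matrix(c(
    sum(ds$truth$event == paste0("inserted_in_", sp[1])),
    sum(ds$truth$event == paste0("deleted_from_", sp[1])),
    sum(ds$truth$event == paste0("inserted_in_", sp[2])),
    sum(ds$truth$event == paste0("deleted_from_", sp[2]))
  ), nrow = 2, byrow = TRUE,
  dimnames = list(sp, c("insertions", "deletions")))
  expect_equal(cls$lineage_table, truth_tab)
})

test_that("swapping the focal species swaps insertion and deletion counts", {
  cfg <- noise_free_config(seed = 77L, n = 150L)
  ds <- simulate_dataset(cfg)
  cls <- classify_dataset(ds)
  sp <- cfg$species
  tab <- lineage_count_table(cls$outcomes, species_order = sp)
  tab_swapped <- lineage_count_table(cls$outcomes,
                                     species_order = rev(sp))
  expect_equal(tab_swapped[1, ], tab[2, ])
  expect_equal(tab_swapped[2, ], tab[1, ])
})

test_that("deletion bias reproduces the published 3.5-fold rodent excess", {
  tab <- matrix(c(2472, 2818, 2790, 11249), nrow = 2, byrow = TRUE,
                dimnames = list(c("human", "mouse"),
                                c("insertions", "deletions")))
  res <- deletion_bias_ratio(tab)
  expect_equal(round(res$fold, 1), 3.5)
  expect_lt(res$p_value, 2.2e-16)
  # equal ratios give fold 1
  eq <- matrix(c(10, 20, 30, 60), nrow = 2, byrow = TRUE)
  dimnames(eq) <- dimnames(tab)
  expect_equal(deletion_bias_ratio(eq)$fold, 1)
  # zero insertions leave the ratio undefined
  z <- matrix(c(0, 5, 3, 4), nrow = 2, byrow = TRUE)
  expect_error(deletion_bias_ratio(z), "zero")
})

test_that("chi-square statistic matches the textbook formula", {
  set.seed(33)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 50) + 1, nrow = 2,
                  dimnames = list(c("a", "b"), c("insertions",
                                                 "deletions")))
    res <- deletion_bias_ratio(tab)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    chi2 <- sum((tab - expected)^2 / expected)
    expect_equal(res$statistic, chi2, tolerance = 1e-12)
  }
})

test_that("tissue summary counts biased promoters and correlates species", {
  profiles <- data.frame(
    promoter_id = c("a1", "a2", "a3", "b1", "b2", "b3"),
    species = rep(c("sp1", "sp2"), each = 3),
    biased_tissues = c("tA", "tA,tB", "", "tA", "tA,tB", ""),
    stringsAsFactors = FALSE
  )
  outcomes <- data.frame(
    promoter_id = profiles$promoter_id,
    species = profiles$species,
    sequence_fate = rep("ALIGNED", 6),
    expression_outcome = rep("MATCHED", 6),
    evidence = "",
    stringsAsFactors = FALSE
  )
  ts <- tissue_outcome_summary(outcomes, profiles)
  tA <- ts$per_tissue[ts$per_tissue$tissue_type == "tA", ]
  expect_equal(tA$n_biased, c(2L, 2L))
  expect_equal(tA$prop_matched, c(1, 1))
  # all matched everywhere -> correlation degenerate, reported NA
  expect_true(is.na(ts$rho_matched_proportion))
  # a tissue with no biased promoters has missing proportions
  profiles$biased_tissues[4] <- "tC"
  ts2 <- tissue_outcome_summary(outcomes, profiles)
  tC1 <- ts2$per_tissue[ts2$per_tissue$tissue_type == "tC" &
                          ts2$per_tissue$species == "sp1", ]
  expect_equal(tC1$n_biased, 0L)
  expect_true(is.na(tC1$prop_matched))
})

test_that("per-tissue biased counts correlate perfectly for identical species", {
  # two species with identical per-tissue biased-promoter counts
  profiles <- data.frame(
    promoter_id = c(paste0("a", 1:6), paste0("b", 1:6)),
    species = rep(c("sp1", "sp2"), each = 6),
    biased_tissues = rep(c("tA", "tA", "tA", "tB", "tB", "tC"), 2),
    stringsAsFactors = FALSE
  )
  outcomes <- data.frame(
    promoter_id = profiles$promoter_id, species = profiles$species,
    sequence_fate = "ALIGNED",
    expression_outcome = rep(c("MATCHED", "DIVERGENT"), 6),
    evidence = "", stringsAsFactors = FALSE
  )
  ts <- tissue_outcome_summary(outcomes, profiles)
  expect_equal(ts$rho_biased_counts, 1)
})
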