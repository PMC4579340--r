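# Compensatory turnover statistic, gene categories and contingency
# enrichments.

make_outcome <- function(pid, species, fate, expr = NA_character_) {
  data.frame(promoter_id = pid, species = species, sequence_fate = fate,
             lineage_of_event = "none", expression_outcome = expr,
             evidence = "", stringsAsFactors = FALSE)
}

test_that("the four-promoter reciprocal-deletion gene has Tc = 2", {
  # promoters 1 and 3 conserved in both species; promoter 2 deleted in the
  # first lineage (survives in the second); promoter 4 deleted in the
  # second lineage (survives in the first)
  oc <- rbind(
    make_outcome(c("h1", "h3"), "human", "ALIGNED", "MATCHED"),
    make_outcome("h4", "human", "DELETED_IN_OPPOSING"),
    make_outcome(c("m1", "m3"), "mouse", "ALIGNED", "MATCHED"),
    make_outcome("m2", "mouse", "DELETED_IN_OPPOSING")
  )
  expressed <- setNames(rep(TRUE, 6),
                        c("human:h1", "human:h3", "human:h4",
                          "mouse:m1", "mouse:m3", "mouse:m2"))
  s <- compute_gene_summary("g1", oc, expressed, c("human", "mouse"))
  expect_equal(s$p_a, 3L)
  expect_equal(s$p_b, 3L)
  expect_equal(s$t_events, 2L)
  expect_equal(s$t_c, 2L)
  expect_true(s$compensatory)
  # both events are deletions (one per lineage): deaths exceed births,
  # with the compensatory pattern carried by Tc > 0
  expect_equal(s$category, "deaths_exceed_births")
})

test_that("single events and conserved complements are not compensatory", {
  # one insertion only: P = (2, 1), t = 1, Tc = 0
  oc <- rbind(
    make_outcome("h1", "human", "ALIGNED", "MATCHED"),
    make_outcome("h2", "human", "INSERTED"),
    make_outcome("m1", "mouse", "ALIGNED", "MATCHED")
  )
  expressed <- setNames(rep(TRUE, 3), c("human:h1", "human:h2",
                                        "mouse:m1"))
  s <- compute_gene_summary("g", oc, expressed, c("human", "mouse"))
  expect_equal(c(s$p_a, s$p_b, s$t_events, s$t_c), c(2L, 1L, 1L, 0L))
  expect_false(s$compensatory)

  # no events, identical complements
  oc2 <- rbind(make_outcome("h1", "human", "ALIGNED", "MATCHED"),
               make_outcome("m1", "mouse", "ALIGNED", "MATCHED"))
  s2 <- compute_gene_summary("g", oc2,
                             setNames(c(TRUE, TRUE),
                                      c("human:h1", "mouse:m1")),
                             c("human", "mouse"))
  expect_equal(s2$category, "conserved_architecture")
  expect_equal(s2$t_c, 0L)

  # expression loss only
  oc3 <- rbind(make_outcome("h1", "human", "ALIGNED", "NO_ACTIVITY"),
               make_outcome("m1", "mouse", "ALIGNED", "MATCHED"))
  s3 <- compute_gene_summary("g", oc3,
                             setNames(c(TRUE, TRUE),
                                      c("human:h1", "mouse:m1")),
                             c("human", "mouse"))
  expect_equal(s3$category, "expression_turnover_only")
  expect_equal(s3$t_events, 1L)
})

test_that("unclassified promoters are excluded from gene summaries", {
  oc <- rbind(
    make_outcome("h1", "human", "ALIGNED", "MATCHED"),
    make_outcome("h2", "human", "UNCLASSIFIED"),
    make_outcome("m1", "mouse", "ALIGNED", "MATCHED")
  )
  expressed <- setNames(rep(TRUE, 3), c("human:h1", "human:h2",
                                        "mouse:m1"))
  s <- compute_gene_summary("g", oc, expressed, c("human", "mouse"))
  expect_equal(s$p_a, 1L)
  expect_equal(s$t_events, 0L)
})

test_that("Tc properties hold over random gene configurations", {
  set.seed(99)
  for (i in seq_len(10000)) {
    births <- rpois(1, 0.7)
    deaths <- rpois(1, 0.7)
    expr_loss <- rpois(1, 0.4)
    shared <- rpois(1, 2)
    # assign events to lineages at random
    b_a <- if (births > 0) rbinom(1, births, 0.5) else 0L
    d_a <- if (deaths > 0) rbinom(1, deaths, 0.5) else 0L
    e_a <- if (expr_loss > 0) rbinom(1, expr_loss, 0.5) else 0L
    # promoter counts implied by the event configuration:
    # shared conserved + own insertions + survivors of opposing deletions
    # + own copy of promoters silent in the other species
    p_a <- shared + b_a + (deaths - d_a) + e_a
    p_b <- shared + (births - b_a) + d_a + (expr_loss - e_a)
    t_ev <- births + deaths + expr_loss
    t_c <- t_ev - abs(p_a - p_b)
    expect_gte(t_c, 0)
  }
})

test_that("adding a conserved promoter pair leaves t and Tc unchanged", {
  oc <- rbind(
    make_outcome("h1", "human", "INSERTED"),
    make_outcome("m1", "mouse", "ALIGNED", "MATCHED"),
    make_outcome("h2", "human", "ALIGNED", "MATCHED")
  )
  expressed <- setNames(rep(TRUE, 5),
                        c("human:h1", "human:h2", "human:h9",
                          "mouse:m1", "mouse:m9"))
  before <- compute_gene_summary("g", oc, expressed, c("human", "mouse"))
  oc_plus <- rbind(oc,
                   make_outcome("h9", "human", "ALIGNED", "MATCHED"),
                   make_outcome("m9", "mouse", "ALIGNED", "MATCHED"))
  after <- compute_gene_summary("g", oc_plus, expressed,
                                c("human", "mouse"))
  expect_equal(after$t_events, before$t_events)
  expect_equal(after$t_c, before$t_c)
  expect_equal(after$p_a, before$p_a + 1L)
  expect_equal(after$p_b, before$p_b + 1L)
})

test_that("noise-free gene census equals the truth-derived census", {
  cfg <- noise_free_config(seed = 202L, n = 300L)
  ds <- simulate_dataset(cfg)
  cls <- classify_dataset(ds)
  sp <- cfg$species
  all_prom <- do.call(rbind, lapply(sp, function(s) ds$promoters[[s]]))
  summaries <- gene_turnover_summaries(cls$outcomes, all_prom,
                                       ds$orthologs, cls$profiles,
                                       species_order = sp)
  census <- gene_category_census(summaries)
  expect_equal(sum(census$by_category), nrow(summaries))
  expect_true(all(summaries$t_c >= 0))
  expect_equal(summaries$t_c,
               summaries$t_events - abs(summaries$p_a - summaries$p_b))

  # truth-derived event counts per gene must match the summaries
  truth_events <- ds$truth$event[all_prom$truth_row]
  gene_plain <- sub("^[^.]*\\.", "", all_prom$gene_id)
  for (k in sample(which(!is.na(summaries$gene_id)), 25)) {
    g <- summaries$gene_id[k]
    g_plain <- sub("^[^.]*\\.", "", strsplit(g, "|", fixed = TRUE)[[1]][1])
    rows <- which(gene_plain == g_plain & !is.na(all_prom$gene_id))
    ev <- truth_events[rows]
    # sequence events appear once per truth promoter; count distinct
    anc <- ds$truth$ancestral_id[all_prom$truth_row[rows]]
    distinct <- !duplicated(anc)
    n_ins <- sum(grepl("^inserted_in_", ev[distinct]))
    n_del <- sum(grepl("^deleted_from_", ev[distinct]))
    n_lost <- sum(grepl("^expression_lost_in_", ev[distinct]))
    expect_equal(summaries$n_insertions[k], n_ins)
    expect_equal(summaries$n_deletions[k], n_del)
    expect_equal(summaries$n_expression_loss[k], n_lost)
  }
})

test_that("enrichment_2x2 computes folds, switches tests, and is antisymmetric", {
  e <- enrichment_2x2(c(170, 1000), c(100, 1000), test = "chisq")
  expect_equal(e$fold, 1.7)
  # identical proportions: fold 1, p ~ 1
  e2 <- enrichment_2x2(c(50, 500), c(50, 500), test = "chisq")
  expect_equal(e2$fold, 1)
  expect_gt(e2$p_value, 0.99)
  # small expected cells switch to Fisher automatically
  e3 <- enrichment_2x2(c(3, 10), c(9, 12))
  expect_equal(e3$test_used, "fisher")
  # Fisher p equals exhaustive hypergeometric enumeration
  expect_equal(e3$p_value, oracle_fisher_p(3, 7, 9, 3), tolerance = 1e-12)
  # antisymmetry of the fold
  set.seed(4)
  for (i in 1:20) {
    ga <- c(sample(1:40, 1), 50)
    gb <- c(sample(1:40, 1), 60)
    ab <- enrichment_2x2(ga, gb, test = "chisq")$fold
    ba <- enrichment_2x2(gb, ga, test = "chisq")$fold
    expect_equal(ab * ba, 1, tolerance = 1e-12)
  }
  # zero hits in the reference group flags an infinite fold
  e4 <- enrichment_2x2(c(5, 10), c(0, 10))
  expect_true(e4$fold_infinite)
})

test_that("gene enrichment report emits BH-adjusted p-values", {
  summaries <- data.frame(
    gene_id = paste0("g", 1:300),
    category = rep(c("conserved_architecture", "births_exceed_deaths",
                     "deaths_exceed_births"), each = 100),
    stringsAsFactors = FALSE
  )
  flagged <- c(paste0("g", 101:140), paste0("g", 1:10))
  rep_tab <- gene_enrichment_report(summaries, flagged)
  row <- rep_tab[rep_tab$category == "births_exceed_deaths", ]
  expect_equal(row$hits, 40)
  expect_equal(row$fold, (40 / 100) / (10 / 100))
  expect_true(all(rep_tab$fdr >= rep_tab$p_value - 1e-12, na.rm = TRUE))
})

test_that("gene category census on empty input is all zero", {
  empty <- data.frame(gene_id = character(), category = character(),
                      compensatory = logical(), stringsAsFactors = FALSE)
  census <- gene_category_census(empty)
  expect_equal(sum(census$by_category), 0L)
})
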