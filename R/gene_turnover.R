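# Gene-level aggregation of promoter outcomes: compensatory-turnover
# statistic Tc = t - |P_a - P_b|, gene categories, and generic 2x2
# contingency enrichments.

GENE_CATEGORIES <- c("conserved_architecture", "births_exceed_deaths",
                     "deaths_exceed_births", "balanced",
                     "expression_turnover_only")

#' Summarise promoter turnover for one orthologous gene
#'
#' Counts expressed promoters per species (P_a, P_b), turnover events t
#' (insertions, deletions in the opposing lineage, and complete expression
#' loss — diminished expression is not an event), and the compensatory
#' statistic Tc = t - |P_a - P_b|; a gene is compensatory when Tc > 0.
#' Promoters with an UNCLASSIFIED fate are excluded before counting.
#'
#' @param gene_id Gene identifier (ortholog pair label).
#' @param outcomes Outcome rows for this gene's promoters in both species.
#' @param expressed Named logical vector: promoter (species-qualified key
#'   `species:promoter_id`) is expressed (max TPM > 0).
#' @param species_order The two focal species, first = species "a".
#' @return One-row data.frame: `gene_id`, `p_a`, `p_b`, `t_events`,
#'   `n_insertions`, `n_deletions`, `n_expression_loss`, `t_c`,
#'   `compensatory`, `category`.
#' @export
compute_gene_summary <- function(gene_id, outcomes, expressed,
                                 species_order) {
  stopifnot(length(species_order) == 2L)
  oc <- outcomes[outcomes$sequence_fate != "UNCLASSIFIED", , drop = FALSE]
  key <- paste(oc$species, oc$promoter_id, sep = ":")
  expr <- expressed[key]
  expr[is.na(expr)] <- FALSE
  p_a <- sum(oc$species == species_order[1L] & expr)
  p_b <- sum(oc$species == species_order[2L] & expr)
  births <- sum(oc$sequence_fate == "INSERTED")
  deaths <- sum(oc$sequence_fate == "DELETED_IN_OPPOSING")
  expr_loss <- sum(oc$sequence_fate == "ALIGNED" &
                     !is.na(oc$expression_outcome) &
                     oc$expression_outcome == "NO_ACTIVITY")
  t_events <- births + deaths + expr_loss
  t_c <- t_events - abs(p_a - p_b)
  category <- if (t_events == 0L) {
    "conserved_architecture"
  } else if (births == 0L && deaths == 0L) {
    "expression_turnover_only"
  } else if (births > deaths) {
    "births_exceed_deaths"
  } else if (deaths > births) {
    "deaths_exceed_births"
  } else {
    "balanced"
  }
  data.frame(
    gene_id = gene_id, p_a = p_a, p_b = p_b, t_events = t_events,
    n_insertions = births, n_deletions = deaths,
    n_expression_loss = expr_loss, t_c = t_c,
    compensatory = t_c > 0L, category = category,
    stringsAsFactors = FALSE
  )
}

#' Gene turnover summaries for every 1:1 ortholog pair
#'
#' @param outcomes Combined outcome data.frame for both species.
#' @param promoters Combined promoter data.frame (supplies `gene_id`).
#' @param orthologs Data.frame with `gene_id_a`, `gene_id_b` (1:1 pairs).
#' @param profiles Combined expression profiles (supplies `max_tpm` for the
#'   expressed-promoter counts).
#' @param species_order The two focal species; defaults to order of
#'   appearance in `promoters`.
#' @return Data.frame, one row per ortholog pair with at least one
#'   classified promoter, as in [compute_gene_summary()].
#' @export
gene_turnover_summaries <- function(outcomes, promoters, orthologs,
                                    profiles,
                                    species_order =
                                      unique(promoters$species)) {
  stopifnot(length(species_order) == 2L)
  gene_of <- promoters$gene_id
  names(gene_of) <- paste(promoters$species, promoters$promoter_id,
                          sep = ":")
  expressed <- profiles$max_tpm > 0
  names(expressed) <- paste(profiles$species, profiles$promoter_id,
                            sep = ":")

  # map each species-specific gene id to the ortholog pair label
  pair_label <- paste(orthologs$gene_id_a, orthologs$gene_id_b, sep = "|")
  pair_of <- c(stats::setNames(pair_label, orthologs$gene_id_a),
               stats::setNames(pair_label, orthologs$gene_id_b))

  okey <- paste(outcomes$species, outcomes$promoter_id, sep = ":")
  ogene <- gene_of[okey]
  opair <- pair_of[ogene]
  keep <- !is.na(opair)
  oc <- outcomes[keep, , drop = FALSE]
  opair <- opair[keep]
  if (nrow(oc) == 0L) {
    return(data.frame(gene_id = character(), p_a = integer(),
                      p_b = integer(), t_events = integer(),
                      n_insertions = integer(), n_deletions = integer(),
                      n_expression_loss = integer(), t_c = integer(),
                      compensatory = logical(), category = character(),
                      stringsAsFactors = FALSE))
  }
  pieces <- lapply(split(seq_len(nrow(oc)), opair), function(idx) {
    compute_gene_summary(opair[idx[1L]], oc[idx, , drop = FALSE],
                         expressed, species_order)
  })
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  res
}

#' Census of gene turnover categories
#'
#' @param summaries Output of [gene_turnover_summaries()].
#' @return List with `by_category` (named counts over all categories) and
#'   `by_category_compensatory` (category x compensatory table).
#' @export
gene_category_census <- function(summaries) {
  cat <- factor(summaries$category, levels = GENE_CATEGORIES)
  comp <- factor(summaries$compensatory, levels = c(FALSE, TRUE),
                 labels = c("not_compensatory", "compensatory"))
  list(by_category = table(cat),
       by_category_compensatory = table(cat, comp))
}

#' Generic 2x2 contingency enrichment
#'
#' Compares hit proportions between two groups: fold change of proportions,
#' odds ratio, and a chi-square test (no continuity correction) that
#' switches automatically to Fisher's exact test when any expected cell is
#' below 5 (recorded in `test_used`).
#'
#' @param group_a,group_b Length-2 numeric vectors `(hits, total)`.
#' @param test "auto" (default), "chisq" or "fisher".
#' @return List of class `contingency_result`: `table`, `fold`,
#'   `odds_ratio`, `p_value`, `test_used`, `fold_infinite`.
#' @export
enrichment_2x2 <- function(group_a, group_b, test = c("auto", "chisq",
                                                      "fisher")) {
  test <- match.arg(test)
  stopifnot(length(group_a) == 2L, length(group_b) == 2L,
            group_a[1L] <= group_a[2L], group_b[1L] <= group_b[2L],
            all(c(group_a, group_b) >= 0))
  m <- matrix(c(group_a[1L], group_a[2L] - group_a[1L],
                group_b[1L], group_b[2L] - group_b[1L]),
              nrow = 2L, byrow = TRUE,
              dimnames = list(c("group_a", "group_b"),
                              c("hits", "non_hits")))
  pa <- group_a[1L] / group_a[2L]
  pb <- group_b[1L] / group_b[2L]
  fold_infinite <- group_b[1L] == 0 && group_a[1L] > 0
  fold <- if (fold_infinite) Inf else pa / pb
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  if (test == "auto") {
    expected <- suppressWarnings(stats::chisq.test(m, correct =
                                                     FALSE)$expected)
    test <- if (any(expected < 5)) "fisher" else "chisq"
  }
  p <- if (test == "fisher") {
    stats::fisher.test(m)$p.value
  } else {
    suppressWarnings(stats::chisq.test(m, correct = FALSE))$p.value
  }
  structure(list(table = m, fold = fold, odds_ratio = or, p_value = p,
                 test_used = test, fold_infinite = fold_infinite),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("2x2 contingency enrichment (", x$test_used, " test)\n", sep = "")
  print(x$table)
  cat(sprintf("fold = %.3g, odds ratio = %.3g, p = %.3g\n",
              x$fold, x$odds_ratio, x$p_value))
  invisible(x)
}

#' Category enrichment report against a gene flag
#'
#' For each turnover category (vs the conserved-architecture baseline),
#' tests whether flagged genes (e.g. genes under coding-sequence positive
#' selection, genes with paralogs) are enriched. Raw p-values and
#' Benjamini-Hochberg FDR are both reported.
#'
#' @param summaries Output of [gene_turnover_summaries()].
#' @param flagged_genes Character vector of flagged gene_id values (pair
#'   labels as used in the summaries).
#' @return Data.frame: category, hits/totals for category and baseline,
#'   fold, odds_ratio, p_value, fdr, test_used.
#' @export
gene_enrichment_report <- function(summaries, flagged_genes) {
  base <- summaries$category == "conserved_architecture"
  base_hits <- sum(summaries$gene_id[base] %in% flagged_genes)
  base_total <- sum(base)
  cats <- setdiff(GENE_CATEGORIES, "conserved_architecture")
  rows <- lapply(cats, function(cc) {
    sel <- summaries$category == cc
    hits <- sum(summaries$gene_id[sel] %in% flagged_genes)
    total <- sum(sel)
    if (total == 0L || base_total == 0L) {
      return(data.frame(category = cc, hits = hits, total = total,
                        baseline_hits = base_hits,
                        baseline_total = base_total,
                        fold = NA_real_, odds_ratio = NA_real_,
                        p_value = NA_real_, test_used = NA_character_,
                        stringsAsFactors = FALSE))
    }
    e <- enrichment_2x2(c(hits, total), c(base_hits, base_total))
    data.frame(category = cc, hits = hits, total = total,
               baseline_hits = base_hits, baseline_total = base_total,
               fold = e$fold, odds_ratio = e$odds_ratio,
               p_value = e$p_value, test_used = e$test_used,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out
}
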