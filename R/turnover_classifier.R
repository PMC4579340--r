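# Resolution of each promoter's evolutionary fate from dual-source alignment
# statuses, outgroup presence, and expression at the projected locus.

#' Classifier configuration
#'
#' Decision thresholds for the evolutionary-outcome taxonomy. The alignment
#' sources name the categories; the numeric cutoffs are package decisions and
#' are reported in output metadata.
#'
#' @param outgroup_species Ordered outgroup list (default dog, horse, cow,
#'   pig).
#' @param absence_max_aligned_fraction ALIGNED projections with a smaller
#'   aligned fraction count as absent (default 0.5).
#' @param diminished_ratio Opposing/focal max-TPM ratio below which
#'   expression is "diminished" (default 0.1).
#' @param matched_min_jaccard Minimum Jaccard similarity of biased-tissue
#'   sets for "matched" expression (default 0.5).
#' @param activity_floor_tpm Max TPM at or below which an opposing locus
#'   counts as silent (default 0).
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(outgroup_species = c("dog", "horse", "cow",
                                                   "pig"),
                              absence_max_aligned_fraction = 0.5,
                              diminished_ratio = 0.1,
                              matched_min_jaccard = 0.5,
                              activity_floor_tpm = 0) {
  assert_prob(absence_max_aligned_fraction, "absence_max_aligned_fraction")
  assert_prob(diminished_ratio, "diminished_ratio")
  assert_prob(matched_min_jaccard, "matched_min_jaccard")
  assert_nonneg(activity_floor_tpm, "activity_floor_tpm")
  structure(list(
    outgroup_species = outgroup_species,
    absence_max_aligned_fraction = absence_max_aligned_fraction,
    diminished_ratio = diminished_ratio,
    matched_min_jaccard = matched_min_jaccard,
    activity_floor_tpm = activity_floor_tpm
  ), class = "classifier_config")
}

# Per-source presence call for vectors of status/fraction.
source_call <- function(status, fraction, threshold) {
  ifelse(status == "MULTI", "multi",
         ifelse(status == "ALIGNED" & fraction >= threshold,
                "present", "absent"))
}

#' Combine dual-source alignment statuses into a presence call
#'
#' Per source, an ALIGNED projection with aligned fraction at or above the
#' absence threshold counts as present; GAPPED/UNMAPPED (or a sub-threshold
#' ALIGNED) counts as absent; MULTI marks multi-locus projection. A missing
#' source row is treated as UNMAPPED. Combined across the two sources: any
#' MULTI gives PRESENT_MULTI; agreement gives that call; present/absent
#' disagreement gives CONFLICT.
#'
#' @param statuses Alignment-status rows for one promoter in one target
#'   species (data.frame with `source`, `status`, `aligned_fraction`).
#' @param config A [classifier_config()].
#' @return One of "PRESENT_UNIQUE", "PRESENT_MULTI", "ABSENT", "CONFLICT".
#' @export
presence_call <- function(statuses, config = classifier_config()) {
  thr <- config$absence_max_aligned_fraction
  calls <- c(msa = "absent", pairwise = "absent")
  if (nrow(statuses) > 0L) {
    sc <- source_call(statuses$status, statuses$aligned_fraction, thr)
    calls[statuses$source] <- sc
  }
  combine_source_calls(calls[["msa"]], calls[["pairwise"]])
}

combine_source_calls <- function(msa, pairwise) {
  if (msa == "multi" || pairwise == "multi") return("PRESENT_MULTI")
  if (msa == pairwise) {
    return(if (msa == "present") "PRESENT_UNIQUE" else "ABSENT")
  }
  "CONFLICT"
}

# Vectorized presence calls for a whole alignment-status table.
# Returns data.frame: promoter_id, target_species, call.
presence_calls_table <- function(status_df, config) {
  thr <- config$absence_max_aligned_fraction
  sc <- source_call(status_df$status, status_df$aligned_fraction, thr)
  key <- paste(status_df$promoter_id, status_df$target_species, sep = "\r")
  msa <- sc[status_df$source == "msa"]
  names(msa) <- key[status_df$source == "msa"]
  pw <- sc[status_df$source == "pairwise"]
  names(pw) <- key[status_df$source == "pairwise"]
  all_keys <- unique(key)
  m <- unname(msa[all_keys])
  p <- unname(pw[all_keys])
  m[is.na(m)] <- "absent"
  p[is.na(p)] <- "absent"
  call <- ifelse(m == "multi" | p == "multi", "PRESENT_MULTI",
                 ifelse(m == p,
                        ifelse(m == "present", "PRESENT_UNIQUE", "ABSENT"),
                        "CONFLICT"))
  parts <- strsplit(all_keys, "\r", fixed = TRUE)
  data.frame(
    promoter_id = vapply(parts, `[`, character(1), 1L),
    target_species = vapply(parts, `[`, character(1), 2L),
    call = call,
    stringsAsFactors = FALSE
  )
}

#' Classify a promoter's sequence fate from presence calls
#'
#' A promoter absent from the opposing species and from all four outgroups
#' is a lineage-specific insertion; absent from the opposing species but
#' uniquely present in at least one outgroup, it was deleted in the opposing
#' lineage; uniquely present in the opposing species, it is aligned. Any
#' CONFLICT among the opposing/outgroup calls, a multi-locus opposing
#' projection, or deletion support resting only on multi-locus outgroup
#' alignments leaves the promoter unclassified.
#'
#' @param opposing_call Presence call in the opposing focal species.
#' @param outgroup_calls Named character vector of presence calls, one per
#'   configured outgroup.
#' @param config A [classifier_config()].
#' @return List with `sequence_fate` and `lineage_of_event`.
#' @export
classify_sequence_fate <- function(opposing_call, outgroup_calls,
                                   config = classifier_config()) {
  missing_og <- setdiff(config$outgroup_species, names(outgroup_calls))
  if (length(missing_og) > 0L) {
    stop("missing outgroup presence call(s): ",
         paste(missing_og, collapse = ", "), call. = FALSE)
  }
  og <- outgroup_calls[config$outgroup_species]
  if (opposing_call == "CONFLICT" || any(og == "CONFLICT") ||
        opposing_call == "PRESENT_MULTI") {
    return(list(sequence_fate = "UNCLASSIFIED", lineage_of_event = "none"))
  }
  if (opposing_call == "PRESENT_UNIQUE") {
    return(list(sequence_fate = "ALIGNED", lineage_of_event = "none"))
  }
  # opposing ABSENT: resolve insertion vs deletion with the outgroups
  if (all(og == "ABSENT")) {
    return(list(sequence_fate = "INSERTED", lineage_of_event = "focal"))
  }
  if (any(og == "PRESENT_UNIQUE")) {
    return(list(sequence_fate = "DELETED_IN_OPPOSING",
                lineage_of_event = "opposing"))
  }
  # ancestral presence supported only by multi-locus outgroup alignments
  list(sequence_fate = "UNCLASSIFIED", lineage_of_event = "none")
}

#' Classify the expression outcome at an aligned promoter
#'
#' The opposing locus is silent (max TPM at or below the activity floor) —
#' no promoter activity; expressed but far below the focal level — diminished;
#' otherwise matched when the biased-tissue sets are similar (Jaccard at or
#' above the threshold, or both empty), else divergent.
#'
#' @param focal_profile,opposing_profile Single-row expression profiles
#'   (lists/rows with `max_tpm` and `biased_tissues`). For silent loci pass
#'   [silent_profile()].
#' @param config A [classifier_config()].
#' @return One of "MATCHED", "DIVERGENT", "DIMINISHED", "NO_ACTIVITY".
#' @export
classify_expression_outcome <- function(focal_profile, opposing_profile,
                                        config = classifier_config()) {
  if (is.null(opposing_profile)) {
    stop("opposing expression profile is required", call. = FALSE)
  }
  opp_max <- opposing_profile$max_tpm
  if (opp_max <= config$activity_floor_tpm) return("NO_ACTIVITY")
  if (opp_max < config$diminished_ratio * focal_profile$max_tpm) {
    return("DIMINISHED")
  }
  bt_f <- split_tissues(focal_profile$biased_tissues)
  bt_o <- split_tissues(opposing_profile$biased_tissues)
  if (length(bt_f) == 0L && length(bt_o) == 0L) return("MATCHED")
  j <- jaccard(bt_f, bt_o)
  if (!is.nan(j) && j >= config$matched_min_jaccard) "MATCHED" else
    "DIVERGENT"
}

#' Profile of a silent (non-promoter) locus
#' @return A one-row profile with zero expression and no biased tissues.
#' @export
silent_profile <- function() {
  list(max_tpm = 0, median_tpm = 0, biased_tissues = "",
       breadth = "tissue_restricted")
}

# Pick the opposing-locus interval from a promoter's status rows:
# prefer the msa projection, fall back to pairwise.
opposing_locus <- function(rows) {
  aligned <- rows[rows$status == "ALIGNED" & !is.na(rows$target_chrom), ,
                  drop = FALSE]
  if (nrow(aligned) == 0L) return(NULL)
  pref <- aligned[order(match(aligned$source, c("msa", "pairwise"))), ,
                  drop = FALSE]
  pref[1L, c("target_chrom", "target_start", "target_end", "target_strand")]
}

#' Classify every promoter of one focal species
#'
#' Runs presence calls, sequence-fate resolution and (for aligned promoters)
#' expression-outcome classification against the opposing species. The
#' opposing locus of an aligned promoter is mapped to an opposing-species
#' promoter by interval overlap of the projected coordinates; loci that
#' overlap no opposing promoter are treated as silent sequence.
#'
#' @param promoters Focal-species promoter data.frame.
#' @param status Alignment-status table for the focal species' promoters.
#' @param profiles Focal-species expression profiles.
#' @param opposing_promoters,opposing_profiles The opposing species'
#'   promoters and profiles.
#' @param opposing_species Name of the opposing species in `status`.
#' @param config A [classifier_config()].
#' @return Data.frame of evolutionary outcomes: `promoter_id`, `species`,
#'   `sequence_fate`, `lineage_of_event`, `expression_outcome`,
#'   `opposing_promoter_id`, `evidence` (JSON of per-species presence
#'   calls).
#' @export
classify_promoters <- function(promoters, status, profiles,
                               opposing_promoters, opposing_profiles,
                               opposing_species,
                               config = classifier_config()) {
  calls <- presence_calls_table(status, config)
  call_key <- paste(calls$promoter_id, calls$target_species, sep = "\r")
  call_map <- calls$call
  names(call_map) <- call_key
  get_call <- function(pid, sp) {
    v <- call_map[paste(pid, sp, sep = "\r")]
    ifelse(is.na(v), "ABSENT", v)
  }

  n <- nrow(promoters)
  pid <- promoters$promoter_id
  opp_call <- unname(get_call(pid, opposing_species))
  og_calls <- vapply(config$outgroup_species,
                     function(sp) unname(get_call(pid, sp)),
                     character(n))
  if (n == 1L) og_calls <- matrix(og_calls, nrow = 1L,
                                  dimnames = list(NULL,
                                                  config$outgroup_species))

  fate <- character(n)
  lineage <- character(n)
  for (i in seq_len(n)) {
    r <- classify_sequence_fate(opp_call[i],
                                stats::setNames(og_calls[i, ],
                                                config$outgroup_species),
                                config)
    fate[i] <- r$sequence_fate
    lineage[i] <- r$lineage_of_event
  }

  # map aligned promoters to opposing promoters via projected coordinates
  opp_gr <- intervals_to_granges(opposing_promoters, use_strand = FALSE)
  prof_idx <- match(pid, profiles$promoter_id)
  opp_prof_idx <- match(opposing_promoters$promoter_id,
                        opposing_profiles$promoter_id)

  expr_out <- rep(NA_character_, n)
  opp_pid <- rep(NA_character_, n)
  aligned_idx <- which(fate == "ALIGNED")
  if (length(aligned_idx) > 0L) {
    loci <- lapply(aligned_idx, function(i) {
      rows <- status[status$promoter_id == pid[i] &
                       status$target_species == opposing_species, ,
                     drop = FALSE]
      opposing_locus(rows)
    })
    has_locus <- !vapply(loci, is.null, logical(1))
    locus_df <- if (any(has_locus)) do.call(rbind, loci[has_locus]) else NULL
    hit_id <- rep(NA_character_, length(aligned_idx))
    if (!is.null(locus_df)) {
      lg <- GenomicRanges::GRanges(
        locus_df$target_chrom,
        IRanges::IRanges(locus_df$target_start + 1L, locus_df$target_end)
      )
      h <- harmonize_seqlevels(lg, opp_gr)
      lg <- h[[1L]]
      opp_gr <- h[[2L]]
      ov <- GenomicRanges::findOverlaps(lg, opp_gr, minoverlap = 1L)
      if (length(ov) > 0L) {
        # keep the opposing promoter with the largest overlap per locus
        width <- GenomicRanges::width(IRanges::pintersect(
          lg[S4Vectors::queryHits(ov)], opp_gr[S4Vectors::subjectHits(ov)]
        ))
        best <- tapply(seq_along(width), S4Vectors::queryHits(ov),
                       function(ii) ii[which.max(width[ii])])
        qh <- as.integer(names(best))
        hit_id[which(has_locus)[qh]] <-
          opposing_promoters$promoter_id[S4Vectors::subjectHits(ov)[unlist(best)]]
      }
    }
    for (k in seq_along(aligned_idx)) {
      i <- aligned_idx[k]
      focal_prof <- profiles[prof_idx[i], , drop = FALSE]
      opp_profile <- if (is.na(hit_id[k])) {
        silent_profile()
      } else {
        j <- opp_prof_idx[match(hit_id[k], opposing_promoters$promoter_id)]
        opposing_profiles[j, , drop = FALSE]
      }
      expr_out[i] <- classify_expression_outcome(focal_prof, opp_profile,
                                                 config)
      opp_pid[i] <- hit_id[k]
    }
  }

  evidence <- vapply(seq_len(n), function(i) {
    ev <- c(stats::setNames(opp_call[i], opposing_species),
            stats::setNames(og_calls[i, ], config$outgroup_species))
    as.character(jsonlite::toJSON(as.list(ev), auto_unbox = TRUE))
  }, character(1))

  data.frame(
    promoter_id = pid,
    species = promoters$species,
    sequence_fate = fate,
    lineage_of_event = lineage,
    expression_outcome = expr_out,
    opposing_promoter_id = opp_pid,
    evidence = evidence,
    stringsAsFactors = FALSE
  )
}

#' Lineage insertion/deletion count table
#'
#' Insertions in a lineage are that species' promoters classified INSERTED;
#' deletions in a lineage are the opposing species' promoters classified
#' DELETED_IN_OPPOSING.
#'
#' @param outcomes Combined outcome data.frame for both focal species.
#' @param species_order Character vector of the two species, ordering the
#'   rows; defaults to order of appearance.
#' @return 2 x 2 integer matrix (rows species, columns
#'   insertions/deletions).
#' @export
lineage_count_table <- function(outcomes,
                                species_order = unique(outcomes$species)) {
  stopifnot(length(species_order) == 2L)
  a <- species_order[1L]
  b <- species_order[2L]
  cnt <- function(sp, fate) {
    sum(outcomes$species == sp & outcomes$sequence_fate == fate)
  }
  m <- matrix(c(cnt(a, "INSERTED"), cnt(b, "DELETED_IN_OPPOSING"),
                cnt(b, "INSERTED"), cnt(a, "DELETED_IN_OPPOSING")),
              nrow = 2L, byrow = TRUE,
              dimnames = list(species_order, c("insertions", "deletions")))
  m
}

#' Deletion bias between lineages
#'
#' Fold change of the deletion:insertion ratio in the second lineage over
#' the first, with a chi-square test (no continuity correction) on the 2 x 2
#' count table. With the published lineage counts this reproduces the
#' 3.5-fold rodent deletion excess.
#'
#' @param table 2 x 2 count matrix as from [lineage_count_table()], rows =
#'   the two lineages, columns = insertions, deletions.
#' @param fisher Use Fisher's exact test instead of chi-square (for small
#'   tables).
#' @return List with `fold`, `statistic`, `p_value`, `test`.
#' @export
deletion_bias_ratio <- function(table, fisher = FALSE) {
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  if (any(table[, 1L] == 0)) {
    stop("insertion count of zero: deletion:insertion ratio undefined",
         call. = FALSE)
  }
  r1 <- table[1L, 2L] / table[1L, 1L]
  r2 <- table[2L, 2L] / table[2L, 1L]
  fold <- r2 / r1
  if (fisher) {
    ft <- stats::fisher.test(table)
    list(fold = fold, statistic = NA_real_, p_value = ft$p.value,
         test = "fisher")
  } else {
    ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
    list(fold = fold, statistic = unname(ct$statistic),
         p_value = ct$p.value, test = "chisq")
  }
}

#' Per-tissue summary of evolutionary outcomes
#'
#' For every tissue type and species, counts and proportions of each
#' outcome among the promoters biased to that tissue, plus Spearman rank
#' correlations between the two species of per-tissue biased-promoter
#' counts and of matched proportions. Tissues with zero biased promoters
#' get missing (NA) proportions. Degenerate correlations (no variation) are
#' reported as NA.
#'
#' @param outcomes Combined outcome data.frame for both species.
#' @param profiles Combined profile data.frame for both species (with
#'   `species` and `biased_tissues` columns).
#' @return List with `per_tissue` (data.frame), `rho_biased_counts`,
#'   `rho_matched_proportion`.
#' @export
tissue_outcome_summary <- function(outcomes, profiles) {
  key <- paste(profiles$species, profiles$promoter_id)
  okey <- paste(outcomes$species, outcomes$promoter_id)
  out_label <- ifelse(outcomes$sequence_fate == "ALIGNED",
                      outcomes$expression_outcome, outcomes$sequence_fate)
  label_map <- out_label
  names(label_map) <- okey

  labels <- c("INSERTED", "DELETED_IN_OPPOSING", "MATCHED", "DIVERGENT",
              "DIMINISHED", "NO_ACTIVITY", "UNCLASSIFIED")
  species <- unique(profiles$species)
  tissues <- sort(unique(unlist(lapply(profiles$biased_tissues,
                                       split_tissues))))
  rows <- list()
  for (sp in species) {
    sel <- profiles$species == sp
    bias_sets <- lapply(profiles$biased_tissues[sel], split_tissues)
    pids <- profiles$promoter_id[sel]
    for (tt in tissues) {
      in_t <- vapply(bias_sets, function(s) tt %in% s, logical(1))
      ids <- pids[in_t]
      lab <- label_map[paste(sp, ids)]
      n <- length(ids)
      counts <- vapply(labels, function(l) sum(lab == l, na.rm = TRUE),
                       integer(1))
      props <- if (n > 0L) counts / n else rep(NA_real_, length(labels))
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, tissue_type = tt, n_biased = n,
        t(stats::setNames(counts, paste0("n_", tolower(labels)))),
        t(stats::setNames(props, paste0("prop_", tolower(labels)))),
        stringsAsFactors = FALSE
      )
    }
  }
  per_tissue <- do.call(rbind, rows)

  rho <- function(col) {
    if (length(species) != 2L) return(NA_real_)
    a <- per_tissue[per_tissue$species == species[1L], col]
    b <- per_tissue[per_tissue$species == species[2L], col]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3L || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
      return(NA_real_)
    }
    suppressWarnings(stats::cor(a[ok], b[ok], method = "spearman"))
  }
  list(per_tissue = per_tissue,
       rho_biased_counts = rho("n_biased"),
       rho_matched_proportion = rho("prop_matched"))
}
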