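# Readers and writers for every on-disk format the pipeline touches.
#
# Conventions: all coordinates are 0-based half-open everywhere inside the
# package; BED/bedGraph files are read and written unchanged, 1-based sources
# (VCF) pass through to_zero_based(). Gzip input is handled transparently.
# Writers prepend a single dialect-version comment line.

DIALECT_COMMENT <- "# promoterTurnover dialect v1"

ALIGNMENT_STATUS_COLS <- c(
  "promoter_id", "target_species", "source", "status",
  "target_chrom", "target_start", "target_end", "target_strand",
  "aligned_fraction"
)

VARIANT_COLS <- c("chrom", "pos", "ref", "alt", "ancestral", "alt_frequency")

read_table_lines <- function(path) {
  con <- open_input(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a BED file of genomic intervals
#'
#' Accepts 3- to 6-column BED. Coordinates are kept 0-based half-open.
#' The name column (4) is used as the interval/promoter identifier; scores
#' (column 5) are read but otherwise ignored.
#'
#' @param path Path to a BED file (optionally gzipped).
#' @param expect_strand If `TRUE`, require a strand column (6 columns).
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path, expect_strand = FALSE) {
  tl <- read_table_lines(path)
  empty <- data.frame(
    chrom = character(), start = integer(), end = integer(),
    name = character(), score = numeric(), strand = character(),
    stringsAsFactors = FALSE
  )
  if (length(tl$lines) == 0L) return(empty)
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- which(nf < 3L)[1L]
    stop(sprintf("malformed BED line %d in %s: fewer than 3 fields",
                 tl$lineno[bad], path), call. = FALSE)
  }
  if (expect_strand && any(nf < 6L)) {
    bad <- which(nf < 6L)[1L]
    stop(sprintf("BED line %d in %s: strand column required but absent",
                 tl$lineno[bad], path), call. = FALSE)
  }
  get_col <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default,
           character(1))
  }
  start <- suppressWarnings(as.integer(get_col(2L, NA_character_)))
  end <- suppressWarnings(as.integer(get_col(3L, NA_character_)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1L]
    stop(sprintf("malformed BED line %d in %s: non-numeric coordinates",
                 tl$lineno[bad], path), call. = FALSE)
  }
  if (any(start < 0L) || any(start >= end)) {
    bad <- which(start < 0L | start >= end)[1L]
    stop(sprintf("BED line %d in %s: requires 0 <= start < end",
                 tl$lineno[bad], path), call. = FALSE)
  }
  strand <- get_col(6L, ".")
  if (any(!strand %in% c("+", "-", "."))) {
    bad <- which(!strand %in% c("+", "-", "."))[1L]
    stop(sprintf("BED line %d in %s: invalid strand '%s'",
                 tl$lineno[bad], path, strand[bad]), call. = FALSE)
  }
  data.frame(
    chrom = get_col(1L, NA_character_),
    start = start, end = end,
    name = get_col(4L, "."),
    score = suppressWarnings(as.numeric(get_col(5L, "0"))),
    strand = strand,
    stringsAsFactors = FALSE
  )
}

#' Write intervals to a BED6 file
#'
#' @param df Data.frame with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand` columns.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(
    chrom = df$chrom,
    start = df$start,
    end = df$end,
    name = if ("name" %in% names(df)) df$name else ".",
    score = if ("score" %in% names(df)) df$score else 0,
    strand = if ("strand" %in% names(df)) df$strand else ".",
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph score track
#'
#' @param path Path to a bedGraph file.
#' @return Data.frame with `chrom`, `start`, `end`, `score` (0-based
#'   half-open intervals).
#' @export
read_bedgraph <- function(path) {
  tl <- read_table_lines(path)
  if (length(tl$lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L)) {
    bad <- which(lengths(fields) < 4L)[1L]
    stop(sprintf("malformed bedGraph line %d in %s", tl$lineno[bad], path),
         call. = FALSE)
  }
  m <- do.call(rbind, fields)
  df <- data.frame(
    chrom = m[, 1L],
    start = as.integer(m[, 2L]),
    end = as.integer(m[, 3L]),
    score = as.numeric(m[, 4L]),
    stringsAsFactors = FALSE
  )
  if (any(df$start < 0L) || any(df$start >= df$end)) {
    stop("bedGraph intervals must satisfy 0 <= start < end: ", path,
         call. = FALSE)
  }
  df
}

#' Write a bedGraph score track
#' @param df Data.frame with `chrom`, `start`, `end`, `score`.
#' @param path Output path.
#' @export
write_bedgraph <- function(df, path) {
  utils::write.table(df[, c("chrom", "start", "end", "score")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read promoter records from BED plus a promoter annotation table
#'
#' The BED name column carries the promoter identifier; promoter class and
#' gene assignment live in a separate TSV (`promoter_id`, `promoter_class`,
#' `gene_id`) so the BED stays standard.
#'
#' @param bed_path BED6 file of promoter intervals.
#' @param species Species identifier attached to every record.
#' @param genemap_path Optional annotation TSV; "." or empty gene_id means
#'   unassigned.
#' @return Data.frame of promoter records: `promoter_id`, `chrom`, `start`,
#'   `end`, `strand`, `species`, `promoter_class`, `gene_id`.
#' @export
read_promoters <- function(bed_path, species, genemap_path = NULL) {
  bed <- read_bed(bed_path, expect_strand = TRUE)
  if (anyDuplicated(bed$name)) {
    stop("duplicate promoter_id in ", bed_path, ": ",
         bed$name[duplicated(bed$name)][1L], call. = FALSE)
  }
  out <- data.frame(
    promoter_id = bed$name,
    chrom = bed$chrom, start = bed$start, end = bed$end,
    strand = bed$strand, species = species,
    promoter_class = NA_character_, gene_id = NA_character_,
    stringsAsFactors = FALSE
  )
  if (!is.null(genemap_path)) {
    gm <- read_gene_map(genemap_path)
    idx <- match(out$promoter_id, gm$promoter_id)
    out$promoter_class <- gm$promoter_class[idx]
    out$gene_id <- gm$gene_id[idx]
  }
  out
}

#' Read a promoter annotation (gene map) table
#' @param path TSV with columns promoter_id, promoter_class, gene_id.
#' @return Data.frame; gene_id "." is converted to NA.
#' @export
read_gene_map <- function(path) {
  con <- open_input(path)
  on.exit(close(con))
  gm <- utils::read.table(con, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("promoter_id", "promoter_class", "gene_id")
  if (!all(need %in% names(gm))) {
    stop("gene map must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  gm$gene_id[gm$gene_id %in% c(".", "")] <- NA_character_
  gm
}

#' Read a 1:1 ortholog table
#' @param path TSV with columns gene_id_a, gene_id_b.
#' @return Data.frame.
#' @export
read_orthologs <- function(path) {
  con <- open_input(path)
  on.exit(close(con))
  o <- utils::read.table(con, header = TRUE, sep = "\t",
                         comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(o) < 2L) stop("ortholog table needs two gene-id columns",
                         call. = FALSE)
  names(o)[1:2] <- c("gene_id_a", "gene_id_b")
  o
}

#' Read an alignment-status table
#'
#' Dialect: 9 tab-separated columns (`promoter_id`, `target_species`,
#' `source`, `status`, `target_chrom`, `target_start`, `target_end`,
#' `target_strand`, `aligned_fraction`), "." for absent fields, one row per
#' (promoter, target species, alignment source) triple. `source` is `msa`
#' (whole-genome multiple alignment) or `pairwise`; `status` is one of
#' ALIGNED, GAPPED, UNMAPPED, MULTI.
#'
#' @param path Path to the TSV (optionally gzipped).
#' @return Data.frame of alignment-status records; target coordinates are NA
#'   unless status is ALIGNED.
#' @export
read_alignment_status <- function(path) {
  con <- open_input(path)
  on.exit(close(con))
  df <- utils::read.table(con, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = ".")
  if (!identical(names(df), ALIGNMENT_STATUS_COLS)) {
    stop("alignment-status header does not match dialect; expected: ",
         paste(ALIGNMENT_STATUS_COLS, collapse = ", "), call. = FALSE)
  }
  if (!all(df$source %in% c("msa", "pairwise"))) {
    stop("alignment source must be 'msa' or 'pairwise'", call. = FALSE)
  }
  if (!all(df$status %in% c("ALIGNED", "GAPPED", "UNMAPPED", "MULTI"))) {
    stop("invalid alignment status value", call. = FALSE)
  }
  key <- paste(df$promoter_id, df$target_species, df$source)
  if (anyDuplicated(key)) {
    stop("duplicate (promoter, target_species, source) triple: ",
         key[duplicated(key)][1L], call. = FALSE)
  }
  aligned <- df$status == "ALIGNED"
  if (any(aligned & (is.na(df$target_chrom) | is.na(df$target_start) |
                       is.na(df$target_end)))) {
    stop("status ALIGNED requires target coordinates", call. = FALSE)
  }
  if (any(!aligned & !is.na(df$target_chrom))) {
    stop("target coordinates are only allowed with status ALIGNED",
         call. = FALSE)
  }
  df$aligned_fraction[is.na(df$aligned_fraction)] <- 0
  if (any(df$aligned_fraction < 0 | df$aligned_fraction > 1)) {
    stop("aligned_fraction must be in [0, 1]", call. = FALSE)
  }
  df
}

#' Write an alignment-status table
#' @param df Data.frame in the alignment-status dialect.
#' @param path Output path.
#' @export
write_alignment_status <- function(df, path) {
  out <- df[, ALIGNMENT_STATUS_COLS]
  for (col in names(out)) {
    v <- out[[col]]
    v <- as.character(v)
    v[is.na(v)] <- "."
    out[[col]] <- v
  }
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(DIALECT_COMMENT, con)
  suppressWarnings(utils::write.table(out, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' Read an expression matrix with its sample sheet
#'
#' The matrix TSV has promoter identifiers in the first column and one
#' column of (raw, tags-per-million scale) expression per sample. The sheet
#' TSV has columns `sample_id`, `species`, `tissue_type`, `replicate_group`,
#' `tissue_category`; every matrix column must appear exactly once.
#'
#' @param matrix_path Expression matrix TSV.
#' @param sheet_path Sample sheet TSV.
#' @return List with `matrix` (numeric matrix, promoters x samples) and
#'   `sheet` (data.frame, ordered to match the matrix columns).
#' @export
read_expression <- function(matrix_path, sheet_path) {
  con <- open_input(matrix_path)
  on.exit(close(con), add = TRUE)
  raw <- utils::read.table(con, header = TRUE, sep = "\t",
                           comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression matrix needs >= 1 sample column",
                           call. = FALSE)
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(mat) <- raw[[1L]]
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop("expression matrix contains missing values",
                       call. = FALSE)
  if (any(mat < 0)) stop("negative expression value in ", matrix_path,
                         call. = FALSE)
  sheet <- read_sample_sheet(sheet_path)
  missing <- setdiff(colnames(mat), sheet$sample_id)
  if (length(missing) > 0L) {
    stop("matrix column(s) absent from sample sheet: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sheet <- sheet[match(colnames(mat), sheet$sample_id), , drop = FALSE]
  rownames(sheet) <- NULL
  list(matrix = mat, sheet = sheet)
}

#' Read a sample sheet
#' @param path TSV with columns sample_id, species, tissue_type,
#'   replicate_group, tissue_category.
#' @return Data.frame.
#' @export
read_sample_sheet <- function(path) {
  con <- open_input(path)
  on.exit(close(con))
  sheet <- utils::read.table(con, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample_id", "species", "tissue_type", "replicate_group",
            "tissue_category")
  if (!all(need %in% names(sheet))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  }
  sheet
}

#' Write an expression matrix and sample sheet
#' @param mat Numeric matrix (promoters x samples) with dimnames.
#' @param sheet Sample-sheet data.frame.
#' @param matrix_path,sheet_path Output paths.
#' @export
write_expression <- function(mat, sheet, matrix_path, sheet_path) {
  df <- data.frame(promoter_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(matrix_path)
}

#' Read a variant table (TSV dialect or minimal VCF)
#'
#' The TSV dialect has columns `chrom`, `pos` (0-based), `ref`, `alt`,
#' `ancestral`, `alt_frequency`. VCF input (detected by extension or
#' `##fileformat` header) expects INFO keys `AA` (ancestral allele) and `AF`
#' (alternate allele frequency); positions are converted to 0-based.
#'
#' Indels and multi-allelic records are dropped with a logged count
#' (attribute `n_dropped`). Records with an unresolved ancestral state
#' (`.`/`N`/missing) are retained and flagged (`unresolved` column) —
#' filtering happens during polarization.
#'
#' @param path Path to the variant file (optionally gzipped).
#' @return Data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `ancestral`, `alt_frequency`, `unresolved`, plus attribute `n_dropped`.
#' @export
read_variants <- function(path) {
  is_vcf <- grepl("\\.vcf(\\.gz)?$", path)
  if (!is_vcf) {
    con <- open_input(path)
    first <- readLines(con, n = 1L)
    close(con)
    is_vcf <- length(first) == 1L && grepl("^##fileformat=VCF", first)
  }
  df <- if (is_vcf) read_variants_vcf(path) else read_variants_tsv(path)
  snp <- nchar(df$ref) == 1L & nchar(df$alt) == 1L &
    !grepl(",", df$alt, fixed = TRUE) &
    df$ref %in% c("A", "C", "G", "T") & df$alt %in% c("A", "C", "G", "T")
  n_dropped <- sum(!snp)
  df <- df[snp, , drop = FALSE]
  if (any(is.na(df$alt_frequency)) ||
        any(df$alt_frequency < 0 | df$alt_frequency > 1)) {
    stop("alt_frequency must be in [0, 1]", call. = FALSE)
  }
  df$ancestral[is.na(df$ancestral)] <- "."
  df$unresolved <- !df$ancestral %in% c("A", "C", "G", "T")
  rownames(df) <- NULL
  attr(df, "n_dropped") <- n_dropped
  df
}

read_variants_tsv <- function(path) {
  con <- open_input(path)
  on.exit(close(con))
  df <- utils::read.table(con, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = c("NA"))
  if (!all(VARIANT_COLS %in% names(df))) {
    stop("variant TSV must have columns: ",
         paste(VARIANT_COLS, collapse = ", "), call. = FALSE)
  }
  df[, VARIANT_COLS]
}

read_variants_vcf <- function(path) {
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  aa <- vcfR::extract.info(v, "AA")
  af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
  data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]) - 1L,
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    ancestral = ifelse(is.na(aa), ".", aa),
    alt_frequency = af,
    stringsAsFactors = FALSE
  )
}

#' Write a variant table in the TSV dialect
#' @param df Variant data.frame (chrom, pos, ref, alt, ancestral,
#'   alt_frequency).
#' @param path Output path.
#' @export
write_variants <- function(df, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(DIALECT_COMMENT, con)
  suppressWarnings(
    utils::write.table(df[, VARIANT_COLS], con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  )
  invisible(path)
}

#' Write a minimal VCF with AA/AF INFO keys
#' @param df Variant data.frame (0-based `pos`; written 1-based).
#' @param path Output path.
#' @export
write_vcf <- function(df, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  if (nrow(df) > 0L) {
    writeLines(sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\tAA=%s;AF=%s",
      df$chrom, df$pos + 1L, df$ref, df$alt, df$ancestral,
      format(df$alt_frequency, trim = TRUE, scientific = FALSE)
    ), con)
  }
  invisible(path)
}
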