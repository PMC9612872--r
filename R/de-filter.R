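# Targeted differential-expression triage: threshold filter, restriction
# to a curated migration gene panel, cross-line intersection. The DE model
# itself (and multiple-testing adjustment) happens upstream; inputs are
# per-gene tables of log2 fold change and FDR-adjusted p.

#' Build a differential-expression table
#'
#' @param gene_id Character vector of unique gene identifiers (opaque,
#'   case-sensitive; no alias resolution is attempted).
#' @param log2fc Log2 fold changes.
#' @param fdr FDR-adjusted p-values in \[0, 1\].
#' @param comparison_label Free-text label, e.g. `"B1 vs C1"`.
#' @return A data.frame of class `de_table` with columns `gene_id`,
#'   `log2fc`, `fdr` and attribute `comparison_label`.
#' @export
de_table <- function(gene_id, log2fc, fdr, comparison_label = "") {
  gene_id <- as.character(gene_id)
  log2fc <- as.numeric(log2fc)
  fdr <- as.numeric(fdr)
  if (length(log2fc) != length(gene_id) || length(fdr) != length(gene_id))
    stop_tm("gene_id, log2fc and fdr must have equal length", "input_error")
  if (anyDuplicated(gene_id))
    stop_tm("gene_id values must be unique within a DE table", "input_error")
  if (any(fdr < 0 | fdr > 1, na.rm = TRUE) || anyNA(fdr))
    stop_tm("fdr values must lie in [0, 1]", "input_error")
  structure(data.frame(gene_id = gene_id, log2fc = log2fc, fdr = fdr,
                       stringsAsFactors = FALSE),
            comparison_label = comparison_label,
            class = c("de_table", "data.frame"))
}

#' Read a DE table from CSV/TSV
#'
#' Expects columns `gene_id`, `log2fc`, `fdr` (case-insensitive;
#' separator sniffed from the header line).
#'
#' @param path File path.
#' @param comparison_label Label attached to the table (default: file name).
#' @return A [de_table()].
#' @export
read_de_table <- function(path, comparison_label = basename(path)) {
  if (!file.exists(path)) stop_tm(sprintf("file not found: %s", path), "io_error")
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("gene_id", "log2fc", "fdr")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_tm(sprintf("DE table missing column(s): %s",
                    paste(miss, collapse = ", ")), "format_error")
  de_table(df$gene_id, df$log2fc, df$fdr, comparison_label)
}

#' A named gene set
#'
#' @param genes Character vector; duplicates are removed (set semantics).
#' @param name Set name.
#' @return A list of class `gene_set` with fields `name` and `genes`.
#' @export
gene_set <- function(genes, name = "set") {
  structure(list(name = name, genes = unique(as.character(genes))),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Read a gene list (one symbol per line)
#'
#' Blank lines and `#` comments are skipped.
#'
#' @param path File path.
#' @param name Set name (default: file name).
#' @return A [gene_set()].
#' @export
read_gene_list <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop_tm(sprintf("file not found: %s", path), "io_error")
  g <- trimws(readLines(path, warn = FALSE))
  g <- g[nzchar(g) & !startsWith(g, "#")]
  gene_set(g, name)
}

#' Threshold filter for differential expression
#'
#' Keeps genes with `|log2fc| > lfc_threshold` and `fdr < fdr_threshold`
#' (both inequalities strict). The default effect threshold of 1 on the
#' log2 scale corresponds to a 2-fold change on the linear scale.
#'
#' @param table A [de_table()].
#' @param lfc_threshold Non-negative log2-fold-change threshold (default 1).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @return A [gene_set()] of the surviving genes.
#' @export
filter_de <- function(table, lfc_threshold = 1, fdr_threshold = 0.05) {
  if (!inherits(table, "de_table"))
    stop_tm("`table` must be a de_table", "input_error")
  if (!is_scalar_num(lfc_threshold) || lfc_threshold < 0)
    stop_tm("`lfc_threshold` must be >= 0", "config_error")
  if (!is_scalar_num(fdr_threshold) || fdr_threshold < 0)
    stop_tm("`fdr_threshold` must be >= 0", "config_error")
  keep <- abs(table$log2fc) > lfc_threshold & table$fdr < fdr_threshold
  gene_set(table$gene_id[keep],
           name = sprintf("DE(%s)", attr(table, "comparison_label")))
}

#' Restrict a gene set to a curated panel
#'
#' @param set A [gene_set()] (e.g. DE survivors).
#' @param migration_list A [gene_set()] panel, e.g. curated
#'   migration-related genes.
#' @return Their intersection as a [gene_set()].
#' @export
restrict_gene_set <- function(set, migration_list) {
  if (!inherits(set, "gene_set") || !inherits(migration_list, "gene_set"))
    stop_tm("both arguments must be gene_set objects", "input_error")
  gene_set(intersect(set$genes, migration_list$genes),
           name = sprintf("%s & %s", set$name, migration_list$name))
}

#' Transcripts shared between two gene sets
#'
#' Symmetric set intersection, e.g. dysregulated transcripts common to two
#' patient-derived lines.
#'
#' @param a,b [gene_set()] objects.
#' @return A [gene_set()].
#' @export
common_transcripts <- function(a, b) {
  if (!inherits(a, "gene_set") || !inherits(b, "gene_set"))
    stop_tm("both arguments must be gene_set objects", "input_error")
  gene_set(intersect(a$genes, b$genes),
           name = sprintf("common(%s, %s)", a$name, b$name))
}

#' Fold-change concordance between two comparisons
#'
#' For each gene of interest, reports the log2 fold change in both tables
#' and whether the signs agree.
#'
#' @param a,b [de_table()] objects.
#' @param genes A [gene_set()]; every gene must be present in both tables.
#' @return data.frame with columns `gene_id`, `log2fc_a`, `log2fc_b`,
#'   `same_sign`.
#' @export
concordant_fold_change <- function(a, b, genes) {
  if (!inherits(a, "de_table") || !inherits(b, "de_table"))
    stop_tm("`a` and `b` must be de_table objects", "input_error")
  if (!inherits(genes, "gene_set"))
    stop_tm("`genes` must be a gene_set", "input_error")
  ia <- match(genes$genes, a$gene_id)
  ib <- match(genes$genes, b$gene_id)
  if (anyNA(ia))
    stop_tm(sprintf("gene '%s' missing from table a",
                    genes$genes[which(is.na(ia))[1L]]), "lookup_error")
  if (anyNA(ib))
    stop_tm(sprintf("gene '%s' missing from table b",
                    genes$genes[which(is.na(ib))[1L]]), "lookup_error")
  data.frame(
    gene_id = genes$genes,
    log2fc_a = a$log2fc[ia],
    log2fc_b = b$log2fc[ib],
    same_sign = sign(a$log2fc[ia]) == sign(b$log2fc[ib]),
    stringsAsFactors = FALSE
  )
}

#' Synthetic DE tables with planted survivor counts
#'
#' Generates a migration gene panel and two DE tables engineered so that
#' `filter_de` + `restrict_gene_set` yields exactly `m` and `n` survivors
#' and their intersection has exactly `overlap` genes — a controllable
#' stand-in for a real transcriptome triage. Non-surviving rows are split
#' among: migration genes failing the effect threshold, migration genes
#' failing the FDR threshold, and strong DE genes outside the panel.
#'
#' @param m,n Survivor counts for tables A and B after restriction to the
#'   panel.
#' @param overlap Planted intersection size, `<= min(m, n)`.
#' @param panel_size Size of the migration panel (default 290).
#' @param n_background Extra non-DE / off-panel rows per table.
#' @param lfc_threshold,fdr_threshold Thresholds the plant is built
#'   against (defaults 1 and 0.05).
#' @param seed RNG seed.
#' @return List with `table_a`, `table_b` ([de_table()]s) and
#'   `migration_list` (a [gene_set()]).
#' @export
simulate_de_tables <- function(m, n, overlap, panel_size = 290L,
                               n_background = 500L, lfc_threshold = 1,
                               fdr_threshold = 0.05, seed = 1L) {
  if (overlap > min(m, n))
    stop_tm("`overlap` cannot exceed min(m, n)", "config_error")
  if (m > panel_size || n > panel_size)
    stop_tm("survivor counts cannot exceed the panel size", "config_error")
  .with_seed(seed, {
    panel <- sprintf("MIG%04d", seq_len(panel_size))
    shared <- panel[seq_len(overlap)]
    only_a <- panel[overlap + seq_len(m - overlap)]
    only_b <- panel[m + seq_len(n - overlap)]
    strong_lfc <- function(k) {
      mag <- stats::runif(k, lfc_threshold + 0.2, lfc_threshold + 3)
      mag * sample(c(-1, 1), k, replace = TRUE)
    }
    weak_lfc <- function(k) stats::runif(k, -lfc_threshold, lfc_threshold)
    low_fdr <- function(k) stats::runif(k, 0, fdr_threshold * 0.9)
    high_fdr <- function(k) stats::runif(k, min(fdr_threshold * 2, 1), 1)
    build <- function(hits) {
      rest <- setdiff(panel, hits)
      off_panel <- sprintf("BKG%04d", seq_len(n_background))
      ids <- c(hits, rest, off_panel)
      lfc <- c(strong_lfc(length(hits)),
               weak_lfc(length(rest)),        # panel genes, no effect
               strong_lfc(n_background))      # strong effects off panel
      fdr <- c(low_fdr(length(hits)),
               ifelse(stats::runif(length(rest)) < 0.5,
                      low_fdr(length(rest)), high_fdr(length(rest))),
               low_fdr(n_background))
      # a slice of panel genes with strong effect but poor FDR
      spoil <- sample(seq_along(rest), min(20L, length(rest)))
      lfc[length(hits) + spoil] <- strong_lfc(length(spoil))
      fdr[length(hits) + spoil] <- high_fdr(length(spoil))
      ord <- sample(length(ids))
      de_table(ids[ord], lfc[ord], fdr[ord])
    }
    list(table_a = build(c(shared, only_a)),
         table_b = build(c(shared, only_b)),
         migration_list = gene_set(panel, "migration_panel"))
  })
}
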