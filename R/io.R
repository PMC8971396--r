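# Readers and writers. CNV tables arrive as BED (0-based half-open) or
# 1-based inclusive TSV and are stored internally in the BED convention;
# reports print 1-based inclusive coordinates. Writers are deterministic
# and echo a provenance block.

CLASSIFICATION_CODES <- c(population = 1, likely_benign = 2, vous = 3,
                          pathogenic = 4)

#' Read a CNV call table
#'
#' Accepts headerless BED4+ (`chrom start end type [cohort sex inheritance
#' classification]`, 0-based half-open) or a headered TSV with the same
#' columns in 1-based inclusive coordinates (`dialect = "tsv_one_based"`,
#' converted on load). Malformed lines (end before start, unknown type or
#' classification) are rejected and collected, not fatal.
#'
#' @param path File path.
#' @param dialect `"bed"` or `"tsv_one_based"`.
#' @return data.frame of validated CNV records (internal 0-based
#'   half-open), with attribute `rejected`: a data.frame of line numbers
#'   and reasons. A header-only/empty file yields zero rows with a warning.
#' @export
read_cnv_table <- function(path, dialect = c("bed", "tsv_one_based")) {
  dialect <- match.arg(dialect)
  cols <- c("chrom", "start", "end", "cnv_type", "cohort", "sex",
            "inheritance", "classification")
  raw <- utils::read.delim(path, header = dialect == "tsv_one_based",
                           stringsAsFactors = FALSE,
                           colClasses = "character",
                           na.strings = c("NA", ""), fill = TRUE)
  if (!nrow(raw)) {
    warning("no CNV records in ", path)
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(cols)), cols))
    attr(out, "rejected") <- data.frame(line = integer(0),
                                        reason = character(0))
    return(out)
  }
  if (dialect == "bed") names(raw) <- cols[seq_len(ncol(raw))]
  for (c in setdiff(cols, names(raw))) raw[[c]] <- NA_character_
  line_off <- if (dialect == "bed") 0L else 1L

  start <- suppressWarnings(as.integer(raw$start))
  end <- suppressWarnings(as.integer(raw$end))
  if (dialect == "tsv_one_based") start <- start - 1L
  cls <- suppressWarnings(as.integer(raw$classification))
  named <- raw$classification %in% names(CLASSIFICATION_CODES)
  cls[named] <- CLASSIFICATION_CODES[raw$classification[named]]

  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(start) | is.na(end)] <- "non-numeric coordinates"
  reason[is.na(reason) & end <= start] <- "end <= start"
  reason[is.na(reason) & !is.na(raw$cnv_type) &
         !(raw$cnv_type %in% c("loss", "gain", NA))] <- "unknown cnv type"
  reason[is.na(reason) & !is.na(raw$classification) & is.na(cls)] <-
    "unknown classification"
  ok <- is.na(reason)

  out <- data.frame(chrom = raw$chrom[ok], start = start[ok], end = end[ok],
                    cnv_type = raw$cnv_type[ok], cohort = raw$cohort[ok],
                    sex = raw$sex[ok], inheritance = raw$inheritance[ok],
                    classification = cls[ok], stringsAsFactors = FALSE)
  attr(out, "rejected") <- data.frame(line = which(!ok) + line_off,
                                      reason = reason[!ok])
  if (any(!ok))
    warning(sum(!ok), " malformed line(s) rejected; see attr 'rejected'")
  out
}

#' Read a harmonized gene-metric table
#'
#' @param path Headered TSV with `symbol` and the raw metric columns used
#'   by [compute_metric_flags()] (plus anything else, carried through).
#' @return data.frame.
#' @export
read_gene_metrics <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!("symbol" %in% names(g))) stop("gene table needs a 'symbol' column")
  g
}

#' Read a human-mouse ortholog phenotype table
#'
#' @param path Headered TSV: `human_symbol`, `mouse_symbol`, optional
#'   `mgi_id`, then one 0/1 column per high-level phenotype.
#' @return List with `pairs` and `phenotypes` ready for
#'   [filter_orthologs()], plus `phenotype_cols`.
#' @export
read_ortholog_table <- function(path) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("human_symbol", "mouse_symbol")
  if (!all(need %in% names(t)))
    stop("ortholog table needs columns: ", paste(need, collapse = ", "))
  flag_cols <- setdiff(names(t), c(need, "mgi_id"))
  list(pairs = t[, intersect(c(need, "mgi_id"), names(t)), drop = FALSE],
       phenotypes = t[, c("mouse_symbol", flag_cols), drop = FALSE],
       phenotype_cols = flag_cols)
}

#' Write a scored gene table
#'
#' Deterministic column order (symbol, ensembl id, the five flags, score,
#' percent, high-scoring), tab-separated.
#'
#' @param scores Output of [score_genes()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  want <- c("symbol", "ensembl_id", FLAG_COLS, "score", "percent",
            "high_scoring")
  cols <- intersect(want, names(scores))
  utils::write.table(scores[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an analysis report with provenance
#'
#' TSV output writes the result data.frame with fixed float precision;
#' JSON wraps it in an object with a provenance block (package version,
#' timestamp-free config echo, seed) so runs are reproducible and outputs
#' byte-identical for identical inputs.
#'
#' @param results data.frame (or coercible) from any analysis function.
#' @param path Destination file.
#' @param format `"tsv"` or `"json"`.
#' @param config Optional named list echoed into the provenance block.
#' @param digits Printed float precision for TSV, default 6 significant.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("tsv", "json"),
                         config = list(), digits = 6) {
  format <- match.arg(format)
  df <- as.data.frame(results)
  if (format == "tsv") {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, digits = digits)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    payload <- list(
      provenance = c(list(package = "neuroscore",
                          version = as.character(utils::packageVersion("neuroscore"))),
                     config),
      results = df)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}
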