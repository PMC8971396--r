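# Gene-metric binarization and cross-source harmonization.
#
# Each candidate metric is reduced to a yes/no evidence flag at a fixed,
# published cutoff. Missing inputs propagate to missing flags; the scorer
# decides what a missing flag means (strict NA scoring by default).

#' Flag loss-of-function constrained genes
#'
#' A gene counts as LOF-constrained when the upper bound of its
#' observed/expected loss-of-function ratio falls strictly below the cutoff.
#' The default cutoff 0.345 corresponds to the conventional "< 0.35" rule
#' applied with rounding from the thousandths place.
#'
#' @param oe_lof_upper Numeric vector of o/e LOF upper bounds (NA allowed).
#' @param threshold Strict upper cutoff; default 0.345.
#' @return Logical vector; NA propagates.
#' @export
binarize_gnomad_lof <- function(oe_lof_upper, threshold = 0.345) {
  if (any(oe_lof_upper < 0, na.rm = TRUE))
    stop("o/e LOF upper bound must be nonnegative")
  oe_lof_upper < threshold
}

#' Flag genes with critically constrained coding regions
#'
#' True when the gene's maximum constrained-region percentile is at or above
#' the requested level (inclusive).
#'
#' @param ccr_max_percentile Numeric vector in \[0, 100\] (NA allowed).
#' @param level Percentile cutoff, 95 or 99.
#' @return Logical vector; NA propagates.
#' @export
binarize_ccr <- function(ccr_max_percentile, level = c(99, 95)) {
  level <- match.arg(as.character(level[1L]), c("99", "95"))
  level <- as.numeric(level)
  if (any(ccr_max_percentile < 0 | ccr_max_percentile > 100, na.rm = TRUE))
    stop("CCR percentile must lie in [0, 100]")
  ccr_max_percentile >= level
}

#' Flag brain-expressed genes from per-tissue median TPM
#'
#' The 13 per-tissue median TPM values are reduced to their median across
#' tissues (even-length median = mean of the middle two), and the gene is
#' flagged when that median is at or above `threshold` transcripts per
#' million. A pre-reduced scalar median may be supplied instead.
#'
#' @param brain_tpm Numeric vector of per-tissue medians, or a single
#'   precomputed median, or NA.
#' @param threshold Inclusive cutoff in TPM; default 10.
#' @return Single logical; NA if the input is missing.
#' @export
binarize_gtex <- function(brain_tpm, threshold = 10) {
  if (length(brain_tpm) == 0L) stop("brain_tpm must not be empty")
  if (all(is.na(brain_tpm))) return(NA)
  if (any(brain_tpm < 0, na.rm = TRUE)) stop("TPM values must be nonnegative")
  stats::median(brain_tpm, na.rm = TRUE) >= threshold
}

#' Flag genes enriched for de novo variants
#'
#' @param denovo_count Nonnegative integer vector of collated de novo
#'   variant counts (NA allowed).
#' @param threshold Inclusive count cutoff; default 10.
#' @return Logical vector; NA propagates.
#' @export
binarize_denovo <- function(denovo_count, threshold = 10) {
  bad <- !is.na(denovo_count) &
    (denovo_count < 0 | denovo_count != round(denovo_count))
  if (any(bad)) stop("de novo counts must be nonnegative integers")
  denovo_count >= threshold
}

#' Promote exon-level index flags to the gene level
#'
#' A gene is index-flagged when at least one of its exons is flagged.
#' An empty exon list yields `FALSE`.
#'
#' @param exon_flags Logical vector of per-exon flags (possibly empty).
#' @return Single logical.
#' @export
binarize_index <- function(exon_flags) {
  if (length(exon_flags) == 0L) return(FALSE)
  any(exon_flags, na.rm = TRUE)
}

#' Deduplicate collated de novo variant reports
#'
#' Variant reports identical on (subject, position, alternate allele) count
#' once, so the same event re-reported across studies is not double counted.
#'
#' @param variants data.frame with columns `gene`, `subject`, `pos`, `alt`.
#' @return data.frame of per-gene deduplicated counts (`gene`, `denovo_count`).
#' @export
dedup_denovo <- function(variants) {
  stopifnot(all(c("gene", "subject", "pos", "alt") %in% names(variants)))
  key <- paste(variants$subject, variants$pos, variants$alt, sep = "\r")
  keep <- !duplicated(paste(variants$gene, key, sep = "\r"))
  tab <- table(variants$gene[keep])
  data.frame(gene = names(tab), denovo_count = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Compute the five evidence flags for a harmonized gene table
#'
#' Applies each binarizer at its default (or supplied) cutoff to the raw
#' metric columns of a gene table, yielding the logical flag columns the
#' scorer consumes.
#'
#' @param genes data.frame with columns `oe_lof_upper`, `ccr_max_percentile`,
#'   `brain_tpm_median`, `denovo_count`, `index_flag` (logical).
#' @param lof_threshold,ccr_level,gtex_threshold,denovo_threshold Cutoffs;
#'   defaults are the published ones.
#' @return `genes` with logical columns `de_novo`, `index`, `ccr99`, `gtex`,
#'   `gnomad_lof` appended.
#' @export
compute_metric_flags <- function(genes, lof_threshold = 0.345, ccr_level = 99,
                                 gtex_threshold = 10, denovo_threshold = 10) {
  need <- c("oe_lof_upper", "ccr_max_percentile", "brain_tpm_median",
            "denovo_count", "index_flag")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("missing metric columns: ", paste(miss, collapse = ", "))
  genes$de_novo <- binarize_denovo(genes$denovo_count, denovo_threshold)
  genes$index <- ifelse(is.na(genes$index_flag), NA, genes$index_flag)
  genes$ccr99 <- binarize_ccr(genes$ccr_max_percentile, ccr_level)
  genes$gtex <- genes$brain_tpm_median >= gtex_threshold
  genes$gnomad_lof <- binarize_gnomad_lof(genes$oe_lof_upper, lof_threshold)
  genes
}

#' Harmonize per-source gene tables into one record per gene
#'
#' Sources are matched by stable Ensembl identifier first, then by current
#' symbol, then through an alias map to the current symbol. Genes missing
#' from at least one metric source are marked (`any_source_missing`) so the
#' scorer can emit NA. Two sources mapping different Ensembl IDs onto one
#' symbol are a conflict: the gene is recorded as unresolved, not merged.
#'
#' @param tables Named list of data.frames, one per metric source. Each must
#'   carry a `symbol` and/or `ensembl_id` column plus its metric column(s).
#' @param alias_map Optional data.frame (`alias`, `symbol`) mapping retired
#'   symbols to current ones.
#' @param biotype Optional data.frame (`symbol`, `biotype`); when supplied,
#'   genes whose biotype is not `protein_coding` are dropped before matching.
#' @return List with `genes` (one merged data.frame, one row per resolved
#'   gene) and `report` (class `harmonization_report`: counts of ID/symbol
#'   matches, renames applied, unresolved symbols, genes needing NA scores).
#' @export
harmonize_gene_tables <- function(tables, alias_map = NULL, biotype = NULL) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("tables must be a named list")

  alias_lookup <- character(0)
  if (!is.null(alias_map)) {
    stopifnot(all(c("alias", "symbol") %in% names(alias_map)))
    alias_lookup <- stats::setNames(as.character(alias_map$symbol),
                                    as.character(alias_map$alias))
  }

  coding <- NULL
  if (!is.null(biotype)) {
    stopifnot(all(c("symbol", "biotype") %in% names(biotype)))
    coding <- biotype$symbol[biotype$biotype == "protein_coding"]
  }

  # canonical key per row of each source: ensembl id when present, else
  # current symbol (after alias renaming)
  renamed <- list()
  norm <- lapply(names(tables), function(src) {
    tab <- tables[[src]]
    if (!("symbol" %in% names(tab)) && !("ensembl_id" %in% names(tab)))
      stop("source '", src, "' has neither symbol nor ensembl_id")
    sym <- if ("symbol" %in% names(tab)) as.character(tab$symbol)
           else rep(NA_character_, nrow(tab))
    hit <- !is.na(sym) & sym %in% names(alias_lookup)
    if (any(hit)) {
      renamed[[src]] <<- data.frame(old = sym[hit],
                                    new = unname(alias_lookup[sym[hit]]),
                                    stringsAsFactors = FALSE)
      sym[hit] <- unname(alias_lookup[sym[hit]])
    }
    ens <- if ("ensembl_id" %in% names(tab)) as.character(tab$ensembl_id)
           else rep(NA_character_, nrow(tab))
    ens[!is.na(ens) & ens == ""] <- NA_character_
    tab$symbol <- sym
    tab$ensembl_id <- ens
    if (!is.null(coding)) tab <- tab[is.na(sym) | sym %in% coding, , drop = FALSE]
    tab
  })
  names(norm) <- names(tables)
  renamed <- if (length(renamed)) unique(do.call(rbind, renamed))
             else data.frame(old = character(0), new = character(0))

  # symbol -> set of ensembl ids seen across sources; conflicts are unresolved
  pairs <- unique(do.call(rbind, lapply(norm, function(t)
    t[!is.na(t$symbol) & !is.na(t$ensembl_id), c("symbol", "ensembl_id")])))
  conflict_syms <- unique(pairs$symbol[duplicated(pairs$symbol)])

  sym2id <- pairs[!(pairs$symbol %in% conflict_syms), , drop = FALSE]
  id_of <- stats::setNames(sym2id$ensembl_id, sym2id$symbol)

  matched_by_id <- 0L
  matched_by_symbol <- 0L
  rows <- list()
  for (src in names(norm)) {
    tab <- norm[[src]]
    tab <- tab[is.na(tab$symbol) | !(tab$symbol %in% conflict_syms), , drop = FALSE]
    if (!nrow(tab)) next
    key <- tab$ensembl_id
    by_id <- !is.na(key)
    # rows without an id resolve through the symbol->id table when possible
    fill <- !by_id & !is.na(tab$symbol) & tab$symbol %in% names(id_of)
    key[fill] <- unname(id_of[tab$symbol[fill]])
    key[is.na(key)] <- paste0("SYM:", tab$symbol[is.na(key)])
    matched_by_id <- matched_by_id + sum(by_id)
    matched_by_symbol <- matched_by_symbol + sum(!by_id)
    tab$.key <- key
    tab$.src <- src
    rows[[src]] <- tab
  }
  if (!length(rows)) {
    all_rows <- data.frame(.key = character(0), .src = character(0),
                           symbol = character(0), ensembl_id = character(0))
  } else {
    all_rows <- do.call(rbind, lapply(rows, function(t)
      t[, c(".key", ".src", "symbol", "ensembl_id"), drop = FALSE]))
  }
  keys <- unique(all_rows$.key)
  merged <- data.frame(.key = keys, stringsAsFactors = FALSE)
  # representative symbol / id per key
  first_of <- function(v, k) {
    ok <- !is.na(v)
    stats::setNames(v[ok], k[ok])[!duplicated(k[ok])]
  }
  symtab <- first_of(all_rows$symbol, all_rows$.key)
  idtab <- first_of(all_rows$ensembl_id, all_rows$.key)
  merged$symbol <- unname(symtab[merged$.key])
  merged$ensembl_id <- unname(idtab[merged$.key])

  # carry metric columns across; later sources never overwrite non-NA values
  meta <- c("symbol", "ensembl_id", ".key", ".src")
  for (src in names(rows)) {
    tab <- rows[[src]]
    for (col in setdiff(names(tab), meta)) {
      if (!(col %in% names(merged))) merged[[col]] <- NA
      idx <- match(tab$.key, merged$.key)
      take <- is.na(merged[[col]][idx]) & !is.na(tab[[col]])
      merged[[col]][idx[take]] <- tab[[col]][take]
    }
  }

  if (length(rows) && nrow(merged)) {
    present <- vapply(rows, function(t) merged$.key %in% t$.key,
                      logical(nrow(merged)))
    if (is.null(dim(present))) present <- matrix(present, nrow = nrow(merged))
    merged$any_source_missing <- rowSums(present) < length(rows)
  } else merged$any_source_missing <- logical(nrow(merged))
  merged$.key <- NULL
  merged <- merged[order(merged$symbol, merged$ensembl_id, na.last = TRUE), ,
                   drop = FALSE]
  rownames(merged) <- NULL

  report <- structure(list(
    matched_by_id = matched_by_id,
    matched_by_symbol = matched_by_symbol,
    renamed = renamed,
    unresolved = sort(conflict_syms),
    na_scored = sum(merged$any_source_missing)
  ), class = "harmonization_report")

  list(genes = merged, report = report)
}

#' @export
print.harmonization_report <- function(x, ...) {
  cat("Gene harmonization report\n")
  cat("  matched by Ensembl ID:", x$matched_by_id, "\n")
  cat("  matched by symbol:    ", x$matched_by_symbol, "\n")
  cat("  symbols renamed:      ", nrow(x$renamed), "\n")
  cat("  unresolved conflicts: ", length(x$unresolved), "\n")
  cat("  genes to score as NA: ", x$na_scored, "\n")
  invisible(x)
}
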