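# sgRNA library manifest: model, read, write, validate.

#' Reserved gene symbol for non-targeting control guides
#'
#' Non-targeting guides match no genomic site and carry this sentinel in the
#' `gene_symbol` column so they aggregate under one pseudo-gene during scoring.
#' @export
NON_TARGETING_SENTINEL <- "NON_TARGETING"

#' Allowed guide categories
#' @export
GUIDE_CATEGORIES <- c("targeting", "non_targeting", "positive_control")

.LIBRARY_COLUMNS <- c("guide_id", "gene_symbol", "protospacer", "category",
                      "domain_annotation")
.PROTOSPACER_MIN <- 18L
.PROTOSPACER_MAX <- 23L

#' Construct an sgRNA library
#'
#' An sgRNA library is an ordered collection of guide records: a unique
#' `guide_id`, the `gene_symbol` it targets (or the non-targeting sentinel),
#' the DNA `protospacer` (A/C/G/T, 18-23 nt), a `category` (one of
#' `"targeting"`, `"non_targeting"`, `"positive_control"`) and an optional
#' free-text `domain_annotation` naming the targeted protein domain.
#'
#' @param records data.frame with columns `guide_id`, `gene_symbol`,
#'   `protospacer`, `category` and optionally `domain_annotation`.
#' @param name library name.
#' @return an object of class `sgrna_library`.
#' @export
sgrna_library <- function(records, name = "sgrna_library") {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(setdiff(.LIBRARY_COLUMNS, "domain_annotation"),
                          names(records))
  if (length(missing_cols) > 0L)
    stop("library records lack required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(records) == 0L)
    stop("an sgRNA library must contain at least one record")
  if (!"domain_annotation" %in% names(records))
    records$domain_annotation <- ""
  records <- records[, .LIBRARY_COLUMNS]
  for (col in .LIBRARY_COLUMNS)
    records[[col]] <- as.character(records[[col]])
  records$protospacer <- toupper(records$protospacer)
  records$domain_annotation[is.na(records$domain_annotation)] <- ""
  .check_library_records(records)
  structure(list(records = records, name = as.character(name)[1]),
            class = "sgrna_library")
}

.check_library_records <- function(records, line_offset = 1L) {
  bad_base <- !grepl("^[ACGT]+$", records$protospacer)
  if (any(bad_base)) {
    i <- which(bad_base)[1]
    stop(sprintf(
      "malformed protospacer for guide '%s' (line %d): '%s' (bases must be A/C/G/T)",
      records$guide_id[i], i + line_offset, records$protospacer[i]))
  }
  len <- nchar(records$protospacer)
  bad_len <- len < .PROTOSPACER_MIN | len > .PROTOSPACER_MAX
  if (any(bad_len)) {
    i <- which(bad_len)[1]
    stop(sprintf(
      "protospacer for guide '%s' (line %d) has length %d; expected %d-%d nt",
      records$guide_id[i], i + line_offset, len[i],
      .PROTOSPACER_MIN, .PROTOSPACER_MAX))
  }
  bad_cat <- !records$category %in% GUIDE_CATEGORIES
  if (any(bad_cat)) {
    i <- which(bad_cat)[1]
    stop(sprintf("unknown category '%s' for guide '%s'; expected one of %s",
                 records$category[i], records$guide_id[i],
                 paste(GUIDE_CATEGORIES, collapse = ", ")))
  }
  dup_id <- duplicated(records$guide_id) | duplicated(records$guide_id, fromLast = TRUE)
  if (any(dup_id))
    stop("duplicate guide_id values: ",
         paste(unique(records$guide_id[dup_id]), collapse = ", "))
  dup_ps <- duplicated(records$protospacer) | duplicated(records$protospacer, fromLast = TRUE)
  if (any(dup_ps)) {
    offenders <- records$guide_id[dup_ps]
    stop("duplicate protospacers shared by guides: ",
         paste(offenders, collapse = ", "))
  }
  nt <- records$category == "non_targeting"
  if (any(nt & records$gene_symbol != NON_TARGETING_SENTINEL))
    stop("non-targeting guides must carry the gene_symbol sentinel '",
         NON_TARGETING_SENTINEL, "'")
  invisible(TRUE)
}

#' @export
length.sgrna_library <- function(x) nrow(x$records)

#' @export
print.sgrna_library <- function(x, ...) {
  counts <- table(factor(x$records$category, levels = GUIDE_CATEGORIES))
  cat(sprintf("sgRNA library '%s': %d guides (%d targeting, %d non-targeting, %d positive-control)\n",
              x$name, nrow(x$records), counts[["targeting"]],
              counts[["non_targeting"]], counts[["positive_control"]]))
  invisible(x)
}

#' Read an sgRNA library manifest
#'
#' The manifest is a headered, tab-separated, unquoted UTF-8 table with
#' columns `guide_id`, `gene_symbol`, `protospacer`, `category`,
#' `domain_annotation`. Row order is preserved; lower-case bases are
#' upper-cased. Duplicated guide ids or protospacers and malformed bases are
#' rejected with messages naming the offenders (and the manifest line for
#' parse errors).
#'
#' @param path path to the TSV manifest.
#' @param name library name; defaults to the file name.
#' @return an [sgrna_library()].
#' @export
read_library_manifest <- function(path, name = NULL) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", check.names = FALSE,
                           na.strings = character())
  missing_cols <- setdiff(setdiff(.LIBRARY_COLUMNS, "domain_annotation"),
                          names(tab))
  if (length(missing_cols) > 0L)
    stop("manifest header lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(tab) == 0L) stop("manifest contains no rows: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  sgrna_library(tab, name = name)
}

#' Write an sgRNA library manifest
#'
#' Writes the tab-separated manifest consumed by [read_library_manifest()].
#' The round trip `read(write(lib))` reproduces the library field for field.
#'
#' @param lib an [sgrna_library()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_library_manifest <- function(lib, path) {
  stopifnot(inherits(lib, "sgrna_library"))
  utils::write.table(lib$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Summarize and sanity-check an sgRNA library
#'
#' Reports guide counts per category, the distinct targeting and
#' positive-control genes, a per-gene guide-count table, and warnings for
#' genes represented by fewer guides than `min_guides` (the design aims for
#' at least five to six independent guides per gene; under-represented genes
#' are flagged, not rejected).
#'
#' @param lib an [sgrna_library()].
#' @param min_guides genes with fewer targeting guides than this are flagged.
#' @return a `library_validation` list: `total`, `category_counts`,
#'   `n_targeting_genes`, `targeting_genes`, `positive_control_genes`,
#'   `gene_guide_counts` (data.frame gene/category/n_guides), `warnings`.
#' @export
validate_library <- function(lib, min_guides = 5L) {
  stopifnot(inherits(lib, "sgrna_library"))
  rec <- lib$records
  category_counts <- as.integer(table(factor(rec$category, levels = GUIDE_CATEGORIES)))
  names(category_counts) <- GUIDE_CATEGORIES
  per_gene <- stats::aggregate(
    list(n_guides = rec$guide_id),
    by = list(gene = rec$gene_symbol, category = rec$category),
    FUN = length)
  per_gene <- per_gene[order(per_gene$gene), , drop = FALSE]
  rownames(per_gene) <- NULL
  targeting_genes <- sort(unique(rec$gene_symbol[rec$category == "targeting"]))
  pc_genes <- sort(unique(rec$gene_symbol[rec$category == "positive_control"]))
  low <- per_gene[per_gene$category == "targeting" &
                    per_gene$n_guides < min_guides, , drop = FALSE]
  warnings <- if (nrow(low) > 0L)
    sprintf("%s: %d guides (<%d)", low$gene, low$n_guides, min_guides)
  else character()
  structure(list(
    total = nrow(rec),
    category_counts = category_counts,
    n_targeting_genes = length(targeting_genes),
    targeting_genes = targeting_genes,
    positive_control_genes = pc_genes,
    gene_guide_counts = per_gene,
    warnings = warnings
  ), class = "library_validation")
}

#' @export
print.library_validation <- function(x, ...) {
  cat(sprintf("sgRNA library: %d guides\n", x$total))
  cat(sprintf("  targeting: %d guides across %d genes\n",
              x$category_counts[["targeting"]], x$n_targeting_genes))
  cat(sprintf("  non-targeting: %d; positive-control: %d (%d genes)\n",
              x$category_counts[["non_targeting"]],
              x$category_counts[["positive_control"]],
              length(x$positive_control_genes)))
  if (length(x$warnings) > 0L) {
    cat(sprintf("  %d warning(s):\n", length(x$warnings)))
    for (w in utils::head(x$warnings, 10L)) cat("   - ", w, "\n", sep = "")
    if (length(x$warnings) > 10L) cat("   ...\n")
  } else cat("  no warnings\n")
  invisible(x)
}
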