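# Essentiality Score (ES) computation and group-differential (lineage-biased)
# ES ranking. ES(gene, line) is the arithmetic mean over the gene's guides of
# log2((final + pseudocount) / (initial + pseudocount)) computed on
# depth-normalized abundances; strongly negative ES marks a dependency.

#' Normalize a count matrix to a common column total
#'
#' Every sample (column) is scaled so its total equals `target_total`; this
#' removes sequencing-depth differences while preserving within-sample
#' ratios. With `target_total = "mean"` (the default) the target is the mean
#' raw column total.
#'
#' @param cm a `count_matrix`, or a numeric matrix with dimnames.
#' @param target_total positive number, or `"mean"`.
#' @return a `normalized_matrix`: list with `values` (numeric matrix) and
#'   `target_total`.
#' @export
normalize_to_common_total <- function(cm, target_total = "mean") {
  m <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  totals <- colSums(m)
  if (any(totals <= 0))
    stop("zero-total sample(s): ",
         paste(colnames(m)[totals <= 0], collapse = ", "))
  if (identical(target_total, "mean")) target_total <- mean(totals)
  target_total <- as.numeric(target_total)
  if (!is.finite(target_total) || target_total <= 0)
    stop("target_total must be a positive number or 'mean'")
  values <- sweep(m, 2L, target_total / totals, `*`)
  structure(list(values = values, target_total = target_total),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d guides x %d samples, column total %.6g\n",
              nrow(x$values), ncol(x$values), x$target_total))
  invisible(x)
}

#' Per-guide log2 fold change
#'
#' `log2((final + pseudocount) / (initial + pseudocount))`. The pseudocount
#' is applied to both numerator and denominator by default, so equal
#' abundances give exactly 0 and a zero initial abundance stays finite;
#' `pseudo_numerator_only = TRUE` applies it to the numerator alone
#' (the literal reading of the screen formula), requiring initial > 0.
#'
#' @param initial,final non-negative normalized abundances (vectors).
#' @param pseudocount positive stabilizer, default 1.
#' @param pseudo_numerator_only apply the pseudocount to the numerator only.
#' @return numeric vector of log2 fold changes (names preserved).
#' @export
sgrna_log2fc <- function(initial, final, pseudocount = 1,
                         pseudo_numerator_only = FALSE) {
  if (any(initial < 0) || any(final < 0))
    stop("abundances must be non-negative")
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be > 0")
  if (pseudo_numerator_only) {
    if (any(initial <= 0))
      stop("numerator-only pseudocount requires all initial abundances > 0")
    log2((final + pseudocount) / initial)
  } else {
    log2((final + pseudocount) / (initial + pseudocount))
  }
}

#' Aggregate guide-level log2 fold changes to gene-level ES
#'
#' ES(gene) is the arithmetic mean of the gene's guides' log2 fold changes.
#' Non-targeting guides aggregate under the sentinel pseudo-gene.
#'
#' @param lfc named numeric vector of per-guide log2 fold changes; names are
#'   guide ids, every one of which must exist in the library.
#' @param lib an [sgrna_library()].
#' @return data.frame with `gene`, `category`, `n_guides`, `es`.
#' @export
gene_es <- function(lfc, lib) {
  stopifnot(inherits(lib, "sgrna_library"))
  if (is.null(names(lfc))) stop("lfc must be named by guide_id")
  idx <- match(names(lfc), lib$records$guide_id)
  if (any(is.na(idx)))
    stop("guide(s) absent from library: ",
         paste(names(lfc)[is.na(idx)][1:min(5, sum(is.na(idx)))], collapse = ", "))
  gene <- lib$records$gene_symbol[idx]
  category <- lib$records$category[idx]
  agg <- stats::aggregate(list(es = lfc),
                          by = list(gene = gene, category = category),
                          FUN = mean)
  n <- stats::aggregate(list(n_guides = lfc),
                        by = list(gene = gene, category = category),
                        FUN = length)
  out <- merge(agg, n, by = c("gene", "category"), sort = TRUE)
  out <- out[order(out$gene), c("gene", "category", "n_guides", "es")]
  rownames(out) <- NULL
  out
}

.pair_samples <- function(sheet) {
  sheet <- sample_sheet(sheet)
  lines <- unique(sheet$cell_line)
  pairs <- lapply(lines, function(cl) {
    ini <- sheet$sample_id[sheet$cell_line == cl & sheet$timepoint == "initial"]
    fin <- sheet$sample_id[sheet$cell_line == cl & sheet$timepoint == "final"]
    if (length(ini) != 1L || length(fin) != 1L)
      stop("cell line '", cl,
           "' must have exactly one initial and one final sample")
    c(initial = ini, final = fin)
  })
  names(pairs) <- lines
  pairs
}

#' Compute the ES table for a whole screen
#'
#' Normalizes all samples to a common total, pairs each cell line's initial
#' and final samples via the sample sheet, computes per-guide log2 fold
#' changes, and averages them per gene.
#'
#' @param cm a `count_matrix` covering all samples in `sheet`.
#' @param sheet a [sample_sheet()] with one initial and one final sample per
#'   cell line.
#' @param lib an [sgrna_library()].
#' @param pseudocount passed to [sgrna_log2fc()].
#' @param target_total passed to [normalize_to_common_total()].
#' @param pseudo_numerator_only passed to [sgrna_log2fc()].
#' @return an `es_table`: list with `es` (genes x cell lines matrix),
#'   `gene_info` (data.frame gene/category/n_guides).
#' @export
compute_es_table <- function(cm, sheet, lib, pseudocount = 1,
                             target_total = "mean",
                             pseudo_numerator_only = FALSE) {
  stopifnot(inherits(cm, "count_matrix"))
  nm <- normalize_to_common_total(cm, target_total)
  pairs <- .pair_samples(sheet)
  per_line <- lapply(pairs, function(p) {
    if (!all(p %in% colnames(nm$values)))
      stop("sample(s) missing from count matrix: ",
           paste(setdiff(p, colnames(nm$values)), collapse = ", "))
    lfc <- sgrna_log2fc(nm$values[, p[["initial"]]], nm$values[, p[["final"]]],
                        pseudocount = pseudocount,
                        pseudo_numerator_only = pseudo_numerator_only)
    names(lfc) <- rownames(nm$values)
    gene_es(lfc, lib)
  })
  gene_info <- per_line[[1]][, c("gene", "category", "n_guides")]
  es <- vapply(per_line, function(df) {
    stopifnot(identical(df$gene, gene_info$gene))
    df$es
  }, numeric(nrow(gene_info)))
  es <- matrix(es, nrow = nrow(gene_info),
               dimnames = list(gene_info$gene, names(pairs)))
  structure(list(es = es, gene_info = gene_info), class = "es_table")
}

#' @export
print.es_table <- function(x, ...) {
  cat(sprintf("es_table: %d genes x %d cell lines\n",
              nrow(x$es), ncol(x$es)))
  invisible(x)
}

#' Group-differential (biased) ES ranking
#'
#' For each gene, `biased_es = mean(ES over group_b) - mean(ES over
#' group_a)`, where `group_a` is the focal group (e.g. the AML lines). A
#' gene strongly depleted in the focal group only (very negative ES there,
#' ~0 elsewhere) gets a large positive biased ES; rank 1 is the most
#' focal-group-biased dependency. Ties are broken lexicographically by gene
#' symbol. Control genes (non-targeting sentinel and positive-control
#' category) are excluded from the ranking by default and can be retained
#' with `exclude_controls = FALSE`.
#'
#' @param es an `es_table` from [compute_es_table()].
#' @param group_a character vector of focal cell lines.
#' @param group_b character vector of comparison cell lines; defaults to all
#'   remaining columns.
#' @param exclude_controls drop non-targeting and positive-control entries
#'   before ranking.
#' @return a `bias_table` data.frame: `gene`, `category`, `mean_group_a`,
#'   `mean_group_b`, `biased_es`, `rank`, sorted by rank.
#' @export
biased_es <- function(es, group_a, group_b = NULL, exclude_controls = TRUE) {
  stopifnot(inherits(es, "es_table"))
  cols <- colnames(es$es)
  if (is.null(group_b)) group_b <- setdiff(cols, group_a)
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be non-empty")
  if (length(intersect(group_a, group_b)) > 0L)
    stop("groups overlap: ", paste(intersect(group_a, group_b), collapse = ", "))
  missing_cl <- setdiff(c(group_a, group_b), cols)
  if (length(missing_cl) > 0L)
    stop("cell line(s) absent from ES table: ",
         paste(missing_cl, collapse = ", "))
  keep <- rep(TRUE, nrow(es$es))
  if (exclude_controls)
    keep <- es$gene_info$category == "targeting"
  m <- es$es[keep, , drop = FALSE]
  mean_a <- rowMeans(m[, group_a, drop = FALSE])
  mean_b <- rowMeans(m[, group_b, drop = FALSE])
  out <- data.frame(
    gene = rownames(m),
    category = es$gene_info$category[keep],
    mean_group_a = as.numeric(mean_a),
    mean_group_b = as.numeric(mean_b),
    biased_es = as.numeric(mean_b - mean_a),
    row.names = NULL
  )
  ord <- order(-out$biased_es, out$gene)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "group_a") <- group_a
  attr(out, "group_b") <- group_b
  class(out) <- c("bias_table", "data.frame")
  out
}

#' Export the per-gene ES heatmap table
#'
#' One row per ranked gene: per-line ES values, the biased ES, and the rank,
#' sorted by rank (descending biased ES, ties by gene symbol). Genes present
#' in the bias table must all exist in the ES table.
#'
#' @param es an `es_table`.
#' @param bias a `bias_table` from [biased_es()].
#' @param path output TSV path.
#' @return the exported data.frame, invisibly.
#' @export
export_es_heatmap_table <- function(es, bias, path) {
  stopifnot(inherits(es, "es_table"), inherits(bias, "bias_table"))
  if (!all(bias$gene %in% rownames(es$es)))
    stop("bias table contains gene(s) absent from the ES table: ",
         paste(setdiff(bias$gene, rownames(es$es)), collapse = ", "))
  m <- es$es[bias$gene, , drop = FALSE]
  out <- data.frame(gene = bias$gene, as.data.frame(m, optional = TRUE),
                    biased_es = bias$biased_es, rank = bias$rank,
                    check.names = FALSE, row.names = NULL)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Write / read an ES table as TSV
#'
#' Columns: `gene`, `category`, `n_guides`, then one column per cell line.
#'
#' @param es an `es_table`.
#' @param path TSV path.
#' @return `path` (write) or an `es_table` (read).
#' @export
write_es_table <- function(es, path) {
  stopifnot(inherits(es, "es_table"))
  out <- data.frame(es$gene_info, as.data.frame(es$es, optional = TRUE),
                    check.names = FALSE, row.names = NULL)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_es_table
#' @export
read_es_table <- function(path) {
  if (!file.exists(path)) stop("ES table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE)
  info_cols <- c("gene", "category", "n_guides")
  if (!all(info_cols %in% names(df)))
    stop("ES table lacks column(s): ",
         paste(setdiff(info_cols, names(df)), collapse = ", "))
  m <- as.matrix(df[, setdiff(names(df), info_cols), drop = FALSE])
  rownames(m) <- df$gene
  structure(list(es = m, gene_info = df[, info_cols]), class = "es_table")
}
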