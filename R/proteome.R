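# Unique-peptide fold enrichment and interactome intersection. An
# interactor passes when its unique-peptide count in the case condition is
# at least `threshold`-fold (default 5, inclusive) its count in the control
# condition; two independently derived interactomes (e.g. an
# immunoprecipitation experiment and a proximity-labeling experiment) are
# then intersected to nominate high-confidence candidates.

#' Construct / read a unique-peptide count table
#'
#' Rows of protein identifier plus non-negative integer unique-peptide
#' counts for a case and a control condition.
#'
#' @param table data.frame with columns `protein_id`, `case_peptides`,
#'   `control_peptides`.
#' @param case_label,control_label condition labels carried as attributes.
#' @return validated data.frame of class `peptide_count_table`.
#' @export
peptide_count_table <- function(table, case_label = "case",
                                control_label = "control") {
  required <- c("protein_id", "case_peptides", "control_peptides")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols) > 0L)
    stop("peptide table lacks column(s): ", paste(missing_cols, collapse = ", "))
  table <- as.data.frame(table)[, required]
  table$protein_id <- as.character(table$protein_id)
  table$case_peptides <- as.integer(table$case_peptides)
  table$control_peptides <- as.integer(table$control_peptides)
  if (anyDuplicated(table$protein_id))
    stop("duplicate protein_id values: ",
         paste(unique(table$protein_id[duplicated(table$protein_id)]),
               collapse = ", "))
  if (any(is.na(table$case_peptides)) || any(is.na(table$control_peptides)) ||
      any(table$case_peptides < 0L) || any(table$control_peptides < 0L))
    stop("peptide counts must be non-negative integers")
  rownames(table) <- NULL
  attr(table, "case_label") <- case_label
  attr(table, "control_label") <- control_label
  class(table) <- c("peptide_count_table", "data.frame")
  table
}

#' @rdname peptide_count_table
#' @param path TSV path with the three columns above.
#' @export
read_peptide_table <- function(path, case_label = "case",
                               control_label = "control") {
  if (!file.exists(path)) stop("peptide table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE)
  peptide_count_table(df, case_label = case_label, control_label = control_label)
}

#' Unique-peptide fold enrichment
#'
#' Ratio of case to control unique-peptide counts per protein. Zero control
#' counts are handled by `zero_policy`:
#' * `"floor_one"` (default): the denominator is floored at one peptide, so
#'   `ratio = case / max(control, 1)`; proteins absent from both conditions
#'   (case = control = 0) are dropped. This keeps ratios finite for proteins
#'   undetected in the control, the situation expected of true interactors.
#' * `"exclude"`: proteins with control = 0 are dropped entirely.
#'
#' @param t a [peptide_count_table()].
#' @param zero_policy `"floor_one"` or `"exclude"`.
#' @return an `enrichment_result` data.frame: `protein_id`, `case_peptides`,
#'   `control_peptides`, `ratio`.
#' @export
fold_enrichment <- function(t, zero_policy = c("floor_one", "exclude")) {
  stopifnot(inherits(t, "peptide_count_table") ||
              all(c("protein_id", "case_peptides", "control_peptides") %in% names(t)))
  zero_policy <- match.arg(zero_policy)
  t <- as.data.frame(t)
  if (zero_policy == "floor_one") {
    t <- t[!(t$case_peptides == 0L & t$control_peptides == 0L), , drop = FALSE]
    ratio <- t$case_peptides / pmax(t$control_peptides, 1L)
  } else {
    t <- t[t$control_peptides > 0L, , drop = FALSE]
    ratio <- t$case_peptides / t$control_peptides
  }
  out <- data.frame(protein_id = t$protein_id,
                    case_peptides = t$case_peptides,
                    control_peptides = t$control_peptides,
                    ratio = as.numeric(ratio),
                    row.names = NULL)
  attr(out, "zero_policy") <- zero_policy
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Proteins enriched at or above a fold threshold
#'
#' The comparison is inclusive (`ratio >= threshold`), per the "at least
#' x-fold" criterion.
#'
#' @param r an `enrichment_result` from [fold_enrichment()].
#' @param threshold fold-enrichment cutoff, default 5.
#' @return character vector of enriched protein ids.
#' @export
enriched_set <- function(r, threshold = 5) {
  stopifnot(is.data.frame(r), "ratio" %in% names(r))
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be > 0")
  r$protein_id[r$ratio >= threshold]
}

#' Intersect two protein sets (Venn overlap)
#'
#' Identifiers are harmonized case-insensitively (and via an optional alias
#' map) before the set algebra; reported members keep the spelling used in
#' set `a` (or `b` for b-only members). Inclusion-exclusion holds exactly:
#' `|a_only| + |both| = |a|` and `|b_only| + |both| = |b|`.
#'
#' @param a,b character vectors of protein identifiers.
#' @param aliases optional named character vector mapping alternative
#'   identifiers to canonical ones (applied case-insensitively).
#' @return a `venn_result` list: `a_only`, `b_only`, `both`, and counts
#'   `n_a`, `n_b`, `n_both`.
#' @export
intersect_sets <- function(a, b, aliases = NULL) {
  canon <- function(x) {
    x <- toupper(as.character(x))
    if (!is.null(aliases)) {
      map <- stats::setNames(toupper(as.character(aliases)),
                             toupper(names(aliases)))
      hit <- x %in% names(map)
      x[hit] <- map[x[hit]]
    }
    x
  }
  a <- a[!duplicated(canon(a))]
  b <- b[!duplicated(canon(b))]
  ca <- canon(a); cb <- canon(b)
  both <- a[ca %in% cb]
  structure(list(
    a_only = a[!ca %in% cb],
    b_only = b[!cb %in% ca],
    both = both,
    n_a = length(a), n_b = length(b), n_both = length(both)
  ), class = "venn_result")
}

#' @export
print.venn_result <- function(x, ...) {
  cat(sprintf("venn: |A|=%d, |B|=%d, overlap=%d (A-only %d, B-only %d)\n",
              x$n_a, x$n_b, x$n_both, length(x$a_only), length(x$b_only)))
  if (x$n_both > 0L && x$n_both <= 25L)
    cat("  shared: ", paste(x$both, collapse = ", "), "\n", sep = "")
  invisible(x)
}
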