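# Demultiplexing of stacking-barcoded screen reads and exact-match guide
# counting. Read layout: [stagger][barcode][anchor][protospacer][...],
# where the stagger is a variable-length random prefix that staggers
# sequencing cycles, the barcode identifies the sample, and the anchor is
# the constant vector sequence immediately 5' of the protospacer.

#' Read a screen sample sheet
#'
#' Tab-separated table with columns `sample_id`, `cell_line`, `timepoint`
#' (`initial` or `final`), `barcode` (DNA) and `stagger_len` (offset of the
#' barcode within the read, >= 0).
#'
#' @param path TSV path.
#' @return validated data.frame of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE,
                           colClasses = "character")
  sample_sheet(tab)
}

#' Construct a sample sheet
#'
#' @param sheet data.frame with columns `sample_id`, `cell_line`,
#'   `timepoint`, `barcode`, `stagger_len`.
#' @return the validated sheet, classed `sample_sheet`.
#' @export
sample_sheet <- function(sheet) {
  required <- c("sample_id", "cell_line", "timepoint", "barcode", "stagger_len")
  missing_cols <- setdiff(required, names(sheet))
  if (length(missing_cols) > 0L)
    stop("sample sheet lacks column(s): ", paste(missing_cols, collapse = ", "))
  sheet <- as.data.frame(sheet)[, required]
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$cell_line <- as.character(sheet$cell_line)
  sheet$timepoint <- as.character(sheet$timepoint)
  sheet$barcode <- toupper(as.character(sheet$barcode))
  sheet$stagger_len <- as.integer(sheet$stagger_len)
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id values: ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]), collapse = ", "))
  if (!all(sheet$timepoint %in% c("initial", "final")))
    stop("timepoint must be 'initial' or 'final'")
  if (!all(grepl("^[ACGT]+$", sheet$barcode)))
    stop("barcodes must be non-empty A/C/G/T strings")
  if (any(is.na(sheet$stagger_len)) || any(sheet$stagger_len < 0L))
    stop("stagger_len must be a non-negative integer")
  key <- paste(sheet$barcode, sheet$stagger_len)
  if (anyDuplicated(key))
    stop("duplicate (barcode, stagger_len) combinations: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  rownames(sheet) <- NULL
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

# Two samples conflict when some read prefix satisfies both of their
# [stagger][barcode][anchor] patterns, i.e. the patterns agree at every
# position both of them fix. The anchor is part of the pattern: without it,
# any two samples with different stagger lengths would be formally ambiguous.
.patterns_compatible <- function(stagger1, fixed1, stagger2, fixed2) {
  pos1 <- stagger1 + seq_len(nchar(fixed1))
  pos2 <- stagger2 + seq_len(nchar(fixed2))
  common <- intersect(pos1, pos2)
  if (length(common) == 0L) return(TRUE)
  c1 <- substring(fixed1, common - stagger1, common - stagger1)
  c2 <- substring(fixed2, common - stagger2, common - stagger2)
  all(c1 == c2)
}

.check_sheet_ambiguity <- function(sheet, anchor) {
  fixed <- paste0(sheet$barcode, anchor)
  n <- nrow(sheet)
  if (n < 2L) return(invisible(TRUE))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (.patterns_compatible(sheet$stagger_len[i], fixed[i],
                             sheet$stagger_len[j], fixed[j]))
      stop(sprintf(
        "samples '%s' and '%s' have (barcode, stagger) patterns that can claim the same read",
        sheet$sample_id[i], sheet$sample_id[j]))
  }
  invisible(TRUE)
}

#' Read a FASTQ file as a character vector of sequences
#'
#' Plain or gzip-compressed FASTQ; qualities are ignored (counting is by
#' exact sequence match).
#'
#' @param path FASTQ path.
#' @return character vector of read sequences.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ not found: ", path)
  reads <- Biostrings::readDNAStringSet(path, format = "fastq")
  as.character(reads, use.names = FALSE)
}

#' Demultiplex stacking-barcoded reads
#'
#' A read is assigned to a sample when the sample's barcode matches exactly
#' at offset `stagger_len` and the anchor follows immediately after.
#' Ambiguous sheets (two samples whose patterns can claim the same read) are
#' rejected up front, so assignment is unique and order-independent. Reads
#' matching no sample are counted as orphans. Assigned reads are returned
#' trimmed to the anchor start (stagger and barcode removed), i.e. only the
#' sgRNA cassette is preserved.
#'
#' @param reads character vector of read sequences, or a FASTQ path.
#' @param sheet a [sample_sheet()].
#' @param anchor constant vector sequence 5' of the protospacer (DNA).
#' @return list with `streams` (named list of trimmed read vectors, one per
#'   sample), `orphans` (count) and `n_reads`.
#' @export
demultiplex <- function(reads, sheet, anchor) {
  sheet <- sample_sheet(sheet)
  anchor <- toupper(anchor)
  if (!grepl("^[ACGT]+$", anchor)) stop("anchor must be a non-empty DNA string")
  .check_sheet_ambiguity(sheet, anchor)
  if (length(reads) == 1L && file.exists(reads)) reads <- read_fastq(reads)
  reads <- toupper(as.character(reads))
  assigned <- logical(length(reads))
  streams <- vector("list", nrow(sheet))
  names(streams) <- sheet$sample_id
  for (i in seq_len(nrow(sheet))) {
    off <- sheet$stagger_len[i]
    bc <- sheet$barcode[i]
    pat <- paste0(bc, anchor)
    hit <- !assigned &
      substr(reads, off + 1L, off + nchar(pat)) == pat
    streams[[i]] <- substr(reads[hit], off + nchar(bc) + 1L, nchar(reads[hit]))
    assigned <- assigned | hit
  }
  list(streams = streams,
       orphans = sum(!assigned),
       n_reads = length(reads))
}

#' Count guides by exact protospacer match
#'
#' A read increments exactly one guide's count if and only if the substring
#' immediately following the anchor equals a library protospacer exactly (no
#' mismatch, no indel). Everything else - anchor absent, mutated protospacer,
#' unknown sequence - increments the sample's unassigned tally. When the
#' library mixes protospacer lengths, longer protospacers are tried first so
#' a guide that extends another guide's protospacer wins the exact match.
#'
#' @param streams named list of per-sample read vectors, trimmed to start at
#'   the anchor (as produced by [demultiplex()]).
#' @param lib an [sgrna_library()].
#' @param anchor constant sequence expected at the start of each read.
#' @return a `count_matrix`: integer matrix guides x samples with an
#'   `unassigned` per-sample attribute.
#' @export
count_guides <- function(streams, lib, anchor) {
  stopifnot(inherits(lib, "sgrna_library"), is.list(streams))
  anchor <- toupper(anchor)
  guides <- lib$records$guide_id
  ps <- lib$records$protospacer
  lens <- sort(unique(nchar(ps)), decreasing = TRUE)
  counts <- matrix(0L, nrow = length(guides), ncol = length(streams),
                   dimnames = list(guides, names(streams)))
  unassigned <- integer(length(streams))
  names(unassigned) <- names(streams)
  alen <- nchar(anchor)
  for (s in seq_along(streams)) {
    reads <- streams[[s]]
    if (length(reads) == 0L) next
    ok <- substr(reads, 1L, alen) == anchor
    hit_guide <- rep(NA_integer_, length(reads))
    payload <- substr(reads[ok], alen + 1L, nchar(reads[ok]))
    idx_ok <- which(ok)
    remaining <- rep(TRUE, length(payload))
    for (L in lens) {
      cand <- substr(payload, 1L, L)
      m <- match(ifelse(nchar(cand) == L & remaining, cand, NA_character_), ps)
      found <- !is.na(m)
      hit_guide[idx_ok[found]] <- m[found]
      remaining <- remaining & !found
    }
    tab <- tabulate(hit_guide[!is.na(hit_guide)], nbins = length(guides))
    counts[, s] <- as.integer(tab)
    unassigned[s] <- length(reads) - sum(tab)
  }
  count_matrix(counts, unassigned = unassigned)
}

#' Construct a guide-by-sample count matrix
#'
#' @param counts non-negative integer matrix, rows = guide ids, columns =
#'   sample ids.
#' @param unassigned per-sample counts of demultiplexed reads that matched no
#'   guide exactly (defaults to zero, e.g. for simulator-made matrices).
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, unassigned = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix needs guide rownames and sample colnames")
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative")
  storage.mode(counts) <- "integer"
  if (is.null(unassigned)) {
    unassigned <- integer(ncol(counts))
    names(unassigned) <- colnames(counts)
  }
  if (!identical(names(unassigned), colnames(counts)))
    unassigned <- unassigned[colnames(counts)]
  structure(list(counts = counts, unassigned = unassigned),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d guides x %d samples; %s assigned reads, %s unassigned\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ","),
              format(sum(x$unassigned), big.mark = ",")))
  invisible(x)
}

#' Demultiplex and count a screen in one call
#'
#' @inheritParams demultiplex
#' @param lib an [sgrna_library()].
#' @return list with `counts` (a `count_matrix`), `orphans` and `n_reads`.
#' @export
quantify_screen <- function(reads, sheet, lib, anchor) {
  dm <- demultiplex(reads, sheet, anchor)
  cm <- count_guides(dm$streams, lib, anchor)
  list(counts = cm, orphans = dm$orphans, n_reads = dm$n_reads)
}

#' Write / read a count matrix as TSV
#'
#' Guides x samples table with a leading `guide_id` column; the per-sample
#' unassigned tallies travel in a trailing `__unassigned__` pseudo-guide row.
#'
#' @param cm a `count_matrix`.
#' @param path TSV path.
#' @return `path` (write) or a `count_matrix` (read).
#' @export
write_count_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  out <- rbind(cm$counts, `__unassigned__` = cm$unassigned)
  df <- data.frame(guide_id = rownames(out), out, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) stop("count table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$guide_id
  un <- NULL
  if ("__unassigned__" %in% rownames(m)) {
    un <- m["__unassigned__", ]
    m <- m[rownames(m) != "__unassigned__", , drop = FALSE]
  }
  count_matrix(m, unassigned = un)
}

#' Per-sample representation QC
#'
#' Fold-representation is assigned reads divided by the number of guides in
#' the library; screens are typically maintained at >= 1000x representation,
#' so samples below `threshold` are flagged. Also reports the fraction of
#' guides with zero counts and the fraction of demultiplexed reads assigned.
#'
#' @param cm a `count_matrix`.
#' @param lib an [sgrna_library()]; its size defines the denominator.
#' @param threshold minimum acceptable fold-representation.
#' @return data.frame of class `qc_report`: one row per sample with
#'   `assigned`, `fold_representation`, `zero_fraction`, `fraction_assigned`,
#'   `flagged`.
#' @export
representation_qc <- function(cm, lib, threshold = 1000) {
  stopifnot(inherits(cm, "count_matrix"), inherits(lib, "sgrna_library"))
  n_guides <- length(lib)
  assigned <- colSums(cm$counts)
  total <- assigned + cm$unassigned
  rep_fold <- assigned / n_guides
  qc <- data.frame(
    sample_id = colnames(cm$counts),
    assigned = as.numeric(assigned),
    fold_representation = as.numeric(rep_fold),
    zero_fraction = as.numeric(colMeans(cm$counts == 0L)),
    fraction_assigned = as.numeric(ifelse(total > 0, assigned / total, 0)),
    flagged = as.numeric(rep_fold) < threshold,
    row.names = NULL
  )
  class(qc) <- c("qc_report", "data.frame")
  attr(qc, "threshold") <- threshold
  qc
}
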