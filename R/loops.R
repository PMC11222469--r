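# Genomic-interval algebra for chromatin loops and ChIP-seq peaks.
# All coordinates are 0-based half-open (BED convention) and kept verbatim
# through I/O; overlap requires >= 1 shared bp unless a slop is requested.
# A loop is a pair of same-chromosome anchor intervals (BEDPE semantics),
# left anchor starting at or before the right anchor.

#' Do two genomic intervals overlap?
#'
#' Half-open semantics: `[start, end)` intervals overlap iff they share the
#' same chromosome and `max(starts) < min(ends)` (at least 1 bp shared);
#' abutting intervals do not overlap.
#'
#' @param a,b lists or one-row data.frames with `chrom`, `start`, `end`.
#' @return logical.
#' @export
intervals_overlap <- function(a, b) {
  stopifnot(a$start < a$end, b$start < b$end,
            nzchar(a$chrom), nzchar(b$chrom))
  a$chrom == b$chrom && max(a$start, b$start) < min(a$end, b$end)
}

#' Construct a set of genomic intervals (peaks)
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `name`.
#' @return validated data.frame of class `interval_set`.
#' @export
interval_set <- function(df) {
  required <- c("chrom", "start", "end")
  if (!all(required %in% names(df)))
    stop("interval set lacks column(s): ",
         paste(setdiff(required, names(df)), collapse = ", "))
  df <- as.data.frame(df)
  df$chrom <- as.character(df$chrom)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  bad <- !nzchar(df$chrom) | is.na(df$start) | is.na(df$end) |
    df$start < 0 | df$start >= df$end
  if (any(bad))
    stop("invalid interval(s) at row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "),
         " (need chrom non-empty, 0 <= start < end)")
  rownames(df) <- NULL
  class(df) <- c("interval_set", "data.frame")
  df
}

#' Construct a loop set
#'
#' @param df data.frame with columns `chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2` (paired anchors, 0-based half-open) and optionally
#'   `name` and `label`.
#' @param name set name.
#' @return validated data.frame of class `loop_set` with attribute `name`.
#' @export
loop_set <- function(df, name = "loops") {
  required <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  if (!all(required %in% names(df)))
    stop("loop set lacks column(s): ",
         paste(setdiff(required, names(df)), collapse = ", "))
  df <- as.data.frame(df)
  for (col in c("chrom1", "chrom2")) df[[col]] <- as.character(df[[col]])
  for (col in c("start1", "end1", "start2", "end2"))
    df[[col]] <- as.numeric(df[[col]])
  if (!"name" %in% names(df))
    df$name <- if (nrow(df) > 0) sprintf("loop_%d", seq_len(nrow(df))) else character()
  if (!"label" %in% names(df)) df$label <- NA_character_
  df <- df[, c(required, "name", "label")]
  bad_anchor <- df$start1 < 0 | df$start1 >= df$end1 |
    df$start2 < 0 | df$start2 >= df$end2
  if (any(bad_anchor))
    stop("invalid anchor interval(s) at row(s): ",
         paste(utils::head(which(bad_anchor), 5), collapse = ", "))
  trans <- df$chrom1 != df$chrom2
  if (any(trans))
    stop("loop anchors must share a chromosome; violated at row(s): ",
         paste(utils::head(which(trans), 5), collapse = ", "))
  swapped <- df$start1 > df$start2
  if (any(swapped))
    stop("left anchor must start at or before right anchor; violated at row(s): ",
         paste(utils::head(which(swapped), 5), collapse = ", "))
  key <- paste(df$chrom1, df$start1, df$end1, df$start2, df$end2)
  if (anyDuplicated(key))
    stop("exact-duplicate anchor pairs at row(s): ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "))
  rownames(df) <- NULL
  attr(df, "name") <- name
  class(df) <- c("loop_set", "data.frame")
  df
}

# 0-based half-open -> 1-based closed GRanges (preserves overlap semantics),
# optionally padded by `slop` bp on each side. `levels` fixes a common
# seqlevels universe so cross-set overlap queries are silent even when the
# two sets cover different chromosomes.
.anchors_granges <- function(chrom, start, end, slop = 0, levels = NULL) {
  if (is.null(levels)) levels <- unique(chrom)
  GenomicRanges::GRanges(factor(chrom, levels = levels),
                         IRanges::IRanges(start = pmax(start + 1 - slop, 1),
                                          end = end + slop))
}

#' Classify test loops as shared or gained against a reference loop set
#'
#' A test loop is *shared* iff there exists one reference loop whose left
#' anchor overlaps the test loop's left anchor AND whose right anchor
#' overlaps the test loop's right anchor (the same reference loop on both
#' sides); otherwise it is *gained*. Reference loops matched by no test loop
#' are *control_only*. Always `shared + gained = |test|`.
#'
#' @param test,reference `loop_set` objects (or coercible data.frames).
#' @param slop pad each anchor by this many bp before testing overlap
#'   (default 0: >= 1 bp shared required).
#' @return a `loop_classification` list: `test` (test set with `label`
#'   filled in), `control_only` (reference subset), `counts` (named vector
#'   shared/gained/control_only).
#' @export
classify_loops <- function(test, reference, slop = 0) {
  test <- loop_set(test, name = attr(test, "name") %||% "test")
  reference <- loop_set(reference, name = attr(reference, "name") %||% "reference")
  if (nrow(test) == 0L || nrow(reference) == 0L) {
    test$label <- rep("gained", nrow(test))
    ref_matched <- logical(nrow(reference))
  } else {
    lev <- unique(c(test$chrom1, reference$chrom1))
    tl <- .anchors_granges(test$chrom1, test$start1, test$end1, slop, lev)
    tr <- .anchors_granges(test$chrom2, test$start2, test$end2, slop, lev)
    rl <- .anchors_granges(reference$chrom1, reference$start1,
                           reference$end1, levels = lev)
    rr <- .anchors_granges(reference$chrom2, reference$start2,
                           reference$end2, levels = lev)
    hl <- GenomicRanges::findOverlaps(tl, rl)
    hr <- GenomicRanges::findOverlaps(tr, rr)
    key_l <- paste(S4Vectors::queryHits(hl), S4Vectors::subjectHits(hl))
    key_r <- paste(S4Vectors::queryHits(hr), S4Vectors::subjectHits(hr))
    both <- key_l %in% key_r
    shared_test <- unique(S4Vectors::queryHits(hl)[both])
    matched_ref <- unique(S4Vectors::subjectHits(hl)[both])
    test$label <- ifelse(seq_len(nrow(test)) %in% shared_test,
                         "shared", "gained")
    ref_matched <- seq_len(nrow(reference)) %in% matched_ref
  }
  control_only <- reference[!ref_matched, , drop = FALSE]
  control_only$label <- rep("control_only", nrow(control_only))
  counts <- c(shared = sum(test$label == "shared"),
              gained = sum(test$label == "gained"),
              control_only = nrow(control_only))
  structure(list(test = loop_set(test, name = attr(test, "name")),
                 control_only = control_only,
                 counts = counts),
            class = "loop_classification")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.loop_classification <- function(x, ...) {
  cat(sprintf("loop classification: %d shared + %d gained (test n=%d); %d reference control-only\n",
              x$counts[["shared"]], x$counts[["gained"]],
              x$counts[["shared"]] + x$counts[["gained"]],
              x$counts[["control_only"]]))
  invisible(x)
}

#' Loop length statistics
#'
#' Loop length is the distance between anchor midpoints in bp
#' (`method = "midpoint"`, robust to anchor width/bin resolution) or between
#' anchor starts (`method = "start"`). The median is the standard order
#' statistic (mean of the middle two for even n); quartiles use the default
#' quantile definition.
#'
#' @param s a `loop_set`.
#' @param method `"midpoint"` (default) or `"start"`.
#' @return list with `n`, `median`, `q1`, `q3`, `lengths`.
#' @export
loop_length_stats <- function(s, method = c("midpoint", "start")) {
  method <- match.arg(method)
  s <- loop_set(s, name = attr(s, "name") %||% "loops")
  if (nrow(s) == 0L) stop("loop set is empty")
  lengths <- if (method == "midpoint") {
    (s$start2 + s$end2) / 2 - (s$start1 + s$end1) / 2
  } else {
    s$start2 - s$start1
  }
  q <- stats::quantile(lengths, c(0.25, 0.75), names = FALSE)
  list(n = length(lengths),
       median = stats::median(lengths),
       q1 = q[1], q3 = q[2],
       lengths = lengths)
}

#' Pairwise Venn overlap of two peak sets
#'
#' A peak in set A is "overlapping" iff it overlaps at least one peak in set
#' B (>= 1 bp, half-open semantics), and symmetrically for B. Because one
#' peak can overlap several on the other side, the two overlap counts need
#' not be equal.
#'
#' @param a,b `interval_set` objects (or coercible data.frames).
#' @return a `peak_venn` list: `a_with_overlap`, `a_only`, `b_with_overlap`,
#'   `b_only` counts plus `n_a`, `n_b`.
#' @export
peak_set_venn <- function(a, b) {
  a <- interval_set(a)
  b <- interval_set(b)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    a_hit <- 0L; b_hit <- 0L
  } else {
    lev <- unique(c(a$chrom, b$chrom))
    ga <- .anchors_granges(a$chrom, a$start, a$end, levels = lev)
    gb <- .anchors_granges(b$chrom, b$start, b$end, levels = lev)
    a_hit <- sum(GenomicRanges::countOverlaps(ga, gb) > 0L)
    b_hit <- sum(GenomicRanges::countOverlaps(gb, ga) > 0L)
  }
  structure(list(
    a_with_overlap = a_hit, a_only = nrow(a) - a_hit,
    b_with_overlap = b_hit, b_only = nrow(b) - b_hit,
    n_a = nrow(a), n_b = nrow(b)
  ), class = "peak_venn")
}

#' @export
print.peak_venn <- function(x, ...) {
  cat(sprintf("peak venn: A n=%d (%d overlapping, %d unique); B n=%d (%d overlapping, %d unique)\n",
              x$n_a, x$a_with_overlap, x$a_only,
              x$n_b, x$b_with_overlap, x$b_only))
  invisible(x)
}

.parse_table_lines <- function(path, min_fields, what) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < min_fields)) {
    i <- which(nf < min_fields)[1]
    stop(sprintf("%s parse error at line %d of %s: expected >= %d tab-separated fields, found %d",
                 what, idx[i], path, min_fields, nf[i]))
  }
  list(fields = fields, line_numbers = idx)
}

.parse_coord <- function(x, line_numbers, path, what) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v))) {
    i <- which(is.na(v))[1]
    stop(sprintf("%s parse error at line %d of %s: non-numeric coordinate '%s'",
                 what, line_numbers[i], path, x[i]))
  }
  v
}

#' Read / write BED interval files
#'
#' Standard 3+ column, headerless, tab-separated BED; `track`/`browser`/`#`
#' lines are skipped; coordinates are kept verbatim (0-based half-open).
#' Malformed lines are rejected with their line number.
#'
#' @param path BED path.
#' @return an `interval_set` (read); `path` invisibly (write).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED not found: ", path)
  p <- .parse_table_lines(path, 3L, "BED")
  if (length(p$fields) == 0L)
    return(interval_set(data.frame(chrom = character(), start = numeric(),
                                   end = numeric())))
  chrom <- vapply(p$fields, `[[`, "", 1L)
  start <- .parse_coord(vapply(p$fields, `[[`, "", 2L), p$line_numbers, path, "BED")
  end <- .parse_coord(vapply(p$fields, `[[`, "", 3L), p$line_numbers, path, "BED")
  name <- vapply(p$fields, function(f) if (length(f) >= 4L) f[[4L]] else "", "")
  df <- data.frame(chrom = chrom, start = start, end = end)
  if (any(nzchar(name))) df$name <- name
  tryCatch(interval_set(df),
           error = function(e) stop("invalid BED intervals in ", path, ": ",
                                    conditionMessage(e)))
}

#' @rdname read_bed
#' @param x an `interval_set`.
#' @export
write_bed <- function(x, path) {
  x <- interval_set(x)
  cols <- data.frame(x$chrom, format_coord(x$start), format_coord(x$end))
  if ("name" %in% names(x)) cols$name <- x$name
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Coordinates are written as plain integers (no scientific notation).
format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read / write BEDPE loop files
#'
#' 6+ column, headerless, tab-separated BEDPE (chrom1 start1 end1 chrom2
#' start2 end2 [name] [label...]); coordinates verbatim, 0-based half-open.
#' Rows whose anchors sit on different chromosomes violate the loop
#' invariant and are rejected.
#'
#' @param path BEDPE path.
#' @param name loop-set name.
#' @return a `loop_set` (read); `path` invisibly (write).
#' @export
read_bedpe <- function(path, name = NULL) {
  if (!file.exists(path)) stop("BEDPE not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  p <- .parse_table_lines(path, 6L, "BEDPE")
  if (length(p$fields) == 0L)
    return(loop_set(data.frame(chrom1 = character(), start1 = numeric(),
                               end1 = numeric(), chrom2 = character(),
                               start2 = numeric(), end2 = numeric()),
                    name = name))
  get <- function(i) vapply(p$fields, `[[`, "", i)
  df <- data.frame(
    chrom1 = get(1L),
    start1 = .parse_coord(get(2L), p$line_numbers, path, "BEDPE"),
    end1 = .parse_coord(get(3L), p$line_numbers, path, "BEDPE"),
    chrom2 = get(4L),
    start2 = .parse_coord(get(5L), p$line_numbers, path, "BEDPE"),
    end2 = .parse_coord(get(6L), p$line_numbers, path, "BEDPE"))
  nm <- vapply(p$fields, function(f) if (length(f) >= 7L) f[[7L]] else "", "")
  if (any(nzchar(nm))) df$name <- nm
  lb <- vapply(p$fields, function(f) if (length(f) >= 8L) f[[8L]] else "", "")
  if (any(nzchar(lb))) df$label <- ifelse(nzchar(lb), lb, NA_character_)
  tryCatch(loop_set(df, name = name),
           error = function(e) stop("invalid BEDPE loops in ", path, ": ",
                                    conditionMessage(e)))
}

#' @rdname read_bedpe
#' @param x a `loop_set`.
#' @export
write_bedpe <- function(x, path) {
  x <- loop_set(x, name = attr(x, "name") %||% "loops")
  out <- data.frame(x$chrom1, format_coord(x$start1), format_coord(x$end1),
                    x$chrom2, format_coord(x$start2), format_coord(x$end2),
                    x$name)
  if (any(!is.na(x$label))) out$label <- ifelse(is.na(x$label), ".", x$label)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
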