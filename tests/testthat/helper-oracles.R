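# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive results with naive double loops and direct string
# arithmetic, sharing no code path with the package implementations.

# Exact-match counting oracle: for each trimmed read, test every library
# protospacer by direct string comparison right after the anchor; longer
# protospacers win, each read counts for at most one guide.
brute_count_reads <- function(reads, protospacers, guide_ids, anchor) {
  counts <- stats::setNames(rep(0L, length(guide_ids)), guide_ids)
  unassigned <- 0L
  ord <- order(-nchar(protospacers))
  for (r in reads) {
    hit <- NA_integer_
    for (g in ord) {
      target <- paste0(anchor, protospacers[g])
      if (nchar(r) >= nchar(target) &&
          substr(r, 1L, nchar(target)) == target) {
        hit <- g
        break
      }
    }
    if (is.na(hit)) unassigned <- unassigned + 1L
    else counts[guide_ids[hit]] <- counts[guide_ids[hit]] + 1L
  }
  list(counts = counts, unassigned = unassigned)
}

# O(n*m) loop classification oracle with its own overlap arithmetic.
brute_overlap <- function(c1, s1, e1, c2, s2, e2) {
  c1 == c2 && max(s1, s2) < min(e1, e2)
}

brute_classify_loops <- function(test, reference) {
  labels <- character(nrow(test))
  ref_matched <- logical(nrow(reference))
  for (i in seq_len(nrow(test))) {
    lab <- "gained"
    for (j in seq_len(nrow(reference))) {
      if (brute_overlap(test$chrom1[i], test$start1[i], test$end1[i],
                        reference$chrom1[j], reference$start1[j], reference$end1[j]) &&
          brute_overlap(test$chrom2[i], test$start2[i], test$end2[i],
                        reference$chrom2[j], reference$start2[j], reference$end2[j])) {
        lab <- "shared"
        ref_matched[j] <- TRUE
      }
    }
    labels[i] <- lab
  }
  list(labels = labels, ref_matched = ref_matched)
}

brute_peak_venn <- function(a, b) {
  a_hit <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (brute_overlap(a$chrom[i], a$start[i], a$end[i],
                        b$chrom[j], b$start[j], b$end[j])) {
        a_hit <- a_hit + 1L
        break
      }
    }
  }
  a_hit
}

# Independent enrichment filter (floor-one policy).
brute_enriched <- function(tab, threshold) {
  out <- character()
  for (i in seq_len(nrow(tab))) {
    cs <- tab$case_peptides[i]
    ct <- tab$control_peptides[i]
    if (cs == 0L && ct == 0L) next
    if (cs / max(ct, 1L) >= threshold) out <- c(out, tab$protein_id[i])
  }
  out
}

# Fixture builders ----------------------------------------------------------

tiny_library <- function() {
  sgrna_library(data.frame(
    guide_id = c("g1", "g2", "g3", "g4", "g5"),
    gene_symbol = c("GENEA", "GENEA", "GENEB", "NON_TARGETING", "PCNA"),
    protospacer = c("ACGTACGTACGTACGTACGT", "TTTTACGTACGTACGTACGT",
                    "GGGGACGTACGTACGTACGT", "CCCCACGTACGTACGTACGT",
                    "AACCACGTACGTACGTACGT"),
    category = c("targeting", "targeting", "targeting",
                 "non_targeting", "positive_control"),
    domain_annotation = c("dom1", "dom1", "", "", "")
  ), name = "tiny")
}

tiny_sheet <- function() {
  sample_sheet(data.frame(
    sample_id = c("L1_initial", "L1_final"),
    cell_line = "L1",
    timepoint = c("initial", "final"),
    barcode = c("ACGT", "TGCA"),
    stagger_len = c(0L, 2L)
  ))
}

small_screen_config <- function(...) {
  screen_sim_config(n_genes = 25, n_targeting_guides = 160,
                    n_nontargeting = 12, n_positive_control_guides = 6,
                    n_biased_genes = 5, representation = 300, ...)
}

random_loop_df <- function(n, chroms = c("chr1", "chr2"), span = 1e6) {
  repeat {
    left <- floor(runif(n, 0, span))
    len <- floor(runif(n, 5e3, 2e5))
    width <- floor(runif(n, 500, 5e3))
    df <- data.frame(chrom1 = sample(chroms, n, replace = TRUE),
                     start1 = left, end1 = left + width,
                     start2 = left + len, end2 = left + len + width)
    df$chrom2 <- df$chrom1
    key <- paste(df$chrom1, df$start1, df$end1, df$start2, df$end2)
    if (!anyDuplicated(key)) return(df)
  }
}
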