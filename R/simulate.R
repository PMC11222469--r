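# Seeded synthetic-data generators with planted ground truth. Defaults
# reproduce the composition of the study conditions every estimator module
# is expected to handle: a 2405-guide / 381-gene domain-focused library with
# 100 non-targeting and 20 positive-control guides screened across 6 cell
# lines (2 AML, 4 non-AML), dual interactome tables with 395 and 60 planted
# interactors sharing 4 proteins, and loop sets of 10,662 reference /
# 11,871 test loops with 225 kb / 310 kb median lengths.

.rand_dna <- function(n, len) {
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n), function(i)
    paste(sample(bases, len, replace = TRUE), collapse = ""), "")
}

.unique_rand_dna <- function(n, len, exclude = character()) {
  out <- character(0)
  tries <- 0L
  while (length(out) < n) {
    need <- n - length(out)
    cand <- .rand_dna(need + ceiling(need * 0.1) + 5L, len)
    cand <- setdiff(unique(cand), c(out, exclude))
    out <- c(out, cand)
    tries <- tries + 1L
    if (tries > 100L) stop("could not generate enough unique sequences")
  }
  out[seq_len(n)]
}

#' Screen simulator configuration
#'
#' Defaults mirror the study library: 2405 targeting guides spread over 381
#' genes (mean 6.3 guides/gene), 100 non-targeting guides, 20
#' positive-control guides over 6 pan-essential genes, screened in 2 AML
#' and 4 non-AML cell lines at 1000x per-guide representation with
#' negative-binomial dispersion 0.05 (a tight, plasmid-pool-like spread).
#' Planted effects are log2 depletion units per population-doubling window:
#' `pan_essential_effect` applies to positive-control genes in every line,
#' `biased_effect` to `n_biased_genes` randomly chosen targeting genes in
#' the lines of `biased_group` only.
#'
#' @param n_genes number of targeting genes.
#' @param n_targeting_guides total targeting guides, distributed as evenly
#'   as possible over genes; ignored when `guides_per_gene` is given.
#' @param guides_per_gene optional fixed guides per gene.
#' @param n_nontargeting non-targeting guide count.
#' @param positive_control_genes names of pan-essential control genes.
#' @param n_positive_control_guides guides spread over the control genes.
#' @param cell_lines named character vector: names are cell lines, values
#'   are group labels (e.g. `"AML"` / `"other"`).
#' @param representation expected reads per guide per sample.
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param pan_essential_effect log2 effect of positive-control genes.
#' @param biased_effect log2 effect of biased genes in the focal group.
#' @param n_biased_genes number of planted group-biased genes.
#' @param biased_group group label receiving the biased effect.
#' @param protospacer_len guide length (nt).
#' @param anchor constant vector sequence placed 5' of the protospacer.
#' @param barcode_len sample barcode length.
#' @param max_stagger stagger lengths cycle over 0..max_stagger.
#' @param error_rate per-base substitution rate applied to simulated reads
#'   (FASTQ output only); default 0, since exact-match counting is the
#'   contract under test.
#' @return config list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_genes = 381L,
                              n_targeting_guides = 2405L,
                              guides_per_gene = NULL,
                              n_nontargeting = 100L,
                              positive_control_genes = c("CDK1", "CDK9", "PCNA",
                                                         "POLR2A", "RPA3", "RPL23A"),
                              n_positive_control_guides = 20L,
                              cell_lines = c(MOLM13 = "AML", MV411 = "AML",
                                             JURKAT = "other", U2932 = "other",
                                             OPM1 = "other", HEPG2 = "other"),
                              representation = 1000,
                              dispersion = 0.05,
                              pan_essential_effect = -3,
                              biased_effect = -2,
                              n_biased_genes = 20L,
                              biased_group = "AML",
                              protospacer_len = 20L,
                              anchor = "GACGAAACACCG",
                              barcode_len = 6L,
                              max_stagger = 7L,
                              error_rate = 0) {
  if (!is.null(guides_per_gene))
    n_targeting_guides <- as.integer(guides_per_gene) * as.integer(n_genes)
  cfg <- list(n_genes = as.integer(n_genes),
              n_targeting_guides = as.integer(n_targeting_guides),
              n_nontargeting = as.integer(n_nontargeting),
              positive_control_genes = positive_control_genes,
              n_positive_control_guides = as.integer(n_positive_control_guides),
              cell_lines = cell_lines,
              representation = representation,
              dispersion = dispersion,
              pan_essential_effect = pan_essential_effect,
              biased_effect = biased_effect,
              n_biased_genes = as.integer(n_biased_genes),
              biased_group = biased_group,
              protospacer_len = as.integer(protospacer_len),
              anchor = toupper(anchor),
              barcode_len = as.integer(barcode_len),
              max_stagger = as.integer(max_stagger),
              error_rate = error_rate)
  stopifnot(cfg$n_genes > 0L, cfg$n_targeting_guides >= cfg$n_genes,
            cfg$n_nontargeting >= 0L, cfg$representation > 0,
            cfg$dispersion > 0, cfg$n_biased_genes <= cfg$n_genes,
            cfg$protospacer_len >= 18L, cfg$protospacer_len <= 23L,
            grepl("^[ACGT]+$", cfg$anchor),
            cfg$error_rate >= 0, cfg$error_rate < 1,
            length(cfg$cell_lines) >= 1L, !is.null(names(cfg$cell_lines)))
  class(cfg) <- "screen_sim_config"
  cfg
}

.build_sim_library <- function(cfg) {
  genes <- sprintf("CRL%03d", seq_len(cfg$n_genes))
  base <- cfg$n_targeting_guides %/% cfg$n_genes
  extra <- cfg$n_targeting_guides %% cfg$n_genes
  per_gene <- rep(base, cfg$n_genes) + c(rep(1L, extra), rep(0L, cfg$n_genes - extra))
  pc_genes <- cfg$positive_control_genes
  pc_per_gene <- tabulate(rep_len(seq_along(pc_genes),
                                  cfg$n_positive_control_guides),
                          nbins = length(pc_genes))
  gene_symbol <- c(rep(genes, per_gene),
                   rep(NON_TARGETING_SENTINEL, cfg$n_nontargeting),
                   rep(pc_genes, pc_per_gene))
  category <- c(rep("targeting", cfg$n_targeting_guides),
                rep("non_targeting", cfg$n_nontargeting),
                rep("positive_control", cfg$n_positive_control_guides))
  n <- length(gene_symbol)
  protospacer <- .unique_rand_dna(n, cfg$protospacer_len)
  records <- data.frame(
    guide_id = sprintf("sg%04d_%s", seq_len(n), gene_symbol),
    gene_symbol = gene_symbol,
    protospacer = protospacer,
    category = category,
    domain_annotation = ifelse(category == "targeting",
                               "receptor-adaptor interacting domain", ""))
  sgrna_library(records, name = "simulated_crl_library")
}

.build_sim_sheet <- function(cfg) {
  lines <- names(cfg$cell_lines)
  samples <- expand.grid(timepoint = c("initial", "final"),
                         cell_line = lines, stringsAsFactors = FALSE)
  n <- nrow(samples)
  for (attempt in seq_len(50L)) {
    barcodes <- .unique_rand_dna(n, cfg$barcode_len)
    sheet <- data.frame(
      sample_id = paste(samples$cell_line, samples$timepoint, sep = "_"),
      cell_line = samples$cell_line,
      timepoint = samples$timepoint,
      barcode = barcodes,
      stagger_len = (seq_len(n) - 1L) %% (cfg$max_stagger + 1L))
    ok <- tryCatch({
      .check_sheet_ambiguity(sample_sheet(sheet), cfg$anchor)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(sample_sheet(sheet))
  }
  stop("could not generate an unambiguous barcode set")
}

#' Simulate a pooled dropout screen with planted fitness effects
#'
#' Initial per-guide counts are negative binomial around the configured
#' representation; expected final counts are the initial expectation times
#' `2^effect(gene, line)`. Non-targeting guides have effect 0 in every
#' line, positive-control genes the pan-essential effect in every line, and
#' the planted biased genes the biased effect in the focal-group lines only.
#'
#' @param cfg a [screen_sim_config()].
#' @param seed integer seed; the same seed and config reproduce identical
#'   output (byte-identical FASTQ in `output = "fastq"` mode).
#' @param output `"counts"` returns a `count_matrix` directly; `"fastq"`
#'   additionally assembles reads as
#'   `[stagger][barcode][anchor][protospacer][scaffold]` and writes one
#'   FASTQ per sample into `dir`.
#' @param dir output directory for FASTQ mode.
#' @return list with `library`, `sheet`, `counts` (a `count_matrix`),
#'   `fastq` (named paths, FASTQ mode only) and `truth` (planted per-gene
#'   effects matrix, biased gene names, per-guide expected counts, config,
#'   seed).
#' @export
simulate_screen <- function(cfg = screen_sim_config(), seed = 1L,
                            output = c("counts", "fastq"), dir = NULL) {
  output <- match.arg(output)
  stopifnot(inherits(cfg, "screen_sim_config"))
  set.seed(as.integer(seed))
  lib <- .build_sim_library(cfg)
  sheet <- .build_sim_sheet(cfg)
  rec <- lib$records
  genes <- unique(rec$gene_symbol)
  lines <- names(cfg$cell_lines)

  targeting_genes <- unique(rec$gene_symbol[rec$category == "targeting"])
  biased_genes <- sort(sample(targeting_genes, cfg$n_biased_genes))
  effects <- matrix(0, nrow = length(genes), ncol = length(lines),
                    dimnames = list(genes, lines))
  pc <- intersect(cfg$positive_control_genes, genes)
  effects[pc, ] <- cfg$pan_essential_effect
  focal_lines <- lines[cfg$cell_lines == cfg$biased_group]
  effects[biased_genes, focal_lines] <- cfg$biased_effect

  n_guides <- nrow(rec)
  mu0 <- cfg$representation
  size <- 1 / cfg$dispersion
  counts <- matrix(0L, nrow = n_guides, ncol = nrow(sheet),
                   dimnames = list(rec$guide_id, sheet$sample_id))
  expected <- matrix(0, nrow = n_guides, ncol = nrow(sheet),
                     dimnames = dimnames(counts))
  for (s in seq_len(nrow(sheet))) {
    eff <- if (sheet$timepoint[s] == "initial") rep(0, n_guides)
           else effects[rec$gene_symbol, sheet$cell_line[s]]
    mu <- mu0 * 2^eff
    counts[, s] <- stats::rnbinom(n_guides, mu = mu, size = size)
    expected[, s] <- mu
  }
  cm <- count_matrix(counts)
  out <- list(library = lib, sheet = sheet, counts = cm,
              truth = list(effects = effects, biased_genes = biased_genes,
                           expected_counts = expected,
                           config = cfg, seed = as.integer(seed)))
  if (output == "fastq") {
    if (is.null(dir)) stop("output = 'fastq' requires a target dir")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    scaffold <- "GTTTAAGAGCTAAGCTGGAA"
    paths <- character(nrow(sheet))
    names(paths) <- sheet$sample_id
    for (s in seq_len(nrow(sheet))) {
      ps <- rep(rec$protospacer, counts[, s])
      ps <- sample(ps)  # shuffle read order
      stagger <- sheet$stagger_len[s]
      prefix <- if (stagger > 0L) .rand_dna(length(ps), stagger) else rep("", length(ps))
      reads <- paste0(prefix, sheet$barcode[s], cfg$anchor, ps, scaffold)
      if (cfg$error_rate > 0) reads <- .mutate_reads(reads, cfg$error_rate)
      paths[s] <- file.path(dir, paste0(sheet$sample_id[s], ".fastq"))
      .write_fastq(reads, paths[s], prefix = sheet$sample_id[s])
    }
    out$fastq <- paths
  }
  out
}

.mutate_reads <- function(reads, rate) {
  bases <- c("A", "C", "G", "T")
  vapply(reads, function(r) {
    chars <- strsplit(r, "", fixed = TRUE)[[1]]
    hit <- stats::runif(length(chars)) < rate
    if (any(hit))
      chars[hit] <- vapply(chars[hit], function(b)
        sample(setdiff(bases, b), 1L), "")
    paste(chars, collapse = "")
  }, "", USE.NAMES = FALSE)
}

.write_fastq <- function(reads, path, prefix = "read") {
  n <- length(reads)
  lines <- character(4L * n)
  if (n > 0L) {
    lines[seq(1L, 4L * n, by = 4L)] <- sprintf("@%s_%07d", prefix, seq_len(n))
    lines[seq(2L, 4L * n, by = 4L)] <- reads
    lines[seq(3L, 4L * n, by = 4L)] <- "+"
    lines[seq(4L, 4L * n, by = 4L)] <- strrep("I", nchar(reads))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate dual unique-peptide interactome experiments
#'
#' Two case/control experiments (immunoprecipitation-style and
#' proximity-labeling-style). Background proteins get a per-protein
#' abundance `lambda ~ lognormal(background_meanlog, background_sdlog)` and
#' Poisson case and control counts around it (consistently detected
#' nonspecific binders). Planted interactors get a low control abundance
#' and a case count of at least `planted_fold * max(control, 1)` peptides
#' (with upward Poisson noise), so every planted protein passes the
#' fold rule at thresholds up to `planted_fold`. The first
#' `n_shared_planted` interactors (named by `shared_proteins`) are planted
#' in both experiments, seeding the Venn intersection; defaults mirror the
#' study's 395- and 60-member interactomes sharing 4 proteins.
#'
#' @param n_proteins proteins per experiment (length-2 vector or scalar).
#' @param n_planted planted interactors per experiment.
#' @param planted_fold guaranteed minimum fold enrichment of planted
#'   interactors.
#' @param n_shared_planted interactors planted in both experiments.
#' @param shared_proteins names given to the shared interactors.
#' @param background_meanlog,background_sdlog lognormal parameters of the
#'   background unique-peptide abundance.
#' @param experiment_names names of the two experiments.
#' @param seed integer seed.
#' @return list with `tables` (named list of two [peptide_count_table()]s)
#'   and `truth` (per-experiment planted protein ids, shared ids, seed).
#' @export
simulate_peptides <- function(n_proteins = c(1500L, 1000L),
                              n_planted = c(395L, 60L),
                              planted_fold = 8,
                              n_shared_planted = 4L,
                              shared_proteins = c("VPRBP", "SMC3", "SMC1A", "MCM4"),
                              background_meanlog = 2.5,
                              background_sdlog = 0.5,
                              experiment_names = c("flag_ip", "proximity"),
                              seed = 1L) {
  set.seed(as.integer(seed))
  n_proteins <- rep_len(as.integer(n_proteins), 2L)
  n_planted <- rep_len(as.integer(n_planted), 2L)
  n_shared_planted <- as.integer(n_shared_planted)
  stopifnot(all(n_planted <= n_proteins), n_shared_planted <= min(n_planted),
            planted_fold > 1, n_shared_planted >= 0L)
  if (length(shared_proteins) < n_shared_planted)
    shared_proteins <- c(shared_proteins,
                         sprintf("SHARED%02d",
                                 seq_len(n_shared_planted - length(shared_proteins))))
  shared <- shared_proteins[seq_len(n_shared_planted)]
  n_bg_max <- max(n_proteins - n_planted)
  bg_pool <- sprintf("BG%05d", seq_len(n_bg_max))
  tables <- list()
  planted_ids <- list()
  for (e in 1:2) {
    n_own <- n_planted[e] - n_shared_planted
    planted <- c(shared,
                 if (n_own > 0L) sprintf("%s_INT%04d",
                                         toupper(experiment_names[e]),
                                         seq_len(n_own)))
    background <- bg_pool[seq_len(n_proteins[e] - n_planted[e])]
    lam_bg <- stats::rlnorm(length(background), background_meanlog,
                            background_sdlog)
    bg_case <- stats::rpois(length(background), lam_bg)
    bg_ctrl <- stats::rpois(length(background), lam_bg)
    lam_pl <- stats::rlnorm(length(planted), meanlog = 0, sdlog = 1)
    pl_ctrl <- stats::rpois(length(planted), lam_pl)
    floor_case <- planted_fold * pmax(pl_ctrl, 1L)
    pl_case <- floor_case + stats::rpois(length(planted), 0.25 * floor_case)
    tab <- data.frame(protein_id = c(planted, background),
                      case_peptides = c(pl_case, bg_case),
                      control_peptides = c(pl_ctrl, bg_ctrl))
    tab <- tab[sample(nrow(tab)), , drop = FALSE]
    tables[[experiment_names[e]]] <- peptide_count_table(tab)
    planted_ids[[experiment_names[e]]] <- planted
  }
  list(tables = tables,
       truth = list(planted = planted_ids, shared = shared,
                    planted_fold = planted_fold, seed = as.integer(seed)))
}

#' Simulate reference and test chromatin-loop sets with planted classes
#'
#' Reference loops (the control condition) get lognormal lengths with
#' median `median_ref`; anchors are one genome bin wide and snapped to the
#' bin grid of a synthetic genome. The test condition copies `n_shared`
#' reference loops (anchors jittered by less than the anchor width, so the
#' overlap is preserved) and adds `n_gained` loops whose anchors avoid
#' every reference anchor bin; the remaining `n_control_only` reference
#' loops have no test counterpart. Gained-loop lengths are drawn from a
#' lognormal whose median is solved internally so the full test set's
#' median length equals `median_test`. Defaults reproduce the study's set
#' sizes (10,662 reference, 11,871 test) and 225 kb / 310 kb medians.
#'
#' @param n_shared test loops copying a reference loop.
#' @param n_gained test loops absent from the reference.
#' @param n_control_only reference loops absent from the test set.
#' @param median_ref,median_test target median loop lengths (bp, anchor
#'   midpoint to anchor midpoint).
#' @param length_sdlog lognormal sd of log loop length.
#' @param bin_size genome bin size (bp); anchors are one bin wide.
#' @param chromosomes named numeric vector of chromosome lengths (bp).
#' @param jitter jitter shared-loop anchors (uniform within +/- half a bin).
#' @param min_length minimum loop length (bp).
#' @param seed integer seed.
#' @return list with `reference` and `test` (`loop_set`s) and `truth`
#'   (`test_labels` in test-row order, `ref_status`, the solved gained-loop
#'   median, config echo, seed).
#' @export
simulate_loops <- function(n_shared = 8000L, n_gained = 3871L,
                           n_control_only = 2662L,
                           median_ref = 225e3, median_test = 310e3,
                           length_sdlog = 0.6,
                           bin_size = 10e3,
                           chromosomes = stats::setNames(rep(130e6, 23),
                                                         paste0("chr", 1:23)),
                           jitter = TRUE, min_length = 30e3,
                           seed = 1L) {
  set.seed(as.integer(seed))
  n_shared <- as.integer(n_shared); n_gained <- as.integer(n_gained)
  n_control_only <- as.integer(n_control_only)
  stopifnot(n_shared >= 0L, n_gained >= 0L, n_control_only >= 0L,
            n_shared + n_control_only + n_gained > 0L,
            bin_size > 0, min_length >= 2 * bin_size,
            length(chromosomes) > 0, !is.null(names(chromosomes)))
  n_ref <- n_shared + n_control_only
  n_test <- n_shared + n_gained

  # solve the gained-loop median so the shared/gained mixture hits median_test
  median_gained <- NA_real_
  if (n_gained > 0L) {
    if (n_shared == 0L) {
      median_gained <- median_test
    } else {
      p <- n_shared / n_test
      f_shared <- stats::plnorm(median_test, log(median_ref), length_sdlog)
      f_gained <- (0.5 - p * f_shared) / (1 - p)
      if (f_gained <= 0 || f_gained >= 1)
        stop("requested test median is infeasible for this shared/gained split")
      median_gained <- exp(log(median_test) -
                             length_sdlog * stats::qnorm(f_gained))
    }
  }

  draw_lengths <- function(n, med) {
    L <- stats::rlnorm(n, meanlog = log(med), sdlog = length_sdlog)
    pmax(round(L / bin_size) * bin_size, min_length)
  }
  place_loops <- function(lengths) {
    n <- length(lengths)
    chrom_idx <- sample.int(length(chromosomes), n, replace = TRUE,
                            prob = chromosomes / sum(chromosomes))
    max_bin <- floor((chromosomes[chrom_idx] - lengths) / bin_size) - 1L
    if (any(max_bin < 1))
      stop("chromosome(s) too short for requested loop lengths")
    left <- (1L + floor(stats::runif(n) * max_bin)) * bin_size
    data.frame(chrom = names(chromosomes)[chrom_idx],
               left = left, right = left + lengths)
  }
  loop_key <- function(df) paste(df$chrom, df$left, df$right)

  # reference set: resample duplicates until all anchor pairs distinct
  ref <- place_loops(draw_lengths(n_ref, median_ref))
  for (i in seq_len(100L)) {
    dup <- duplicated(loop_key(ref))
    if (!any(dup)) break
    ref[dup, ] <- place_loops(draw_lengths(sum(dup), median_ref))
  }
  if (anyDuplicated(loop_key(ref))) stop("infeasible reference placement")

  ref_bins <- unique(paste(ref$chrom, c(ref$left, ref$right)))

  gained <- NULL
  if (n_gained > 0L) {
    gained <- place_loops(draw_lengths(n_gained, median_gained))
    for (i in seq_len(100L)) {
      clash <- paste(gained$chrom, gained$left) %in% ref_bins |
        paste(gained$chrom, gained$right) %in% ref_bins |
        duplicated(loop_key(gained))
      if (!any(clash)) break
      gained[clash, ] <- place_loops(draw_lengths(sum(clash), median_gained))
    }
    if (any(paste(gained$chrom, gained$left) %in% ref_bins |
              paste(gained$chrom, gained$right) %in% ref_bins) ||
        anyDuplicated(loop_key(gained)))
      stop("infeasible gained-loop placement after bounded retries")
  }

  shared_idx <- if (n_shared > 0L) sort(sample.int(n_ref, n_shared)) else integer()
  shared <- ref[shared_idx, , drop = FALSE]
  if (jitter && n_shared > 0L) {
    jmax <- max(floor(bin_size / 2) - 1, 0)
    shared$left <- pmax(shared$left +
                          sample(seq(-jmax, jmax), n_shared, replace = TRUE), 0)
    shared$right <- shared$right +
      sample(seq(-jmax, jmax), n_shared, replace = TRUE)
  }

  as_loopset <- function(df, name, ids) {
    loop_set(data.frame(chrom1 = df$chrom, start1 = df$left,
                        end1 = df$left + bin_size,
                        chrom2 = df$chrom, start2 = df$right,
                        end2 = df$right + bin_size,
                        name = ids), name = name)
  }
  ref_set <- as_loopset(ref, "reference", sprintf("ref_%05d", seq_len(n_ref)))
  test_df <- rbind(shared, gained)
  test_ids <- c(sprintf("shared_%05d", seq_len(n_shared)),
                if (n_gained > 0L) sprintf("gained_%05d", seq_len(n_gained)))
  test_labels <- c(rep("shared", n_shared), rep("gained", n_gained))
  if (n_test > 0L) {
    ord <- sample.int(n_test)  # shuffle so class is not encoded in row order
    test_df <- test_df[ord, , drop = FALSE]
    test_ids <- test_ids[ord]
    test_labels <- test_labels[ord]
  }
  test_set <- as_loopset(test_df, "test", test_ids)
  ref_status <- rep("control_only", n_ref)
  ref_status[shared_idx] <- "shared"
  list(reference = ref_set, test = test_set,
       truth = list(test_labels = stats::setNames(test_labels, test_ids),
                    ref_status = ref_status,
                    median_gained = median_gained,
                    n_shared = n_shared, n_gained = n_gained,
                    n_control_only = n_control_only,
                    median_ref = median_ref, median_test = median_test,
                    seed = as.integer(seed)))
}
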