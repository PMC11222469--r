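# Assay-level normalizations: competition-proliferation relative
# proportions, drug-sensitization ratios, and DNA-fiber restart ratios with
# a nonparametric two-sample comparison.

#' Construct a fluorescence time course
#'
#' A competition-proliferation assay tracks the percentage of
#' fluorescence-positive (sgRNA+) cells in a mixed population over days
#' post-infection; depletion of the sgRNA+ fraction indicates a fitness
#' cost of the knockout.
#'
#' @param day integer days, strictly increasing.
#' @param percent_positive percentages in \[0, 100\].
#' @param label sample label.
#' @return a `time_course` data.frame.
#' @export
time_course <- function(day, percent_positive, label = "sample") {
  day <- as.integer(day)
  percent_positive <- as.numeric(percent_positive)
  if (length(day) != length(percent_positive) || length(day) == 0L)
    stop("day and percent_positive must be non-empty and equal length")
  if (any(diff(day) <= 0L)) stop("days must be strictly increasing")
  if (any(percent_positive < 0) || any(percent_positive > 100))
    stop("percent_positive must lie in [0, 100]")
  df <- data.frame(day = day, percent_positive = percent_positive)
  attr(df, "label") <- label
  class(df) <- c("time_course", "data.frame")
  df
}

#' @rdname time_course
#' @param path TSV with columns `day`, `percent_positive`.
#' @export
read_time_course <- function(path, label = NULL) {
  if (!file.exists(path)) stop("time course not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "")
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  time_course(df$day, df$percent_positive, label = label)
}

#' Baseline-normalized relative proportions
#'
#' Each day's sgRNA+ percentage is divided by the baseline day's value
#' (day 3 post-infection by default, the earliest reliable flow readout),
#' so the baseline maps to exactly 1.0. If a control time course (e.g. a
#' safe-harbor-targeting guide co-tracked in the same experiment) is
#' supplied, each day is further divided by the control's same-day
#' baseline-normalized value.
#'
#' @param tc a [time_course()].
#' @param baseline_day day used as the normalization baseline.
#' @param control optional [time_course()] with values at every day of `tc`.
#' @return data.frame with `day` and `relative_proportion`.
#' @export
relative_proportion <- function(tc, baseline_day = 3L, control = NULL) {
  stopifnot(inherits(tc, "data.frame"))
  base_idx <- match(baseline_day, tc$day)
  if (is.na(base_idx))
    stop("baseline day ", baseline_day, " absent from time course")
  base <- tc$percent_positive[base_idx]
  if (base <= 0) stop("baseline percentage must be > 0")
  rel <- tc$percent_positive / base
  if (!is.null(control)) {
    ctrl_idx <- match(tc$day, control$day)
    if (any(is.na(ctrl_idx)))
      stop("control time course lacks day(s): ",
           paste(tc$day[is.na(ctrl_idx)], collapse = ", "))
    cb_idx <- match(baseline_day, control$day)
    if (is.na(cb_idx))
      stop("baseline day ", baseline_day, " absent from control time course")
    cbase <- control$percent_positive[cb_idx]
    if (cbase <= 0 || any(control$percent_positive[ctrl_idx] <= 0))
      stop("control percentages must be > 0 on all matched days")
    rel <- rel / (control$percent_positive[ctrl_idx] / cbase)
  }
  data.frame(day = tc$day, relative_proportion = rel)
}

#' Drug-sensitization ratio series
#'
#' Ratio of sgRNA+ proportions under drug treatment to the matched vehicle
#' (DMSO) series, day by day. A ratio below 1 indicates drug-specific
#' depletion of the knockout population, i.e. sensitization.
#'
#' @param treated,vehicle [time_course()] objects measured on the same days.
#' @return data.frame with `day` and `ratio`.
#' @export
drug_sensitization <- function(treated, vehicle) {
  if (!identical(as.integer(treated$day), as.integer(vehicle$day)))
    stop("treated and vehicle series must cover identical days")
  if (any(vehicle$percent_positive <= 0))
    stop("vehicle percentages must be > 0 at every day")
  data.frame(day = treated$day,
             ratio = treated$percent_positive / vehicle$percent_positive)
}

.fiber_ratios <- function(fibers, label, include_zero_restart) {
  stopifnot(all(c("cldu_len", "idu_len") %in% names(fibers)))
  cldu <- as.numeric(fibers$cldu_len)
  idu <- as.numeric(fibers$idu_len)
  bad <- !is.finite(cldu) | cldu <= 0 | !is.finite(idu) | idu < 0
  if (any(bad)) {
    warning(sprintf("%s: excluding %d fiber(s) with non-positive CldU or invalid IdU tract",
                    label, sum(bad)))
    cldu <- cldu[!bad]; idu <- idu[!bad]
  }
  ratios <- idu / cldu
  if (!include_zero_restart) ratios <- ratios[ratios > 0]
  ratios
}

#' DNA-fiber restart ratios and nonparametric comparison
#'
#' Per fiber, the IdU tract length is normalized to the matched CldU tract
#' (`ratio = idu / cldu`), which cancels fork-speed differences between
#' experimental conditions; the two conditions' ratio distributions are
#' compared with a two-tailed Mann-Whitney rank-sum test (exact when both
#' arms have <= 20 fibers and no ties, normal approximation with tie
#' correction otherwise). Fibers with a non-positive CldU tract are excluded
#' with a warning; fibers with a zero IdU tract (no restart) are kept as
#' ratio 0 by default.
#'
#' @param cond_a,cond_b data.frames with columns `cldu_len` and `idu_len`
#'   (one row per fiber), or numeric vectors of pre-computed ratios.
#' @param include_zero_restart keep fibers with idu = 0 as ratio 0.
#' @return list with `ratios_a`, `ratios_b`, `median_a`, `median_b`,
#'   `n_a`, `n_b`, `p_value` (two-tailed).
#' @export
fiber_restart <- function(cond_a, cond_b, include_zero_restart = TRUE) {
  ra <- if (is.numeric(cond_a)) as.numeric(cond_a)
        else .fiber_ratios(cond_a, "cond_a", include_zero_restart)
  rb <- if (is.numeric(cond_b)) as.numeric(cond_b)
        else .fiber_ratios(cond_b, "cond_b", include_zero_restart)
  if (length(ra) < 1L || length(rb) < 1L)
    stop("each condition needs at least one usable fiber")
  p <- NA_real_
  if (length(ra) >= 3L && length(rb) >= 3L) {
    use_exact <- max(length(ra), length(rb)) <= 20L
    p <- suppressWarnings(
      stats::wilcox.test(ra, rb, alternative = "two.sided",
                         exact = use_exact)$p.value)
  }
  list(ratios_a = ra, ratios_b = rb,
       median_a = stats::median(ra), median_b = stats::median(rb),
       n_a = length(ra), n_b = length(rb),
       p_value = p)
}

#' Read a fiber-length table
#'
#' @param path TSV with columns `cldu_len` and `idu_len` (tract lengths in
#'   micrometres or arbitrary units; the ratio is unit-free).
#' @return data.frame.
#' @export
read_fiber_table <- function(path) {
  if (!file.exists(path)) stop("fiber table not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "")
}
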