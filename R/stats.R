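# Per-sample aggregation and the nonparametric group comparisons used
# for imaging readouts, with the significance-star mapping
# * p < 0.05, ** p < 0.005, *** p < 0.001, **** p < 0.0001.

#' Map a p-value to significance stars
#'
#' `ns` for p >= 0.05, `*` for p < 0.05, `**` for p < 0.005, `***` for
#' p < 0.001, `****` for p < 0.0001 (the most significant applicable
#' level). Note the unusual `**` cut at 0.005.
#'
#' @param p p-value in `[0, 1]`.
#' @return Character scalar.
#' @export
p_stars <- function(p) {
  stopifnot(is.finite(p), p >= 0, p <= 1)
  if (p < 0.0001) "****"
  else if (p < 0.001) "***"
  else if (p < 0.005) "**"
  else if (p < 0.05) "*"
  else "ns"
}

new_group_comparison <- function(test, groups, statistic, p_value, method_detail,
                                 excluded = character(0)) {
  structure(list(test = test, groups = groups,
                 n = vapply(groups, length, integer(1)),
                 statistic = unname(statistic), p_value = unname(p_value),
                 stars = p_stars(p_value), method_detail = method_detail,
                 excluded = excluded),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (%s): statistic = %.4g, p = %.4g [%s]; n = %s\n",
              x$test, x$method_detail, x$statistic, x$p_value, x$stars,
              paste(sprintf("%s:%d", names(x$n), x$n), collapse = ", ")))
  if (length(x$excluded))
    cat("  excluded (undefined metric):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Two-sided Mann-Whitney test
#'
#' U statistic with midrank tie handling. The p-value is exact (full
#' enumeration of group assignments) when the combined sample size is
#' at most 12 and there are no ties, and otherwise uses the normal
#' approximation with tie and continuity correction.
#'
#' @param a,b numeric value vectors, each non-empty.
#' @return A `group_comparison` with `test = "mann_whitney"`.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 12) && !ties
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided",
                                     exact = exact, correct = TRUE))
  new_group_comparison("mann_whitney", list(a = a, b = b),
                       statistic = wt$statistic, p_value = wt$p.value,
                       method_detail = if (exact) "exact enumeration"
                                       else "normal approximation, tie/continuity corrected")
}

#' Kruskal-Wallis one-way ANOVA on ranks
#'
#' H statistic with tie correction; p from the chi-square approximation
#' with k - 1 degrees of freedom. The degenerate all-tied input returns
#' H = 0, p = 1 with a warning.
#'
#' @param groups named list (>= 2 entries) of numeric vectors, each
#'   non-empty, total n >= 3.
#' @return A `group_comparison` with `test = "kruskal_wallis"`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 1))
    stop("every group must be non-empty")
  values <- unlist(groups, use.names = FALSE)
  if (length(values) < 3) stop("need total n >= 3")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  labels <- factor(rep(names(groups), vapply(groups, length, integer(1))),
                   levels = names(groups))
  if (length(unique(values)) == 1) {
    warning("all values identical; H = 0, p = 1")
    return(new_group_comparison("kruskal_wallis", groups, statistic = 0,
                                p_value = 1, method_detail = "degenerate (all tied)"))
  }
  kt <- kruskal.test(values, labels)
  new_group_comparison("kruskal_wallis", groups, statistic = kt$statistic,
                       p_value = kt$p.value,
                       method_detail = "chi-square approximation, tie corrected")
}

#' Summarize one sample for group statistics
#'
#' Combines subtype calls, compartment allocations, morphometry and
#' (optionally) contact results of one sample into the per-sample row
#' that feeds group comparisons. Multi-image samples are summed before
#' percentages: pass a list of per-image `(calls, locations)` pairs or
#' pre-concatenated data frames. Percentages with an empty denominator
#' are `NA` (flagged undefined), never silently 0.
#'
#' @param calls a `subtype_calls` object, a calls data frame, or a list
#'   of either (multi-image sample).
#' @param locations output of [assign_cells()] matching `calls`
#'   row-for-row (or a list thereof).
#' @param morphometry a `region_morphometry` (see [measure_regions()]),
#'   or `NULL`.
#' @param contact_result a `contact_result` (see [detect_contacts()]),
#'   or `NULL`.
#' @param sample_id sample identifier.
#' @param group_label group membership label.
#' @param n_b optional count of single-positive B cells (CD19+BCL6-)
#'   measured separately from the colocalization calls.
#' @return One-row data frame of class `sample_summary`.
#' @export
summarize_sample <- function(calls, locations, morphometry = NULL,
                             contact_result = NULL,
                             sample_id = "sample", group_label = "other",
                             n_b = NA_integer_) {
  as_df <- function(x) if (inherits(x, "subtype_calls")) x$calls else x
  if (is.list(calls) && !is.data.frame(calls) &&
      !inherits(calls, "subtype_calls")) {
    calls <- do.call(rbind, lapply(calls, as_df))
    locations <- do.call(rbind, locations)
  } else {
    calls <- as_df(calls)
  }
  if (!is.null(calls$sample_id) && length(unique(calls$sample_id)) > 1)
    stop("mixed sample_ids in calls: ",
         paste(unique(calls$sample_id), collapse = ", "))
  stopifnot(nrow(calls) == nrow(locations))
  merged <- merge(calls, locations, by = "cell_id")
  count <- function(subtype, comp = NULL) {
    sel <- merged$subtype == subtype
    if (!is.null(comp)) {
      sel <- sel & if (comp == "follicular")
        merged$compartment %in% c("GC", "follicle") else merged$compartment == comp
    }
    sum(sel)
  }
  n_tfh <- count("T_FH"); n_tfk <- count("T_FK")
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  out <- data.frame(
    sample_id = sample_id, group_label = group_label,
    n_b = n_b,
    n_gcb = count("GC-B"),
    n_tfh = n_tfh, n_tfk = n_tfk,
    n_treg = if (!is.null(contact_result)) contact_result$n_treg_total else NA_integer_,
    n_tfk_gc = count("T_FK", "GC"),
    n_tfk_follicular = count("T_FK", "follicular"),
    n_tfh_gc = count("T_FH", "GC"),
    n_tfh_follicular = count("T_FH", "follicular"),
    pct_tfk_of_tfh = pct(n_tfk, n_tfh + n_tfk),
    pct_tfk_in_gcs = pct(count("T_FK", "GC"), n_tfk),
    pct_tfk_in_follicles = pct(count("T_FK", "follicular"), n_tfk),
    pct_tfk_in_contact = if (!is.null(contact_result))
      contact_result$pct_tfk_in_contact else NA_real_,
    stringsAsFactors = FALSE)
  if (!is.null(morphometry)) {
    out$n_follicles <- morphometry$n_follicles
    out$n_gcs <- morphometry$n_gcs
    out$mean_follicle_area_um2 <- morphometry$mean_follicle_area_um2
    out$mean_gc_area_um2 <- morphometry$mean_gc_area_um2
    out$follicle_coverage <- morphometry$follicle_coverage
    out$gc_coverage <- morphometry$gc_coverage
  }
  class(out) <- c("sample_summary", class(out))
  out
}

#' Compare a per-sample metric between groups
#'
#' Dispatches to [mann_whitney()] for two groups or [kruskal_wallis()]
#' for more. Samples whose metric is undefined (`NA`) are excluded and
#' reported; each compared group must retain at least 2 samples.
#'
#' @param summaries data frame of stacked [summarize_sample()] rows.
#' @param metric name of a numeric column of `summaries`.
#' @param design `"auto"` (by number of groups), `"two_group"` or
#'   `"k_group"`.
#' @param group_col grouping column name.
#' @return A `group_comparison`.
#' @export
compare_groups <- function(summaries, metric,
                           design = c("auto", "two_group", "k_group"),
                           group_col = "group_label") {
  design <- match.arg(design)
  if (!metric %in% names(summaries))
    stop("metric not in summaries: ", metric)
  ok <- !is.na(summaries[[metric]])
  excluded <- summaries$sample_id[!ok]
  if (length(excluded))
    message("excluding sample(s) with undefined '", metric, "': ",
            paste(excluded, collapse = ", "))
  d <- summaries[ok, ]
  groups <- split(d[[metric]], d[[group_col]], drop = TRUE)
  if (length(groups) < 2) stop("fewer than 2 groups with defined metric")
  small <- names(groups)[vapply(groups, length, integer(1)) < 2]
  if (length(small))
    stop("group(s) with fewer than 2 samples after exclusions: ",
         paste(small, collapse = ", "))
  if (design == "two_group" && length(groups) != 2)
    stop("two_group design but ", length(groups), " groups present")
  if (design == "auto") design <- if (length(groups) == 2) "two_group" else "k_group"
  res <- if (design == "two_group")
    mann_whitney(groups[[1]], groups[[2]])
  else kruskal_wallis(groups)
  res$groups <- groups
  res$n <- vapply(groups, length, integer(1))
  res$excluded <- as.character(excluded)
  res$metric <- metric
  res
}
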