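#' Summarize scored cells for one image and region
#'
#' Per image x region: cell count, tetraspanin OD mean/min/max, percent
#' bright among all cells, and percent bright within the lineage-positive
#' subset. Strata with fewer than `low_n` cells trigger a low-n warning
#' (small populations, like T cells in appendix, are reported but flagged).
#'
#' @param records Scored cell records of one image ([score_cells()]).
#' @param region Region name to summarize.
#' @param low_n Warning threshold on stratum size (default 20).
#' @return One-row data frame: `image_id`, `region`, `n_cells`,
#'   `od_mean`, `od_min`, `od_max`, `pct_bright`, `n_lineage_pos`,
#'   `pct_bright_lineage_pos`.
#' @export
summarize_region <- function(records, region, low_n = 20) {
  stopifnot(length(unique(records$image_id)) <= 1)
  img <- if (nrow(records)) records$image_id[1] else NA_character_
  r <- records[records$region == region, , drop = FALSE]
  n <- nrow(r)
  if (n == 0) {
    warning("no cells in region '", region, "' for image ", img)
    return(data.frame(image_id = img, region = region, n_cells = 0L,
                      od_mean = NA_real_, od_min = NA_real_, od_max = NA_real_,
                      pct_bright = NA_real_, n_lineage_pos = 0L,
                      pct_bright_lineage_pos = NA_real_))
  }
  if (any(is.na(r$phenotype))) stop("records must be scored before summarizing")
  if (n < low_n) warning(sprintf("low n: %d cells in region '%s' of image %s",
                                 n, region, img))
  bright <- grepl("bright", r$phenotype, fixed = TRUE)
  linpos <- grepl("lin+", r$phenotype, fixed = TRUE)
  nlp <- sum(linpos)
  if (nlp > 0 && nlp < low_n)
    warning(sprintf("low n: %d lineage-positive cells in region '%s' of image %s",
                    nlp, region, img))
  data.frame(
    image_id = img, region = region, n_cells = n,
    od_mean = mean(r$od_tet), od_min = min(r$od_tet), od_max = max(r$od_tet),
    pct_bright = 100 * mean(bright),
    n_lineage_pos = nlp,
    pct_bright_lineage_pos = if (nlp > 0) 100 * mean(bright[linpos]) else NA_real_
  )
}

#' Summarize all regions of all images
#'
#' Convenience wrapper applying [summarize_region()] to every image x
#' region combination present in the records.
#'
#' @param records Scored cell records (multiple images allowed).
#' @param regions Regions to include; default all regions present.
#' @param low_n Passed to [summarize_region()].
#' @return Data frame of region summaries.
#' @export
summarize_regions <- function(records, regions = NULL, low_n = 20) {
  regions <- regions %||% sort(unique(records$region))
  out <- list()
  for (img in unique(records$image_id)) {
    ri <- records[records$image_id == img, , drop = FALSE]
    for (reg in regions) {
      if (!any(ri$region == reg)) next
      out[[length(out) + 1L]] <- summarize_region(ri, reg, low_n = low_n)
    }
  }
  do.call(rbind, out)
}

#' Bin optical densities into the standard 0.05-wide histogram
#'
#' Left-closed right-open bins `[0, 0.05), [0.05, 0.10), ...` up to the
#' maximum value, with heights normalized so the modal bin equals 100
#' ("% of max") — the standard presentation of per-cell OD distributions
#' per tissue region.
#'
#' @param ods Non-negative OD values (non-empty).
#' @param bin_width Bin width (default 0.05 OD).
#' @return Object of class `od_histogram`: `breaks`, `counts`,
#'   `normalized` (percent of modal count), `bin_width`, `n`.
#' @export
#' @examples
#' bin_od_histogram(c(0.02, 0.03, 0.07))$normalized # c(100, 50)
bin_od_histogram <- function(ods, bin_width = 0.05) {
  if (length(ods) == 0) stop("empty OD input")
  stopifnot(all(is.finite(ods)), all(ods >= 0), bin_width > 0)
  # tolerant flooring so boundary values land in their left-closed bin
  bin <- floor(ods / bin_width + 1e-9)
  nb <- max(bin) + 1
  counts <- tabulate(bin + 1L, nbins = nb)
  structure(list(
    breaks = seq(0, nb * bin_width, by = bin_width),
    counts = counts,
    normalized = 100 * counts / max(counts),
    bin_width = bin_width,
    n = length(ods)
  ), class = "od_histogram")
}

#' @export
print.od_histogram <- function(x, ...) {
  cat(sprintf("OD histogram: %d values, %d bins of width %g, modal count %d\n",
              x$n, length(x$counts), x$bin_width, max(x$counts)))
  invisible(x)
}

#' @export
plot.od_histogram <- function(x, xlab = "optical density",
                              ylab = "% of max", ...) {
  mids <- utils::head(x$breaks, -1) + x$bin_width / 2
  graphics::plot(mids, x$normalized, type = "s", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk normality is assessed per group (groups with n < 3 or
#' constant values are treated as non-Gaussian). When both groups pass,
#' an unpaired equal-variance Student's t test is used; otherwise a
#' two-sided Mann-Whitney test, exact when the combined sample size is at
#' most 20 and there are no ties, else normal approximation with tie and
#' continuity corrections. Differences with p <= alpha are flagged
#' significant.
#'
#' @param values_a,values_b Numeric group samples (non-empty).
#' @param alpha Significance level (default 0.05).
#' @param normality_alpha Level of the Shapiro-Wilk gate (default 0.05).
#' @param welch Use Welch's t instead of the equal-variance Student's t.
#' @return One-row data frame of class `stat_result`: `test`
#'   (`t_test_unpaired` or `mann_whitney`), `statistic`, `p`,
#'   `significant`, `n_a`, `n_b`, `normality_p_a`, `normality_p_b`.
#' @export
#' @examples
#' compare_groups(c(1, 2), c(3, 4))$p # 1/3 (exact Mann-Whitney)
compare_groups <- function(values_a, values_b, alpha = 0.05,
                           normality_alpha = 0.05, welch = FALSE) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) == 0 || length(b) == 0) stop("empty group")
  stopifnot(all(is.finite(a)), all(is.finite(b)))

  shap <- function(x) {
    if (length(x) < 3 || stats::sd(x) == 0) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  pa <- shap(a); pb <- shap(b)
  gaussian <- !is.na(pa) && !is.na(pb) &&
    pa > normality_alpha && pb > normality_alpha

  if (gaussian && length(a) >= 2 && length(b) >= 2) {
    ht <- stats::t.test(a, b, var.equal = !welch)
    test <- "t_test_unpaired"
  } else {
    ties <- any(duplicated(c(a, b)))
    ht <- suppressWarnings(stats::wilcox.test(
      a, b, exact = (length(a) + length(b) <= 20) && !ties, correct = TRUE))
    test <- "mann_whitney"
  }
  structure(data.frame(
    test = test,
    statistic = unname(ht$statistic),
    p = ht$p.value,
    significant = ht$p.value <= alpha,
    n_a = length(a), n_b = length(b),
    normality_p_a = pa, normality_p_b = pb
  ), class = c("stat_result", "data.frame"))
}

#' Run a plan of region-vs-region comparisons across images
#'
#' The statistical unit is one image: for each planned comparison
#' (a summary metric in region A vs region B), the per-image values of
#' that metric are collected from the region summaries and compared with
#' [compare_groups()]. Comparisons where either region has fewer than two
#' images are skipped with a warning.
#'
#' @param summaries Region summaries from [summarize_regions()].
#' @param plan Data frame with columns `metric` (a numeric column of the
#'   summaries, e.g. `"pct_bright"`, `"od_mean"`,
#'   `"pct_bright_lineage_pos"`), `region_a`, `region_b`.
#' @param alpha,normality_alpha Passed to [compare_groups()].
#' @return Data frame with the plan columns, group sizes, test used,
#'   statistic, p and significance; one row per executed comparison.
#' @export
run_comparisons <- function(summaries, plan, alpha = 0.05,
                            normality_alpha = 0.05) {
  stopifnot(all(c("metric", "region_a", "region_b") %in% colnames(plan)))
  out <- list()
  for (i in seq_len(nrow(plan))) {
    m <- plan$metric[i]
    if (!m %in% colnames(summaries)) stop("unknown metric: ", m)
    va <- summaries[[m]][summaries$region == plan$region_a[i]]
    vb <- summaries[[m]][summaries$region == plan$region_b[i]]
    va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
    if (length(va) < 2 || length(vb) < 2) {
      warning(sprintf("skipping %s: %s vs %s (images per group: %d vs %d)",
                      m, plan$region_a[i], plan$region_b[i],
                      length(va), length(vb)))
      next
    }
    res <- compare_groups(va, vb, alpha = alpha,
                          normality_alpha = normality_alpha)
    out[[length(out) + 1L]] <- cbind(
      data.frame(metric = m, region_a = plan$region_a[i],
                 region_b = plan$region_b[i],
                 mean_a = mean(va), mean_b = mean(vb)),
      as.data.frame(res))
  }
  if (length(out) == 0) {
    return(data.frame(metric = character(0), region_a = character(0),
                      region_b = character(0)))
  }
  do.call(rbind, out)
}

#' Subsample cells for per-image scatter export
#'
#' At most `n_max` cells per image x region, sampled without replacement
#' with a fixed seed — mirroring scatter plots that show a representative
#' 2000 cells per tissue region.
#'
#' @param records Cell records.
#' @param n_max Maximum cells per image x region (default 2000).
#' @param seed Seed for the subsample.
#' @return Subset of `records`.
#' @export
sample_cells_for_scatter <- function(records, n_max = 2000, seed = 1) {
  with_seed(seed, {
    keep <- unlist(lapply(split(seq_len(nrow(records)),
                                list(records$image_id, records$region),
                                drop = TRUE), function(ix) {
      if (length(ix) <= n_max) ix else sort(sample(ix, n_max))
    }))
    records[sort(unname(keep)), , drop = FALSE]
  })
}
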