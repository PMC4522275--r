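mk_scored <- function(od_tet, phenotype, region = "follicle", image_id = "i1") {
  data.frame(image_id = image_id, cell_id = seq_along(od_tet), y = 1, x = 1,
             area = 30, region = region, od_lineage = 0.1, od_tet = od_tet,
             od_nuclear = 0.5, phenotype = phenotype)
}

test_that("region summaries aggregate OD and class fractions", {
  rec <- mk_scored(c(0.1, 0.2, 0.3),
                   c("lin-/dim", "lin+/dim", "lin+/bright"))
  s <- suppressWarnings(summarize_region(rec, "follicle"))  # low-n flag expected
  expect_equal(s$od_mean, 0.2)
  expect_equal(s$pct_bright, 100 / 3, tolerance = 1e-10)
  expect_equal(s$n_lineage_pos, 2)
  expect_equal(s$pct_bright_lineage_pos, 50)
  expect_equal(s$od_min, 0.1); expect_equal(s$od_max, 0.3)

  all_bright <- mk_scored(rep(0.5, 25), rep("lin-/bright", 25))
  expect_equal(suppressWarnings(summarize_region(all_bright, "follicle"))$pct_bright, 100)
})

test_that("degenerate strata are flagged, not fabricated", {
  rec <- mk_scored(rep(0.1, 30), rep("lin-/dim", 30))
  s <- summarize_region(rec, "follicle")
  expect_equal(s$n_lineage_pos, 0)
  expect_true(is.na(s$pct_bright_lineage_pos))
  expect_warning(summarize_region(rec, "stroma"), "no cells")
  small <- mk_scored(rep(0.1, 5), rep("lin-/dim", 5))
  expect_warning(summarize_region(small, "follicle"), "low n")
})

test_that("OD histograms use half-open 0.05 bins normalized to % of max", {
  h <- bin_od_histogram(c(0.02, 0.03, 0.07))
  expect_equal(h$counts, c(2, 1))
  expect_equal(h$normalized, c(100, 50))
  expect_equal(h$breaks, c(0, 0.05, 0.1))

  h2 <- bin_od_histogram(0.12)
  expect_equal(h2$counts, c(0, 0, 1))
  expect_equal(h2$normalized[3], 100)
  expect_equal(h2$breaks[3:4], c(0.10, 0.15))

  # boundary value falls in the right (left-closed) bin
  h3 <- bin_od_histogram(c(0.04, 0.05))
  expect_equal(h3$counts, c(1, 1))

  expect_error(bin_od_histogram(numeric(0)), "empty")

  set.seed(13)
  for (i in 1:5) {
    x <- runif(200, 0, 2)
    h <- bin_od_histogram(x)
    expect_equal(sum(h$counts), 200)
    expect_equal(max(h$normalized), 100)
    expect_equal(length(h$counts), length(h$breaks) - 1)
    # bins partition [0, max]: every value lands in exactly one bin
    expect_true(max(x) < max(h$breaks))
  }
})

test_that("identical groups give t = 0 and p = 1", {
  r <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_false(r$significant)
})

test_that("tiny groups route to the exact Mann-Whitney test", {
  r <- compare_groups(c(1, 2), c(3, 4))
  expect_equal(r$test, "mann_whitney")
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  expect_error(compare_groups(numeric(0), 1:3), "empty")
})

test_that("skewed samples fail the normality gate", {
  a <- c(1, 1, 1, 1, 1, 50, 120, 400)
  b <- c(2, 2, 2, 1, 3, 60, 150, 300)
  expect_lt(stats::shapiro.test(a)$p.value, 0.05)   # oracle for the gate
  r <- compare_groups(a, b)
  expect_equal(r$test, "mann_whitney")
})

test_that("the exact Mann-Whitney p matches exhaustive enumeration", {
  set.seed(31)
  sizes <- list(c(2, 2), c(2, 3), c(3, 3), c(4, 4), c(5, 5), c(2, 8),
                c(1, 9), c(4, 6), c(3, 7))
  for (sz in sizes) {
    for (rep in 1:3) {
      vals <- sample(seq_len(20), sum(sz))    # distinct, no ties
      a <- vals[seq_len(sz[1])]
      b <- vals[-seq_len(sz[1])]
      r <- compare_groups(a, b, normality_alpha = 1)  # force the rank test
      expect_equal(r$test, "mann_whitney")
      expect_equal(r$p, mw_enum_p(a, b), tolerance = 1e-12)
    }
  }
})

test_that("comparison plans run across per-image region values", {
  summaries <- rbind(
    data.frame(image_id = paste0("i", 1:3), region = "follicle", n_cells = 100,
               od_mean = c(10, 11, 12), od_min = 0, od_max = 20,
               pct_bright = c(80, 82, 81), n_lineage_pos = 50,
               pct_bright_lineage_pos = c(90, 91, 92)),
    data.frame(image_id = paste0("i", 1:3), region = "stroma", n_cells = 100,
               od_mean = c(30, 31, 32), od_min = 0, od_max = 40,
               pct_bright = c(40, 42, 41), n_lineage_pos = 50,
               pct_bright_lineage_pos = c(60, 61, 62)))
  plan <- data.frame(metric = "od_mean", region_a = "follicle",
                     region_b = "stroma")
  res <- run_comparisons(summaries, plan)
  expect_equal(nrow(res), 1)
  expect_true(res$significant)
  expect_equal(res$n_a, 3)
  # absent region -> warning, no result
  bad <- data.frame(metric = "od_mean", region_a = "follicle",
                    region_b = "t_zone")
  expect_warning(res2 <- run_comparisons(summaries, bad), "skipping")
  expect_equal(nrow(res2), 0)
  expect_error(run_comparisons(summaries,
                               data.frame(metric = "nope", region_a = "a",
                                          region_b = "b")), "unknown metric")
})

test_that("scatter subsampling is capped, seeded and without replacement", {
  rec <- mk_scored(runif(3000), rep("lin-/dim", 3000))
  rec2 <- mk_scored(runif(100), rep("lin-/dim", 100), region = "stroma")
  all <- rbind(rec, rec2)
  s1 <- sample_cells_for_scatter(all, n_max = 2000, seed = 5)
  s2 <- sample_cells_for_scatter(all, n_max = 2000, seed = 5)
  expect_identical(s1, s2)
  expect_equal(sum(s1$region == "follicle"), 2000)
  expect_equal(sum(s1$region == "stroma"), 100)
  expect_false(any(duplicated(paste(s1$region, s1$cell_id))))
})
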