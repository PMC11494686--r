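test_that("ROI means equal the explicit column loop", {
  sch <- roi_scheme()
  set.seed(15)
  vals <- matrix(abs(rnorm(5 * sch$n_regions, 10)), 5, sch$n_regions,
                 dimnames = list(NULL, scheme_labels(sch)))
  tab <- activation_table(vals, "object_location", "storage")
  rois <- memory_roi_sets(sch)
  got <- roi_mean(tab, rois$scene, sch)
  idx <- which(sch$regions$label %in% rois$scene$labels)
  manual <- sapply(1:5, function(p) mean(vals[p, idx]))
  expect_equal(got, manual)
  # single-region ROI returns that column
  one <- roi_set("v1", "V1", scheme = sch)
  expect_equal(roi_mean(tab, one, sch, hemisphere = "L"),
               vals[, "V1_L"])
  # two regions valued 2 and 4 average to 3
  v2 <- vals; v2[, "V1_L"] <- 2; v2[, "V1_R"] <- 4
  t2 <- activation_table(v2, "a", "storage")
  expect_equal(roi_mean(t2, one, sch), rep(3, 5))
})

test_that("paired t matches the closed-form statistic digit for digit", {
  a <- c(11.2, 9.8, 13.1, 10.4, 12.0)
  b <- c(10.1, 9.9, 11.8, 10.0, 11.1)
  res <- paired_t(a, b)
  d <- a - b
  t_manual <- mean(d) / (sd(d) / sqrt(5))
  p_manual <- 2 * pt(-abs(t_manual), df = 4)
  expect_equal(res$t, t_manual, tolerance = 1e-12)
  expect_equal(res$p, p_manual, tolerance = 1e-12)
  expect_equal(res$df, 4L)
  expect_equal(res$mean_a, mean(a))
})

test_that("paired t handles identity, sign, shift and degenerate inputs", {
  set.seed(16)
  a <- rnorm(23); b <- rnorm(23)
  expect_equal(paired_t(a, a)$t, 0)
  expect_equal(paired_t(a, a)$p, 1)
  expect_equal(paired_t(a, b)$df, 22L)
  r1 <- paired_t(a, b); r2 <- paired_t(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)
  r3 <- paired_t(a + 5, b + 5)
  expect_equal(r3$t, r1$t, tolerance = 1e-10)
  # zero-variance differences
  expect_equal(paired_t(a + 1, a)$t, Inf)
  expect_equal(paired_t(a + 1, a)$p, 0)
  expect_equal(paired_t(a - 1, a)$t, -Inf)
  expect_error(paired_t(a, b[1:5]), "equal length")
})

test_that("the battery flags injected effects and reports them per ROI", {
  sch <- roi_scheme()
  scene_idx <- roi_indices(memory_roi_sets(sch)$scene, sch)
  # additive scene effect in object-location storage, about d = 2
  tabs <- null_tables(sch, n = 23, seed = 21,
                      effect = list(task = "object_location",
                                    phase = "storage", idx = scene_idx,
                                    delta = 1.2))
  rep_tab <- run_contrast_battery(tabs, scheme = sch)
  expect_equal(nrow(rep_tab), 9L)
  expect_true(all(rep_tab$df == 22L))
  scene_row <- rep_tab[rep_tab$roi == "scene" &
                         grepl("storage", rep_tab$contrast), ]
  expect_true(scene_row$significant)
  expect_gt(scene_row$t, 0)
})

test_that("an empty contrast list yields an empty report", {
  sch <- roi_scheme()
  tabs <- null_tables(sch, n = 5, seed = 3)
  rep_tab <- run_contrast_battery(tabs, specs = list(), scheme = sch)
  expect_equal(nrow(rep_tab), 0L)
  expect_named(rep_tab, c("roi", "contrast", "t", "df", "p", "significant"))
})

test_that("missing activation tables are reported by name", {
  sch <- roi_scheme()
  tabs <- null_tables(sch, n = 5, seed = 4)
  tabs[["word_pair"]][["storage"]] <- NULL
  expect_error(run_contrast_battery(tabs, scheme = sch),
               "word_pair.*storage|storage.*word_pair")
})

test_that("each contrast holds its false-positive rate at alpha on nulls", {
  sch <- roi_scheme()
  counts <- NULL
  n_rep <- 200
  for (rep_i in seq_len(n_rep)) {
    tabs <- null_tables(sch, n = 23, seed = rep_i + 5000)
    rep_tab <- run_contrast_battery(tabs, scheme = sch)
    if (is.null(counts)) counts <- integer(nrow(rep_tab))
    counts <- counts + rep_tab$significant
  }
  bounds <- qbinom(c(0.025, 0.975), n_rep, 0.02)
  expect_true(all(counts >= bounds[1] & counts <= bounds[2]),
              info = paste("per-contrast counts:",
                           paste(counts, collapse = " ")))
})

test_that("the battery is a pure function of its inputs", {
  sch <- roi_scheme()
  tabs <- null_tables(sch, n = 8, seed = 5)
  expect_identical(run_contrast_battery(tabs, scheme = sch),
                   run_contrast_battery(tabs, scheme = sch))
})
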