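write_scheme_tsv <- function(scheme, path) {
  write.table(scheme$regions, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  path
}

tiny_config <- function(root) {
  sch <- roi_scheme()
  sch_path <- file.path(root, "scheme.tsv")
  write_scheme_tsv(sch, sch_path)
  cfg_path <- file.path(root, "config.yaml")
  yaml::write_yaml(list(
    seed = 5, out_dir = file.path(root, "out"), scheme = sch_path,
    log_level = "quiet",
    cohort = list(n_participants = 3),
    gec = list(max_iter = 3, sim_length_samples = 200)), cfg_path)
  load_config(cfg_path)
}

test_that("the default configuration validates and fills defaults", {
  cfg <- load_config()
  expect_s3_class(cfg, "pipeline_config")
  expect_equal(cfg$acquisition$TR, 0.8)
  expect_equal(cfg$acquisition$n_samples, 696L)
  expect_equal(cfg$fc_band$low, 0.008)
  expect_equal(cfg$gec$clip_max, 0.2)
  expect_equal(cfg$battery$alpha, 0.02)
  # the packaged YAML restates the defaults exactly
  pkg_cfg <- load_config(system.file("config", "default.yaml",
                                     package = "hopfec"))
  pkg_cfg$out_dir <- cfg$out_dir
  expect_equal(unclass(pkg_cfg), unclass(cfg))
})

test_that("config validation enumerates every problem and names fields", {
  bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    typo_key = 1,
    fc_band = list(low = 0.1, high = 0.01),
    battery = list(alpha = 2)), bad)
  err <- tryCatch(load_config(bad), error = conditionMessage)
  expect_match(err, "typo_key")
  expect_match(err, "fc_band")
  expect_match(err, "battery.alpha")
})

test_that("labelled matrices round-trip exactly with their sidecars", {
  set.seed(17)
  m <- matrix(rnorm(100), 10, 10,
              dimnames = list(paste0("r", 1:10), paste0("r", 1:10)))
  path <- tempfile(fileext = ".tsv")
  write_matrix_tsv(m, path, meta = list(reversed = TRUE, lag_samples = 3))
  back <- read_matrix_tsv(path)
  expect_equal(back$values, m, tolerance = 1e-12)
  expect_true(back$meta$reversed)
  expect_equal(back$meta$orientation, "column->row")
  # shuffled label order is reindexed on request
  perm <- sample(10)
  mp <- m[perm, perm]
  path2 <- tempfile(fileext = ".tsv")
  write_matrix_tsv(mp, path2)
  back2 <- read_matrix_tsv(path2, labels = rownames(m))
  expect_equal(back2$values, m, tolerance = 1e-12)
  expect_error(read_matrix_tsv(path2, labels = paste0("x", 1:10)),
               "labels")
})

test_that("the pipeline runs end to end, deterministically", {
  root <- file.path(tempdir(), "pipe")
  dir.create(root, showWarnings = FALSE)
  cfg <- tiny_config(root)
  run_command("simulate", cfg)
  expect_true(file.exists(file.path(cfg$out_dir, "cohort", "manifest.json")))
  paths <- run_command("activation", cfg)
  expect_length(paths, 6L)  # 3 tasks x 2 phases
  sums1 <- tools::md5sum(paths)
  run_command("activation", cfg)
  expect_identical(tools::md5sum(paths), sums1)
  run_command("gec", cfg)
  ec_path <- file.path(cfg$out_dir, "gec", "ec_object_location.tsv")
  expect_true(file.exists(ec_path))
  ec <- read_matrix_tsv(ec_path)
  expect_true(all(ec$values >= 0 & ec$values <= 0.2))
  expect_true(ec$meta$reversed)
  # per-hemisphere default: half the scheme's regions
  expect_equal(nrow(ec$values), roi_scheme()$n_per_hemisphere)
  stats_path <- run_command("stats", cfg)
  rep_tab <- read.table(stats_path, header = TRUE, sep = "\t")
  expect_equal(nrow(rep_tab), 9L)
  rep_paths <- run_command("report", cfg)
  expect_true(any(grepl("summary_object_location_storage", rep_paths)))
  expect_true(any(grepl("ec_asymmetry", rep_paths)))
  unlink(root, recursive = TRUE)
})

test_that("downstream commands fail loudly without upstream artifacts", {
  root <- file.path(tempdir(), "pipe-missing")
  dir.create(root, showWarnings = FALSE)
  cfg <- tiny_config(root)
  expect_error(run_command("activation", cfg), "manifest.json")
  run_command("simulate", cfg)
  err <- tryCatch(run_command("stats", cfg), error = conditionMessage)
  expect_match(err, "act_object_location_storage.tsv", fixed = TRUE)
  unlink(root, recursive = TRUE)
})
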