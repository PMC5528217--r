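test_that("wide CSV reads into a validated dataset", {
  ds <- read_samples(write_tmp_csv(toy_wide()))
  expect_s3_class(ds, "fly_dataset")
  expect_equal(nrow(ds$samples), 3L)
  expect_equal(sum(as.matrix(ds$counts[, -1])), 8)
  expect_setequal(ds$flies$fly_id, c("flyA", "flyB"))
})

test_that("long and wide dialects produce identical datasets", {
  wide <- read_samples(write_tmp_csv(toy_wide()))
  long <- read_samples(write_tmp_csv(toy_long()))
  expect_equal(long$samples, wide$samples)
  expect_equal(long$counts, wide$counts)
  expect_equal(long$flies, wide$flies)
})

test_that("dialect equivalence holds on random tables", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(4:12, 1)
    nf <- sample(2:4, 1)
    wide <- tibble::tibble(
      sample_id = sprintf("s%02d", seq_len(n)),
      plant_id = sample(c("pa", "pb", "pc"), n, replace = TRUE),
      period = sample(c("before", "after"), n, replace = TRUE))
    for (f in paste0("fly", seq_len(nf))) {
      wide[[f]] <- rpois(n, 2)
    }
    long <- tidyr::pivot_longer(wide, cols = dplyr::starts_with("fly"),
                                names_to = "fly_id", values_to = "count")
    a <- read_samples(write_tmp_csv(wide))
    b <- read_samples(write_tmp_csv(long))
    expect_equal(a$counts, b$counts)
    expect_equal(a$samples, b$samples)
  }
})

test_that("negative counts are rejected naming the sample", {
  bad <- toy_wide()
  bad$flyA[2] <- -1
  expect_error(read_samples(write_tmp_csv(bad)), "s2")
  badl <- toy_long()
  badl$count[badl$sample_id == "s3" & badl$fly_id == "flyA"] <- -1
  expect_error(read_samples(write_tmp_csv(badl)), "s3")
})

test_that("strict registry policy rejects unknown flies", {
  reg <- tibble::tibble(fly_id = "flyA", name = "A", guild = "generalist")
  expect_error(
    read_samples(write_tmp_csv(toy_wide()), flies = reg,
                 fly_registry_policy = "strict"),
    "flyB")
  ok <- read_samples(write_tmp_csv(toy_wide()[, -5]), flies = reg,
                     fly_registry_policy = "strict")
  expect_equal(ok$flies$guild, "generalist")
})

test_that("period is derived from dates, invasion year counting as after", {
  df <- toy_wide()[, -3]
  df$date <- c("1995-03-01", "2000-01-15", "2007-11-30")
  ds <- read_samples(write_tmp_csv(df), invasion_year = 2000)
  expect_equal(ds$samples$period, c("before", "after", "after"))
  bad <- df
  bad$date[2] <- "not-a-date"
  expect_error(read_samples(write_tmp_csv(bad)), "s2")
})

test_that("dataset round-trips through CSV", {
  ds <- read_samples(write_tmp_csv(toy_wide()))
  path <- withr::local_tempfile(fileext = ".csv")
  write_samples(ds, path)
  back <- read_samples(path)
  expect_equal(back$counts, ds$counts)
  expect_equal(back$samples$period, ds$samples$period)
})

test_that("tree reading enforces rootedness and branch lengths", {
  tmp <- function(text) {
    p <- withr::local_tempfile(fileext = ".nwk", .local_envir = parent.frame())
    writeLines(text, p)
    p
  }
  tr <- read_tree(tmp("((A:1,B:1):1,C:2);"))
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  single <- read_tree(tmp("(A:1);"))
  expect_equal(ape::Ntip(single), 1L)
  expect_error(read_tree(tmp("(A,B);")), "lengths")
  expect_error(read_tree(tmp("(A:1,B:1,C:1);")), "rooted")
  expect_error(read_tree(tmp("((A:1,B:1):1,C:2);\n((A:1,C:1):1,B:2);")),
               "single")
})

test_that("run_config validates thresholds and round-trips as JSON", {
  expect_error(run_config(decrease_threshold = 0), "decrease_threshold")
  expect_error(run_config(ci_quantiles = c(0.9, 0.1)), "ci_quantiles")
  cfg <- run_config(bootstrap_reps = 77, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_run_config(cfg, path)
  expect_equal(read_run_config(path), cfg)
})

test_that("reports round-trip with full precision and expected schema", {
  ds <- filter_plants(counted_dataset(
    n_before = c(p1 = 4, p2 = 5), n_after = c(p1 = 4, p2 = 6)))
  cfg <- run_config(bootstrap_reps = 50, seed = 4)
  rep <- bootstrap_indices(ds, "before", config = cfg)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, csv)
  tab <- readr::read_csv(csv, show_col_types = FALSE)
  expect_true(all(c("fly_id", "period", "richness", "d_alpha_mean",
                    "ci_low", "ci_high") %in% names(tab)))
  js <- withr::local_tempfile(fileext = ".json")
  write_report(rep, js)
  back <- read_report(js)
  expect_equal(back$alpha$d_alpha_mean, rep$alpha$d_alpha_mean,
               tolerance = 1e-12)
  expect_equal(back$pairs$turnover_mean, rep$pairs$turnover_mean,
               tolerance = 1e-12)
})

test_that("qic_table reports rank in ascending-QIC order", {
  tab <- tibble::tibble(model_id = c("M1", "M2", "M3", "M4"),
                        qic = c(100, 90, 50, 20),
                        quasi_lik = 0, trace_term = 0, n_params = 1,
                        note = "")
  tab$rank <- rank(tab$qic)
  tab <- structure(tab, class = c("qic_table", class(tab)),
                   period = "before", unit = "sample",
                   qic_delta = 10, selected = "M4",
                   m4_components = tibble::tibble())
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(tab, path)
  out <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(out), 4L)
  expect_equal(out$rank, 1:4)
  expect_equal(out$model_id[1], "M4")
})
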