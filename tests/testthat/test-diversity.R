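test_that("alpha diversity validates its input", {
  expect_error(alpha_diversity(c(0.6, 0.6)), "sums to")
  expect_error(alpha_diversity(c(-0.2, 1.2)), "negative")
  expect_equal(alpha_diversity(1), 1)
  expect_equal(alpha_diversity(c(0.5, 0.25, 0.25)), 2^1.5,
               tolerance = 1e-12)
})

test_that("turnover validates input and hits its boundary cases", {
  expect_error(beta_turnover(c(1, 0), c(0.5, 0.25, 0.25)), "plant orders")
  expect_equal(beta_turnover(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(beta_turnover(c(1, 0, 0), c(0, 0.5, 0.5)), 1)
  expect_lt(abs(beta_turnover(c(1, 0), c(0.5, 0.5)) - 0.240806), 1e-6)
  expect_equal(beta_turnover(c(0.5, 0.5), c(1, 0)),
               beta_turnover(c(1, 0), c(0.5, 0.5)))
})

test_that("alpha diversity is Schur-concave under Robin Hood transfers", {
  set.seed(19)
  for (i in 1:40) {
    k <- sample(3:10, 1)
    p <- rgamma(k, 1)
    p <- p / sum(p)
    hi <- which.max(p)
    lo <- which.min(p)
    eps <- runif(1, 0, (p[hi] - p[lo]) / 2)
    q <- p
    q[hi] <- q[hi] - eps
    q[lo] <- q[lo] + eps
    expect_gte(alpha_diversity(q) + 1e-12, alpha_diversity(p))
    expect_true(alpha_diversity(p) >= 1 && alpha_diversity(p) <= k)
  }
})

test_that("normalisation divides rows by capacity then columns by totals", {
  raw <- matrix(c(6, 0), 2, 1, dimnames = list(c("p1", "p2"), "f1"))
  w <- tibble::tibble(plant_id = c("p1", "p2"), w = c(3, 2))
  expect_equal(unname(normalize_matrix(raw, w)[, 1]), c(1, 0))
  raw2 <- matrix(c(2, 2), 2, 1, dimnames = list(c("p1", "p2"), "f1"))
  w2 <- tibble::tibble(plant_id = c("p1", "p2"), w = c(1, 2))
  expect_equal(unname(normalize_matrix(raw2, w2)[, 1]), c(2 / 3, 1 / 3))
  # all-zero column flagged invalid rather than divided 0/0
  raw3 <- cbind(raw, f2 = c(0, 0))
  p3 <- normalize_matrix(raw3, w)
  expect_true(all(is.na(p3[, "f2"])))
  expect_equal(attr(p3, "invalid"), "f2")
  # inconsistent capacity is an error
  w0 <- tibble::tibble(plant_id = c("p1", "p2"), w = c(0, 2))
  expect_error(normalize_matrix(raw, w0), "p1")
})

test_that("one-fruit resampling is uniform over a plant's samples", {
  ds <- counted_dataset(n_before = c(pA = 1, pB = 2),
                        n_after = c(pA = 1, pB = 1))
  ds$counts$f1 <- seq_len(nrow(ds$counts))  # make fruits distinguishable
  set.seed(101)
  draws <- replicate(4000, resample_one_fruit(ds, "before")["pB", "f1"])
  # the single-sample plant always returns its one fruit
  one <- replicate(20, resample_one_fruit(ds, "before")["pA", "f1"])
  expect_equal(unique(one), ds$counts$f1[ds$counts$sample_id == "pA_before_1"])
  freq <- mean(draws == draws[which.max(draws)])
  expect_lt(abs(freq - 0.5), 3 * sqrt(0.25 / 4000))
  # fixed seed reproduces the matrix sequence
  set.seed(7); a <- replicate(5, resample_one_fruit(ds, "before"))
  set.seed(7); b <- replicate(5, resample_one_fruit(ds, "before"))
  expect_identical(a, b)
})

test_that("degenerate bootstraps collapse to the point estimate", {
  ds <- counted_dataset(n_before = c(pA = 1, pB = 1),
                        n_after = c(pA = 1, pB = 1))
  ds$counts$f1 <- c(2, 3, 2, 3)
  ds$counts$f2 <- c(1, 0, 1, 0)
  cfg <- run_config(min_samples_before = 1, min_samples_after = 1,
                    bootstrap_reps = 200, seed = 5)
  rep <- bootstrap_indices(ds, "before", config = cfg)
  expect_equal(rep$alpha$ci_low, rep$alpha$d_alpha_mean)
  expect_equal(rep$alpha$ci_high, rep$alpha$d_alpha_mean)
  one <- bootstrap_indices(ds, "before",
                           config = run_config(min_samples_before = 1,
                                               min_samples_after = 1,
                                               bootstrap_reps = 1, seed = 5))
  expect_equal(one$alpha$d_alpha_mean, one$alpha$ci_low)
  expect_equal(one$alpha$n_valid_reps, c(1L, 1L))
})

test_that("bootstrap distribution matches exhaustive enumeration on a toy", {
  # 3 plants with 2/3/2 fruits: 12 equally likely one-fruit matrices
  samples <- tibble::tibble(
    sample_id = sprintf("s%d", 1:7),
    plant_id = c("pA", "pA", "pB", "pB", "pB", "pC", "pC"),
    period = "before")
  counts <- tibble::tibble(sample_id = samples$sample_id,
                           f1 = c(3, 1, 0, 2, 4, 1, 0),
                           f2 = c(0, 2, 1, 1, 0, 0, 3))
  after <- samples
  after$sample_id <- paste0(after$sample_id, "_a")
  after$period <- "after"
  counts_a <- counts
  counts_a$sample_id <- after$sample_id
  ds <- fly_dataset(dplyr::bind_rows(samples, after),
                    dplyr::bind_rows(counts, counts_a))
  w <- biotic_capacity(ds)
  wv <- setNames(w$w, w$plant_id)

  combos <- expand.grid(a = 1:2, b = 3:5, c = 6:7)
  cm <- as.matrix(counts[, c("f1", "f2")])
  enum <- apply(combos, 1, function(idx) {
    raw <- cm[idx, , drop = FALSE]
    rownames(raw) <- c("pA", "pB", "pC")
    p <- normalize_matrix(raw, wv[c("pA", "pB", "pC")])
    c(f1 = if (all(is.na(p[, 1]))) NA else alpha_diversity(p[, 1]),
      f2 = if (all(is.na(p[, 2]))) NA else alpha_diversity(p[, 2]))
  })
  exact_mean <- rowMeans(enum, na.rm = TRUE)

  cfg <- run_config(min_samples_before = 1, min_samples_after = 1,
                    bootstrap_reps = 20000, seed = 2)
  rep <- bootstrap_indices(ds, "before", w = w, config = cfg)
  for (f in c("f1", "f2")) {
    est <- rep$alpha$d_alpha_mean[rep$alpha$fly_id == f]
    draws <- rep$alpha_draws[, f]
    mc_se <- stats::sd(draws, na.rm = TRUE) /
      sqrt(sum(!is.na(draws)))
    expect_lt(abs(est - exact_mean[[f]]), 4 * mc_se + 1e-9)
  }
  # each of the 12 matrices has mass 1/12 > 2.5%, so the exact quantiles
  # sit on the extreme support points
  expect_equal(rep$alpha$ci_low[rep$alpha$fly_id == "f1"],
               min(enum["f1", ]), tolerance = 1e-9)
  expect_equal(rep$alpha$ci_high[rep$alpha$fly_id == "f1"],
               max(enum["f1", ]), tolerance = 1e-9)
})

test_that("replicates with empty fly columns are excluded, not imputed", {
  # f2 appears in one of pA's two fruits only: ~half the replicates invalid
  samples <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                            plant_id = c("pA", "pA", "pB"),
                            period = "before")
  counts <- tibble::tibble(sample_id = samples$sample_id,
                           f1 = c(2, 2, 2), f2 = c(4, 0, 0))
  ds <- fly_dataset(samples, counts)
  cfg <- run_config(min_samples_before = 1, min_samples_after = 1,
                    bootstrap_reps = 2000, seed = 11)
  w <- tibble::tibble(plant_id = c("pA", "pB"), w = c(4, 2))
  rep <- bootstrap_indices(ds, "before", w = w, config = cfg)
  nv <- rep$alpha$n_valid_reps[rep$alpha$fly_id == "f2"]
  expect_lt(abs(nv / 2000 - 0.5), 3 * sqrt(0.25 / 2000))
  # every valid replicate has f2 on a single host: Dalpha exactly 1
  expect_equal(rep$alpha$d_alpha_mean[rep$alpha$fly_id == "f2"], 1)
})

test_that("period comparison flags only disjoint CIs", {
  a <- tibble::tibble(fly_id = c("f1", "f2"), period = "before",
                      richness = c(5L, 3L),
                      d_alpha_mean = c(10.37, 3.5),
                      ci_low = c(7.45, 3.0), ci_high = c(13.33, 4.0),
                      n_valid_reps = 100L)
  b <- tibble::tibble(fly_id = c("f1", "f2"), period = "after",
                      richness = c(4L, 3L),
                      d_alpha_mean = c(5.24, 1.5),
                      ci_low = c(2.89, 1.0), ci_high = c(7.75, 2.0),
                      n_valid_reps = 100L)
  mkrep <- function(alpha, period) {
    stub_report(matrix(0, 1, 1, dimnames = list("p", "f1")),
                alpha = alpha,
                pairs = tibble::tibble(fly_i = character(),
                                       fly_k = character(),
                                       period = character(),
                                       turnover_mean = numeric(),
                                       ci_low = numeric(),
                                       ci_high = numeric(),
                                       n_valid_reps = integer()),
                period = period)
  }
  cmp <- compare_periods(mkrep(a, "before"), mkrep(b, "after"))
  # overlapping CIs (7.45 < 7.75) are not "significant" even with a big drop
  expect_false(cmp$alpha$ci_disjoint[cmp$alpha$fly_id == "f1"])
  expect_true(cmp$alpha$ci_disjoint[cmp$alpha$fly_id == "f2"])
  expect_equal(cmp$alpha$delta_d_alpha,
               c(5.24 - 10.37, 1.5 - 3.5), tolerance = 1e-12)
  ident <- compare_periods(mkrep(a, "before"), mkrep(a, "after"))
  expect_true(all(ident$alpha$delta_d_alpha == 0))
  expect_false(any(ident$alpha$ci_disjoint))
})
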