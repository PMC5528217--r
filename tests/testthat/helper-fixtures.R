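# Fixture builders shared across test files; everything is generated in code.

# the canonical two-fly, three-sample toy (wide layout)
toy_wide <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    plant_id = c("p1", "p1", "p2"),
    period = c("before", "after", "before"),
    flyA = c(2, 0, 5), flyB = c(0, 1, 0))
}

toy_long <- function() {
  tidyr::pivot_longer(toy_wide(), cols = c("flyA", "flyB"),
                      names_to = "fly_id", values_to = "count")
}

write_tmp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(df, path, progress = FALSE)
  path
}

# dataset with explicit per-plant, per-period sample counts; every sample of
# plant j carries count j for fly "f1" so matrices are easy to predict
counted_dataset <- function(n_before, n_after, plant_ids = names(n_before),
                            flies = c("f1", "f2")) {
  rows <- list()
  for (j in seq_along(plant_ids)) {
    for (period in c("before", "after")) {
      n <- if (period == "before") n_before[[j]] else n_after[[j]]
      if (n == 0) next
      rows[[paste(j, period)]] <- tibble::tibble(
        sample_id = sprintf("%s_%s_%d", plant_ids[j], period, seq_len(n)),
        plant_id = plant_ids[j], period = period)
    }
  }
  samples <- dplyr::bind_rows(rows)
  counts <- tibble::tibble(sample_id = samples$sample_id)
  for (f in flies) counts[[f]] <- rep(1, nrow(samples))
  fly_dataset(samples, counts)
}

# a minimal diversity_report carrying just the pieces interaction_change and
# compare_periods read
stub_report <- function(mean_matrix, lo = NULL, hi = NULL, alpha = NULL,
                        pairs = NULL, period = "before") {
  lo <- lo %||% mean_matrix
  hi <- hi %||% mean_matrix
  structure(list(period = period,
                 alpha = alpha %||% tibble::tibble(),
                 pairs = pairs %||% tibble::tibble(),
                 mean_matrix = mean_matrix,
                 cell_ci = list(lo = lo, hi = hi),
                 reps = 1L, seed = 1L),
            class = "diversity_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic small random binary regression problems for oracle checks;
# regenerates until the GLM is comfortably away from separation
random_glm_problem <- function(seed) {
  set.seed(seed)
  repeat {
    n <- sample(20:200, 1)
    p <- sample(1:4, 1)
    x <- cbind(1, matrix(rnorm(n * p), n, p))
    colnames(x) <- c("(Intercept)", paste0("x", seq_len(p)))
    beta <- rnorm(p + 1, sd = 0.8)
    y <- rbinom(n, 1, plogis(drop(x %*% beta)))
    if (sum(y) >= 3 && sum(1 - y) >= 3) {
      fit <- suppressWarnings(
        glm.fit(x, y, family = binomial(),
                control = list(epsilon = 1e-12)))
      if (max(abs(fit$coefficients)) < 5) {
        return(list(x = x, y = y, glm_coef = fit$coefficients))
      }
    }
  }
}
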