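shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Niche breadth as a Shannon number equivalent
#'
#' \eqn{D_\alpha = \exp(-\sum_j p_j \log p_j)} (natural log, 0 log 0 = 0):
#' the number of equally used host plants that would give the same entropy.
#' Ranges from 1 (single host) to the number of plants (uniform use).
#'
#' @param p Nonnegative host-use distribution summing to 1 (within 1e-9).
#' @return A single number in `[1, length(p)]`.
#' @export
alpha_diversity <- function(p) {
  if (any(p < 0)) abort("negative proportions in host-use distribution")
  if (abs(sum(p) - 1) > 1e-9) {
    abort(paste0("host-use distribution sums to ", format(sum(p)),
                 ", not 1"))
  }
  exp(shannon(p))
}

#' Pairwise niche turnover from Shannon beta diversity
#'
#' For two host-use distributions with equal community weights, beta
#' diversity in number equivalents is
#' \eqn{D_\beta = \exp(H_\gamma - H_\alpha)} with
#' \eqn{H_\alpha = (H(p)+H(q))/2} and \eqn{H_\gamma = H((p+q)/2)}; the
#' turnover index rescales it to
#' \eqn{T = (D_\beta - 1)/(N - 1)} with \eqn{N = 2} communities, so that
#' identical niches give 0 and fully disjoint niches give 1.
#'
#' @param p,q Host-use distributions over the same plant order (each sums
#'   to 1 within 1e-9).
#' @return A single number in `[0, 1]`.
#' @export
beta_turnover <- function(p, q) {
  if (length(p) != length(q)) {
    abort("the two distributions cover different plant orders")
  }
  if (any(p < 0) || any(q < 0)) abort("negative proportions")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9) {
    abort("distributions must each sum to 1")
  }
  if (!any(p > 0 & q > 0)) {
    return(1)   # fully disjoint diets: the boundary case, exactly
  }
  h_alpha <- (shannon(p) + shannon(q)) / 2
  h_gamma <- shannon((p + q) / 2)
  d_beta <- exp(h_gamma - h_alpha)
  min(max(d_beta - 1, 0), 1)
}

#' Draw one fruit per plant
#'
#' One bootstrap replicate of the interaction data: for every retained
#' plant, one uniformly chosen fruit sample of the period; the replicate
#' matrix row is that fruit's per-fly count vector. Uses (and advances) the
#' current RNG state.
#'
#' @param dataset A filtered [fly_dataset()].
#' @param period `"before"` or `"after"`.
#' @return Plants x flies count matrix in registry order.
#' @export
resample_one_fruit <- function(dataset, period) {
  prep <- resample_prep(dataset, period)
  idx <- vapply(prep$rows, function(r) r[sample.int(length(r), 1L)], 0L)
  m <- prep$counts[idx, , drop = FALSE]
  rownames(m) <- prep$plants
  m
}

resample_prep <- function(dataset, period) {
  sel <- dataset$samples$period == period
  counts <- count_matrix(dataset)[sel, , drop = FALSE]
  plant <- dataset$samples$plant_id[sel]
  rows <- split(seq_along(plant), factor(plant,
                                         levels = dataset$plants$plant_id))
  empty <- names(rows)[lengths(rows) == 0L]
  if (length(empty)) {
    abort(paste0("plant(s) without samples in period ", period, ": ",
                 paste(empty, collapse = ", ")))
  }
  rows <- lapply(rows, as.integer)
  list(counts = counts, rows = rows, plants = dataset$plants$plant_id)
}

#' Normalise a raw one-fruit matrix into interaction proportions
#'
#' Two steps: each row (plant) is divided by the plant's biotic capacity
#' `w_j` (mean total flies per fruit over the whole dataset); each column
#' (fly) is then divided by its total, so every fly's host-use proportions
#' sum to 1. Columns with no flies in this replicate are flagged invalid
#' (`NA`) rather than divided by zero.
#'
#' @param raw Plants x flies count matrix (one fruit per plant).
#' @param w Biotic capacity tibble from [biotic_capacity()], aligned to the
#'   rows of `raw`.
#' @return Matrix of proportions `p_ij`; invalid columns are all-`NA` and
#'   listed in attribute `"invalid"`.
#' @export
normalize_matrix <- function(raw, w) {
  wv <- if (is.data.frame(w)) setNames(w$w, w$plant_id)[rownames(raw)] else w
  if (anyNA(wv) || length(wv) != nrow(raw)) {
    abort("biotic capacity does not cover the matrix rows")
  }
  bad <- wv == 0 & rowSums(raw) > 0
  if (any(bad)) {
    abort(paste0("zero biotic capacity but nonzero counts for plant: ",
                 paste(rownames(raw)[bad], collapse = ", ")))
  }
  x <- raw / ifelse(wv > 0, wv, 1)
  tot <- colSums(x)
  p <- sweep(x, 2, ifelse(tot > 0, tot, 1), "/")
  p[, tot == 0] <- NA_real_
  structure(p, invalid = colnames(raw)[tot == 0])
}

#' Bootstrap niche-breadth and turnover indices for one period
#'
#' Builds `config$bootstrap_reps` interaction matrices by resampling one
#' fruit per plant, normalising by biotic capacity and by column totals,
#' and computing each fly's niche breadth (number equivalents of Shannon
#' entropy) and each fly pair's turnover per matrix. Reports per-index
#' means and the configured quantiles over the valid replicates; a fly
#' whose column is empty in a replicate is excluded from that replicate's
#' pool (`n_valid_reps` records how many remained), and a fly with no valid
#' replicate is reported absent (`NA`) rather than imputed.
#'
#' Reproducible bit-for-bit given `(config$seed, config$bootstrap_reps)`;
#' the two periods use distinct streams derived from the seed.
#'
#' @param dataset A filtered [fly_dataset()].
#' @param period `"before"` or `"after"`.
#' @param w Biotic capacity ([biotic_capacity()], whole-dataset pooling);
#'   computed if omitted.
#' @param config A [run_config()].
#' @return A `diversity_report`: tibbles `alpha` (per fly: richness,
#'   `d_alpha_mean`, CI bounds, `n_valid_reps`) and `pairs` (per fly pair:
#'   `turnover_mean`, CI bounds), the bootstrap-mean interaction matrix,
#'   per-cell CI matrices, and the alpha/turnover draws.
#' @export
bootstrap_indices <- function(dataset, period, w = NULL,
                              config = run_config()) {
  stopifnot(inherits(dataset, "fly_dataset"))
  if (is.null(w)) w <- biotic_capacity(dataset)
  prep <- resample_prep(dataset, period)
  reps <- config$bootstrap_reps
  wv <- setNames(w$w, w$plant_id)[prep$plants]
  nf <- ncol(prep$counts)
  np <- length(prep$plants)
  flies <- colnames(prep$counts)

  # distinct, reproducible stream per (seed, period)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed + ifelse(period == "after", 1L, 0L) * 500009L)

  # all fruit choices up front: one column of row indices per replicate
  choice <- matrix(0L, np, reps)
  for (j in seq_len(np)) {
    r <- prep$rows[[j]]
    choice[j, ] <- if (length(r) == 1L) r else
      r[sample.int(length(r), reps, replace = TRUE)]
  }

  alpha_draws <- matrix(NA_real_, reps, nf, dimnames = list(NULL, flies))
  pair_idx <- if (nf >= 2) utils::combn(nf, 2) else
    matrix(integer(), nrow = 2, ncol = 0)
  pair_names <- paste(flies[pair_idx[1, ]], flies[pair_idx[2, ]], sep = "|")
  t_draws <- matrix(NA_real_, reps, ncol(pair_idx),
                    dimnames = list(NULL, pair_names))
  p_sum <- matrix(0, np, nf, dimnames = list(prep$plants, flies))
  p_cells <- array(NA_real_, c(reps, np, nf))
  n_valid <- integer(nf)

  for (r in seq_len(reps)) {
    raw <- prep$counts[choice[, r], , drop = FALSE]
    x <- raw / ifelse(wv > 0, wv, 1)
    tot <- colSums(x)
    valid <- tot > 0
    if (!any(valid)) next
    p <- sweep(x, 2, ifelse(valid, tot, 1), "/")
    p[, !valid] <- NA_real_
    p_cells[r, , ] <- p
    vp <- p[, valid, drop = FALSE]
    p_sum[, valid] <- p_sum[, valid] + vp
    n_valid[valid] <- n_valid[valid] + 1L
    alpha_draws[r, valid] <- apply(vp, 2, shannon)
    for (k in seq_len(ncol(pair_idx))) {
      i1 <- pair_idx[1, k]; i2 <- pair_idx[2, k]
      if (valid[i1] && valid[i2]) {
        if (!any(p[, i1] > 0 & p[, i2] > 0)) {
          t_draws[r, k] <- 1   # disjoint supports, exactly
        } else {
          hg <- shannon((p[, i1] + p[, i2]) / 2)
          ha <- (alpha_draws[r, i1] + alpha_draws[r, i2]) / 2
          t_draws[r, k] <- min(max(exp(hg - ha) - 1, 0), 1)
        }
      }
    }
  }
  alpha_draws <- exp(alpha_draws)

  qs <- config$ci_quantiles
  col_stats <- function(m) {
    if (ncol(m) == 0L) {
      return(tibble::tibble(mean = numeric(), ci_low = numeric(),
                            ci_high = numeric()))
    }
    tibble::tibble(
      mean = unname(apply(m, 2, function(v) if (all(is.na(v))) NA_real_ else
        mean(v, na.rm = TRUE))),
      ci_low = unname(apply(m, 2, function(v) if (all(is.na(v))) NA_real_ else
        quantile(v, qs[1], na.rm = TRUE, names = FALSE))),
      ci_high = unname(apply(m, 2, function(v) if (all(is.na(v))) NA_real_ else
        quantile(v, qs[2], na.rm = TRUE, names = FALSE))))
  }
  a_st <- col_stats(alpha_draws)
  rich <- host_richness(dataset, period, config)
  alpha <- tibble::tibble(
    fly_id = flies, period = period,
    richness = rich$richness[match(flies, rich$fly_id)],
    d_alpha_mean = a_st$mean, ci_low = a_st$ci_low, ci_high = a_st$ci_high,
    n_valid_reps = n_valid)

  t_st <- col_stats(t_draws)
  pairs <- tibble::tibble(
    fly_i = flies[pair_idx[1, ]], fly_k = flies[pair_idx[2, ]],
    period = period, turnover_mean = t_st$mean,
    ci_low = t_st$ci_low, ci_high = t_st$ci_high,
    n_valid_reps = colSums(!is.na(t_draws)))

  mean_matrix <- sweep(p_sum, 2, ifelse(n_valid > 0, n_valid, 1), "/")
  mean_matrix[, n_valid == 0] <- NA_real_
  cell_q <- function(prob) {
    out <- matrix(NA_real_, np, nf, dimnames = dimnames(mean_matrix))
    for (i in seq_len(nf)) {
      if (n_valid[i] > 0) {
        out[, i] <- apply(p_cells[, , i, drop = FALSE], 2, quantile,
                          probs = prob, na.rm = TRUE, names = FALSE)
      }
    }
    out
  }

  structure(
    list(period = period, alpha = alpha, pairs = pairs,
         mean_matrix = mean_matrix,
         cell_ci = list(lo = cell_q(qs[1]), hi = cell_q(qs[2])),
         alpha_draws = alpha_draws, turnover_draws = t_draws,
         reps = reps, seed = config$seed),
    class = "diversity_report")
}

#' @export
print.diversity_report <- function(x, ...) {
  cat("<diversity_report> period=", x$period, ", ", x$reps,
      " bootstrap replicates\n", sep = "")
  print(x$alpha)
  invisible(x)
}

#' Tidy a diversity report
#'
#' @param x A `diversity_report`.
#' @param ... Unused.
#' @return The per-fly alpha-diversity tibble.
#' @export
tidy.diversity_report <- function(x, ...) x$alpha

#' Compare niche indices between periods
#'
#' Per fly: change in mean niche breadth and whether the two bootstrap CIs
#' are disjoint (the "significant" change criterion); per fly pair: the
#' same for turnover.
#'
#' @param before,after `diversity_report`s for the two periods.
#' @return A `period_comparison`: tibbles `alpha` and `pairs`.
#' @export
compare_periods <- function(before, after) {
  stopifnot(inherits(before, "diversity_report"),
            inherits(after, "diversity_report"))
  j <- dplyr::full_join(before$alpha, after$alpha, by = "fly_id",
                        suffix = c("_before", "_after"))
  alpha <- tibble::tibble(
    fly_id = j$fly_id,
    richness_before = j$richness_before, richness_after = j$richness_after,
    d_alpha_before = j$d_alpha_mean_before,
    d_alpha_after = j$d_alpha_mean_after,
    delta_d_alpha = j$d_alpha_mean_after - j$d_alpha_mean_before,
    ci_disjoint = !is.na(j$d_alpha_mean_before) &
      !is.na(j$d_alpha_mean_after) &
      (j$ci_high_after < j$ci_low_before | j$ci_high_before < j$ci_low_after))
  jp <- dplyr::full_join(before$pairs, after$pairs, by = c("fly_i", "fly_k"),
                         suffix = c("_before", "_after"))
  pairs <- tibble::tibble(
    fly_i = jp$fly_i, fly_k = jp$fly_k,
    turnover_before = jp$turnover_mean_before,
    turnover_after = jp$turnover_mean_after,
    delta_turnover = jp$turnover_mean_after - jp$turnover_mean_before,
    ci_disjoint = !is.na(jp$turnover_mean_before) &
      !is.na(jp$turnover_mean_after) &
      (jp$ci_high_after < jp$ci_low_before |
         jp$ci_high_before < jp$ci_low_after))
  structure(list(alpha = alpha, pairs = pairs), class = "period_comparison")
}

#' @export
print.period_comparison <- function(x, ...) {
  cat("<period_comparison>\n")
  print(x$alpha)
  invisible(x)
}

#' Plot niche breadth before and after the invasion
#'
#' @param object A `period_comparison` or `diversity_report`.
#' @param ... For a single report, unused; internally shared.
#' @return A ggplot of per-fly niche breadth with bootstrap CIs.
#' @export
autoplot.diversity_report <- function(object, ...) {
  df <- object$alpha
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fly_id, y = .data$d_alpha_mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::labs(x = NULL, y = expression(D[alpha]),
                  title = paste0("Niche breadth (", object$period,
                                 " period)")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.diversity_report
#' @export
autoplot.period_comparison <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$alpha[, c("fly_id", "d_alpha_before", "d_alpha_after")],
    cols = -"fly_id", names_to = "period", names_prefix = "d_alpha_",
    values_to = "d_alpha")
  df$period <- factor(df$period, levels = c("before", "after"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fly_id, y = .data$d_alpha,
                                   fill = .data$period)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = expression(D[alpha]), fill = NULL,
                  title = "Niche breadth before vs after invasion") +
    ggplot2::theme_minimal()
}
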