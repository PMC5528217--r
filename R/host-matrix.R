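#' Apply the per-period minimum-sampling filter
#'
#' Retains exactly the plants with at least `min_samples_before` fruit
#' samples before the invasion AND at least `min_samples_after` after it
#' (regardless of how many flies emerged); samples of excluded plants are
#' dropped and the exclusion log is attached as attribute `"excluded"`.
#'
#' @param dataset A [fly_dataset()].
#' @param config A [run_config()].
#' @return The filtered `fly_dataset`; idempotent.
#' @export
filter_plants <- function(dataset, config = run_config()) {
  stopifnot(inherits(dataset, "fly_dataset"))
  tally <- dataset$samples |>
    dplyr::count(.data$plant_id, .data$period) |>
    tidyr::pivot_wider(names_from = "period", values_from = "n",
                       values_fill = 0L)
  for (p in c("before", "after")) if (!p %in% names(tally)) tally[[p]] <- 0L
  tally$retained <- tally$before >= config$min_samples_before &
    tally$after >= config$min_samples_after
  keep <- tally$plant_id[tally$retained]
  if (length(keep) == 0L) {
    abort(paste0("no plant passes the sampling filter (>= ",
                 config$min_samples_before, " before and >= ",
                 config$min_samples_after,
                 " after); review the thresholds"))
  }
  excluded <- tally[!tally$retained, c("plant_id", "before", "after")]
  if (nrow(excluded)) {
    inform(paste0("filter_plants: dropped ", nrow(excluded), " plant(s): ",
                  paste(excluded$plant_id, collapse = ", ")))
  }
  sel <- dataset$samples$plant_id %in% keep
  dataset$samples <- dataset$samples[sel, , drop = FALSE]
  dataset$counts <- dataset$counts[
    dataset$counts$sample_id %in% dataset$samples$sample_id, , drop = FALSE]
  dataset$plants <- dataset$plants[dataset$plants$plant_id %in% keep, ,
                                   drop = FALSE]
  attr(dataset, "excluded") <- excluded
  dataset
}

# per-period total flies per (plant, fly): plants x flies matrix in registry order
period_totals <- function(dataset, period) {
  if (!period %in% c("before", "after")) {
    abort(paste0("unknown period: ", period))
  }
  m <- count_matrix(dataset, period)
  plant <- dataset$samples$plant_id[dataset$samples$period == period]
  tot <- rowsum(m, group = plant)
  out <- matrix(0, nrow(dataset$plants), ncol(m),
                dimnames = list(dataset$plants$plant_id, colnames(m)))
  out[rownames(tot), ] <- tot
  out
}

#' Binary presence matrix for one period
#'
#' Cell (j, i) is 1 when the total number of flies of species i emerged over
#' the period's samples of plant j reaches `presence_threshold`.
#'
#' @param dataset A filtered [fly_dataset()].
#' @param period `"before"` or `"after"`.
#' @param config A [run_config()].
#' @return A `presence_matrix`: plants x flies binary matrix (registry
#'   order) with attributes `period` and `threshold`.
#' @export
build_presence <- function(dataset, period, config = run_config()) {
  tot <- period_totals(dataset, period)
  m <- (tot >= config$presence_threshold) * 1L
  structure(m, period = period, threshold = config$presence_threshold,
            class = c("presence_matrix", class(m)))
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("<presence_matrix> period=", attr(x, "period"), ", ",
      nrow(x), " plants x ", ncol(x), " flies, ", sum(x), " presences\n",
      sep = "")
  invisible(x)
}

#' Tidy a presence matrix into long form
#'
#' @param x A `presence_matrix`.
#' @param ... Unused.
#' @return Tibble `plant_id, fly_id, present, period`.
#' @export
tidy.presence_matrix <- function(x, ...) {
  tibble::tibble(plant_id = rep(rownames(x), ncol(x)),
                 fly_id = rep(colnames(x), each = nrow(x)),
                 present = as.integer(x),
                 period = attr(x, "period"))
}

#' Biotic capacity of each plant
#'
#' The mean, over all fruit samples of a plant in the entire dataset (both
#' periods pooled), of the total number of flies of any species emerged per
#' fruit. Used to weight raw counts before diets are compared.
#'
#' @param dataset A filtered [fly_dataset()].
#' @param periods Periods pooled into the mean; default both.
#' @return Tibble `plant_id, w` in registry order.
#' @export
biotic_capacity <- function(dataset, periods = c("before", "after")) {
  stopifnot(inherits(dataset, "fly_dataset"))
  sel <- dataset$samples$period %in% periods
  totals <- rowSums(count_matrix(dataset)[sel, , drop = FALSE])
  df <- tibble::tibble(plant_id = dataset$samples$plant_id[sel],
                       total = totals) |>
    dplyr::summarise(w = mean(.data$total), .by = "plant_id")
  missing <- setdiff(dataset$plants$plant_id, df$plant_id)
  if (length(missing)) {
    abort(paste0("plants without samples in the pooled periods: ",
                 paste(missing, collapse = ", ")))
  }
  out <- df[match(dataset$plants$plant_id, df$plant_id), ]
  if (any(out$w == 0)) {
    warn(paste0("biotic capacity is zero for: ",
                paste(out$plant_id[out$w == 0], collapse = ", "),
                " (all-zero samples); downstream division is guarded"))
  }
  out
}

#' Host richness per fly species
#'
#' Number of host plants in the diet: the count of 1-cells in the fly's
#' presence-matrix column for the period.
#'
#' @inheritParams build_presence
#' @return Tibble `fly_id, period, richness`.
#' @export
host_richness <- function(dataset, period, config = run_config()) {
  m <- build_presence(dataset, period, config)
  tibble::tibble(fly_id = colnames(m), period = period,
                 richness = as.integer(colSums(m)))
}

#' Flag interactions that weakened after the invasion
#'
#' Compares the bootstrap-mean interaction proportions of the two periods
#' and flags (fly, plant) pairs whose mean p_ij dropped by at least
#' `decrease_threshold`. Pairs additionally report whether the per-cell
#' bootstrap CIs of the two periods are disjoint.
#'
#' @param before,after `diversity_report`s from [bootstrap_indices()] for
#'   the two periods.
#' @param config A [run_config()].
#' @return Tibble `fly_id, plant_id, p_before, p_after, drop, flagged,
#'   ci_disjoint`.
#' @export
interaction_change <- function(before, after, config = run_config()) {
  stopifnot(inherits(before, "diversity_report"),
            inherits(after, "diversity_report"))
  mb <- before$mean_matrix
  ma <- after$mean_matrix
  if (!identical(rownames(mb), rownames(ma))) {
    abort("the two reports cover different plant registries")
  }
  shared <- intersect(colnames(mb), colnames(ma))
  grid <- tibble::tibble(
    fly_id = rep(shared, each = nrow(mb)),
    plant_id = rep(rownames(mb), length(shared)),
    p_before = as.vector(mb[, shared]),
    p_after = as.vector(ma[, shared]))
  grid$drop <- grid$p_before - grid$p_after
  grid$flagged <- grid$drop >= config$decrease_threshold
  lo_b <- before$cell_ci$lo[, shared, drop = FALSE]
  hi_b <- before$cell_ci$hi[, shared, drop = FALSE]
  lo_a <- after$cell_ci$lo[, shared, drop = FALSE]
  hi_a <- after$cell_ci$hi[, shared, drop = FALSE]
  grid$ci_disjoint <- as.vector(hi_a < lo_b | hi_b < lo_a)
  grid[order(-grid$drop), ]
}
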