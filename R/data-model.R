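#' Assemble a fruit-fly emergence dataset
#'
#' The central data container: one row per collected fruit in `samples`,
#' per-fruit emergence counts for every fly species in `counts` (wide, one
#' column per fly), plus fly and plant registries. The period of a sample is
#' `"before"` or `"after"` the invasion year.
#'
#' @param samples Tibble with columns `sample_id`, `plant_id`, `period`
#'   (or a `year`/`date` column from which the period is derived), and
#'   optionally `site_id`, `weight_g`.
#' @param counts Tibble with `sample_id` and one non-negative numeric column
#'   per fly species.
#' @param flies Optional fly registry (`fly_id`, `name`, `guild`); inferred
#'   from the count columns when absent. The `guild` label is annotation
#'   only and never enters any computation.
#' @param plants Optional plant registry (`plant_id`, `name`, `family`,
#'   `tree_tip_label`); inferred from `samples$plant_id` when absent.
#' @param invasion_year Integer year splitting the record into periods;
#'   samples from the invasion year itself count as `"after"`.
#' @return An object of class `fly_dataset`.
#' @export
fly_dataset <- function(samples, counts, flies = NULL, plants = NULL,
                        invasion_year = 2000L) {
  samples <- tibble::as_tibble(samples)
  counts <- tibble::as_tibble(counts)
  if (!all(c("sample_id", "plant_id") %in% names(samples))) {
    abort("`samples` needs `sample_id` and `plant_id` columns.")
  }
  if (anyDuplicated(samples$sample_id)) {
    abort(paste0("duplicated sample_id: ",
                 samples$sample_id[duplicated(samples$sample_id)][1]))
  }
  samples <- derive_period(samples, invasion_year)
  if (!"site_id" %in% names(samples)) samples$site_id <- NA_character_
  if (!"weight_g" %in% names(samples)) samples$weight_g <- NA_real_

  if (!"sample_id" %in% names(counts)) abort("`counts` needs a `sample_id` column.")
  fly_ids <- setdiff(names(counts), "sample_id")
  if (length(fly_ids) == 0L) abort("`counts` has no fly count columns.")
  for (f in fly_ids) {
    x <- counts[[f]]
    if (!is.numeric(x) || anyNA(x)) {
      abort(paste0("counts for fly `", f, "` must be numeric and complete"))
    }
    if (any(x < 0)) {
      bad <- counts$sample_id[which(x < 0)[1]]
      abort(paste0("negative count for fly `", f, "` in sample `", bad, "`"))
    }
  }
  missing_counts <- setdiff(samples$sample_id, counts$sample_id)
  if (length(missing_counts)) {
    abort(paste0("samples without count rows: ",
                 paste(head(missing_counts, 3), collapse = ", ")))
  }
  counts <- counts[match(samples$sample_id, counts$sample_id), , drop = FALSE]

  if (is.null(flies)) {
    flies <- tibble::tibble(fly_id = fly_ids, name = fly_ids,
                            guild = "unknown")
  }
  flies <- tibble::as_tibble(flies)
  if (!"name" %in% names(flies)) flies$name <- flies$fly_id
  if (!"guild" %in% names(flies)) flies$guild <- "unknown"
  if (anyDuplicated(flies$fly_id)) abort("fly_id must be unique in the registry")
  unknown_fly <- setdiff(fly_ids, flies$fly_id)
  if (length(unknown_fly)) {
    abort(paste0("count columns not in fly registry: ",
                 paste(unknown_fly, collapse = ", ")))
  }
  # registry order governs column order everywhere downstream
  keep <- intersect(flies$fly_id, fly_ids)
  counts <- counts[, c("sample_id", keep), drop = FALSE]

  if (is.null(plants)) {
    plants <- tibble::tibble(plant_id = unique(samples$plant_id))
  }
  plants <- tibble::as_tibble(plants)
  if (!"name" %in% names(plants)) plants$name <- plants$plant_id
  if (!"family" %in% names(plants)) plants$family <- NA_character_
  if (!"tree_tip_label" %in% names(plants)) plants$tree_tip_label <- plants$plant_id
  if (anyDuplicated(plants$plant_id)) abort("plant_id must be unique in the registry")
  unknown_plant <- setdiff(samples$plant_id, plants$plant_id)
  if (length(unknown_plant)) {
    abort(paste0("samples reference unknown plants: ",
                 paste(unknown_plant, collapse = ", ")))
  }

  structure(
    list(samples = samples[, c("sample_id", "plant_id", "period",
                               "site_id", "weight_g")],
         counts = counts, flies = flies, plants = plants,
         invasion_year = as.integer(invasion_year)),
    class = "fly_dataset"
  )
}

derive_period <- function(samples, invasion_year) {
  if ("period" %in% names(samples)) {
    bad <- setdiff(unique(samples$period), c("before", "after"))
    if (length(bad)) abort(paste0("invalid period label: ", bad[1]))
    return(samples)
  }
  yr <- if ("year" %in% names(samples)) {
    suppressWarnings(as.integer(samples$year))
  } else if ("date" %in% names(samples)) {
    d <- as.Date(as.character(samples$date))
    as.integer(format(d, "%Y"))
  } else {
    abort("`samples` needs a `period`, `year` or `date` column.")
  }
  if (anyNA(yr)) {
    abort(paste0("unparseable collection date for sample `",
                 samples$sample_id[which(is.na(yr))[1]], "`"))
  }
  # the invasion year itself belongs to the post-invasion period
  samples$period <- ifelse(yr < invasion_year, "before", "after")
  samples
}

#' @export
print.fly_dataset <- function(x, ...) {
  cat("<fly_dataset> ", nrow(x$samples), " fruit samples, ",
      nrow(x$plants), " plants, ", nrow(x$flies), " flies; invasion year ",
      x$invasion_year, "\n", sep = "")
  tab <- table(x$samples$period)
  cat("  periods: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Per-fruit counts in long form
#'
#' @param dataset A [fly_dataset()].
#' @param period Optional `"before"`/`"after"` filter.
#' @return Tibble `sample_id, plant_id, period, fly_id, count`.
#' @export
count_long <- function(dataset, period = NULL) {
  stopifnot(inherits(dataset, "fly_dataset"))
  out <- dplyr::left_join(dataset$samples[, c("sample_id", "plant_id", "period")],
                          dataset$counts, by = "sample_id") |>
    tidyr::pivot_longer(cols = -c("sample_id", "plant_id", "period"),
                        names_to = "fly_id", values_to = "count")
  if (!is.null(period)) out <- out[out$period == period, , drop = FALSE]
  out
}

# counts as a plain matrix (samples x flies), rows aligned to dataset$samples
count_matrix <- function(dataset, period = NULL) {
  m <- as.matrix(dataset$counts[, -1, drop = FALSE])
  rownames(m) <- dataset$counts$sample_id
  if (!is.null(period)) m <- m[dataset$samples$period == period, , drop = FALSE]
  m
}

#' Read per-fruit emergence records from CSV
#'
#' Accepts two dialects. Wide: `sample_id, plant_id, date|year|period,
#' [site_id], [weight_g]`, plus one count column per fly species. Long: the
#' same sample columns plus `fly_id` and `count`, one row per (sample, fly);
#' pairs absent from the file are zero. Both dialects yield identical
#' datasets.
#'
#' @param path CSV file.
#' @param invasion_year Year used to derive the period from dates.
#' @param flies,plants Optional registries; under `fly_registry_policy =
#'   "strict"` every fly in the file must already be registered.
#' @param fly_registry_policy `"infer"` (register unseen flies) or `"strict"`.
#' @return A [fly_dataset()].
#' @export
read_samples <- function(path, invasion_year = 2000L, flies = NULL,
                         plants = NULL,
                         fly_registry_policy = c("infer", "strict")) {
  fly_registry_policy <- match.arg(fly_registry_policy)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  meta_cols <- c("sample_id", "plant_id", "period", "date", "year",
                 "site_id", "weight_g")
  raw$sample_id <- as.character(raw$sample_id)
  long_dialect <- all(c("fly_id", "count") %in% names(raw))
  if (long_dialect) {
    samples <- dplyr::distinct(raw[, intersect(meta_cols, names(raw)),
                                   drop = FALSE])
    if (anyDuplicated(samples$sample_id)) {
      abort("inconsistent sample metadata across long-format rows")
    }
    neg <- raw$count < 0
    if (any(neg)) {
      abort(paste0("negative count in sample `",
                   raw$sample_id[which(neg)[1]], "`"))
    }
    counts <- raw |>
      dplyr::summarise(count = sum(.data$count),
                       .by = c("sample_id", "fly_id")) |>
      tidyr::pivot_wider(names_from = "fly_id", values_from = "count",
                         values_fill = 0)
  } else {
    samples <- raw[, intersect(meta_cols, names(raw)), drop = FALSE]
    counts <- raw[, c("sample_id", setdiff(names(raw), meta_cols)),
                  drop = FALSE]
  }
  file_flies <- setdiff(names(counts), "sample_id")
  if (fly_registry_policy == "strict") {
    if (is.null(flies)) abort("strict policy needs a fly registry")
    extra <- setdiff(file_flies, flies$fly_id)
    if (length(extra)) {
      abort(paste0("unregistered fly species under strict policy: ",
                   paste(extra, collapse = ", ")))
    }
    # registered flies absent from the file contribute zero columns
    for (f in setdiff(flies$fly_id, file_flies)) counts[[f]] <- 0
  } else if (!is.null(flies)) {
    new <- setdiff(file_flies, flies$fly_id)
    if (length(new)) {
      flies <- dplyr::bind_rows(
        flies, tibble::tibble(fly_id = new, name = new, guild = "unknown"))
    }
    for (f in setdiff(flies$fly_id, file_flies)) counts[[f]] <- 0
  }
  if (fly_registry_policy == "strict" && !is.null(plants)) {
    extra <- setdiff(unique(samples$plant_id), plants$plant_id)
    if (length(extra)) {
      abort(paste0("unregistered plants under strict policy: ",
                   paste(extra, collapse = ", ")))
    }
  }
  ds <- fly_dataset(samples, counts, flies = flies, plants = plants,
                    invasion_year = invasion_year)
  # canonical fly order: registry order if given, else alphabetical
  if (is.null(flies)) {
    ord <- order(ds$flies$fly_id)
    ds$flies <- ds$flies[ord, , drop = FALSE]
    ds$counts <- ds$counts[, c("sample_id", ds$flies$fly_id), drop = FALSE]
  }
  ds
}

#' Write a dataset back to wide CSV
#'
#' @param dataset A [fly_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(dataset, path) {
  stopifnot(inherits(dataset, "fly_dataset"))
  wide <- dplyr::left_join(dataset$samples, dataset$counts, by = "sample_id")
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read a rooted host-plant phylogeny
#'
#' Newick input; exactly one rooted tree with branch lengths. Polytomies are
#' allowed; missing branch lengths are an error (no default is substituted).
#'
#' @param path Newick file.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) abort("expected a single tree, found several")
    tr <- tr[[1L]]
  }
  if (!inherits(tr, "phylo")) abort("could not parse a tree from file")
  check_tree(tr)
  tr
}

check_tree <- function(tr) {
  if (is.null(tr$edge.length) && nrow(tr$edge) > 0L) {
    abort("tree has no branch lengths; lengths are required")
  }
  if (!is.null(tr$edge.length) &&
      (anyNA(tr$edge.length) || any(tr$edge.length < 0))) {
    abort("tree has missing or negative branch lengths")
  }
  if (ape::Ntip(tr) > 1L && !ape::is.rooted(tr)) {
    abort("tree must be rooted")
  }
  invisible(tr)
}

#' Analysis configuration
#'
#' Collects the constants of the analysis: the invasion year, the per-period
#' minimum-sampling filter, bootstrap size and CI quantiles, the presence
#' threshold, the QIC support margin, and the interaction-decrease flag
#' threshold.
#'
#' @param invasion_year Year of the invasion (samples from this year are
#'   "after").
#' @param min_samples_before,min_samples_after Minimum number of fruit
#'   samples per plant in each period; plants below either bound are dropped.
#' @param bootstrap_reps Number of one-fruit-per-plant interaction matrices.
#' @param ci_quantiles Lower/upper quantiles of the bootstrap distribution.
#' @param presence_threshold Minimum total emerged flies over a period for a
#'   (plant, fly) presence cell to score 1.
#' @param qic_delta QIC difference required to call a model selected.
#' @param decrease_threshold Drop in mean interaction proportion flagged as
#'   a diet loss.
#' @param ridge Ridge penalty engaged when a GEE fit separates.
#' @param unit Observation unit for the model suite: `"sample"` (one binary
#'   row per fruit x fly) or `"cell"` (one row per presence cell).
#' @param seed Integer seed for all randomised stages.
#' @return A `run_config` list.
#' @export
run_config <- function(invasion_year = 2000L, min_samples_before = 4L,
                       min_samples_after = 4L, bootstrap_reps = 10000L,
                       ci_quantiles = c(0.025, 0.975),
                       presence_threshold = 1L, qic_delta = 10,
                       decrease_threshold = 0.10, ridge = 1e-4,
                       unit = c("sample", "cell"), seed = 1L) {
  unit <- match.arg(unit)
  cfg <- list(invasion_year = as.integer(invasion_year),
              min_samples_before = as.integer(min_samples_before),
              min_samples_after = as.integer(min_samples_after),
              bootstrap_reps = as.integer(bootstrap_reps),
              ci_quantiles = as.numeric(ci_quantiles),
              presence_threshold = as.integer(presence_threshold),
              qic_delta = as.numeric(qic_delta),
              decrease_threshold = as.numeric(decrease_threshold),
              ridge = as.numeric(ridge), unit = unit, seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$min_samples_before > 0, cfg$min_samples_after > 0,
            cfg$bootstrap_reps >= 1, cfg$presence_threshold > 0,
            cfg$qic_delta > 0, cfg$ridge > 0)
  if (!(cfg$decrease_threshold > 0 && cfg$decrease_threshold < 1)) {
    abort("decrease_threshold must lie in (0, 1)")
  }
  q <- cfg$ci_quantiles
  if (length(q) != 2L || any(q <= 0) || any(q >= 1) || q[1] >= q[2]) {
    abort("ci_quantiles must be an ordered pair in (0, 1)")
  }
  invisible(cfg)
}

#' Read/write a run configuration as JSON
#'
#' @param path JSON file.
#' @return `read_run_config()` returns a `run_config`; `write_run_config()`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, vals[intersect(names(vals), names(formals(run_config)))])
}

#' @rdname read_run_config
#' @param config A [run_config()].
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
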