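#' Diagnose inputs before running the analysis
#'
#' Reports, without modifying anything: per-plant sample counts per period
#' against the filter thresholds (plants that would be excluded), tree
#' coverage of the retained plants, and a fly-registry summary flagging
#' species seen only after the invasion (invader-like). Fatal findings are
#' those that would abort [run_analysis()].
#'
#' @param dataset A [fly_dataset()].
#' @param tree Optional host phylogeny to check coverage against.
#' @param config A [run_config()].
#' @return A `hostshift_diagnostics` list: tibbles `plants` and `flies`,
#'   character vector `findings`, logical `fatal`.
#' @export
validate_dataset <- function(dataset, tree = NULL, config = run_config()) {
  stopifnot(inherits(dataset, "fly_dataset"))
  tally <- dataset$samples |>
    dplyr::count(.data$plant_id, .data$period) |>
    tidyr::pivot_wider(names_from = "period", values_from = "n",
                       values_fill = 0L)
  for (p in c("before", "after")) if (!p %in% names(tally)) tally[[p]] <- 0L
  tally$retained <- tally$before >= config$min_samples_before &
    tally$after >= config$min_samples_after
  findings <- character()
  fatal <- FALSE
  if (!any(tally$retained)) {
    findings <- c(findings, "FATAL: no plant passes the sampling filter")
    fatal <- TRUE
  } else if (any(!tally$retained)) {
    findings <- c(findings,
                  paste0("would be excluded by the sampling filter: ",
                         paste(tally$plant_id[!tally$retained],
                               collapse = ", ")))
  }
  cm <- count_matrix(dataset)
  per_period <- rowsum(cm, dataset$samples$period)
  flies <- tibble::tibble(
    fly_id = colnames(cm),
    total_before = if ("before" %in% rownames(per_period))
      as.numeric(per_period["before", ]) else 0,
    total_after = if ("after" %in% rownames(per_period))
      as.numeric(per_period["after", ]) else 0)
  flies$status <- dplyr::case_when(
    flies$total_before == 0 & flies$total_after > 0 ~ "after-only (invader-like)",
    flies$total_after == 0 & flies$total_before > 0 ~ "before-only",
    flies$total_before == 0 & flies$total_after == 0 ~ "never observed",
    TRUE ~ "both periods")
  for (f in flies$fly_id[flies$status == "after-only (invader-like)"]) {
    findings <- c(findings, paste0("fly `", f,
                                   "` seen only after the invasion year"))
  }
  if (!is.null(tree)) {
    retained <- dataset$plants[dataset$plants$plant_id %in%
                                 tally$plant_id[tally$retained], ]
    lab <- retained$tree_tip_label %||% retained$plant_id
    lab <- ifelse(is.na(lab), retained$plant_id, lab)
    miss <- retained$plant_id[!lab %in% tree$tip.label]
    if (length(miss)) {
      findings <- c(findings,
                    paste0("FATAL: retained plant(s) missing from the tree: ",
                           paste(miss, collapse = ", ")))
      fatal <- TRUE
    }
  }
  structure(list(plants = tally, flies = flies, findings = findings,
                 fatal = fatal),
            class = "hostshift_diagnostics")
}

#' @export
print.hostshift_diagnostics <- function(x, ...) {
  cat("<hostshift_diagnostics> ",
      sum(x$plants$retained), "/", nrow(x$plants), " plants retained; ",
      length(x$findings), " finding(s)", if (x$fatal) " [FATAL]", "\n",
      sep = "")
  for (f in x$findings) cat("  - ", f, "\n", sep = "")
  invisible(x)
}

#' Run the full before/after host-range analysis
#'
#' Orchestrates the pipeline: sampling filter, biotic capacity, presence
#' matrix (before period), phylogenetic correlation, GEE model suite with
#' QIC selection, bootstrap diversity indices for both periods, the
#' period comparison, and the interaction-decrease flags. Any stage error
#' aborts with the stage named; outputs written before the failure are
#' preserved.
#'
#' @param dataset A [fly_dataset()] or a samples CSV path.
#' @param tree An [ape::phylo] or a newick path.
#' @param config A [run_config()] or a JSON config path.
#' @param out_dir Optional directory; when given, the QIC table, both
#'   diversity reports, the change table, the interaction flags and a run
#'   manifest (with content digests) are written there.
#' @return A `hostshift_run` list: `qic_table, diversity_before,
#'   diversity_after, comparison, interactions, dataset, manifest`.
#' @export
run_analysis <- function(dataset, tree, config = run_config(),
                         out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  validate_config(config)
  if (is.character(dataset)) {
    dataset <- read_samples(dataset, invasion_year = config$invasion_year)
  }
  if (is.character(tree)) tree <- read_tree(tree)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  warnings_log <- character()
  stage <- function(name, expr) {
    s <- proc.time()[["elapsed"]]
    out <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        abort(paste0("pipeline stage `", name, "` failed: ",
                     conditionMessage(e)))
      }),
      warning = function(w) {
        warnings_log <<- c(warnings_log,
                           paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - s, 3)
    out
  }

  filtered <- stage("filter", filter_plants(dataset, config))
  w <- stage("biotic_capacity", biotic_capacity(filtered))
  corr <- stage("phylo_correlation", {
    align_to_registry(phylo_correlation(tree), filtered$plants)
  })
  qic_tab <- stage("model_suite",
                   fit_model_suite(filtered, corr, period = "before",
                                   config = config))
  div_before <- stage("diversity_before",
                      bootstrap_indices(filtered, "before", w, config))
  div_after <- stage("diversity_after",
                     bootstrap_indices(filtered, "after", w, config))
  comparison <- stage("compare", compare_periods(div_before, div_after))
  interactions <- stage("interaction_change",
                        interaction_change(div_before, div_after, config))

  manifest <- list(
    package_version = as.character(utils::packageVersion("hostshift")),
    seed = config$seed, config = unclass(config),
    n_samples = nrow(filtered$samples), n_plants = nrow(filtered$plants),
    n_flies = nrow(filtered$flies),
    excluded_plants = attr(filtered, "excluded")$plant_id %||% character(),
    selected_model = as.character(attr(qic_tab, "selected")),
    timings_s = as.list(timings),
    total_s = round(proc.time()[["elapsed"]] - t0, 3),
    warnings = warnings_log, outputs = list())

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(qic_table = "qic_table.csv",
               diversity_before = "diversity_before.csv",
               diversity_after = "diversity_after.csv",
               comparison = "comparison.csv",
               interaction_change = "interaction_change.csv")
    write_report(qic_tab, file.path(out_dir, paths["qic_table"]))
    write_report(div_before, file.path(out_dir, paths["diversity_before"]))
    write_report(div_after, file.path(out_dir, paths["diversity_after"]))
    write_report(comparison, file.path(out_dir, paths["comparison"]))
    readr::write_csv(interactions,
                     file.path(out_dir, paths["interaction_change"]),
                     progress = FALSE)
    written <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
    manifest$outputs <- lapply(setNames(tools::md5sum(written),
                                        basename(written)), unname)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(qic_table = qic_tab, diversity_before = div_before,
                 diversity_after = div_after, comparison = comparison,
                 interactions = interactions, dataset = filtered,
                 manifest = manifest),
            class = "hostshift_run")
}

#' @export
print.hostshift_run <- function(x, ...) {
  cat("<hostshift_run> model selected: ", x$manifest$selected_model,
      " | ", x$manifest$n_samples, " fruit samples, ",
      x$manifest$n_plants, " plants, ", x$manifest$n_flies, " flies\n",
      sep = "")
  print(x$comparison$alpha)
  invisible(x)
}
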