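#' Fit the community-structure model suite (M1-M4) and compute QIC
#'
#' Four marginal models for the probability that fly species i occurs on
#' plant j, compared by QIC:
#' * **M1** fly-species effects only;
#' * **M2** additive fly + plant effects;
#' * **M3** fly x plant interaction;
#' * **M4** one GEE per fly species over the plants, one parameter per
#'   plant, all plants in a single cluster whose working correlation is the
#'   fixed Brownian tip correlation of the host phylogeny; its QIC is the
#'   sum over fly species.
#'
#' M1-M3 use the independence working correlation with plants as clusters.
#' With `unit = "sample"` (default) the observations are one binary row per
#' fruit x fly (M4 aggregates them to per-plant binomial proportions); with
#' `unit = "cell"` the observations are the cells of the period's presence
#' matrix, in which case M3 and M4 are saturated and are ridge-stabilised
#' (noted in the table). Flies absent from the period are excluded from the
#' matrices.
#'
#' @param dataset A filtered [fly_dataset()].
#' @param corr A `phylo_corr` aligned (or alignable) to the plant registry,
#'   or a tree ([ape::phylo]) from which it is computed.
#' @param period `"before"` (the study's choice) or `"after"`.
#' @param config A [run_config()]; `config$unit` picks the observation unit
#'   unless `unit` is given.
#' @param unit Override of the observation unit.
#' @param models Subset of `c("M1", "M2", "M3", "M4")` to fit (all by
#'   default); the support-margin selection is applied to whatever is
#'   fitted.
#' @return A `qic_table` tibble (`model_id, qic, quasi_lik, trace_term,
#'   n_params, note, rank`) with the selection result in attribute
#'   `"selected"` and per-fly M4 components in `"m4_components"`.
#' @export
fit_model_suite <- function(dataset, corr, period = "before",
                            config = run_config(), unit = NULL,
                            models = c("M1", "M2", "M3", "M4")) {
  models <- match.arg(models, several.ok = TRUE)
  stopifnot(inherits(dataset, "fly_dataset"))
  unit <- unit %||% config$unit
  if (inherits(corr, "phylo")) corr <- phylo_correlation(corr)
  corr <- align_to_registry(corr, dataset$plants)
  check_phylo_corr(corr, tol_psd = -1e-8)

  if (unit == "sample") {
    m <- count_matrix(dataset, period)
    plant <- dataset$samples$plant_id[dataset$samples$period == period]
    pres <- (m > 0) * 1L
  } else {
    pm <- build_presence(dataset, period, config)
    pres <- unclass(pm)
    plant <- rownames(pres)
  }
  active <- colnames(pres)[colSums(pres) > 0]
  if (length(active) < 2L) abort("fewer than two fly species occur in this period")
  pres <- pres[, active, drop = FALSE]

  nf <- length(active)
  plant_f <- factor(plant, levels = dataset$plants$plant_id)
  df <- data.frame(
    y = as.vector(pres),
    fly = factor(rep(active, each = nrow(pres)), levels = active),
    plant = rep(plant_f, nf))
  # sample mode: the independent sampling unit is the fruit, and the fly
  # rows of one fruit form a cluster; with plants as clusters the saturated
  # M3 score vanishes identically and its sandwich (hence the QIC penalty)
  # collapses to zero. Cell mode has one row per cell, clustered by plant.
  cluster <- if (unit == "sample") rep(seq_len(nrow(pres)), nf) else df$plant

  fit_one <- function(form) {
    x <- model.matrix(form, df)
    fit_gee(df$y, x, cluster = cluster, working = "independence",
            ridge = config$ridge)
  }
  forms <- list(M1 = ~fly, M2 = ~ fly + plant, M3 = ~ fly * plant)
  fits <- purrr::map(forms[intersect(c("M1", "M2", "M3"), models)], fit_one)

  # M4: per fly, per-plant means, one cluster, fixed phylogenetic correlation
  m4 <- if (!"M4" %in% models) list() else purrr::map(active, function(f) {
    sub <- df[df$fly == f, ]
    n_j <- as.vector(table(sub$plant))
    ybar <- as.vector(tapply(sub$y, sub$plant, mean))
    ok <- n_j > 0
    x <- diag(sum(ok))
    colnames(x) <- levels(plant_f)[ok]
    fit_gee(ybar[ok], x, cluster = rep(1L, sum(ok)), working = "fixed",
            corr = corr[ok, ok, drop = FALSE], weights = n_j[ok],
            ridge = config$ridge)
  })
  names(m4) <- if (length(m4)) active else character()

  q123 <- purrr::map(fits, qic)
  q4 <- purrr::map(m4, qic)
  m4_components <- tibble::tibble(
    fly_id = names(m4),
    qic = purrr::map_dbl(q4, as.numeric),
    quasi_lik = purrr::map_dbl(m4, "quasi_lik"),
    ridge_used = purrr::map_lgl(m4, "ridge_used"))

  tab <- tibble::tibble(
    model_id = c(names(fits), if (length(m4)) "M4"),
    qic = c(purrr::map_dbl(q123, as.numeric),
            if (length(m4)) sum(m4_components$qic)),
    quasi_lik = c(purrr::map_dbl(fits, "quasi_lik"),
                  if (length(m4)) sum(purrr::map_dbl(m4, "quasi_lik"))),
    trace_term = c(purrr::map_dbl(q123, attr, "trace_term"),
                   if (length(m4)) sum(purrr::map_dbl(q4, attr,
                                                      "trace_term"))),
    n_params = c(purrr::map_int(fits, ~length(.x$kept)),
                 if (length(m4)) sum(purrr::map_int(m4, ~length(.x$kept)))),
    note = c(purrr::map_chr(fits, fit_note),
             if (length(m4))
               paste0("sum of ", nf, " per-fly fits",
                      if (any(m4_components$ridge_used)) "; ridge-stabilised"
                      else "")))
  tab$rank <- rank(tab$qic, ties.method = "min")
  tab <- structure(tab, class = c("qic_table", class(tab)),
                   period = period, unit = unit,
                   m4_components = m4_components,
                   qic_delta = config$qic_delta)
  attr(tab, "selected") <- select_model(tab, config)
  tab
}

fit_note <- function(fit) {
  paste0(if (fit$ridge_used) "ridge-stabilised" else "plain",
         if (!fit$converged) "; NOT converged" else "")
}

#' Apply the QIC support rule to a model table
#'
#' The lowest-QIC model is selected when the runner-up exceeds it by more
#' than `qic_delta`; otherwise `"inconclusive"`, with every model inside the
#' margin listed in attribute `"within_delta"`.
#'
#' @param table A `qic_table` (or any tibble with `model_id` and `qic`).
#' @param config A [run_config()].
#' @return Character scalar: a model id or `"inconclusive"`.
#' @export
select_model <- function(table, config = run_config()) {
  ord <- order(table$qic)
  best <- table$model_id[ord[1]]
  if (nrow(table) == 1L) {
    return(structure(best, margin = Inf, within_delta = best))
  }
  margin <- table$qic[ord[2]] - table$qic[ord[1]]
  within <- table$model_id[table$qic - table$qic[ord[1]] <= config$qic_delta]
  if (margin > config$qic_delta) {
    structure(best, margin = margin, within_delta = within)
  } else {
    structure("inconclusive", margin = margin, within_delta = within)
  }
}

#' @export
print.qic_table <- function(x, ...) {
  cat("<qic_table> period=", attr(x, "period"), ", unit=", attr(x, "unit"),
      ", selected: ", attr(x, "selected"), "\n", sep = "")
  print(tibble::as_tibble(x))
  invisible(x)
}

#' Plot a QIC model comparison
#'
#' @param object A `qic_table`.
#' @param ... Unused.
#' @return A ggplot: QIC per model, the selected model highlighted.
#' @export
autoplot.qic_table <- function(object, ...) {
  sel <- attr(object, "selected")
  df <- tibble::as_tibble(object)
  df$selected <- df$model_id == sel
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model_id, y = .data$qic,
                                   fill = .data$selected)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                          `FALSE` = "grey65")) +
    ggplot2::labs(x = NULL, y = "QIC",
                  title = paste0("Model comparison (", attr(object, "period"),
                                 " period)"),
                  subtitle = paste0("selected: ", sel)) +
    ggplot2::theme_minimal()
}
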