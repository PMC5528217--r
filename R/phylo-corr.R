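#' Brownian-motion covariance of a rooted tree
#'
#' Entry (a, b) is the shared root-to-MRCA path length of tips a and b; the
#' diagonal is the root-to-tip distance. Polytomies need no resolution under
#' this definition.
#'
#' @param tree A rooted [ape::phylo] with branch lengths.
#' @return Symmetric covariance matrix with tip labels as dimnames.
#' @export
brownian_vcv <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) && nrow(tree$edge) > 0L) {
    abort("tree has no branch lengths; lengths are required")
  }
  if (!is.null(tree$edge.length) &&
      (anyNA(tree$edge.length) || any(tree$edge.length < 0))) {
    abort("tree has missing or negative branch lengths")
  }
  # basal polytomies (star trees) are fine: the shared-path definition
  # roots them at the basal node
  if (ape::Ntip(tree) == 1L) {
    d <- sum(tree$edge.length %||% 0)
    return(matrix(d, 1, 1, dimnames = list(tree$tip.label, tree$tip.label)))
  }
  ape::vcv.phylo(tree)
}

#' Standardise a covariance to a tip correlation
#'
#' @param vcv Covariance matrix from [brownian_vcv()] (strictly positive
#'   diagonal).
#' @param lambda Optional off-diagonal scaling in `[0, 1]` (sensitivity
#'   analyses only; 1 leaves the Brownian structure untouched).
#' @return A `phylo_corr`: unit-diagonal correlation matrix, tip order in
#'   dimnames.
#' @export
to_correlation <- function(vcv, lambda = 1) {
  stopifnot(is.matrix(vcv), nrow(vcv) == ncol(vcv))
  d <- diag(vcv)
  if (any(d <= 0)) {
    abort(paste0("zero or negative diagonal (root-to-tip distance) for tip: ",
                 paste(rownames(vcv)[d <= 0], collapse = ", ")))
  }
  cm <- vcv / sqrt(outer(d, d))
  if (lambda != 1) {
    cm <- lambda * cm
  }
  diag(cm) <- 1
  cm <- (cm + t(cm)) / 2
  structure(cm, class = c("phylo_corr", class(cm)))
}

#' Tip correlation of a tree, in one step
#'
#' @inheritParams brownian_vcv
#' @inheritParams to_correlation
#' @export
phylo_correlation <- function(tree, lambda = 1) {
  to_correlation(brownian_vcv(tree), lambda = lambda)
}

#' Align a tip correlation with a plant registry
#'
#' Rows and columns are permuted to registry order; tips not matching any
#' retained plant are dropped (logged). Matching uses `tree_tip_label` when
#' present, else `plant_id`.
#'
#' @param corr A `phylo_corr`.
#' @param plants Plant registry tibble (`plant_id` and optionally
#'   `tree_tip_label`), e.g. `dataset$plants`.
#' @return A `phylo_corr` with rows/cols named by `plant_id` in registry
#'   order.
#' @export
align_to_registry <- function(corr, plants) {
  tips <- rownames(corr)
  lab <- plants$tree_tip_label %||% plants$plant_id
  lab <- ifelse(is.na(lab), plants$plant_id, lab)
  missing <- plants$plant_id[!lab %in% tips]
  if (length(missing)) {
    abort(paste0("retained plant(s) missing from the tree: ",
                 paste(missing, collapse = ", ")))
  }
  dup <- lab[duplicated(lab)]
  if (length(dup)) {
    abort(paste0("tree tip label matched by several plants: ", dup[1]))
  }
  extra <- setdiff(tips, lab)
  if (length(extra)) {
    inform(paste0("align_to_registry: dropping ", length(extra),
                  " tree tip(s) without a retained plant: ",
                  paste(extra, collapse = ", ")))
  }
  out <- corr[lab, lab, drop = FALSE]
  dimnames(out) <- list(plants$plant_id, plants$plant_id)
  structure(out, class = c("phylo_corr", "matrix", "array"))
}

check_phylo_corr <- function(corr, tol_sym = 1e-12, tol_psd = -1e-10) {
  stopifnot(is.matrix(corr))
  if (max(abs(corr - t(corr))) > tol_sym) abort("correlation is not symmetric")
  if (any(abs(diag(corr) - 1) > 0)) abort("diagonal must be exactly 1")
  if (min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values) < tol_psd) {
    abort("correlation is not positive semidefinite")
  }
  invisible(corr)
}
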