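#' Fit a binomial-logit generalized estimating equation
#'
#' Solves the estimating equations
#' \deqn{\sum_c D_c' V_c^{-1} (y_c - \mu_c) = 0}
#' by iteratively reweighted updates, with logit link, binomial variance
#' \eqn{\mu(1-\mu)} and working covariance
#' \eqn{V_c = \phi S_c^{1/2} R_c S_c^{1/2}} (S the variance function over
#' prior weights). Returns both the model-based and the robust (sandwich)
#' covariance. Under the independence working structure with unit weights
#' this reproduces the ordinary logistic GLM.
#'
#' Responses may be binary or binomial proportions with denominators in
#' `weights`. If the fit separates (any |linear predictor| > 30) or fails to
#' converge, a ridge-penalised refit (penalty `ridge`) is engaged and
#' flagged, never thrown.
#'
#' @param y Response in `[0, 1]`.
#' @param x Design matrix (degenerate columns are pruned).
#' @param cluster Cluster id per observation.
#' @param working `"independence"`, `"exchangeable"`, or `"fixed"`.
#' @param corr For `working = "fixed"`: correlation matrix whose dimension
#'   matches each cluster's size (observation order within cluster), never
#'   re-estimated.
#' @param weights Binomial denominators (prior weights).
#' @param phi Dispersion; fixed at 1 by default (binary-data convention).
#'   `phi = NULL` estimates it from Pearson residuals.
#' @param ridge Ridge penalty for the separation fallback.
#' @param max_iter,tol Convergence controls (max |change in beta| < tol).
#' @return A `gee_fit`.
#' @export
fit_gee <- function(y, x, cluster = seq_along(y),
                    working = c("independence", "exchangeable", "fixed"),
                    corr = NULL, weights = NULL, phi = 1, ridge = 1e-4,
                    max_iter = 100L, tol = 1e-8) {
  working <- match.arg(working)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  stopifnot(length(y) == nrow(x))
  if (is.null(weights)) weights <- rep(1, length(y))
  stopifnot(length(weights) == length(y), all(weights > 0),
            all(y >= 0 & y <= 1))
  if (working == "fixed" && is.null(corr)) {
    abort("working = \"fixed\" needs `corr`")
  }
  keep <- prune_columns(x)
  xk <- x[, keep, drop = FALSE]
  cl <- split(seq_along(y), factor(cluster, levels = unique(cluster)))
  if (working == "fixed") {
    sizes <- lengths(cl)
    if (any(sizes != nrow(corr))) {
      abort("fixed working correlation dimension must match cluster sizes")
    }
  }

  res <- gee_irls(y, xk, cl, working, corr, weights, phi,
                  penalty = 0, max_iter = max_iter, tol = tol)
  ridge_used <- FALSE
  if (res$separated || !res$converged) {
    res <- gee_irls(y, xk, cl, working, corr, weights, phi,
                    penalty = ridge, max_iter = max_iter, tol = tol)
    ridge_used <- TRUE
  }

  beta <- setNames(rep(0, ncol(x)), colnames(x))
  beta[keep] <- res$beta
  structure(
    list(coefficients = beta, kept = keep, vcov_model = res$vcov_model,
         vcov_robust = res$vcov_robust, phi = res$phi,
         quasi_lik = quasi_likelihood(y, res$mu, weights),
         fitted = res$mu, eta = res$eta, residuals = y - res$mu,
         y = y, x = xk, weights = weights, clusters = cl,
         working = working, rho = res$rho, n_iter = res$iter,
         converged = res$converged, ridge_used = ridge_used,
         ridge = if (ridge_used) ridge else 0),
    class = "gee_fit"
  )
}

# drop all-constant-zero and aliased columns
prune_columns <- function(x) {
  nz <- colSums(abs(x)) > 0
  xk <- x[, nz, drop = FALSE]
  q <- qr(xk)
  keep_idx <- q$pivot[seq_len(q$rank)]
  colnames(x)[nz][sort(keep_idx)]
}

gee_irls <- function(y, x, cl, working, corr, w, phi_arg, penalty,
                     max_iter, tol) {
  p <- ncol(x)
  beta <- rep(0, p)
  rho <- 0
  est_phi <- is.null(phi_arg)
  phi <- if (est_phi) 1 else phi_arg
  converged <- FALSE
  separated <- FALSE
  iter <- 0L
  cl_vec <- rep(seq_along(cl), lengths(cl))[order(unlist(cl))]

  score_pieces <- function(beta, want_scores = FALSE) {
    eta <- drop(x %*% beta)
    mu <- plogis(eta)
    a <- pmax(mu * (1 - mu), 1e-12)  # variance function and d mu / d eta
    s <- a / w                       # Var(y_i)/phi
    e <- (y - mu) / sqrt(s)          # Pearson residuals (phi = 1 scale)
    if (est_phi) {
      phi <<- sum(e^2) / max(length(y) - p, 1)
    }
    if (working == "exchangeable") {
      num <- 0; den <- 0
      for (idx in cl) {
        ec <- e[idx]; nc <- length(ec)
        if (nc > 1) {
          num <- num + (sum(ec)^2 - sum(ec^2)) / 2
          den <- den + nc * (nc - 1) / 2
        }
      }
      rho <<- if (den > 0) max(min(num / (phi * den), 0.99), -0.99) else 0
    }
    if (working == "independence") {
      # diagonal working covariance: no cluster loop needed
      H <- crossprod(x, x * (a * w / phi))
      g <- drop(crossprod(x, w * (y - mu) / phi))
      scores <- if (want_scores) x * (w * (y - mu) / phi)  # per-obs rows
      return(list(eta = eta, mu = mu, a = a, H = H, g = g, scores = scores))
    }
    H <- matrix(0, p, p)
    g <- rep(0, p)
    g_cl <- matrix(0, length(cl), p)
    for (ci in seq_along(cl)) {
      idx <- cl[[ci]]
      xc <- x[idx, , drop = FALSE]
      ac <- a[idx]; sc <- s[idx]; rc <- (y - mu)[idx]
      dm <- xc * ac                    # D_c
      nc <- length(idx)
      if (nc == 1L) {
        vinv_d <- dm / (phi * sc)
        vinv_r <- rc / (phi * sc)
      } else {
        R <- if (working == "fixed") corr else {
          m <- matrix(rho, nc, nc); diag(m) <- 1; m
        }
        ss <- sqrt(sc)
        V <- phi * (R * outer(ss, ss))
        vi <- tryCatch(chol2inv(chol(V)), error = function(e)
          chol2inv(chol(V + diag(1e-10, nc))))
        vinv_d <- vi %*% dm
        vinv_r <- drop(vi %*% rc)
      }
      H <- H + crossprod(dm, vinv_d)
      g_cl[ci, ] <- drop(crossprod(dm, vinv_r))
    }
    g <- colSums(g_cl)
    list(eta = eta, mu = mu, a = a, H = H, g = g, g_cl = g_cl)
  }

  pieces <- NULL
  for (iter in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    if (max(abs(eta)) > 30 && penalty == 0) {
      separated <- TRUE
      break
    }
    pieces <- score_pieces(beta)
    H <- pieces$H
    g <- pieces$g
    if (penalty > 0) {
      H <- H + diag(penalty, p)
      g <- g - penalty * beta
    }
    step <- tryCatch(solve(H, g), error = function(e) {
      solve(H + diag(1e-8, p), g)
    })
    beta <- beta + step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  # bread and meat evaluated at the final coefficients
  pieces <- score_pieces(beta, want_scores = TRUE)
  bread <- pieces$H
  if (penalty > 0) bread <- bread + diag(penalty, p)
  g_cl <- if (working == "independence") {
    rowsum(pieces$scores, cl_vec)
  } else {
    pieces$g_cl
  }
  meat <- crossprod(g_cl)
  bread_inv <- tryCatch(solve(bread), error = function(e) {
    solve(bread + diag(1e-8, p))
  })
  list(beta = beta, mu = pieces$mu, eta = pieces$eta, phi = phi, rho = rho,
       iter = iter, converged = converged, separated = separated,
       vcov_model = phi * bread_inv,
       vcov_robust = bread_inv %*% meat %*% bread_inv)
}

#' Binomial quasi-likelihood under the independence model
#'
#' \eqn{Q = \sum_i w_i [y_i \log \mu_i + (1-y_i)\log(1-\mu_i)]}, with
#' \eqn{\mu} clipped at `1e-12` so perfectly fitted 0/1 observations
#' contribute 0 in the limit.
#'
#' @param y Observed responses in `[0, 1]`.
#' @param mu Fitted means.
#' @param weights Binomial denominators.
#' @return A single number, `<= 0`.
#' @export
quasi_likelihood <- function(y, mu, weights = NULL) {
  if (length(y) != length(mu)) abort("y and mu have different lengths")
  if (is.null(weights)) weights <- rep(1, length(y))
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  sum(weights * (y * log(mu) + (1 - y) * log(1 - mu)))
}

#' Quasi-likelihood information criterion (Pan's QIC)
#'
#' \eqn{QIC = -2Q(\hat\beta) + 2\,\mathrm{tr}(\hat\Omega_I \hat V_R)}, with
#' \eqn{\hat\Omega_I} the model-based information recomputed under the
#' independence working structure at \eqn{\hat\beta} and \eqn{\hat V_R} the
#' robust sandwich covariance of the fit.
#'
#' @param fit A `gee_fit`.
#' @return A single number; attributes `quasi_lik` and `trace_term` carry
#'   the two components.
#' @export
qic <- function(fit) {
  stopifnot(inherits(fit, "gee_fit"))
  a <- pmax(fit$fitted * (1 - fit$fitted), 1e-12)
  omega_i <- crossprod(fit$x, fit$x * (fit$weights * a)) / fit$phi
  if (rcond(omega_i) < 1e-14 && fit$ridge == 0) {
    abort("independence information is singular; prune the design")
  }
  tr <- sum(omega_i * fit$vcov_robust)
  structure(-2 * fit$quasi_lik + 2 * tr,
            quasi_lik = fit$quasi_lik, trace_term = tr)
}

#' @export
print.gee_fit <- function(x, ...) {
  cat("<gee_fit> ", length(x$coefficients), " coefficient(s), working=",
      x$working, ", ", length(x$clusters), " cluster(s)",
      if (x$ridge_used) ", ridge-stabilised", "\n", sep = "")
  cat("  quasi-likelihood ", format(x$quasi_lik), ", ",
      x$n_iter, " iteration(s)", if (!x$converged) " (NOT converged)",
      "\n", sep = "")
  invisible(x)
}

#' Tidy a GEE fit
#'
#' @param x A `gee_fit`.
#' @param ... Unused.
#' @return Tibble `term, estimate, std.error, robust.se`.
#' @export
tidy.gee_fit <- function(x, ...) {
  se_m <- se_r <- setNames(rep(NA_real_, length(x$coefficients)),
                           names(x$coefficients))
  se_m[x$kept] <- sqrt(pmax(diag(x$vcov_model), 0))
  se_r[x$kept] <- sqrt(pmax(diag(x$vcov_robust), 0))
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(se_m), robust.se = unname(se_r))
}

#' One-line summary of a GEE fit
#'
#' @param x A `gee_fit`.
#' @param ... Unused.
#' @return Tibble with quasi-likelihood, QIC, dispersion, iteration count
#'   and flags.
#' @export
glance.gee_fit <- function(x, ...) {
  tibble::tibble(quasi_lik = x$quasi_lik, qic = as.numeric(qic(x)),
                 phi = x$phi, n_obs = length(x$y),
                 n_clusters = length(x$clusters), n_iter = x$n_iter,
                 converged = x$converged, ridge_used = x$ridge_used)
}
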