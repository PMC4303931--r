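#' Design matrix for the meta-regression
#'
#' Builds the N x k design matrix X: an intercept column followed by the
#' requested covariates. With a `subgroup` factor, each level gets its own
#' intercept and its own slope for every covariate (cell-means
#' parameterization), so a single model yields per-level estimates.
#'
#' @inheritParams validate_records
#' @param covariates Character vector of numeric covariate columns in
#'   `records` (typically `"phylo_distance"`); may be empty for an
#'   intercept-only model.
#' @param subgroup Optional name of a factor column; per-level intercepts and
#'   slopes are produced.
#' @return A numeric matrix with informative column names.
#' @export
build_design_matrix <- function(records, covariates = "phylo_distance",
                                subgroup = NULL) {
  records <- tibble::as_tibble(records)
  for (cv in covariates) {
    if (!cv %in% names(records)) {
      stop("covariate column not found: ", cv, call. = FALSE)
    }
    if (!is.numeric(records[[cv]]) || anyNA(records[[cv]]) ||
        any(!is.finite(records[[cv]]))) {
      stop("covariate ", cv, " must be finite numeric", call. = FALSE)
    }
  }
  n <- nrow(records)
  base <- cbind(intercept = rep(1, n))
  for (cv in covariates) base <- cbind(base, records[[cv]])
  colnames(base) <- c("intercept", covariates)
  if (is.null(subgroup)) {
    X <- base
  } else {
    f <- records[[subgroup]]
    f <- if (is.factor(f)) f else factor(f)   # keep declared (even empty) levels
    if (anyNA(f)) stop("missing values in subgroup factor ", subgroup,
                       call. = FALSE)
    levs <- levels(f)
    X <- matrix(0, n, length(levs) * ncol(base))
    labs <- character(0)
    for (l in seq_along(levs)) {
      sel <- f == levs[l]
      cols <- (l - 1) * ncol(base) + seq_len(ncol(base))
      X[sel, cols] <- base[sel, , drop = FALSE]
      labs <- c(labs, paste(colnames(base), levs[l], sep = ":"))
    }
    colnames(X) <- labs
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  X
}

#' Hierarchical block covariance matrix Delta
#'
#' The hierarchical deviations delta have variance tau2 for every effect and
#' covariance zeta = rho * tau2 between effects in the same hierarchical block
#' (typically the same study). Delta is block diagonal, positive semidefinite
#' for rho in [0, 1).
#'
#' @param tau2 Hierarchical variance (>= 0).
#' @param rho Hierarchical correlation in [0, 1); `zeta = rho * tau2`.
#' @param blocks Vector of block identifiers, one per effect.
#' @return An N x N numeric matrix.
#' @export
build_delta <- function(tau2, rho, blocks) {
  stopifnot(tau2 >= 0, rho >= 0, rho < 1)
  blocks <- as.character(blocks)
  n <- length(blocks)
  same <- outer(blocks, blocks, "==")
  D <- matrix(0, n, n)
  D[same] <- rho * tau2
  diag(D) <- tau2
  D
}

#' Assemble a meta-analysis dataset
#'
#' Bundles the effect-size vector d, design matrix X, sampling covariance V
#' and the hierarchical block structure into the object the model fitters
#' consume.
#'
#' @inheritParams build_design_matrix
#' @inheritParams build_sampling_covariance
#' @return An object of class `"psf_meta_dataset"`: a list with `d`, `X`,
#'   `V`, `blocks`, `effects`, `records`.
#' @export
meta_dataset <- function(records, covariates = "phylo_distance",
                         subgroup = NULL,
                         method = c("gleser-olkin", "simple")) {
  sc <- build_sampling_covariance(records, method = method)
  records <- validate_records(records)
  X <- build_design_matrix(records, covariates = covariates,
                           subgroup = subgroup)
  structure(list(
    d = sc$effects$d,
    X = X,
    V = unname(sc$V),
    blocks = as.character(records$hier_group_id),
    effects = sc$effects,
    records = records
  ), class = "psf_meta_dataset")
}

#' @export
print.psf_meta_dataset <- function(x, ...) {
  cat("<psf_meta_dataset> N =", length(x$d), "effect sizes,",
      ncol(x$X), "model terms,",
      length(unique(x$blocks)), "hierarchical blocks\n")
  invisible(x)
}

#' Prior on the hierarchical scale tau
#'
#' The hierarchical Bayes fit places a flat prior on the coefficients and a
#' uniform prior on tau = sqrt(tau2) over `[0, tau_max]`, integrated by
#' trapezoid quadrature on a regular grid. `rho` fixes the within-block
#' correlation, `zeta = rho * tau2`.
#'
#' @param tau_max Upper bound for tau. `NULL` defaults to `5 * SD(d)` at fit
#'   time, wide enough that the posterior mass is interior for any dataset
#'   whose heterogeneity is of the order of the effect spread.
#' @param grid_size Number of quadrature nodes (>= 50 for production fits;
#'   smaller grids are permitted for diagnostics).
#' @param rho Hierarchical correlation in [0, 1); 0 removes block covariance.
#' @return An object of class `"psf_variance_prior"`.
#' @export
variance_prior <- function(tau_max = NULL, grid_size = 200, rho = 0.5) {
  stopifnot(is.null(tau_max) || tau_max > 0, grid_size >= 1,
            rho >= 0, rho < 1)
  structure(list(tau_max = tau_max, grid_size = as.integer(grid_size),
                 rho = rho),
            class = "psf_variance_prior")
}

# Cholesky of Sigma with a one-shot jitter fallback
chol_sigma <- function(Sigma, context = "Sigma") {
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) {
    jit <- 1e-10 * sum(diag(Sigma)) / nrow(Sigma)
    warning("adding jitter ", format(jit), " to ", context,
            " after Cholesky failure", call. = FALSE)
    R <- tryCatch(chol(Sigma + diag(jit, nrow(Sigma))),
                  error = function(e) {
                    stop(context, " is not positive definite", call. = FALSE)
                  })
  }
  R
}

# GLS given the Cholesky factor of Sigma: returns beta-hat, its covariance,
# log|Sigma|, log|X' Sigma^-1 X| and the residual quadratic form
gls_components <- function(d, X, R) {
  Z <- backsolve(R, X, transpose = TRUE)      # R' Z = X
  zd <- backsolve(R, d, transpose = TRUE)     # R' zd = d
  XtSiX <- crossprod(Z)
  XtSid <- drop(crossprod(Z, zd))
  Rx <- chol_sigma(XtSiX, context = "X' Sigma^-1 X")
  beta <- backsolve(Rx, backsolve(Rx, XtSid, transpose = TRUE))
  cov_beta <- chol2inv(Rx)
  quad <- sum(zd^2) - sum(XtSid * beta)
  list(beta = drop(beta), cov = cov_beta,
       logdet_sigma = 2 * sum(log(diag(R))),
       logdet_xsx = 2 * sum(log(diag(Rx))),
       quad = max(quad, 0))
}

#' Marginal log posterior of tau
#'
#' With a flat prior on the coefficients they integrate out analytically,
#' leaving for each tau (Sigma = V + Delta(tau^2)):
#' `log p(tau | d) = log prior(tau) - 1/2 log|Sigma| - 1/2 log|X' Sigma^-1 X|
#'  - 1/2 r' Sigma^-1 r`, with `r = d - X beta_hat(tau^2)` the GLS residual.
#' This is the integrand the quadrature in [fit_hblm()] weighs.
#'
#' @param tau Hierarchical SD (scalar or vector).
#' @param dataset A [meta_dataset()].
#' @param prior A [variance_prior()].
#' @return Log posterior value(s), unnormalized.
#' @export
marginal_log_posterior_tau <- function(tau, dataset, prior = variance_prior()) {
  stopifnot(inherits(dataset, "psf_meta_dataset"))
  tau_max <- prior$tau_max %||% (5 * stats::sd(dataset$d))
  vapply(tau, function(t1) {
    if (t1 < 0 || t1 > tau_max) return(-Inf)
    Sigma <- dataset$V + build_delta(t1^2, prior$rho, dataset$blocks)
    R <- chol_sigma(Sigma, context = paste0("Sigma at tau=", format(t1)))
    g <- gls_components(dataset$d, dataset$X, R)
    -log(tau_max) - 0.5 * (g$logdet_sigma + g$logdet_xsx + g$quad)
  }, numeric(1))
}

hblm_result <- function(beta, cov_beta, level, N, k, model_tag,
                        terms, tau2 = 0, tau_grid = NULL, tau_weights = NULL) {
  se <- sqrt(pmax(diag(cov_beta), 0))
  tq <- stats::qt((1 + level) / 2, df = N - k)
  structure(list(
    beta = tibble::tibble(
      term = terms, estimate = unname(beta), se = se,
      ci_lower = unname(beta) - tq * se, ci_upper = unname(beta) + tq * se),
    cov_beta = cov_beta,
    tau2_posterior_mean = tau2,
    N = N, k = k, df = N - k, level = level, model_tag = model_tag,
    tau_grid = tau_grid, tau_weights = tau_weights
  ), class = "psf_hblm")
}

#' Fit the hierarchical Bayes linear meta-regression
#'
#' Fits `d = X beta + delta + epsilon` where `epsilon ~ N(0, V)` carries the
#' known sampling variances and shared-control covariances and
#' `delta ~ N(0, Delta(tau^2))` carries the hierarchical (within-study)
#' dependence. The coefficients get a flat prior; tau gets the uniform prior
#' of [variance_prior()]. Conditional on tau the posterior of beta is the GLS
#' solution with `Sigma = V + Delta`; the marginal posterior mean and
#' covariance of beta are obtained by trapezoid quadrature over the tau grid
#' (law of total variance), and credible intervals multiply the posterior SE
#' by the appropriate quantile of a t distribution with N - k degrees of
#' freedom.
#'
#' @param dataset A [meta_dataset()].
#' @param prior A [variance_prior()].
#' @param level Credible level (default 0.95).
#' @param tau_grid Optional explicit vector of tau nodes overriding the
#'   prior's regular grid (used mainly for quadrature diagnostics).
#' @return An object of class `"psf_hblm"`; see [tidy.psf_hblm()].
#' @examples
#' rec <- simulate_dataset(sim_config(n_studies = 10, seed = 1))
#' ds <- meta_dataset(annotate_distances(rec$records, rec$tree))
#' fit_hblm(ds)
#' @export
fit_hblm <- function(dataset, prior = variance_prior(), level = 0.95,
                     tau_grid = NULL) {
  stopifnot(inherits(dataset, "psf_meta_dataset"), level > 0, level < 1)
  N <- length(dataset$d); k <- ncol(dataset$X)
  if (N <= k) {
    stop("need N > k for the t-based intervals (N = ", N, ", k = ", k, ")",
         call. = FALSE)
  }
  tau_max <- prior$tau_max %||% (5 * stats::sd(dataset$d))
  if (!is.finite(tau_max) || tau_max <= 0) tau_max <- 1
  grid <- tau_grid %||% seq(0, tau_max, length.out = prior$grid_size)
  G <- length(grid)

  lp <- numeric(G)
  fits <- vector("list", G)
  for (g in seq_len(G)) {
    Sigma <- dataset$V + build_delta(grid[g]^2, prior$rho, dataset$blocks)
    R <- chol_sigma(Sigma, context = paste0("Sigma at tau=", format(grid[g])))
    fits[[g]] <- gls_components(dataset$d, dataset$X, R)
    lp[g] <- -0.5 * (fits[[g]]$logdet_sigma + fits[[g]]$logdet_xsx +
                       fits[[g]]$quad)
  }
  # trapezoid quadrature weights times normalized posterior mass
  tw <- if (G == 1) 1 else {
    h <- diff(grid)
    c(h[1] / 2, (h[-1] + h[-length(h)]) / 2, h[length(h)] / 2)
  }
  w <- tw * exp(lp - max(lp))
  w <- w / sum(w)

  B <- vapply(fits, `[[`, numeric(k), "beta")
  B <- matrix(B, nrow = k)
  beta_mean <- drop(B %*% w)
  cov_cond <- Reduce(`+`, Map(function(f, wt) wt * f$cov, fits, w))
  dev <- B - beta_mean
  cov_mean <- dev %*% (w * t(dev))
  cov_beta <- cov_cond + cov_mean
  tau2_mean <- sum(w * grid^2)

  hblm_result(beta_mean, cov_beta, level, N, k, "hierarchical",
              colnames(dataset$X), tau2 = tau2_mean,
              tau_grid = grid, tau_weights = w)
}

#' Fixed-effects GLS fit (no hierarchical dependence)
#'
#' The model with Delta = 0: `beta_hat = (X' V^-1 X)^-1 X' V^-1 d` with
#' coefficient covariance `(X' V^-1 X)^-1`. Intervals use the same t rule as
#' [fit_hblm()]. This is the model plotted in funnel-style regression figures
#' and used by the resampling diagnostics.
#'
#' @inheritParams fit_hblm
#' @return An object of class `"psf_hblm"` with `model_tag = "fixed"`.
#' @export
fit_fixed <- function(dataset, level = 0.95) {
  stopifnot(inherits(dataset, "psf_meta_dataset"), level > 0, level < 1)
  N <- length(dataset$d); k <- ncol(dataset$X)
  if (N <= k) {
    stop("need N > k for the t-based intervals (N = ", N, ", k = ", k, ")",
         call. = FALSE)
  }
  R <- chol_sigma(dataset$V, context = "V")
  g <- gls_components(dataset$d, dataset$X, R)
  hblm_result(g$beta, g$cov, level, N, k, "fixed", colnames(dataset$X))
}

#' Per-subgroup meta-regression fits
#'
#' Refits the phylogenetic-distance meta-regression within each level of a
#' grouping factor (life form, life cycle or provenance), yielding one
#' intercept and one slope per level. By default each level is fitted as a
#' separate model on its subset; `method = "interaction"` instead fits one
#' joint model with per-level intercepts and slopes (see
#' [build_design_matrix()]). Levels with fewer than 3 effect sizes are
#' flagged and their estimates suppressed.
#'
#' @inheritParams validate_records
#' @param factor Name of the grouping column (`"life_form"`, `"life_cycle"`
#'   or `"provenance"`).
#' @param covariate Numeric covariate column, default `"phylo_distance"`.
#' @inheritParams fit_hblm
#' @param method `"separate"` (default) or `"interaction"`.
#' @param model `"hierarchical"` (default) or `"fixed"`.
#' @return A tibble with one row per level: `level`, `n`, intercept and slope
#'   estimates with SEs and credible bounds, and a `flagged` column.
#' @export
fit_subgroups <- function(records, factor, covariate = "phylo_distance",
                          prior = variance_prior(), level = 0.95,
                          method = c("separate", "interaction"),
                          model = c("hierarchical", "fixed")) {
  method <- match.arg(method)
  model <- match.arg(model)
  records <- validate_records(records)
  if (!factor %in% names(records)) {
    stop("grouping column not found: ", factor, call. = FALSE)
  }
  f <- factor(records[[factor]])
  if (anyNA(f)) stop("missing values in ", factor, call. = FALSE)
  levs <- levels(f)

  empty_row <- function(lev, n) tibble::tibble(
    level = lev, n = n,
    intercept = NA_real_, intercept_se = NA_real_,
    intercept_lower = NA_real_, intercept_upper = NA_real_,
    slope = NA_real_, slope_se = NA_real_,
    slope_lower = NA_real_, slope_upper = NA_real_,
    flagged = TRUE)

  row_from <- function(lev, n, est) tibble::tibble(
    level = lev, n = n,
    intercept = est$estimate[1], intercept_se = est$se[1],
    intercept_lower = est$ci_lower[1], intercept_upper = est$ci_upper[1],
    slope = est$estimate[2], slope_se = est$se[2],
    slope_lower = est$ci_lower[2], slope_upper = est$ci_upper[2],
    flagged = FALSE)

  if (method == "interaction") {
    ok <- table(f)
    if (any(ok < 3)) {
      out <- purrr::map(levs[ok[levs] < 3], function(l)
        empty_row(l, sum(f == l)))
      keep <- levs[ok[levs] >= 3]
      records <- records[f %in% keep, , drop = FALSE]
      f <- droplevels(f[f %in% keep])
    } else {
      out <- list(); keep <- levs
    }
    ds <- meta_dataset(records, covariates = covariate, subgroup = factor)
    fit <- if (model == "fixed") fit_fixed(ds, level = level) else
      fit_hblm(ds, prior = prior, level = level)
    for (l in levels(f)) {
      sel <- fit$beta$term %in% paste(c("intercept", covariate), l, sep = ":")
      out <- c(out, list(row_from(l, sum(f == l), fit$beta[sel, ])))
    }
    res <- dplyr::bind_rows(out)
    return(dplyr::arrange(res, match(level, levs)))
  }

  purrr::map_dfr(levs, function(l) {
    sub <- records[f == l, , drop = FALSE]
    if (nrow(sub) < 3) return(empty_row(l, nrow(sub)))
    ds <- meta_dataset(sub, covariates = covariate)
    fit <- if (model == "fixed") fit_fixed(ds, level = level) else
      fit_hblm(ds, prior = prior, level = level)
    row_from(l, nrow(sub), fit$beta)
  })
}

#' @export
print.psf_hblm <- function(x, digits = 4, ...) {
  cat("<psf_hblm> ", x$model_tag, " model: N = ", x$N, ", k = ", x$k,
      ", ", format(100 * x$level), "% credible intervals (t, df = ", x$df,
      ")\n", sep = "")
  print(as.data.frame(x$beta), digits = digits, row.names = FALSE)
  if (x$model_tag == "hierarchical") {
    cat("posterior mean tau^2:", format(x$tau2_posterior_mean,
                                        digits = digits), "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
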