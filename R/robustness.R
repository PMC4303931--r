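#' Trim the dataset so no species is replicated across studies
#'
#' Multiple studies often test the same species, so effect sizes for one
#' species can appear in several hierarchical groups. This subset analysis
#' selects a set of studies such that no species occurs in more than one
#' selected study, maximizing the total number of retained effect sizes --
#' a weighted set-packing problem. Up to `exact_limit` studies it is solved
#' exactly by branch and bound (verified against exhaustive search in the
#' test suite); above that a greedy largest-study-first heuristic with
#' conflict removal is used, and the `method` element reports which ran.
#' Ties on retained effects are broken toward the lexicographically smaller
#' set of study identifiers.
#'
#' @inheritParams validate_records
#' @param group Column defining the non-independence group, default
#'   `"study_id"`.
#' @param species_cols Columns whose values constitute "the species of a
#'   study"; default both the focal and the soil-culturing species.
#' @param refit If `TRUE` (default) and the records carry `phylo_distance`,
#'   refit the hierarchical model on the kept subset.
#' @param exact_limit Largest number of studies for the exact search.
#' @inheritParams fit_hblm
#' @return A list of class `"psf_subset"`: `kept_studies`,
#'   `kept_record_ids`, `n_kept`, `method`, and `fit` (a `"psf_hblm"` or
#'   `NULL`).
#' @export
trim_unique_species <- function(records, group = "study_id",
                                species_cols = c("focal_species",
                                                 "soil_species"),
                                refit = TRUE, prior = variance_prior(),
                                level = 0.95, exact_limit = 25) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L) {
    return(structure(list(kept_studies = character(),
                          kept_record_ids = character(), n_kept = 0L,
                          method = "exact", fit = NULL),
                     class = "psf_subset"))
  }
  g <- as.character(records[[group]])
  sets <- lapply(split(records[species_cols], g), function(s)
    unique(normalize_species(unlist(s, use.names = FALSE))))
  ids <- names(sets)
  wts <- as.integer(table(g)[ids])
  sel <- if (length(ids) <= exact_limit) {
    pack_exact(sets, wts, ids)
  } else {
    pack_greedy(sets, wts, ids)
  }
  kept <- sort(ids[sel])
  keep_rows <- g %in% kept
  fit <- NULL
  if (refit && any(keep_rows) && "phylo_distance" %in% names(records) &&
      sum(keep_rows) > 3) {
    fit <- fit_hblm(meta_dataset(records[keep_rows, , drop = FALSE]),
                    prior = prior, level = level)
  }
  structure(list(
    kept_studies = kept,
    kept_record_ids = as.character(records$experiment_id[keep_rows]),
    n_kept = sum(keep_rows),
    method = if (length(ids) <= exact_limit) "exact" else "greedy",
    fit = fit
  ), class = "psf_subset")
}

# prefer higher weight; on ties, lexicographically smaller sorted id set
better_selection <- function(w_new, ids_new, w_old, ids_old) {
  if (w_new != w_old) return(w_new > w_old)
  a <- paste(sort(ids_new), collapse = "\r")
  b <- paste(sort(ids_old), collapse = "\r")
  a < b
}

# exact weighted set packing by depth-first branch and bound
pack_exact <- function(sets, wts, ids) {
  ord <- order(-wts, ids)
  sets_o <- sets[ord]; wts_o <- wts[ord]; ids_o <- ids[ord]
  n <- length(sets_o)
  best_w <- -1L; best_ids <- character(0)
  suffix <- rev(cumsum(rev(wts_o)))
  sel <- logical(n)
  recurse <- function(i, w, used) {
    if (i > n) {
      if (better_selection(w, ids_o[sel], best_w, best_ids)) {
        best_w <<- w; best_ids <<- ids_o[sel]
      }
      return(invisible())
    }
    # strict inequality so equal-weight branches survive for the tie rule
    if (w + suffix[i] < best_w) return(invisible())
    if (!any(sets_o[[i]] %in% used)) {
      sel[i] <<- TRUE
      recurse(i + 1L, w + wts_o[i], c(used, sets_o[[i]]))
      sel[i] <<- FALSE
    }
    recurse(i + 1L, w, used)
  }
  recurse(1L, 0L, character(0))
  ids %in% best_ids
}

pack_greedy <- function(sets, wts, ids) {
  ord <- order(-wts, ids)
  used <- character(0)
  keep <- character(0)
  for (i in ord) {
    if (!any(sets[[i]] %in% used)) {
      keep <- c(keep, ids[i])
      used <- c(used, sets[[i]])
    }
  }
  ids %in% keep
}

#' @export
print.psf_subset <- function(x, ...) {
  cat("<psf_subset> kept", length(x$kept_studies), "studies /", x$n_kept,
      "effect sizes (", x$method, "search )\n")
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}

#' Distance-balanced slope resampling
#'
#' Corrects for unbalanced representation along the phylogenetic-distance
#' gradient: in each replicate, exactly one effect size is drawn uniformly
#' for every unique distance value (distances compared after rounding to
#' `digits` decimal My), the meta-regression is refitted on the balanced
#' subset, and the slope recorded. Reported are the mean slope and its
#' standard error `SD(slopes)/sqrt(reps)` across replicates.
#'
#' @inheritParams validate_records
#' @param reps Number of resampling replicates (>= 1), default 100.
#' @param seed Integer seed; the report is bit-identical under the same seed.
#' @param model `"fixed"` (default, matching the plotted regression) or
#'   `"hierarchical"`.
#' @param digits Decimals used when grouping distances for uniqueness.
#' @inheritParams fit_hblm
#' @return A list of class `"psf_resample"`: `reps`, `slopes`, `mean_slope`,
#'   `se_slope`, `seed`.
#' @export
distance_balanced_slopes <- function(records, reps = 100, seed = 1,
                                     model = c("fixed", "hierarchical"),
                                     prior = variance_prior(), digits = 6) {
  model <- match.arg(model)
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  records <- validate_records(records)
  if (!"phylo_distance" %in% names(records)) {
    stop("records need a phylo_distance column; run annotate_distances()",
         call. = FALSE)
  }
  key <- round(records$phylo_distance, digits)
  groups <- split(seq_len(nrow(records)), key)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  slopes <- vapply(seq_len(reps), function(r) {
    pick <- vapply(groups, function(idx)
      if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)],
      integer(1))
    ds <- meta_dataset(records[sort(pick), , drop = FALSE])
    fit <- if (model == "fixed") fit_fixed(ds) else fit_hblm(ds, prior)
    fit$beta$estimate[fit$beta$term == "phylo_distance"]
  }, numeric(1))
  structure(list(reps = as.integer(reps), slopes = slopes,
                 mean_slope = mean(slopes),
                 se_slope = stats::sd(slopes) / sqrt(reps),
                 seed = as.integer(seed)),
            class = "psf_resample")
}

#' @export
print.psf_resample <- function(x, ...) {
  cat("<psf_resample>", x$reps, "replicates: mean slope",
      format(x$mean_slope, digits = 4), "+/-",
      format(x$se_slope, digits = 4), "SE (seed", paste0(x$seed, ")\n"))
  invisible(x)
}

#' Funnel-plot data
#'
#' @param effects A data frame with columns `d` and `var` (e.g. the
#'   `effects` element of [build_sampling_covariance()] or a tidy fit input).
#' @return A tibble `(d, se)` in input order, `se = sqrt(var)`.
#' @export
funnel_data <- function(effects) {
  effects <- tibble::as_tibble(effects)
  tibble::tibble(d = effects$d, se = sqrt(effects$var))
}

# DerSimonian-Laird random-effects pooled mean
dl_pool <- function(d, v) {
  w <- 1 / v
  mu_fe <- sum(w * d) / sum(w)
  Q <- sum(w * (d - mu_fe)^2)
  tau2 <- max(0, (Q - (length(d) - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (v + tau2)
  mu <- sum(wr * d) / sum(wr)
  list(mu = mu, se = sqrt(1 / sum(wr)), tau2 = tau2)
}

# one full L0 (or R0) run with studies imputed on `side`
trim_fill_side <- function(d, v, side, estimator, maxiter = 50) {
  # work on the flipped scale so "imputing on the left" always means the
  # extreme *positive* observed values are the unmatched ones
  s <- if (side == "left") 1 else -1
  y <- s * d
  n <- length(y)
  k0 <- 0L
  for (it in seq_len(maxiter)) {
    keep <- if (k0 > 0) order(y)[seq_len(n - k0)] else seq_len(n)
    mu <- dl_pool(y[keep], v[keep])$mu
    # round before ranking so exact mirror pairs tie instead of being
    # ordered by floating-point noise
    cent <- round(y - mu, 10)
    r <- rank(abs(cent), ties.method = "average")
    Tn <- sum(r[cent > 0])
    k0_new <- if (estimator == "R0") {
      # rightmost run of positive signed ranks
      srt <- order(r, decreasing = TRUE)
      run <- 0L
      for (i in srt) {
        if (cent[i] > 0) run <- run + 1L else break
      }
      max(run - 1L, 0L)
    } else {
      as.integer(max(0, round((4 * Tn - n * (n + 1)) / (2 * n - 1))))
    }
    k0_new <- min(k0_new, n - 2L)
    if (k0_new == k0) break
    k0 <- k0_new
  }
  keep <- if (k0 > 0) order(y)[seq_len(n - k0)] else seq_len(n)
  mu_trim <- dl_pool(y[keep], v[keep])$mu
  filled <- if (k0 > 0) {
    top <- order(y, decreasing = TRUE)[seq_len(k0)]
    tibble::tibble(d = s * (2 * mu_trim - y[top]), var = v[top],
                   filled = TRUE)
  } else {
    tibble::tibble(d = double(), var = double(), filled = logical())
  }
  list(k0 = k0, filled = filled)
}

#' Duval-Tweedie trim-and-fill publication-bias assessment
#'
#' Estimates the number `k0` of funnel-plot-suppressed studies by the
#' iterative nonparametric trim-and-fill procedure (rank-based `L0`
#' estimator by default, `R0` optional), imputes their mirror images about
#' the trimmed pooled mean, and reports an adjusted pooled effect from a
#' DerSimonian-Laird random-effects fit on observed plus imputed values.
#' `side` is where the missing studies are imputed; `"auto"` runs both sides
#' and keeps the one with the larger `k0` (ties go to `"left"`, the side
#' where suppressed unfavourable results canonically sit).
#'
#' @inheritParams funnel_data
#' @param side `"left"`, `"right"` or `"auto"`.
#' @param estimator `"L0"` (default) or `"R0"`.
#' @param level Confidence level for the adjusted mean.
#' @return A list of class `"psf_trimfill"`: `k0`, `side`, `estimator`,
#'   `adjusted_mean`, `se`, `ci_lower`, `ci_upper`, `unadjusted_mean`, and
#'   `filled` (tibble of imputed values).
#' @export
trim_and_fill <- function(effects, side = c("auto", "left", "right"),
                          estimator = c("L0", "R0"), level = 0.95) {
  side <- match.arg(side)
  estimator <- match.arg(estimator)
  effects <- tibble::as_tibble(effects)
  d <- effects$d; v <- effects$var
  if (length(d) < 3) {
    stop("trim-and-fill needs at least 3 effect sizes", call. = FALSE)
  }
  if (side == "auto") {
    left <- trim_fill_side(d, v, "left", estimator)
    right <- trim_fill_side(d, v, "right", estimator)
    if (right$k0 > left$k0) {
      res <- right; side <- "right"
    } else {
      res <- left; side <- "left"
    }
  } else {
    res <- trim_fill_side(d, v, side, estimator)
  }
  d_all <- c(d, res$filled$d)
  v_all <- c(v, res$filled$var)
  pool <- dl_pool(d_all, v_all)
  un <- dl_pool(d, v)
  z <- stats::qnorm((1 + level) / 2)
  structure(list(
    k0 = res$k0, side = side, estimator = estimator,
    adjusted_mean = pool$mu, se = pool$se,
    ci_lower = pool$mu - z * pool$se, ci_upper = pool$mu + z * pool$se,
    unadjusted_mean = un$mu,
    filled = res$filled
  ), class = "psf_trimfill")
}

#' @export
print.psf_trimfill <- function(x, ...) {
  cat("<psf_trimfill>", x$estimator, "estimator, imputing on the", x$side,
      ": k0 =", x$k0, "\n  adjusted mean",
      format(x$adjusted_mean, digits = 4), "(",
      format(x$ci_lower, digits = 4), ",",
      format(x$ci_upper, digits = 4), "); unadjusted",
      format(x$unadjusted_mean, digits = 4), "\n")
  invisible(x)
}

#' Cumulative meta-analysis ordered by precision
#'
#' Sorts the effect sizes by increasing sampling variance and refits the
#' meta-regression on the first m = k + 2, ..., N of them. Drift of the
#' slope along the trajectory indicates that imprecise (high within-study
#' error) experiments pull the estimate -- a small-study / publication-bias
#' signal.
#'
#' @inheritParams fit_hblm
#' @param model `"fixed"` (default) or `"hierarchical"` refits.
#' @param term Coefficient tracked along the trajectory (default the
#'   phylogenetic-distance slope, falling back to the last term).
#' @return A tibble of class `"psf_cumulative"` with one row per step:
#'   `n_included`, `estimate`, `se`, `ci_lower`, `ci_upper`. The final row
#'   equals the full-dataset fit.
#' @export
cumulative_meta <- function(dataset, model = c("fixed", "hierarchical"),
                            prior = variance_prior(), level = 0.95,
                            term = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(dataset, "psf_meta_dataset"))
  N <- length(dataset$d); k <- ncol(dataset$X)
  if (N < k + 2) stop("need N >= k + 2 for a trajectory", call. = FALSE)
  term <- term %||% utils::tail(colnames(dataset$X), 1)
  ord <- order(diag(dataset$V))
  steps <- seq(k + 2, N)
  rows <- purrr::map(steps, function(m) {
    idx <- ord[seq_len(m)]
    sub <- subset_dataset(dataset, idx)
    fit <- tryCatch(
      if (model == "fixed") fit_fixed(sub, level = level) else
        fit_hblm(sub, prior = prior, level = level),
      error = function(e) stop("cumulative refit failed at m = ", m, ": ",
                               conditionMessage(e), call. = FALSE))
    b <- fit$beta[fit$beta$term == term, ]
    tibble::tibble(n_included = m, estimate = b$estimate, se = b$se,
                   ci_lower = b$ci_lower, ci_upper = b$ci_upper)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("psf_cumulative", class(out))
  attr(out, "term") <- term
  out
}

# row subset of a meta dataset, preserving V's block structure
subset_dataset <- function(dataset, idx) {
  structure(list(
    d = dataset$d[idx],
    X = dataset$X[idx, , drop = FALSE],
    V = dataset$V[idx, idx, drop = FALSE],
    blocks = dataset$blocks[idx],
    effects = dataset$effects[idx, , drop = FALSE],
    records = dataset$records[idx, , drop = FALSE]
  ), class = "psf_meta_dataset")
}
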