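#' Hedges' d standardized mean difference for a plant-soil feedback experiment
#'
#' Computes the bias-corrected standardized mean difference between plant
#' performance on conspecific-cultured soil (the control) and on
#' heterospecific-cultured soil (the treatment), together with its sampling
#' variance. The sign convention follows the plant-soil feedback literature:
#' `d = J(m) * (mean_con - mean_het) / s_pooled`, so a *negative* d means the
#' plant did better on heterospecific soil than on its own cultured soil --
#' the signal of a negative feedback.
#'
#' The pooled SD is `s_pooled = sqrt(((n_con-1) sd_con^2 + (n_het-1) sd_het^2) / m)`
#' with `m = n_con + n_het - 2`, and `J(m) = 1 - 3/(4m - 1)` is the small-sample
#' bias correction. The sampling variance is
#' `var = 1/n_con + 1/n_het + d^2 / (2 (n_con + n_het))`, using the corrected d.
#'
#' @param mean_con,sd_con,n_con Mean, SD and replicate count of the biomass
#'   response on conspecific-cultured soil. Units of mean/SD are arbitrary but
#'   must match the heterospecific group.
#' @param mean_het,sd_het,n_het Same summary statistics on
#'   heterospecific-cultured soil.
#'
#' @return A tibble with columns `d` (unitless effect size) and `var`
#'   (its sampling variance), one row per input experiment. Vectorized over
#'   all six arguments.
#' @examples
#' hedges_d(8, 2, 5, 10, 2, 5)   # heterospecific advantage: d < 0
#' @export
hedges_d <- function(mean_con, sd_con, n_con, mean_het, sd_het, n_het) {
  args <- vctrs_recycle(mean_con = mean_con, sd_con = sd_con, n_con = n_con,
                        mean_het = mean_het, sd_het = sd_het, n_het = n_het)
  with(args, {
    if (length(n_con) && any(n_con < 2 | n_het < 2)) {
      stop("insufficient replication: every group needs n >= 2", call. = FALSE)
    }
    if (length(sd_con) && any(sd_con < 0 | sd_het < 0)) {
      stop("negative SD supplied", call. = FALSE)
    }
    m <- n_con + n_het - 2
    s_pooled <- sqrt(((n_con - 1) * sd_con^2 + (n_het - 1) * sd_het^2) / m)
    if (length(s_pooled) && any(s_pooled == 0)) {
      stop("degenerate variance: pooled SD is zero (both group SDs zero)",
           call. = FALSE)
    }
    d <- hedges_j(m) * (mean_con - mean_het) / s_pooled
    v <- 1 / n_con + 1 / n_het + d^2 / (2 * (n_con + n_het))
    tibble::tibble(d = d, var = v)
  })
}

#' @rdname hedges_d
#' @param m Degrees of freedom `n_con + n_het - 2`.
#' @export
hedges_j <- function(m) 1 - 3 / (4 * m - 1)

# recycle scalar args against the common length, erroring on mismatch
vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args), 0L)
  bad <- !(lengths(args) %in% c(if (n > 0) 1L, n))
  if (any(bad)) {
    stop("arguments have incompatible lengths: ",
         paste(names(args)[bad], collapse = ", "), call. = FALSE)
  }
  lapply(args, rep_len, length.out = n)
}

#' Sampling covariance of two effect sizes sharing a conspecific control
#'
#' Two Hedges' d values computed against the *same* conspecific control group
#' are correlated: the control mean and SD enter both. The covariance used is
#' the standardized-mean-difference shared-control form
#' `cov = 1/n_con + d_i * d_j / (2 (n_con + n_i + n_j))`
#' (`method = "gleser-olkin"`), or simply `1/n_con` (`method = "simple"`).
#' Effect sizes with different `control_i` / `control_j` identifiers are
#' independent and get covariance 0.
#'
#' @param d_i,d_j The two effect sizes.
#' @param control_i,control_j Control-group identifiers; covariance is zero
#'   unless they are equal.
#' @param n_con Replicate count of the shared conspecific control group.
#' @param n_i,n_j Replicate counts of the two heterospecific treatment groups.
#' @param method Covariance formula, see Details.
#' @return Numeric covariance (vectorized).
#' @export
shared_control_covariance <- function(d_i, d_j, control_i, control_j,
                                      n_con, n_i, n_j,
                                      method = c("gleser-olkin", "simple")) {
  method <- match.arg(method)
  args <- vctrs_recycle(d_i = d_i, d_j = d_j, n_con = n_con, n_i = n_i,
                        n_j = n_j,
                        ci = as.character(control_i),
                        cj = as.character(control_j))
  with(args, {
    cv <- if (method == "simple") {
      1 / n_con
    } else {
      1 / n_con + d_i * d_j / (2 * (n_con + n_i + n_j))
    }
    ifelse(ci == cj, cv, 0)
  })
}

experiment_record_cols <- c(
  "study_id", "experiment_id", "focal_species", "soil_species",
  "control_group_id", "hier_group_id",
  "mean_con", "sd_con", "n_con", "mean_het", "sd_het", "n_het",
  "life_form", "life_cycle", "provenance"
)

#' Validate a table of pairwise feedback experiments
#'
#' Checks the per-row invariants every downstream step relies on: at least two
#' replicates per group, non-negative SDs with a positive pooled SD, focal and
#' soil species distinct, and identical control summary statistics within each
#' shared-control group.
#'
#' @param records A data frame with the experiment-record columns (see
#'   [read_records()] for the schema).
#' @param action `"error"` aborts on the first class of violation; `"filter"`
#'   drops offending rows and attaches the diagnostics as the `"rejected"`
#'   attribute (a tibble of row number + reason).
#' @return The validated (possibly filtered) records as a tibble, invisibly
#'   carrying rejection diagnostics.
#' @export
validate_records <- function(records, action = c("error", "filter")) {
  action <- match.arg(action)
  records <- tibble::as_tibble(records)
  missing_cols <- setdiff(experiment_record_cols, names(records))
  # moderators are optional for purely numerical work
  missing_req <- setdiff(missing_cols, c("life_form", "life_cycle", "provenance"))
  if (length(missing_req)) {
    stop("records are missing required columns: ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  }
  num_cols <- c("mean_con", "sd_con", "n_con", "mean_het", "sd_het", "n_het")
  for (cl in num_cols) {
    if (!is.numeric(records[[cl]])) {
      stop("column ", cl, " is not numeric", call. = FALSE)
    }
  }

  reason <- rep(NA_character_, nrow(records))
  flag <- function(bad, why) {
    reason[is.na(reason) & bad] <<- why
  }
  with(records, {
    flag(!stats::complete.cases(records[num_cols]), "missing summary statistic")
    flag(n_con < 2 | n_het < 2, "insufficient replication (n < 2)")
    flag(sd_con < 0 | sd_het < 0, "negative SD")
    flag(sd_con == 0 & sd_het == 0, "degenerate variance (both SDs zero)")
    flag(normalize_species(focal_species) == normalize_species(soil_species),
         "focal and soil species identical")
  })

  # shared-control consistency: all rows in a control group must carry the
  # same study and control statistics
  grp <- split(seq_len(nrow(records)), records$control_group_id)
  for (idx in grp) {
    sub <- records[idx, c("study_id", "focal_species",
                          "mean_con", "sd_con", "n_con")]
    if (nrow(unique(sub)) > 1L) {
      reason[idx][is.na(reason[idx])] <-
        "inconsistent control statistics within control_group_id"
    }
  }

  rejected <- tibble::tibble(row = which(!is.na(reason)),
                             reason = reason[!is.na(reason)])
  if (nrow(rejected) && action == "error") {
    stop("invalid records (rows ",
         paste(utils::head(rejected$row, 5), collapse = ", "),
         if (nrow(rejected) > 5) ", ..." else "", "): ",
         rejected$reason[1], call. = FALSE)
  }
  out <- records[is.na(reason), , drop = FALSE]
  attr(out, "rejected") <- rejected
  out
}

#' Effect sizes and the sampling variance-covariance matrix V
#'
#' Computes Hedges' d for every experiment and assembles the N x N sampling
#' covariance matrix V: variances on the diagonal, shared-control covariances
#' (see [shared_control_covariance()]) between experiments that used the same
#' conspecific control soil, zero elsewhere. V is block-diagonal under the
#' grouping by `control_group_id`, with row order matching record order.
#'
#' @inheritParams validate_records
#' @param method Passed to [shared_control_covariance()].
#' @return A list with `effects` (tibble: `experiment_id`, `d`, `var`,
#'   `control_group_id`, `hier_group_id`) and `V` (numeric matrix). Each
#'   control block of V is checked for positive definiteness; a failing block
#'   aborts naming the offending control group.
#' @export
build_sampling_covariance <- function(records,
                                      method = c("gleser-olkin", "simple")) {
  method <- match.arg(method)
  records <- validate_records(records)
  n <- nrow(records)
  if (n == 0L) {
    return(list(
      effects = tibble::tibble(experiment_id = character(), d = double(),
                               var = double(), control_group_id = character(),
                               hier_group_id = character()),
      V = matrix(0, 0, 0)
    ))
  }
  es <- hedges_d(records$mean_con, records$sd_con, records$n_con,
                 records$mean_het, records$sd_het, records$n_het)
  effects <- tibble::tibble(
    experiment_id = as.character(records$experiment_id),
    d = es$d, var = es$var,
    control_group_id = as.character(records$control_group_id),
    hier_group_id = as.character(records$hier_group_id)
  )
  V <- diag(es$var, n, n)
  blocks <- split(seq_len(n), effects$control_group_id)
  for (idx in blocks) {
    if (length(idx) < 2L) next
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in seq((a + 1), length(idx))) {
        i <- idx[a]; j <- idx[b]
        cv <- shared_control_covariance(
          es$d[i], es$d[j], 1, 1,
          n_con = records$n_con[i],
          n_i = records$n_het[i], n_j = records$n_het[j],
          method = method)
        V[i, j] <- V[j, i] <- cv
      }
    }
    ev <- eigen(V[idx, idx, drop = FALSE], symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) <= 0) {
      stop("sampling covariance block for control group '",
           effects$control_group_id[idx[1]],
           "' is not positive definite (min eigenvalue ",
           format(min(ev)), ")", call. = FALSE)
    }
  }
  dimnames(V) <- list(effects$experiment_id, effects$experiment_id)
  list(effects = effects, V = V)
}

#' @describeIn build_sampling_covariance Pipe-friendly helper: append `d` and
#'   `var` columns to the records table.
#' @export
add_effect_sizes <- function(records) {
  records <- validate_records(records)
  dplyr::bind_cols(records,
                   hedges_d(records$mean_con, records$sd_con, records$n_con,
                            records$mean_het, records$sd_het, records$n_het))
}
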