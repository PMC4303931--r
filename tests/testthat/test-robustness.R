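test_that("species trimming keeps everything when species are unique", {
  rec <- trim_fixture(list(list(id = "S1", species = c("A", "B"), n = 2),
                           list(id = "S2", species = c("C", "D"), n = 3)))
  out <- trim_unique_species(rec, refit = FALSE)
  expect_setequal(out$kept_studies, c("S1", "S2"))
  expect_equal(out$n_kept, nrow(rec))
  expect_equal(out$method, "exact")
})

test_that("species trimming solves the worked packing instance", {
  # S1 {A,B} x4, S2 {A,D} x2, S3 {D,E} x3: optimum keeps S1 + S3 = 7 effects
  set.seed(1)
  rec <- trim_fixture(list(list(id = "S1", species = c("A", "B"), n = 4),
                           list(id = "S2", species = c("A", "D"), n = 2),
                           list(id = "S3", species = c("D", "E"), n = 3)))
  out <- trim_unique_species(rec, refit = FALSE)
  expect_equal(out$kept_studies, c("S1", "S3"))
  expect_equal(out$n_kept, 7L)
})

test_that("ties between interchangeable studies go to the smaller id", {
  set.seed(2)
  rec <- trim_fixture(list(list(id = "S1", species = c("A", "B"), n = 3),
                           list(id = "S2", species = c("A", "B"), n = 3)))
  out <- trim_unique_species(rec, refit = FALSE)
  expect_equal(out$kept_studies, "S1")
  # more effects beat the smaller id
  rec2 <- trim_fixture(list(list(id = "S1", species = c("A", "B"), n = 3),
                            list(id = "S2", species = c("A", "B"), n = 5)))
  out2 <- trim_unique_species(rec2, refit = FALSE)
  expect_equal(out2$kept_studies, "S2")
})

test_that("branch-and-bound packing matches exhaustive search", {
  set.seed(3)
  pool <- sprintf("sp%02d", 1:10)
  for (i in 1:40) {
    n_studies <- sample(3:9, 1)
    spec <- lapply(seq_len(n_studies), function(s)
      list(id = sprintf("S%02d", s),
           species = sample(pool, sample(2:4, 1)),
           n = sample(1:5, 1)))
    rec <- trim_fixture(spec)
    out <- trim_unique_species(rec, refit = FALSE)
    sets <- lapply(spec, `[[`, "species")
    # the species set actually used per study (records may use a subset)
    g <- split(rec[c("focal_species", "soil_species")], rec$study_id)
    sets <- lapply(g, function(x) unique(unlist(x, use.names = FALSE)))
    wts <- as.integer(table(rec$study_id)[names(sets)])
    oracle <- oracle_pack(sets, wts, names(sets))
    expect_equal(sum(table(rec$study_id)[out$kept_studies]),
                 oracle$weight, ignore_attr = TRUE)
    expect_equal(out$kept_studies, oracle$ids)
  }
})

test_that("greedy packing produces a valid disjoint selection", {
  set.seed(4)
  spec <- lapply(1:12, function(s)
    list(id = sprintf("S%02d", s),
         species = sample(sprintf("sp%02d", 1:15), 3), n = sample(1:4, 1)))
  rec <- trim_fixture(spec)
  out <- trim_unique_species(rec, refit = FALSE, exact_limit = 5)
  expect_equal(out$method, "greedy")
  kept <- rec[rec$study_id %in% out$kept_studies, ]
  sp_by_study <- split(c(kept$focal_species, kept$soil_species),
                       rep(kept$study_id, 2))
  sp_by_study <- lapply(sp_by_study, unique)
  expect_false(anyDuplicated(unlist(sp_by_study)) > 0)
  # empty input allowed
  out0 <- trim_unique_species(rec[0, ], refit = FALSE)
  expect_equal(out0$n_kept, 0L)
})

test_that("distance-balanced resampling is degenerate when already balanced", {
  sim <- simulate_dataset(sim_config(n_studies = 8, seed = 5))
  rec <- annotate_distances(sim$records, sim$tree)
  # keep one effect per unique distance so every balanced draw is identical
  rec <- rec[!duplicated(round(rec$phylo_distance, 6)), ]
  rs <- distance_balanced_slopes(rec, reps = 20, seed = 99)
  expect_equal(rs$se_slope, 0)
  full <- fit_fixed(meta_dataset(rec))
  expect_equal(rs$mean_slope,
               full$beta$estimate[full$beta$term == "phylo_distance"])
})

test_that("resampling mean matches the exhaustive enumeration", {
  # two distance values; the second has two candidate effects, so exactly
  # two distinct balanced subsets exist
  rec <- dplyr::bind_rows(
    make_record(study_id = "S1", experiment_id = "e1",
                control_group_id = "c1", focal_species = "A",
                soil_species = "B", mean_het = 12),
    make_record(study_id = "S2", experiment_id = "e2",
                control_group_id = "c2", focal_species = "A",
                soil_species = "D", mean_het = 11),
    make_record(study_id = "S3", experiment_id = "e3",
                control_group_id = "c3", focal_species = "A",
                soil_species = "C", mean_het = 9),
    make_record(study_id = "S4", experiment_id = "e4",
                control_group_id = "c4", focal_species = "A",
                soil_species = "C", mean_het = 14))
  rec$phylo_distance <- c(100, 200, 300, 300)
  slope_of <- function(idx) {
    f <- fit_fixed(meta_dataset(rec[idx, ]))
    f$beta$estimate[f$beta$term == "phylo_distance"]
  }
  cases <- c(slope_of(1:3), slope_of(c(1, 2, 4)))
  enum_mean <- mean(cases)
  rs <- distance_balanced_slopes(rec, reps = 100, seed = 7)
  expect_true(all(rs$slopes %in% cases))
  mc_se <- sd(rs$slopes) / sqrt(rs$reps)
  expect_lt(abs(rs$mean_slope - enum_mean), 3 * mc_se)
  expect_equal(rs$se_slope, mc_se)
})

test_that("resampling is reproducible and validates reps", {
  sim <- simulate_dataset(sim_config(n_studies = 6, seed = 6))
  rec <- annotate_distances(sim$records, sim$tree)
  rec$phylo_distance <- round(rec$phylo_distance, -2)  # force duplicates
  a <- distance_balanced_slopes(rec, reps = 10, seed = 42)
  b <- distance_balanced_slopes(rec, reps = 10, seed = 42)
  expect_identical(a, b)
  expect_error(distance_balanced_slopes(rec, reps = 0), "reps")
})

test_that("funnel data carries sqrt(var) in input order", {
  eff <- tibble::tibble(d = c(0, -0.5), var = c(0.4, 0.25))
  fd <- funnel_data(eff)
  expect_equal(fd$d, eff$d)
  expect_equal(fd$se, c(sqrt(0.4), 0.5))
  expect_equal(nrow(funnel_data(eff[0, ])), 0L)
})

test_that("trim-and-fill finds nothing to impute in symmetric funnels", {
  d <- c(-4, -2, -1, 0, 1, 2, 4) * 0.25
  tf <- trim_and_fill(tibble::tibble(d = d, var = rep(0.2, 7)))
  expect_equal(tf$k0, 0L)
  expect_equal(tf$adjusted_mean, tf$unadjusted_mean)
  expect_equal(nrow(tf$filled), 0L)
  # property: random mirror-symmetric sets with equal variances
  set.seed(8)
  for (i in 1:25) {
    half <- runif(sample(3:8, 1), 0.1, 2)
    centre <- runif(1, -1, 1)
    dd <- centre + c(-half, half)
    tf <- trim_and_fill(tibble::tibble(d = dd,
                                       var = rep(runif(1, 0.05, 0.5),
                                                 length(dd))))
    expect_equal(tf$k0, 0L)
  }
})

test_that("trim-and-fill k0 matches the step-by-step L0 oracle", {
  # deterministic constructed asymmetric set
  d <- c(-0.3, 0, 0.3, 0.6, 0.9, 1.2)
  v <- rep(0.2, 6)
  tf <- trim_and_fill(tibble::tibble(d = d, var = v), side = "left")
  expect_equal(tf$k0, oracle_L0_left(d, v))
  # random right-skewed sets (suppression on the left)
  set.seed(10)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    dd <- rnorm(n, 0.2, 0.5) + rexp(n, 1.5) * rbinom(n, 1, 0.5)
    vv <- runif(n, 0.05, 0.4)
    tf <- trim_and_fill(tibble::tibble(d = dd, var = vv), side = "left")
    expect_equal(tf$k0, oracle_L0_left(dd, vv))
  }
})

test_that("trim-and-fill agrees with an established implementation", {
  skip_if_not_installed("metafor")
  set.seed(11)
  for (i in 1:10) {
    n <- sample(8:20, 1)
    dd <- rnorm(n, 0, 0.5) + rexp(n, 2) * rbinom(n, 1, 0.4)
    vv <- runif(n, 0.05, 0.4)
    for (sd_ in c("left", "right")) {
      ours <- trim_and_fill(tibble::tibble(d = dd, var = vv), side = sd_)
      mf <- metafor::trimfill(metafor::rma(yi = dd, vi = vv, method = "DL"),
                              estimator = "L0", side = sd_)
      expect_equal(ours$k0, as.integer(mf$k0))
      expect_equal(ours$adjusted_mean, as.numeric(mf$beta),
                   tolerance = 1e-8)
    }
  }
})

test_that("trim-and-fill input validation and mirroring", {
  expect_error(trim_and_fill(tibble::tibble(d = c(0, 1), var = c(1, 1))),
               "at least 3")
  # imputed values are mirror images with the donor variances
  d <- c(-0.3, 0, 0.3, 0.6, 0.9, 1.2)
  v <- c(0.2, 0.2, 0.2, 0.21, 0.22, 0.23)
  tf <- trim_and_fill(tibble::tibble(d = d, var = v), side = "left")
  if (tf$k0 > 0) {
    expect_equal(sort(tf$filled$var),
                 sort(v[order(d, decreasing = TRUE)[seq_len(tf$k0)]]))
  }
})

subset_psf <- function(ds, idx) psfmeta:::subset_dataset(ds, idx)

test_that("cumulative meta-analysis ends at the full-data fit", {
  sim <- simulate_dataset(sim_config(n_studies = 8, seed = 12))
  rec <- annotate_distances(sim$records, sim$tree)
  ds <- meta_dataset(rec)
  traj <- cumulative_meta(ds)
  k <- ncol(ds$X)
  N <- length(ds$d)
  expect_equal(nrow(traj), N - (k + 2) + 1)
  expect_equal(traj$n_included, seq(k + 2, N))
  full <- fit_fixed(ds)
  last <- traj[nrow(traj), ]
  expect_equal(last$estimate,
               full$beta$estimate[full$beta$term == "phylo_distance"])
  expect_equal(last$se, full$beta$se[full$beta$term == "phylo_distance"])
  expect_error(cumulative_meta(subset_psf(ds, 1:3)), "trajectory")
})

test_that("early cumulative steps use the most precise effects", {
  sim <- simulate_dataset(sim_config(n_studies = 8, seed = 13))
  rec <- annotate_distances(sim$records, sim$tree)
  ds <- meta_dataset(rec)
  traj <- cumulative_meta(ds)
  ord <- order(diag(ds$V))
  m0 <- ncol(ds$X) + 2
  first <- fit_fixed(subset_psf(ds, ord[seq_len(m0)]))
  expect_equal(traj$estimate[1],
               first$beta$estimate[first$beta$term == "phylo_distance"])
})

test_that("precision-ordered trajectories show no drift on unbiased data", {
  # first-vs-last slope difference within 3 combined SEs in >= 90/100 sims
  set.seed(14)
  ok <- 0
  for (i in 1:100) {
    sim <- simulate_dataset(sim_config(n_studies = 10,
                                       experiments_per_study = c(2, 6),
                                       seed = 1000 + i))
    rec <- annotate_distances(sim$records, sim$tree)
    ds <- meta_dataset(rec)
    ord <- order(diag(ds$V))
    m0 <- ncol(ds$X) + 2
    # tiny first subsets can need the jitter fallback; that is fine here
    first <- suppressWarnings(fit_fixed(subset_psf(ds, ord[seq_len(m0)])))
    last <- fit_fixed(ds)
    b1 <- first$beta[first$beta$term == "phylo_distance", ]
    b2 <- last$beta[last$beta$term == "phylo_distance", ]
    if (abs(b1$estimate - b2$estimate) <= 3 * sqrt(b1$se^2 + b2$se^2))
      ok <- ok + 1
  }
  expect_gte(ok, 90)
})
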