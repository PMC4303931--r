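#' Configuration for the synthetic plant-soil feedback generator
#'
#' Describes a simulated meta-analytic dataset with the same structure as a
#' compiled table of pairwise feedback experiments: studies containing
#' several experiments (hierarchical dependence), experiments within a study
#' that reuse the same conspecific control soil (sampling dependence), and
#' true standardized effects that are linear in phylogenetic distance with
#' block-structured hierarchical deviations,
#' `theta_i = beta0 + beta1 * PD_i + delta_i`,
#' `delta ~ N(0, tau2 [(1 - rho) I + rho J])` within each study.
#'
#' Defaults mirror the scale of the compiled literature this pipeline is
#' aimed at: about 130 species on an angiosperm-depth chronogram, around 55
#' studies of 2-10 experiments each (roughly 330 effect sizes), greenhouse
#' replication of 4-10 plants per soil group, an overall feedback of
#' `beta0 = -0.33`, a distance slope of `beta1 = -0.00035` per My of
#' patristic distance, hierarchical variance `tau2 = 0.2` and within-study
#' correlation `rho = 0.5`.
#'
#' @param n_species Number of tree tips.
#' @param tree_depth Root-to-tip depth of the simulated chronogram (My).
#' @param n_studies Number of studies.
#' @param experiments_per_study Integer range `c(lo, hi)` of experiments per
#'   study.
#' @param shared_control_prob Probability that an experiment reuses one of
#'   its study's existing conspecific controls rather than growing a new one.
#' @param beta0,beta1 True mean effect and slope per My.
#' @param tau2,rho Hierarchical variance and within-study correlation
#'   (`zeta = rho * tau2`).
#' @param sigma_within Within-group SD of raw biomass (arbitrary mass units).
#' @param mu_biomass Mean baseline biomass about which control-group means
#'   are drawn (SD 1 mass unit).
#' @param n_per_group Integer range `c(lo, hi)` of replicates per soil group.
#' @param seed Master seed; stage seeds for the tree and the dataset are
#'   derived from it (see [stage_seed()]).
#' @return A list of class `"psf_sim_config"`.
#' @export
sim_config <- function(n_species = 130, tree_depth = 250, n_studies = 55,
                       experiments_per_study = c(2, 10),
                       shared_control_prob = 0.5,
                       beta0 = -0.33, beta1 = -0.00035,
                       tau2 = 0.2, rho = 0.5,
                       sigma_within = 1, mu_biomass = 10,
                       n_per_group = c(4, 10), seed = 1) {
  cfg <- list(n_species = n_species, tree_depth = tree_depth,
              n_studies = n_studies,
              experiments_per_study = as.integer(experiments_per_study),
              shared_control_prob = shared_control_prob,
              beta0 = beta0, beta1 = beta1, tau2 = tau2, rho = rho,
              sigma_within = sigma_within, mu_biomass = mu_biomass,
              n_per_group = as.integer(n_per_group), seed = as.integer(seed))
  stopifnot(cfg$n_species >= 2, cfg$tree_depth > 0, cfg$n_studies >= 1,
            length(cfg$experiments_per_study) == 2,
            cfg$experiments_per_study[1] >= 1,
            diff(cfg$experiments_per_study) >= 0,
            cfg$shared_control_prob >= 0, cfg$shared_control_prob <= 1,
            cfg$tau2 >= 0, cfg$rho >= 0, cfg$rho < 1,
            cfg$sigma_within > 0,
            length(cfg$n_per_group) == 2, cfg$n_per_group[1] >= 2,
            diff(cfg$n_per_group) >= 0)
  structure(cfg, class = "psf_sim_config")
}

#' Derive a stage seed from the master seed
#'
#' Each simulation stage (tree, dataset) draws from its own seed computed
#' deterministically from the master seed, so stages are independently
#' reproducible. The result stays within the 32-bit integer range.
#'
#' @param seed Master integer seed.
#' @param stage Small integer stage index.
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 48271 + stage * 1000003) %% 2147483647)
}

#' Simulate an ultrametric chronogram
#'
#' A pure-birth (Yule) tree rescaled to an exact root-to-tip depth, so it is
#' ultrametric by construction. Tips are labelled `sp_001, sp_002, ...`.
#'
#' @param n_species Number of tips (>= 2).
#' @param depth Root-to-tip depth in My.
#' @param seed Integer seed; identical seeds give identical Newick output.
#' @return A `"phylo"` chronogram.
#' @export
simulate_tree <- function(n_species, depth, seed = 1) {
  stopifnot(n_species >= 2, depth > 0)
  set.seed(seed)
  tree <- if (n_species == 2) {
    ape::read.tree(text = sprintf("(t1:%.6f,t2:%.6f);", depth, depth))
  } else {
    ape::rphylo(n_species, birth = 1, death = 0)
  }
  cur <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * depth / cur
  tree$tip.label <- sprintf("sp_%03d", seq_len(n_species))
  tree
}

#' Simulate a full pairwise feedback dataset with known truth
#'
#' Simulates raw per-plant biomasses (not effect sizes directly), so the
#' whole Hedges machinery -- including the covariance induced by reused
#' conspecific controls -- is exercised exactly as it would be on real data.
#' Per study, control groups grow plants at a baseline mean; each experiment
#' either reuses an existing control of its study (probability
#' `shared_control_prob`) or grows a new one with a freshly drawn focal
#' species. The treatment group on soil of a heterospecific species grows at
#' the baseline shifted by `-theta_i * sigma_within`, where the true
#' standardized effect `theta_i` follows the linear-in-distance model with
#' block-correlated hierarchical deviations.
#'
#' @param config A [sim_config()].
#' @param tree Optional `"phylo"` chronogram; simulated from the config when
#'   `NULL`.
#' @return A list: `records` (tibble in the experiment-record schema),
#'   `truth` (generating parameters plus a per-effect tibble with
#'   `phylo_distance`, `delta` and `theta`), and `tree`.
#' @export
simulate_dataset <- function(config = sim_config(), tree = NULL) {
  stopifnot(inherits(config, "psf_sim_config"))
  if (is.null(tree)) {
    tree <- simulate_tree(config$n_species, config$tree_depth,
                          seed = stage_seed(config$seed, 1L))
  }
  pick_in <- function(rng) if (rng[1] == rng[2]) rng[1] else
    sample(seq(rng[1], rng[2]), 1)
  tips <- tree$tip.label
  D <- ape::cophenetic.phylo(tree)
  set.seed(stage_seed(config$seed, 2L))

  life_forms <- c("grass", "herb", "shrub", "tree")
  life_cycles <- c("annual", "biennial", "perennial")
  provenances <- c("native", "exotic")

  recs <- list()
  truth_rows <- list()
  for (s in seq_len(config$n_studies)) {
    study_id <- sprintf("S%03d", s)
    n_exp <- pick_in(config$experiments_per_study)
    b_study <- stats::rnorm(1, 0, sqrt(config$rho * config$tau2))
    controls <- list()
    for (e in seq_len(n_exp)) {
      reuse <- length(controls) > 0 &&
        stats::runif(1) < config$shared_control_prob
      if (reuse) {
        ctl <- controls[[sample.int(length(controls), 1)]]
      } else {
        focal <- sample(tips, 1)
        n_con <- pick_in(config$n_per_group)
        mu_c <- stats::rnorm(1, config$mu_biomass, 1)
        raw <- stats::rnorm(n_con, mu_c, config$sigma_within)
        # treatment groups are centred on the *population* control mean, so
        # experiments reusing this control share only its sampling noise --
        # exactly the dependence V encodes
        ctl <- list(id = sprintf("%sC%02d", study_id, length(controls) + 1),
                    focal = focal, mu_true = mu_c,
                    mean = mean(raw), sd = stats::sd(raw), n = n_con)
        controls[[length(controls) + 1]] <- ctl
      }
      soil <- sample(setdiff(tips, ctl$focal), 1)
      pd <- D[ctl$focal, soil]
      delta <- b_study +
        stats::rnorm(1, 0, sqrt((1 - config$rho) * config$tau2))
      theta <- config$beta0 + config$beta1 * pd + delta
      n_het <- pick_in(config$n_per_group)
      raw_t <- stats::rnorm(n_het, ctl$mu_true - theta * config$sigma_within,
                            config$sigma_within)
      exp_id <- sprintf("%sE%02d", study_id, e)
      recs[[length(recs) + 1]] <- tibble::tibble(
        study_id = study_id, experiment_id = exp_id,
        focal_species = ctl$focal, soil_species = soil,
        control_group_id = ctl$id, hier_group_id = study_id,
        mean_con = ctl$mean, sd_con = ctl$sd, n_con = ctl$n,
        mean_het = mean(raw_t), sd_het = stats::sd(raw_t), n_het = n_het,
        life_form = sample(life_forms, 1),
        life_cycle = sample(life_cycles, 1),
        provenance = sample(provenances, 1))
      truth_rows[[length(truth_rows) + 1]] <- tibble::tibble(
        experiment_id = exp_id, phylo_distance = pd,
        delta = delta, theta = theta)
    }
  }
  list(
    records = dplyr::bind_rows(recs),
    truth = list(beta0 = config$beta0, beta1 = config$beta1,
                 tau2 = config$tau2, rho = config$rho,
                 per_effect = dplyr::bind_rows(truth_rows)),
    tree = tree
  )
}
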