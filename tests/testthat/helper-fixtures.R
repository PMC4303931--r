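# Small in-code fixtures shared across test files.

# one experiment record with overridable fields
make_record <- function(study_id = "S1", experiment_id = "E1",
                        focal_species = "A", soil_species = "B",
                        control_group_id = paste0(study_id, "c1"),
                        hier_group_id = study_id,
                        mean_con = 10, sd_con = 2, n_con = 5,
                        mean_het = 12, sd_het = 2, n_het = 5,
                        life_form = "herb", life_cycle = "perennial",
                        provenance = "native") {
  tibble::tibble(study_id = study_id, experiment_id = experiment_id,
                 focal_species = focal_species, soil_species = soil_species,
                 control_group_id = control_group_id,
                 hier_group_id = hier_group_id,
                 mean_con = mean_con, sd_con = sd_con, n_con = n_con,
                 mean_het = mean_het, sd_het = sd_het, n_het = n_het,
                 life_form = life_form, life_cycle = life_cycle,
                 provenance = provenance)
}

# random but always-valid records: n_studies studies, a few experiments each,
# some sharing controls; no tree involved
random_records <- function(n_studies = 3, max_exp = 4, share_p = 0.5) {
  species <- sprintf("sp%02d", 1:12)
  rows <- list()
  for (s in seq_len(n_studies)) {
    sid <- sprintf("S%02d", s)
    n_exp <- sample(1:max_exp, 1)
    controls <- list()
    for (e in seq_len(n_exp)) {
      if (length(controls) && stats::runif(1) < share_p) {
        ctl <- controls[[sample.int(length(controls), 1)]]
      } else {
        ctl <- list(id = sprintf("%sc%d", sid, length(controls) + 1),
                    focal = sample(species, 1),
                    mean = stats::runif(1, 5, 15),
                    sd = stats::runif(1, 0.5, 3),
                    n = sample(3:10, 1))
        controls[[length(controls) + 1]] <- ctl
      }
      soil <- sample(setdiff(species, ctl$focal), 1)
      rows[[length(rows) + 1]] <- make_record(
        study_id = sid, experiment_id = sprintf("%se%d", sid, e),
        focal_species = ctl$focal, soil_species = soil,
        control_group_id = ctl$id,
        mean_con = ctl$mean, sd_con = ctl$sd, n_con = ctl$n,
        mean_het = stats::runif(1, 5, 15), sd_het = stats::runif(1, 0.5, 3),
        n_het = sample(3:10, 1))
    }
  }
  dplyr::bind_rows(rows)
}

# intercept + distance dataset from d / var / pd vectors, all independent
toy_dataset <- function(d, v, pd = NULL, blocks = seq_along(d)) {
  X <- if (is.null(pd)) cbind(intercept = rep(1, length(d))) else
    cbind(intercept = rep(1, length(d)), phylo_distance = pd)
  structure(list(d = d, X = X, V = diag(v, length(d)),
                 blocks = as.character(blocks),
                 effects = tibble::tibble(
                   experiment_id = as.character(seq_along(d)), d = d,
                   var = v, control_group_id = as.character(seq_along(d)),
                   hier_group_id = as.character(blocks)),
                 records = NULL),
            class = "psf_meta_dataset")
}

trim_fixture <- function(spec) {
  # spec: list of list(id, species (chr vec), n_effects)
  rows <- list()
  for (s in spec) {
    for (e in seq_len(s$n)) {
      sp <- if (length(s$species) >= 2) sample(s$species, 2) else
        c(s$species, "zz_other")
      rows[[length(rows) + 1]] <- make_record(
        study_id = s$id, experiment_id = paste0(s$id, "e", e),
        control_group_id = paste0(s$id, "c", e),
        focal_species = sp[1], soil_species = sp[2])
    }
  }
  dplyr::bind_rows(rows)
}
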