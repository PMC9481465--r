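#' Bootstrap one contact-energy matrix from force pools
#'
#' For each cell-type pair, resamples the pair's adhesion-force pool
#' with replacement (same size as the pool), takes the mean, and maps it
#' to a contact energy with [force_to_contact_energy()]. The cell-medium
#' entries come from the configuration. Repeating this across an
#' ensemble propagates the measurement variability of the force data
#' into the simulated outcome distribution.
#'
#' @param pools Named list of numeric force vectors (canonical pair ids;
#'   see [build_force_pools()]).
#' @param config Configuration list.
#' @param seed Integer seed for the resampling.
#' @return 4x4 symmetric contact-energy matrix.
#' @export
bootstrap_j_matrix <- function(pools, config = default_config(),
                               seed = 1L) {
  need <- c("ES-ES", "ES-TS", "ES-XEN", "TS-TS", "TS-XEN", "XEN-XEN")
  names(pools) <- vapply(names(pools), pair_id, character(1))
  if (!all(need %in% names(pools))) {
    stop("missing force pools for: ",
         paste(setdiff(need, names(pools)), collapse = ", "))
  }
  if (any(vapply(pools[need], length, integer(1)) == 0L)) {
    stop("empty force pool")
  }
  means <- local_seed(seed, {
    vapply(need, function(p) {
      x <- pools[[p]]
      mean(x[sample.int(length(x), length(x), replace = TRUE)])
    }, numeric(1))
  })
  contact_energy_matrix(means, config)
}

#' Run a bootstrap ensemble of CPM simulations
#'
#' The in-silico assembly experiment: `n_bootstrap` independent
#' (J-matrix resample, simulation, final-snapshot classification)
#' triples, fully determined by `master_seed` (per-run seeds are derived
#' by counter, so any single run can be reproduced in isolation). Failed
#' runs are recorded under the label `"failed"`, never dropped.
#'
#' @param config Configuration list.
#' @param n_bootstrap Ensemble size. The reference in-silico experiment
#'   used ~500 resamples; 200 keeps a desk-scale run while leaving the
#'   modal class well resolved.
#' @param master_seed Integer master seed.
#' @param pools Optional force pools; default builds the synthetic pools
#'   at the published sample sizes from `master_seed`, honouring any
#'   `forces:` overrides in the configuration.
#' @param progress Print a progress line every 25 runs.
#' @return List of class `bootstrap_ensemble`: `summary`
#'   (an [summarize_ensemble()] object), `records` (one row per run),
#'   `manifest` (a [run_manifest()]).
#' @export
run_bootstrap_ensemble <- function(config = default_config(),
                                   n_bootstrap = 200L, master_seed = 1L,
                                   pools = NULL, progress = FALSE) {
  config <- validate_config(config)
  stopifnot(n_bootstrap >= 1L)
  if (is.null(pools)) {
    pools <- build_force_pools(wt_cell_pair_specs(config_force_specs(config)),
                               seed = derive_seed(master_seed, 999983L))
  }
  manifest <- run_manifest(config, master_seed, n_bootstrap)
  rows <- vector("list", n_bootstrap)
  for (i in seq_len(n_bootstrap)) {
    seed_i <- manifest$run_seeds[i]
    rows[[i]] <- tryCatch({
      J <- bootstrap_j_matrix(pools, config,
                              seed = derive_seed(seed_i, 3L))
      traj <- run_simulation(config, J = J, seed = seed_i)
      cl <- classify(traj$snapshots[[length(traj$snapshots)]],
                     config$envelopment_threshold,
                     config$lattice$neighbourhood)
      data.frame(run_id = i, seed = seed_i, label_id = cl$label_id,
                 interposition = cl$interposition,
                 enveloping_type = if (is.na(cl$enveloping_type))
                   NA_character_ else cl$enveloping_type,
                 env_XEN = cl$envelopment[["XEN"]],
                 final_energy = traj$energies[length(traj$energies)])
    }, error = function(e) {
      data.frame(run_id = i, seed = seed_i, label_id = "failed",
                 interposition = NA, enveloping_type = NA_character_,
                 env_XEN = NA_real_, final_energy = NA_real_)
    })
    if (progress && i %% 25L == 0L) {
      message(sprintf("bootstrap run %d / %d", i, n_bootstrap))
    }
  }
  records <- do.call(rbind, rows)
  structure(list(
    summary = summarize_ensemble(records$label_id, config$group_threshold),
    records = records,
    manifest = manifest
  ), class = "bootstrap_ensemble")
}

#' @export
print.bootstrap_ensemble <- function(x, ...) {
  cat(sprintf("<bootstrap_ensemble> master_seed = %d\n",
              x$manifest$master_seed))
  print(x$summary)
  invisible(x)
}

first_passage_mcs <- function(traj, threshold) {
  nb <- traj$params$config$lattice$neighbourhood
  for (i in seq_along(traj$snapshots)) {
    m <- contact_lengths(traj$snapshots[[i]], nb)
    surface <- m[1:3, "Medium"]
    if (sum(surface) > 0 && surface["XEN"] / sum(surface) >= threshold) {
      return(traj$mcs[i])
    }
  }
  Inf
}

#' Sweep the XEN cortical-stiffness parameter
#'
#' Varies the XEN perimeter-constraint coefficient
#' \eqn{\lambda_P^{XEN}} over a grid of multiples of its default while
#' holding everything else fixed, with paired seeds across the grid (the
#' same replicate index uses the same initialization and J resample at
#' every lambda value). For each value it reports the XEN
#' externalization frequency (fraction of runs whose final snapshot has
#' XEN envelopment at or above the threshold) and the median
#' first-passage time to externalization in MCS (`Inf` when never
#' reached).
#'
#' @param lambda_factors Numeric grid of multipliers on the default XEN
#'   stiffness, all `> 0`, at least 2 values.
#' @param replicates Paired replicates per grid value.
#' @param config Configuration list.
#' @param master_seed Integer master seed.
#' @param pools Optional force pools (defaults as in
#'   [run_bootstrap_ensemble()]).
#' @return List of class `stiffness_sweep`: `table` (one row per lambda
#'   value: `lambda_factor`, `lambda_p_xen`,
#'   `externalization_frequency`, `median_mcs_to_externalization`,
#'   `n_replicates`) and `records` (one row per run).
#' @export
stiffness_sweep <- function(lambda_factors = c(0.5, 1, 2, 4),
                            replicates = 50L, config = default_config(),
                            master_seed = 1L, pools = NULL) {
  stopifnot(length(lambda_factors) >= 2L, all(lambda_factors > 0))
  config <- validate_config(config)
  if (is.null(pools)) {
    pools <- build_force_pools(wt_cell_pair_specs(config_force_specs(config)),
                               seed = derive_seed(master_seed, 999983L))
  }
  base_xen <- config$stiffness$XEN
  rows <- list()
  for (li in seq_along(lambda_factors)) {
    cfg <- config
    cfg$stiffness$XEN <- base_xen * lambda_factors[li]
    lam <- cfg$lambda_perimeter_base * cfg$stiffness$XEN
    for (r in seq_len(replicates)) {
      seed_r <- derive_seed(master_seed, r)  # shared across lambda values
      J <- bootstrap_j_matrix(pools, cfg, seed = derive_seed(seed_r, 3L))
      traj <- run_simulation(cfg, J = J, seed = seed_r)
      fin <- classify(traj$snapshots[[length(traj$snapshots)]],
                      cfg$envelopment_threshold,
                      cfg$lattice$neighbourhood)
      rows[[length(rows) + 1L]] <- data.frame(
        lambda_factor = lambda_factors[li], lambda_p_xen = lam,
        replicate = r, seed = seed_r,
        env_XEN = fin$envelopment[["XEN"]],
        externalized = fin$envelopment[["XEN"]] >=
          cfg$envelopment_threshold,
        mcs_to_externalization = first_passage_mcs(
          traj, cfg$envelopment_threshold),
        label_id = fin$label_id)
    }
  }
  records <- do.call(rbind, rows)
  tab <- do.call(rbind, lapply(split(records, records$lambda_factor),
    function(d) data.frame(
      lambda_factor = d$lambda_factor[1],
      lambda_p_xen = d$lambda_p_xen[1],
      externalization_frequency = mean(d$externalized),
      median_mcs_to_externalization =
        stats::median(d$mcs_to_externalization),
      n_replicates = nrow(d))))
  tab <- tab[order(tab$lambda_factor), ]
  rownames(tab) <- NULL
  structure(list(table = tab, records = records),
            class = "stiffness_sweep")
}

#' @export
print.stiffness_sweep <- function(x, ...) {
  cat("<stiffness_sweep>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Vary the seeded cell numbers
#'
#' Runs paired-seed ensembles for several cell-count compositions and
#' reports per-variant label frequencies plus the frequency of
#' XEN-enveloping outcomes (any class whose outer layer is XEN). Used to
#' probe how the small number of XEN cells limits coverage of the
#' aggregate.
#'
#' @param counts_variants Named list of `c(ES=, TS=, XEN=)` vectors.
#' @param replicates Replicates per variant (seeds paired across
#'   variants).
#' @param config Configuration list.
#' @param master_seed Integer master seed.
#' @param pools Optional force pools.
#' @return List of class `cell_number_experiment`: `table` (variant,
#'   counts, `xen_enveloping_frequency`), `label_freq` (named list of
#'   frequency vectors), `records`.
#' @export
cell_number_experiment <- function(counts_variants, replicates = 20L,
                                   config = default_config(),
                                   master_seed = 1L, pools = NULL) {
  stopifnot(length(counts_variants) >= 1L)
  config <- validate_config(config)
  if (is.null(pools)) {
    pools <- build_force_pools(wt_cell_pair_specs(config_force_specs(config)),
                               seed = derive_seed(master_seed, 999983L))
  }
  if (is.null(names(counts_variants))) {
    names(counts_variants) <- vapply(counts_variants, function(x)
      paste(sprintf("%s%d", names(x), x), collapse = "_"), character(1))
  }
  rows <- list()
  for (vi in seq_along(counts_variants)) {
    cfg <- config
    cts <- counts_variants[[vi]]
    cfg$cells <- as.list(cts[c("ES", "TS", "XEN")])
    for (r in seq_len(replicates)) {
      seed_r <- derive_seed(master_seed, r)
      J <- bootstrap_j_matrix(pools, cfg, seed = derive_seed(seed_r, 3L))
      traj <- run_simulation(cfg, J = J, seed = seed_r)
      fin <- classify(traj$snapshots[[length(traj$snapshots)]],
                      cfg$envelopment_threshold,
                      cfg$lattice$neighbourhood)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = names(counts_variants)[vi], replicate = r,
        seed = seed_r, n_total = sum(unlist(cfg$cells)),
        label_id = fin$label_id,
        xen_enveloping = identical(fin$enveloping_type, "XEN"))
    }
  }
  records <- do.call(rbind, rows)
  split_rec <- split(records, records$variant)[names(counts_variants)]
  tab <- do.call(rbind, lapply(names(split_rec), function(v) {
    cts <- counts_variants[[v]]
    data.frame(variant = v, ES = cts[["ES"]], TS = cts[["TS"]],
               XEN = cts[["XEN"]],
               xen_enveloping_frequency =
                 mean(split_rec[[v]]$xen_enveloping),
               n_replicates = nrow(split_rec[[v]]))
  }))
  rownames(tab) <- NULL
  label_freq <- lapply(split_rec, function(d)
    summarize_ensemble(d$label_id, config$group_threshold)$freq)
  structure(list(table = tab, label_freq = label_freq, records = records),
            class = "cell_number_experiment")
}

#' @export
print.cell_number_experiment <- function(x, ...) {
  cat("<cell_number_experiment>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
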