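#' Default study conditions
#'
#' The shared conditions under which the package's experiments run: focal
#' mean excitability `mu = -1.6`, healthy excitability
#' `x0_nonfocal = -2.2` (below threshold yet recruitable), focal-edge
#' prominence `K = 10`, per-node coupling budget 2.15, run length `6 * tau0`
#' at `dt = 0.05` with the first `tau0` discarded as transient.  See the
#' methods vignette for how each value was fixed.
#'
#' @return Named list of condition values.
#' @export
study_conditions <- function() {
  list(mu = -1.6, x0_nonfocal = -2.2, K = 10, coupling_budget = 2.15,
       dt = 0.05, duration = 6 * 2857, save_every = 20L,
       transient_fraction = 1 / 6, jitter = 0.05)
}

# Counter-based sub-seed expansion: one root seed per experiment,
# deterministically mapped per replicate/stream so replicate counts can
# grow without reshuffling earlier replicates.  Kept within 32-bit range.
sub_seed <- function(root, counter, stream = 0L) {
  as.integer((as.double(root) * 7919 + counter * 104729 + stream * 130003)
             %% 2147483629 + 1)
}

# Base network rescaled so every node's total base input equals the
# study's per-node coupling budget.  The ring-distance weights sum to
# roughly 2 * log(n / 2) per node, so without this normalization the
# effective drive a node receives would grow with network size and the
# dynamical regime would shift between the differently sized experiments.
scaled_base_network <- function(n, cond = study_conditions()) {
  base <- build_base_network(n)
  base$global_scale <- cond$coupling_budget / mean(rowSums(base$weights))
  base
}

# assemble a prominently-embedded focal network under the study conditions
focal_network <- function(n, spec, seed, cond = study_conditions()) {
  base <- scaled_base_network(n, cond)
  fadj <- build_focal_adjacency(spec, seed = seed)
  embed_focal(base, fadj, seq_len(spec$n_focal), K = cond$K)
}

run_one <- function(S, profile, seed, cond = study_conditions(),
                    params = model_params()) {
  cfg <- network_run_config(duration = cond$duration, dt = cond$dt,
                            seed = seed, jitter = cond$jitter,
                            save_every = cond$save_every)
  simulate_network(S, profile, params = params, cfg = cfg)
}

write_report_table <- function(df, out_dir, name, meta) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, paste0(name, ".tsv"))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  yaml::write_yaml(meta, file.path(out_dir, paste0(name, ".meta.yml")))
  invisible(path)
}

#' Locate the epileptogenicity threshold (experiment driver)
#'
#' Bisects the isolated oscillator's quiescent/oscillatory boundary and
#' reports the probe trace together with the bracket-endpoint
#' classifications.
#'
#' @param lo,hi,tol bisection bracket and tolerance on x0.
#' @param params an [model_params()] object.
#' @param dt,duration integration settings per probe.
#' @param out_dir directory for the tabular report (`NULL` = don't
#'   write).
#' @return A list with `estimate`, the probe `trace` data frame, and the
#'   `config` used.
#' @export
run_threshold_scan <- function(lo = -2.5, hi = -1.6, tol = 0.01,
                               params = model_params(), dt = 0.05,
                               duration = 6 * params$tau0,
                               out_dir = NULL) {
  est <- find_threshold(params, lo = lo, hi = hi, tol = tol,
                        duration = duration, dt = dt, trace = TRUE)
  trace <- attr(est, "trace")
  report <- list(estimate = as.numeric(est), trace = trace,
                 config = list(lo = lo, hi = hi, tol = tol, dt = dt,
                               duration = duration))
  write_report_table(trace, out_dir, "threshold_scan",
                     c(report$config, estimate = report$estimate))
  report
}

#' Recruitment experiment
#'
#' Reproduces the three whole-network conditions: (a) fully connected
#' base with a prominently embedded focal subnetwork, (b) the same
#' fully connected base with no focal nodes, and (c) sparse random
#' connectivity with focal nodes, the last repeated over several seeds.
#' Reports the recruitment fraction and onset-delay summary per
#' condition.
#'
#' @param n network size.
#' @param focal_prop fraction of nodes that are focal.
#' @param density edge density of the sparse random condition.
#' @param sparse_weight uniform edge weight of the sparse condition.
#'   Applied as-is (the global coupling scale is not layered on top), so
#'   the sparse runs are directly comparable across condition sets.
#' @param n_sparse_seeds how many sparse-network seeds to run.
#' @param seed root seed.
#' @param cond study conditions, see [study_conditions()].
#' @param params an [model_params()] object.
#' @param out_dir optional output directory.
#' @return List with `summary` (one row per run: condition, seed,
#'   recruitment, median_delay, synchrony) and `delays` (per-node delay
#'   table of the full+focal run), plus `config`.
#' @export
run_recruitment <- function(n = 20, focal_prop = 0.2, density = 0.1,
                            sparse_weight = 0.5, n_sparse_seeds = 5,
                            seed = 1L, cond = study_conditions(),
                            params = model_params(), out_dir = NULL) {
  nf <- max(2L, round(n * focal_prop))
  focal <- seq_len(nf)
  rows <- list()
  measure <- function(tr, focal_idx) {
    ev <- detect_events(tr)
    rf <- recruitment_fraction(ev, focal_idx)
    md <- if (length(focal_idx) &&
              any(vapply(ev$events[focal_idx], nrow, integer(1)) > 0)) {
      d <- onset_delays(ev, focal_idx)$delay
      if (all(is.na(d))) NA_real_ else median(d, na.rm = TRUE)
    } else NA_real_
    sync <- mean_pairwise_synchrony(sle_signal(tr))
    list(rf = rf, md = md, sync = as.numeric(sync), ev = ev)
  }

  # (a) fully connected + focal
  if (nf < 3) stop("need at least 3 focal nodes (n * focal_prop too small)")
  S <- focal_network(n, focal_topology(nf, "regular", k = 2),
                     seed = sub_seed(seed, 1), cond = cond)
  prof <- sample_x0(n, focal, mu = cond$mu, sigma = 0,
                    x0_nonfocal = cond$x0_nonfocal, params = params,
                    seed = sub_seed(seed, 2))
  tr <- run_one(S, prof, sub_seed(seed, 3), cond, params)
  m <- measure(tr, focal)
  rows[[1]] <- data.frame(condition = "full_focal", seed = seed,
                          recruitment = m$rf, median_delay = m$md,
                          synchrony = m$sync)
  delays <- onset_delays(m$ev, focal)

  # (b) fully connected, no focal nodes
  base <- scaled_base_network(n, cond)
  tr <- run_one(base, rep(cond$x0_nonfocal, n), sub_seed(seed, 4), cond,
                params)
  m <- measure(tr, integer(0))
  rows[[2]] <- data.frame(condition = "full_nofocal", seed = seed,
                          recruitment = recruitment_fraction(
                            detect_events(tr), integer(0)),
                          median_delay = NA_real_, synchrony = m$sync)

  # (c) sparse random + focal, several network seeds
  for (s in seq_len(n_sparse_seeds)) {
    sp <- build_sparse_random_network(n, density, weight = sparse_weight,
                                      seed = sub_seed(seed, s, stream = 1L))
    prof <- sample_x0(n, focal, mu = cond$mu, sigma = 0,
                      x0_nonfocal = cond$x0_nonfocal, params = params,
                      seed = sub_seed(seed, s, stream = 2L))
    tr <- run_one(sp, prof, sub_seed(seed, s, stream = 3L), cond, params)
    m <- measure(tr, focal)
    rows[[2 + s]] <- data.frame(condition = "sparse_focal",
                                seed = sub_seed(seed, s, stream = 1L),
                                recruitment = m$rf, median_delay = m$md,
                                synchrony = m$sync)
  }
  summary <- do.call(rbind, rows)
  config <- list(n = n, focal_prop = focal_prop, density = density,
                 sparse_weight = sparse_weight,
                 n_sparse_seeds = n_sparse_seeds, seed = seed,
                 conditions = cond)
  write_report_table(summary, out_dir, "recruitment", config)
  list(summary = summary, delays = delays, config = config)
}

#' Seizure-period sweeps
#'
#' Sweeps the mean focal excitability `mu`, the focal proportion, and the
#' excitability heterogeneity `sigma` on a fixed fully connected base
#' network, reporting the pooled mean onset-to-onset period per cell with
#' replicate spread.
#'
#' @param n network size.
#' @param mu_grid values of the focal mean excitability.
#' @param prop_grid focal proportions.
#' @param sigma_grid heterogeneity values.
#' @param mu_fixed,prop_fixed the values held fixed while the other
#'   parameters sweep.
#' @param replicates replicates per cell (distinct x0/jitter seeds).
#' @param seed root seed.
#' @param cond,params,out_dir as in [run_recruitment()].
#' @return List with `table` (sweep, value, replicate, period) and
#'   `config`.  Cells whose runs yield too few events are reported as
#'   `NA` periods.
#' @export
run_period_sweep <- function(n = 30, mu_grid = c(-1.9, -1.7, -1.5),
                             prop_grid = c(0.1, 0.2, 0.4),
                             sigma_grid = c(0, 0.05, 0.1),
                             mu_fixed = -1.6, prop_fixed = 0.2,
                             replicates = 1, seed = 1L,
                             cond = study_conditions(),
                             params = model_params(), out_dir = NULL) {
  # paired design: within a sweep, a replicate reuses the same network,
  # x0 and jitter seeds at every swept value, so the contrast along the
  # sweep is not diluted by seed-to-seed variance
  cell_period <- function(nf, mu, sigma, rep_i, stream) {
    spec <- focal_topology(nf, "regular", k = min(2L, nf - 1L))
    S <- focal_network(n, spec, seed = sub_seed(seed, rep_i, stream),
                       cond = cond)
    prof <- sample_x0(n, seq_len(nf), mu = mu, sigma = sigma,
                      x0_nonfocal = cond$x0_nonfocal, params = params,
                      seed = sub_seed(seed, rep_i, stream + 1L))
    tr <- run_one(S, prof, sub_seed(seed, rep_i, stream + 2L), cond,
                  params)
    # the system rhythm is read off the recruited (non-focal) population:
    # the focal pacemakers cycle faster than the bulk they entrain, and it
    # is the propagated bulk oscillation the period curves describe
    ev <- detect_events(tr)
    tryCatch(mean_period(ev, node_subset = seq.int(nf + 1L, n)),
             error = function(e) NA_real_)
  }
  rows <- list()
  add <- function(sweep, value, rep_i, period) {
    rows[[length(rows) + 1L]] <<- data.frame(
      sweep = sweep, value = value, replicate = rep_i, period = period)
  }
  nf_fixed <- max(2L, round(n * prop_fixed))
  for (mu in mu_grid) for (r in seq_len(replicates))
    add("mu", mu, r, cell_period(nf_fixed, mu, 0, r, 10L))
  for (pr in prop_grid) for (r in seq_len(replicates))
    add("proportion", pr, r,
        cell_period(max(2L, round(n * pr)), mu_fixed, 0, r, 20L))
  for (sg in sigma_grid) for (r in seq_len(replicates))
    add("sigma", sg, r, cell_period(nf_fixed, mu_fixed, sg, r, 30L))
  table <- do.call(rbind, rows)
  config <- list(n = n, mu_grid = mu_grid, prop_grid = prop_grid,
                 sigma_grid = sigma_grid, mu_fixed = mu_fixed,
                 prop_fixed = prop_fixed, replicates = replicates,
                 seed = seed, conditions = cond)
  write_report_table(table, out_dir, "period_sweep", config)
  list(table = table, config = config)
}

#' Functional-network degree versus excitability heterogeneity
#'
#' For each focal-subnetwork family and each heterogeneity level `sigma`,
#' simulates `replicates` independent (network seed, x0 seed) pairs,
#' builds the functional network from pairwise Pearson correlations of
#' the slow permittivity signal thresholded at the top `kept_fraction`
#' of edges, and records the normalized average degree of the focal
#' nodes.
#'
#' @param n network size (the headline analysis uses 100; `full = TRUE`
#'   forces that).
#' @param focal_prop focal proportion.
#' @param sigma_grid heterogeneity values.
#' @param p_grid rewiring probabilities of the lattice families.
#' @param gamma_grid scale-free power-law exponents.
#' @param replicates independent replicates per cell.
#' @param kept_fraction fraction of strongest correlations kept.
#' @param fc_signal `"z"` (default): correlate the slow permittivity
#'   variable, the seizure-envelope carrier; `"sle"`: correlate the raw
#'   electrographic observable.
#' @param full run at the headline 100-node size regardless of `n`.
#' @param seed root seed.
#' @param cond,params,out_dir as in [run_recruitment()].
#' @return List with `table` (family, param, sigma, replicate, value),
#'   `summary` (replicate means and sds per cell), and `config`.
#' @export
run_heterogeneity_degree <- function(n = 40, focal_prop = 0.2,
                                     sigma_grid = c(0, 0.05, 0.10, 0.15),
                                     p_grid = c(0, 0.3, 1),
                                     gamma_grid = c(2.2, 3.0),
                                     replicates = 10,
                                     kept_fraction = 0.275,
                                     fc_signal = c("z", "sle"),
                                     full = FALSE, seed = 1L,
                                     cond = study_conditions(),
                                     params = model_params(),
                                     out_dir = NULL) {
  fc_signal <- match.arg(fc_signal)
  if (full) n <- 100L
  nf <- max(2L, round(n * focal_prop))
  focal <- seq_len(nf)
  fams <- c(lapply(p_grid, function(p) {
    fam <- if (p == 0) "regular" else if (p == 1) "random" else "smallworld"
    list(label = sprintf("lattice_p%g", p), param = p,
         spec = focal_topology(nf, fam, p = p, k = min(4L, nf - 1L - ((nf - 1L) %% 2L))))
  }), lapply(gamma_grid, function(g) {
    list(label = sprintf("scalefree_gamma%g", g), param = g,
         spec = focal_topology(nf, "scalefree", gamma_sf = g,
                               k = min(4L, nf - 1L - ((nf - 1L) %% 2L))))
  }))
  rows <- list()
  fi <- 0L
  for (fam in fams) {
    fi <- fi + 1L
    for (sg in sigma_grid) {
      for (r in seq_len(replicates)) {
        # paired design with common random numbers: the network draw and
        # the x0 seed depend on (family, replicate) only, so every sigma
        # level sees the same focal graphs and the same underlying normal
        # deviates (scaled by sigma); the sigma contrast is then a smooth
        # within-replicate comparison, not diluted by seed-to-seed variance
        net_seed <- sub_seed(seed, 1000L * fi + r, 1L)
        x0_seed <- sub_seed(seed, 1000L * fi + r, 2L)
        run_seed <- sub_seed(seed, 1000L * fi + r, 3L)
        S <- focal_network(n, fam$spec, seed = net_seed, cond = cond)
        prof <- sample_x0(n, focal, mu = cond$mu, sigma = sg,
                          x0_nonfocal = cond$x0_nonfocal, params = params,
                          seed = x0_seed)
        tr <- run_one(S, prof, run_seed, cond, params)
        sig <- if (fc_signal == "z") tr$z else sle_signal(tr)
        cm <- correlation_matrix(sig,
                                 transient_fraction = cond$transient_fraction)
        fn <- threshold_top_fraction(cm, kept_fraction)
        rows[[length(rows) + 1L]] <- data.frame(
          family = fam$label, param = fam$param, sigma = sg,
          replicate = r, value = average_degree(fn, focal,
                                                normalized = TRUE))
      }
    }
  }
  table <- do.call(rbind, rows)
  agg_mean <- aggregate(value ~ family + param + sigma, table, mean)
  agg_sd <- aggregate(value ~ family + param + sigma, table, stats::sd)
  summary <- merge(agg_mean, agg_sd,
                   by = c("family", "param", "sigma"),
                   suffixes = c("_mean", "_sd"))
  summary <- summary[order(summary$family, summary$sigma), ]
  config <- list(n = n, focal_prop = focal_prop, sigma_grid = sigma_grid,
                 p_grid = p_grid, gamma_grid = gamma_grid,
                 replicates = replicates, kept_fraction = kept_fraction,
                 fc_signal = fc_signal, seed = seed, conditions = cond)
  write_report_table(table, out_dir, "heterogeneity_degree", config)
  if (!is.null(out_dir))
    write_report_table(summary, out_dir, "heterogeneity_degree_summary",
                       config)
  list(table = table, summary = summary, config = config)
}
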