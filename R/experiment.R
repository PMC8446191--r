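#' Run one breeding scenario for several replicates
#'
#' Simulates a closed nucleus: a founder population, then the configured
#' number of non-overlapping generations of index selection and random
#' mating among the selected parents, with Mendelian sampling variance
#' shrunk by parental inbreeding and (when configured) linear inbreeding
#' depression on fertility.  Pedigree inbreeding is tracked exactly via
#' the tabular relationship recursion restricted to the selected parents
#' of each generation.  Each replicate is seeded as
#' \code{seed + replicate}, so runs are reproducible and replicate seeds
#' are shared across scenarios (common random numbers).
#'
#' @param params A \code{\link{parameter_set}}.
#' @param scenario A \code{\link{scenario_spec}} (validated against
#'   \code{params}).
#' @param generations,replicates,n_animals Overrides of the programme
#'   defaults in \code{params}.
#' @param seed Root integer seed.
#' @param base_weights Base-scenario weights for Index0; default taken
#'   from \code{params}.
#' @param record_pedigree Keep the full 3-column pedigree of each
#'   replicate (id, sire, dam; memory grows with n x generations).
#' @return An object of class \code{scenario_run}: \code{results} (one
#'   row per replicate: realized gains per trait, reported-scale gains
#'   for binary traits, final resilience mean, Index0, profit at +0/1/2
#'   degrees C, final mean inbreeding), \code{trajectories} (per
#'   replicate x generation trait means, genetic variances, mean F) and
#'   \code{summary} (replicate means and SEs).
#' @export
run_scenario <- function(params, scenario, generations = NULL,
                         replicates = NULL, n_animals = NULL, seed = 1L,
                         base_weights = NULL, record_pedigree = FALSE) {
  params <- load_parameter_set(params, check = FALSE)
  scenario <- validate_scenario(scenario, params)
  prog <- params$program
  G <- as.integer(generations %||% prog$generations)
  R <- as.integer(replicates %||% prog$replicates)
  n <- as.integer(n_animals %||% prog$n_animals)
  if (G < 1L) stop("generations must be >= 1")
  if (R < 1L) stop("replicates must be >= 1")
  bw <- base_weights %||% params$base_weights
  ap <- active_parameters(params, scenario$resilience_mode)
  nm <- names(ap$traits)
  res_tr <- ap$resilience_trait
  caps <- c(sire = prog$max_offspring_sire, dam = prog$max_offspring_dam)
  dep <- params$inbreeding_depression
  if (!is.null(dep) && !dep$trait %in% nm) dep <- NULL
  binary <- nm[!is.na(ap$thresholds)]

  results <- vector("list", R)
  trajectories <- vector("list", R)
  pedigrees <- if (record_pedigree) vector("list", R)

  for (r in seq_len(R)) {
    set.seed(seed + r)
    pop <- simulate_base_population(n, ap)
    if (!is.null(dep))
      pop <- apply_inbreeding_depression(pop, dep$trait, dep$slope)
    base_pop <- pop
    base_rep <- reported_means(pop, ap)
    kin_sel <- NULL      # relationship among current selected parents
    traj <- list(.traj_row(pop, ap, r, 0L))
    ped <- if (record_pedigree)
      data.frame(id = pop$id, sire = 0L, dam = 0L)

    for (g in seq_len(G)) {
      pop <- simulate_ebv(pop, ap)
      z <- standardize_ebv(pop)
      merits <- .merit_matrix(z, pop, ap)
      index <- compute_index(merits, scenario$weights)
      sel <- select_parents(pop, index, prog$prop_male, prog$prop_female)
      sel_all <- c(sel$sire_idx, sel$dam_idx)
      ns <- length(sel$sire_idx)

      if (is.null(kin_sel)) {            # parents are founders
        kin_new <- founder_kinship(pop$f[sel_all])
      } else {
        kin_new <- offspring_kinship(
          kin_sel,
          attr(pop, "sire_slot")[sel_all],
          attr(pop, "dam_slot")[sel_all],
          n_sires = attr(kin_sel, "n_sires"))
        diag(kin_new) <- 1 + pop$f[sel_all]
      }
      attr(kin_new, "n_sires") <- ns

      pop <- breed_generation(sel$sires, sel$dams, n, caps = caps,
                              params = ap, parent_kinship = kin_new,
                              id_start = g * n + 1L)
      if (!is.null(dep))
        pop <- apply_inbreeding_depression(pop, dep$trait, dep$slope)
      kin_sel <- kin_new
      traj[[g + 1L]] <- .traj_row(pop, ap, r, g)
      if (record_pedigree)
        ped <- rbind(ped, data.frame(id = pop$id, sire = pop$sire,
                                     dam = pop$dam))
    }

    gains <- realized_gain(base_pop, pop)
    rep_means <- reported_means(pop, ap)
    gains_rep <- gains
    gains_rep[binary] <- rep_means[binary] - base_rep[binary]
    res_mean <- if (is.na(res_tr)) NA_real_ else mean(pop$phen[, res_tr])
    res_abs <- if (is.na(res_tr)) NA_real_ else mean(abs(pop$phen[, res_tr]))
    idx0 <- compute_index0(gains, bw, ap)
    prof_gains <- gains_rep[setdiff(nm, res_tr)]
    L_mean <- if (scenario$resilience_mode == "absolute") res_abs else
      res_mean
    prof <- vapply(c(0, 1, 2), function(dt)
      compute_profit(prof_gains, L_mean, params$economics, dt,
                     mode = scenario$resilience_mode), 0)

    row <- data.frame(scenario = scenario$name, replicate = r)
    for (k in nm) row[[paste0("gain_", k)]] <- gains[[k]]
    for (k in binary) row[[paste0("gain_inc_", k)]] <- gains_rep[[k]]
    row$resilience_final <- res_mean
    row$resilience_abs_final <- res_abs
    row$index0 <- idx0
    row$profit0 <- prof[1L]
    row$profit1 <- prof[2L]
    row$profit2 <- prof[3L]
    row$mean_f_final <- mean(pop$f)
    results[[r]] <- row
    trajectories[[r]] <- do.call(rbind, traj)
    if (record_pedigree) pedigrees[[r]] <- ped
  }

  results <- do.call(rbind, results)
  structure(list(scenario = scenario, zone = params$zone,
                 resilience_trait = res_tr,
                 generations = G, replicates = R, n_animals = n,
                 seed = seed,
                 results = results,
                 trajectories = do.call(rbind, trajectories),
                 summary = if (R >= 2L) summarize_replicates(results),
                 pedigrees = pedigrees),
            class = "scenario_run")
}

.traj_row <- function(pop, ap, replicate, generation) {
  nm <- colnames(pop$phen)
  row <- data.frame(replicate = replicate, generation = generation)
  mu <- colMeans(pop$phen)
  rep_mu <- reported_means(pop, ap)
  vg <- apply(pop$tbv, 2L, stats::var)
  for (k in nm) row[[paste0("mean_", k)]] <- mu[[k]]
  for (k in nm[!is.na(ap$thresholds)])
    row[[paste0("inc_", k)]] <- rep_mu[[k]]
  for (k in nm) row[[paste0("varg_", k)]] <- vg[[k]]
  row$mean_f <- mean(pop$f)
  row
}

#' @export
print.scenario_run <- function(x, ...) {
  cat(sprintf("Scenario run '%s' (%s): %d replicates x %d generations, n = %d\n",
              x$scenario$name, x$zone, x$replicates, x$generations,
              x$n_animals))
  s <- x$summary
  if (!is.null(s))
    cat(sprintf("  final resilience mean %.4g (SE %.2g), Index0 %.4g, profit0 %.4g\n",
                s$resilience_final_mean, s$resilience_final_se,
                s$index0_mean, s$profit0_mean))
  invisible(x)
}

#' Configure a full scenario-sweep experiment
#'
#' @param parameter_set Built-in name, path to a YAML parameter file, or
#'   a \code{\link{parameter_set}} object.
#' @param scenarios Named list of \code{\link{scenario_spec}}s; default
#'   is the zone's full built-in grid.
#' @param generations,replicates,n_animals Optional overrides.
#' @param seed Root seed (per-replicate seeds are seed + replicate).
#' @param output_dir Optional directory for CSV outputs.
#' @return A list of class \code{experiment_config}.
#' @export
experiment_config <- function(parameter_set, scenarios = NULL,
                              generations = NULL, replicates = NULL,
                              n_animals = NULL, seed = 1L,
                              output_dir = NULL) {
  params <- load_parameter_set(parameter_set, check = FALSE)
  if (is.null(scenarios)) {
    if (!params$zone %in% builtin_parameter_sets())
      stop("scenarios must be supplied for custom parameter sets")
    scenarios <- builtin_scenarios(params$zone)
  }
  if (!length(scenarios)) stop("scenario list must not be empty")
  scenarios <- lapply(scenarios, validate_scenario, params = params)
  names(scenarios) <- vapply(scenarios, `[[`, "", "name")
  if (!is.null(generations) && generations < 1L)
    stop("generations must be >= 1")
  if (!is.null(replicates) && replicates < 1L)
    stop("replicates must be >= 1")
  structure(list(params = params, scenarios = scenarios,
                 generations = generations, replicates = replicates,
                 n_animals = n_animals, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "experiment_config")
}

#' Run a scenario-sweep experiment
#'
#' Runs every configured scenario with shared per-replicate seeds and
#' collects per-replicate results, per-generation trajectories and
#' per-scenario summaries.  With an output directory set, writes
#' \code{results.csv} (one row per scenario x replicate),
#' \code{summary.csv} (one row per scenario) and
#' \code{trajectories.csv}.
#'
#' @param config An \code{\link{experiment_config}} (or arguments to
#'   build one, passed through).
#' @param ... Forwarded to \code{experiment_config} when \code{config}
#'   is not already one.
#' @return An object of class \code{resilience_experiment}.
#' @export
run_experiment <- function(config, ...) {
  if (!inherits(config, "experiment_config"))
    config <- experiment_config(config, ...)
  runs <- lapply(config$scenarios, function(sc)
    run_scenario(config$params, sc,
                 generations = config$generations,
                 replicates = config$replicates,
                 n_animals = config$n_animals,
                 seed = config$seed))
  results <- do.call(rbind, lapply(runs, `[[`, "results"))
  rownames(results) <- NULL
  summaries <- do.call(rbind, lapply(runs, `[[`, "summary"))
  rownames(summaries) <- NULL
  traj <- do.call(rbind, lapply(names(runs), function(nm)
    cbind(scenario = nm, runs[[nm]]$trajectories)))
  out <- structure(list(zone = config$params$zone, runs = runs,
                        results = results, summary = summaries,
                        trajectories = traj, seed = config$seed),
                   class = "resilience_experiment")
  if (!is.null(config$output_dir)) write_experiment(out, config$output_dir)
  out
}

#' Write experiment tables to CSV
#'
#' @param x A \code{resilience_experiment}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_experiment <- function(x, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory '", dir, "'")
  paths <- file.path(dir, c("results.csv", "summary.csv",
                            "trajectories.csv"))
  utils::write.csv(x$results, paths[1L], row.names = FALSE)
  utils::write.csv(x$summary, paths[2L], row.names = FALSE)
  utils::write.csv(x$trajectories, paths[3L], row.names = FALSE)
  invisible(paths)
}

#' Export a replicate's pedigree as a 3-column text file
#'
#' @param run A \code{scenario_run} created with
#'   \code{record_pedigree = TRUE}.
#' @param path Output path (whitespace-separated id, sire, dam; 0 for
#'   founder parents).
#' @param replicate Which replicate's pedigree to write.
#' @return Invisibly, \code{path}.
#' @export
write_pedigree <- function(run, path, replicate = 1L) {
  ped <- run$pedigrees[[replicate]]
  if (is.null(ped))
    stop("run was not created with record_pedigree = TRUE")
  utils::write.table(ped, path, row.names = FALSE, col.names = TRUE,
                     quote = FALSE)
  invisible(path)
}

#' @export
print.resilience_experiment <- function(x, ...) {
  cat(sprintf("Experiment (%s): %d scenarios, seed %d\n", x$zone,
              length(x$runs), x$seed))
  cols <- intersect(c("scenario", "resilience_final_mean", "index0_mean",
                      "profit0_mean", "profit2_mean", "mean_f_final_mean"),
                    names(x$summary))
  print(x$summary[, cols], digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
summary.resilience_experiment <- function(object, ...) object$summary

#' Plot resilience trajectories of an experiment
#'
#' Mean resilience phenotype per generation, one line per scenario.
#'
#' @param x A \code{resilience_experiment}.
#' @param ... Passed to \code{matplot}.
#' @return Invisibly, the matrix of generation-by-scenario means.
#' @export
plot.resilience_experiment <- function(x, ...) {
  res_tr <- vapply(x$runs, `[[`, "", "resilience_trait")
  sc <- names(x$runs)
  gens <- sort(unique(x$trajectories$generation))
  m <- sapply(sc, function(s) {
    tr <- x$trajectories[x$trajectories$scenario == s, ]
    col <- paste0("mean_", res_tr[[s]])
    tapply(tr[[col]], tr$generation, mean)
  })
  graphics::matplot(gens, m, type = "l", lty = 1,
                    xlab = "generation",
                    ylab = "mean resilience phenotype", ...)
  graphics::legend("topleft", legend = sc, col = seq_along(sc), lty = 1,
                   cex = 0.7, bty = "n")
  invisible(m)
}
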