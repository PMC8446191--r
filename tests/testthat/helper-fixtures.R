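# Shared fixtures and small utilities for the suite.  Expensive full-size
# scenario runs are computed once per session and cached.

goat_params <- local({
  ps <- NULL
  function() {
    if (is.null(ps)) ps <<- load_parameter_set("atlantic-goat",
                                               check = FALSE)
    ps
  }
})

sheep_params <- local({
  ps <- NULL
  function() {
    if (is.null(ps)) ps <<- load_parameter_set("mediterranean-sheep",
                                               check = FALSE)
    ps
  }
})

# a small two-trait set with round numbers, used where the zone fixtures
# would only slow things down
tiny_params <- function(rho_g = 0.3, rho_e = 0, acc = c(A = 0.8, B = 0.6),
                        check = FALSE) {
  nm <- c("A", "B")
  cg <- matrix(c(1, rho_g, rho_g, 1), 2, dimnames = list(nm, nm))
  ce <- matrix(c(1, rho_e, rho_e, 1), 2, dimnames = list(nm, nm))
  parameter_set(
    zone = "custom",
    traits = list(
      trait_spec("A", "u", mean = 10, sd = sqrt(8), goal = "increase"),
      trait_spec("B", "u", mean = 0, sd = sqrt(5), goal = "increase")),
    covariance = covariance_spec(
      var_genetic = c(A = 4, B = 1),
      var_residual = c(A = 4, B = 4),
      cor_genetic = cg, cor_residual = ce,
      accuracies = acc),
    economics = economic_weights(values = c(A = 1, B = 2),
                                 climate_price = 1),
    program = breeding_program(n_animals = 40L, generations = 3L,
                               replicates = 2L, prop_male = 0.5,
                               prop_female = 0.5,
                               max_offspring_sire = 100L,
                               max_offspring_dam = 100L),
    base_weights = c(A = 0.5, B = 0.5),
    check = check)
}

# random-mating propagation (no selection): the first n_sires males and
# n_dams females breed each generation, with exact kinship tracking
random_mating_run <- function(params, n, generations, n_sires, n_dams) {
  ap <- active_parameters(params, "none")
  pop <- simulate_base_population(n, ap)
  kin <- NULL
  mean_tbv <- matrix(NA_real_, generations + 1L, ncol(pop$tbv),
                     dimnames = list(NULL, colnames(pop$tbv)))
  mean_f <- numeric(generations + 1L)
  mean_tbv[1L, ] <- colMeans(pop$tbv)
  for (g in seq_len(generations)) {
    si <- which(pop$sex == "M")[seq_len(n_sires)]
    di <- which(pop$sex == "F")[seq_len(n_dams)]
    sel <- c(si, di)
    kin_new <- if (is.null(kin)) founder_kinship(pop$f[sel]) else
      offspring_kinship(kin, attr(pop, "sire_slot")[sel],
                        attr(pop, "dam_slot")[sel],
                        n_sires = attr(kin, "n_sires"))
    attr(kin_new, "n_sires") <- n_sires
    pop <- breed_generation(subset_population(pop, si),
                            subset_population(pop, di),
                            n, caps = c(sire = n, dam = n), params = ap,
                            parent_kinship = kin_new,
                            id_start = g * n + 1L)
    kin <- kin_new
    mean_tbv[g + 1L, ] <- colMeans(pop$tbv)
    mean_f[g + 1L] <- mean(pop$f)
  }
  list(mean_tbv = mean_tbv, mean_f = mean_f)
}

# full-size scenario runs at the packaged study conditions (1,000
# animals, 20 generations, 20 replicates), shared across test files
run_cache <- new.env(parent = emptyenv())

cached_full_run <- function(zone, scenario_name, seed = 42L) {
  key <- paste(zone, scenario_name, seed)
  if (is.null(run_cache[[key]])) {
    ps <- load_parameter_set(zone, check = FALSE)
    sc <- builtin_scenarios(zone)[[scenario_name]]
    run_cache[[key]] <- run_scenario(ps, sc, seed = seed)
  }
  run_cache[[key]]
}
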