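#' Names of the built-in parameter sets
#'
#' \code{"atlantic-goat"}: a UK-style dairy goat programme (daily milk
#' yield, productive life, age at first kidding, mastitis incidence, and
#' the slope of milk yield on daily temperature as resilience, with the
#' absolute slope as an alternative stability trait).
#' \code{"mediterranean-sheep"}: a Spanish dairy sheep programme (milk,
#' fat and protein yields, fertility, and the slope of protein yield
#' under heat stress as resilience; stability shares the slope's
#' parameters).
#'
#' @return Character vector of fixture names.
#' @export
builtin_parameter_sets <- function() c("atlantic-goat", "mediterranean-sheep")

.sym <- function(nm, pairs) {
  m <- diag(length(nm))
  dimnames(m) <- list(nm, nm)
  for (p in pairs) m[p[[1L]], p[[2L]]] <- m[p[[2L]], p[[1L]]] <- p[[3L]]
  m
}

# Atlantic dairy goats.  Variances on the diagonal, correlations off it;
# the actual slope (Res) and its absolute value (Stab) are alternative
# resilience definitions with no mutual correlation (never co-selected).
.goat_params <- function(check = TRUE) {
  nm <- c("DMY", "Long", "KA", "Mast", "Res", "Stab")
  cg <- .sym(nm, list(
    list("DMY", "Long", 0.276), list("DMY", "KA", -0.127),
    list("DMY", "Mast", 0.495), list("DMY", "Res", 0.032),
    list("DMY", "Stab", 0.422),
    list("Long", "KA", -0.003), list("Long", "Mast", -0.429),
    list("Long", "Res", -0.109), list("Long", "Stab", -0.119),
    list("KA", "Mast", 0.075), list("KA", "Res", 0.112),
    list("KA", "Stab", -0.033),
    list("Mast", "Res", 0.067), list("Mast", "Stab", 0.253)))
  ce <- .sym(nm, list(
    list("DMY", "Long", 0.118), list("DMY", "KA", 0.109),
    list("DMY", "Mast", -0.076), list("DMY", "Res", 0.009),
    list("DMY", "Stab", 0.088),
    list("Long", "KA", 0.0144), list("Long", "Mast", -0.074),
    list("Long", "Res", 0.078), list("Long", "Stab", -0.011),
    list("KA", "Mast", 0.035), list("KA", "Res", 0.043),
    list("KA", "Stab", 0.052),
    list("Mast", "Res", 0.012), list("Mast", "Stab", 0.017)))
  cg["Res", "Stab"] <- cg["Stab", "Res"] <- NA
  ce["Res", "Stab"] <- ce["Stab", "Res"] <- NA
  cov <- covariance_spec(
    var_genetic = c(DMY = 0.370, Long = 11282, KA = 2.72, Mast = 0.002,
                    Res = 0.0002, Stab = 0.0001),
    var_residual = c(DMY = 0.570, Long = 101850, KA = 5.880, Mast = 0.122,
                     Res = 0.002, Stab = 0.001),
    cor_genetic = cg, cor_residual = ce,
    accuracies = c(DMY = 0.62, Long = 0.51, KA = 0.60, Mast = 0.40,
                   Res = 0.51, Stab = 0.51))
  traits <- list(
    trait_spec("DMY", "kg/day", mean = 3.59, sd = 1.05,
               bounds = c(0.42, 6.81), goal = "increase"),
    trait_spec("Long", "days", mean = 962, sd = 618.9,
               bounds = c(91, 3584), goal = "increase"),
    # kidding age is stabilized toward the biologically desired 12 months
    trait_spec("KA", "months", mean = 14.8, sd = 3.08, bounds = c(9, 39),
               goal = "stabilize", target = 12),
    # mastitis incidence is held at its current (manageable) level
    trait_spec("Mast", "0/1", mean = 0.14, sd = 0.35, bounds = c(0, 1),
               scale = "binary-threshold", goal = "stabilize",
               target = 0.14),
    # resilience objective: a milk-yield slope of zero on temperature
    trait_spec("Res", "kg/degC/day", mean = 0.03, sd = 0.05,
               bounds = c(-0.17, 0.37), goal = "stabilize", target = 0,
               role = "resilience-actual"),
    # |slope| has no published descriptive row; mean/SD derived from the
    # folded normal of the slope's distribution (synthetic, see vignette)
    trait_spec("Stab", "kg/degC/day", mean = 0.047, sd = 0.035,
               bounds = c(0, 0.37), goal = "decrease",
               role = "resilience-absolute"))
  parameter_set(
    zone = "atlantic-goat", traits = traits, covariance = cov,
    economics = economic_weights(
      values = c(DMY = 0.73, Long = 0.055, KA = -0.16, Mast = -231),
      climate_price = 0.73),
    program = breeding_program(n_animals = 1000L, generations = 20L,
                               replicates = 20L, prop_male = 0.30,
                               prop_female = 0.50),
    base_weights = c(DMY = 5, Long = 31.25, KA = 18.75, Mast = 45),
    check = check)
}

# Mediterranean dairy sheep.  Residual correlations were not estimated
# (zero here); fertility is recorded as a proportion in [0, 1]; the
# stability (absolute slope) alternative shares the slope's parameters,
# so absolute-mode runs reuse the Res trait with a stabilize-at-zero goal.
.sheep_params <- function(check = TRUE) {
  nm <- c("DMY", "DFY", "DPY", "Fert", "Res")
  cg <- .sym(nm, list(
    list("DMY", "DFY", 0.687), list("DMY", "DPY", 0.724),
    list("DMY", "Fert", -0.118), list("DMY", "Res", -0.158),
    list("DFY", "DPY", 0.914), list("DFY", "Fert", -0.183),
    list("DFY", "Res", -0.126),
    list("DPY", "Fert", -0.169), list("DPY", "Res", -0.111),
    list("Fert", "Res", 0.175)))
  ce <- .sym(nm, list())
  cov <- covariance_spec(
    var_genetic = c(DMY = 0.051, DFY = 128.03, DPY = 82.523,
                    Fert = 0.501, Res = 0.020),
    var_residual = c(DMY = 0.204, DFY = 405.4, DPY = 192.6,
                     Fert = 2.836, Res = 0.381),
    cor_genetic = cg, cor_residual = ce,
    accuracies = c(DMY = 0.60, DFY = 0.60, DPY = 0.65, Fert = 0.35,
                   Res = 0.50))
  traits <- list(
    trait_spec("DMY", "kg/day", mean = 1.30, sd = 0.68,
               bounds = c(0.20, 9.78), goal = "increase"),
    trait_spec("DFY", "g/day", mean = 84.2, sd = 42.6,
               bounds = c(12, 340), goal = "increase"),
    trait_spec("DPY", "g/day", mean = 67.9, sd = 34.5,
               bounds = c(12, 240), goal = "increase"),
    trait_spec("Fert", "proportion", mean = 0.42, sd = 0.49,
               bounds = c(0, 1), scale = "binary-threshold",
               goal = "increase"),
    # Mediterranean objective: push the heat-stress slope toward positive
    trait_spec("Res", "g/degC/day", mean = -0.70, sd = 1.28,
               bounds = c(-1.30, 1.14), goal = "increase",
               role = "resilience-actual"))
  parameter_set(
    zone = "mediterranean-sheep", traits = traits, covariance = cov,
    economics = economic_weights(
      values = c(DMY = 0.73, DFY = 0.072, DPY = 0.076, Fert = 137.6),
      climate_price = 0.076),
    program = breeding_program(n_animals = 1000L, generations = 20L,
                               replicates = 20L, prop_male = 0.10,
                               prop_female = 0.50),
    base_weights = c(DMY = 43.75, DFY = 21.875, DPY = 21.875,
                     Fert = 12.5),
    inbreeding_depression = list(trait = "Fert", slope = 0.5),
    check = check)
}

.builtin_params <- function(name, check = TRUE) {
  switch(name,
         "atlantic-goat" = .goat_params(check = check),
         "mediterranean-sheep" = .sheep_params(check = check),
         stop("unknown built-in parameter set: ", name))
}
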