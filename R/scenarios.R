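#' Define a breeding scenario
#'
#' A scenario is a vector of relative selection-index weights over the
#' traits active in a run, together with the resilience definition in
#' force: \code{"none"} (conventional programme, slope carried with zero
#' weight for reporting only), \code{"actual"} (the slope itself is in
#' the index) or \code{"absolute"} (the absolute value of the slope,
#' i.e. stability, is in the index).
#'
#' @param name Scenario identifier.
#' @param weights Named non-negative weights; accepted on the 0-100
#'   (percent) or 0-1 scale and normalized internally to sum to 1.
#' @param resilience_mode \code{"none"}, \code{"actual"} or
#'   \code{"absolute"}.
#' @return An object of class \code{scenario_spec}.
#' @export
scenario_spec <- function(name, weights,
                          resilience_mode = c("none", "actual",
                                              "absolute")) {
  resilience_mode <- match.arg(resilience_mode)
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("weights must be a fully named numeric vector")
  if (any(!is.finite(weights)))
    stop("weights must be finite")
  if (any(weights < 0))
    stop("negative index weight on trait(s): ",
         paste(names(weights)[weights < 0], collapse = ", "))
  if (sum(weights) <= 0)
    stop("weights must not all be zero")
  structure(list(name = name, weights = weights / sum(weights),
                 resilience_mode = resilience_mode),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Scenario", x$name, "(resilience mode:", x$resilience_mode, ")\n")
  w <- sprintf("%s %.4g%%", names(x$weights), 100 * x$weights)
  cat(" ", paste(w, collapse = ", "), "\n")
  invisible(x)
}

#' Validate a scenario against a parameter set
#'
#' Checks that every weighted trait exists, that at most one resilience
#' definition carries weight, and that the declared resilience mode is
#' consistent with which resilience trait is weighted.  Weights are
#' re-normalized to sum to exactly 1.
#'
#' @param spec A \code{\link{scenario_spec}}.
#' @param params A \code{\link{parameter_set}}.
#' @return The validated (normalized) \code{scenario_spec}.
#' @export
validate_scenario <- function(spec, params) {
  if (!inherits(spec, "scenario_spec"))
    spec <- do.call(scenario_spec, spec)
  nm <- names(params$traits)
  unknown <- setdiff(names(spec$weights), nm)
  if (length(unknown))
    stop("scenario '", spec$name, "' weights unknown trait(s): ",
         paste(unknown, collapse = ", "))
  roles <- vapply(params$traits, `[[`, "", "role")
  res_all <- nm[roles != "production"]
  w_res <- spec$weights[intersect(names(spec$weights), res_all)]
  weighted_res <- names(w_res)[w_res > 0]
  if (length(weighted_res) > 1L)
    stop("scenario '", spec$name, "' weights both resilience definitions (",
         paste(weighted_res, collapse = ", "),
         "); they are never co-selected")
  if (spec$resilience_mode == "none" && length(weighted_res))
    stop("scenario '", spec$name,
         "' has resilience mode 'none' but weights ", weighted_res)
  # a mode other than "none" with zero resilience weight is a
  # reporting-only control of that resilience definition and is allowed
  if (length(weighted_res)) {
    role <- roles[weighted_res]
    ap <- active_parameters(params, spec$resilience_mode)
    if (!weighted_res %in% names(ap$traits))
      stop("scenario '", spec$name, "' weights the ", role,
           " trait but declares mode '", spec$resilience_mode, "'")
  }
  spec$weights <- spec$weights / sum(spec$weights)
  spec
}

# scenario family builder: resilience takes w_res (percent), production
# weights keep their mutual ratios
.scaled_scenario <- function(name, prod_w, res_trait, w_res, mode) {
  w <- prod_w / sum(prod_w) * (100 - w_res)
  w[res_trait] <- w_res
  scenario_spec(name, w, resilience_mode = mode)
}

#' Built-in scenario grids for the two packaged programmes
#'
#' Reconstructs the scenario families evaluated for each zone.  In both,
#' the Base scenario excludes resilience; further scenarios move 10-40\%
#' (goats) or 10-30\% (sheep) of the index onto the resilience trait
#' while the production-trait weights keep their Base ratios.  The goat
#' list additionally carries the stability (absolute-slope) family,
#' including the variants that fix the milk-yield weight at 14\% with the
#' remaining weight split in the 20:12:44 ratio over productive life,
#' kidding age and mastitis.
#'
#' @param zone A built-in zone name (see
#'   \code{\link{builtin_parameter_sets}}).
#' @return Named list of \code{\link{scenario_spec}} objects.
#' @export
builtin_scenarios <- function(zone) {
  zone <- match.arg(zone, builtin_parameter_sets())
  if (zone == "atlantic-goat") {
    prod <- c(DMY = 5, Long = 31.25, KA = 18.75, Mast = 45)
    sc <- list(
      Base = scenario_spec("Base", prod, "none"),
      S1 = .scaled_scenario("S1", prod, "Res", 10, "actual"),
      S2 = .scaled_scenario("S2", prod, "Res", 20, "actual"),
      S3 = .scaled_scenario("S3", prod, "Res", 30, "actual"),
      S4 = .scaled_scenario("S4", prod, "Res", 40, "actual"),
      Base2 = scenario_spec("Base2", prod, "absolute"),
      S5 = .scaled_scenario("S5", prod, "Stab", 20, "absolute"),
      S6 = .scaled_scenario("S6", prod, "Stab", 40, "absolute"))
    milky <- function(name, w_res) {
      rest <- (100 - 14 - w_res) * c(Long = 20, KA = 12, Mast = 44) / 76
      scenario_spec(name, c(DMY = 14, rest, Stab = w_res), "absolute")
    }
    sc$S7 <- milky("S7", 5)
    sc$S8 <- milky("S8", 10)   # weights 14/20/12/44/10
    sc$S9 <- milky("S9", 20)
    sc$S10 <- milky("S10", 30)
    sc$S11 <- milky("S11", 40)
    sc
  } else {
    prod <- c(DMY = 43.75, DFY = 21.875, DPY = 21.875, Fert = 12.5)
    list(
      Base = scenario_spec("Base", prod, "none"),
      S1 = .scaled_scenario("S1", prod, "Res", 10, "actual"),
      S2 = .scaled_scenario("S2", prod, "Res", 20, "actual"),
      S3 = .scaled_scenario("S3", prod, "Res", 30, "actual"),
      S4 = scenario_spec("S4", prod, "absolute"),
      S5 = .scaled_scenario("S5", prod, "Res", 10, "absolute"),
      S6 = .scaled_scenario("S6", prod, "Res", 20, "absolute"),
      S7 = .scaled_scenario("S7", prod, "Res", 30, "absolute"))
  }
}
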