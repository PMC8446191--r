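#' Define a simulated trait
#'
#' A trait is simulated on a continuous scale as phenotype = base mean +
#' true breeding value + environmental deviation.  Traits recorded as 0/1
#' in the field (mastitis incidence, fertility) use
#' \code{scale = "binary-threshold"}: simulation and selection operate on
#' the continuous underlying scale, and incidences are reported by
#' thresholding at the quantile matching the base incidence.
#'
#' @param name Trait identifier (e.g. \code{"DMY"}).
#' @param units Free-text units, e.g. \code{"kg/day"}.
#' @param mean Base-population phenotypic mean.
#' @param sd Base-population phenotypic standard deviation (must be > 0).
#' @param bounds Optional length-2 numeric \code{c(min, max)}; must bracket
#'   \code{mean}.  Used for validation only, phenotypes are not clamped.
#' @param scale \code{"continuous"} or \code{"binary-threshold"}.
#' @param goal Desired direction of selection: \code{"increase"},
#'   \code{"decrease"} or \code{"stabilize"} (toward \code{target}).
#' @param target Target phenotypic value, required when
#'   \code{goal = "stabilize"}.
#' @param role \code{"production"} for ordinary breeding-goal traits,
#'   \code{"resilience-actual"} for the slope of production on
#'   temperature, \code{"resilience-absolute"} for the absolute value of
#'   that slope (stability).
#' @return An object of class \code{trait_spec}.
#' @export
trait_spec <- function(name, units = "", mean, sd, bounds = NULL,
                       scale = c("continuous", "binary-threshold"),
                       goal = c("increase", "decrease", "stabilize"),
                       target = NULL,
                       role = c("production", "resilience-actual",
                                "resilience-absolute")) {
  scale <- match.arg(scale)
  goal <- match.arg(goal)
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0)
    stop("trait '", name, "': phenotypic sd must be a positive number")
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean))
    stop("trait '", name, "': phenotypic mean must be a finite number")
  if (!is.null(bounds)) {
    bounds <- as.numeric(bounds)
    if (length(bounds) != 2L || bounds[1L] >= bounds[2L])
      stop("trait '", name, "': bounds must satisfy min < max")
    if (mean < bounds[1L] || mean > bounds[2L])
      stop("trait '", name, "': bounds must contain the phenotypic mean")
  }
  if (goal == "stabilize") {
    if (is.null(target) || !is.finite(target))
      stop("trait '", name, "': stabilizing goal requires a finite target")
  } else if (!is.null(target)) {
    stop("trait '", name, "': target is only meaningful for goal 'stabilize'")
  }
  structure(list(name = name, units = units, mean = mean, sd = sd,
                 bounds = bounds, scale = scale, goal = goal,
                 target = target, role = role),
            class = "trait_spec")
}

#' Assemble a covariance matrix from variances and correlations
#'
#' Builds \code{Sigma[i, j] = rho[i, j] * sqrt(v[i] * v[j])} and, when the
#' result is indefinite through rounding of published estimates, repairs
#' it to the nearest positive semi-definite matrix by eigenvalue clipping
#' (see \code{\link{nearest_psd}}).  A matrix whose smallest eigenvalue is
#' below \code{-0.05} times the largest is considered irreparably
#' indefinite and raises an error.
#'
#' @param variances Named positive numeric vector of per-trait variances.
#' @param correlations Symmetric correlation matrix (unit diagonal,
#'   entries in [-1, 1]) with dimnames matching \code{variances}.
#' @param repair Apply the PSD repair if needed (default \code{TRUE}).
#' @param tol Eigenvalue tolerance below which repair is triggered.
#' @return Symmetric positive semi-definite covariance matrix.
#' @export
assemble_covariance <- function(variances, correlations, repair = TRUE,
                                tol = 1e-8) {
  if (is.null(names(variances)))
    stop("variances must be named")
  if (any(!is.finite(variances)) || any(variances <= 0))
    stop("variances must be positive and finite")
  k <- length(variances)
  correlations <- as.matrix(correlations)
  if (!identical(dim(correlations), c(k, k)))
    stop("correlation matrix dimension does not match the variances")
  if (is.null(dimnames(correlations)))
    dimnames(correlations) <- list(names(variances), names(variances))
  correlations <- correlations[names(variances), names(variances)]
  if (anyNA(correlations))
    stop("correlation matrix contains missing entries for traits: ",
         paste(names(variances)[apply(is.na(correlations), 1L, any)],
               collapse = ", "))
  if (max(abs(correlations - t(correlations))) > 1e-10)
    stop("correlation matrix is not symmetric")
  if (any(abs(correlations) > 1 + 1e-12))
    stop("correlations must lie in [-1, 1]")
  if (max(abs(diag(correlations) - 1)) > 1e-12)
    stop("correlation matrix must have a unit diagonal")
  s <- sqrt(variances)
  sigma <- correlations * tcrossprod(s)
  diag(sigma) <- variances
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -0.05 * max(ev))
    stop("covariance matrix is indefinite beyond repair (min eigenvalue ",
         signif(min(ev), 3), ")")
  if (min(ev) < -tol) {
    if (!repair)
      stop("covariance matrix is not positive semi-definite ",
           "(min eigenvalue ", signif(min(ev), 3), ") and repair is disabled")
    sigma <- nearest_psd(sigma, tol = tol)
    message("covariance matrix repaired to nearest PSD ",
            "(min eigenvalue was ", signif(min(ev), 3), ")")
  }
  sigma
}

#' Nearest positive semi-definite repair by eigenvalue clipping
#'
#' Negative eigenvalues are clipped to zero, the matrix is reconstructed,
#' and rows/columns are rescaled so the original diagonal (the published
#' variances) is preserved.
#'
#' @param x Symmetric matrix.
#' @param tol Eigenvalues below \code{-tol} trigger clipping.
#' @return Positive semi-definite matrix with the diagonal of \code{x}.
#' @export
nearest_psd <- function(x, tol = 1e-8) {
  x <- (x + t(x)) / 2
  e <- eigen(x, symmetric = TRUE)
  if (min(e$values) >= -tol) return(x)
  lam <- pmax(e$values, 0)
  y <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(diag(x) / pmax(diag(y), .Machine$double.eps))
  y <- y * tcrossprod(d)
  diag(y) <- diag(x)
  dimnames(y) <- dimnames(x)
  (y + t(y)) / 2
}

#' Covariance structure of the simulated traits
#'
#' Holds per-trait genetic and residual variances, the two correlation
#' matrices, and the accuracy of genetic evaluation for each trait.
#' Correlations between the two alternative resilience definitions
#' (actual slope vs absolute slope) may be \code{NA}: the two are never
#' simulated together.
#'
#' @param var_genetic,var_residual Named positive numeric vectors.
#' @param cor_genetic,cor_residual Symmetric correlation matrices with
#'   matching dimnames; \code{NA} allowed only between the two resilience
#'   variants.
#' @param accuracies Named numeric vector with entries in (0, 1].
#' @return An object of class \code{covariance_spec}.
#' @export
covariance_spec <- function(var_genetic, var_residual, cor_genetic,
                            cor_residual, accuracies) {
  nm <- names(var_genetic)
  if (is.null(nm)) stop("var_genetic must be named")
  for (v in list(var_residual, accuracies)) {
    if (!identical(sort(names(v)), sort(nm)))
      stop("all covariance components must cover the same traits")
  }
  if (any(accuracies <= 0) || any(accuracies > 1))
    stop("accuracies must lie in (0, 1]")
  if (any(var_genetic <= 0) || any(var_residual <= 0))
    stop("variances must be positive")
  chk <- function(m, what) {
    m <- as.matrix(m)
    if (!identical(sort(rownames(m)), sort(nm)))
      stop(what, " correlation matrix must cover the same traits")
    m <- m[nm, nm]
    if (max(abs(m - t(m)), na.rm = TRUE) > 1e-10)
      stop(what, " correlation matrix is not symmetric")
    if (any(abs(m) > 1 + 1e-12, na.rm = TRUE))
      stop(what, " correlations must lie in [-1, 1]")
    m
  }
  structure(list(var_genetic = var_genetic[nm],
                 var_residual = var_residual[nm],
                 cor_genetic = chk(cor_genetic, "genetic"),
                 cor_residual = chk(cor_residual, "residual"),
                 accuracies = accuracies[nm]),
            class = "covariance_spec")
}

#' Economic values for a breeding programme
#'
#' @param values Named numeric vector, euros per unit of realized gain in
#'   each non-resilience trait.  Signs encode desirability (negative for
#'   mastitis incidence and kidding age).
#' @param climate_price Euros per unit of the resilience slope: the milk
#'   price for the goat programme, the protein price for the sheep one.
#' @return An object of class \code{economic_weights}.
#' @export
economic_weights <- function(values, climate_price) {
  if (is.null(names(values)) || any(!is.finite(values)))
    stop("economic values must be a named finite numeric vector")
  if (!is.finite(climate_price))
    stop("climate_price must be finite")
  structure(list(values = values, climate_price = climate_price),
            class = "economic_weights")
}

#' Breeding-programme structure
#'
#' @param n_animals Animals per generation (default 1000, half of each sex).
#' @param generations Number of discrete (non-overlapping) generations.
#' @param replicates Number of Monte-Carlo replicates.
#' @param prop_male,prop_female Selected proportion of each sex, in (0, 1].
#' @param max_offspring_sire,max_offspring_dam Offspring caps per parent.
#' @return A plain list with class \code{breeding_program}.
#' @export
breeding_program <- function(n_animals = 1000L, generations = 20L,
                             replicates = 20L, prop_male, prop_female,
                             max_offspring_sire = 100L,
                             max_offspring_dam = 7L) {
  if (n_animals < 2L || n_animals %% 2L != 0L)
    stop("n_animals must be an even number >= 2")
  if (generations < 1L) stop("generations must be >= 1")
  if (replicates < 1L) stop("replicates must be >= 1")
  for (p in c(prop_male, prop_female))
    if (!is.finite(p) || p <= 0 || p > 1)
      stop("selected proportions must lie in (0, 1]")
  structure(list(n_animals = as.integer(n_animals),
                 generations = as.integer(generations),
                 replicates = as.integer(replicates),
                 prop_male = prop_male, prop_female = prop_female,
                 max_offspring_sire = as.integer(max_offspring_sire),
                 max_offspring_dam = as.integer(max_offspring_dam)),
            class = "breeding_program")
}

#' Assemble and validate a complete parameter set
#'
#' A parameter set is one climate-zone case: the ordered trait list, the
#' genetic/residual covariance structure and evaluation accuracies, the
#' economic values, the breeding-programme structure, the Base-scenario
#' index weights (used for the Index0 progress statistic) and, for the
#' sheep case, the linear inbreeding-depression slope on fertility.
#'
#' @param zone Identifier, e.g. \code{"atlantic-goat"} or \code{"custom"}.
#' @param traits List of \code{\link{trait_spec}} objects (order is kept).
#' @param covariance A \code{\link{covariance_spec}}.
#' @param economics An \code{\link{economic_weights}}.
#' @param program A \code{\link{breeding_program}}.
#' @param base_weights Named weights of the Base scenario over the
#'   non-resilience traits (normalized internally to sum to 1).
#' @param inbreeding_depression Named list \code{list(trait =, slope =)}
#'   or \code{NULL}; the named trait's phenotype is reduced by
#'   \code{slope * F} per individual.
#' @param check Cross-check Table-style phenotypic SDs against
#'   \code{sqrt(var_g + var_e)} and warn on >15\% disagreement.
#' @return An object of class \code{parameter_set}.
#' @export
parameter_set <- function(zone, traits, covariance, economics, program,
                          base_weights, inbreeding_depression = NULL,
                          check = TRUE) {
  if (!length(traits)) stop("trait list must not be empty")
  if (!all(vapply(traits, inherits, TRUE, "trait_spec")))
    stop("traits must be a list of trait_spec objects")
  nm <- vapply(traits, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicated trait names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  names(traits) <- nm
  if (!inherits(covariance, "covariance_spec"))
    stop("covariance must be a covariance_spec")
  if (!identical(sort(names(covariance$var_genetic)), sort(nm)))
    stop("covariance does not cover exactly the declared traits; missing: ",
         paste(setdiff(nm, names(covariance$var_genetic)), collapse = ", "))
  if (!inherits(economics, "economic_weights"))
    stop("economics must be an economic_weights object")
  if (!inherits(program, "breeding_program"))
    stop("program must be a breeding_program object")
  roles <- vapply(traits, `[[`, "", "role")
  non_res <- nm[roles == "production"]
  bw <- base_weights[non_res]
  if (anyNA(bw))
    stop("base_weights must name every non-resilience trait")
  if (any(bw < 0) || sum(bw) <= 0)
    stop("base_weights must be non-negative and not all zero")
  bw <- bw / sum(bw)
  if (!is.null(inbreeding_depression)) {
    if (!all(c("trait", "slope") %in% names(inbreeding_depression)) ||
        !inbreeding_depression$trait %in% nm)
      stop("inbreeding_depression must be list(trait =, slope =) on a ",
           "declared trait")
  }

  ps <- structure(list(zone = zone, traits = traits,
                       covariance = covariance, economics = economics,
                       program = program, base_weights = bw,
                       inbreeding_depression = inbreeding_depression),
                  class = "parameter_set")
  # validate that each runnable trait subset assembles to a PSD matrix
  modes <- "none"
  if (any(roles == "resilience-actual")) modes <- c(modes, "actual")
  if (any(roles != "production")) modes <- c(modes, "absolute")
  for (mode in unique(modes))
    active_parameters(ps, mode)
  if (check) check_phenotypic_consistency(ps)
  ps
}

#' Cross-check phenotypic SDs against variance components
#'
#' Warns (never errors) for every trait whose stated phenotypic SD
#' disagrees with \code{sqrt(var_genetic + var_residual)} by more than
#' \code{tol} relative.  Published descriptive tables and variance
#' components often come from different data edits, so disagreement is
#' reported rather than rejected.
#'
#' @param params A \code{\link{parameter_set}}.
#' @param tol Relative tolerance (default 0.15).
#' @return Invisibly, a named logical vector (TRUE = consistent).
#' @export
check_phenotypic_consistency <- function(params, tol = 0.15) {
  nm <- names(params$traits)
  sd_tab <- vapply(params$traits, `[[`, 0, "sd")
  sd_cmp <- sqrt(params$covariance$var_genetic[nm] +
                 params$covariance$var_residual[nm])
  ok <- abs(sd_cmp - sd_tab) <= tol * sd_tab
  if (any(!ok)) {
    bad <- nm[!ok]
    warning(sprintf(paste0(
      "phenotypic SD inconsistent with variance components (>%.0f%%) ",
      "for: %s"), 100 * tol,
      paste(sprintf("%s (stated %.3g, implied %.3g)", bad, sd_tab[!ok],
                    sd_cmp[!ok]), collapse = ", ")), call. = FALSE)
  }
  invisible(ok)
}

#' Restrict a parameter set to the traits active under a resilience mode
#'
#' Exactly one resilience definition is ever simulated: under
#' \code{"actual"} (and \code{"none"}, where the slope is carried with
#' zero weight for reporting) the actual-slope trait is kept and any
#' absolute-slope trait dropped; under \code{"absolute"} the
#' absolute-slope trait is kept if the zone defines one (goats), else the
#' actual-slope trait is retained with its goal rewritten to stabilize at
#' zero (sheep, where stability shares the slope's parameters).
#'
#' @param params A \code{\link{parameter_set}}.
#' @param resilience_mode \code{"none"}, \code{"actual"} or
#'   \code{"absolute"}.
#' @return A \code{parameter_set} restricted to the active traits, with
#'   attributes \code{resilience_trait} (name) and precomputed genetic and
#'   residual covariance matrices (\code{G0}, \code{E}) and binary
#'   thresholds.
#' @export
active_parameters <- function(params,
                              resilience_mode = c("none", "actual",
                                                  "absolute")) {
  resilience_mode <- match.arg(resilience_mode)
  roles <- vapply(params$traits, `[[`, "", "role")
  keep <- names(roles)[roles == "production"]
  if (all(roles == "production")) {
    # plain multi-trait set without a resilience definition
    traits <- params$traits
    res <- NA_character_
  } else if (resilience_mode %in% c("none", "actual")) {
    res <- names(roles)[roles == "resilience-actual"]
    if (!length(res)) stop("parameter set defines no actual-slope trait")
    traits <- params$traits[c(keep, res)]
  } else {
    res <- names(roles)[roles == "resilience-absolute"]
    if (length(res)) {
      traits <- params$traits[c(keep, res)]
    } else {
      res <- names(roles)[roles == "resilience-actual"]
      if (!length(res)) stop("parameter set defines no resilience trait")
      traits <- params$traits[c(keep, res)]
      traits[[res]]$goal <- "stabilize"
      traits[[res]]$target <- 0
    }
  }
  if (!is.na(res[1L]) && length(res) != 1L)
    stop("exactly one resilience trait must be active, found ", length(res))
  res <- res[1L]
  nm <- names(traits)
  cv <- params$covariance
  G0 <- assemble_covariance(cv$var_genetic[nm], cv$cor_genetic[nm, nm])
  E <- assemble_covariance(cv$var_residual[nm], cv$cor_residual[nm, nm])
  out <- params
  out$traits <- traits
  out$resilience_trait <- res
  out$resilience_mode <- resilience_mode
  out$G0 <- G0
  out$E <- E
  out$thresholds <- .binary_thresholds(traits, cv)
  class(out) <- c("active_parameter_set", "parameter_set")
  out
}

# fixed thresholds giving the base incidence on the continuous scale
.binary_thresholds <- function(traits, cv) {
  th <- rep(NA_real_, length(traits))
  names(th) <- names(traits)
  for (nm in names(traits)) {
    tr <- traits[[nm]]
    if (tr$scale == "binary-threshold") {
      s <- sqrt(cv$var_genetic[nm] + cv$var_residual[nm])
      th[nm] <- tr$mean + stats::qnorm(1 - tr$mean) * s
    }
  }
  th
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("Parameter set:", x$zone, "\n")
  cat("  traits:", paste(names(x$traits), collapse = ", "), "\n")
  roles <- vapply(x$traits, `[[`, "", "role")
  cat("  resilience:",
      paste(names(roles)[roles != "production"], collapse = ", "), "\n")
  p <- x$program
  cat(sprintf("  programme: %d animals, %d generations, %d replicates\n",
              p$n_animals, p$generations, p$replicates))
  cat(sprintf("  selection: best %.0f%% males / %.0f%% females; caps %d/%d\n",
              100 * p$prop_male, 100 * p$prop_female,
              p$max_offspring_sire, p$max_offspring_dam))
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

.cor_to_pairs <- function(m) {
  nm <- rownames(m)
  out <- list()
  for (i in seq_len(nrow(m) - 1L))
    for (j in (i + 1L):ncol(m)) {
      if (is.na(m[i, j])) next
      out[[length(out) + 1L]] <-
        list(traits = c(nm[i], nm[j]), value = m[i, j])
    }
  out
}

.pairs_to_cor <- function(pairs, nm) {
  m <- diag(length(nm))
  dimnames(m) <- list(nm, nm)
  m[upper.tri(m)] <- NA
  m[lower.tri(m)] <- NA
  diag(m) <- 1
  for (p in pairs) {
    i <- p$traits[[1L]]; j <- p$traits[[2L]]
    m[i, j] <- m[j, i] <- p$value
  }
  m
}

#' Write a parameter set to a YAML configuration file
#'
#' The file round-trips: \code{\link{load_parameter_set}} on the result
#' reproduces the original object.
#'
#' @param params A \code{\link{parameter_set}}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_parameter_set <- function(params, path) {
  tr <- lapply(params$traits, function(t) {
    l <- list(name = t$name, units = t$units, mean = t$mean, sd = t$sd,
              scale = t$scale, goal = t$goal, role = t$role)
    if (!is.null(t$bounds)) l$bounds <- as.list(t$bounds)
    if (!is.null(t$target)) l$target <- t$target
    l
  })
  cv <- params$covariance
  doc <- list(
    zone = params$zone,
    traits = unname(tr),
    covariance = list(
      var_genetic = as.list(cv$var_genetic),
      var_residual = as.list(cv$var_residual),
      cor_genetic = .cor_to_pairs(cv$cor_genetic),
      cor_residual = .cor_to_pairs(cv$cor_residual),
      accuracies = as.list(cv$accuracies)),
    economics = list(values = as.list(params$economics$values),
                     climate_price = params$economics$climate_price),
    program = unclass(params$program),
    base_weights = as.list(params$base_weights),
    inbreeding_depression = params$inbreeding_depression)
  writeLines(yaml::as.yaml(doc, precision = 15L), path)
  invisible(path)
}

.params_from_list <- function(doc, check = TRUE) {
  req <- c("zone", "traits", "covariance", "economics", "program",
           "base_weights")
  miss <- setdiff(req, names(doc))
  if (length(miss))
    stop("parameter configuration lacks field(s): ",
         paste(miss, collapse = ", "))
  if (!length(doc$traits)) stop("trait list must not be empty")
  traits <- lapply(doc$traits, function(t)
    trait_spec(name = t$name, units = t$units %||% "", mean = t$mean,
               sd = t$sd, bounds = if (!is.null(t$bounds)) unlist(t$bounds),
               scale = t$scale %||% "continuous",
               goal = t$goal %||% "increase", target = t$target,
               role = t$role %||% "production"))
  nm <- vapply(traits, `[[`, "", "name")
  cv <- doc$covariance
  covariance <- covariance_spec(
    var_genetic = unlist(cv$var_genetic)[nm],
    var_residual = unlist(cv$var_residual)[nm],
    cor_genetic = .pairs_to_cor(cv$cor_genetic, nm),
    cor_residual = .pairs_to_cor(cv$cor_residual, nm),
    accuracies = unlist(cv$accuracies)[nm])
  parameter_set(
    zone = doc$zone, traits = traits, covariance = covariance,
    economics = economic_weights(unlist(doc$economics$values),
                                 doc$economics$climate_price),
    program = do.call(breeding_program, doc$program),
    base_weights = unlist(doc$base_weights),
    inbreeding_depression = doc$inbreeding_depression,
    check = check)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a built-in or user-supplied parameter set
#'
#' @param source One of the built-in fixture names (see
#'   \code{\link{builtin_parameter_sets}}), the path to a YAML
#'   configuration written by \code{\link{write_parameter_set}} (or by
#'   hand following the same schema), or a list with the same structure.
#' @param check Run \code{\link{check_phenotypic_consistency}} (warns on
#'   mismatch; the shipped fixtures themselves warn for traits whose
#'   published descriptive SD includes variation beyond the fitted
#'   genetic + residual components).
#' @return A validated \code{\link{parameter_set}}.
#' @export
load_parameter_set <- function(source, check = TRUE) {
  if (inherits(source, "parameter_set")) return(source)
  if (is.list(source)) return(.params_from_list(source, check = check))
  stopifnot(is.character(source), length(source) == 1L)
  if (source %in% builtin_parameter_sets())
    return(.builtin_params(source, check = check))
  if (!file.exists(source))
    stop("'", source, "' is neither a built-in parameter set (",
         paste(builtin_parameter_sets(), collapse = ", "),
         ") nor an existing file")
  .params_from_list(yaml::read_yaml(source), check = check)
}
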