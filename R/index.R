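#' Standardize EBVs within a generation
#'
#' Centres and scales each trait's EBVs to mean 0 and SD 1 within the
#' current population, using the population (divisor n) SD so that two
#' animals with EBVs {1, 3} standardize to {-1, +1}.
#'
#' @param pop A \code{sim_population} with simulated EBVs.
#' @return Matrix of z-scores, one column per trait.
#' @export
standardize_ebv <- function(pop) {
  if (is.null(pop$ebv)) stop("population has no EBVs; run simulate_ebv()")
  n <- nrow(pop$ebv)
  if (n < 2L) stop("at least 2 individuals are required")
  ctr <- sweep(pop$ebv, 2L, colMeans(pop$ebv))
  s <- sqrt(colMeans(ctr^2))
  if (any(s <= 0))
    stop("zero EBV variance for trait(s): ",
         paste(colnames(pop$ebv)[s <= 0], collapse = ", "),
         " (degenerate population)")
  sweep(ctr, 2L, s, "/")
}

#' Per-trait merit of a standardized EBV under a selection goal
#'
#' Maps a z-score to the merit scale on which index weights act:
#' \code{increase} rewards +z, \code{decrease} rewards -z,
#' \code{stabilize} penalizes distance from a target
#' (\code{-|z - target_z|}, maximal at the target).  The resilience
#' aliases follow the two zone conventions: \code{resilience-actual}
#' pushes the slope up (+z, Mediterranean), \code{resilience-absolute}
#' pushes the absolute-slope trait down (-z, Atlantic).
#'
#' @param z Numeric vector of standardized EBVs.
#' @param goal One of \code{"increase"}, \code{"decrease"},
#'   \code{"stabilize"}, \code{"resilience-actual"},
#'   \code{"resilience-absolute"}.
#' @param target_z Target on the z scale; required iff
#'   \code{goal = "stabilize"}.
#' @return Numeric vector of merits.
#' @export
trait_merit <- function(z, goal, target_z = NULL) {
  switch(goal,
         "increase" = ,
         "resilience-actual" = {
           if (!is.null(target_z))
             stop("target_z is only meaningful for goal 'stabilize'")
           z
         },
         "decrease" = ,
         "resilience-absolute" = {
           if (!is.null(target_z))
             stop("target_z is only meaningful for goal 'stabilize'")
           -z
         },
         "stabilize" = {
           if (is.null(target_z) || !is.finite(target_z))
             stop("stabilizing merit requires a finite target_z")
           -abs(z - target_z)
         },
         stop("unknown selection goal: ", goal))
}

# z-scale stabilizing targets, re-anchored each generation: the target
# phenotype is mapped through the population's current mean and the
# EBV-scale SD equivalent r * sigma_g, so selection pressure vanishes
# once the population mean sits on the target (true stabilizing
# selection) instead of pushing past it
.stabilize_targets <- function(pop, params) {
  nm <- colnames(pop$phen)
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  r <- params$covariance$accuracies[nm]
  sg <- sqrt(diag(params$G0)[nm])
  mu_now <- colMeans(pop$phen)
  for (k in nm) {
    tr <- params$traits[[k]]
    if (tr$goal == "stabilize")
      out[k] <- (tr$target - mu_now[k]) / (r[k] * sg[k])
  }
  out
}

# merit matrix for all traits of the active set
.merit_matrix <- function(z, pop, params) {
  nm <- colnames(z)
  tz <- .stabilize_targets(pop, params)
  m <- z
  for (k in nm) {
    goal <- params$traits[[k]]$goal
    m[, k] <- trait_merit(z[, k], goal,
                          target_z = if (goal == "stabilize") tz[k])
  }
  m
}

#' Combine per-trait merits into a selection index
#'
#' The index is the weighted sum of merits; traits absent from the
#' weight vector (or weighted zero) contribute nothing.
#'
#' @param merits Matrix of per-trait merits (columns named by trait).
#' @param weights Named weight vector (a \code{\link{scenario_spec}} is
#'   also accepted).
#' @return Numeric index per individual.
#' @export
compute_index <- function(merits, weights) {
  if (inherits(weights, "scenario_spec")) weights <- weights$weights
  if (is.null(names(weights)))
    stop("weights must be named by trait")
  unknown <- setdiff(names(weights), colnames(merits))
  if (length(unknown))
    stop("weights refer to trait(s) without merits: ",
         paste(unknown, collapse = ", "))
  w <- stats::setNames(rep(0, ncol(merits)), colnames(merits))
  w[names(weights)] <- weights
  drop(merits %*% w)
}

#' Truncation-select parents within each sex
#'
#' The best \code{ceiling(prop * n)} animals of each sex by index are
#' selected; ties are broken by (index, id) so selection is
#' deterministic.
#'
#' @param pop A \code{sim_population}.
#' @param index Numeric selection index, one value per animal.
#' @param prop_male,prop_female Selected proportions in (0, 1].
#' @return List with \code{sires} and \code{dams}
#'   (\code{sim_population} subsets) and their row positions
#'   \code{sire_idx}, \code{dam_idx} in \code{pop}.
#' @export
select_parents <- function(pop, index, prop_male, prop_female) {
  for (p in c(prop_male, prop_female))
    if (!is.finite(p) || p <= 0 || p > 1)
      stop("selected proportions must lie in (0, 1]")
  if (length(index) != length(pop$id))
    stop("index length does not match the population")
  pick <- function(sex, prop) {
    cand <- which(pop$sex == sex)
    k <- ceiling(prop * length(cand))
    if (k < 1L)
      stop("selection would retain no ", if (sex == "M") "males" else
        "females")
    cand[order(-index[cand], pop$id[cand])][seq_len(k)]
  }
  si <- pick("M", prop_male)
  di <- pick("F", prop_female)
  list(sires = subset_population(pop, si),
       dams = subset_population(pop, di),
       sire_idx = si, dam_idx = di)
}
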