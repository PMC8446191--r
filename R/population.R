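#' Simulate the base (founder) population
#'
#' True breeding values are drawn from MVN(0, G0) and environmental
#' deviations independently from MVN(0, E); continuous phenotypes are
#' base mean + TBV + deviation.  Sexes alternate male/female so the split
#' is exactly even.
#'
#' @param n Number of animals (even, >= 2).
#' @param params An \code{\link{active_parameters}} set (or a
#'   \code{parameter_set}, restricted with mode \code{"none"}).
#' @param seed Optional integer seed; \code{NULL} uses the current RNG
#'   stream.
#' @return An object of class \code{sim_population}: parallel vectors
#'   \code{id}, \code{sex} ("M"/"F"), \code{sire}, \code{dam} (NA for
#'   founders), \code{f} (pedigree inbreeding), and n-by-traits matrices
#'   \code{tbv}, \code{env}, \code{phen}, \code{ebv}.
#' @export
simulate_base_population <- function(n, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.numeric(n) || n < 2L) stop("n must be >= 2")
  n <- as.integer(n)
  if (n %% 2L != 0L) stop("n must be even (equal sex split)")
  params <- .as_active(params)
  nm <- names(params$traits)
  mu <- vapply(params$traits, `[[`, 0, "mean")
  tbv <- MASS::mvrnorm(n, mu = rep(0, length(nm)), Sigma = params$G0)
  env <- MASS::mvrnorm(n, mu = rep(0, length(nm)), Sigma = params$E)
  colnames(tbv) <- colnames(env) <- nm
  pop <- structure(list(
    generation = 0L,
    id = seq_len(n),
    sex = rep(c("M", "F"), length.out = n),
    sire = rep(NA_integer_, n),
    dam = rep(NA_integer_, n),
    f = rep(0, n),
    tbv = tbv, env = env,
    phen = sweep(tbv + env, 2L, mu, "+"),
    ebv = NULL), class = "sim_population")
  pop
}

.as_active <- function(params) {
  if (inherits(params, "active_parameter_set")) return(params)
  active_parameters(params, "none")
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("Population of %d animals, generation %d (%d M / %d F)\n",
              length(x$id), x$generation, sum(x$sex == "M"),
              sum(x$sex == "F")))
  cat(sprintf("  mean inbreeding F = %.4f\n", mean(x$f)))
  cat("  trait means:",
      paste(sprintf("%s %.4g", colnames(x$phen), colMeans(x$phen)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Extract a subset of animals from a population
#'
#' @param pop A \code{sim_population}.
#' @param idx Integer or logical index of animals to keep.
#' @return A \code{sim_population} with the selected animals.
#' @export
subset_population <- function(pop, idx) {
  out <- pop
  for (fld in c("id", "sex", "sire", "dam", "f"))
    out[[fld]] <- pop[[fld]][idx]
  for (fld in c("tbv", "env", "phen", "ebv"))
    if (!is.null(pop[[fld]])) out[[fld]] <- pop[[fld]][idx, , drop = FALSE]
  for (a in c("sire_slot", "dam_slot"))
    if (!is.null(attr(pop, a))) attr(out, a) <- attr(pop, a)[idx]
  out
}

#' Simulate pseudo-estimated breeding values at a stated accuracy
#'
#' For each trait, EBV = r * TBV / sigma_g + sqrt(1 - r^2) * z with z
#' standard normal, independent across animals and traits, so that the
#' population correlation between EBV and TBV converges to the accuracy
#' r.  EBVs are re-simulated whenever evaluation is repeated (each
#' generation in a running programme).  sigma_g is the base-generation
#' genetic SD, so EBVs are on a unitless, approximately unit-variance
#' scale.
#'
#' @param pop A \code{sim_population}.
#' @param params The active parameter set (supplies base genetic SDs and
#'   default accuracies).
#' @param accuracies Optional named override, entries in (0, 1].
#' @param seed Optional integer seed.
#' @return The population with its \code{ebv} matrix filled in.
#' @export
simulate_ebv <- function(pop, params, accuracies = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params <- .as_active(params)
  nm <- colnames(pop$tbv)
  r <- accuracies %||% params$covariance$accuracies[nm]
  r <- r[nm]
  if (anyNA(r)) stop("missing accuracy for trait(s): ",
                     paste(nm[is.na(r)], collapse = ", "))
  if (any(r <= 0) || any(r > 1))
    stop("accuracies must lie in (0, 1]")
  sg <- sqrt(diag(params$G0)[nm])
  n <- length(pop$id)
  noise <- matrix(stats::rnorm(n * length(nm)), n)
  pop$ebv <- sweep(pop$tbv, 2L, sg, "/") %*% diag(r, length(nm)) +
    noise %*% diag(sqrt(1 - r^2), length(nm))
  colnames(pop$ebv) <- nm
  pop
}

#' Mendelian sampling covariance for one mating
#'
#' Returns 0.5 * G0 * (1 - Fbar), where Fbar is the mean of the two
#' parents' pedigree inbreeding coefficients; with fully inbred parents
#' the Mendelian sampling variance vanishes.
#'
#' @param g0 Base-generation genetic covariance matrix.
#' @param f_sire,f_dam Parental inbreeding coefficients in [0, 1].
#' @return Covariance matrix of the Mendelian sampling deviation.
#' @export
mendelian_variance <- function(g0, f_sire, f_dam) {
  for (f in c(f_sire, f_dam))
    if (!is.finite(f) || f < 0 || f > 1)
      stop("parental inbreeding coefficients must lie in [0, 1]")
  0.5 * g0 * (1 - (f_sire + f_dam) / 2)
}

# capacity-respecting uniform assignment of offspring to parents:
# repeated uniform draws over parents with remaining capacity, accepting
# draws in order up to each parent's remaining cap
.sample_capped <- function(n_parents, cap, n_off) {
  counts <- integer(n_parents)
  out <- integer(0)
  while (length(out) < n_off) {
    need <- n_off - length(out)
    open <- which(counts < cap)
    draw <- if (length(open) == 1L) rep.int(open, need) else
      sample(open, need, replace = TRUE)
    occ <- stats::ave(seq_along(draw), draw, FUN = seq_along)
    keep <- draw[occ <= (cap - counts)[draw]]
    counts <- counts + tabulate(keep, nbins = n_parents)
    out <- c(out, keep)
  }
  out
}

#' Breed the next generation from selected parents
#'
#' Parent pairs are drawn uniformly among parents with remaining
#' capacity (no sire exceeds its cap, nor any dam hers).  Offspring true
#' breeding values are the mid-parent mean plus a Mendelian sampling
#' deviation with covariance \code{\link{mendelian_variance}}; fresh
#' environmental deviations come from MVN(0, E).  Offspring sexes
#' alternate male/female.
#'
#' @param sires,dams \code{sim_population} objects holding the selected
#'   parents of each sex.
#' @param n_offspring Number of offspring to produce.
#' @param caps Length-2 vector \code{c(sire =, dam =)} of offspring caps.
#' @param params The active parameter set.
#' @param seed Optional integer seed.
#' @param parent_kinship Optional additive-relationship matrix over
#'   \code{c(sires, dams)} in that order; offspring inbreeding is half
#'   the parents' relationship.  When omitted the parents are taken as
#'   unrelated and offspring F is 0.
#' @param id_start First offspring id (defaults to max parent id + 1).
#' @return A \code{sim_population} of offspring, with attributes
#'   \code{sire_slot}/\code{dam_slot} giving each offspring's parents as
#'   positions within \code{sires} and \code{dams}.
#' @export
breed_generation <- function(sires, dams, n_offspring,
                             caps = c(sire = 100, dam = 7), params,
                             seed = NULL, parent_kinship = NULL,
                             id_start = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params <- .as_active(params)
  ns <- length(sires$id); nd <- length(dams$id)
  cap_s <- caps[[1L]]; cap_d <- caps[[2L]]
  if (ns * cap_s < n_offspring)
    stop("insufficient sire capacity: ", ns, " sires x cap ", cap_s,
         " < ", n_offspring, " offspring")
  if (nd * cap_d < n_offspring)
    stop("insufficient dam capacity: ", nd, " dams x cap ", cap_d,
         " < ", n_offspring, " offspring")
  nm <- colnames(sires$tbv)
  mu <- vapply(params$traits[nm], `[[`, 0, "mean")

  si <- .sample_capped(ns, cap_s, n_offspring)
  di <- .sample_capped(nd, cap_d, n_offspring)

  fbar <- (sires$f[si] + dams$f[di]) / 2
  ms <- MASS::mvrnorm(n_offspring, mu = rep(0, length(nm)),
                      Sigma = 0.5 * params$G0) * sqrt(1 - fbar)
  tbv <- 0.5 * (sires$tbv[si, , drop = FALSE] +
                dams$tbv[di, , drop = FALSE]) + ms
  env <- MASS::mvrnorm(n_offspring, mu = rep(0, length(nm)),
                       Sigma = params$E)
  colnames(tbv) <- colnames(env) <- nm

  f_off <- if (is.null(parent_kinship)) rep(0, n_offspring) else
    0.5 * parent_kinship[cbind(si, ns + di)]

  if (is.null(id_start))
    id_start <- max(c(sires$id, dams$id)) + 1L
  off <- structure(list(
    generation = max(sires$generation, dams$generation) + 1L,
    id = seq.int(id_start, length.out = n_offspring),
    sex = rep(c("M", "F"), length.out = n_offspring),
    sire = sires$id[si],
    dam = dams$id[di],
    f = f_off,
    tbv = tbv, env = env,
    phen = sweep(tbv + env, 2L, mu, "+"),
    ebv = NULL), class = "sim_population")
  attr(off, "sire_slot") <- si
  attr(off, "dam_slot") <- di
  off
}

#' Kinship (additive relationship) matrix of founders
#'
#' @param f Vector of founder inbreeding coefficients (typically zero).
#' @return Diagonal matrix with entries 1 + f.
#' @export
founder_kinship <- function(f) diag(1 + f, length(f))

#' Propagate an additive-relationship matrix to offspring
#'
#' Given the relationship matrix among the parents (sires then dams) and
#' each offspring's parent positions, returns the relationship matrix
#' among the offspring: off-diagonals are the mean of the four
#' parent-pair relationships, the diagonal is 1 + F with F half the
#' relationship between the individual's own parents (the tabular
#' method, restricted to one generation step).
#'
#' @param parent_kinship Relationship matrix over the combined parents.
#' @param sire_slot,dam_slot Parent positions of each offspring, with
#'   dams indexed after sires (i.e. dam j is column n_sires + j).
#' @param n_sires Number of sires in \code{parent_kinship}.
#' @return Relationship matrix among the offspring.
#' @export
offspring_kinship <- function(parent_kinship, sire_slot, dam_slot,
                              n_sires) {
  n <- length(sire_slot)
  np <- nrow(parent_kinship)
  m <- matrix(0, n, np)
  m[cbind(seq_len(n), sire_slot)] <- 0.5
  m[cbind(seq_len(n), n_sires + dam_slot)] <-
    m[cbind(seq_len(n), n_sires + dam_slot)] + 0.5
  a <- m %*% parent_kinship %*% t(m)
  f <- 0.5 * parent_kinship[cbind(sire_slot, n_sires + dam_slot)]
  diag(a) <- 1 + f
  a
}

#' Pedigree inbreeding coefficients by the tabular method
#'
#' Builds the full additive-relationship matrix over a sorted pedigree
#' (parents listed before offspring) and returns Wright's inbreeding
#' coefficient F for every individual; founders have F = 0.
#'
#' @param pedigree Data frame with columns \code{id}, \code{sire},
#'   \code{dam} (NA or 0 for unknown founder parents).
#' @return Named numeric vector of inbreeding coefficients.
#' @export
compute_inbreeding <- function(pedigree) {
  id <- pedigree$id
  n <- length(id)
  sire <- match(pedigree$sire, id)
  dam <- match(pedigree$dam, id)
  known_s <- !is.na(pedigree$sire) & pedigree$sire != 0
  known_d <- !is.na(pedigree$dam) & pedigree$dam != 0
  if (any(known_s & is.na(sire)) || any(known_d & is.na(dam)))
    stop("pedigree references unknown parent id(s)")
  if (any(known_s & sire >= seq_len(n), na.rm = TRUE) ||
      any(known_d & dam >= seq_len(n), na.rm = TRUE))
    stop("pedigree must list parents before their offspring")
  sire[!known_s] <- NA
  dam[!known_d] <- NA
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + 0.5 * A[s, j]
      if (!is.na(d)) row <- row + 0.5 * A[d, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  stats::setNames(diag(A) - 1, id)
}

#' Apply linear inbreeding depression to a trait's phenotype
#'
#' Reduces each animal's continuous-scale phenotype by
#' \code{slope * F}.  True breeding values are untouched: depression is
#' an environmental (dominance-mediated) penalty, not a change in
#' additive merit.  A negative slope (inbreeding improving the trait) is
#' unusual and triggers a warning, not an error.
#'
#' @param pop A \code{sim_population}.
#' @param trait Trait name (e.g. \code{"Fert"}).
#' @param slope Phenotypic reduction per unit of F, in trait units.
#' @return The population with the adjusted phenotype.
#' @export
apply_inbreeding_depression <- function(pop, trait, slope) {
  if (!trait %in% colnames(pop$phen))
    stop("trait '", trait, "' not present in the population")
  if (slope < 0)
    warning("negative inbreeding-depression slope: inbreeding would ",
            "improve '", trait, "'", call. = FALSE)
  pop$phen[, trait] <- pop$phen[, trait] - slope * pop$f
  pop
}

#' Report trait means on the recorded scale
#'
#' Continuous traits report their phenotypic mean; binary-threshold
#' traits report the incidence, i.e. the fraction of animals whose
#' continuous phenotype exceeds the fixed base-calibrated threshold.
#'
#' @param pop A \code{sim_population}.
#' @param params The active parameter set (supplies thresholds).
#' @return Named numeric vector of means/incidences.
#' @export
reported_means <- function(pop, params) {
  params <- .as_active(params)
  nm <- colnames(pop$phen)
  out <- colMeans(pop$phen)
  for (k in nm) {
    th <- params$thresholds[k]
    if (!is.na(th)) out[k] <- mean(pop$phen[, k] > th)
  }
  out
}
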