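#' Realized gain per trait between two populations
#'
#' Difference in continuous-scale phenotypic means, final minus base.
#'
#' @param base,final \code{sim_population} objects over the same traits.
#' @return Named numeric vector of gains in trait units.
#' @export
realized_gain <- function(base, final) {
  if (!identical(colnames(base$phen), colnames(final$phen)))
    stop("populations do not share the same trait set")
  colMeans(final$phen) - colMeans(base$phen)
}

#' Standardized overall progress index (Index0)
#'
#' Combines realized gains on every trait except resilience, each
#' standardized by its base phenotypic SD and signed so that the
#' desirable direction counts positive, weighted by the Base scenario's
#' index weights.  Directional traits contribute
#' \code{w * sign * gain / sd}; stabilizing traits contribute the
#' standardized reduction in distance to target,
#' \code{w * (|shift| - |gain - shift|) / sd} with \code{shift} the
#' distance from base mean to target, so an unchanged population scores
#' zero on every trait and landing exactly on the target scores the
#' maximum.
#'
#' @param gains Named gains on the continuous scale (resilience entries
#'   are ignored).
#' @param base_weights Named Base-scenario weights over the
#'   non-resilience traits; normalized to sum to 1.
#' @param params A \code{\link{parameter_set}}.
#' @return Scalar Index0 value (unitless).
#' @export
compute_index0 <- function(gains, base_weights, params) {
  roles <- vapply(params$traits, `[[`, "", "role")
  nm <- names(roles)[roles == "production"]
  w <- base_weights[nm]
  if (anyNA(w))
    stop("base_weights must cover every non-resilience trait")
  w <- w / sum(w)
  total <- 0
  for (k in nm) {
    tr <- params$traits[[k]]
    if (!k %in% names(gains) || is.na(gains[[k]]))
      stop("missing gain for trait '", k, "'")
    g <- gains[[k]]
    shift <- if (tr$goal == "stabilize") tr$target - tr$mean
    total <- total + switch(tr$goal,
      increase = w[[k]] * g / tr$sd,
      decrease = -w[[k]] * g / tr$sd,
      stabilize = w[[k]] * (abs(shift) - abs(g - shift)) / tr$sd)
  }
  total
}

#' Economic profit of realized gains under a climate delta
#'
#' Profit is the economic-value-weighted sum of realized gains plus a
#' climate loss term L.  At the current climate (delta_t = 0) L is zero;
#' under warming it values the final population's resilience:
#' \code{L = mean_slope * delta_t * climate_price} when resilience is
#' the actual slope (a negative slope loses money as temperature rises),
#' and \code{L = -mean_abs_slope * delta_t * climate_price} when
#' resilience is stability (any deviation of the slope from zero is a
#' loss under increased weather volatility).  Optionally the resilience
#' gain itself can also be priced independently of warming.
#'
#' @param gains Named realized gains over the non-resilience traits, on
#'   the recorded scale (incidences for binary traits).
#' @param final_resilience_mean Final-generation mean of the resilience
#'   phenotype: the mean slope for \code{mode = "actual"}/\code{"none"},
#'   the mean absolute slope for \code{mode = "absolute"}.
#' @param econ An \code{\link{economic_weights}} object.
#' @param delta_t Temperature increase in degrees C (0, 1 or 2).
#' @param mode Resilience definition in force.
#' @param resilience_gain Realized gain of the resilience trait; only
#'   used when \code{price_slope_gain = TRUE}.
#' @param price_slope_gain Also price the resilience gain at delta_t = 0
#'   (default \code{FALSE}: the slope only enters through L).
#' @return Profit in euros (per animal and trait-recording unit).
#' @export
compute_profit <- function(gains, final_resilience_mean, econ, delta_t,
                           mode = c("actual", "none", "absolute"),
                           resilience_gain = NULL,
                           price_slope_gain = FALSE) {
  mode <- match.arg(mode)
  if (!delta_t %in% c(0, 1, 2))
    stop("delta_t must be 0, 1 or 2")
  v <- econ$values[names(gains)]
  if (anyNA(v))
    stop("missing economic value for trait(s): ",
         paste(names(gains)[is.na(v)], collapse = ", "))
  profit <- sum(unlist(gains) * v)
  if (price_slope_gain) {
    if (is.null(resilience_gain))
      stop("price_slope_gain = TRUE requires resilience_gain")
    profit <- profit + resilience_gain * econ$climate_price
  }
  loss <- if (mode == "absolute")
    -abs(final_resilience_mean) * delta_t * econ$climate_price
  else final_resilience_mean * delta_t * econ$climate_price
  profit + loss
}

#' Mean and standard error over scenario replicates
#'
#' @param results Data frame with one row per replicate of a single
#'   scenario (column \code{scenario} required) and numeric outcome
#'   columns.
#' @return One-row data frame with \code{<col>_mean} and \code{<col>_se}
#'   for every numeric column; SE is the between-replicate standard
#'   deviation over sqrt(replicates).
#' @export
summarize_replicates <- function(results) {
  if (!"scenario" %in% names(results))
    stop("results must carry a 'scenario' column")
  if (length(unique(results$scenario)) != 1L)
    stop("summarize_replicates() expects a single scenario; got: ",
         paste(unique(results$scenario), collapse = ", "))
  if (nrow(results) < 2L)
    stop("at least 2 replicates are required")
  num <- vapply(results, is.numeric, TRUE)
  num["replicate"] <- FALSE
  out <- data.frame(scenario = results$scenario[1L],
                    replicates = nrow(results))
  for (k in names(results)[num]) {
    out[[paste0(k, "_mean")]] <- mean(results[[k]])
    out[[paste0(k, "_se")]] <- stats::sd(results[[k]]) / sqrt(nrow(results))
  }
  out
}
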