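# Linear-model decomposition of peri-landing rates into human, location and
# human x location terms, and the coding-class rules built on it.

#' Fit the landing-rate linear model and test its terms
#'
#' Least-squares fit of per-trial peri-landing window rate on two non-ordinal
#' categorical predictors - the human at the landing location and the landing
#' location itself - plus their interaction, using sum-to-zero (effects)
#' contrasts. Each term's p-value comes from a nested model comparison
#' (type-II F tests: each main effect against the two-main-effects model, the
#' interaction against the additive model). Cells with no trials drop their
#' unestimable interaction coefficients (lm aliasing), with a message.
#'
#' @param rates per-trial rates, Hz.
#' @param humans human label per trial (>= 2 levels represented).
#' @param locations landing location per trial (>= 2 levels represented).
#' @return list(p_human, p_location, p_interaction, model). A constant
#'   response yields p = 1 for all terms.
#' @export
fitLandingModel <- function(rates, humans, locations) {
  d <- data.frame(rate = rates, human = factor(humans),
                  location = factor(locations))
  d <- droplevels(d[complete.cases(d), ])
  if (nlevels(d$human) < 2 || nlevels(d$location) < 2)
    stop("need >= 2 humans and >= 2 locations represented")
  if (sd(d$rate) == 0)
    return(list(p_human = 1, p_location = 1, p_interaction = 1, model = NULL))
  ctr <- list(human = "contr.sum", location = "contr.sum")
  full <- lm(rate ~ human * location, data = d, contrasts = ctr)
  if (any(is.na(coef(full))))
    message("empty human x location cells: unestimable interaction ",
            "coefficients dropped")
  add <- lm(rate ~ human + location, data = d, contrasts = ctr)
  noH <- lm(rate ~ location, data = d, contrasts = ctr["location"])
  noL <- lm(rate ~ human, data = d, contrasts = ctr["human"])
  pOf <- function(reduced, fuller) {
    a <- anova(reduced, fuller)
    pv <- a$`Pr(>F)`[2]
    if (is.na(pv)) 1 else pv
  }
  list(p_human = pOf(noH, add), p_location = pOf(noL, add),
       p_interaction = pOf(add, full), model = full)
}

#' Map term p-values to a coding class
#'
#' Rules (threshold p < 0.05): "additive" = significant human and location
#' terms without a significant interaction; "conjunctive" = a significant
#' interaction term (with significant human and/or location terms;
#' interaction-only units are also called conjunctive by default -
#' interaction presence governs, set `interactionAlone = "none"` for the
#' stricter reading that requires at least one main effect); "human_only" /
#' "location_only" = exactly that main effect; "none" otherwise.
#'
#' @param p_human,p_location,p_interaction term p-values.
#' @param alpha significance threshold (default 0.05).
#' @param interactionAlone class for interaction-significant units with no
#'   significant main effect: "conjunctive" (default) or "none".
#' @return one of "additive", "conjunctive", "human_only", "location_only",
#'   "none".
#' @export
classifyCoding <- function(p_human, p_location, p_interaction, alpha = 0.05,
                           interactionAlone = c("conjunctive", "none")) {
  interactionAlone <- match.arg(interactionAlone)
  h <- is.finite(p_human) && p_human < alpha
  l <- is.finite(p_location) && p_location < alpha
  i <- is.finite(p_interaction) && p_interaction < alpha
  if (i) {
    if (h || l) return("conjunctive")
    return(if (interactionAlone == "conjunctive") "conjunctive" else "none")
  }
  if (h && l) return("additive")
  if (h) return("human_only")
  if (l) return("location_only")
  "none"
}

#' Histogram of significantly modulated locations per unit
#'
#' Only units analyzable at `minLocations` or more locations enter; each is
#' binned by its number of significantly identity-modulated locations.
#'
#' @param permResults data.frame from [identityModulation()] pooled over
#'   units (columns unit, location, significant; NA significant =
#'   not analyzable).
#' @param minLocations minimum analyzable locations per unit (default 4).
#' @return list(histogram = named count vector over 0..max locations,
#'   included_units, excluded_units).
#' @export
countMultilocationModulation <- function(permResults, minLocations = 4) {
  units <- unique(permResults$unit)
  nSig <- integer(0); kept <- character(0); dropped <- character(0)
  for (u in units) {
    sub <- permResults[permResults$unit == u, , drop = FALSE]
    ana <- !is.na(sub$significant)
    if (sum(ana) < minLocations) { dropped <- c(dropped, u); next }
    kept <- c(kept, u)
    nSig <- c(nSig, sum(sub$significant[ana]))
  }
  maxN <- if (length(nSig)) max(nSig) else 0
  hist <- vapply(0:maxN, function(k) sum(nSig == k), integer(1))
  names(hist) <- 0:maxN
  list(histogram = hist, included_units = kept, excluded_units = dropped)
}
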