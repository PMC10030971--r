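#' Monod functional response
#'
#' Per-capita growth rate of a consumer on a single resource,
#' \eqn{\mu(R) = \mu_{max} R / (K_s + R)}.
#'
#' @param mu_max maximum growth rate (h^-1), positive.
#' @param k_s half-saturation constant (resource-concentration units),
#'   positive.
#' @param r resource concentration, non-negative.
#' @return Growth rate in `[0, mu_max)`. Vectorised over all arguments.
#' @examples
#' monod_rate(1, 1, 1) # half saturation: 0.5
#' @export
monod_rate <- function(mu_max, k_s, r) {
  if (any(mu_max <= 0) || any(k_s <= 0)) {
    stop("`mu_max` and `k_s` must be positive")
  }
  if (any(r < 0)) {
    stop("negative resource concentration passed to monod_rate()")
  }
  mu_max * r / (k_s + r)
}

#' System state of the consumer-resource model
#'
#' @param consumers numeric vector of consumer densities `N_i` (>= 0).
#' @param resources numeric vector of resource concentrations `R_j` (>= 0).
#' @param time time in hours.
#' @return An object of class `system_state`.
#' @export
system_state <- function(consumers, resources, time = 0) {
  if (any(consumers < 0) || any(resources < 0)) {
    stop("consumer densities and resource concentrations must be non-negative")
  }
  structure(list(consumers = consumers, resources = resources, time = time),
            class = "system_state")
}

#' Model specification
#'
#' Bundles a trait set with the resource-use rule, mortality, dilution and
#' resource supply of the environment.  Under continuous supply the resource
#' supply function is realised as chemostat inflow \eqn{D (S_j - R_j)} and
#' per-capita mortality equals the dilution rate (`dilution_rate ==
#' mortality_rate`).  Under pulsed supply the same `D` and `m` set the
#' flux-matched pulse size \eqn{D S_j T} and the transfer survival
#' \eqn{e^{-mT}}.
#'
#' @param traits a [trait_set()].
#' @param resource_rule `"substitutable"` (growth terms sum over resources) or
#'   `"essential"` (Liebig's law of the minimum).
#' @param mortality_rate per-capita mortality rate `m` due to dilution, h^-1.
#' @param supply_concentration supply-point concentrations `S_j`; a scalar is
#'   recycled over resources.
#' @param dilution_rate dilution rate `D`, h^-1. Defaults to `mortality_rate`
#'   (the chemostat convention, required under the continuous regime).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(traits,
                       resource_rule = c("substitutable", "essential"),
                       mortality_rate = 0.2,
                       supply_concentration = 1,
                       dilution_rate = mortality_rate) {
  stopifnot(inherits(traits, "trait_set"))
  resource_rule <- match.arg(resource_rule)
  if (mortality_rate <= 0) stop("`mortality_rate` must be positive")
  if (dilution_rate <= 0) stop("`dilution_rate` must be positive")
  S <- rep_len(as.numeric(supply_concentration), traits$n_resources)
  if (any(S <= 0)) stop("`supply_concentration` must be positive")
  structure(
    list(traits = traits, resource_rule = resource_rule,
         mortality_rate = mortality_rate, supply_concentration = S,
         dilution_rate = dilution_rate),
    class = "model_spec"
  )
}

# Monod matrix mu_ij(R_j) for all consumer-resource pairs
monod_matrix <- function(traits, resources) {
  rmat <- matrix(resources, traits$n_consumers, traits$n_resources,
                 byrow = TRUE)
  traits$mu_max * rmat / (traits$k_s + rmat)
}

#' Per-capita growth rate of consumers
#'
#' The functional response given current resource concentrations: the sum of
#' Monod terms over resources when resources are substitutable, or the
#' minimum term (Liebig's law) when resources are essential.
#'
#' @param traits a [trait_set()].
#' @param resources resource concentrations (length `n_resources`, >= 0).
#' @param rule `"substitutable"` or `"essential"`.
#' @param consumer optional consumer index; default returns all consumers.
#' @return Per-capita growth rate(s), h^-1.
#' @export
growth_rate <- function(traits, resources,
                        rule = c("substitutable", "essential"),
                        consumer = NULL) {
  stopifnot(inherits(traits, "trait_set"))
  rule <- match.arg(rule)
  if (any(resources < 0)) stop("resource concentrations must be non-negative")
  mm <- monod_matrix(traits, resources)
  g <- switch(rule,
    substitutable = rowSums(mm),
    essential = apply(mm, 1, min)
  )
  if (is.null(consumer)) g else g[[consumer]]
}

# per-pair uptake rates u_ij; under the essential rule every resource is
# consumed in proportion to the realised (minimum-limited) growth rate
uptake_matrix <- function(traits, resources, rule) {
  mm <- monod_matrix(traits, resources)
  if (rule == "substitutable") {
    mm
  } else {
    g <- apply(mm, 1, min)
    matrix(g, traits$n_consumers, traits$n_resources)
  }
}

rhs_core <- function(state, spec, supply_on, mortality_on, clip = TRUE) {
  N <- state$consumers
  R <- state$resources
  if (clip) {
    N <- pmax(N, 0)
    R <- pmax(R, 0)
  }
  traits <- spec$traits
  g <- growth_rate(traits, pmax(R, 0), spec$resource_rule)
  u <- uptake_matrix(traits, pmax(R, 0), spec$resource_rule)
  dN <- N * (g - mortality_on * spec$mortality_rate)
  consumption <- colSums(traits$quota * u * N)
  dR <- supply_on * spec$dilution_rate * (spec$supply_concentration - R) -
    consumption
  list(consumers = dN, resources = dR)
}

#' Time derivatives under continuous (chemostat) resource supply
#'
#' \eqn{dN_i/dt = N_i(\sum_j \mu_{ij}(R_j) - m)} and
#' \eqn{dR_j/dt = D(S_j - R_j) - \sum_i Q_{ij} u_{ij}(R_j) N_i}.
#' Negative state values (integrator overshoot) are treated as zero.
#'
#' @param state a [system_state()].
#' @param spec a [model_spec()].
#' @return List with elements `consumers` and `resources` holding the time
#'   derivatives.
#' @export
rhs_continuous <- function(state, spec) {
  rhs_core(state, spec, supply_on = 1, mortality_on = 1)
}

#' Time derivatives during the batch phase of a pulsed regime
#'
#' Between pulses the supply function is switched off; mortality is switched
#' off too under intermittent mortality (dilution happens only at transfer)
#' or kept on under the continuous-mortality variant.
#'
#' @inheritParams rhs_continuous
#' @param mortality `"intermittent"` (no mortality between pulses, default) or
#'   `"continuous"` (the -mN term keeps acting).
#' @return List with elements `consumers` and `resources`.
#' @export
rhs_batch <- function(state, spec, mortality = c("intermittent", "continuous")) {
  mortality <- match.arg(mortality)
  rhs_core(state, spec, supply_on = 0,
           mortality_on = as.numeric(mortality == "continuous"))
}

#' Break-even resource concentration R*
#'
#' The concentration at which growth on a single resource exactly balances
#' mortality: \eqn{R^* = K_s m / (\mu_{max} - m)}.  The consumer with the
#' lowest R* wins equilibrium competition for one continuously supplied
#' resource.  Returns `Inf` when `mu_max <= m` (the consumer cannot persist).
#'
#' @param mu_max maximum growth rate, h^-1.
#' @param k_s half-saturation constant.
#' @param m mortality rate, h^-1.
#' @return Break-even concentration(s); vectorised.
#' @export
rstar <- function(mu_max, k_s, m) {
  ifelse(mu_max > m, k_s * m / (mu_max - m), Inf)
}

#' Closed-form chemostat equilibrium for a single consumer on one resource
#'
#' \eqn{R^* = K_s m/(\mu_{max}-m)} and \eqn{N^* = D(S - R^*)/(Q m)}.
#'
#' @param spec a [model_spec()] with exactly one consumer and one resource.
#' @return List with `resources` (R*) and `consumers` (N*).
#' @export
chemostat_equilibrium <- function(spec) {
  tr <- spec$traits
  if (tr$n_consumers != 1L || tr$n_resources != 1L) {
    stop("closed form requires a single consumer on a single resource")
  }
  m <- spec$mortality_rate
  rs <- rstar(tr$mu_max[1, 1], tr$k_s[1, 1], m)
  ns <- spec$dilution_rate * (spec$supply_concentration[1] - rs) /
    (tr$quota[1, 1] * m)
  list(resources = rs, consumers = max(ns, 0))
}

#' Read and write model specifications as JSON
#'
#' @param spec a [model_spec()].
#' @param path file path.
#' @return `write_model_spec()` returns `path` invisibly; `read_model_spec()`
#'   returns a [model_spec()].
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "model_spec"))
  x <- list(
    resource_rule = spec$resource_rule,
    mortality_rate = spec$mortality_rate,
    dilution_rate = spec$dilution_rate,
    supply_concentration = spec$supply_concentration,
    traits = list(
      mu_max = spec$traits$mu_max,
      k_s = spec$traits$k_s,
      quota = spec$traits$quota,
      consumers = rownames(spec$traits$mu_max),
      resources = colnames(spec$traits$mu_max)
    )
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  dn <- list(x$traits$consumers, x$traits$resources)
  mk <- function(m) matrix(as.numeric(m), nrow = length(dn[[1]]), dimnames = dn)
  traits <- trait_set(mk(x$traits$mu_max), mk(x$traits$k_s), mk(x$traits$quota))
  model_spec(traits, resource_rule = x$resource_rule,
             mortality_rate = x$mortality_rate,
             supply_concentration = x$supply_concentration,
             dilution_rate = x$dilution_rate)
}
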