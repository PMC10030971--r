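# smooth (unclipped) RHS restricted to a subset of consumers; x packs the
# retained consumer densities followed by all resource concentrations
reduced_rhs <- function(x, spec, keep) {
  nc <- spec$traits$n_consumers
  nr <- spec$traits$n_resources
  N <- numeric(nc)
  N[keep] <- x[seq_len(sum(keep))]
  R <- x[sum(keep) + seq_len(nr)]
  traits <- spec$traits
  rmat <- matrix(R, nc, nr, byrow = TRUE)
  mm <- traits$mu_max * rmat / (traits$k_s + rmat)
  g <- if (spec$resource_rule == "substitutable") rowSums(mm) else
    apply(mm, 1, min)
  u <- if (spec$resource_rule == "substitutable") mm else matrix(g, nc, nr)
  dN <- N * (g - spec$mortality_rate)
  dR <- spec$dilution_rate * (spec$supply_concentration - R) -
    colSums(traits$quota * u * N)
  c(dN[keep], dR)
}

# central-difference Jacobian with relative step size
numeric_jacobian <- function(f, x, rel_step = 1e-7) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), n)
  for (k in seq_len(n)) {
    h <- rel_step * max(abs(x[k]), 1)
    xp <- x; xp[k] <- x[k] + h
    xm <- x; xm[k] <- x[k] - h
    J[, k] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' Find the continuous-supply steady state
#'
#' Simulates the chemostat to (near) steady state, removes consumers below
#' the extinction threshold, and refines the surviving subsystem's state
#' with a root search on the unclipped right-hand side.  If the root search
#' fails or leaves a residual above `residual_tol`, the simulated end state
#' is returned with `refined = FALSE` and a warning.
#'
#' @param spec a [model_spec()] (continuous regime, so `dilution_rate` must
#'   equal `mortality_rate`).
#' @param seed_state optional starting point: a [simulate_community()] result
#'   for this spec, or a [system_state()] near equilibrium.  By default a
#'   fresh continuous simulation is run.
#' @param extinction_frac extinction threshold as a fraction of the initial
#'   density.
#' @param residual_tol maximum RHS norm accepted for a refined equilibrium.
#' @param horizon_h horizon of the seeding simulation.
#' @param controls [solver_controls()] for the seeding simulation.
#' @return A list with `consumers` (full-length densities, zero for extinct
#'   species), `resources`, `persistent` (logical), `residual_norm` and
#'   `refined`.
#' @export
find_equilibrium <- function(spec, seed_state = NULL, extinction_frac = 1e-4,
                             residual_tol = 1e-9, horizon_h = 1000,
                             controls = solver_controls()) {
  stopifnot(inherits(spec, "model_spec"))
  nc <- spec$traits$n_consumers
  nr <- spec$traits$n_resources
  if (is.null(seed_state)) {
    seed_state <- simulate_community(spec, supply_regime("continuous"),
                                     horizon_h = horizon_h,
                                     controls = controls)
  }
  if (inherits(seed_state, "crm_sim")) {
    threshold <- extinction_frac * seed_state$init_density
    N0 <- seed_state$final_composition
    R0 <- seed_state$final_resources
  } else if (inherits(seed_state, "system_state")) {
    threshold <- extinction_frac * max(seed_state$consumers)
    N0 <- seed_state$consumers
    R0 <- seed_state$resources
  } else {
    stop("`seed_state` must be a crm_sim or a system_state")
  }
  keep <- N0 > threshold

  f <- function(x) reduced_rhs(x, spec, keep)
  x0 <- c(N0[keep], R0)
  refined <- max(abs(f(x0))) <= residual_tol
  x <- x0
  if (!refined) {
    sol <- tryCatch(
      suppressWarnings(pracma::fsolve(f, x0, tol = .Machine$double.eps^0.8)),
      error = function(e) NULL
    )
    if (!is.null(sol) && all(is.finite(sol$x))) x <- sol$x
    # Newton polish (also covers cases fsolve cannot handle, e.g. 1-d)
    for (it in 1:25) {
      fx <- f(x)
      if (max(abs(fx)) <= residual_tol) break
      J <- numeric_jacobian(f, x)
      step <- tryCatch(solve(J, -fx), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      x <- x + step
    }
    refined <- max(abs(f(x))) <= residual_tol && all(x > -1e-12)
    if (refined) x <- pmax(x, 0) else x <- x0
  }
  if (!refined) {
    warning("equilibrium refinement did not converge; ",
            "returning the simulated end state")
  }
  consumers <- numeric(nc)
  consumers[keep] <- x[seq_len(sum(keep))]
  names(consumers) <- rownames(spec$traits$mu_max)
  resources <- setNames(x[sum(keep) + seq_len(nr)],
                        colnames(spec$traits$mu_max))
  list(consumers = consumers, resources = resources, persistent = keep,
       residual_norm = max(abs(f(x))), refined = refined)
}

#' Leading eigenvalue of the community Jacobian at equilibrium
#'
#' Local stability of the continuous-supply steady state: the maximum real
#' part over the eigenvalues of the finite-difference (central) Jacobian of
#' the chemostat right-hand side.  With `subsystem = "persistent"` (default)
#' the Jacobian is taken on the surviving consumers plus all resources;
#' `subsystem = "full"` keeps extinct consumers in the state, whose
#' eigenvalues are their invasion rates \eqn{\mu(R^*) - m}.
#'
#' @param spec a [model_spec()].
#' @param equilibrium result of [find_equilibrium()].
#' @param subsystem `"persistent"` or `"full"`.
#' @param rel_step relative finite-difference step.
#' @return The leading real part (h^-1), with the full eigenvalue vector as
#'   attribute `"eigenvalues"`.
#' @export
jacobian_leading_eigenvalue <- function(spec, equilibrium,
                                        subsystem = c("persistent", "full"),
                                        rel_step = 1e-7) {
  subsystem <- match.arg(subsystem)
  keep <- if (subsystem == "persistent") equilibrium$persistent else
    rep(TRUE, spec$traits$n_consumers)
  x <- c(equilibrium$consumers[keep], equilibrium$resources)
  J <- numeric_jacobian(function(z) reduced_rhs(z, spec, keep), x,
                        rel_step = rel_step)
  ev <- eigen(J, only.values = TRUE)$values
  structure(max(Re(ev)), eigenvalues = ev)
}

#' Stability versus variability of compositional overlap
#'
#' For each combination, pairs the local stability of its continuous-supply
#' steady state (leading Jacobian eigenvalue) with the variance of its
#' Jaccard similarities across the pulsing-interval grid.  A weakly stable
#' equilibrium (leading eigenvalue near 0) is expected to go with a more
#' variable, less predictable response to pulsing.
#'
#' @param specs list of [model_spec()]s, one per combination.
#' @param continuous_sims list of the combinations' continuous-supply
#'   [simulate_community()] results (used to seed the equilibrium search).
#' @param combo_summary the `combo_summary` tibble of [summarise_study()].
#' @param extinction_frac extinction threshold fraction.
#' @param subsystem Jacobian state space, see
#'   [jacobian_leading_eigenvalue()].
#' @return Tibble of class addition `stability_report`: `combo_id`,
#'   `leading_eigenvalue_real`, `jaccard_variance`, `n_persistent`,
#'   `equilibrium_refined`.
#' @export
stability_report <- function(specs, continuous_sims, combo_summary,
                             extinction_frac = 1e-4,
                             subsystem = c("persistent", "full")) {
  subsystem <- match.arg(subsystem)
  combo_ids <- unique(combo_summary$combo_id)
  stopifnot(length(specs) == length(combo_ids),
            length(continuous_sims) == length(combo_ids))
  rows <- lapply(seq_along(combo_ids), function(ci) {
    eq <- suppressWarnings(
      find_equilibrium(specs[[ci]], seed_state = continuous_sims[[ci]],
                       extinction_frac = extinction_frac)
    )
    lev <- jacobian_leading_eigenvalue(specs[[ci]], eq, subsystem = subsystem)
    jv <- combo_summary |>
      dplyr::filter(.data$combo_id == combo_ids[ci],
                    .data$regime != "continuous", .data$pair_converged)
    tibble::tibble(
      combo_id = combo_ids[ci],
      leading_eigenvalue_real = as.numeric(lev),
      jaccard_variance = if (nrow(jv) >= 2) var(jv$jaccard_vs_continuous)
        else NA_real_,
      n_persistent = sum(eq$persistent),
      equilibrium_refined = eq$refined
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("stability_report", class(out))
  out
}
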