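#' Resource supply regime
#'
#' Continuous supply is the chemostat limit: constant inflow `D (S - R)` and
#' constant dilution mortality `m`.  Pulsed supply replaces both with
#' discrete events every `interval_h` hours: cells are transferred with
#' survival \eqn{e^{-mT}} and resources replenished by \eqn{D S_j T}, so that
#' total resource flux and total mortality per unit time are identical for
#' every interval (less frequent replenishment means larger pulses).
#'
#' @param kind `"continuous"` or `"pulsed"`.
#' @param interval_h inter-pulse interval `T` in hours (pulsed only); the
#'   study grid is `c(0.5, 1, 2, 4, 12, 24)`.
#' @param mortality_mode `"intermittent"` (mortality only at transfer events,
#'   the serial-batch default) or `"continuous"` (the -mN term keeps acting
#'   between pulses; transfer events then add resources without diluting
#'   cells, so total mortality stays constant).
#' @param pulse_dialect `"serial_transfer"` (residual medium is diluted with
#'   the cells and flux-matched fresh input added, the default since transfer
#'   implies passage into fresh medium) or `"additive"` (resources are topped
#'   up in place with no residual dilution).
#' @return An object of class `supply_regime`.
#' @examples
#' supply_regime("pulsed", interval_h = 2)
#' @export
supply_regime <- function(kind = c("continuous", "pulsed"),
                          interval_h = NULL,
                          mortality_mode = c("intermittent", "continuous"),
                          pulse_dialect = c("serial_transfer", "additive")) {
  kind <- match.arg(kind)
  mortality_mode <- match.arg(mortality_mode)
  pulse_dialect <- match.arg(pulse_dialect)
  if (kind == "pulsed") {
    if (is.null(interval_h) || !is.numeric(interval_h) || interval_h <= 0) {
      stop("pulsed regimes need a positive `interval_h`")
    }
  } else {
    interval_h <- NA_real_
  }
  structure(
    list(kind = kind, interval_h = interval_h,
         mortality_mode = mortality_mode, pulse_dialect = pulse_dialect),
    class = "supply_regime"
  )
}

#' @export
print.supply_regime <- function(x, ...) {
  if (x$kind == "continuous") {
    cat("<supply_regime> continuous (chemostat)\n")
  } else {
    cat("<supply_regime> pulsed every", x$interval_h, "h;",
        x$mortality_mode, "mortality,", x$pulse_dialect, "dialect\n")
  }
  invisible(x)
}

#' Apply one resource pulse / transfer event
#'
#' Cells are diluted by the survival fraction \eqn{d = e^{-mT}} (intermittent
#' mortality) and resources replenished by the flux-matched input
#' \eqn{D S_j T}.  Under the serial-transfer dialect residual resources are
#' carried through the same dilution as the cells
#' (\eqn{R_j \leftarrow d R_j + D S_j T}); under the additive dialect they are
#' topped up in place.  With continuous mortality cells are not diluted and
#' resources are always topped up additively.
#'
#' @param state a [system_state()].
#' @param spec a [model_spec()].
#' @param regime a pulsed [supply_regime()].
#' @return The post-pulse [system_state()].
#' @export
apply_pulse <- function(state, spec, regime) {
  stopifnot(inherits(state, "system_state"), inherits(spec, "model_spec"),
            inherits(regime, "supply_regime"))
  if (regime$kind != "pulsed" || !is.finite(regime$interval_h) ||
      regime$interval_h <= 0) {
    stop("`apply_pulse()` requires a pulsed regime with a positive interval")
  }
  T <- regime$interval_h
  d <- exp(-spec$mortality_rate * T)
  input <- spec$dilution_rate * spec$supply_concentration * T
  N <- state$consumers
  R <- state$resources
  if (regime$mortality_mode == "intermittent") {
    N <- d * N
    R <- if (regime$pulse_dialect == "serial_transfer") d * R + input else R + input
  } else {
    R <- R + input
  }
  system_state(N, R, time = state$time)
}

#' Integrator controls
#'
#' @param rtol,atol relative and absolute solver tolerances (lsoda).
#' @param dt_out target spacing of trajectory output points, hours; for
#'   pulsed runs it is rounded so that an integer number of output points
#'   fits in each inter-pulse interval.
#' @param check_window_h length of the steady-state comparison window, hours;
#'   pulsed runs round it up to a whole number of pulse cycles.
#' @param ss_tol relative change in (cycle-averaged) abundances between
#'   consecutive windows below which the run is declared steady.
#' @param ss_floor abundance floor used in the relative-change denominator so
#'   that species far below the extinction threshold cannot block
#'   convergence.
#' @param keep_trajectory store the (thinned) trajectory in the result.
#' @param thin keep every `thin`-th output row when storing the trajectory.
#' @return A list of class `solver_controls`.
#' @export
solver_controls <- function(rtol = 1e-8, atol = 1e-10, dt_out = 0.1,
                            check_window_h = 96, ss_tol = 1e-3,
                            ss_floor = 1e-6, keep_trajectory = FALSE,
                            thin = 10L) {
  structure(list(rtol = rtol, atol = atol, dt_out = dt_out,
                 check_window_h = check_window_h, ss_tol = ss_tol,
                 ss_floor = ss_floor, keep_trajectory = keep_trajectory,
                 thin = as.integer(thin)),
            class = "solver_controls")
}

# parameter vector for the compiled RHS/event functions; layout documented
# in src/crm.c
pack_parms <- function(spec, supply_on, mortality_on, d_surv = 1,
                       pulse_add = NULL, additive = 0, dilute_cells = 0) {
  tr <- spec$traits
  if (is.null(pulse_add)) pulse_add <- rep(0, tr$n_resources)
  c(tr$n_consumers, tr$n_resources,
    spec$mortality_rate, spec$dilution_rate,
    as.numeric(spec$resource_rule == "essential"),
    supply_on, mortality_on, d_surv, additive, dilute_cells,
    spec$supply_concentration, pulse_add,
    as.vector(tr$mu_max), as.vector(tr$k_s), as.vector(tr$quota))
}

# trapezoid mean over uniformly spaced rows
trapezoid_mean <- function(mat) {
  n <- nrow(mat)
  if (n == 1L) return(mat[1, ])
  (colSums(mat) - (mat[1, ] + mat[n, ]) / 2) / (n - 1)
}

#' Simulate a community to steady state under a supply regime
#'
#' Continuous regimes integrate the chemostat equations; pulsed regimes
#' integrate the batch-phase equations with transfer/replenishment events at
#' exact multiples of the pulse interval (the solver restarts at every event,
#' so event timing is deterministic).  Integration proceeds in windows of
#' `controls$check_window_h` hours (rounded up to whole pulse cycles) and
#' stops early once the window-averaged abundances (pulsed) or the endpoint
#' abundances (continuous) change by less than `controls$ss_tol` between
#' consecutive windows.
#'
#' @param spec a [model_spec()].
#' @param regime a [supply_regime()].
#' @param init initial [system_state()]; default `N_i = 0.01`, `R_j = S_j`.
#' @param horizon_h maximum simulated time, hours.
#' @param controls a [solver_controls()].
#' @return An object of class `crm_sim`: a list with
#'   `final_composition` (named consumer abundances; time-averaged over a
#'   trailing 24 h window covering whole pulse cycles for pulsed runs, the
#'   final state for continuous runs), `final_resources` (same convention),
#'   `final_state` (the instantaneous end state), `converged`, `failed`,
#'   `time_simulated`, `regime`, `init_density` (maximum initial consumer
#'   density, used for default extinction thresholds) and optionally
#'   `trajectory`.
#' @export
simulate_community <- function(spec, regime, init = NULL, horizon_h = 1000,
                               controls = solver_controls()) {
  stopifnot(inherits(spec, "model_spec"), inherits(regime, "supply_regime"))
  tr <- spec$traits
  nc <- tr$n_consumers
  nr <- tr$n_resources
  if (is.null(init)) {
    init <- system_state(rep(0.01, nc), spec$supply_concentration)
  }
  if (length(init$consumers) != nc || length(init$resources) != nr) {
    stop("`init` does not match the trait set dimensions")
  }
  cons_names <- rownames(tr$mu_max)
  res_names <- colnames(tr$mu_max)
  y <- c(setNames(init$consumers, cons_names),
         setNames(init$resources, res_names))

  pulsed <- regime$kind == "pulsed"
  if (pulsed) {
    T <- regime$interval_h
    nsteps <- max(1L, as.integer(round(T / controls$dt_out)))
    dt <- T / nsteps
    n_cyc <- max(1L, as.integer(ceiling(controls$check_window_h / T - 1e-9)))
    chunk_h <- n_cyc * T
    parms <- pack_parms(
      spec,
      supply_on = 0,
      mortality_on = as.numeric(regime$mortality_mode == "continuous"),
      d_surv = exp(-spec$mortality_rate * T),
      pulse_add = spec$dilution_rate * spec$supply_concentration * T,
      additive = as.numeric(regime$pulse_dialect == "additive"),
      dilute_cells = as.numeric(regime$mortality_mode == "intermittent")
    )
    n_rows <- nsteps * n_cyc + 1L
  } else {
    if (abs(spec$dilution_rate - spec$mortality_rate) > 1e-12) {
      stop("under the continuous regime `dilution_rate` must equal ",
           "`mortality_rate` (chemostat convention)")
    }
    chunk_h <- controls$check_window_h
    nsteps_chunk <- max(1L, as.integer(round(chunk_h / controls$dt_out)))
    dt <- chunk_h / nsteps_chunk
    parms <- pack_parms(spec, supply_on = 1, mortality_on = 1)
    n_rows <- nsteps_chunk + 1L
  }
  rel_times <- dt * seq.int(0L, n_rows - 1L)

  n_chunks <- max(1L, as.integer(floor(horizon_h / chunk_h + 1e-9)))
  t0 <- 0
  prev_avg <- NULL
  converged <- FALSE
  failed <- FALSE
  last_chunk <- NULL
  traj <- if (controls$keep_trajectory) vector("list", n_chunks) else NULL

  for (k in seq_len(n_chunks)) {
    times <- t0 + rel_times
    ev <- if (pulsed && n_cyc > 1L) {
      list(func = "crm_event", time = times[1L + nsteps * seq_len(n_cyc - 1L)])
    } else NULL
    out <- tryCatch(
      suppressWarnings(
        deSolve::lsoda(y, times, func = "crm_derivs", parms = parms,
                       dllname = "pulseCR", initfunc = "crm_init",
                       events = ev, rtol = controls$rtol, atol = controls$atol)
      ),
      error = function(e) e
    )
    ok <- !inherits(out, "error") && is.matrix(out) && nrow(out) == n_rows &&
      !anyNA(out) && attr(out, "istate")[1] >= 0
    if (!ok) {
      failed <- TRUE
      warning("solver failure at t = ", t0, "; run flagged non-converged")
      break
    }
    mat <- unclass(out)
    last_chunk <- mat
    if (controls$keep_trajectory) {
      traj[[k]] <- mat[unique(c(seq(1L, n_rows, by = controls$thin), n_rows)), ,
                       drop = FALSE]
    }
    y_end <- mat[n_rows, -1L]
    t0 <- t0 + chunk_h

    # the solver reports the pre-event state at event times, so the pulse
    # that closes the window is applied here before the next window starts
    if (pulsed) {
      st <- apply_pulse(
        system_state(pmax(y_end[seq_len(nc)], 0),
                     pmax(y_end[nc + seq_len(nr)], 0), time = t0),
        spec, regime
      )
      y <- c(setNames(st$consumers, cons_names),
             setNames(st$resources, res_names))
    } else {
      y <- y_end
    }

    avg <- if (pulsed) {
      trapezoid_mean(mat[, 1L + seq_len(nc), drop = FALSE])
    } else {
      y_end[seq_len(nc)]
    }
    if (!is.null(prev_avg)) {
      delta <- max(abs(avg - prev_avg) / pmax(prev_avg, controls$ss_floor))
      if (delta < controls$ss_tol) {
        converged <- TRUE
        break
      }
    }
    prev_avg <- avg
  }

  if (is.null(last_chunk)) {
    # solver failed in the very first window: flag the run, never drop it
    return(structure(
      list(final_composition = setNames(rep(0, nc), cons_names),
           final_resources = setNames(rep(NA_real_, nr), res_names),
           final_state = init, converged = FALSE, failed = TRUE,
           time_simulated = 0, regime = regime,
           init_density = max(init$consumers), trajectory = NULL),
      class = "crm_sim"
    ))
  }

  if (pulsed) {
    window_h <- ceiling(24 / regime$interval_h - 1e-9) * regime$interval_h
    window_h <- min(window_h, chunk_h)
    n_win <- as.integer(round(window_h / dt))
    rows <- seq.int(nrow(last_chunk) - n_win, nrow(last_chunk))
    final_composition <- trapezoid_mean(last_chunk[rows, 1L + seq_len(nc),
                                                   drop = FALSE])
    final_resources <- trapezoid_mean(last_chunk[rows, 1L + nc + seq_len(nr),
                                                 drop = FALSE])
  } else {
    final_composition <- last_chunk[nrow(last_chunk), 1L + seq_len(nc)]
    final_resources <- last_chunk[nrow(last_chunk), 1L + nc + seq_len(nr)]
  }
  end_state <- last_chunk[nrow(last_chunk), -1L]

  trajectory <- NULL
  if (controls$keep_trajectory) {
    tm <- do.call(rbind, traj[!vapply(traj, is.null, logical(1))])
    trajectory <- tibble::as_tibble(as.data.frame(tm))
    names(trajectory)[1] <- "time"
    trajectory <- trajectory[!duplicated(trajectory$time), ]
  }

  structure(
    list(
      final_composition = pmax(setNames(as.numeric(final_composition),
                                        cons_names), 0),
      final_resources = pmax(setNames(as.numeric(final_resources),
                                      res_names), 0),
      final_state = system_state(pmax(end_state[seq_len(nc)], 0),
                                 pmax(end_state[nc + seq_len(nr)], 0),
                                 time = t0),
      converged = converged,
      failed = failed,
      time_simulated = t0,
      regime = regime,
      init_density = max(init$consumers),
      trajectory = trajectory
    ),
    class = "crm_sim"
  )
}

#' @export
print.crm_sim <- function(x, ...) {
  lab <- if (x$regime$kind == "continuous") "continuous" else
    paste0("pulsed T = ", x$regime$interval_h, " h")
  cat("<crm_sim> ", lab, "; ", x$time_simulated, " h simulated; ",
      if (x$converged) "steady" else "NOT steady", "\n", sep = "")
  print(signif(x$final_composition, 4))
  invisible(x)
}

#' Detect steady state in a trajectory
#'
#' Compares mean abundances over the last two non-overlapping windows of
#' length `window_h`; the trajectory is steady when every column changes by
#' less than `tol` in relative terms.  For pulsed dynamics choose `window_h`
#' as a whole number of pulse cycles so that limit cycles with the pulse
#' period register as steady.
#'
#' @param trajectory data frame with a `time` column and one column per
#'   state variable (uniformly spaced times).
#' @param window_h window length, hours; the trajectory must span at least
#'   two windows.
#' @param tol relative-change tolerance.
#' @param floor denominator floor for the relative change.
#' @return Logical flag.
#' @export
detect_steady_state <- function(trajectory, window_h, tol = 1e-3,
                                floor = 1e-6) {
  trajectory <- as.data.frame(trajectory)
  if (!"time" %in% names(trajectory)) stop("`trajectory` needs a `time` column")
  tend <- max(trajectory$time)
  span <- tend - min(trajectory$time)
  if (span < 2 * window_h) stop("trajectory must span at least two windows")
  vals <- as.matrix(trajectory[setdiff(names(trajectory), "time")])
  w2 <- trajectory$time > tend - window_h
  w1 <- trajectory$time > tend - 2 * window_h & !w2
  m1 <- colMeans(vals[w1, , drop = FALSE])
  m2 <- colMeans(vals[w2, , drop = FALSE])
  max(abs(m2 - m1) / pmax(m1, floor)) < tol
}
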