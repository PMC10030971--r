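#' Community composition from steady-state abundances
#'
#' Applies an extinction threshold to (time-averaged) steady-state
#' abundances.  The default threshold is `1e-4` times the initial density,
#' i.e. a species counts as persisting only if it holds at least 0.01% of
#' its inoculum.
#'
#' @param x a [simulate_community()] result or a named numeric vector of
#'   abundances.
#' @param threshold absolute extinction threshold; defaults to
#'   `extinction_frac * init_density` for `crm_sim` input and must be given
#'   for raw vectors.
#' @param extinction_frac fraction of the initial density used for the
#'   default threshold.
#' @param source optional label (regime/interval) carried along.
#' @return An object of class `community_composition` with elements
#'   `abundances`, `persistent` (named logical), `threshold` and `source`.
#' @export
community_composition <- function(x, threshold = NULL,
                                  extinction_frac = 1e-4, source = NULL) {
  if (inherits(x, "crm_sim")) {
    ab <- x$final_composition
    if (is.null(threshold)) threshold <- extinction_frac * x$init_density
    if (is.null(source)) {
      source <- if (x$regime$kind == "continuous") "continuous" else
        paste0("pulsed_", x$regime$interval_h, "h")
    }
  } else {
    ab <- x
    if (is.null(names(ab))) stop("abundance vectors must be named")
    if (is.null(threshold)) stop("`threshold` is required for raw abundances")
  }
  structure(
    list(abundances = ab, persistent = ab > threshold,
         threshold = threshold, source = source),
    class = "community_composition"
  )
}

#' @export
print.community_composition <- function(x, ...) {
  cat("<community_composition>",
      if (!is.null(x$source)) paste0("[", x$source, "]"), "persisting:",
      paste(names(x$persistent)[x$persistent], collapse = ", "), "\n")
  invisible(x)
}

#' Number of persisting species
#'
#' @param comp a [community_composition()].
#' @return Integer richness.
#' @export
richness <- function(comp) {
  stopifnot(inherits(comp, "community_composition"))
  sum(comp$persistent)
}

#' Jaccard similarity of two communities
#'
#' \eqn{J(A, B) = |A \cap B| / |A \cup B|} over the sets of persisting
#' species.  Both sets empty is treated as identical communities
#' (\eqn{J = 1}).
#'
#' @param a,b [community_composition()] objects over the same consumer
#'   universe.
#' @return Similarity in `[0, 1]`.
#' @examples
#' u <- c(sp1 = 1, sp2 = 1, sp3 = 1, sp4 = 0, sp5 = 0)
#' v <- c(sp1 = 0, sp2 = 1, sp3 = 1, sp4 = 1, sp5 = 0)
#' jaccard(community_composition(u, 0.5), community_composition(v, 0.5)) # 0.5
#' @export
jaccard <- function(a, b) {
  stopifnot(inherits(a, "community_composition"),
            inherits(b, "community_composition"))
  if (!identical(names(a$persistent), names(b$persistent))) {
    stop("communities are defined over different consumer universes")
  }
  inter <- sum(a$persistent & b$persistent)
  union <- sum(a$persistent | b$persistent)
  if (union == 0) 1 else inter / union
}

#' Abundance-weighted mean traits of a community
#'
#' Each consumer's trait is first averaged across resources (mean affinity
#' \eqn{\mu_{max}/K_s} and mean \eqn{\mu_{max}}); the community value is the
#' mean over persisting consumers weighted by their steady-state abundance
#' (weights normalised to 1).  An empty community yields `NA`s.
#'
#' @param comp a [community_composition()].
#' @param traits the community's [trait_set()].
#' @return Named numeric vector `c(affinity = , mu_max = )`.
#' @export
weighted_trait_means <- function(comp, traits) {
  stopifnot(inherits(comp, "community_composition"),
            inherits(traits, "trait_set"))
  if (!identical(names(comp$persistent), rownames(traits$mu_max))) {
    stop("composition and trait set refer to different consumers")
  }
  if (!any(comp$persistent)) {
    return(c(affinity = NA_real_, mu_max = NA_real_))
  }
  mean_aff <- rowMeans(affinity(traits))
  mean_mu <- rowMeans(traits$mu_max)
  w <- comp$abundances[comp$persistent]
  w <- w / sum(w)
  c(affinity = sum(w * mean_aff[comp$persistent]),
    mu_max = sum(w * mean_mu[comp$persistent]))
}

#' Summarise a simulated study across regimes
#'
#' Scores every combination's pulsed compositions against its own
#' continuous-supply composition (Jaccard similarity of persistence sets),
#' and computes richness and abundance-weighted mean traits per run, plus
#' grand means per interval.  Runs that did not reach steady state are
#' excluded from the summaries and counted; a combination whose continuous
#' run is missing is an error.
#'
#' @param results list over combinations; each element a list with elements
#'   `continuous` (a `crm_sim`) and `pulsed` (a list of `crm_sim` named by
#'   interval in hours).
#' @param study the [sample_study()] the simulations were run on (first
#'   `length(results)` combinations).
#' @param extinction_frac extinction threshold as a fraction of the initial
#'   density.
#' @return A list of class `experiment_table` with tibbles `runs` (one row
#'   per combo x regime x consumer), `combo_summary` (one row per combo x
#'   regime: `jaccard_vs_continuous`, `richness`, `weighted_mean_affinity`,
#'   `weighted_mean_mu_max`, `converged`) and `interval_summary` (grand means
#'   per regime with counts of used and excluded runs).
#' @export
summarise_study <- function(results, study, extinction_frac = 1e-4) {
  stopifnot(inherits(study, "crm_study"))
  if (length(results) > length(study$traits)) {
    stop("more results than sampled combinations")
  }
  combo_ids <- names(study$traits)[seq_along(results)]

  run_rows <- list()
  combo_rows <- list()
  for (ci in seq_along(results)) {
    res <- results[[ci]]
    if (is.null(res$continuous)) {
      stop("combination ", combo_ids[ci], " is missing its continuous run")
    }
    traits <- study$traits[[ci]]
    sims <- c(list(continuous = res$continuous), res$pulsed)
    intervals <- c(NA_real_, as.numeric(names(res$pulsed)))
    comp_cont <- community_composition(res$continuous,
                                       extinction_frac = extinction_frac)
    for (si in seq_along(sims)) {
      sim <- sims[[si]]
      comp <- community_composition(sim, extinction_frac = extinction_frac)
      wtm <- weighted_trait_means(comp, traits)
      jac <- if (si == 1L) 1 else jaccard(comp_cont, comp)
      lab <- if (si == 1L) "continuous" else names(sims)[si]
      run_rows[[length(run_rows) + 1L]] <- tibble::tibble(
        combo_id = combo_ids[ci], regime = lab, interval_h = intervals[si],
        consumer = names(comp$abundances),
        abundance = as.numeric(comp$abundances),
        persistent = as.logical(comp$persistent),
        converged = sim$converged
      )
      combo_rows[[length(combo_rows) + 1L]] <- tibble::tibble(
        combo_id = combo_ids[ci], regime = lab, interval_h = intervals[si],
        jaccard_vs_continuous = jac, richness = richness(comp),
        weighted_mean_affinity = wtm[["affinity"]],
        weighted_mean_mu_max = wtm[["mu_max"]],
        converged = sim$converged,
        pair_converged = sim$converged && res$continuous$converged
      )
    }
  }
  runs <- dplyr::bind_rows(run_rows)
  combo_summary <- dplyr::bind_rows(combo_rows)

  interval_summary <- combo_summary |>
    dplyr::group_by(.data$regime, .data$interval_h) |>
    dplyr::summarise(
      mean_jaccard = mean(.data$jaccard_vs_continuous[.data$pair_converged]),
      se_jaccard = stats::sd(.data$jaccard_vs_continuous[.data$pair_converged]) /
        sqrt(sum(.data$pair_converged)),
      mean_richness = mean(.data$richness[.data$pair_converged]),
      mean_weighted_affinity = mean(.data$weighted_mean_affinity[.data$pair_converged],
                                    na.rm = TRUE),
      mean_weighted_mu_max = mean(.data$weighted_mean_mu_max[.data$pair_converged],
                                  na.rm = TRUE),
      n_used = sum(.data$pair_converged),
      n_excluded = sum(!.data$pair_converged),
      .groups = "drop"
    ) |>
    dplyr::arrange(!is.na(.data$interval_h), .data$interval_h)

  structure(
    list(runs = runs, combo_summary = combo_summary,
         interval_summary = interval_summary,
         extinction_frac = extinction_frac),
    class = "experiment_table"
  )
}

#' @export
print.experiment_table <- function(x, ...) {
  cat("<experiment_table> ", dplyr::n_distinct(x$combo_summary$combo_id),
      " combos x ", dplyr::n_distinct(x$combo_summary$regime),
      " regimes\n", sep = "")
  print(x$interval_summary)
  invisible(x)
}
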