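# evaluate `code` under `seed` without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

rdirichlet_rows <- function(n, k, conc) {
  g <- matrix(rgamma(n * k, shape = conc), n, k)
  g / rowSums(g)
}

#' Trait sampler configuration
#'
#' Configures the random generation of consumer-resource trait sets.  Each
#' consumer's minimum doubling time (when all resources are non-limiting) is
#' drawn uniformly between `doubling_min_min` and `doubling_min_max` minutes;
#' the implied total maximum growth rate is then split across resources to
#' create resource-use differentiation.  Half-saturation constants are drawn
#' log-uniformly (no trade-off) or set by a gleaner-opportunist trade-off
#' that makes affinity a decreasing power of the maximum growth rate,
#' \eqn{a_{ij} = c\,\mu_{max,ij}^{-\theta}}, optionally blurred with
#' lognormal noise (`tradeoff = "weak"`).
#'
#' @param n_consumers,n_resources community size; the study uses 5 x 5.
#' @param n_combos number of independent competitor combinations per study
#'   (study: 100).
#' @param doubling_min_min,doubling_min_max bounds of the minimum doubling
#'   time in minutes (study: 21 and 52, i.e. total maximum growth rates
#'   between ln2/(52/60) ~ 0.80 and ln2/(21/60) ~ 1.98 h^-1).
#' @param tradeoff `"none"`, `"strict"` or `"weak"`.
#' @param tradeoff_exponent trade-off steepness `theta` (>= 0).
#' @param tradeoff_scale the constant `c` in `a = c mu^(-theta)`; the default
#'   places the resulting half-saturation constants on both sides of the
#'   supply concentration so that Monod curves of gleaners and opportunists
#'   cross at ecologically relevant concentrations.
#' @param tradeoff_noise_sd lognormal sd applied to affinity in `"weak"` mode.
#' @param k_s_log_range range of the log-uniform half-saturation draw in
#'   no-trade-off mode, in supply-concentration units.
#' @param rate_convention how the non-limiting growth rate relates to the
#'   per-resource `mu_max`: `"sum"` (substitutable resources; per-resource
#'   rates split by a symmetric Dirichlet) or `"min"` (essential resources;
#'   the limiting rate equals the drawn rate and the others exceed it by
#'   log-uniform factors up to `min_spread_max`).
#' @param dirichlet_conc concentration of the symmetric Dirichlet split.
#' @param min_spread_max upper bound of the spread factors under
#'   `rate_convention = "min"`.
#' @param seed master RNG seed; the study is a pure function of this
#'   configuration.
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(n_consumers = 5, n_resources = 5, n_combos = 100,
                           doubling_min_min = 21, doubling_min_max = 52,
                           tradeoff = c("none", "strict", "weak"),
                           tradeoff_exponent = 1.5,
                           tradeoff_scale = 0.3,
                           tradeoff_noise_sd = 0.5,
                           k_s_log_range = c(0.01, 0.5),
                           rate_convention = c("sum", "min"),
                           dirichlet_conc = 5,
                           min_spread_max = 4,
                           seed = 1L) {
  tradeoff <- match.arg(tradeoff)
  rate_convention <- match.arg(rate_convention)
  if (n_consumers < 1 || n_resources < 1) stop("community must be non-empty")
  if (doubling_min_min <= 0 || doubling_min_max < doubling_min_min) {
    stop("doubling-time bounds must be positive and ordered")
  }
  if (tradeoff_exponent < 0) stop("`tradeoff_exponent` must be >= 0")
  if (tradeoff_scale <= 0) stop("`tradeoff_scale` must be positive")
  if (length(k_s_log_range) != 2 || any(k_s_log_range <= 0) ||
      diff(k_s_log_range) <= 0) {
    stop("`k_s_log_range` must be positive and increasing")
  }
  structure(
    list(n_consumers = as.integer(n_consumers),
         n_resources = as.integer(n_resources),
         n_combos = as.integer(n_combos),
         doubling_min_min = doubling_min_min,
         doubling_min_max = doubling_min_max,
         tradeoff = tradeoff,
         tradeoff_exponent = tradeoff_exponent,
         tradeoff_scale = tradeoff_scale,
         tradeoff_noise_sd = tradeoff_noise_sd,
         k_s_log_range = as.numeric(k_s_log_range),
         rate_convention = rate_convention,
         dirichlet_conc = dirichlet_conc,
         min_spread_max = min_spread_max,
         seed = as.integer(seed)),
    class = "sampler_config"
  )
}

#' Draw one random trait set
#'
#' @param config a [sampler_config()].
#' @param seed RNG seed for this draw; defaults to `config$seed`.  The same
#'   seed always yields the same trait set.
#' @return A [trait_set()].
#' @examples
#' tr <- sample_traits(sampler_config(seed = 42))
#' range(min_doubling_time(tr)) # within [21, 52] min
#' @export
sample_traits <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sampler_config"))
  nc <- config$n_consumers
  nr <- config$n_resources
  with_seed(seed, {
    dbl_min <- runif(nc, config$doubling_min_min, config$doubling_min_max)
    g <- log(2) / (dbl_min / 60) # total non-limiting growth rate, h^-1
    mu <- if (config$rate_convention == "sum") {
      g * rdirichlet_rows(nc, nr, config$dirichlet_conc)
    } else {
      x <- matrix(exp(runif(nc * nr, 0, log(config$min_spread_max))), nc, nr)
      g * x / apply(x, 1, min)
    }
    ks <- switch(config$tradeoff,
      none = matrix(exp(runif(nc * nr, log(config$k_s_log_range[1]),
                              log(config$k_s_log_range[2]))), nc, nr),
      strict = mu^(1 + config$tradeoff_exponent) / config$tradeoff_scale,
      weak = {
        a <- config$tradeoff_scale * mu^(-config$tradeoff_exponent) *
          exp(matrix(rnorm(nc * nr, sd = config$tradeoff_noise_sd), nc, nr))
        mu / a
      }
    )
    trait_set(mu, ks)
  })
}

#' Draw a study: a collection of independent trait sets
#'
#' Child seeds for each competitor combination are derived deterministically
#' from the master seed, so the study is a pure function of its
#' configuration and any prefix of combinations is stable under
#' down-sampling (used by [reduced_run()]).
#'
#' @param config a [sampler_config()].
#' @param n_combos number of combinations to realise; defaults to
#'   `config$n_combos`, and must not exceed it.
#' @return An object of class `crm_study`: a list with `config`, integer
#'   `seeds`, and `traits` (a list of [trait_set()]s).
#' @export
sample_study <- function(config, n_combos = config$n_combos) {
  stopifnot(inherits(config, "sampler_config"))
  if (n_combos < 1) stop("`n_combos` must be at least 1")
  if (n_combos > config$n_combos) {
    stop("`n_combos` exceeds the configured study size")
  }
  seeds <- with_seed(config$seed,
                     sample.int(.Machine$integer.max, config$n_combos))
  seeds <- seeds[seq_len(n_combos)]
  traits <- lapply(seeds, function(s) sample_traits(config, seed = s))
  names(traits) <- sprintf("combo%03d", seq_len(n_combos))
  structure(list(config = config, seeds = seeds, traits = traits),
            class = "crm_study")
}

#' @export
print.crm_study <- function(x, ...) {
  cat("<crm_study> ", length(x$traits), " combos of ",
      x$config$n_consumers, " consumers x ", x$config$n_resources,
      " resources; tradeoff = ", x$config$tradeoff,
      "; master seed = ", x$config$seed, "\n", sep = "")
  invisible(x)
}
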