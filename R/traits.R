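#' Consumer-resource trait set
#'
#' A trait set holds the Monod growth parameters of every consumer on every
#' resource: the maximum growth rate \eqn{\mu_{max,ij}} (h\eqn{^{-1}}), the
#' half-saturation constant \eqn{K_{s,ij}} (resource-concentration units) and
#' the resource quota \eqn{Q_{ij}} (amount of resource incorporated per unit
#' of consumer biomass produced).
#'
#' @param mu_max numeric matrix (consumers x resources) of maximum growth
#'   rates, h^-1; all entries must be positive and finite.
#' @param k_s numeric matrix of half-saturation constants, same shape as
#'   `mu_max`; positive and finite.
#' @param quota resource quotas: a scalar (recycled) or a matrix of the same
#'   shape; positive. Default 1, so traits differ only in `mu_max` and `k_s`.
#'
#' @return An object of class `trait_set`: a list with elements `mu_max`,
#'   `k_s`, `quota` (matrices with consumer rownames and resource colnames),
#'   `n_consumers` and `n_resources`.
#' @examples
#' tr <- trait_set(mu_max = matrix(c(1, 2), 2, 1), k_s = matrix(c(1, 4), 2, 1))
#' affinity(tr)
#' @export
trait_set <- function(mu_max, k_s, quota = 1) {
  mu_max <- as.matrix(mu_max)
  k_s <- as.matrix(k_s)
  if (!all(dim(k_s) == dim(mu_max))) {
    stop("`mu_max` and `k_s` must have the same dimensions")
  }
  nc <- nrow(mu_max)
  nr <- ncol(mu_max)
  if (length(quota) == 1L) quota <- matrix(quota, nc, nr)
  quota <- as.matrix(quota)
  if (!all(dim(quota) == c(nc, nr))) {
    stop("`quota` must be a scalar or a matrix matching `mu_max`")
  }
  for (nm in c("mu_max", "k_s", "quota")) {
    x <- get(nm)
    if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)) || any(x <= 0)) {
      stop("all `", nm, "` entries must be positive and finite")
    }
  }
  cn <- rownames(mu_max)
  rn <- colnames(mu_max)
  if (is.null(cn)) cn <- paste0("sp", seq_len(nc))
  if (is.null(rn)) rn <- paste0("res", seq_len(nr))
  dn <- list(cn, rn)
  dimnames(mu_max) <- dimnames(k_s) <- dimnames(quota) <- dn
  structure(
    list(mu_max = mu_max, k_s = k_s, quota = quota,
         n_consumers = nc, n_resources = nr),
    class = "trait_set"
  )
}

#' @export
print.trait_set <- function(x, ...) {
  cat("<trait_set> ", x$n_consumers, " consumers x ", x$n_resources,
      " resources\n", sep = "")
  cat("mu_max (h^-1):\n")
  print(signif(x$mu_max, 4))
  cat("k_s:\n")
  print(signif(x$k_s, 4))
  invisible(x)
}

#' Resource affinity
#'
#' Affinity is the initial slope of the Monod curve,
#' \eqn{a_{ij} = \mu_{max,ij}/K_{s,ij}}; it measures competitiveness at low
#' resource concentrations.
#'
#' @param traits a [trait_set()].
#' @return Matrix of affinities (consumers x resources).
#' @export
affinity <- function(traits) {
  stopifnot(inherits(traits, "trait_set"))
  traits$mu_max / traits$k_s
}

#' Minimum doubling time of each consumer
#'
#' The doubling time when all resources are at saturating concentration.
#' Under the substitutable rule the non-limiting growth rate of consumer
#' \eqn{i} is \eqn{\sum_j \mu_{max,ij}} (`convention = "sum"`); under the
#' essential (Liebig) rule it is \eqn{\min_j \mu_{max,ij}}
#' (`convention = "min"`).
#'
#' @param traits a [trait_set()].
#' @param convention `"sum"` (substitutable resources) or `"min"` (essential
#'   resources).
#' @return Named numeric vector of doubling times in minutes.
#' @export
min_doubling_time <- function(traits, convention = c("sum", "min")) {
  stopifnot(inherits(traits, "trait_set"))
  convention <- match.arg(convention)
  rate <- switch(convention,
    sum = rowSums(traits$mu_max),
    min = apply(traits$mu_max, 1, min)
  )
  60 * log(2) / rate
}

#' Read and write trait sets as CSV
#'
#' Trait sets are serialised in long format with columns `consumer`,
#' `resource`, `mu_max`, `k_s`, `quota` (one row per consumer-resource pair).
#'
#' @param traits a [trait_set()].
#' @param path file path.
#' @return `write_traits()` returns `path` invisibly; `read_traits()` returns
#'   a [trait_set()].
#' @export
write_traits <- function(traits, path) {
  stopifnot(inherits(traits, "trait_set"))
  readr::write_csv(as_trait_tibble(traits), path)
  invisible(path)
}

#' @rdname write_traits
#' @export
read_traits <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("consumer", "resource", "mu_max", "k_s", "quota")
  if (!all(need %in% names(df))) {
    stop("trait CSV must have columns: ", paste(need, collapse = ", "))
  }
  cons <- unique(df$consumer)
  res <- unique(df$resource)
  shape <- function(col) {
    m <- matrix(NA_real_, length(cons), length(res),
                dimnames = list(cons, res))
    m[cbind(match(df$consumer, cons), match(df$resource, res))] <- df[[col]]
    m
  }
  trait_set(shape("mu_max"), shape("k_s"), shape("quota"))
}

# long-format tibble used by serialisation and the experiment outputs
as_trait_tibble <- function(traits, combo_id = NULL) {
  dn <- dimnames(traits$mu_max)
  out <- tibble::tibble(
    consumer = rep(dn[[1]], times = traits$n_resources),
    resource = rep(dn[[2]], each = traits$n_consumers),
    mu_max = as.vector(traits$mu_max),
    k_s = as.vector(traits$k_s),
    quota = as.vector(traits$quota)
  )
  if (!is.null(combo_id)) out <- dplyr::mutate(out, combo_id = combo_id, .before = 1)
  out
}
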