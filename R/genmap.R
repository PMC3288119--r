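#' Haldane map function
#'
#' Converts between recombination fraction and map distance under the Haldane
#' (no crossover interference) model: d = -50 log(1 - 2r) and
#' r = (1 - exp(-2d/100)) / 2.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @param d map distance(s) in cM, non-negative.
#' @return `haldane_cm()` returns distances in cM; `haldane_r()` returns
#'   recombination fractions.
#' @examples
#' haldane_cm(0.25) # ~34.657
#' haldane_r(haldane_cm(0.1)) # 0.1
#' @export
haldane_cm <- function(r) {
  if (any(!is.finite(r)) || any(r < 0) || any(r >= 0.5)) {
    abort("`r` must lie in [0, 0.5)")
  }
  -50 * log(1 - 2 * r)
}

#' @rdname haldane_cm
#' @export
haldane_r <- function(d) {
  if (any(!is.finite(d)) || any(d < 0)) abort("`d` must be non-negative")
  0.5 * (1 - exp(-2 * d / 100))
}

#' Two-point recombination estimate from transmitted-allele indicators
#'
#' Estimates the recombination fraction between two markers from the meioses
#' of one parent: among progeny of that parent for which both markers are
#' informative, the recombinant fraction of transmitted-haplotype indicator
#' pairs. Phase is taken as known (simulator truth or phased input). The
#' linkage LOD is the log10 likelihood ratio of the binomial model at
#' `r_hat` versus free recombination (r = 0.5).
#'
#' @param pop a `diallel_pop` (see [sim_population()]).
#' @param m1,m2 marker ids.
#' @param parent parent id; the estimate uses only meioses of this parent.
#' @return one-row tibble `parent, marker1, marker2, n, r_hat, lod`.
#' @export
estimate_recombination <- function(pop, m1, m2, parent) {
  stopifnot(inherits(pop, "diallel_pop"))
  for (m in c(m1, m2)) {
    if (!m %in% colnames(pop$xf)) abort(sprintf("unknown marker '%s'", m))
  }
  x1 <- parent_indicator(pop, parent, m1)
  x2 <- parent_indicator(pop, parent, m2)
  keep <- !is.na(x1) & !is.na(x2)
  n <- sum(keep)
  if (n == 0) abort("uninformative pair: no meioses informative at both markers")
  k <- sum(x1[keep] != x2[keep])
  r_hat <- min(k / n, 0.5)
  lod <- binom_linkage_lod(k, n, r_hat)
  tibble(
    parent = parent, marker1 = m1, marker2 = m2,
    n = n, r_hat = r_hat, lod = lod
  )
}

# log10 LR of binomial(n, r) against r = 0.5, evaluated at r (0*log 0 := 0)
binom_linkage_lod <- function(k, n, r) {
  term <- function(count, p) if (count == 0) 0 else count * log10(p / 0.5)
  max(0, term(k, max(r, .Machine$double.xmin)) + term(n - k, 1 - r))
}

# transmitted-allele indicator column of `parent` at `marker` across all
# progeny (NA where the parent is not a parent of the progeny, or homozygous)
parent_indicator <- function(pop, parent, marker) {
  ind <- pop$individuals
  if (!parent %in% c(ind$female, ind$male)) {
    abort(sprintf("unknown parent '%s'", parent))
  }
  out <- rep(NA_real_, nrow(ind))
  is_f <- ind$female == parent
  is_m <- ind$male == parent
  out[is_f] <- pop$xf[is_f, marker]
  out[is_m] <- pop$xm[is_m, marker]
  out
}

#' All-pairs two-point estimates for one parent
#'
#' @inheritParams estimate_recombination
#' @param markers optional subset of marker ids (default: all map markers).
#' @return tibble with one row per marker pair informative in `parent`.
#' @export
estimate_recombination_all <- function(pop, parent, markers = NULL) {
  markers <- markers %||% pop$map$marker_id
  x <- vapply(markers, function(m) parent_indicator(pop, parent, m),
    numeric(nrow(pop$individuals))
  )
  pairs <- utils::combn(seq_along(markers), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    keep <- !is.na(x[, i1]) & !is.na(x[, i2])
    n <- sum(keep)
    if (n == 0) return(NULL)
    k <- sum(x[keep, i1] != x[keep, i2])
    r_hat <- min(k / n, 0.5)
    tibble(
      parent = parent, marker1 = markers[i1], marker2 = markers[i2],
      n = n, r_hat = r_hat, lod = binom_linkage_lod(k, n, r_hat)
    )
  })
}
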