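# Shared fixtures and independent oracles, all built in code at test time.

# small two-linkage-group map
mini_map <- function(n_markers = 26, n_lg = 2, spacing = 10) {
  sim_genetic_map(n_markers, n_lg, spacing)
}

# single-cross population with a chosen progeny size / heterozygosity
single_cross_pop <- function(n_progeny, map = mini_map(), het = 1, seed = 1) {
  parents <- sim_parents(map, c("F1", "M1"), het_fraction = het, seed = seed)
  design <- diallel_design(tibble::tibble(
    cross_id = "c1", female = "F1", male = "M1", n_progeny = n_progeny
  ))
  sim_population(map, parents, design, seed = seed + 1)
}

# default four-cross study population on a reduced map
study_pop <- function(map = mini_map(), het = 0.28, seed = 1) {
  parents <- sim_parents(map, het_fraction = het, seed = seed)
  sim_population(map, parents, seed = seed + 1)
}

# ---- independent oracles -------------------------------------------------

# all perfect matchings of 1..n (n even), as 2-column index matrices
all_matchings <- function(n) {
  rec <- function(idx) {
    if (length(idx) == 0) {
      return(list(matrix(integer(0), 0, 2)))
    }
    i <- idx[1]
    out <- list()
    for (j in idx[-1]) {
      for (m in rec(setdiff(idx, c(i, j)))) {
        out <- c(out, list(rbind(c(i, j), m)))
      }
    }
    out
  }
  rec(seq_len(n))
}

# exact maximum mean-distance matching by enumeration
brute_force_matching <- function(d) {
  objs <- vapply(
    all_matchings(nrow(d)),
    function(p) mean(d[p]),
    numeric(1)
  )
  max(objs)
}

# OLS residual sum of squares via explicit normal equations
ols_rss <- function(X, y) {
  b <- solve(crossprod(X), crossprod(X, y))
  sum((y - X %*% b)^2)
}

# draws from the null partial-correlation density with kappa df
r_null_draws <- function(n, kappa) {
  sample(c(-1, 1), n, replace = TRUE) * sqrt(rbeta(n, 1 / 2, (kappa - 1) / 2))
}

# gaussian sample from a chain precision matrix (adjacent pcor = rho)
sim_chain_data <- function(n, p, rho = 0.4) {
  omega <- diag(p)
  for (i in seq_len(p - 1)) omega[i, i + 1] <- omega[i + 1, i] <- -rho
  sigma <- solve(omega)
  x <- matrix(rnorm(n * p), n, p) %*% chol(sigma)
  colnames(x) <- sprintf("g%02d", seq_len(p))
  x
}

# symmetric pcor-like matrix filled from a vector of off-diagonal values
pcor_from_offdiag <- function(vals, p) {
  stopifnot(length(vals) >= p * (p - 1) / 2)
  m <- diag(p)
  m[upper.tri(m)] <- vals[seq_len(p * (p - 1) / 2)]
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}
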