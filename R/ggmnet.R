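#' Shrinkage partial correlations (graphical Gaussian model)
#'
#' Estimates the gene-gene partial-correlation matrix from expression
#' residuals with the analytic shrinkage estimator: the sample correlation
#' matrix R is shrunk towards the identity target,
#' `R* = (1 - lambda) R + lambda I`, with
#' `lambda = min(1, sum var_hat(r_ij) / sum r_ij^2)` over off-diagonal
#' entries, and partial correlations are read off the scaled negative
#' inverse, `pcor_ij = -omega_ij / sqrt(omega_ii omega_jj)` with
#' `Omega = (R*)^-1`. The shrinkage keeps R* positive definite and
#' invertible even when genes far outnumber samples, and inverting removes
#' indirect (marginal-only) correlations so edges represent direct
#' conditional dependencies.
#'
#' @param x numeric matrix (individuals x genes) or a `residual_matrix`.
#' @return list of class `gg_pcor`: `pcor` (symmetric, unit diagonal),
#'   `lambda`, `n`, `genes`.
#' @export
shrinkage_partial_correlation <- function(x) {
  if (inherits(x, "residual_matrix")) x <- x$resid
  if (!is.matrix(x)) x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 3) abort("need at least 3 individuals")
  if (p < 2) abort("need at least 2 genes")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0] %||% which(sds == 0)
    abort(paste("constant gene column(s):", paste(head(bad, 5), collapse = ", ")))
  }
  xs <- scale(x) # centred, unit sd (denominator n-1)
  r <- crossprod(xs) / (n - 1)
  # unbiased-variance estimate of each r_ij from the products w_k = x_ki x_kj
  sw2 <- crossprod(xs^2) # sum_k w_k^2
  sw <- (n - 1) * r # sum_k w_k
  var_r <- n / (n - 1)^3 * (sw2 - sw^2 / n)
  off <- upper.tri(r)
  denom <- sum(r[off]^2)
  lambda <- if (denom <= 0) 1 else min(1, sum(var_r[off]) / denom)
  rs <- (1 - lambda) * r
  diag(rs) <- 1
  omega <- solve(rs)
  d <- sqrt(diag(omega))
  pcor <- -omega / tcrossprod(d)
  diag(pcor) <- 1
  pcor <- (pcor + t(pcor)) / 2
  structure(
    list(
      pcor = pcor, lambda = lambda, n = n,
      genes = colnames(x) %||% sprintf("g%03d", seq_len(p))
    ),
    class = "gg_pcor"
  )
}

# null density of a (partial) correlation with kappa degrees of freedom:
# f0(r; kappa) = (1 - r^2)^((kappa - 3) / 2) / Beta(1/2, (kappa - 1)/2)
dcor0 <- function(r, kappa, log = FALSE) {
  ld <- ((kappa - 3) / 2) * log1p(-r^2) - lbeta(1 / 2, (kappa - 1) / 2)
  if (log) ld else exp(ld)
}

# draw from f0(r; kappa): r = sign * sqrt(B), B ~ Beta(1/2, (kappa-1)/2)
rcor0 <- function(n, kappa) {
  sample(c(-1, 1), n, replace = TRUE) * sqrt(rbeta(n, 1 / 2, (kappa - 1) / 2))
}

#' Posterior edge probabilities from partial correlations
#'
#' Fits a two-component mixture to the off-diagonal partial correlations:
#' a null component `eta0 * f0(r; kappa)` with
#' `f0 proportional to (1 - r^2)^((kappa - 3)/2)` and a uniform alternative
#' on (-1, 1). `kappa` is profiled over a geometric grid and `eta0` fit by
#' EM at each grid point; the maximum-likelihood pair is kept. The
#' probability of a direct gene-pair connection is one minus the local
#' false discovery rate, `1 - eta0 f0(r) / f(r)`, clipped to the unit
#' interval.
#'
#' @param pcor a `gg_pcor` or a symmetric partial-correlation matrix.
#' @param kappa_grid grid of candidate null degrees of freedom.
#' @param max_iter,tol EM controls.
#' @return list of class `gg_edgeprob`: `prob` matrix, `eta0`, `kappa`,
#'   `pcor`, `genes`.
#' @export
edge_probabilities <- function(pcor, kappa_grid = NULL, max_iter = 100,
                               tol = 1e-8) {
  genes <- NULL
  lambda <- NA_real_
  if (inherits(pcor, "gg_pcor")) {
    genes <- pcor$genes
    lambda <- pcor$lambda
    pcor <- pcor$pcor
  }
  off <- upper.tri(pcor)
  r <- pcor[off]
  if (length(r) < 50) abort("fewer than 50 gene pairs: mixture unidentifiable")
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    abort("off-diagonal partial correlations must be finite and inside (-1, 1)")
  }
  kappa_grid <- kappa_grid %||% exp(seq(log(3.5), log(8000), length.out = 80))
  f_alt <- 0.5 # uniform on (-1, 1)
  best <- NULL
  for (kappa in kappa_grid) {
    f0 <- dcor0(r, kappa)
    eta0 <- 0.9
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      f <- eta0 * f0 + (1 - eta0) * f_alt
      gamma <- eta0 * f0 / f
      eta0 <- min(1 - 1e-12, max(1e-12, mean(gamma)))
      ll <- sum(log(eta0 * f0 + (1 - eta0) * f_alt))
      if (abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    if (is.null(best) || ll > best$ll) {
      best <- list(ll = ll, kappa = kappa, eta0 = eta0)
    }
  }
  f0 <- dcor0(pcor, best$kappa)
  f <- best$eta0 * f0 + (1 - best$eta0) * f_alt
  prob <- 1 - best$eta0 * f0 / f
  prob[!is.finite(prob)] <- 0
  prob[prob < 0] <- 0
  prob[prob > 1] <- 1
  diag(prob) <- 0
  dimnames(prob) <- dimnames(pcor)
  structure(
    list(
      prob = prob, eta0 = best$eta0, kappa = best$kappa,
      pcor = pcor, lambda = lambda,
      genes = genes %||% colnames(pcor) %||% sprintf("g%03d", seq_len(ncol(pcor)))
    ),
    class = "gg_edgeprob"
  )
}

#' Build the thresholded co-expression network
#'
#' Undirected edges are gene pairs whose posterior connection probability is
#' at or above the cutoff (inclusive; default 0.80). Isolated genes remain
#' in the node list.
#'
#' @param ep a `gg_edgeprob`.
#' @param cutoff probability cutoff in (0, 1).
#' @return list of class `gg_network`: `nodes`, `edges` tibble
#'   (`gene_a`, `gene_b`, `pcor`, `probability`), `cutoff`, `lambda`,
#'   `eta0`, `kappa`.
#' @export
build_network <- function(ep, cutoff = 0.80) {
  stopifnot(inherits(ep, "gg_edgeprob"))
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0 || cutoff >= 1) {
    abort("cutoff must lie strictly inside (0, 1)")
  }
  genes <- ep$genes
  idx <- which(upper.tri(ep$prob) & ep$prob >= cutoff, arr.ind = TRUE)
  edges <- tibble(
    gene_a = genes[idx[, 1]],
    gene_b = genes[idx[, 2]],
    pcor = ep$pcor[idx],
    probability = ep$prob[idx]
  ) |>
    dplyr::arrange(dplyr::desc(.data$probability))
  structure(
    list(
      nodes = genes, edges = edges, cutoff = cutoff,
      lambda = ep$lambda, eta0 = ep$eta0, kappa = ep$kappa
    ),
    class = "gg_network"
  )
}

#' @export
print.gg_network <- function(x, ...) {
  cat(sprintf(
    "<gg_network> %d nodes, %d edges at probability >= %.2f (lambda = %.3f)\n",
    length(x$nodes), nrow(x$edges), x$cutoff,
    ifelse(is.na(x$lambda), NA, x$lambda)
  ))
  invisible(x)
}

#' Export a network
#'
#' `write_edge_list()` writes the TSV `gene_a gene_b pcor probability`;
#' `write_pajek()` writes the thresholded undirected network in Pajek NET
#' format with the partial correlation as edge weight.
#'
#' @param net a `gg_network`.
#' @param path file path.
#' @export
write_edge_list <- function(net, path) {
  readr::write_tsv(net$edges, path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_pajek <- function(net, path) {
  idx <- setNames(seq_along(net$nodes), net$nodes)
  lines <- c(
    sprintf("*Vertices %d", length(net$nodes)),
    sprintf('%d "%s"', seq_along(net$nodes), net$nodes),
    "*Edges",
    sprintf(
      "%d %d %.6f",
      idx[net$edges$gene_a], idx[net$edges$gene_b], net$edges$pcor
    )
  )
  writeLines(lines, path)
  invisible(path)
}
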