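#' Fraction of a gene's eQTLs collocated with a trait's pQTLs
#'
#' Collocation means the identical framework marker (QTLs are reported at
#' peak markers after support-interval merging).
#'
#' @param gene_eqtls character vector of the gene's eQTL marker ids.
#' @param trait_pqtls character vector of the trait's pQTL marker ids.
#' @return `|eQTL markers in pQTL markers| / |eQTL markers|`.
#' @examples
#' collocation_fraction(c("m1", "m2", "m3"), c("m2", "m3", "m9")) # 2/3
#' @export
collocation_fraction <- function(gene_eqtls, trait_pqtls) {
  gene_eqtls <- unique(gene_eqtls)
  if (length(gene_eqtls) == 0) abort("no eQTLs for gene")
  mean(gene_eqtls %in% trait_pqtls)
}

#' Collocation permutation test for positional candidacy
#'
#' Null model: the gene's eQTLs are re-placed uniformly at random over all
#' mapped markers (distinct markers, conditioning on the observed pQTL
#' landscape) and the collocation fraction recomputed; for the uniform null
#' this intersection count is drawn exactly as a hypergeometric sample. The
#' permutation p-value uses the add-one estimator
#' `(1 + #{perm >= obs}) / (n_perm + 1)` (never zero); with
#' `tie_break = "randomized"` ties are broken uniformly, which makes the
#' p-value exactly uniform under the null (used for calibration checks).
#' A gene is a candidate for the trait when at least 40% of its eQTLs
#' collocate and p <= 0.05.
#'
#' @param gene_eqtls gene's eQTL marker ids.
#' @param trait_pqtls trait's pQTL marker ids.
#' @param map genetic map (or an integer number of markers).
#' @param n_perm number of randomizations (default 10000).
#' @param min_fraction candidate rule fraction (default 0.40).
#' @param alpha candidate rule significance level (default 0.05).
#' @param weights optional per-marker placement weights (e.g. the empirical
#'   eQTL density) instead of the uniform null; named by marker id.
#' @param tie_break `"conservative"` (add-one, default) or `"randomized"`.
#' @param seed optional integer seed.
#' @return one-row tibble `n_eqtls`, `fraction`, `p_perm`, `candidate`.
#' @export
collocation_test <- function(gene_eqtls, trait_pqtls, map, n_perm = 10000,
                             min_fraction = 0.40, alpha = 0.05,
                             weights = NULL,
                             tie_break = c("conservative", "randomized"),
                             seed = NULL) {
  tie_break <- match.arg(tie_break)
  if (n_perm < 100) abort("n_perm must be at least 100")
  markers <- if (is.data.frame(map)) map$marker_id else sprintf("m%03d", seq_len(map))
  gene_eqtls <- unique(gene_eqtls)
  trait_pqtls <- unique(trait_pqtls)
  k <- length(gene_eqtls)
  if (k == 0) abort("no eQTLs for gene")
  if (!all(gene_eqtls %in% markers) || !all(trait_pqtls %in% markers)) {
    abort("QTL markers must be on the map")
  }
  obs_hits <- sum(gene_eqtls %in% trait_pqtls)
  m <- length(markers)
  s <- length(trait_pqtls)
  with_seed(seed, {
    if (is.null(weights)) {
      # uniform re-placement of k distinct markers: intersection with the
      # s pQTL markers is exactly hypergeometric
      perm_hits <- rhyper(n_perm, s, m - s, k)
    } else {
      w <- weights[markers]
      w[is.na(w)] <- 0
      perm_hits <- vapply(seq_len(n_perm), function(i) {
        sum(sample(markers, k, prob = w) %in% trait_pqtls)
      }, numeric(1))
    }
    p <- if (tie_break == "conservative") {
      (1 + sum(perm_hits >= obs_hits)) / (n_perm + 1)
    } else {
      (sum(perm_hits > obs_hits) + runif(1) * (1 + sum(perm_hits == obs_hits))) /
        (n_perm + 1)
    }
    frac <- obs_hits / k
    tibble(
      n_eqtls = k, fraction = frac, p_perm = p,
      candidate = frac >= min_fraction && p <= alpha
    )
  })
}

#' Collocation tests for every gene x trait combination
#'
#' @param eqtls significant eQTL table (`gg_qtl`: columns `trait` = gene,
#'   `marker_id`).
#' @param pqtls significant pQTL table (columns `trait`, `marker_id`).
#' @param map genetic map.
#' @inheritParams collocation_test
#' @return tibble `gene`, `trait`, `n_eqtls`, `fraction`, `p_perm`,
#'   `candidate`, of class `gg_candidates`.
#' @export
collocation_scan <- function(eqtls, pqtls, map, n_perm = 10000,
                             min_fraction = 0.40, alpha = 0.05, seed = NULL) {
  gene_sets <- split(eqtls$marker_id, eqtls$trait)
  trait_sets <- split(pqtls$marker_id, pqtls$trait)
  grid <- tidyr::expand_grid(
    gene = names(gene_sets), trait = names(trait_sets)
  )
  if (nrow(grid) == 0) {
    out <- tibble(
      gene = character(), trait = character(), n_eqtls = integer(),
      fraction = double(), p_perm = double(), candidate = logical()
    )
    class(out) <- c("gg_candidates", class(out))
    return(out)
  }
  out <- purrr::pmap_dfr(grid, function(gene, trait) {
    res <- collocation_test(
      gene_sets[[gene]], trait_sets[[trait]], map,
      n_perm = n_perm, min_fraction = min_fraction, alpha = alpha,
      seed = substream(seed, paste0("colloc_", gene, "_", trait))
    )
    dplyr::bind_cols(tibble(gene = gene, trait = trait), res)
  })
  class(out) <- c("gg_candidates", class(out))
  out
}

#' Candidates for the composite resistance phenotype
#'
#' A gene is a general-resistance candidate when it is a positional
#' candidate for every one of the six resistance traits (attack and
#' oviposition in both years plus their sums).
#'
#' @param results tibble from [collocation_scan()] (columns `gene`, `trait`,
#'   `candidate`).
#' @param resistance_traits the six trait names (default from
#'   [trait_groups()]).
#' @return character vector of gene ids.
#' @export
general_resistance_candidates <- function(results,
                                          resistance_traits = trait_groups()$resistance) {
  sub <- dplyr::filter(results, .data$trait %in% resistance_traits)
  cover <- sub |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_traits = dplyr::n_distinct(.data$trait),
      all_candidate = all(.data$candidate)
    )
  if (any(cover$n_traits < length(resistance_traits))) {
    bad <- cover$gene[cover$n_traits < length(resistance_traits)]
    abort(paste(
      "missing trait results for gene(s):",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  sort(cover$gene[cover$all_candidate])
}

#' Write candidate results as TSV
#'
#' `gene trait n_eqtls fraction p_perm candidate general_resistance` layout.
#'
#' @param results `gg_candidates` tibble.
#' @param path file path.
#' @export
write_candidates <- function(results, path) {
  gr <- tryCatch(general_resistance_candidates(results), error = function(e) character(0))
  results |>
    dplyr::mutate(general_resistance = .data$gene %in% gr) |>
    readr::write_tsv(path)
  invisible(path)
}
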