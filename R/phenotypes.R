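#' Planted phenotype architecture
#'
#' Ground truth for the ten study phenotypes: four continuous growth traits
#' (initial height `hgt1995`, heights `hgt1997`, `hgt1999`, leader length
#' `ldr1999`), two 3-class ordinal weevil-attack traits (`atk2000`,
#' `atk2001`: no attack / failed attack / top kill), two 5-class ordinal
#' oviposition traits (`egg2000`, `egg2001`), plus the derived sums
#' `sum_atk` and `sum_egg`. Ordinal traits are threshold models on a normal
#' liability. Resistance traits share a common set of planted resistance
#' loci (plus trait-specific ones) and growth traits share growth loci, so
#' pQTLs co-locate across years as in real multi-year scoring.
#'
#' @param map genetic map.
#' @param parents `phased_parents`.
#' @param n_qtl_shared number of loci shared within each trait group.
#' @param n_qtl_specific extra trait-specific loci per trait.
#' @param beta_range absolute effect-size range on the liability scale;
#'   the default gives each locus roughly 10-15% of liability variance.
#' @param sigma liability residual sd.
#' @param shared_markers optional named list (`resistance`, `growth`) of
#'   marker ids to use as the shared group loci instead of random draws
#'   (e.g. to co-plant resistance pQTLs at an eQTL hotspot marker).
#' @param seed optional integer seed.
#' @return tibble of class `pheno_arch`: `trait`, `type`, `n_classes`,
#'   list-columns `thresholds` and `qtls`, and `sigma`.
#' @export
sim_pheno_architecture <- function(map, parents, n_qtl_shared = 3,
                                   n_qtl_specific = 1,
                                   beta_range = c(0.8, 1.2), sigma = 1,
                                   shared_markers = NULL, seed = NULL) {
  validate_map(map)
  het <- parents$het
  informative <- colnames(het)[colSums(het) > 0]
  base <- tibble(
    trait = c(
      "hgt1995", "hgt1997", "hgt1999", "ldr1999",
      "atk2000", "atk2001", "egg2000", "egg2001"
    ),
    type = c(rep("continuous", 4), rep("ordinal", 4)),
    n_classes = c(rep(NA_integer_, 4), 3L, 3L, 5L, 5L),
    group = c(rep("growth", 4), rep("resistance", 4))
  )
  with_seed(seed, {
    shared_mk <- list(
      growth = shared_markers$growth %||% sample(informative, n_qtl_shared),
      resistance = shared_markers$resistance %||% sample(informative, n_qtl_shared)
    )
    if (!all(unlist(shared_mk) %in% informative)) {
      abort("shared_markers must be informative map markers")
    }
    # a shared locus is one allele from one parent with one effect size,
    # expressed consistently in every trait of the group (the genetic
    # premise of a resistance/growth QTL scored across seasons)
    shared <- lapply(shared_mk, function(mk) {
      tibble(
        marker_id = mk,
        parent = vapply(mk, function(m) {
          sample(rep(rownames(het)[het[, m]], 2), 1)
        }, character(1)),
        beta = runif(length(mk), beta_range[1], beta_range[2]) *
          sample(c(-1, 1), length(mk), replace = TRUE),
        cis = FALSE
      )
    })
    draw_qtls <- function(group) {
      mk <- setdiff(sample(informative, n_qtl_specific), shared[[group]]$marker_id)
      par <- vapply(mk, function(m) {
        sample(rep(rownames(het)[het[, m]], 2), 1)
      }, character(1))
      beta <- runif(length(mk), beta_range[1], beta_range[2]) *
        sample(c(-1, 1), length(mk), replace = TRUE)
      dplyr::bind_rows(
        shared[[group]],
        tibble(marker_id = mk, parent = unname(par), beta = beta, cis = FALSE)
      )
    }
    out <- base |>
      dplyr::mutate(
        qtls = purrr::map(.data$group, draw_qtls),
        thresholds = purrr::map2(.data$type, .data$n_classes, function(ty, k) {
          if (ty == "continuous") return(numeric(0))
          # liability cut points: moderate prevalence classes
          if (k == 3) c(0.2, 1.1) else c(-0.5, 0.3, 1.0, 1.7)
        }),
        sigma = sigma
      ) |>
      dplyr::select("trait", "type", "n_classes", "thresholds", "sigma", "qtls", "group")
    class(out) <- c("pheno_arch", class(out))
    out
  })
}

#' Simulate phenotypes from a planted architecture
#'
#' Continuous traits are the liability itself; ordinal traits are the class
#' index (0-based) obtained by thresholding the liability; `sum_atk` and
#' `sum_egg` are the sums of the two yearly attack / oviposition traits.
#'
#' @param pop `diallel_pop`.
#' @param arch `pheno_arch` (default: [sim_pheno_architecture()] on the
#'   population's map and parents).
#' @param seed optional integer seed.
#' @return tibble with column `individual` and one column per trait
#'   (the 8 base traits plus `sum_atk`, `sum_egg`).
#' @export
sim_phenotypes <- function(pop, arch = NULL, seed = NULL) {
  stopifnot(inherits(pop, "diallel_pop"))
  arch <- arch %||% sim_pheno_architecture(pop$map, pop$parents,
    seed = substream(seed, "pheno_arch")
  )
  bad <- purrr::map2_lgl(arch$thresholds, arch$n_classes, function(th, k) {
    length(th) > 0 && (is.unsorted(th, strictly = TRUE) || length(th) != k - 1)
  })
  if (any(bad)) abort("thresholds must be strictly increasing with n_classes - 1 cuts")
  n <- nrow(pop$individuals)
  with_seed(seed, {
    cols <- purrr::pmap(
      list(arch$trait, arch$type, arch$thresholds, arch$sigma, arch$qtls),
      function(trait, type, th, sigma, q) {
        liab <- rnorm(n, sd = sigma)
        if (nrow(q) > 0) {
          for (j in seq_len(nrow(q))) {
            x <- parent_indicator(pop, q$parent[j], q$marker_id[j])
            x[is.na(x)] <- 0
            liab <- liab + q$beta[j] * x
          }
        }
        if (type == "continuous") liab else as.integer(findInterval(liab, th))
      }
    )
    out <- tibble(individual = pop$individuals$id)
    out[arch$trait] <- cols
    if (all(c("atk2000", "atk2001") %in% names(out))) {
      out$sum_atk <- out$atk2000 + out$atk2001
    }
    if (all(c("egg2000", "egg2001") %in% names(out))) {
      out$sum_egg <- out$egg2000 + out$egg2001
    }
    out
  })
}

#' Default trait groups
#'
#' Partition of the ten study traits into resistance (attack, oviposition
#' and their sums) and growth (heights, leader length) groups, used when
#' classifying phenotype-associated hotspots.
#'
#' @return named list of character vectors.
#' @export
trait_groups <- function() {
  list(
    resistance = c("atk2000", "atk2001", "sum_atk", "egg2000", "egg2001", "sum_egg"),
    growth = c("hgt1995", "hgt1997", "hgt1999", "ldr1999")
  )
}
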