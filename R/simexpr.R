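#' Planted eQTL architecture
#'
#' Draws a ground-truth regulatory architecture for a set of expression
#' traits: each gene gets a map locus, a Poisson number of QTLs placed at
#' framework markers (uniformly at random, i.e. no clustering unless
#' requested), per-parent additive allele-substitution effects, and a
#' residual sd. A QTL is attached to a parent that is heterozygous at the
#' chosen marker, so every planted effect segregates in at least one cross.
#'
#' Optionally a *trans*-regulatory hotspot is planted: the first
#' `hotspot_genes` genes carry exactly one eQTL, at `hotspot_marker`,
#' acting through one parent heterozygous there (a polymorphic regulator
#' allele segregating from a single parent). The default hotspot effect
#' (0.4 on the stabilized scale) makes each such eQTL explain roughly
#' 15-20% of the gene's expression variance: reliably detectable at the
#' marker itself without lighting up distant linked markers.
#'
#' @param map genetic map.
#' @param parents `phased_parents` (used to pick informative parents).
#' @param n_genes number of expression traits (default 428).
#' @param mean_qtl mean number of planted QTLs per gene (Poisson; default 10,
#'   which at 428 genes emulates a heavily trans-regulated architecture of
#'   roughly 4,200 planted effects).
#' @param p_cis probability that one QTL of a gene is placed at the marker
#'   nearest the gene's own locus.
#' @param beta_range absolute effect size range (uniform draw, random sign).
#' @param sigma residual sd of the latent expression trait.
#' @param hotspot_marker,hotspot_genes,hotspot_beta optional planted hotspot.
#' @param seed optional integer seed.
#' @return tibble of class `eqtl_arch`: `gene_id`, `linkage_group`,
#'   `position_cm`, `sigma`, and list-column `qtls` (tibbles with
#'   `marker_id`, `parent`, `beta`, `cis`).
#' @export
sim_eqtl_architecture <- function(map, parents, n_genes = 428, mean_qtl = 10,
                                  p_cis = 0.3, beta_range = c(0.4, 0.8),
                                  sigma = 0.2,
                                  hotspot_marker = NULL, hotspot_genes = 0,
                                  hotspot_beta = 0.4, seed = NULL) {
  validate_map(map)
  stopifnot(inherits(parents, "phased_parents"))
  if (!is.null(hotspot_marker) && !hotspot_marker %in% map$marker_id) {
    abort("hotspot_marker not on the map")
  }
  het <- parents$het
  informative <- colnames(het)[colSums(het) > 0]
  if (length(informative) == 0) abort("no informative markers in parents")
  with_seed(seed, {
    genes <- tibble(
      gene_id = sprintf("g%03d", seq_len(n_genes)),
      locus_row = sample.int(nrow(map), n_genes, replace = TRUE),
      sigma = sigma
    ) |>
      dplyr::mutate(
        linkage_group = map$linkage_group[.data$locus_row],
        position_cm = map$position_cm[.data$locus_row]
      )
    qtls <- purrr::map(seq_len(n_genes), function(i) {
      k <- rpois(1, mean_qtl)
      out <- NULL
      if (k > 0) {
        mk <- sample(informative, min(k, length(informative)))
        cis <- rep(FALSE, length(mk))
        if (runif(1) < p_cis) {
          # replace the first marker by the one nearest the gene locus
          own <- nearest_marker(map, genes$linkage_group[i], genes$position_cm[i],
            candidates = informative
          )
          if (!is.na(own) && !own %in% mk[-1]) {
            mk[1] <- own
            cis[1] <- TRUE
          }
        }
        par <- vapply(mk, function(m) {
          sample(rep(rownames(het)[het[, m]], 2), 1)
        }, character(1))
        beta <- runif(length(mk), beta_range[1], beta_range[2]) *
          sample(c(-1, 1), length(mk), replace = TRUE)
        out <- tibble(marker_id = mk, parent = par, beta = beta, cis = cis)
      }
      if (!is.null(hotspot_marker) && i <= hotspot_genes) {
        hp <- rownames(het)[het[, hotspot_marker]]
        if (length(hp) == 0) abort("hotspot_marker informative in no parent")
        out <- tibble(
          marker_id = hotspot_marker, parent = sample(rep(hp, 2), 1),
          beta = hotspot_beta * sample(c(-1, 1), 1), cis = FALSE
        )
      }
      out %||% tibble(
        marker_id = character(), parent = character(),
        beta = numeric(), cis = logical()
      )
    })
    out <- genes |>
      dplyr::select(-"locus_row") |>
      dplyr::mutate(qtls = qtls) |>
      dplyr::select("gene_id", "linkage_group", "position_cm", "sigma", "qtls")
    class(out) <- c("eqtl_arch", class(out))
    out
  })
}

nearest_marker <- function(map, lg, pos, candidates = map$marker_id) {
  sub <- map[map$linkage_group == lg & map$marker_id %in% candidates, ]
  if (nrow(sub) == 0) return(NA_character_)
  sub$marker_id[which.min(abs(sub$position_cm - pos))]
}

#' Truth table of planted QTLs
#'
#' Flattens an architecture into the TSV-ready truth table consumed by
#' recovery tests: one row per (trait, marker, parent) planted effect.
#'
#' @param arch an `eqtl_arch` or `pheno_arch`.
#' @param kind `"eqtl"` or `"pqtl"` label.
#' @return tibble `trait_id, marker_id, parent, effect, kind`.
#' @export
truth_table <- function(arch, kind = if (inherits(arch, "pheno_arch")) "pqtl" else "eqtl") {
  id_col <- if ("gene_id" %in% names(arch)) "gene_id" else "trait"
  arch |>
    dplyr::select(trait_id = dplyr::all_of(id_col), "qtls") |>
    tidyr::unnest("qtls") |>
    dplyr::transmute(
      trait_id = .data$trait_id, marker_id = .data$marker_id,
      parent = .data$parent, effect = .data$beta, kind = kind
    )
}

#' Technical effect model for two-colour intensities
#'
#' Fixed-effect tables for the measurement model
#' `h = mu + dye + block + batch + person + g + eps`:
#' dye, replicate block, fabrication batch and experimenter effects (each
#' centred to sum to zero), a per-gene baseline sd, the gene-level residual
#' sd `sigma_e`, and the intensity-scale parameters used to map the latent
#' stabilized value back to a raw fluorescence channel
#' (`foreground = sinh(h) * scale + subgrid background`).
#'
#' @param mu overall mean of the stabilized intensity (log-like scale).
#' @param dye named channel effects (sum to zero).
#' @param block,batch,person named stratum effects (each centred).
#' @param baseline_sd sd of per-gene expression baselines.
#' @param sigma_bg sd of the polygenic genetic-background term.
#' @param sigma_e gene-level measurement residual sd.
#' @param scale linear intensity scale.
#' @param n_subgrids number of print subgrids per slide.
#' @param bg_range uniform range of per-(slide, subgrid) local background.
#' @return list of class `technical_model`.
#' @export
technical_model <- function(mu = 8,
                            dye = c(Cy3 = -0.25, Cy5 = 0.25),
                            block = c(A = -0.3, B = 0, C = 0.3),
                            batch = c(b1 = -0.2, b2 = 0.2),
                            person = c(p1 = -0.15, p2 = 0, p3 = 0.15),
                            baseline_sd = 1, sigma_bg = 0.3, sigma_e = 0.15,
                            scale = 30, n_subgrids = 4,
                            bg_range = c(50, 150)) {
  ctr <- function(x) x - mean(x)
  structure(
    list(
      mu = mu, dye = ctr(dye), block = ctr(block), batch = ctr(batch),
      person = ctr(person), baseline_sd = baseline_sd, sigma_bg = sigma_bg,
      sigma_e = sigma_e, scale = scale, n_subgrids = n_subgrids,
      bg_range = bg_range
    ),
    class = "technical_model"
  )
}

# latent genetic value matrix (individuals x genes): planted QTL effects on
# transmitted-allele indicators plus a polygenic background from many tiny
# marker effects
latent_genetic <- function(pop, arch, sigma_bg) {
  n <- nrow(pop$individuals)
  G <- matrix(0, n, nrow(arch), dimnames = list(pop$individuals$id, arch$gene_id))
  for (i in seq_len(nrow(arch))) {
    q <- arch$qtls[[i]]
    if (nrow(q) == 0) next
    if (!all(q$marker_id %in% pop$map$marker_id)) {
      abort(sprintf("architecture for %s references markers absent from the map",
        arch$gene_id[i]))
    }
    for (j in seq_len(nrow(q))) {
      x <- parent_indicator(pop, q$parent[j], q$marker_id[j])
      x[is.na(x)] <- 0
      G[, i] <- G[, i] + q$beta[j] * x
    }
  }
  if (sigma_bg > 0) {
    H <- cbind(pop$hf, pop$hm) - 0.5
    W <- matrix(rnorm(ncol(H) * nrow(arch), sd = sigma_bg / sqrt(ncol(H) / 4)),
      ncol(H), nrow(arch)
    )
    G <- G + H %*% W
  }
  G
}

#' Simulate raw two-channel microarray intensities
#'
#' Generates spot-level foreground/background intensities for every slide of
#' a hybridization plan, by inverting the stabilized-intensity measurement
#' model: the latent value `h = mu + gene baseline + dye + block + batch +
#' person + genetic value + eps` is mapped to fluorescence as
#' `sinh(h) * scale + local subgrid background`, so that the normalization
#' pipeline (background subtraction, arsinh stabilization, residualization)
#' can round-trip the genetic signal.
#'
#' @param pop `diallel_pop`.
#' @param arch `eqtl_arch` ground truth.
#' @param tech `technical_model`.
#' @param plan hybridization plan: tibble with `slide_id`, `sample_cy3`,
#'   `sample_cy5`, `block`, `batch`, `person` (see [assign_dyes()]).
#' @param seed optional integer seed.
#' @return list of class `sim_expression`: `intensities` tibble
#'   (`slide`, `channel`, `subgrid`, `spot`, `foreground`, `background`),
#'   `samples` covariate tibble (slide/channel to individual, dye, block,
#'   batch, person, family), `truth` planted-eQTL table, and the latent
#'   genetic matrix `latent`.
#' @export
sim_expression <- function(pop, arch, tech = technical_model(), plan,
                           seed = NULL) {
  stopifnot(inherits(pop, "diallel_pop"), inherits(tech, "technical_model"))
  req <- c("slide_id", "sample_cy3", "sample_cy5", "block", "batch", "person")
  if (!all(req %in% names(plan))) {
    abort(paste("plan must have columns", paste(req, collapse = ", ")))
  }
  profiled <- unique(c(plan$sample_cy3, plan$sample_cy5))
  if (!all(profiled %in% pop$individuals$id)) {
    abort("plan references individuals absent from the population")
  }
  with_seed(seed, {
    G <- latent_genetic(pop, arch, tech$sigma_bg)
    n_genes <- ncol(G)
    baseline <- rnorm(n_genes, sd = tech$baseline_sd)
    subgrid <- ((seq_len(n_genes) - 1) %% tech$n_subgrids) + 1
    samples <- tidyr::expand_grid(
      slide = plan$slide_id, channel = c("Cy3", "Cy5")
    ) |>
      dplyr::left_join(
        plan |>
          dplyr::select(
            slide = "slide_id", Cy3 = "sample_cy3", Cy5 = "sample_cy5",
            "block", "batch", "person"
          ) |>
          tidyr::pivot_longer(c("Cy3", "Cy5"),
            names_to = "channel", values_to = "individual"
          ),
        by = c("slide", "channel")
      ) |>
      dplyr::mutate(dye = .data$channel) |>
      dplyr::left_join(
        dplyr::select(pop$individuals, individual = "id", family = "cross_id"),
        by = "individual"
      )
    bg_tbl <- tidyr::expand_grid(
      slide = plan$slide_id, subgrid = seq_len(tech$n_subgrids)
    ) |>
      dplyr::mutate(background = runif(dplyr::n(), tech$bg_range[1], tech$bg_range[2]))
    n_obs <- nrow(samples)
    # h: observations x genes
    h <- matrix(tech$mu, n_obs, n_genes) +
      matrix(baseline, n_obs, n_genes, byrow = TRUE) +
      tech$dye[samples$dye] + tech$block[samples$block] +
      tech$batch[samples$batch] + tech$person[samples$person] +
      G[samples$individual, , drop = FALSE] +
      matrix(rnorm(n_obs * n_genes, sd = tech$sigma_e), n_obs, n_genes)
    intensities <- tibble(
      slide = rep(samples$slide, each = n_genes),
      channel = rep(samples$channel, each = n_genes),
      subgrid = rep(subgrid, times = n_obs),
      spot = rep(colnames(G), times = n_obs),
      foreground = as.vector(t(sinh(h) * tech$scale))
    ) |>
      dplyr::left_join(bg_tbl, by = c("slide", "subgrid")) |>
      dplyr::mutate(foreground = .data$foreground + .data$background)
    structure(
      list(
        intensities = intensities, samples = samples,
        truth = truth_table(arch), latent = G, arch = arch, tech = tech
      ),
      class = "sim_expression"
    )
  })
}
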