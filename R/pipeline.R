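#' Pipeline configuration
#'
#' Collects every tunable of an end-to-end run. Defaults equal the study
#' constants: LOD threshold 3.84, 1,000 hotspot randomization replicates,
#' 40% collocation fraction at alpha 0.05 with 10,000 randomizations, at
#' least 3 collocated pQTLs for a phenotype-associated hotspot, and the
#' 0.80 edge-probability cutoff.
#'
#' @param seed master seed; every stage draws from a named substream.
#' @param n_markers,n_lg,spacing_cm framework map layout.
#' @param het_fraction parent heterozygosity (see [sim_parents()]).
#' @param design a [diallel_design()].
#' @param n_genes,mean_qtl,hotspot_marker,hotspot_genes,hotspot_beta
#'   expression architecture (see [sim_eqtl_architecture()]).
#' @param lod_threshold QTL significance threshold.
#' @param hotspot_reps randomization replicates for the hotspot threshold.
#' @param pheno_shared_markers optional named list passed to
#'   [sim_pheno_architecture()] `shared_markers` (pin group pQTL loci).
#' @param pheno_beta_range liability effect-size range for planted pQTLs.
#' @param colloc_frac,colloc_perms,colloc_alpha candidate rule.
#' @param min_pqtl minimum collocated pQTLs for hotspot classification.
#' @param edge_prob network edge-probability cutoff.
#' @param n_restarts pairing optimizer restarts.
#' @param out_dir optional output directory for TSV/JSON artefacts.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_markers = 252, n_lg = 13, spacing_cm = 10,
                       het_fraction = 0.28, design = diallel_design(),
                       n_genes = 428, mean_qtl = 10,
                       hotspot_marker = NULL, hotspot_genes = 0,
                       hotspot_beta = 0.4, pheno_shared_markers = NULL,
                       pheno_beta_range = c(0.8, 1.2),
                       lod_threshold = 3.84, hotspot_reps = 1000,
                       colloc_frac = 0.40, colloc_perms = 10000,
                       colloc_alpha = 0.05, min_pqtl = 3, edge_prob = 0.80,
                       n_restarts = 10, out_dir = NULL) {
  check_number(lod_threshold, "lod_threshold", lower = 0)
  check_number(hotspot_reps, "hotspot_reps", lower = 1)
  check_number(colloc_frac, "colloc_frac", lower = 0, upper = 1)
  check_number(colloc_alpha, "colloc_alpha", lower = 0, upper = 1)
  check_number(edge_prob, "edge_prob", lower = 1e-9, upper = 1 - 1e-9)
  check_number(min_pqtl, "min_pqtl", lower = 1)
  structure(
    list(
      seed = seed, n_markers = n_markers, n_lg = n_lg, spacing_cm = spacing_cm,
      het_fraction = het_fraction, design = design, n_genes = n_genes,
      mean_qtl = mean_qtl, hotspot_marker = hotspot_marker,
      hotspot_genes = hotspot_genes, hotspot_beta = hotspot_beta,
      pheno_shared_markers = pheno_shared_markers,
      pheno_beta_range = pheno_beta_range,
      lod_threshold = lod_threshold, hotspot_reps = hotspot_reps,
      colloc_frac = colloc_frac, colloc_perms = colloc_perms,
      colloc_alpha = colloc_alpha, min_pqtl = min_pqtl,
      edge_prob = edge_prob, n_restarts = n_restarts, out_dir = out_dir
    ),
    class = "run_config"
  )
}

#' Run the full genetical-genomics pipeline
#'
#' simulate -> design -> normalize -> scan -> hotspots -> candidates ->
#' network, with one seed substream per stage so reruns with the same
#' config reproduce every stochastic output bit for bit. When
#' `config$out_dir` is set, every inter-stage table is written as TSV plus
#' a JSON manifest.
#'
#' @param config a [run_config()].
#' @return list of class `gg_run`: all intermediate objects plus `manifest`
#'   (per-stage row counts, seeds, key statistics).
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  stage <- function(name) substream(seed, name)

  map <- sim_genetic_map(config$n_markers, config$n_lg, config$spacing_cm)
  parents <- sim_parents(map,
    het_fraction = config$het_fraction, seed = stage("parents")
  )
  pop <- sim_population(map, parents, config$design, seed = stage("population"))

  pheno_arch <- sim_pheno_architecture(map, parents,
    beta_range = config$pheno_beta_range,
    shared_markers = config$pheno_shared_markers, seed = stage("pheno_arch")
  )
  phenotypes <- sim_phenotypes(pop, pheno_arch, seed = stage("phenotypes"))

  earch <- sim_eqtl_architecture(map, parents,
    n_genes = config$n_genes, mean_qtl = config$mean_qtl,
    hotspot_marker = config$hotspot_marker,
    hotspot_genes = config$hotspot_genes,
    hotspot_beta = config$hotspot_beta, seed = stage("eqtl_arch")
  )

  dists <- lapply(
    setNames(config$design$cross_id, config$design$cross_id),
    function(cid) genetic_distance_matrix(pop, cid)
  )
  plan <- optimize_pairs(dists,
    n_restarts = config$n_restarts, seed = stage("pairing")
  ) |>
    assign_dyes(seed = stage("dyes"))
  improvement <- improvement_vs_random(plan, dists,
    n_random = 200, seed = stage("improvement")
  )

  expr <- sim_expression(pop, earch, technical_model(), plan,
    seed = stage("expression")
  )
  resid_eq1 <- normalize_expression(expr$intensities, expr$samples, "eq1")
  resid_eq2 <- normalize_expression(expr$intensities, expr$samples, "eq2")

  escan <- lod_scan(traits_from_residuals(resid_eq1), pop)
  eqtls <- significant_qtls(escan, threshold = config$lod_threshold) |>
    classify_cis_trans(earch)
  pscan <- lod_scan(phenotypes, pop)
  pqtls <- significant_qtls(pscan, threshold = config$lod_threshold)

  counts <- count_per_marker(eqtls, map)
  gof <- if (nrow(eqtls) == 0) {
    tibble(
      chi2 = NA_real_, df = nrow(map) - 1, p = NA_real_,
      n_eqtl = 0L, n_markers = nrow(map)
    )
  } else {
    gof_uniform(counts)
  }
  hot_threshold <- randomization_threshold(
    nrow(eqtls), nrow(map), config$hotspot_reps,
    seed = stage("hotspot_threshold")
  )
  hotspots <- declare_hotspots(counts, max(1, hot_threshold)) |>
    phenotype_association(pqtls, min_pqtl = config$min_pqtl)

  candidates <- collocation_scan(eqtls, pqtls, map,
    n_perm = config$colloc_perms, min_fraction = config$colloc_frac,
    alpha = config$colloc_alpha, seed = stage("collocation")
  )
  general_res <- tryCatch(
    general_resistance_candidates(candidates),
    error = function(e) character(0)
  )

  network <- shrinkage_partial_correlation(resid_eq2) |>
    edge_probabilities() |>
    build_network(cutoff = config$edge_prob)

  manifest <- list(
    seed = seed,
    stage_seeds = lapply(
      setNames(, c(
        "parents", "population", "pheno_arch", "phenotypes", "eqtl_arch",
        "pairing", "dyes", "improvement", "expression", "hotspot_threshold",
        "collocation"
      )),
      stage
    ),
    counts = list(
      markers = nrow(map), individuals = nrow(pop$individuals),
      genes = config$n_genes, slides = nrow(plan),
      intensity_rows = nrow(expr$intensities),
      eqtl_records = nrow(eqtls), pqtl_records = nrow(pqtls),
      hotspots = sum(hotspots$hotspot),
      candidate_pairs = sum(candidates$candidate),
      general_resistance = length(general_res),
      network_edges = nrow(network$edges)
    ),
    statistics = list(
      pairing_objective = attr(plan, "objective"),
      improvement_pct = improvement,
      gof_chi2 = gof$chi2, gof_df = gof$df, gof_p = gof$p,
      hotspot_threshold = hot_threshold,
      network_lambda = network$lambda, network_eta0 = network$eta0
    )
  )

  run <- structure(
    list(
      config = config, map = map, pop = pop, pheno_arch = pheno_arch,
      phenotypes = phenotypes, eqtl_arch = earch, plan = plan,
      expression = expr, resid_eq1 = resid_eq1, resid_eq2 = resid_eq2,
      escan = escan, eqtls = eqtls, pscan = pscan, pqtls = pqtls,
      counts = counts, gof = gof, hotspot_threshold = hot_threshold,
      hotspots = hotspots, candidates = candidates,
      general_resistance = general_res, network = network,
      manifest = manifest
    ),
    class = "gg_run"
  )
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' @export
print.gg_run <- function(x, ...) {
  m <- x$manifest$counts
  cat(sprintf(
    paste0(
      "<gg_run> %d individuals, %d genes, %d markers\n",
      "  eQTLs %d | pQTLs %d | hotspots %d (threshold %d) | ",
      "candidate pairs %d | edges %d\n"
    ),
    m$individuals, m$genes, m$markers, m$eqtl_records, m$pqtl_records,
    m$hotspots, x$hotspot_threshold, m$candidate_pairs, m$network_edges
  ))
  invisible(x)
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genetic_map(run$map, file.path(dir, "map.tsv"))
  write_genotypes(run$pop, file.path(dir, "genotypes.csv"))
  readr::write_csv(run$phenotypes, file.path(dir, "phenotypes.csv"))
  write_design(run$plan, file.path(dir, "design.tsv"))
  readr::write_tsv(truth_table(run$eqtl_arch), file.path(dir, "truth_eqtl.tsv"))
  readr::write_tsv(truth_table(run$pheno_arch), file.path(dir, "truth_pqtl.tsv"))
  write_qtl_table(run$eqtls, file.path(dir, "eqtls.tsv"))
  write_qtl_table(run$pqtls, file.path(dir, "pqtls.tsv"))
  write_hotspot_report(run$hotspots, file.path(dir, "hotspots.tsv"))
  write_candidates(run$candidates, file.path(dir, "candidates.tsv"))
  write_edge_list(run$network, file.path(dir, "network_edges.tsv"))
  write_pajek(run$network, file.path(dir, "network.net"))
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Ingest a QTL table
#'
#' Validates and normalizes an externally supplied QTL table (columns
#' `trait`, `marker` or `marker_id`, `lod`, optionally `effect`, `pve`,
#' `parents`) so hotspot and candidate analyses can run without re-scanning.
#' Duplicated (trait, marker) rows are collapsed to the peak LOD with a
#' warning; rows below `lod_threshold` are dropped when a threshold is
#' given.
#'
#' @param x file path (TSV) or tibble.
#' @param map genetic map for marker validation.
#' @param lod_threshold optional filter threshold.
#' @return tibble with `trait`, `marker_id`, `linkage_group`,
#'   `position_cm`, `lod` (+ passthrough columns).
#' @export
ingest_qtl_table <- function(x, map, lod_threshold = NULL) {
  validate_map(map)
  tbl <- if (is.character(x)) readr::read_tsv(x, show_col_types = FALSE) else as_tibble(x)
  if ("marker" %in% names(tbl) && !"marker_id" %in% names(tbl)) {
    tbl <- dplyr::rename(tbl, marker_id = "marker")
  }
  req <- c("trait", "marker_id", "lod")
  if (!all(req %in% names(tbl))) {
    abort(paste("QTL table must have columns", paste(req, collapse = ", ")))
  }
  bad <- !tbl$marker_id %in% map$marker_id
  if (any(bad)) {
    abort(sprintf(
      "unknown marker(s) in rows %s: %s",
      paste(head(which(bad), 5), collapse = ","),
      paste(head(unique(tbl$marker_id[bad]), 5), collapse = ", ")
    ))
  }
  dup <- duplicated(tbl[c("trait", "marker_id")])
  if (any(dup)) {
    warn(sprintf("collapsing %d duplicated (trait, marker) rows to peak LOD", sum(dup)))
    tbl <- tbl |>
      dplyr::group_by(.data$trait, .data$marker_id) |>
      dplyr::slice_max(.data$lod, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  if (!is.null(lod_threshold)) tbl <- dplyr::filter(tbl, .data$lod >= lod_threshold)
  tbl |>
    dplyr::select(-dplyr::any_of(c("linkage_group", "position_cm"))) |>
    dplyr::left_join(map, by = "marker_id") |>
    dplyr::relocate("trait", "marker_id", "linkage_group", "position_cm", "lod")
}
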