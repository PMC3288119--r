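#' Tally eQTLs per marker
#'
#' Integer count of significant eQTLs at every framework marker; markers
#' with no eQTL get zero. Counts assume one record per (trait, support
#' interval) peak marker, as produced by [significant_qtls()].
#'
#' @param eqtls tibble with a `marker_id` column (a `gg_qtl`).
#' @param map genetic map.
#' @return tibble `marker_id`, `linkage_group`, `position_cm`, `eqtl_count`.
#' @export
count_per_marker <- function(eqtls, map) {
  validate_map(map)
  if (nrow(eqtls) > 0 && !all(eqtls$marker_id %in% map$marker_id)) {
    bad <- setdiff(eqtls$marker_id, map$marker_id)
    abort(paste("unknown marker id(s):", paste(head(bad, 5), collapse = ", ")))
  }
  counts <- table(factor(eqtls$marker_id, levels = map$marker_id))
  dplyr::mutate(map, eqtl_count = as.integer(counts[map$marker_id]))
}

#' Goodness-of-fit test against uniform eQTL placement
#'
#' Pearson chi-squared test of the observed per-marker eQTL frequencies
#' against the uniform expectation N/M, with df = M - 1 and an upper-tail
#' p-value.
#'
#' @param counts integer vector of per-marker counts, or the tibble from
#'   [count_per_marker()].
#' @return one-row tibble `chi2`, `df`, `p`, `n_eqtl`, `n_markers`.
#' @export
gof_uniform <- function(counts) {
  if (is.data.frame(counts)) counts <- counts$eqtl_count
  m <- length(counts)
  n <- sum(counts)
  if (m < 2) abort("need at least 2 markers")
  if (n == 0) abort("no eQTLs to test")
  e <- n / m
  chi2 <- sum((counts - e)^2 / e)
  tibble(
    chi2 = chi2, df = m - 1, p = pchisq(chi2, m - 1, lower.tail = FALSE),
    n_eqtl = n, n_markers = m
  )
}

#' Randomization threshold for eQTL hotspot declaration
#'
#' Drops `n_eqtl` eQTLs independently and uniformly at random over
#' `n_markers` markers, `n_reps` times, and returns the maximum per-marker
#' cluster size observed over all replicates (the hotspot declaration
#' threshold; with the study numbers 4,221 eQTLs, 252 markers and 1,000
#' replicates this lands at 38). `mode = "q95"` instead returns the 95th
#' percentile of the per-replicate maxima, for sensitivity analysis.
#'
#' Each replicate draws from its own pre-drawn seed, so with a shared seed
#' the result is non-decreasing in both `n_eqtl` (the first placements of a
#' replicate coincide) and `n_reps` (earlier replicates are unchanged).
#'
#' @param n_eqtl number of eQTLs to place.
#' @param n_markers number of markers.
#' @param n_reps number of replicates (default 1000).
#' @param seed optional integer seed.
#' @param mode `"max"` (global maximum, default) or `"q95"`.
#' @return integer threshold.
#' @examples
#' randomization_threshold(4221, 252, 1000, seed = 1)
#' @export
randomization_threshold <- function(n_eqtl, n_markers, n_reps = 1000,
                                    seed = NULL, mode = c("max", "q95")) {
  mode <- match.arg(mode)
  check_number(n_eqtl, "n_eqtl", lower = 0)
  check_number(n_markers, "n_markers", lower = 1)
  check_number(n_reps, "n_reps", lower = 1)
  if (n_eqtl == 0) return(0L)
  rep_seeds <- if (is.null(seed)) {
    NULL
  } else {
    with_seed(seed, sample.int(2147483646L, n_reps))
  }
  maxima <- vapply(seq_len(n_reps), function(i) {
    with_seed(rep_seeds[i], {
      max(tabulate(sample.int(n_markers, n_eqtl, replace = TRUE), nbins = n_markers))
    })
  }, integer(1))
  if (mode == "max") max(maxima) else as.integer(quantile(maxima, 0.95, type = 1))
}

#' Declare eQTL hotspots
#'
#' A marker is a hotspot when its eQTL count is at or above the threshold
#' (inclusive).
#'
#' @param counts tibble from [count_per_marker()].
#' @param threshold integer threshold (see [randomization_threshold()]).
#' @return the tibble with a logical `hotspot` column; class `gg_hotspots`.
#' @export
declare_hotspots <- function(counts, threshold) {
  check_number(threshold, "threshold", lower = 1)
  out <- dplyr::mutate(counts, hotspot = .data$eqtl_count >= threshold)
  attr(out, "threshold") <- threshold
  class(out) <- c("gg_hotspots", setdiff(class(out), "gg_hotspots"))
  out
}

#' Classify hotspots by collocated phenotype QTLs
#'
#' Counts significant pQTLs collocated (same framework marker) with each
#' hotspot and classifies the hotspot by the trait groups of those pQTLs:
#' `none` below `min_pqtl` collocated pQTLs, otherwise `resistance`,
#' `growth`, or `both`.
#'
#' @param hotspots tibble from [declare_hotspots()].
#' @param pqtls significant pQTL table (`gg_qtl`; columns `trait`,
#'   `marker_id`).
#' @param min_pqtl minimum collocated pQTLs for a phenotype association
#'   (default 3).
#' @param groups named list partitioning trait names (default
#'   [trait_groups()]).
#' @return the hotspot tibble with `n_pqtls` and `phenotype_class` columns.
#' @export
phenotype_association <- function(hotspots, pqtls, min_pqtl = 3,
                                  groups = trait_groups()) {
  known <- unlist(groups, use.names = FALSE)
  if (nrow(pqtls) > 0 && !all(pqtls$trait %in% known)) {
    bad <- setdiff(unique(pqtls$trait), known)
    abort(paste("trait(s) not in any group:", paste(bad, collapse = ", ")))
  }
  per_marker <- pqtls |>
    dplyr::group_by(.data$marker_id) |>
    dplyr::summarise(
      n_pqtls = dplyr::n(),
      has_res = any(.data$trait %in% groups$resistance),
      has_gro = any(.data$trait %in% groups$growth)
    )
  out <- hotspots |>
    dplyr::left_join(per_marker, by = "marker_id") |>
    dplyr::mutate(
      n_pqtls = dplyr::coalesce(.data$n_pqtls, 0L),
      has_res = dplyr::coalesce(.data$has_res, FALSE),
      has_gro = dplyr::coalesce(.data$has_gro, FALSE),
      phenotype_class = dplyr::case_when(
        !.data$hotspot | .data$n_pqtls < min_pqtl ~ "none",
        .data$has_res & .data$has_gro ~ "both",
        .data$has_res ~ "resistance",
        .data$has_gro ~ "growth",
        TRUE ~ "none"
      )
    ) |>
    dplyr::select(-"has_res", -"has_gro")
  attr(out, "threshold") <- attr(hotspots, "threshold")
  class(out) <- c("gg_hotspots", setdiff(class(out), "gg_hotspots"))
  out
}

#' Write a hotspot report as TSV
#'
#' `marker lg position_cm eqtl_count n_pqtls hotspot class` layout.
#'
#' @param report a `gg_hotspots` tibble (after [phenotype_association()]).
#' @param path file path.
#' @export
write_hotspot_report <- function(report, path) {
  report |>
    dplyr::transmute(
      marker = .data$marker_id, lg = .data$linkage_group,
      position_cm = .data$position_cm, eqtl_count = .data$eqtl_count,
      n_pqtls = if ("n_pqtls" %in% names(report)) .data$n_pqtls else 0L,
      hotspot = .data$hotspot,
      class = if ("phenotype_class" %in% names(report)) .data$phenotype_class else "none"
    ) |>
    readr::write_tsv(path)
  invisible(path)
}
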