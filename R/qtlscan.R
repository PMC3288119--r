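#' Single-marker LOD scan in an outbred diallel
#'
#' At every framework marker, fits the full model
#' `trait = cross mean + sum_p beta_p * x_p` over the parents heterozygous
#' (informative) at that marker, against the cross-means null, by ordinary
#' least squares. `x_p` is the transmitted-allele indicator of parent `p`
#' (0/1 for progeny of `p`, 0 otherwise; rare missing indicators are mean
#' imputed). The LOD is `(n/2) * log10(RSS0/RSS1)`; per-parent LODs drop one
#' parent's term from the full model. Markers informative in no parent are
#' skipped. A perfect fit (RSS1 = 0) is capped at LOD 99.
#'
#' @param traits tibble with an `individual` column and one numeric column
#'   per trait (e.g. phenotypes or a residual matrix via
#'   [traits_from_residuals()]), or a numeric matrix with individual ids as
#'   rownames.
#' @param pop `diallel_pop`.
#' @return tibble of class `gg_scan`: one row per (trait, marker) with
#'   `trait`, `marker_id`, `linkage_group`, `position_cm`, `n`, `lod`,
#'   `pve`, and list-columns `effects` and `parent_lod` (named per parent).
#' @examples
#' pop <- sim_population(sim_genetic_map(26, 2), seed = 4)
#' ph <- sim_phenotypes(pop, seed = 4)
#' scan <- lod_scan(ph["individual"] |> dplyr::mutate(y = ph$hgt1999), pop)
#' @export
lod_scan <- function(traits, pop) {
  stopifnot(inherits(pop, "diallel_pop"))
  Y <- traits_to_matrix(traits, pop)
  if (ncol(Y) == 0) abort("no trait columns")
  if (nrow(Y) < 10) abort("need traits for at least 10 genotyped individuals")
  all_na <- apply(Y, 2, function(y) all(is.na(y)))
  if (any(all_na)) {
    abort(paste("all-missing trait(s):", paste(colnames(Y)[all_na], collapse = ", ")))
  }
  if (anyNA(Y)) {
    # per-NA-pattern subscans keep the fast matrix path
    pat <- apply(is.na(Y), 2, paste, collapse = "")
    out <- purrr::map_dfr(unique(pat), function(p) {
      cols <- which(pat == p)
      keep <- !is.na(Y[, cols[1]])
      scan_matrix(Y[keep, cols, drop = FALSE], subset_pop(pop, rownames(Y)[keep]))
    })
    return(as_gg_scan(out))
  }
  as_gg_scan(scan_matrix(Y, pop))
}

traits_to_matrix <- function(traits, pop) {
  if (is.matrix(traits)) {
    if (is.null(rownames(traits))) abort("trait matrix needs individual rownames")
    ids <- intersect(pop$individuals$id, rownames(traits))
    return(traits[ids, , drop = FALSE])
  }
  if (!"individual" %in% names(traits)) {
    abort("traits must contain an `individual` column")
  }
  keep <- traits$individual %in% pop$individuals$id
  tr <- traits[keep, ]
  m <- as.matrix(tr[setdiff(names(tr), "individual")])
  rownames(m) <- tr$individual
  storage.mode(m) <- "double"
  m
}

subset_pop <- function(pop, ids) {
  sel <- pop$individuals$id %in% ids
  pop$individuals <- pop$individuals[sel, ]
  for (f in c("xf", "xm", "hf", "hm", "geno")) pop[[f]] <- pop[[f]][ids, , drop = FALSE]
  pop
}

scan_matrix <- function(Y, pop) {
  ind <- pop$individuals[match(rownames(Y), pop$individuals$id), ]
  n <- nrow(Y)
  X0 <- if (length(unique(ind$cross_id)) > 1) {
    model.matrix(~ 0 + factor(ind$cross_id))
  } else {
    matrix(1, n, 1)
  }
  q0 <- qr(X0)
  rss0 <- colSums(qr.resid(q0, Y)^2)
  ss_tot <- colSums(Y^2)
  parents <- unique(c(pop$design$female, pop$design$male))
  purrr::map_dfr(seq_len(nrow(pop$map)), function(j) {
    mk <- pop$map$marker_id[j]
    cols <- list()
    for (p in parents) {
      if (!pop$parents$het[p, mk]) next
      x <- parent_indicator_sub(pop, ind, p, mk)
      if (is.null(x)) next
      cols[[p]] <- x
    }
    if (length(cols) == 0) return(NULL)
    Xp <- do.call(cbind, cols)
    X1 <- cbind(X0, Xp)
    q1 <- qr(X1)
    r1 <- qr.resid(q1, Y)
    rss1 <- colSums(r1^2)
    lod <- lod_from_rss(rss0, rss1, n, ss_tot)
    cf <- qr.coef(q1, Y)
    betas <- cf[ncol(X0) + seq_along(cols), , drop = FALSE]
    rownames(betas) <- names(cols)
    plod <- vapply(seq_along(cols), function(k) {
      Xd <- X1[, -(ncol(X0) + k), drop = FALSE]
      rssd <- colSums(qr.resid(qr(Xd), Y)^2)
      lod_from_rss(rssd, rss1, n, ss_tot)
    }, numeric(length(rss1)))
    if (is.null(dim(plod))) plod <- matrix(plod, nrow = 1)
    colnames(plod) <- names(cols)
    tibble(
      trait = colnames(Y),
      marker_id = mk,
      linkage_group = pop$map$linkage_group[j],
      position_cm = pop$map$position_cm[j],
      n = n,
      lod = lod,
      pve = 100 * (1 - rss1 / rss0),
      effects = purrr::map(seq_along(lod), function(t) setNames(betas[, t], names(cols))),
      parent_lod = purrr::map(seq_along(lod), function(t) setNames(plod[t, ], names(cols)))
    )
  })
}

lod_from_rss <- function(rss_null, rss_full, n, ss_tot = Inf) {
  out <- numeric(length(rss_full))
  # constant (or cross-mean-constant) trait: no evidence either way
  degenerate <- rss_null <= pmax(1e-16 * ss_tot, 1e-300)
  perfect <- !degenerate & rss_full < 1e-12 * rss_null
  mid <- !degenerate & !perfect
  out[perfect] <- 99
  out[mid] <- pmax(0, (n / 2) * log10(rss_null[mid] / rss_full[mid]))
  pmin(out, 99)
}

# informative-parent indicator restricted to the scan individuals; NULL when
# the column has no variance (uninformative in this subset)
parent_indicator_sub <- function(pop, ind, parent, marker) {
  x <- rep(0, nrow(ind))
  is_f <- ind$female == parent
  is_m <- ind$male == parent
  if (!any(is_f | is_m)) return(NULL)
  x[is_f] <- pop$xf[ind$id[is_f], marker]
  x[is_m] <- pop$xm[ind$id[is_m], marker]
  if (anyNA(x)) {
    mis <- is.na(x)
    obs_mean <- mean(x[(is_f | is_m) & !mis])
    x[mis] <- if (is.finite(obs_mean)) obs_mean else 0
  }
  if (var(x) < .Machine$double.eps) return(NULL)
  x
}

as_gg_scan <- function(x) {
  class(x) <- c("gg_scan", setdiff(class(x), "gg_scan"))
  x
}

#' Filter and merge significant QTLs
#'
#' Keeps records with `lod >= threshold` (inclusive, default 3.84) that are
#' detected for at least one parent (per-parent drop-one LOD at the same
#' threshold), then merges adjacent significant markers of a trait on the
#' same linkage group into one support interval when consecutive markers
#' are within `merge_cm`, keeping the peak marker. This prevents one broad
#' QTL from inflating neighbouring markers in hotspot tallies.
#'
#' @param scan a `gg_scan`.
#' @param threshold LOD significance threshold (default 3.84).
#' @param require_any_parent drop records with no per-parent LOD at or above
#'   the threshold.
#' @param merge_cm support-interval merging window in cM (default 10).
#' @return tibble of class `gg_qtl`: significant peak records with
#'   `detected_in` (comma separated parents), `n_merged`, `support_lo`,
#'   `support_hi`.
#' @export
significant_qtls <- function(scan, threshold = 3.84, require_any_parent = TRUE,
                             merge_cm = 10) {
  if (nrow(scan) == 0) abort("empty scan")
  sig <- scan |>
    dplyr::mutate(
      detected_parents = purrr::map(.data$parent_lod, function(pl) {
        names(pl)[pl >= threshold]
      })
    ) |>
    dplyr::filter(.data$lod >= threshold)
  if (require_any_parent) {
    sig <- dplyr::filter(sig, purrr::map_int(.data$detected_parents, length) > 0)
  }
  if (nrow(sig) == 0) {
    out <- dplyr::mutate(sig,
      detected_in = character(0), n_merged = integer(0),
      support_lo = numeric(0), support_hi = numeric(0)
    )
    class(out) <- c("gg_qtl", class(out))
    return(out)
  }
  out <- sig |>
    dplyr::arrange(.data$trait, .data$linkage_group, .data$position_cm) |>
    dplyr::group_by(.data$trait, .data$linkage_group) |>
    dplyr::mutate(
      gap = c(0, diff(.data$position_cm)),
      cluster = cumsum(.data$gap > merge_cm)
    ) |>
    dplyr::group_by(.data$trait, .data$linkage_group, .data$cluster) |>
    dplyr::summarise(
      peak = which.max(.data$lod),
      support_lo = min(.data$position_cm),
      support_hi = max(.data$position_cm),
      n_merged = dplyr::n(),
      detected_in = paste(.data$detected_parents[[.data$peak]], collapse = ","),
      marker_id = .data$marker_id[.data$peak],
      position_cm = .data$position_cm[.data$peak],
      n = .data$n[.data$peak],
      pve = .data$pve[.data$peak],
      effects = .data$effects[.data$peak],
      parent_lod = .data$parent_lod[.data$peak],
      lod = .data$lod[.data$peak],
      .groups = "drop"
    ) |>
    dplyr::select(-"cluster", -"peak")
  class(out) <- c("gg_qtl", class(out))
  out
}

#' Classify eQTLs as cis or trans
#'
#' An eQTL is *cis* when the regulated gene has a known map locus on the
#' same linkage group within `window_cm` of the eQTL marker; *trans* when a
#' locus is known and the condition fails; *unknown* when the gene has no
#' map position.
#'
#' @param qtls a `gg_qtl` (or any tibble with `trait`, `linkage_group`,
#'   `position_cm`).
#' @param gene_loci tibble `gene_id`, `linkage_group`, `position_cm`
#'   (possibly NA), e.g. an `eqtl_arch`.
#' @param window_cm cis window (default 10 cM).
#' @return input with `gene_lg`, `gene_pos` and `class` columns.
#' @export
classify_cis_trans <- function(qtls, gene_loci, window_cm = 10) {
  loci <- gene_loci |>
    dplyr::select("gene_id",
      gene_lg = "linkage_group", gene_pos = "position_cm"
    )
  qtls |>
    dplyr::left_join(loci, by = c(trait = "gene_id")) |>
    dplyr::mutate(class = dplyr::case_when(
      is.na(.data$gene_lg) | is.na(.data$gene_pos) ~ "unknown",
      .data$gene_lg == .data$linkage_group &
        abs(.data$gene_pos - .data$position_cm) <= window_cm ~ "cis",
      TRUE ~ "trans"
    ))
}

#' Write a QTL table as TSV
#'
#' `trait marker linkage_group position_cm lod effect pve parents` layout;
#' `effect` is the largest-magnitude per-parent effect.
#'
#' @param qtls a `gg_qtl`.
#' @param path file path.
#' @export
write_qtl_table <- function(qtls, path) {
  qtls |>
    dplyr::transmute(
      trait = .data$trait, marker = .data$marker_id,
      linkage_group = .data$linkage_group, position_cm = .data$position_cm,
      lod = .data$lod,
      effect = purrr::map_dbl(.data$effects, function(e) e[which.max(abs(e))]),
      pve = .data$pve, parents = .data$detected_in
    ) |>
    readr::write_tsv(path)
  invisible(path)
}
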