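test_that("LOD equals the brute-force OLS likelihood ratio", {
  map <- mini_map(6, 1)
  pop <- single_cross_pop(12, map, het = 1, seed = 2)
  set.seed(3)
  y <- pop$xf[, "m003"] + rnorm(12, 0, 0.1)
  traits <- tibble::tibble(individual = pop$individuals$id, y = y)
  scan <- lod_scan(traits, pop)
  row <- dplyr::filter(scan, marker_id == "m003")
  # oracle: explicit (n/2) log10(RSS0/RSS1) with normal equations
  X0 <- matrix(1, 12, 1)
  X1 <- cbind(1, pop$xf[, "m003"], pop$xm[, "m003"])
  lod_oracle <- (12 / 2) * log10(ols_rss(X0, y) / ols_rss(X1, y))
  expect_equal(row$lod, lod_oracle, tolerance = 1e-9)
  # effect estimate close to the planted 1 for the female parent
  expect_equal(unname(row$effects[[1]]["F1"]), 1, tolerance = 0.15)
})

test_that("LOD is zero for constant traits and invariant to affine rescaling", {
  pop <- study_pop(seed = 6)
  set.seed(1)
  y <- rnorm(nrow(pop$individuals))
  traits <- tibble::tibble(
    individual = pop$individuals$id,
    const = 1, y = y, y_affine = -3.7 * y + 11
  )
  expect_error(lod_scan(traits, pop), NA)
  scan <- lod_scan(dplyr::select(traits, individual, y, y_affine), pop)
  wide <- tidyr::pivot_wider(
    scan[c("trait", "marker_id", "lod")],
    names_from = trait, values_from = lod
  )
  expect_equal(wide$y, wide$y_affine, tolerance = 1e-9)
  sc <- lod_scan(dplyr::select(traits, individual, const), pop)
  expect_true(all(sc$lod == 0))
})

test_that("significance filtering is inclusive and respects per-parent detection", {
  rec <- tibble::tibble(
    trait = "t", marker_id = c("a", "b", "c"),
    linkage_group = 1L, position_cm = c(0, 50, 100), n = 100,
    lod = c(3.84, 3.83, 10),
    pve = 10,
    effects = list(c(P = 1), c(P = 1), c(P = 1)),
    parent_lod = list(c(P = 3.84), c(P = 3.84), c(P = 1))
  )
  class(rec) <- c("gg_scan", class(rec))
  kept <- significant_qtls(rec)
  expect_equal(kept$marker_id, "a") # 3.84 kept, 3.83 dropped, no-parent dropped
  kept2 <- significant_qtls(rec, require_any_parent = FALSE)
  expect_setequal(kept2$marker_id, c("a", "c"))
})

test_that("adjacent significant markers merge into one support interval", {
  rec <- tibble::tibble(
    trait = "t",
    marker_id = c("a", "b", "c", "d"),
    linkage_group = c(1L, 1L, 1L, 1L),
    position_cm = c(0, 10, 20, 60), n = 100,
    lod = c(5, 9, 6, 4.5),
    pve = 10,
    effects = rep(list(c(P = 1)), 4),
    parent_lod = rep(list(c(P = 5)), 4)
  )
  class(rec) <- c("gg_scan", class(rec))
  merged <- significant_qtls(rec)
  expect_equal(nrow(merged), 2)
  peak <- dplyr::filter(merged, marker_id == "b")
  expect_equal(peak$n_merged, 3L)
  expect_equal(peak$support_lo, 0)
  expect_equal(peak$support_hi, 20)
  expect_true("d" %in% merged$marker_id)
})

test_that("cis/trans classification follows the 10 cM same-group window", {
  qtls <- tibble::tibble(
    trait = c("g1", "g1", "g2"),
    marker_id = c("a", "b", "c"),
    linkage_group = c(1L, 2L, 1L),
    position_cm = c(5, 5, 50)
  )
  loci <- tibble::tibble(
    gene_id = c("g1", "g2"),
    linkage_group = c(1L, NA),
    position_cm = c(0, NA)
  )
  out <- classify_cis_trans(qtls, loci)
  expect_equal(out$class, c("cis", "trans", "unknown"))
  # window boundary: exactly 10 cM away is cis, 10.5 is trans
  qtls2 <- tibble::tibble(
    trait = "g1", marker_id = c("a", "b"), linkage_group = 1L,
    position_cm = c(10, 10.5)
  )
  out2 <- classify_cis_trans(qtls2, loci)
  expect_equal(out2$class, c("cis", "trans"))
})

test_that("null traits keep genome-wide false positives below 0.1%", {
  map <- sim_genetic_map()
  pop <- study_pop(map, het = 0.28, seed = 12)
  set.seed(13)
  n_null <- 200
  Y <- matrix(rnorm(nrow(pop$individuals) * n_null), nrow(pop$individuals))
  rownames(Y) <- pop$individuals$id
  colnames(Y) <- sprintf("null%03d", seq_len(n_null))
  scan <- lod_scan(Y, pop)
  frac <- mean(scan$lod >= 3.84)
  expect_lt(frac, 0.001)
})

test_that("strong planted eQTLs are recovered at the true or adjacent marker", {
  map <- sim_genetic_map()
  pop <- study_pop(map, het = 0.28, seed = 21)
  het <- pop$parents$het
  informative <- colnames(het)[colSums(het) > 0]
  n_rep <- 100
  set.seed(22)
  mks <- sample(informative, n_rep, replace = TRUE)
  Y <- matrix(0, nrow(pop$individuals), n_rep,
    dimnames = list(pop$individuals$id, sprintf("t%03d", seq_len(n_rep)))
  )
  for (i in seq_len(n_rep)) {
    p <- sample(rep(rownames(het)[het[, mks[i]]], 2), 1)
    x <- diallelgg:::parent_indicator(pop, p, mks[i])
    x[is.na(x)] <- 0
    # effect scaled for 25% of trait variance
    Y[, i] <- x + rnorm(nrow(Y), 0, sqrt(3 * var(x)))
  }
  scan <- lod_scan(Y, pop)
  hits <- 0
  for (i in seq_len(n_rep)) {
    sub <- dplyr::filter(scan, trait == sprintf("t%03d", i))
    peak <- sub$marker_id[which.max(sub$lod)]
    true_idx <- match(mks[i], map$marker_id)
    ok <- match(peak, map$marker_id) %in% (true_idx + c(-1, 0, 1))
    hits <- hits + ok
  }
  expect_gte(hits, 95)
})

test_that("scan errors on unusable traits and skips uninformative markers", {
  pop <- study_pop(seed = 6)
  bad <- tibble::tibble(individual = pop$individuals$id, y = NA_real_)
  expect_error(lod_scan(bad, pop), "all-missing")
  # markers informative in no parent are absent from the scan
  scan <- lod_scan(
    tibble::tibble(individual = pop$individuals$id, y = rnorm(nrow(pop$individuals))),
    pop
  )
  no_info <- colnames(pop$parents$het)[colSums(pop$parents$het) == 0]
  expect_false(any(scan$marker_id %in% no_info))
})
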