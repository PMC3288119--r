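test_that("genetic map has the study layout and validates", {
  map <- sim_genetic_map()
  expect_equal(nrow(map), 252)
  expect_equal(length(unique(map$linkage_group)), 13)
  expect_false(anyDuplicated(map$marker_id) > 0)
  by_lg <- split(map$position_cm, map$linkage_group)
  expect_true(all(vapply(by_lg, function(p) !is.unsorted(p), logical(1))))
  expect_error(read_genetic_map(tempfile()))
})

test_that("heterozygosity boundaries behave and counts are binomial", {
  map <- sim_genetic_map()
  hom <- sim_parents(map, het_fraction = 0, seed = 1)
  expect_false(any(hom$het))
  expect_true(all(hom$hap1 == hom$hap2))
  het1 <- sim_parents(map, het_fraction = 1, seed = 1)
  expect_true(all(het1$het))
  expect_true(all(het1$hap1 != het1$hap2))
  # per-parent heterozygous count within the binomial 99% interval
  p5 <- sim_parents(map, het_fraction = 0.5, seed = 42)
  counts <- rowSums(p5$het)
  lo <- qbinom(0.005, 252, 0.5)
  hi <- qbinom(0.995, 252, 0.5)
  expect_true(all(counts >= lo & counts <= hi))
})

test_that("default heterozygosity yields ~122 segregating loci per cross", {
  pop <- study_pop(sim_genetic_map(), het = 0.28, seed = 7)
  het <- pop$parents$het
  seg <- vapply(seq_len(nrow(pop$design)), function(i) {
    sum(het[pop$design$female[i], ] | het[pop$design$male[i], ])
  }, numeric(1))
  expect_true(all(abs(seg - 122) < 25))
})

test_that("progeny alleles are Mendelian at every locus", {
  pop <- study_pop(seed = 3)
  par <- pop$parents
  for (k in seq_len(nrow(pop$individuals))) {
    ind <- pop$individuals[k, ]
    mk <- pop$map$marker_id
    a_f <- ifelse(pop$hf[k, ] == 0, par$hap1[ind$female, mk], par$hap2[ind$female, mk])
    a_m <- ifelse(pop$hm[k, ] == 0, par$hap1[ind$male, mk], par$hap2[ind$male, mk])
    expect_equal(unname(pop$geno[k, ]), paste0(pmin(a_f, a_m), pmax(a_f, a_m)))
  }
  # indicators defined exactly at informative markers
  expect_true(all(is.na(pop$xf[1, !par$het[pop$individuals$female[1], ]])))
  expect_true(all(!is.na(pop$xf[1, par$het[pop$individuals$female[1], ]])))
})

test_that("transmission is fair and linked markers recombine per Haldane", {
  # map with gaps 0, 5, 10, 20, 50 cM plus a second linkage group
  map <- tibble::tibble(
    marker_id = sprintf("m%02d", 1:7),
    linkage_group = c(1, 1, 1, 1, 1, 1, 2),
    position_cm = c(0, 0, 5, 15, 35, 85, 0)
  )
  pop <- single_cross_pop(10000, map, het = 1, seed = 9)
  h <- pop$hf
  # fairness: each haplotype transmitted at 0.5 within 3 SE
  se <- 0.5 / sqrt(nrow(h))
  expect_true(all(abs(colMeans(h) - 0.5) <= 3 * se))
  # zero distance: indicators identical
  expect_equal(h[, 1], h[, 2])
  # Haldane recovery within +/- 0.01 for d in {5, 10, 20, 50}
  for (j in 3:6) {
    d <- map$position_cm[j] - map$position_cm[j - 1]
    r_obs <- mean(h[, j] != h[, j - 1])
    expect_lt(abs(r_obs - haldane_r(d)), 0.01)
  }
  # different linkage groups segregate independently (r ~ 0.5)
  expect_lt(abs(mean(h[, 6] != h[, 7]) - 0.5), 0.015)
})

test_that("planted eQTL effects appear in the latent trait", {
  map <- mini_map()
  pop <- study_pop(map, het = 1, seed = 5)
  arch <- sim_eqtl_architecture(map, pop$parents,
    n_genes = 1, mean_qtl = 0,
    hotspot_marker = "m010", hotspot_genes = 1, hotspot_beta = 1, seed = 2
  )
  q <- arch$qtls[[1]]
  expect_equal(nrow(q), 1)
  tech0 <- technical_model(baseline_sd = 0, sigma_bg = 0, sigma_e = 0)
  plan <- assign_dyes(optimize_pairs(
    lapply(
      setNames(pop$design$cross_id, pop$design$cross_id),
      function(c) genetic_distance_matrix(pop, c)
    ),
    n_restarts = 2, seed = 1
  ), seed = 2)
  expr <- sim_expression(pop, arch, tech0, plan, seed = 3)
  xs <- ifelse(pop$individuals$female == q$parent,
    pop$xf[, q$marker_id], pop$xm[, q$marker_id]
  )
  xs[!(pop$individuals$female == q$parent | pop$individuals$male == q$parent)] <- 0
  g <- expr$latent[, 1]
  diff <- mean(g[xs == 1]) - mean(g[xs == 0])
  se <- sqrt(var(g[xs == 1]) / sum(xs == 1) + var(g[xs == 0]) / sum(xs == 0))
  expect_lt(abs(abs(diff) - 1), max(3 * se, 1e-8))
})

test_that("zero-variance configuration collapses to the overall mean", {
  map <- mini_map()
  pop <- study_pop(map, het = 1, seed = 5)
  arch <- sim_eqtl_architecture(map, pop$parents, n_genes = 3, mean_qtl = 0, seed = 2)
  tech0 <- technical_model(
    dye = c(Cy3 = 0, Cy5 = 0), block = c(A = 0, B = 0, C = 0),
    batch = c(b1 = 0, b2 = 0), person = c(p1 = 0, p2 = 0, p3 = 0),
    baseline_sd = 0, sigma_bg = 0, sigma_e = 0
  )
  plan <- assign_dyes(optimize_pairs(
    lapply(
      setNames(pop$design$cross_id, pop$design$cross_id),
      function(c) genetic_distance_matrix(pop, c)
    ),
    n_restarts = 2, seed = 1
  ), seed = 2)
  expr <- sim_expression(pop, arch, tech0, plan, seed = 3)
  h_rec <- asinh((expr$intensities$foreground - expr$intensities$background) / tech0$scale)
  expect_equal(h_rec, rep(tech0$mu, length(h_rec)), tolerance = 1e-12)
})

test_that("a planted dye offset shows up as the channel mean difference", {
  map <- mini_map()
  pop <- study_pop(map, het = 1, seed = 5)
  arch <- sim_eqtl_architecture(map, pop$parents, n_genes = 40, mean_qtl = 0, seed = 2)
  tech <- technical_model(dye = c(Cy3 = 0, Cy5 = 0.5))
  plan <- assign_dyes(optimize_pairs(
    lapply(
      setNames(pop$design$cross_id, pop$design$cross_id),
      function(c) genetic_distance_matrix(pop, c)
    ),
    n_restarts = 2, seed = 1
  ), seed = 2)
  expr <- sim_expression(pop, arch, tech, plan, seed = 3)
  h_rec <- asinh((expr$intensities$foreground - expr$intensities$background) / tech$scale)
  d <- tapply(h_rec, expr$intensities$channel, mean)
  se <- sqrt(2 * var(h_rec) / (length(h_rec) / 2))
  expect_lt(abs((d[["Cy5"]] - d[["Cy3"]]) - 0.5), 3 * se)
})

test_that("architectures referencing absent markers are rejected", {
  map <- mini_map()
  pop <- study_pop(map, het = 1, seed = 5)
  arch <- sim_eqtl_architecture(map, pop$parents, n_genes = 1, mean_qtl = 1, seed = 2)
  arch$qtls[[1]]$marker_id <- "nonexistent"
  plan <- assign_dyes(optimize_pairs(
    lapply(
      setNames(pop$design$cross_id, pop$design$cross_id),
      function(c) genetic_distance_matrix(pop, c)
    ),
    n_restarts = 2, seed = 1
  ), seed = 2)
  expect_error(
    sim_expression(pop, arch, technical_model(), plan, seed = 1),
    "absent"
  )
})

test_that("ordinal phenotype classes follow the liability thresholds", {
  map <- mini_map()
  design <- diallel_design(tibble::tibble(
    cross_id = c("a", "b"), female = c("F1", "F1"),
    male = c("M1", "M2"), n_progeny = c(1000, 1000)
  ))
  parents <- sim_parents(map, c("F1", "M1", "M2"), het_fraction = 0.5, seed = 2)
  pop <- sim_population(map, parents, design, seed = 3)
  arch <- sim_pheno_architecture(map, parents,
    n_qtl_shared = 0, n_qtl_specific = 0, seed = 4
  )
  ph <- sim_phenotypes(pop, arch, seed = 5)
  th3 <- arch$thresholds[[which(arch$trait == "atk2000")]]
  p3 <- diff(c(0, pnorm(th3), 1))
  gof <- suppressWarnings(chisq.test(table(factor(ph$atk2000, levels = 0:2)), p = p3))
  expect_gt(gof$p.value, 0.01)
  th5 <- arch$thresholds[[which(arch$trait == "egg2000")]]
  p5 <- diff(c(0, pnorm(th5), 1))
  gof5 <- suppressWarnings(chisq.test(table(factor(ph$egg2000, levels = 0:4)), p = p5))
  expect_gt(gof5$p.value, 0.01)
  # sums are the sums of the yearly classes
  expect_equal(ph$sum_atk, ph$atk2000 + ph$atk2001)
  expect_equal(ph$sum_egg, ph$egg2000 + ph$egg2001)
})

test_that("degenerate thresholds collapse ordinal traits to one class", {
  map <- mini_map()
  pop <- study_pop(map, seed = 2)
  arch <- sim_pheno_architecture(map, pop$parents, seed = 4)
  i <- which(arch$trait == "atk2000")
  arch$thresholds[[i]] <- c(-Inf, Inf)
  ph <- sim_phenotypes(pop, arch, seed = 5)
  expect_true(all(ph$atk2000 == 1))
})

test_that("population simulation is reproducible from its seed", {
  map <- mini_map()
  p1 <- sim_population(map, seed = 11)
  p2 <- sim_population(map, seed = 11)
  expect_identical(p1$geno, p2$geno)
  expect_identical(p1$xf, p2$xf)
})
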