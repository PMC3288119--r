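intensity_fixture <- function(n_slides = 4, n_spots = 300, fun, seed = 1) {
  withr_seed <- seed
  set.seed(withr_seed)
  tidyr::expand_grid(
    slide = sprintf("s%d", seq_len(n_slides)),
    channel = c("Cy3", "Cy5"),
    spot = sprintf("g%03d", seq_len(n_spots))
  ) |>
    dplyr::mutate(subgrid = 1L, foreground = fun(dplyr::n()), background = 30)
}

test_that("background subtraction is exact and keeps negatives", {
  raw <- intensity_fixture(fun = function(n) rep(c(100, 10), length.out = n))
  out <- subtract_background(raw)
  expect_equal(out$net, out$foreground - 30)
  expect_true(any(out$net < 0))
  raw0 <- dplyr::mutate(raw, background = 0)
  expect_equal(subtract_background(raw0)$net, raw0$foreground)
  expect_error(
    subtract_background(dplyr::mutate(raw, background = NA_real_)),
    "background"
  )
})

test_that("arsinh transform is strictly monotone and centred", {
  raw <- intensity_fixture(fun = function(n) rlnorm(n, 5, 1))
  h <- vsn_transform(subtract_background(raw))
  one <- dplyr::filter(h, slide == "s1", channel == "Cy3")
  ord <- order(one$net)
  expect_true(all(diff(one$h[ord]) > 0))
  # value at the channel median maps to 0
  expect_lt(min(abs(one$h)), 0.05)
  cst <- dplyr::mutate(raw, foreground = 50)
  expect_error(vsn_transform(subtract_background(cst)), "zero MAD")
})

test_that("arsinh transform stabilizes multiplicative-plus-additive noise", {
  # independent oracle: rank regression of the mean-normalized replicate
  # spread on the signal rank; intensities follow a lognormal expression
  # profile over an additive noise floor
  set.seed(42)
  n_spots <- 400
  mu <- exp(qnorm(ppoints(n_spots), log(500), 2))
  raw <- tidyr::expand_grid(
    slide = sprintf("s%d", 1:6), channel = "Cy3",
    spot = sprintf("g%03d", seq_len(n_spots))
  ) |>
    dplyr::mutate(
      subgrid = 1L,
      foreground = rep(mu, times = 6) * exp(rnorm(dplyr::n(), 0, 0.3)) +
        rnorm(dplyr::n(), 0, 200),
      background = 0
    )
  h <- vsn_transform(subtract_background(raw))
  s_raw <- tapply(h$net, h$spot, sd)[sprintf("g%03d", seq_len(n_spots))]
  s_h <- tapply(h$h, h$spot, sd)[sprintf("g%03d", seq_len(n_spots))]
  rk <- rank(mu)
  slope_raw <- coef(lm(I(s_raw / mean(s_raw)) ~ rk))[2]
  slope_h <- coef(lm(I(s_h / mean(s_h)) ~ rk))[2]
  expect_lt(abs(slope_h), 0.25 * abs(slope_raw))
})

test_that("cross-slide calibration standardizes and is idempotent", {
  raw <- intensity_fixture(fun = function(n) rlnorm(n, 5, 1))
  h <- vsn_transform(subtract_background(raw)) |>
    dplyr::mutate(h = h + ifelse(slide == "s2", 5, 0)) # planted shift
  cal <- calibrate_across_slides(h)
  stats <- cal |>
    dplyr::group_by(slide, channel) |>
    dplyr::summarise(med = median(h), mad_ = mad(h), .groups = "drop")
  expect_true(all(abs(stats$med) < 1e-12))
  expect_true(all(abs(stats$mad_ - 1) < 1e-9))
  twice <- calibrate_across_slides(cal)
  expect_equal(twice$h, cal$h, tolerance = 1e-12)
})

test_that("technical model fit matches a normal-equations oracle", {
  pop <- study_pop(seed = 4)
  arch <- sim_eqtl_architecture(mini_map(), pop$parents, n_genes = 5, mean_qtl = 2, seed = 1)
  dists <- lapply(
    setNames(pop$design$cross_id, pop$design$cross_id),
    function(c) genetic_distance_matrix(pop, c)
  )
  plan <- assign_dyes(optimize_pairs(dists, n_restarts = 2, seed = 1), seed = 2)
  expr <- sim_expression(pop, arch, technical_model(), plan, seed = 3)
  h <- calibrate_across_slides(vsn_transform(subtract_background(expr$intensities)))
  fit <- fit_technical_model(h, expr$samples, "eq1")
  # oracle: explicit normal equations per gene on the same design
  X <- fit$design
  hw <- h |>
    dplyr::inner_join(expr$samples, by = c("slide", "channel")) |>
    dplyr::select(slide, channel, spot, h) |>
    tidyr::pivot_wider(names_from = spot, values_from = h)
  for (g in colnames(fit$obs_resid)[1:3]) {
    y <- hw[[g]]
    b <- solve(crossprod(X), crossprod(X, y))
    expect_equal(unname(fit$obs_resid[, g]), unname(as.vector(y - X %*% b)),
      tolerance = 1e-9
    )
  }
})

test_that("residuals are orthogonal to every design column", {
  pop <- study_pop(seed = 4)
  arch <- sim_eqtl_architecture(mini_map(), pop$parents, n_genes = 8, mean_qtl = 2, seed = 1)
  dists <- lapply(
    setNames(pop$design$cross_id, pop$design$cross_id),
    function(c) genetic_distance_matrix(pop, c)
  )
  plan <- assign_dyes(optimize_pairs(dists, n_restarts = 2, seed = 1), seed = 2)
  expr <- sim_expression(pop, arch, technical_model(), plan, seed = 3)
  for (model in c("eq1", "eq2")) {
    fit <- normalize_expression(expr$intensities, expr$samples, model)
    E <- fit$obs_resid
    X <- fit$design
    dots <- abs(t(X) %*% E) / outer(sqrt(colSums(X^2)), sqrt(colSums(E^2)))
    expect_true(all(dots < 1e-8))
    expect_true(all(abs(colMeans(E)) < 1e-10))
  }
})

test_that("planted technical effects are recovered within 3 SE", {
  pop <- study_pop(seed = 4)
  arch <- sim_eqtl_architecture(mini_map(), pop$parents,
    n_genes = 60, mean_qtl = 0, seed = 1
  )
  tech <- technical_model(block = c(A = -1, B = 0, C = 1))
  dists <- lapply(
    setNames(pop$design$cross_id, pop$design$cross_id),
    function(c) genetic_distance_matrix(pop, c)
  )
  plan <- assign_dyes(optimize_pairs(dists, n_restarts = 2, seed = 1), seed = 2)
  expr <- sim_expression(pop, arch, tech, plan, seed = 3)
  # work on the un-calibrated arsinh scale so planted effects keep their units
  h <- vsn_transform(subtract_background(expr$intensities)) |>
    dplyr::mutate(h = asinh((foreground - background) / tech$scale))
  fit <- fit_technical_model(h, expr$samples, "eq1")
  bl <- fit$effects |>
    dplyr::filter(grepl("^block", term)) |>
    dplyr::group_by(term) |>
    dplyr::summarise(est = mean(estimate), se = sd(estimate) / sqrt(dplyr::n()))
  # contr.sum coding: block1 = effect of A (-1), block2 = effect of B (0)
  expect_lt(abs(bl$est[bl$term == "block1"] - (-1)), 3 * bl$se[bl$term == "block1"])
  expect_lt(abs(bl$est[bl$term == "block2"] - 0), 3 * bl$se[bl$term == "block2"])
})

test_that("pure dye structure projects out exactly and refit is idempotent", {
  pop <- study_pop(seed = 4)
  samples <- tidyr::expand_grid(
    slide = sprintf("s%d", 1:6), channel = c("Cy3", "Cy5")
  ) |>
    dplyr::mutate(
      individual = pop$individuals$id[seq_len(dplyr::n())],
      dye = channel, block = "A", batch = "b1", person = "p1",
      family = "26"
    )
  h <- tidyr::expand_grid(
    slide = sprintf("s%d", 1:6), channel = c("Cy3", "Cy5"),
    spot = c("g1", "g2")
  ) |>
    dplyr::mutate(h = ifelse(channel == "Cy5", 0.5, 0))
  fit <- fit_technical_model(h, samples, "eq1")
  means <- tapply(fit$obs_resid[, "g1"], fit$obs$dye, mean)
  expect_true(all(abs(means) < 1e-9))
  # residualizing residuals changes nothing
  h2 <- h |> dplyr::mutate(h = fit$obs_resid[cbind(
    match(paste(slide, channel), paste(fit$obs$slide, fit$obs$channel)),
    match(spot, colnames(fit$obs_resid))
  )])
  fit2 <- fit_technical_model(h2, samples, "eq1")
  expect_equal(fit2$obs_resid, fit$obs_resid, tolerance = 1e-10)
})

test_that("single-level covariates reduce to centring and aliasing errors name factors", {
  samples <- tibble::tibble(
    slide = sprintf("s%d", 1:4), channel = "Cy3",
    individual = sprintf("i%d", 1:4), dye = "Cy3", block = "A",
    batch = "b1", person = "p1", family = "f"
  )
  h <- tidyr::expand_grid(slide = sprintf("s%d", 1:4), channel = "Cy3", spot = "g1") |>
    dplyr::mutate(h = c(1, 2, 3, 6))
  fit <- fit_technical_model(h, samples, "eq1")
  expect_equal(unname(fit$obs_resid[, 1]), c(1, 2, 3, 6) - 3)
  # confounded factors: block perfectly aliased with batch
  samples2 <- samples |>
    dplyr::mutate(block = c("A", "A", "B", "B"), batch = c("b1", "b1", "b2", "b2"))
  expect_error(fit_technical_model(h, samples2, "eq1"), "aliased")
})

test_that("normalization round-trips the planted genetic signal", {
  map <- mini_map()
  pop <- study_pop(map, het = 1, seed = 5)
  arch <- sim_eqtl_architecture(map, pop$parents,
    n_genes = 200, mean_qtl = 2, seed = 2
  )
  tech <- technical_model(sigma_e = 0.05)
  dists <- lapply(
    setNames(pop$design$cross_id, pop$design$cross_id),
    function(c) genetic_distance_matrix(pop, c)
  )
  plan <- assign_dyes(optimize_pairs(dists, n_restarts = 2, seed = 1), seed = 2)
  expr <- sim_expression(pop, arch, tech, plan, seed = 3)
  rm1 <- normalize_expression(expr$intensities, expr$samples, "eq1")
  cors <- vapply(seq_len(ncol(rm1$resid)), function(j) {
    cor(rm1$resid[, j], expr$latent[rownames(rm1$resid), j])
  }, numeric(1))
  expect_gte(median(cors), 0.9)
  expect_gte(quantile(cors, 0.1), 0.75)
})
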