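#' Subtract local subgrid background
#'
#' Per-spot `foreground - background`, using the local background of the
#' spot's print subgrid. Negative values are retained; the downstream arsinh
#' transform is defined on all reals.
#'
#' @param raw intensity tibble with `slide`, `channel`, `subgrid`, `spot`,
#'   `foreground`, `background`.
#' @return the tibble with a `net` column added.
#' @export
subtract_background <- function(raw) {
  req <- c("slide", "channel", "subgrid", "spot", "foreground", "background")
  if (!all(req %in% names(raw))) {
    abort(paste("intensity table must have columns", paste(req, collapse = ", ")))
  }
  if (anyNA(raw$background)) abort("missing background for some subgrid")
  dplyr::mutate(raw, net = .data$foreground - .data$background)
}

#' Variance-stabilizing arsinh transform
#'
#' Robust-affine stabilization per slide-channel:
#' `h = asinh((net - median(net)) / mad(net))`. The transform is strictly
#' increasing in the net intensity; for large intensities it behaves like a
#' logarithm, so multiplicative noise components are stabilized.
#'
#' @param bg_subtracted tibble from [subtract_background()] (column `net`).
#' @return the tibble with an `h` column added.
#' @export
vsn_transform <- function(bg_subtracted) {
  if (!"net" %in% names(bg_subtracted)) {
    abort("run subtract_background() first (column `net` missing)")
  }
  bg_subtracted |>
    dplyr::group_by(.data$slide, .data$channel) |>
    dplyr::mutate(h = {
      x <- .data$net
      if (sum(is.finite(x)) < 2) abort("fewer than 2 finite values in a channel")
      b <- mad(x, na.rm = TRUE)
      if (b == 0) abort(sprintf(
        "constant channel (zero MAD): slide %s %s",
        .data$slide[1], .data$channel[1]
      ))
      asinh((x - median(x, na.rm = TRUE)) / b)
    }) |>
    dplyr::ungroup()
}

#' Simultaneous cross-slide calibration
#'
#' Rescales every slide-channel to a common location and spread (median 0,
#' MAD 1) so that overall expression level and variance are
#' array-independent. Idempotent to numerical tolerance.
#'
#' @param stabilized tibble with column `h` (from [vsn_transform()]).
#' @return the tibble with `h` recalibrated.
#' @export
calibrate_across_slides <- function(stabilized) {
  if (!"h" %in% names(stabilized)) abort("column `h` missing")
  if (dplyr::n_distinct(stabilized$slide, stabilized$channel) < 2) {
    abort("need at least 2 channels to calibrate")
  }
  stabilized |>
    dplyr::group_by(.data$slide, .data$channel) |>
    dplyr::mutate(h = {
      b <- mad(.data$h, na.rm = TRUE)
      if (b == 0) abort(sprintf(
        "constant channel (zero MAD): slide %s %s",
        .data$slide[1], .data$channel[1]
      ))
      (.data$h - median(.data$h, na.rm = TRUE)) / b
    }) |>
    dplyr::ungroup()
}

#' Fit the fixed-effects technical model and extract residuals
#'
#' Per-gene ordinary least squares of the stabilized intensity on the
#' technical covariates, with sum-to-zero factor coding:
#' model `"eq1"` uses dye + block + batch + person; model `"eq2"`
#' additionally removes the family (cross) effect, as required before
#' co-expression network inference. Residuals are returned per observation
#' and averaged per individual when an individual was measured on more than
#' one channel.
#'
#' @param stabilized calibrated tibble with columns `slide`, `channel`,
#'   `spot`, `h`.
#' @param samples covariate tibble keyed by (`slide`, `channel`):
#'   `individual`, `dye`, `block`, `batch`, `person`, `family`.
#' @param model `"eq1"` or `"eq2"`.
#' @return object of class `residual_matrix`: list with `resid`
#'   (individuals x genes), `obs_resid` (observations x genes), `effects`
#'   tibble (gene, term, estimate), `design` matrix, `obs` covariates and
#'   `model_tag`.
#' @export
fit_technical_model <- function(stabilized, samples, model = c("eq1", "eq2")) {
  model <- match.arg(model)
  req <- c("individual", "dye", "block", "batch", "person")
  if (model == "eq2") req <- c(req, "family")
  if (!all(c("slide", "channel", req) %in% c(names(samples), "slide", "channel"))) {
    abort(paste("samples must have columns", paste(req, collapse = ", ")))
  }
  obs <- stabilized |>
    dplyr::select("slide", "channel", "spot", "h") |>
    dplyr::inner_join(samples, by = c("slide", "channel"))
  if (anyNA(obs[req])) abort("covariate table incomplete for some observation")
  wide <- obs |>
    dplyr::select("slide", "channel", "individual", "spot", "h",
      dplyr::all_of(req)
    ) |>
    tidyr::pivot_wider(names_from = "spot", values_from = "h")
  covars <- wide[req]
  genes <- setdiff(names(wide), c("slide", "channel", "individual", req))
  Y <- as.matrix(wide[genes])
  terms <- c("dye", "block", "batch", if (model == "eq2") "family", "person")
  # factors with >1 level enter the design with sum-to-zero contrasts
  active <- terms[vapply(terms, function(t) length(unique(covars[[t]])) > 1, logical(1))]
  if (length(active) == 0) {
    X <- matrix(1, nrow(Y), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    fml <- stats::as.formula(paste("~", paste(active, collapse = " + ")))
    df <- as.data.frame(lapply(covars[active], factor))
    X <- model.matrix(fml, df,
      contrasts.arg = lapply(df, function(x) "contr.sum")
    )
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    abort(paste("rank-deficient design; aliased terms:", paste(aliased, collapse = ", ")))
  }
  E <- qr.resid(qx, Y)
  coefs <- qr.coef(qx, Y)
  eff <- as_tibble(t(coefs), rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "term", values_to = "estimate")
  resid_by_ind <- rowsum(E, wide$individual) /
    as.vector(table(wide$individual)[sort(unique(wide$individual))])
  structure(
    list(
      resid = resid_by_ind, obs_resid = E, effects = eff,
      design = X, obs = wide[c("slide", "channel", "individual", req)],
      model_tag = model
    ),
    class = "residual_matrix"
  )
}

#' @export
print.residual_matrix <- function(x, ...) {
  cat(sprintf(
    "<residual_matrix> %d individuals x %d genes (model %s)\n",
    nrow(x$resid), ncol(x$resid), x$model_tag
  ))
  invisible(x)
}

#' Run the full normalization pipeline
#'
#' Background subtraction, arsinh stabilization, cross-slide calibration and
#' technical-model residualization in one call.
#'
#' @param raw raw intensity tibble.
#' @param samples covariate tibble (see [fit_technical_model()]).
#' @param model `"eq1"` (eQTL analysis) or `"eq2"` (network analysis).
#' @return a `residual_matrix`.
#' @export
normalize_expression <- function(raw, samples, model = c("eq1", "eq2")) {
  raw |>
    subtract_background() |>
    vsn_transform() |>
    calibrate_across_slides() |>
    fit_technical_model(samples, model = model)
}

#' Residual matrix as a trait table
#'
#' Converts a `residual_matrix` into the tibble layout expected by
#' [lod_scan()] (one `individual` column plus one column per gene).
#'
#' @param rm a `residual_matrix`.
#' @return tibble.
#' @export
traits_from_residuals <- function(rm) {
  stopifnot(inherits(rm, "residual_matrix"))
  dplyr::bind_cols(
    tibble(individual = rownames(rm$resid)),
    as_tibble(rm$resid)
  )
}
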