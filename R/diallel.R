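#' Partial diallel crossing design
#'
#' The default mirrors a 2 females x 2 males partial diallel with four
#' full-sib families: crosses 26 (PG87 x PG165, 48 progeny), 27 (PG87 x
#' PG117, 36), 29 (PG21 x PG165, 50) and 32 (PG21 x PG117, 54), i.e. 188
#' profiled progeny in total.
#'
#' @param crosses tibble with columns `cross_id`, `female`, `male`,
#'   `n_progeny`. Defaults to the four-family design above.
#' @return a validated `diallel_design` tibble.
#' @export
diallel_design <- function(crosses = NULL) {
  crosses <- crosses %||% tibble(
    cross_id = c("26", "27", "29", "32"),
    female = c("PG87", "PG87", "PG21", "PG21"),
    male = c("PG165", "PG117", "PG165", "PG117"),
    n_progeny = c(48L, 36L, 50L, 54L)
  )
  req <- c("cross_id", "female", "male", "n_progeny")
  if (!all(req %in% names(crosses))) {
    abort(paste("crosses must have columns", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(crosses$cross_id)) abort("cross_ids must be unique")
  if (any(crosses$n_progeny < 1)) abort("n_progeny must be positive")
  class(crosses) <- c("diallel_design", class(crosses))
  crosses
}

#' Simulate phased parental genotypes
#'
#' Each parent is made heterozygous at a binomial fraction of markers; at a
#' heterozygous marker the two phased alleles are distinct letters from
#' {a,b,c,d}, at a homozygous marker both haplotypes carry the same letter.
#' The default heterozygosity is chosen so that a cross between two random
#' parents segregates at roughly 122 of 252 loci
#' (1 - (1 - 0.28)^2 ~ 0.48).
#'
#' @param map genetic map tibble (see [sim_genetic_map()]).
#' @param parent_ids character vector of parent names.
#' @param het_fraction probability that a parent is heterozygous at a marker.
#' @param seed optional integer seed.
#' @return object of class `phased_parents`: list with character matrices
#'   `hap1`, `hap2` (parents x markers) and logical `het`.
#' @export
sim_parents <- function(map, parent_ids = c("PG87", "PG21", "PG165", "PG117"),
                        het_fraction = 0.28, seed = NULL) {
  validate_map(map)
  check_number(het_fraction, "het_fraction", lower = 0, upper = 1)
  n_p <- length(parent_ids)
  n_m <- nrow(map)
  alphabet <- c("a", "b", "c", "d")
  with_seed(seed, {
    het <- matrix(runif(n_p * n_m) < het_fraction, n_p, n_m,
      dimnames = list(parent_ids, map$marker_id)
    )
    hap1 <- matrix(sample(alphabet, n_p * n_m, replace = TRUE), n_p, n_m,
      dimnames = dimnames(het)
    )
    shift <- matrix(sample(1:3, n_p * n_m, replace = TRUE), n_p, n_m)
    hap2 <- hap1
    # heterozygous: second haplotype gets a different letter
    idx1 <- match(hap1, alphabet)
    hap2[het] <- alphabet[((idx1[het] - 1 + shift[het]) %% 4) + 1]
    structure(
      list(parent_ids = parent_ids, hap1 = hap1, hap2 = hap2, het = het),
      class = "phased_parents"
    )
  })
}

# Simulate n gametes from one parent: matrix (n x markers) of transmitted
# haplotype indicators (0 = hap1, 1 = hap2). Crossovers between adjacent
# markers at distance d cM occur with Haldane probability; linkage groups
# are independent.
sim_gametes <- function(map, n) {
  m <- nrow(map)
  ind <- matrix(0L, n, m, dimnames = list(NULL, map$marker_id))
  new_lg <- c(TRUE, diff(map$linkage_group) != 0)
  gap <- c(0, pmax(0, diff(map$position_cm)))
  r <- haldane_r(gap)
  for (j in seq_len(m)) {
    if (new_lg[j]) {
      ind[, j] <- rbinom(n, 1L, 0.5)
    } else {
      swap <- runif(n) < r[j]
      ind[, j] <- ifelse(swap, 1L - ind[, j - 1L], ind[, j - 1L])
    }
  }
  ind
}

#' Simulate one full-sib cross
#'
#' Each progeny receives one recombinant haplotype from each parent, with
#' crossovers placed by the Haldane map function. Transmitted-allele
#' indicators are reported only at markers where the corresponding parent is
#' heterozygous (informative meioses); elsewhere they are `NA`.
#'
#' @param parents a `phased_parents` object.
#' @param female,male parent ids.
#' @param n_progeny number of progeny.
#' @param map genetic map.
#' @param cross_id label used to form progeny ids.
#' @param seed optional integer seed.
#' @return list with `individuals` tibble, indicator matrices `xf`, `xm`
#'   (NA at uninformative markers), full transmission matrices `hf`, `hm`,
#'   and genotype-string matrix `geno` (e.g. `"ab"`, unordered).
#' @export
sim_cross <- function(parents, female, male, n_progeny, map,
                      cross_id = paste0(female, "x", male), seed = NULL) {
  stopifnot(inherits(parents, "phased_parents"))
  for (p in c(female, male)) {
    if (!p %in% parents$parent_ids) abort(sprintf("unknown parent '%s'", p))
  }
  if (n_progeny < 1) abort("n_progeny must be >= 1")
  with_seed(seed, {
    hf <- sim_gametes(map, n_progeny)
    hm <- sim_gametes(map, n_progeny)
    mk <- map$marker_id
    a_f <- ifelse(hf == 0L,
      matrix(parents$hap1[female, mk], n_progeny, length(mk), byrow = TRUE),
      matrix(parents$hap2[female, mk], n_progeny, length(mk), byrow = TRUE)
    )
    a_m <- ifelse(hm == 0L,
      matrix(parents$hap1[male, mk], n_progeny, length(mk), byrow = TRUE),
      matrix(parents$hap2[male, mk], n_progeny, length(mk), byrow = TRUE)
    )
    geno <- matrix(paste0(pmin(a_f, a_m), pmax(a_f, a_m)),
      n_progeny, length(mk),
      dimnames = list(NULL, mk)
    )
    xf <- hf
    xf[, !parents$het[female, mk]] <- NA
    xm <- hm
    xm[, !parents$het[male, mk]] <- NA
    ids <- sprintf("%s_%03d", cross_id, seq_len(n_progeny))
    rownames(xf) <- rownames(xm) <- rownames(hf) <- rownames(hm) <-
      rownames(geno) <- ids
    list(
      individuals = tibble(
        id = ids, cross_id = cross_id, female = female, male = male
      ),
      xf = xf, xm = xm, hf = hf, hm = hm, geno = geno
    )
  })
}

#' Simulate a full diallel population
#'
#' Runs [sim_cross()] for every cross of a [diallel_design()] and stacks the
#' results into one population object used by all downstream stages.
#'
#' @param map genetic map.
#' @param parents `phased_parents`; defaults to [sim_parents()] on `map`.
#' @param design `diallel_design`; defaults to the study layout.
#' @param seed optional integer seed (spawns one substream per cross).
#' @return object of class `diallel_pop`: list with `map`, `design`,
#'   `parents`, `individuals` tibble (`id`, `cross_id`, `female`, `male`),
#'   indicator matrices `xf`, `xm` (progeny x markers, NA = uninformative),
#'   full transmissions `hf`, `hm`, and genotype strings `geno`.
#' @examples
#' pop <- sim_population(sim_genetic_map(24, 2), seed = 1)
#' nrow(pop$individuals)
#' @export
sim_population <- function(map, parents = NULL, design = diallel_design(),
                           seed = NULL) {
  validate_map(map)
  parents <- parents %||% sim_parents(map, seed = substream(seed, "parents"))
  crosses <- purrr::pmap(
    list(design$cross_id, design$female, design$male, design$n_progeny),
    function(cid, f, m, n) {
      sim_cross(parents, f, m, n, map,
        cross_id = cid, seed = substream(seed, paste0("cross_", cid))
      )
    }
  )
  pop <- structure(
    list(
      map = map, design = design, parents = parents,
      individuals = purrr::map_dfr(crosses, "individuals"),
      xf = do.call(rbind, purrr::map(crosses, "xf")),
      xm = do.call(rbind, purrr::map(crosses, "xm")),
      hf = do.call(rbind, purrr::map(crosses, "hf")),
      hm = do.call(rbind, purrr::map(crosses, "hm")),
      geno = do.call(rbind, purrr::map(crosses, "geno"))
    ),
    class = "diallel_pop"
  )
  pop
}

#' @export
print.diallel_pop <- function(x, ...) {
  cat(sprintf(
    "<diallel_pop> %d progeny in %d crosses, %d markers on %d linkage groups\n",
    nrow(x$individuals), nrow(x$design), nrow(x$map),
    length(unique(x$map$linkage_group))
  ))
  invisible(x)
}

#' Write population genotypes / read them back
#'
#' CSV with rows = individuals and columns = markers; cells are unordered
#' genotype strings such as `"ab"`, missing as `NA`.
#'
#' @param pop a `diallel_pop`.
#' @param path file path.
#' @export
write_genotypes <- function(pop, path) {
  geno <- as_tibble(pop$geno) |>
    dplyr::mutate(id = rownames(pop$geno), .before = 1)
  readr::write_csv(geno, path)
  invisible(path)
}
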