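#' Simulate a framework genetic linkage map
#'
#' Generates an ordered SNP marker map spread over a fixed number of linkage
#' groups. The default emulates a conifer framework map: 252 markers on 13
#' linkage groups at roughly 10 cM spacing, the coordinate system for all QTL
#' results produced by this package.
#'
#' @param n_markers total number of markers (default 252).
#' @param n_lg number of linkage groups (default 13).
#' @param spacing_cm average distance between adjacent markers, in cM.
#' @param jitter_cm uniform jitter applied to inter-marker gaps (0 = evenly
#'   spaced). Positions remain non-decreasing.
#' @param seed optional integer seed (only used when `jitter_cm > 0`).
#' @return A tibble with columns `marker_id`, `linkage_group`, `position_cm`,
#'   ordered by linkage group and position.
#' @examples
#' map <- sim_genetic_map()
#' dplyr::count(map, linkage_group)
#' @export
sim_genetic_map <- function(n_markers = 252, n_lg = 13, spacing_cm = 10,
                            jitter_cm = 0, seed = NULL) {
  check_number(n_markers, "n_markers", lower = 1)
  check_number(n_lg, "n_lg", lower = 1)
  check_number(spacing_cm, "spacing_cm", lower = 0)
  # split markers as evenly as possible across groups
  per_lg <- diff(floor(seq(0, n_markers, length.out = n_lg + 1)))
  with_seed(seed, {
    purrr::map2_dfr(seq_len(n_lg), per_lg, function(lg, k) {
      gaps <- rep(spacing_cm, k - 1)
      if (jitter_cm > 0 && k > 1) {
        gaps <- pmax(0, gaps + runif(k - 1, -jitter_cm, jitter_cm))
      }
      tibble(
        linkage_group = lg,
        position_cm = cumsum(c(0, gaps))
      )
    })
  }) |>
    dplyr::mutate(marker_id = sprintf("m%03d", dplyr::row_number())) |>
    dplyr::select("marker_id", "linkage_group", "position_cm")
}

validate_map <- function(map) {
  req <- c("marker_id", "linkage_group", "position_cm")
  if (!all(req %in% names(map))) {
    abort(paste("map must have columns", paste(req, collapse = ", ")))
  }
  if (nrow(map) == 0) abort("map is empty")
  if (anyDuplicated(map$marker_id)) abort("duplicate marker_ids in map")
  ok <- map |>
    dplyr::group_by(.data$linkage_group) |>
    dplyr::summarise(sorted = !is.unsorted(.data$position_cm)) |>
    dplyr::pull(.data$sorted)
  if (!all(ok)) abort("positions must be non-decreasing within linkage groups")
  invisible(map)
}

#' Read / write a genetic map as TSV
#'
#' Plain `marker_id  linkage_group  position_cm` layout.
#'
#' @param path file path.
#' @return `read_genetic_map()` returns the map tibble; `write_genetic_map()`
#'   returns `path` invisibly.
#' @export
read_genetic_map <- function(path) {
  map <- readr::read_tsv(path, col_types = readr::cols(
    marker_id = readr::col_character(),
    linkage_group = readr::col_integer(),
    position_cm = readr::col_double()
  ))
  validate_map(map)
  map
}

#' @rdname read_genetic_map
#' @param map a genetic map tibble.
#' @export
write_genetic_map <- function(map, path) {
  validate_map(map)
  readr::write_tsv(map, path)
  invisible(path)
}
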