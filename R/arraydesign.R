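#' Genetic distance between two individuals
#'
#' Simple mismatch fraction: the share of compared loci at which the two
#' genotype states differ. Loci missing in either individual are excluded
#' from numerator and denominator.
#'
#' @param g_i,g_j character vectors of genotype states (e.g. `"ab"`),
#'   aligned on the same loci.
#' @return fraction in `[0, 1]`.
#' @examples
#' genetic_distance(c("ab", "ab", "cd"), c("ab", "cd", "ab"))
#' @export
genetic_distance <- function(g_i, g_j) {
  if (length(g_i) != length(g_j)) abort("genotype vectors differ in length")
  keep <- !is.na(g_i) & !is.na(g_j)
  if (!any(keep)) abort("zero comparable loci")
  mean(g_i[keep] != g_j[keep])
}

#' Pairwise genetic distances within a cross
#'
#' Distances are computed over the segregating loci of the cross (markers at
#' which at least one parent is heterozygous), mirroring the use of all
#' segregating SNP loci for probe-pair selection.
#'
#' @param pop `diallel_pop`.
#' @param cross_id one cross id from the design.
#' @param loci optional explicit marker subset.
#' @return symmetric distance matrix with individual ids as dimnames.
#' @export
genetic_distance_matrix <- function(pop, cross_id, loci = NULL) {
  stopifnot(inherits(pop, "diallel_pop"))
  row <- pop$design[pop$design$cross_id == cross_id, ]
  if (nrow(row) != 1) abort(sprintf("unknown cross '%s'", cross_id))
  if (is.null(loci)) {
    het <- pop$parents$het
    seg <- het[row$female, ] | het[row$male, ]
    loci <- colnames(het)[seg]
  }
  ids <- pop$individuals$id[pop$individuals$cross_id == cross_id]
  g <- pop$geno[ids, loci, drop = FALSE]
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- genetic_distance(g[i, ], g[j, ])
    }
  }
  d
}

# mean pair distance of a matching given as a 2-column index matrix
matching_objective <- function(d, pairs) {
  mean(d[cbind(pairs[, 1], pairs[, 2])])
}

# one random perfect matching over n slots (n even)
random_matching <- function(n) {
  p <- sample.int(n)
  cbind(p[seq(1, n, by = 2)], p[seq(2, n, by = 2)])
}

# greedy construction: repeatedly pick a random unmatched slot and pair it
# with the farthest unmatched slot
greedy_matching <- function(d) {
  n <- nrow(d)
  unmatched <- seq_len(n)
  pairs <- matrix(0L, n / 2, 2)
  for (k in seq_len(n / 2)) {
    i <- unmatched[sample.int(length(unmatched), 1)]
    rest <- setdiff(unmatched, i)
    j <- rest[which.max(d[i, rest])]
    pairs[k, ] <- c(i, j)
    unmatched <- setdiff(unmatched, c(i, j))
  }
  pairs
}

# 2-exchange hill climbing; returns pairs and the monotone objective trace
improve_matching <- function(d, pairs) {
  obj <- matching_objective(d, pairs)
  trace <- obj
  repeat {
    improved <- FALSE
    np <- nrow(pairs)
    for (a in seq_len(np - 1)) {
      for (b in (a + 1):np) {
        i <- pairs[a, 1]; j <- pairs[a, 2]
        k <- pairs[b, 1]; l <- pairs[b, 2]
        cur <- d[i, j] + d[k, l]
        alt1 <- d[i, k] + d[j, l]
        alt2 <- d[i, l] + d[j, k]
        if (max(alt1, alt2) > cur + 1e-12) {
          if (alt1 >= alt2) {
            pairs[a, ] <- c(i, k); pairs[b, ] <- c(j, l)
          } else {
            pairs[a, ] <- c(i, l); pairs[b, ] <- c(j, k)
          }
          improved <- TRUE
        }
      }
    }
    obj <- matching_objective(d, pairs)
    trace <- c(trace, obj)
    if (!improved) break
  }
  list(pairs = pairs, objective = obj, trace = trace)
}

#' Distant-pair hybridization design
#'
#' Pairs individuals within each cross so that co-hybridized samples are
#' genetically as distant as possible: best of `n_restarts` greedy
#' farthest-neighbour constructions, each refined by 2-exchange hill
#' climbing. Odd cross sizes are handled by profiling one individual (the
#' one with the largest mean distance) on two slides.
#'
#' @param distances symmetric distance matrix (one cross) or a named list of
#'   such matrices (one per cross).
#' @param n_restarts number of greedy restarts.
#' @param seed optional integer seed.
#' @return tibble of class `pairing_plan` with `slide_id`, `cross_id`,
#'   `sample_cy3`, `sample_cy5`; attribute `objective` holds the mean
#'   pairwise distance (overall and per cross).
#' @export
optimize_pairs <- function(distances, n_restarts = 20, seed = NULL) {
  if (is.matrix(distances)) distances <- list(cross = distances)
  if (is.null(names(distances))) names(distances) <- seq_along(distances)
  with_seed(seed, {
    plans <- purrr::imap(distances, function(d, cid) {
      if (!is.matrix(d) || nrow(d) != ncol(d)) abort("distances must be square")
      if (nrow(d) < 2) abort(sprintf("cross '%s' has fewer than 2 individuals", cid))
      ids <- rownames(d) %||% as.character(seq_len(nrow(d)))
      if (nrow(d) %% 2 == 1) {
        # duplicate the most distant individual; forbid self-pairing
        dup <- which.max(rowMeans(d))
        d <- rbind(cbind(d, d[, dup]), c(d[dup, ], 0))
        ids <- c(ids, ids[dup])
      }
      best <- NULL
      for (r in seq_len(n_restarts)) {
        cand <- improve_matching(d, greedy_matching(d))
        if (is.null(best) || cand$objective > best$objective) best <- cand
      }
      tibble(
        cross_id = cid,
        sample_cy3 = ids[best$pairs[, 1]],
        sample_cy5 = ids[best$pairs[, 2]],
        pair_distance = d[best$pairs]
      )
    })
    out <- dplyr::bind_rows(plans) |>
      dplyr::mutate(slide_id = sprintf("s%03d", dplyr::row_number()), .before = 1)
    attr(out, "objective") <- mean(out$pair_distance)
    class(out) <- c("pairing_plan", class(out))
    out
  })
}

#' Improvement of a pairing plan over random pairing
#'
#' `100 * (objective(plan) - mean random objective) / mean random objective`,
#' where the random reference is the mean pair distance of `n_random`
#' uniformly random perfect matchings drawn within each cross.
#'
#' @param plan a `pairing_plan`.
#' @param distances the distance matrix / list used to build the plan.
#' @param n_random number of random matchings.
#' @param seed optional integer seed.
#' @return percent improvement (scalar).
#' @export
improvement_vs_random <- function(plan, distances, n_random = 1000, seed = NULL) {
  if (is.matrix(distances)) distances <- list(cross = distances)
  if (is.null(names(distances))) names(distances) <- seq_along(distances)
  if (all(unlist(distances) == 0)) abort("degenerate distance matrix: all zero")
  check_number(n_random, "n_random", lower = 1)
  with_seed(seed, {
    rand_means <- purrr::map(distances, function(d) {
      n <- nrow(d)
      ids <- rownames(d) %||% as.character(seq_len(n))
      if (n %% 2 == 1) {
        dup <- which.max(rowMeans(d))
        d <- rbind(cbind(d, d[, dup]), c(d[dup, ], 0))
        n <- n + 1
      }
      vapply(seq_len(n_random), function(i) {
        matching_objective(d, random_matching(n))
      }, numeric(1))
    })
    # average over crosses weighted by slides per cross, matching the plan objective
    weights <- vapply(distances, function(d) ceiling(nrow(d) / 2), numeric(1))
    rand_obj <- mean(vapply(
      seq_len(n_random),
      function(i) {
        sum(vapply(seq_along(rand_means), function(c) {
          rand_means[[c]][i] * weights[c]
        }, numeric(1))) / sum(weights)
      },
      numeric(1)
    ))
    obs <- attr(plan, "objective") %||% mean(plan$pair_distance)
    100 * (obs - rand_obj) / rand_obj
  })
}

#' Assign dyes and technical strata to a pairing plan
#'
#' Distributes slides over replicate blocks, fabrication batches and
#' experimenters (round-robin within each cross so crosses are spread over
#' strata), then balances dye orientation deterministically: within every
#' (block, batch, person) stratum the two orientations of each cross differ
#' by at most one slide, and odd strata donate their extra slide so that
#' per-block dye totals also differ by at most one. Slides in odd-sized
#' strata are flagged `unbalanced`.
#'
#' @param plan a `pairing_plan`.
#' @param blocks,batches,persons stratum labels.
#' @param seed unused (assignment is deterministic); kept for call-site
#'   stability.
#' @return the plan with columns `block`, `batch`, `person`, `dye_swapped`,
#'   `unbalanced`; `sample_cy3`/`sample_cy5` reflect the final orientation.
#' @export
assign_dyes <- function(plan, blocks = c("A", "B", "C"),
                        batches = c("b1", "b2"), persons = c("p1", "p2", "p3"),
                        seed = NULL) {
  if (length(blocks) == 0 || length(batches) == 0 || length(persons) == 0) {
    abort("infeasible balance: empty stratum")
  }
  n <- nrow(plan)
  out <- plan |>
    dplyr::group_by(.data$cross_id) |>
    dplyr::mutate(
      block = blocks[((dplyr::row_number() - 1) %% length(blocks)) + 1],
      batch = batches[((dplyr::row_number() - 1) %/% length(blocks)) %% length(batches) + 1],
      person = persons[((dplyr::row_number() - 1) %/% (length(blocks) * length(batches))) %% length(persons) + 1]
    ) |>
    dplyr::ungroup()
  # alternate orientations within each stratum; an odd stratum donates its
  # extra slide to whichever orientation balances the block total, so both
  # the stratum-level and the block-level dye-count differences stay <= 1
  out$dye_swapped <- FALSE
  out$unbalanced <- FALSE
  block_bal <- setNames(rep(0, length(blocks)), blocks)
  key <- paste(out$block, out$batch, out$person, out$cross_id)
  for (k in unique(key)) {
    idx <- which(key == k)
    b <- out$block[idx[1]]
    n_k <- length(idx)
    start_swapped <- n_k %% 2 == 1 && block_bal[b] > 0
    sw <- rep(c(start_swapped, !start_swapped), length.out = n_k)
    out$dye_swapped[idx] <- sw
    out$unbalanced[idx] <- n_k %% 2 == 1
    block_bal[b] <- block_bal[b] + sum(!sw) - sum(sw)
  }
  swapped <- out$dye_swapped
  cy3 <- ifelse(swapped, out$sample_cy5, out$sample_cy3)
  cy5 <- ifelse(swapped, out$sample_cy3, out$sample_cy5)
  out$sample_cy3 <- cy3
  out$sample_cy5 <- cy5
  attr(out, "objective") <- attr(plan, "objective")
  class(out) <- c("pairing_plan", class(out))
  out
}

#' Write a hybridization design as TSV
#'
#' `slide_id  block  batch  person  cy3_sample  cy5_sample` layout.
#'
#' @param plan a `pairing_plan` with strata assigned.
#' @param path file path.
#' @export
write_design <- function(plan, path) {
  plan |>
    dplyr::select(
      "slide_id", "block", "batch", "person",
      cy3_sample = "sample_cy3", cy5_sample = "sample_cy5"
    ) |>
    readr::write_tsv(path)
  invisible(path)
}
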