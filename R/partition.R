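## Homology-aware partitioning: 30% holdout, maximal-k equal-size grouping,
## balanced K-medoids clustering on pairwise E-value distances.

#' Random holdout split
#'
#' Selects `round(fraction * n)` accessions for final validation and keeps
#' them strictly aside from cross-validation.  Deterministic given the seed.
#'
#' @param accessions character vector (n >= 2).
#' @param fraction holdout fraction in (0, 1); default 0.30.
#' @param seed integer seed.
#' @return list with `holdout` and `remainder` accession vectors.
#' @export
holdout_split <- function(accessions, fraction = 0.30, seed = 1L) {
  n <- length(accessions)
  if (n < 2L) stop("need at least 2 accessions to split")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)")
  m <- round(fraction * n)
  idx <- with_seed(seed, sample.int(n, m))
  list(holdout = sort(accessions[idx]), remainder = sort(accessions[-idx]))
}

#' Maximal admissible number of equal-size cross-validation groups
#'
#' Both the positive and the negative remainder must split into k groups of
#' at least `min_size` proteins, and the two sets must share the same k;
#' the largest such k >= 2 is returned.  When no k >= 2 is admissible the
#' term can still be trained but not cross-validated: 1 is returned with a
#' warning.
#'
#' @param n_pos,n_neg remainder sizes after the holdout split.
#' @param min_size minimum group size (default 35).
#' @return integer k.
#' @export
max_k <- function(n_pos, n_neg, min_size = 35) {
  kmax <- min(n_pos %/% min_size, n_neg %/% min_size)
  if (kmax < 2) {
    warning("no k >= 2 satisfies the minimum group size; returning k = 1")
    return(1L)
  }
  as.integer(kmax)
}

.check_distance <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance must be a square matrix")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix is not symmetric")
  if (is.null(rownames(d))) stop("distance matrix needs accession dimnames")
  invisible(d)
}

# greedy capacity-constrained assignment to nearest medoid, visiting points
# in decreasing order of assignment margin (d to second-nearest free medoid
# minus d to nearest); ties broken by accession order.
.assign_balanced <- function(d, medoids, sizes) {
  n <- nrow(d)
  acc <- rownames(d)
  assign <- integer(n)
  left <- sizes
  dm <- d[, medoids, drop = FALSE]         # n x k, fixed for this call
  unas <- order(acc)                       # lexicographic visiting base order
  while (length(unas)) {
    free <- which(left > 0L)
    sub <- dm[unas, free, drop = FALSE]
    nearest <- max.col(-sub, ties.method = "first")
    best <- sub[cbind(seq_along(unas), nearest)]
    second <- if (length(free) > 1L) {
      sub[cbind(seq_along(unas), nearest)] <- Inf
      sub[cbind(seq_along(unas), max.col(-sub, ties.method = "first"))]
    } else best
    pick <- which.max(second - best)       # first max = lexicographic tie-break
    i <- unas[pick]
    g <- free[nearest[pick]]
    assign[i] <- g
    left[g] <- left[g] - 1L
    unas <- unas[-pick]
  }
  assign
}

.update_medoids <- function(d, assign, k) {
  acc <- rownames(d)
  vapply(seq_len(k), function(g) {
    members <- which(assign == g)
    costs <- colSums(d[members, members, drop = FALSE])
    members[order(costs, acc[members])][1]
  }, integer(1))
}

# local swap refinement: accept pairwise swaps between groups that strictly
# reduce total distance-to-medoid.  For each ordered group pair the best
# single swap is found vectorially; passes repeat until no swap improves.
.swap_refine <- function(d, assign, medoids, max_pass = 50L) {
  k <- length(medoids)
  dm <- d[, medoids, drop = FALSE]
  for (pass in seq_len(max_pass)) {
    improved <- FALSE
    for (gi in seq_len(k - 1L)) for (gj in (gi + 1L):k) {
      mi <- which(assign == gi); mj <- which(assign == gj)
      # gain of moving each member to the other group's medoid
      di <- dm[mi, gj] - dm[mi, gi]
      dj <- dm[mj, gi] - dm[mj, gj]
      bi <- which.min(di); bj <- which.min(dj)
      if (di[bi] + dj[bj] < -1e-12) {
        assign[mi[bi]] <- gj
        assign[mj[bj]] <- gi
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  assign
}

#' Equal-size K-medoids clustering
#'
#' Groups accessions into k clusters of near-equal size (sizes differ by at
#' most one; larger groups take the remainder) while minimising
#' within-group distance to the medoid, in the spirit of K-medoids but with
#' a hard balance constraint.  The algorithm seeds medoids
#' farthest-point-style from a seeded random start, assigns points greedily
#' (largest assignment margin first) to the nearest medoid with remaining
#' capacity, then alternates medoid updates, reassignment and pairwise swap
#' refinement until stable (at most 100 iterations).  All tie-breaks are by
#' accession order, so the result is deterministic given the seed.
#'
#' @param d symmetric non-negative distance matrix with accession dimnames.
#' @param k number of groups (1 <= k <= n).
#' @param seed integer seed.
#' @return list of k character vectors (accessions per group), ordered by
#'   group; attribute `medoids` carries the final medoid accessions.
#' @export
balanced_kmedoids <- function(d, k, seed = 1L) {
  .check_distance(d)
  n <- nrow(d)
  acc <- rownames(d)
  if (k < 1 || k > n) stop("k must be between 1 and n")
  if (k == 1L) return(list(sort(acc)))
  if (k == n) return(as.list(sort(acc)))

  sizes <- rep(n %/% k, k)
  if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L

  # farthest-point seeding from a seeded random start
  first <- with_seed(seed, sample.int(n, 1L))
  medoids <- first
  while (length(medoids) < k) {
    dmin <- apply(d[, medoids, drop = FALSE], 1, min)
    dmin[medoids] <- -Inf
    cand <- which(dmin == max(dmin))
    medoids <- c(medoids, cand[order(acc[cand])][1])
  }

  assign <- .assign_balanced(d, medoids, sizes)
  for (iter in seq_len(100L)) {
    new_medoids <- .update_medoids(d, assign, k)
    new_assign <- .assign_balanced(d, new_medoids, sizes)
    new_assign <- .swap_refine(d, new_assign, new_medoids)
    if (identical(new_assign, assign) && identical(new_medoids, medoids)) break
    medoids <- new_medoids
    assign <- new_assign
  }
  groups <- lapply(seq_len(k), function(g) sort(acc[assign == g]))
  groups <- groups[order(vapply(groups, `[`, "", 1))]
  attr(groups, "medoids") <- acc[medoids]
  groups
}

#' Build a partition plan: holdout plus k homology-clustered groups
#'
#' Convenience wrapper combining [holdout_split()] and
#' [balanced_kmedoids()] for one accession set.
#'
#' @param accessions accession vector.
#' @param d full distance matrix (subset internally).
#' @param k group count.
#' @param fraction holdout fraction.
#' @param seed integer seed.
#' @return an `fp_partition`: list `holdout`, `groups`, `k`, `seed`.
#' @export
partition_plan <- function(accessions, d, k, fraction = 0.30, seed = 1L) {
  hs <- holdout_split(accessions, fraction, seed)
  groups <- if (k == 1L) list(hs$remainder)
            else balanced_kmedoids(d[hs$remainder, hs$remainder, drop = FALSE],
                                   k, seed = seed + 1L)
  structure(list(holdout = hs$holdout, groups = groups, k = k, seed = seed),
            class = "fp_partition")
}

#' @export
print.fp_partition <- function(x, ...) {
  cat(sprintf("fp_partition: %d held out, k=%d groups of sizes %s\n",
              length(x$holdout), x$k,
              paste(lengths(x$groups), collapse = "/")))
  invisible(x)
}

#' Pairwise homology distance from an alignment scorer
#'
#' Computes a symmetric distance matrix where `d(i, j)` is the minimum of
#' all E-value-like statistics the aligner reports for the pair, over both
#' orderings, capped at `cap`.  Pairs with no reported alignment (or where
#' the aligner fails) get the cap — the missing-hit convention.  The
#' diagonal is forced to 0.
#'
#' @param sequences named character vector of sequences.
#' @param aligner function `(seq_a, seq_b) -> numeric` returning zero or
#'   more E-values for the ordered pair.
#' @param cap maximum distance (default 10; E-values are unbounded above).
#' @return square distance matrix with accession dimnames and attribute
#'   `metric_note`.
#' @export
pairwise_distance <- function(sequences, aligner, cap = 10) {
  n <- length(sequences)
  acc <- names(sequences)
  if (is.null(acc)) stop("sequences must be named by accession")
  d <- matrix(cap, n, n, dimnames = list(acc, acc))
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ev <- tryCatch(aligner(sequences[[i]], sequences[[j]]),
                   error = function(e) numeric(0))
    if (length(ev)) d[i, j] <- min(min(ev), cap)
  }
  d <- pmin(d, t(d))     # symmetrize by the minimum over both orderings
  d[d < 0] <- 0
  attr(d, "metric_note") <- "min pairwise alignment E-value, capped"
  d
}

#' Write / read a partition plan as TSV (accession, role)
#' @param plan an `fp_partition`.
#' @param path file path.
#' @export
write_partition <- function(plan, path) {
  rows <- rbind(
    data.frame(accession = plan$holdout, role = "holdout"),
    do.call(rbind, lapply(seq_along(plan$groups), function(g)
      data.frame(accession = plan$groups[[g]], role = paste0("group_", g)))))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  gnames <- sort(unique(d$role[d$role != "holdout"]))
  structure(list(holdout = d$accession[d$role == "holdout"],
                 groups = lapply(gnames, function(g) d$accession[d$role == g]),
                 k = length(gnames), seed = NA_integer_),
            class = "fp_partition")
}

#' Write / read a distance matrix as long-format TSV (acc_i, acc_j, d)
#' @param d distance matrix.
#' @param path file path.
#' @export
write_distances <- function(d, path) {
  idx <- which(upper.tri(d), arr.ind = TRUE)
  out <- data.frame(acc_i = rownames(d)[idx[, 1]],
                    acc_j = colnames(d)[idx[, 2]],
                    d = d[idx])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distances
#' @export
read_distances <- function(path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  acc <- sort(unique(c(long$acc_i, long$acc_j)))
  d <- matrix(0, length(acc), length(acc), dimnames = list(acc, acc))
  d[cbind(long$acc_i, long$acc_j)] <- long$d
  d[cbind(long$acc_j, long$acc_i)] <- long$d
  d
}
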