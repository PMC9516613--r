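# De-novo re-derivation of surface clusters: agglomerative clustering of
# the 128 surface columns on correlation distance with Ward linkage,
# used to check that a generating 5-cluster structure is recoverable
# from surface-level data.

#' Binary surface-affection matrix of a cohort
#'
#' @param cohort A validated `caries_cohort`.
#' @param drop_edentulous Drop all-missing subjects (default `TRUE`);
#'   their rows are constant 1 and carry no pattern information.
#' @return Integer 0/1 matrix, subjects x 128 surfaces in canonical
#'   order (1 = decayed, filled, or missing).
#' @export
surface_affection_matrix <- function(cohort, drop_edentulous = TRUE) {
  stopifnot(inherits(cohort, "caries_cohort"), n_subjects(cohort) > 0L)
  m <- matrix(as.integer(cohort$status %in% AFFECTED_STATUSES),
              nrow = nrow(cohort$status),
              dimnames = dimnames(cohort$status))
  if (drop_edentulous) {
    ic <- index_counts(cohort)
    m <- m[!ic$edentulous, , drop = FALSE]
  }
  m
}

#' Derive surface clusters by hierarchical clustering
#'
#' Clusters the 128 surface columns with distance 1 - Pearson
#' correlation and Ward linkage, cutting the tree at `k` clusters.
#' Constant (zero-variance) columns carry no correlation signal and are
#' assigned to the cluster of their nearest non-constant neighbour by
#' Hamming distance.
#'
#' @param matrix A binary surface-affection matrix
#'   (see [surface_affection_matrix()]), at least 2 rows.
#' @param k Number of clusters to cut at (default 5).
#' @return List with elements `map` (a valid [cluster_map()]) and
#'   `tree` (the `hclust` object over the non-constant columns).
#' @export
derive_clusters <- function(matrix, k = 5L) {
  stopifnot(is.matrix(matrix), ncol(matrix) == 128L)
  if (nrow(matrix) < 2L) {
    stop("derive_clusters needs at least 2 subjects", call. = FALSE)
  }
  stopifnot(k >= 1L, k <= 128L)
  keys <- surface_keys()
  colnames(matrix) <- keys

  v <- apply(matrix, 2L, stats::var)
  nonconst <- which(v > 0)
  if (!length(nonconst)) {
    stop("all surface columns are constant; no pattern to cluster",
         call. = FALSE)
  }
  if (k == 1L) {
    return(list(map = cluster_map(setNames(rep(1L, 128L), keys),
                                  name = "derived-k1"),
                tree = NULL))
  }
  if (length(nonconst) < k) {
    stop(sprintf("only %d non-constant surfaces; cannot form %d clusters",
                 length(nonconst), k), call. = FALSE)
  }

  x <- matrix[, nonconst, drop = FALSE]
  d <- stats::as.dist(1 - stats::cor(x))
  tree <- stats::hclust(d, method = "ward.D2")
  lab <- stats::cutree(tree, k = k)

  assignment <- setNames(rep(NA_integer_, 128L), keys)
  assignment[nonconst] <- lab
  const <- setdiff(seq_len(128L), nonconst)
  if (length(const)) {
    for (j in const) {
      ham <- colSums(abs(x - matrix[, j]))
      assignment[j] <- lab[which.min(ham)]
    }
  }
  list(map = cluster_map(assignment, name = sprintf("derived-k%d", k)),
       tree = tree)
}

#' Adjusted Rand index between two surface-cluster maps
#'
#' Chance-corrected agreement between the two partitions of the 128
#' index surfaces: 1 for identical partitions (up to relabeling), about
#' 0 at chance level.
#'
#' @param map_a,map_b `cluster_map` objects over the same surfaces.
#' @return A number in \[-1, 1\].
#' @export
adjusted_rand <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "cluster_map"), inherits(map_b, "cluster_map"))
  if (!setequal(names(map_a$assignment), names(map_b$assignment))) {
    stop("cluster maps cover different surface universes", call. = FALSE)
  }
  keys <- names(map_a$assignment)
  mclust::adjustedRandIndex(map_a$assignment[keys], map_b$assignment[keys])
}
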