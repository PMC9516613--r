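# Tier-3 precision phenotypes: partition of the 128 index surfaces into
# five caries-susceptibility clusters, and per-subject cluster scores
# (affected surfaces in the cluster divided by cluster size).

DEFAULT_CLUSTER_LABELS <- c(
  "1" = "molar pits and fissures",
  "2" = "lower anterior teeth",
  "3" = "molar smooth surfaces, premolar pits, and proximal surfaces",
  "4" = "maxillary incisors",
  "5" = "maxillary canines and premolar smooth surfaces"
)

#' Construct and validate a surface-cluster partition
#'
#' @param assignment Named integer vector: names are the 128 surface keys
#'   (e.g. `"16O"`), values cluster labels `1..k`.
#' @param labels Optional named character vector of descriptive cluster
#'   names, names being the cluster labels as strings.
#' @param name Name of the map.
#' @return Object of class `cluster_map`.
#' @export
cluster_map <- function(assignment, labels = NULL, name = "custom") {
  keys <- surface_keys()
  an <- names(assignment)
  if (is.null(an)) stop("assignment must be named by surface key", call. = FALSE)
  dup <- an[duplicated(an)]
  if (length(dup)) {
    stop("duplicate surface(s) in cluster map: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(keys, an)
  if (length(missing)) {
    stop("missing surface(s) in cluster map: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" ... (%d total)", length(missing)),
         call. = FALSE)
  }
  unknown <- setdiff(an, keys)
  if (length(unknown)) {
    stop("unknown surface(s) in cluster map: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  assignment <- assignment[keys]
  vals <- sort(unique(as.integer(assignment)))
  if (any(is.na(assignment)) || any(!(assignment %in% seq_len(max(vals))))) {
    stop("unknown cluster label(s): ",
         paste(setdiff(unique(assignment), seq_len(max(vals))), collapse = ", "),
         call. = FALSE)
  }
  k <- max(vals)
  empty <- setdiff(seq_len(k), vals)
  if (length(empty)) {
    stop("empty cluster(s): ", paste(empty, collapse = ", "), call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- setNames(paste("cluster", seq_len(k)), as.character(seq_len(k)))
  }
  structure(list(name = name,
                 assignment = setNames(as.integer(assignment), keys),
                 labels = labels, k = k),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat(sprintf("<cluster_map> '%s': %d clusters over 128 index surfaces\n",
              x$name, x$k))
  sz <- cluster_sizes(x)
  for (c in seq_len(x$k)) {
    cat(sprintf("  %d (%d surfaces): %s\n", c, sz[c],
                x$labels[as.character(c)]))
  }
  invisible(x)
}

#' Cluster sizes of a map
#'
#' @param map A `cluster_map`.
#' @return Integer vector of length k (number of surfaces per cluster).
#' @export
cluster_sizes <- function(map) {
  stopifnot(inherits(map, "cluster_map"))
  as.integer(tabulate(map$assignment, nbins = map$k))
}

#' The builtin default five-cluster map
#'
#' A provisional surface-to-cluster assignment constructed from the
#' published cluster names: cluster 1 = molar pits and fissures (molar
#' occlusal plus mandibular-molar buccal and maxillary-molar lingual);
#' cluster 2 = all surfaces of mandibular incisors and canines;
#' cluster 3 = molar smooth (proximal) surfaces plus the maxillary-molar
#' buccal / mandibular-molar lingual surfaces, premolar occlusal and
#' premolar proximal surfaces; cluster 4 = maxillary incisors; cluster 5
#' = maxillary canines and premolar buccal/lingual surfaces.  Cluster
#' sizes are 16, 24, 48, 16, 24.  Any alternative published assignment
#' can be supplied via [read_cluster_map()] without code change.
#'
#' @return A `cluster_map` with five clusters.
#' @export
default_cluster_map <- function() {
  surf <- index_surfaces()
  q <- surf$tooth %/% 10L
  p <- surf$tooth %% 10L
  s <- surf$surface
  molar <- p %in% 6:7
  premolar <- p %in% 4:5
  incisor <- p %in% 1:2
  canine <- p == 3L
  maxi <- q %in% 1:2
  mand <- q %in% 3:4

  lab <- integer(nrow(surf))
  lab[molar & s == "O"] <- 1L
  lab[molar & mand & s == "B"] <- 1L
  lab[molar & maxi & s == "L"] <- 1L
  lab[mand & (incisor | canine)] <- 2L
  lab[molar & s %in% c("M", "D")] <- 3L
  lab[molar & maxi & s == "B"] <- 3L
  lab[molar & mand & s == "L"] <- 3L
  lab[premolar & s %in% c("O", "M", "D")] <- 3L
  lab[maxi & incisor] <- 4L
  lab[maxi & canine] <- 5L
  lab[premolar & s %in% c("B", "L")] <- 5L

  cluster_map(setNames(lab, surf$key), labels = DEFAULT_CLUSTER_LABELS,
              name = "builtin-default")
}

#' Read a cluster map from a 128-row CSV
#'
#' Expected columns: `tooth_fdi,surface,cluster`.
#'
#' @param path CSV path.
#' @param name Name to give the map.
#' @return A validated `cluster_map`.
#' @export
read_cluster_map <- function(path, name = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("tooth_fdi", "surface", "cluster")
  if (!all(needed %in% names(df))) {
    stop("cluster map CSV must have columns ", paste(needed, collapse = ","),
         call. = FALSE)
  }
  cluster_map(setNames(as.integer(df$cluster),
                       paste0(df$tooth_fdi, df$surface)),
              name = name)
}

#' Write a cluster map as CSV
#'
#' @param map A `cluster_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_map <- function(map, path) {
  stopifnot(inherits(map, "cluster_map"))
  surf <- index_surfaces()
  utils::write.csv(
    data.frame(tooth_fdi = surf$tooth, surface = surf$surface,
               cluster = unname(map$assignment[surf$key])),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Score subjects on the surface clusters
#'
#' The score of subject i on cluster c is the number of surfaces in c
#' with status `DECAYED`, `FILLED` or `MISSING_TOOTH`, divided by the
#' fixed cluster size, so each score lies in \[0, 1\] and the weighted sum
#' of scores over clusters recovers the subject's DMFS exactly.
#'
#' @param cohort A validated `caries_cohort`.
#' @param map A `cluster_map` (default: [default_cluster_map()]).
#' @return Numeric matrix, subjects x k, columns `cluster_1..cluster_k`.
#' @export
cluster_scores <- function(cohort, map = default_cluster_map()) {
  stopifnot(inherits(cohort, "caries_cohort"), inherits(map, "cluster_map"))
  aff <- matrix(cohort$status %in% AFFECTED_STATUSES,
                nrow = nrow(cohort$status))
  out <- matrix(NA_real_, nrow = nrow(aff), ncol = map$k,
                dimnames = list(cohort$subjects$subject_id,
                                paste0("cluster_", seq_len(map$k))))
  for (c in seq_len(map$k)) {
    cols <- which(map$assignment == c)
    out[, c] <- rowSums(aff[, cols, drop = FALSE]) / length(cols)
  }
  out
}

#' Summarize a cohort's demographics and caries experience
#'
#' One row shaped like a consortium summary-table entry: n, age, sex,
#' edentulism, remaining teeth, binary case status, the tooth-morbidity
#' indices, and per-cluster mean/SD scores.
#'
#' @param cohort A validated, nonempty `caries_cohort`.
#' @param map A `cluster_map`.
#' @param sd `"population"` (divide by n, default) or `"sample"`.
#' @param cohort_name Name recorded in the output row.
#' @return One-row data frame.
#' @export
summarize_cohort <- function(cohort, map = default_cluster_map(),
                             sd = c("population", "sample"),
                             cohort_name = "cohort") {
  sd <- match.arg(sd)
  if (!inherits(cohort, "caries_cohort") || n_subjects(cohort) == 0L) {
    stop("summarize_cohort needs a nonempty cohort", call. = FALSE)
  }
  sdev <- function(x) {
    if (sd == "sample") stats::sd(x)
    else sqrt(mean((x - mean(x))^2))
  }
  ic <- index_counts(cohort)
  sc <- cluster_scores(cohort, map)
  n <- nrow(ic)
  out <- data.frame(
    cohort = cohort_name,
    n = n,
    age_mean = mean(cohort$subjects$age),
    age_sd = sdev(cohort$subjects$age),
    pct_women = 100 * mean(cohort$subjects$sex == "female"),
    pct_edentulous = 100 * mean(ic$edentulous),
    teeth_mean = mean(ic$n_teeth_present),
    teeth_sd = sdev(ic$n_teeth_present),
    cases = sum(ic$dmfs > 0L),
    pct_cases = 100 * mean(ic$dmfs > 0L),
    dmft_mean = mean(ic$dmft),
    dmft_sd = sdev(ic$dmft),
    dmfs_mean = mean(ic$dmfs),
    dmfs_sd = sdev(ic$dmfs),
    stringsAsFactors = FALSE
  )
  for (c in seq_len(map$k)) {
    out[[sprintf("c%d_mean", c)]] <- mean(sc[, c])
    out[[sprintf("c%d_sd", c)]] <- sdev(sc[, c])
  }
  out
}

#' Plain-text odontogram rendering of a cluster map
#'
#' One glyph (the cluster label) per surface, teeth laid out per arch in
#' anatomical FDI order, for quick visual inspection in documentation.
#'
#' @param map A `cluster_map`.
#' @return Character vector of lines, invisibly printed with `cat()`.
#' @export
render_odontogram <- function(map = default_cluster_map()) {
  stopifnot(inherits(map, "cluster_map"))
  glyph <- function(tooth, surface) {
    key <- paste0(tooth, surface)
    if (surface %in% tooth_surfaces(tooth)) as.character(map$assignment[key])
    else "."
  }
  arch_lines <- function(teeth) {
    hdr <- paste(sprintf(" %2d ", teeth), collapse = " ")
    rows <- vapply(SURFACE_ORDER, function(s) {
      paste(vapply(teeth, function(t) sprintf("  %s ", glyph(t, s)),
                   character(1)), collapse = " ")
    }, character(1))
    c(hdr, paste0(SURFACE_ORDER, " ", substring(rows, 3)))
  }
  upper <- c(17:11, 21:27)
  lower <- c(47:41, 31:37)
  lines <- c(sprintf("cluster map '%s' (glyph = cluster, . = no surface)",
                     map$name),
             "maxilla:", arch_lines(upper),
             "mandible:", arch_lines(lower))
  cat(lines, sep = "\n")
  invisible(lines)
}
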