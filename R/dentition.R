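#' @keywords internal
"_PACKAGE"

# Surface codes in canonical within-tooth order: occlusal first, then
# mesial, distal, buccal/facial, lingual/palatal.
SURFACE_ORDER <- c("O", "M", "D", "B", "L")

STATUS_LEVELS <- c("SOUND", "DECAYED", "FILLED", "MISSING_TOOTH", "EXCLUDED")
AFFECTED_STATUSES <- c("DECAYED", "FILLED", "MISSING_TOOTH")

#' FDI codes of the 28 index teeth
#'
#' The permanent dentition excluding third molars, in canonical order
#' (quadrants 1-4, positions 1-7 within each quadrant).
#'
#' @return Integer vector of length 28 of two-digit FDI codes.
#' @export
index_teeth <- function() {
  as.integer(10L * rep(1:4, each = 7) + rep(1:7, times = 4))
}

#' Is an FDI code a third molar?
#'
#' @param fdi Integer vector of two-digit FDI codes.
#' @return Logical vector.
#' @export
is_third_molar <- function(fdi) {
  (fdi %/% 10L) %in% 1:4 & fdi %% 10L == 8L
}

is_index_tooth <- function(fdi) {
  (fdi %/% 10L) %in% 1:4 & (fdi %% 10L) %in% 1:7
}

#' Scorable surfaces of one tooth
#'
#' Anterior teeth (positions 1-3) carry the four surfaces M, D, B, L;
#' posterior teeth (positions 4-7) additionally carry the occlusal
#' surface O.  Incisal edges are not treated as separate surfaces, which
#' fixes the DMFS surface universe at 12 x 4 + 16 x 5 = 128.
#'
#' @param fdi A single two-digit FDI code of an index tooth.
#' @return Character vector of surface codes in canonical order.
#' @export
tooth_surfaces <- function(fdi) {
  stopifnot(length(fdi) == 1L, is_index_tooth(fdi))
  if (fdi %% 10L >= 4L) SURFACE_ORDER else c("M", "D", "B", "L")
}

#' Map Universal (1-32) tooth numbering to FDI
#'
#' @param universal Integer vector of Universal tooth numbers (1-32).
#' @return Integer vector of FDI codes (third molars map to 18/28/38/48).
#' @export
universal_to_fdi <- function(universal) {
  if (any(!(universal %in% 1:32))) {
    stop("Universal tooth numbers must be integers in 1..32", call. = FALSE)
  }
  # Universal counts 1..16 across the maxilla from the upper-right third
  # molar, then 17..32 back across the mandible from the lower-left.
  map <- c(
    18:11, 21:28,  # 1..16
    38:31, 41:48   # 17..32
  )
  as.integer(map[universal])
}

.surface_universe <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      teeth <- index_teeth()
      rows <- lapply(teeth, function(t) {
        data.frame(tooth = t, surface = tooth_surfaces(t),
                   stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, rows)
      df$key <- paste0(df$tooth, df$surface)
      cache <<- df
    }
    cache
  }
})

#' Enumerate the 128 index tooth surfaces
#'
#' Deterministic, stable ordering: by FDI code, then surface code in the
#' order O, M, D, B, L.  Third molars never appear.
#'
#' @return Data frame with columns `tooth` (FDI integer), `surface`
#'   (surface code) and `key` (e.g. `"16O"`), 128 rows.
#' @export
index_surfaces <- function() {
  .surface_universe()
}

surface_keys <- function() .surface_universe()$key

#' Construct a cohort of surface-level caries records
#'
#' The central container: per-subject demographics plus a subjects x 128
#' status matrix over the canonical surface universe.
#'
#' @param subjects Data frame with columns `subject_id`, `age`, `sex`.
#' @param status Character matrix, one row per subject, 128 columns named
#'   by surface key, entries among `SOUND`, `DECAYED`, `FILLED`,
#'   `MISSING_TOOTH`, `EXCLUDED` (or `NA` for not-yet-covered surfaces).
#' @return An object of class `caries_cohort`.
#' @export
caries_cohort <- function(subjects, status) {
  stopifnot(is.data.frame(subjects),
            all(c("subject_id", "age", "sex") %in% names(subjects)),
            is.matrix(status),
            nrow(status) == nrow(subjects))
  keys <- surface_keys()
  if (is.null(colnames(status)) || !identical(colnames(status), keys)) {
    if (!setequal(colnames(status), keys)) {
      stop("status matrix columns must be the 128 index surface keys",
           call. = FALSE)
    }
    status <- status[, keys, drop = FALSE]
  }
  bad <- !(status %in% STATUS_LEVELS | is.na(status))
  if (any(bad)) {
    stop("invalid surface status value(s): ",
         paste(unique(status[bad]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(subjects$subject_id)) {
    stop("duplicated subject_id in cohort", call. = FALSE)
  }
  rownames(status) <- subjects$subject_id
  structure(list(subjects = subjects, status = status),
            class = "caries_cohort")
}

#' @export
print.caries_cohort <- function(x, ...) {
  cat(sprintf("<caries_cohort> %d subjects x 128 index surfaces\n",
              nrow(x$subjects)))
  cat(sprintf("  age: %s   sex: %s\n",
              paste(range(x$subjects$age, na.rm = TRUE), collapse = "-"),
              paste(names(table(x$subjects$sex)), collapse = "/")))
  tab <- table(factor(x$status, levels = STATUS_LEVELS))
  cat("  surface statuses:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.caries_cohort <- function(x) dim(x$status)

n_subjects <- function(cohort) nrow(cohort$status)

#' Build a single-subject record
#'
#' Convenience constructor used throughout the tests and examples: all
#' 128 surfaces start at `default`, individual surfaces are overridden by
#' the named `statuses` vector, and whole teeth can be marked missing.
#'
#' @param subject_id Subject identifier.
#' @param age Age in years.
#' @param sex `"female"`, `"male"` or `"unknown"`.
#' @param statuses Named character vector, names are surface keys such as
#'   `"16O"`, values are status tokens.
#' @param missing_teeth Integer vector of FDI codes to mark entirely
#'   `MISSING_TOOTH`.
#' @param default Status assigned to all surfaces not otherwise set.
#' @return A one-subject `caries_cohort`.
#' @export
subject_record <- function(subject_id, age = NA_real_, sex = "unknown",
                           statuses = character(), missing_teeth = integer(),
                           default = "SOUND") {
  keys <- surface_keys()
  st <- matrix(default, nrow = 1L, ncol = length(keys),
               dimnames = list(subject_id, keys))
  if (length(statuses)) {
    unknown <- setdiff(names(statuses), keys)
    if (length(unknown)) {
      stop("unknown surface key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    st[1L, names(statuses)] <- statuses
  }
  for (t in missing_teeth) {
    st[1L, paste0(t, tooth_surfaces(t))] <- "MISSING_TOOTH"
  }
  caries_cohort(
    data.frame(subject_id = subject_id, age = age, sex = sex,
               stringsAsFactors = FALSE),
    st
  )
}

#' Combine cohorts row-wise
#'
#' @param ... `caries_cohort` objects with disjoint subject ids.
#' @return A single `caries_cohort`.
#' @export
bind_cohorts <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "caries_cohort")) {
    parts <- parts[[1]]
  }
  stopifnot(all(vapply(parts, inherits, logical(1), "caries_cohort")))
  caries_cohort(
    do.call(rbind, lapply(parts, `[[`, "subjects")),
    do.call(rbind, lapply(parts, `[[`, "status"))
  )
}

#' Validate surface records against the odontogram invariants
#'
#' Violations are returned as data, not thrown: one row per problem with
#' the subject, tooth, surface and a human-readable message.  Checks the
#' full-coverage invariant (no `NA` entries), status vocabulary, and the
#' whole-tooth consistency of `MISSING_TOOTH`.
#'
#' @param cohort A `caries_cohort`.
#' @return Data frame with columns `subject_id`, `tooth`, `surface`,
#'   `violation`; zero rows when every invariant holds.
#' @export
validate_records <- function(cohort) {
  stopifnot(inherits(cohort, "caries_cohort"))
  surf <- index_surfaces()
  st <- cohort$status
  out <- list()
  add <- function(subject_id, tooth, surface, violation) {
    out[[length(out) + 1L]] <<- data.frame(
      subject_id = subject_id, tooth = tooth, surface = surface,
      violation = violation, stringsAsFactors = FALSE)
  }
  na_idx <- which(is.na(st), arr.ind = TRUE)
  if (nrow(na_idx)) {
    for (i in seq_len(nrow(na_idx))) {
      add(rownames(st)[na_idx[i, 1L]],
          surf$tooth[na_idx[i, 2L]], surf$surface[na_idx[i, 2L]],
          "uncovered surface")
    }
  }
  for (t in index_teeth()) {
    cols <- which(surf$tooth == t)
    sub <- st[, cols, drop = FALSE]
    n_miss <- rowSums(sub == "MISSING_TOOTH", na.rm = TRUE)
    partial <- which(n_miss > 0L & n_miss < length(cols))
    for (i in partial) {
      not_missing <- cols[which(sub[i, ] != "MISSING_TOOTH")]
      for (j in not_missing) {
        add(rownames(st)[i], surf$tooth[j], surf$surface[j],
            "partial missing tooth")
      }
    }
  }
  if (!length(out)) {
    return(data.frame(subject_id = character(), tooth = integer(),
                      surface = character(), violation = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
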