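# Long-format surface CSV dialect:
#   subject_id,age,sex,tooth_fdi,surface,status
# with status either a token (SOUND/DECAYED/FILLED/MISSING/EXCLUDED) or
# an integer ICDAS score 0-6, thresholded at ingestion.

STATUS_TOKENS <- c(SOUND = "SOUND", DECAYED = "DECAYED", FILLED = "FILLED",
                   MISSING = "MISSING_TOOTH", EXCLUDED = "EXCLUDED")

#' Read a long-format surface-level caries CSV
#'
#' Ingests per-subject, per-tooth-surface examination records and returns
#' a fully populated [caries_cohort()].  ICDAS severity scores are
#' harmonized to binary decay at `icdas_threshold` (default: the moderate
#' lesion threshold, ICDAS >= 3).  Third-molar rows are accepted but
#' dropped with a message, since third molars contribute to no index.
#' A `MISSING` row propagates to every surface of its tooth.
#'
#' @param path Path to the CSV file.
#' @param icdas_threshold Integer in 1..6; ICDAS scores at or above it
#'   become `DECAYED`, below it `SOUND`.
#' @param unlisted_policy What to do with index surfaces that have no row:
#'   `"error"` (default, forces cohorts to be explicit), `"sound"`, or
#'   `"excluded"`.
#' @param tooth_numbering `"fdi"` (default) or `"universal"`; with
#'   `"universal"` the `tooth_fdi` column is interpreted as Universal
#'   1-32 numbering and converted.
#' @return A validated `caries_cohort`.
#' @export
read_surface_csv <- function(path,
                             icdas_threshold = 3L,
                             unlisted_policy = c("error", "sound", "excluded"),
                             tooth_numbering = c("fdi", "universal")) {
  unlisted_policy <- match.arg(unlisted_policy)
  tooth_numbering <- match.arg(tooth_numbering)
  stopifnot(length(icdas_threshold) == 1L, icdas_threshold %in% 1:6)

  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  needed <- c("subject_id", "age", "sex", "tooth_fdi", "surface", "status")
  if (!all(needed %in% names(raw))) {
    stop("surface CSV must have columns ", paste(needed, collapse = ","),
         call. = FALSE)
  }
  if (!nrow(raw)) stop("surface CSV has no data rows", call. = FALSE)

  errors <- character()
  err <- function(...) errors <<- c(errors, sprintf(...))

  tooth <- suppressWarnings(as.integer(raw$tooth_fdi))
  if (tooth_numbering == "universal") {
    bad <- is.na(tooth) | !(tooth %in% 1:32)
    if (any(bad)) {
      for (i in which(bad)) {
        err("subject %s: malformed Universal tooth number '%s'",
            raw$subject_id[i], raw$tooth_fdi[i])
      }
    }
    tooth[!bad] <- universal_to_fdi(tooth[!bad])
  }
  bad_fdi <- is.na(tooth) | !(is_index_tooth(tooth) | is_third_molar(tooth))
  for (i in which(bad_fdi)) {
    err("subject %s: malformed FDI code '%s'",
        raw$subject_id[i], raw$tooth_fdi[i])
  }

  third <- !bad_fdi & is_third_molar(tooth)
  n_third <- sum(third)
  if (n_third > 0L) {
    message(sprintf("read_surface_csv: dropped %d third-molar row(s)",
                    n_third))
  }
  keep <- !bad_fdi & !third

  # resolve statuses: token or ICDAS integer
  resolve_status <- function(s) {
    s <- trimws(s)
    if (s %in% names(STATUS_TOKENS)) return(unname(STATUS_TOKENS[s]))
    if (grepl("^[0-6]$", s)) {
      return(if (as.integer(s) >= icdas_threshold) "DECAYED" else "SOUND")
    }
    NA_character_
  }
  status <- vapply(raw$status, resolve_status, character(1), USE.NAMES = FALSE)
  for (i in which(keep & is.na(status))) {
    err("subject %s tooth %s surface %s: unrecognized status '%s'",
        raw$subject_id[i], raw$tooth_fdi[i], raw$surface[i], raw$status[i])
  }

  # surface validity per tooth
  surf_ok <- rep(TRUE, nrow(raw))
  for (i in which(keep)) {
    if (!(raw$surface[i] %in% tooth_surfaces(tooth[i]))) {
      surf_ok[i] <- FALSE
      err("subject %s tooth %d: surface '%s' is not valid for this tooth",
          raw$subject_id[i], tooth[i], raw$surface[i])
    }
  }
  keep <- keep & surf_ok & !is.na(status)

  keys <- surface_keys()
  ids <- unique(raw$subject_id)
  st <- matrix(NA_character_, nrow = length(ids), ncol = length(keys),
               dimnames = list(ids, keys))
  for (i in which(keep)) {
    id <- raw$subject_id[i]
    key <- paste0(tooth[i], raw$surface[i])
    prev <- st[id, key]
    if (!is.na(prev) && prev != status[i]) {
      err("subject %s tooth %d surface %s: conflicting statuses %s vs %s",
          id, tooth[i], raw$surface[i], prev, status[i])
    } else {
      st[id, key] <- status[i]
    }
  }

  # propagate MISSING_TOOTH across each tooth, flagging partial listings
  surf <- index_surfaces()
  for (t in index_teeth()) {
    cols <- which(surf$tooth == t)
    sub <- st[, cols, drop = FALSE]
    has_missing <- rowSums(sub == "MISSING_TOOTH", na.rm = TRUE) > 0L
    for (r in which(has_missing)) {
      other <- sub[r, ]
      conflict <- which(!is.na(other) & other != "MISSING_TOOTH")
      if (length(conflict)) {
        err("subject %s tooth %d: MISSING on only part of the tooth (%s)",
            ids[r], t, paste(surf$surface[cols[conflict]], collapse = ","))
      } else {
        st[r, cols] <- "MISSING_TOOTH"
      }
    }
  }

  uncovered <- is.na(st)
  if (any(uncovered)) {
    if (unlisted_policy == "error") {
      idx <- which(uncovered, arr.ind = TRUE)
      shown <- head(seq_len(nrow(idx)), 10L)
      for (i in shown) {
        err("subject %s tooth %d surface %s: no status listed",
            ids[idx[i, 1L]], surf$tooth[idx[i, 2L]], surf$surface[idx[i, 2L]])
      }
      if (nrow(idx) > 10L) {
        err("... and %d more unlisted surfaces", nrow(idx) - 10L)
      }
    } else {
      fill <- if (unlisted_policy == "sound") "SOUND" else "EXCLUDED"
      st[uncovered] <- fill
    }
  }

  if (length(errors)) {
    stop("surface CSV validation failed:\n  ",
         paste(errors, collapse = "\n  "), call. = FALSE)
  }

  first <- !duplicated(raw$subject_id)
  subjects <- data.frame(
    subject_id = raw$subject_id[first],
    age = suppressWarnings(as.numeric(raw$age[first])),
    sex = raw$sex[first],
    stringsAsFactors = FALSE
  )
  subjects <- subjects[match(ids, subjects$subject_id), , drop = FALSE]
  rownames(subjects) <- NULL
  caries_cohort(subjects, st)
}

#' Write a cohort back to the long-format surface CSV dialect
#'
#' Emits one row per subject per index surface, in deterministic order
#' (subject as loaded, then tooth, then canonical surface order), using
#' the same dialect [read_surface_csv()] ingests, so that a write/read
#' round trip is the identity on validated records.
#'
#' @param cohort A `caries_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_surface_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "caries_cohort"))
  surf <- index_surfaces()
  n <- n_subjects(cohort)
  tokens <- setNames(names(STATUS_TOKENS), STATUS_TOKENS)
  df <- data.frame(
    subject_id = rep(cohort$subjects$subject_id, each = nrow(surf)),
    age = rep(cohort$subjects$age, each = nrow(surf)),
    sex = rep(cohort$subjects$sex, each = nrow(surf)),
    tooth_fdi = rep(surf$tooth, times = n),
    surface = rep(surf$surface, times = n),
    status = tokens[as.vector(t(cohort$status))],
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
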