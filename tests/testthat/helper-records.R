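# Programmatic fixtures: random but invariant-respecting cohorts, and a
# writer for tiny long-format surface CSVs used by the loader tests.

# Random cohort with whole-tooth missingness and a mix of statuses.
random_cohort <- function(n, seed,
                          p_tooth_missing = 0.08,
                          status_probs = c(SOUND = 0.60, DECAYED = 0.15,
                                           FILLED = 0.20, EXCLUDED = 0.05)) {
  set.seed(seed)
  surf <- index_surfaces()
  keys <- surf$key
  st <- matrix(
    sample(names(status_probs), n * 128L, replace = TRUE,
           prob = status_probs),
    nrow = n, dimnames = list(sprintf("r%04d", seq_len(n)), keys))
  miss <- matrix(runif(n * 28L) < p_tooth_missing, nrow = n)
  tooth_idx <- match(surf$tooth, index_teeth())
  st[miss[, tooth_idx, drop = FALSE]] <- "MISSING_TOOTH"
  caries_cohort(
    data.frame(subject_id = rownames(st),
               age = round(runif(n, 18, 90), 1),
               sex = sample(c("female", "male"), n, replace = TRUE),
               stringsAsFactors = FALSE),
    st)
}

edentulous_record <- function(id = "edent", age = 80, sex = "female") {
  subject_record(id, age = age, sex = sex, missing_teeth = index_teeth())
}

# Write a long-format surface CSV from a data frame of rows.
write_rows_csv <- function(rows) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}

# A complete one-subject listing (all 128 surfaces SOUND) to overlay
# specific rows onto.
full_sound_rows <- function(id = "s1", age = 40, sex = "female") {
  surf <- index_surfaces()
  data.frame(subject_id = id, age = age, sex = sex,
             tooth_fdi = surf$tooth, surface = surf$surface,
             status = "SOUND", stringsAsFactors = FALSE)
}
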