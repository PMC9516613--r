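# Tier-1 (binary case status) and tier-2 (severity) phenotypes.
#
# Teeth missing due to ALL causes count in the M component, giving the
# tooth-morbidity indices DMFS (0-128) and DMFT (0-28).  EXCLUDED
# surfaces contribute nothing and the denominators stay fixed at 128/28.

#' Per-subject decayed/missing/filled index counts
#'
#' Computes surface- and tooth-level components of the tooth-morbidity
#' indices.  A `MISSING_TOOTH` tooth contributes all of its 4 or 5
#' surfaces to the surface M component and one tooth to the tooth M
#' component.  For the tooth-level classification a tooth counts at most
#' once, with precedence MISSING > DECAYED > FILLED.
#'
#' @param cohort A validated `caries_cohort`.
#' @return Data frame, one row per subject: `subject_id`, `d_surfaces`,
#'   `f_surfaces`, `m_surfaces`, `d_teeth`, `f_teeth`, `m_teeth`,
#'   `dmfs`, `dmft`, `n_teeth_present`, `edentulous`.
#' @export
index_counts <- function(cohort) {
  stopifnot(inherits(cohort, "caries_cohort"))
  st <- cohort$status
  surf <- index_surfaces()
  n <- nrow(st)

  d_s <- rowSums(st == "DECAYED")
  f_s <- rowSums(st == "FILLED")
  m_s <- rowSums(st == "MISSING_TOOTH")

  d_t <- f_t <- m_t <- integer(n)
  for (t in index_teeth()) {
    cols <- which(surf$tooth == t)
    sub <- st[, cols, drop = FALSE]
    miss <- rowSums(sub == "MISSING_TOOTH") > 0L
    dec <- !miss & rowSums(sub == "DECAYED") > 0L
    fil <- !miss & !dec & rowSums(sub == "FILLED") > 0L
    m_t <- m_t + miss
    d_t <- d_t + dec
    f_t <- f_t + fil
  }

  data.frame(
    subject_id = cohort$subjects$subject_id,
    d_surfaces = as.integer(d_s),
    f_surfaces = as.integer(f_s),
    m_surfaces = as.integer(m_s),
    d_teeth = as.integer(d_t),
    f_teeth = as.integer(f_t),
    m_teeth = as.integer(m_t),
    dmfs = as.integer(d_s + f_s + m_s),
    dmft = as.integer(d_t + f_t + m_t),
    n_teeth_present = as.integer(28L - m_t),
    edentulous = m_t == 28L,
    stringsAsFactors = FALSE
  )
}

#' Binary caries case status
#'
#' A subject is a case when the corresponding tooth-morbidity index
#' exceeds zero (one or more decayed, missing or filled teeth/surfaces).
#'
#' @param cohort A validated `caries_cohort`.
#' @param level `"surface"` (DMFS > 0, default) or `"tooth"` (DMFT > 0).
#' @return Logical vector, one entry per subject.
#' @export
case_status <- function(cohort, level = c("surface", "tooth")) {
  level <- match.arg(level)
  ic <- index_counts(cohort)
  if (level == "surface") ic$dmfs > 0L else ic$dmft > 0L
}

#' Per-subject phenotype table across all three tiers' person-level traits
#'
#' @param cohort A validated `caries_cohort`.
#' @return Data frame `subject_id, age, sex, case_status, dmft, dmfs,
#'   d_surf, f_surf, m_surf, n_teeth, edentulous`.
#' @export
phenotype_table <- function(cohort) {
  ic <- index_counts(cohort)
  data.frame(
    subject_id = ic$subject_id,
    age = cohort$subjects$age,
    sex = cohort$subjects$sex,
    case_status = ic$dmfs > 0L,
    dmft = ic$dmft,
    dmfs = ic$dmfs,
    d_surf = ic$d_surfaces,
    f_surf = ic$f_surfaces,
    m_surf = ic$m_surfaces,
    n_teeth = ic$n_teeth_present,
    edentulous = ic$edentulous,
    stringsAsFactors = FALSE
  )
}
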