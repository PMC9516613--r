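# Consortium cohort registry: one denormalized row per cohort with
# trait-availability flags and optional printed summary statistics,
# plus the roll-up operations (tier totals, pooled caries-free
# fraction, target-sample coverage).

REGISTRY_REQUIRED <- c("cohort", "region", "n",
                       "prevalence", "severity", "patterns")
REGISTRY_OPTIONAL <- c(
  "notes", "age_mean", "age_sd", "pct_women", "pct_edentulous",
  "teeth_mean", "teeth_sd", "cases", "pct_cases",
  "dmft_mean", "dmft_sd", "dmfs_mean", "dmfs_sd",
  paste0(rep(paste0("c", 1:5), each = 2), c("_mean", "_sd"))
)

#' Load a cohort registry CSV
#'
#' Parses the denormalized one-row-per-cohort schema.  Sample sizes may
#' be printed with thousands separators and a leading `~` for
#' approximate counts; `~` is stripped and recorded in the
#' `n_approximate` flag.  Tier-availability columns parse to logicals.
#' Unknown columns are rejected by name.
#'
#' @param path CSV with columns `cohort,region,n,prevalence,severity,
#'   patterns` plus optional summary columns (`cases`, `age_mean`, ...).
#' @return Data frame of cohort entries with `n` integer and an added
#'   `n_approximate` logical column.
#' @export
read_cohort_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!nrow(df)) stop("registry file has no cohort rows", call. = FALSE)
  missing <- setdiff(REGISTRY_REQUIRED, names(df))
  if (length(missing)) {
    stop("registry is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(df), c(REGISTRY_REQUIRED, REGISTRY_OPTIONAL))
  if (length(unknown)) {
    stop("registry has unknown column(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  raw_n <- trimws(df$n)
  approx <- startsWith(raw_n, "~")
  digits <- gsub("[~,]", "", raw_n)
  bad <- !grepl("^[0-9]+$", digits)
  if (any(bad)) {
    stop("non-numeric n for cohort(s): ",
         paste(df$cohort[bad], collapse = ", "), call. = FALSE)
  }
  df$n <- as.integer(digits)
  df$n_approximate <- approx

  to_flag <- function(x) {
    x <- tolower(trimws(x))
    out <- x %in% c("1", "true", "yes", "y")
    bad <- !(x %in% c("1", "true", "yes", "y", "0", "false", "no", "n", ""))
    if (any(bad)) stop("unparseable availability flag: ",
                       paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    out
  }
  for (col in c("prevalence", "severity", "patterns")) {
    df[[col]] <- to_flag(df[[col]])
  }
  for (col in intersect(REGISTRY_OPTIONAL, names(df))) {
    if (col == "notes") next
    df[[col]] <- suppressWarnings(as.numeric(gsub(",", "", df[[col]])))
  }
  if ("cases" %in% names(df)) {
    over <- !is.na(df$cases) & df$cases > df$n
    if (any(over)) {
      stop("case count exceeds n for cohort(s): ",
           paste(df$cohort[over], collapse = ", "), call. = FALSE)
    }
  }
  df
}

#' Total consortium sample size by phenotype tier
#'
#' @param registry Data frame from [read_cohort_registry()].
#' @param tier `"all"` (default), `"prevalence"`, `"severity"` or
#'   `"patterns"`: sum `n` over cohorts with that trait available.
#' @return Integer total (0 for an empty selection).
#' @export
total_n <- function(registry, tier = c("all", "prevalence", "severity",
                                       "patterns")) {
  tier <- match.arg(tier)
  sel <- if (tier == "all") rep(TRUE, nrow(registry)) else registry[[tier]]
  sum(registry$n[sel])
}

#' Pooled caries-free count and percentage
#'
#' Across cohorts that report a binary case count, the number and
#' percentage of participants with no caries experience
#' (count = sum of n - cases; percent = 100 * count / sum of n).
#'
#' @param registry Data frame including a numeric `cases` column.
#' @return List with `count` (integer) and `percent` (numeric).
#' @export
pooled_caries_free <- function(registry) {
  if (!("cases" %in% names(registry)) || any(is.na(registry$cases))) {
    stop("every selected cohort must report a case count", call. = FALSE)
  }
  count <- sum(registry$n - registry$cases)
  list(count = as.integer(count),
       percent = 100 * count / sum(registry$n))
}

#' Coverage of the target analytic sample
#'
#' @param current_n Currently contributed sample size.
#' @param target_n Maximum target sample size (> 0).
#' @return Percent, `100 * current_n / target_n`.
#' @export
coverage_fraction <- function(current_n, target_n) {
  if (target_n <= 0) stop("target_n must be positive", call. = FALSE)
  100 * current_n / target_n
}

#' Per-cohort caries prevalence recomputed from counts
#'
#' @param registry Data frame with `cases` and `n`.
#' @return Numeric vector of percentages, named by cohort.
#' @export
cohort_prevalence <- function(registry) {
  if (!("cases" %in% names(registry))) {
    stop("registry has no case counts", call. = FALSE)
  }
  setNames(100 * registry$cases / registry$n, registry$cohort)
}

#' Path to a bundled registry fixture
#'
#' Two fixtures ship with the package: `"cohort_registry"` (the 21
#' consortium cohorts with tier-availability flags) and
#' `"cohort_summaries"` (the 8 cohorts contributing surface-level
#' caries-pattern data, with full printed summary statistics).
#'
#' @param which `"cohort_registry"` or `"cohort_summaries"`.
#' @return File path.
#' @export
registry_fixture <- function(which = c("cohort_registry",
                                       "cohort_summaries")) {
  which <- match.arg(which)
  system.file("extdata", paste0(which, ".csv"), package = "cariesharm",
              mustWork = TRUE)
}
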