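# Synthetic surface-level cohorts with the statistical structure the
# downstream analyses assume: cluster-specific susceptibility, a shared
# age effect, a person-level frailty (normal random intercept shared
# between the caries and tooth-loss processes), and all-cause per-tooth
# loss.  Every draw is governed by the params seed, so equal params give
# bit-identical cohorts.

#' Parameters of a synthetic surface-level cohort
#'
#' Defaults describe a middle-aged adult screening cohort: mean age 50
#' (SD 15, truncated to 18-100), even sex split, per-surface baseline
#' log-odds by cluster chosen so that at age 50 the five cluster
#' affection probabilities are roughly 0.55, 0.07, 0.40, 0.25 and 0.24
#' (molar pits-and-fissures most susceptible, lower anterior teeth
#' least), a shared age slope of 0.035 log-odds per year, frailty SD
#' 1.5, and an all-cause tooth-loss process giving roughly 10% missing
#' teeth at age 50 rising with age.
#'
#' @param n Number of subjects (>= 1).
#' @param age_mean,age_sd Age distribution in years, truncated to
#'   \[18, 100\].
#' @param pct_female Percent female in \[0, 100\].
#' @param cluster_logits Numeric vector, one per cluster of
#'   `map`: per-surface baseline log-odds of affection by cluster.
#' @param age_slope Shared log-odds change per year of age.
#' @param frailty_sd SD (>= 0) of the person-level normal random
#'   intercept shared by the caries and tooth-loss processes.
#' @param tooth_loss_intercept,tooth_loss_age_slope Log-odds intercept
#'   and per-year slope of per-tooth all-cause missingness (use a large
#'   negative intercept such as -50 to disable tooth loss).
#' @param map Generating `cluster_map` (default builtin).
#' @param seed Integer RNG seed.
#' @param cohort Cohort name.
#' @return Object of class `cohort_params`.
#' @export
cohort_params <- function(n = 500L,
                          age_mean = 50, age_sd = 15,
                          pct_female = 50,
                          cluster_logits = c(-1.55, -4.35, -2.15,
                                             -2.85, -2.90),
                          age_slope = 0.035,
                          frailty_sd = 1.5,
                          tooth_loss_intercept = -3.05,
                          tooth_loss_age_slope = 0.017,
                          map = default_cluster_map(),
                          seed = 1L,
                          cohort = "synthetic") {
  stopifnot(n >= 1L, age_sd >= 0, pct_female >= 0, pct_female <= 100,
            frailty_sd >= 0, inherits(map, "cluster_map"),
            length(cluster_logits) == map$k)
  structure(list(n = as.integer(n), age_mean = age_mean, age_sd = age_sd,
                 pct_female = pct_female, cluster_logits = cluster_logits,
                 age_slope = age_slope, frailty_sd = frailty_sd,
                 tooth_loss_intercept = tooth_loss_intercept,
                 tooth_loss_age_slope = tooth_loss_age_slope,
                 map = map, seed = as.integer(seed), cohort = cohort),
            class = "cohort_params")
}

rtrunc_norm <- function(n, mean, sd, lower = 18, upper = 100) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic surface-level cohort
#'
#' For subject i: draw age, sex and frailty `u_i ~ N(0, sigma^2)`; each
#' tooth goes missing with probability
#' `plogis(m0 + m1 * age_i + u_i)`; each surface of a remaining tooth,
#' belonging to cluster c, is affected with probability
#' `plogis(a_c + b * age_i + u_i)`, split 50/50 between `DECAYED` and
#' `FILLED`.  Identical params (including seed) give bit-identical
#' cohorts.
#'
#' @param params A [cohort_params()] object.
#' @return List with `cohort` (a `caries_cohort`) and `truth` (the
#'   generating parameters echoed back).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(params$seed)

  n <- params$n
  surf <- index_surfaces()
  keys <- surf$key
  cl <- params$map$assignment[keys]

  age <- rtrunc_norm(n, params$age_mean, params$age_sd)
  sex <- ifelse(stats::runif(n) < params$pct_female / 100,
                "female", "male")
  u <- stats::rnorm(n, 0, params$frailty_sd)

  # per-tooth all-cause missingness
  p_miss <- stats::plogis(params$tooth_loss_intercept +
                            params$tooth_loss_age_slope * age + u)
  miss_tooth <- matrix(stats::runif(n * 28L) < p_miss, nrow = n)

  # per-surface affection: a_c + b*age + u on the logit scale
  lin <- outer(params$age_slope * age + u, rep(1, 128L)) +
    matrix(params$cluster_logits[cl], nrow = n, ncol = 128L, byrow = TRUE)
  affected <- matrix(stats::runif(n * 128L), nrow = n) < stats::plogis(lin)
  decayed <- matrix(stats::runif(n * 128L), nrow = n) < 0.5

  st <- matrix("SOUND", nrow = n, ncol = 128L)
  st[affected & decayed] <- "DECAYED"
  st[affected & !decayed] <- "FILLED"
  tooth_idx <- match(surf$tooth, index_teeth())
  st[miss_tooth[, tooth_idx, drop = FALSE]] <- "MISSING_TOOTH"
  colnames(st) <- keys

  ids <- sprintf("%s_%05d", params$cohort, seq_len(n))
  rownames(st) <- ids
  cohort <- caries_cohort(
    data.frame(subject_id = ids, age = age, sex = sex,
               stringsAsFactors = FALSE),
    st)
  list(cohort = cohort, truth = params)
}

#' Generate an independent multi-cohort consortium
#'
#' Each cohort is generated independently; when `master_seed` is given,
#' per-cohort seeds are derived from it deterministically (so the whole
#' consortium is reproducible from one integer).
#'
#' @param param_list Nonempty list of [cohort_params()] objects.
#' @param master_seed Optional integer; overrides each cohort's seed
#'   with one drawn deterministically from this master seed.
#' @return List of `list(cohort, truth)` elements, one per cohort.
#' @export
generate_consortium <- function(param_list, master_seed = NULL) {
  if (!length(param_list)) {
    stop("generate_consortium needs at least one cohort", call. = FALSE)
  }
  stopifnot(all(vapply(param_list, inherits, logical(1), "cohort_params")))
  if (!is.null(master_seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    set.seed(master_seed)
    seeds <- sample.int(.Machine$integer.max - 1L, length(param_list))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    for (i in seq_along(param_list)) param_list[[i]]$seed <- seeds[i]
  }
  lapply(param_list, generate_cohort)
}

#' Default eight-cohort consortium design
#'
#' A desk-scale stand-in for a multi-cohort consortium: eight cohorts
#' whose mean ages span young adulthood to old age (23 to 74 years),
#' sharing the default susceptibility and age-effect parameters, so
#' that cohort-level cluster scores increase with cohort mean age.
#'
#' @param master_seed Integer master seed.
#' @param n_per_cohort Subjects per cohort (default 400).
#' @param age_slope Shared log-odds-per-year age effect.
#' @param frailty_sd Person-level frailty SD.
#' @return List of [cohort_params()], one per cohort.
#' @export
consortium_params <- function(master_seed = 1L, n_per_cohort = 400L,
                              age_slope = 0.035, frailty_sd = 1.5) {
  ages <- c(74, 49, 68, 64, 44, 32, 49, 23)
  sds <- c(8, 19, 18, 8, 16, 6, 13, 2)
  lapply(seq_along(ages), function(i) {
    cohort_params(
      n = n_per_cohort, age_mean = ages[i], age_sd = sds[i],
      age_slope = age_slope, frailty_sd = frailty_sd,
      seed = master_seed + i,
      cohort = sprintf("synth_%02d", i))
  })
}
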