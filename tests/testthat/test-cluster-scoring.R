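test_that("the builtin default map is a valid partition with the documented sizes", {
  m <- default_cluster_map()
  expect_s3_class(m, "cluster_map")
  expect_equal(cluster_sizes(m), c(16L, 24L, 48L, 16L, 24L))
  expect_equal(sum(cluster_sizes(m)), 128L)
})

test_that("non-partitions are rejected with distinct errors", {
  m <- default_cluster_map()
  a <- m$assignment
  expect_error(cluster_map(a[names(a) != "11M"]), "missing surface")
  dup <- c(a, c("16O" = 2L))
  expect_error(cluster_map(dup), "duplicate surface")
  b <- a; b[b == 3L] <- 5L  # label 3 left with no surfaces
  expect_error(cluster_map(b), "empty cluster")
  expect_error(cluster_map(setNames(a, c("XX", names(a)[-1]))),
               "unknown surface|missing surface")
})

test_that("cluster map CSV round-trips through the config format", {
  m <- default_cluster_map()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cluster_map(m, path)
  back <- read_cluster_map(path)
  expect_equal(back$assignment, m$assignment)
})

test_that("subject scores are affected-fraction per cluster", {
  m <- default_cluster_map()
  expect_equal(unname(cluster_scores(subject_record("a"), m)[1, ]),
               rep(0, 5))
  expect_equal(unname(cluster_scores(edentulous_record(), m)[1, ]),
               rep(1, 5))
  # exactly the 8 molar occlusal surfaces decayed: 8 of cluster 1's 16
  molars <- index_teeth()[index_teeth() %% 10 %in% 6:7]
  st <- setNames(rep("DECAYED", 8), paste0(molars, "O"))
  sc <- cluster_scores(subject_record("molarO", statuses = st), m)
  expect_equal(unname(sc[1, ]), c(0.5, 0, 0, 0, 0))
})

test_that("cluster scores decompose the surface morbidity index exactly", {
  m <- default_cluster_map()
  sizes <- cluster_sizes(m)
  for (seed in 1:4) {
    co <- random_cohort(50, seed = seed)
    sc <- cluster_scores(co, m)
    expect_equal(drop(sc %*% sizes), as.numeric(index_counts(co)$dmfs),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("cohort mean DMFS is invariant to the choice of cluster map", {
  co <- random_cohort(40, seed = 8)
  m1 <- default_cluster_map()
  set.seed(2)
  # random valid 5-cluster partition
  lab <- sample(rep(1:5, length.out = 128))
  m2 <- cluster_map(setNames(lab, surface_keys()))
  s1 <- summarize_cohort(co, m1)
  s2 <- summarize_cohort(co, m2)
  expect_equal(s1$dmfs_mean, s2$dmfs_mean)
  expect_equal(s1$dmft_mean, s2$dmft_mean)
})

test_that("cohort summaries mirror the two-point closed form", {
  co <- bind_cohorts(subject_record("sound", age = 30, sex = "male"),
                     edentulous_record("edent", age = 70))
  s <- summarize_cohort(co)
  expect_equal(unlist(s[paste0("c", 1:5, "_mean")], use.names = FALSE),
               rep(0.5, 5))
  # population SD of {0,1} is 0.5; sample SD is 1/sqrt(2)
  expect_equal(unlist(s[paste0("c", 1:5, "_sd")], use.names = FALSE),
               rep(0.5, 5))
  s2 <- summarize_cohort(co, sd = "sample")
  expect_equal(s2$c1_sd, sqrt(0.5))
  expect_equal(s$pct_edentulous, 50)
  expect_equal(s$pct_cases, 50)
  expect_equal(s$cases, 1L)
})

test_that("trivial cohorts summarize to the expected extremes", {
  both_sound <- bind_cohorts(subject_record("a", age = 20, sex = "female"),
                             subject_record("b", age = 25, sex = "female"))
  s <- summarize_cohort(both_sound)
  expect_true(all(unlist(s[paste0("c", 1:5, "_mean")]) == 0))
  expect_equal(s$pct_cases, 0)
  s1 <- summarize_cohort(edentulous_record())
  expect_true(all(unlist(s1[paste0("c", 1:5, "_mean")]) == 1))
  expect_equal(s1$pct_edentulous, 100)
  expect_error(summarize_cohort(list()), "nonempty")
})

test_that("cluster-1-dominant susceptibility yields the published rank order", {
  # a1 > a3 > a5 > a4 > a2 in the generator must surface as the same
  # ordering of cohort cluster means
  p <- cohort_params(n = 2000, cluster_logits = c(0.5, -3.5, -0.5, -1.5, -1.0),
                     age_slope = 0, frailty_sd = 1,
                     tooth_loss_intercept = -50, tooth_loss_age_slope = 0,
                     seed = 31)
  s <- summarize_cohort(generate_cohort(p)$cohort)
  means <- unlist(s[paste0("c", 1:5, "_mean")], use.names = FALSE)
  expect_equal(order(means, decreasing = TRUE), c(1, 3, 5, 4, 2))
  expect_equal(which.max(means), 1L)
  expect_equal(which.min(means), 2L)
})

test_that("the odontogram rendering covers every surface once", {
  lines <- render_odontogram(default_cluster_map())
  glyphs <- unlist(strsplit(paste(grep("^[OMDBL] ", lines, value = TRUE),
                                  collapse = " "), "\\s+"))
  expect_equal(sum(glyphs %in% as.character(1:5)), 128)
})
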