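test_that("the index surface universe has 128 surfaces and no third molars", {
  surf <- index_surfaces()
  expect_equal(nrow(surf), 128L)
  expect_false(any(surf$tooth %% 10 == 8))
  expect_equal(sum(table(surf$tooth) == 4), 12)  # anterior teeth
  expect_equal(sum(table(surf$tooth) == 5), 16)  # posterior teeth
  # anterior teeth have M,D,B,L only; posterior add O
  expect_setequal(surf$surface[surf$tooth == 11], c("M", "D", "B", "L"))
  expect_setequal(surf$surface[surf$tooth == 46], c("O", "M", "D", "B", "L"))
  # stable canonical ordering: FDI then O,M,D,B,L
  expect_equal(surf$key[1:4], c("11M", "11D", "11B", "11L"))
  expect_equal(surf$key[surf$tooth == 14][1], "14O")
})

test_that("Universal numbering maps onto FDI", {
  expect_equal(universal_to_fdi(c(1, 8, 9, 16, 17, 24, 25, 32)),
               c(18L, 11L, 21L, 28L, 38L, 31L, 41L, 48L))
  expect_error(universal_to_fdi(33), "1..32")
})

test_that("ICDAS scores threshold to binary decay at ingestion", {
  rows <- full_sound_rows()
  rows$status[rows$tooth_fdi == 16 & rows$surface == "O"] <- "4"
  rows$status[rows$tooth_fdi == 16 & rows$surface == "M"] <- "2"
  co <- read_surface_csv(write_rows_csv(rows))
  expect_equal(unname(co$status[1, "16O"]), "DECAYED")
  expect_equal(unname(co$status[1, "16M"]), "SOUND")
  # custom threshold: ICDAS >= 1 marks any lesion
  co1 <- read_surface_csv(write_rows_csv(rows), icdas_threshold = 1L)
  expect_equal(unname(co1$status[1, "16M"]), "DECAYED")
})

test_that("raising the ICDAS threshold never increases decayed surfaces", {
  set.seed(11)
  rows <- full_sound_rows()
  rows$status <- as.character(sample(0:6, nrow(rows), replace = TRUE))
  path <- write_rows_csv(rows)
  n_dec <- vapply(1:6, function(th) {
    sum(read_surface_csv(path, icdas_threshold = th)$status == "DECAYED")
  }, numeric(1))
  expect_true(all(diff(n_dec) <= 0))
})

test_that("a MISSING row propagates to the whole tooth", {
  rows <- data.frame(subject_id = "s1", age = 50, sex = "male",
                     tooth_fdi = 46, surface = "M", status = "MISSING")
  co <- read_surface_csv(write_rows_csv(rows), unlisted_policy = "sound")
  keys <- paste0(46, tooth_surfaces(46))
  expect_true(all(co$status[1, keys] == "MISSING_TOOTH"))
  expect_true(all(co$status[1, setdiff(colnames(co$status), keys)] == "SOUND"))
})

test_that("third-molar rows are dropped with a message, not rejected", {
  rows <- rbind(full_sound_rows(),
                data.frame(subject_id = "s1", age = 40, sex = "female",
                           tooth_fdi = 18, surface = "O", status = "DECAYED"))
  expect_message(co <- read_surface_csv(write_rows_csv(rows)),
                 "dropped 1 third-molar")
  expect_equal(sum(co$status == "DECAYED"), 0)
})

test_that("the loader reports distinct, named validation errors", {
  base <- full_sound_rows()
  add <- function(...) rbind(base, data.frame(..., stringsAsFactors = FALSE))
  # malformed FDI code
  expect_error(read_surface_csv(write_rows_csv(
    add(subject_id = "s1", age = 40, sex = "female",
        tooth_fdi = 99, surface = "O", status = "SOUND"))),
    "malformed FDI")
  # surface invalid for an incisor
  expect_error(read_surface_csv(write_rows_csv(
    add(subject_id = "s1", age = 40, sex = "female",
        tooth_fdi = 11, surface = "O", status = "SOUND"))),
    "not valid for this tooth")
  # conflicting statuses for one surface
  expect_error(read_surface_csv(write_rows_csv(
    add(subject_id = "s1", age = 40, sex = "female",
        tooth_fdi = 16, surface = "O", status = "FILLED"))),
    "conflicting statuses")
  # MISSING on only part of a tooth
  rows <- base
  rows$status[rows$tooth_fdi == 46 & rows$surface == "O"] <- "MISSING"
  expect_error(read_surface_csv(write_rows_csv(rows)),
               "MISSING on only part of the tooth")
})

test_that("unlisted surfaces follow the chosen policy", {
  rows <- data.frame(subject_id = "s1", age = 50, sex = "male",
                     tooth_fdi = 16, surface = "O", status = "DECAYED")
  path <- write_rows_csv(rows)
  expect_error(read_surface_csv(path), "no status listed")
  co_s <- read_surface_csv(path, unlisted_policy = "sound")
  expect_equal(sum(co_s$status == "SOUND"), 127)
  co_e <- read_surface_csv(path, unlisted_policy = "excluded")
  expect_equal(sum(co_e$status == "EXCLUDED"), 127)
})

test_that("write/read round trip is the identity on validated records", {
  co <- random_cohort(6, seed = 21)
  path <- withr::local_tempfile(fileext = ".csv")
  write_surface_csv(co, path)
  back <- read_surface_csv(path)
  expect_identical(back$status, co$status)
  expect_equal(back$subjects$age, co$subjects$age)
  expect_equal(back$subjects$sex, co$subjects$sex)
})

test_that("validation reports violations as data", {
  expect_equal(nrow(validate_records(subject_record("ok"))), 0)
  # partial missing tooth: one violation row per inconsistent surface
  bad <- subject_record("s1", statuses = c("46O" = "MISSING_TOOTH"))
  rep <- validate_records(bad)
  expect_equal(unique(rep$violation), "partial missing tooth")
  expect_equal(nrow(rep), 4)  # the other 4 surfaces of tooth 46
  # uncovered surfaces are counted against the 128-surface universe
  co <- subject_record("s2")
  co$status[1, c("11M", "24O", "47L")] <- NA
  rep2 <- validate_records(co)
  expect_equal(sum(rep2$violation == "uncovered surface"), 3)
})
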