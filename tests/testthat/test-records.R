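ped3 <- pedigree(id = c("A", "B", "C"), sire = c(NA, NA, NA),
                 dam = c(NA, NA, NA), sex = c("male", "female", "male"),
                 birth = c("2010-01-01", "2010-01-01", NA))

test_that("once affected = affected, with the worst grade retained", {
  rec <- simple_records(rep("A", 3),
                        c("2012-01-01", "2013-01-01", "2014-01-01"),
                        c("unaffected", "affected", "unaffected"))
  cl <- clean_records(rec, ped3)
  expect_equal(cl$diagnosis, "affected")
  expect_equal(cl$y, 1L)
  ## retained date = first affected exam (age at diagnosis)
  expect_equal(cl$exam_date, as.Date("2013-01-01"))

  rec2 <- simple_records(rep("A", 2), c("2012-01-01", "2013-06-01"),
                         c("affected", "affected"),
                         grade = c("mild", "moderate"))
  cl2 <- clean_records(rec2, ped3)
  expect_equal(cl2$grade, "moderate")
  expect_equal(cl2$exam_date, as.Date("2012-01-01"))
})

test_that("animals with missing dates are removed and counted", {
  rec <- simple_records(c("A", "B", "C"),
                        c("2012-01-01", NA, "2012-05-01"),
                        c("unaffected", "affected", "affected"))
  cl <- clean_records(rec, ped3)
  rep_ <- attr(cl, "report")
  ## B: no dated exam; C: no birth date in the pedigree
  expect_equal(rep_$n_removed_missing_exam_date, 1L)
  expect_equal(rep_$n_removed_missing_birth_date, 1L)
  expect_equal(cl$animal, "A")
  expect_equal(rep_$n_final, rep_$n_unique -
                 rep_$n_removed_missing_exam_date -
                 rep_$n_removed_missing_birth_date)
})

test_that("a dog is kept if at least one dated record remains", {
  rec <- simple_records(c("A", "A"), c(NA, "2012-01-01"),
                        c("affected", "unaffected"))
  cl <- clean_records(rec, ped3)
  expect_equal(nrow(cl), 1L)
  expect_equal(attr(cl, "report")$n_removed_missing_exam_date, 0L)
})

test_that("graded-but-unaffected records are rejected with a warning", {
  expect_warning(
    rec <- exam_records(c("A", "A"), c("2012-01-01", "2012-06-01"),
                        c("unaffected", "affected"),
                        grade = c("mild", "mild")),
    "rejected")
  expect_equal(nrow(rec), 1L)
  expect_equal(attr(rec, "n_rejected"), 1L)
})

test_that("first-vs-last transitions are counted over multiply-examined dogs", {
  once <- simple_records(c("A", "B"), c("2012-01-01", "2012-02-01"),
                         c("affected", "unaffected"))
  expect_equal(unname(transition_counts(once)), c(0L, 0L))

  up <- simple_records(c("A", "A"), c("2012-01-01", "2013-01-01"),
                       c("unaffected", "affected"))
  expect_equal(unname(transition_counts(up)), c(1L, 0L))

  down <- simple_records(rep("A", 3),
                         c("2012-01-01", "2013-01-01", "2014-01-01"),
                         c("affected", "unaffected", "unaffected"))
  expect_equal(unname(transition_counts(down)), c(0L, 1L))
})

test_that("ages are completed years and continuous years", {
  same <- compute_age("2010-01-01", "2010-01-01")
  expect_equal(same$age_years, 0L)
  expect_equal(same$age_continuous, 0)

  d730 <- compute_age(as.Date("2010-01-01"), as.Date("2010-01-01") + 730)
  expect_equal(d730$age_years, 1L)
  expect_equal(d730$age_continuous, 730 / 365.25, tolerance = 1e-12)

  d400 <- compute_age(as.Date("2010-01-01"), as.Date("2010-01-01") + 400)
  expect_equal(d400$age_years, 1L)
  expect_equal(d400$age_continuous, 1.0951, tolerance = 1e-4)

  expect_error(compute_age("2010-01-01", "2009-12-31"), "precedes")
})

test_that("cleaning is idempotent and affected status is monotone", {
  set.seed(5)
  n <- 60
  ids <- sample(c("A", "B"), n, replace = TRUE)
  rec <- simple_records(ids,
                        as.Date("2012-01-01") + sample.int(900, n, TRUE),
                        sample(c("affected", "unaffected"), n, TRUE))
  cl1 <- clean_records(rec, ped3[ped3$id != "C", ])
  rec2 <- simple_records(cl1$animal, cl1$exam_date, cl1$diagnosis,
                         ifelse(cl1$grade == "none", NA, cl1$grade))
  cl2 <- clean_records(rec2, ped3[ped3$id != "C", ])
  expect_equal(cl1$diagnosis, cl2$diagnosis)
  expect_equal(cl1$grade, cl2$grade)
  expect_equal(cl1$exam_date, cl2$exam_date)

  ## adding an affected exam never flips an animal to unaffected
  rec_plus <- simple_records(c(rec$animal, "A"),
                             c(rec$exam_date, as.Date("2015-01-01")),
                             c(rec$diagnosis, "affected"))
  cl3 <- clean_records(rec_plus, ped3[ped3$id != "C", ])
  expect_equal(cl3[cl3$animal == "A", "diagnosis"], "affected")
  was_aff <- cl1$animal[cl1$diagnosis == "affected"]
  expect_true(all(cl3[match(was_aff, cl3$animal), "diagnosis"] == "affected"))
})
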