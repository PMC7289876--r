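test_that("organ mean dose equals the brute-force mean over the mask", {
  vocab <- organ_vocabulary()
  liver_label <- vocab$label[vocab$organ == "liver"]
  set.seed(42)
  vals <- array(runif(64, 0, 30), c(4, 4, 4))
  labels <- array(0L, c(4, 4, 4))
  idx <- sample(64, 7)
  labels[idx] <- liver_label
  m <- fake_dose_map(vals)
  expect_identical(organ_mean_dose(m, labels, "liver"), sum(vals[idx]) / 7)

  uniform <- fake_dose_map(array(12.5, c(4, 4, 4)))
  expect_equal(organ_mean_dose(uniform, labels, "liver"), 12.5)

  expect_error(organ_mean_dose(m, labels, "spleen"), "missing")
  expect_error(organ_mean_dose(m, labels, "gizzard"), "unknown organ")
  expect_error(organ_mean_dose(m, array(0L, c(2, 2, 2)), "liver"), "congruent")
  unscaled <- m
  unscaled$absorbed_dose <- NULL
  expect_error(organ_mean_dose(unscaled, labels, "liver"), "scale_to_absorbed")
})

test_that("equivalent dose is the identity for photons", {
  expect_equal(equivalent_dose(13.4), 13.4)
  expect_equal(equivalent_dose(0), 0)
  expect_error(equivalent_dose(-1), "non-negative")
})

test_that("effective organ dose applies the tissue weighting factor", {
  wf <- icrp_weights("female")
  expect_equal(effective_organ_dose(21.2, "thyroid", wf), 0.848)
  expect_equal(effective_organ_dose(13.4, "lung", wf), 1.608)
  expect_equal(effective_organ_dose(0, "colon", wf), 0)
  expect_error(effective_organ_dose(5, "prostate", wf), "not in weighting table")
  wm <- icrp_weights("male")
  expect_equal(effective_organ_dose(11.4, "prostate", wm), 11.4 * 0.0092)
})

test_that("weighting tables carry the sex-appropriate organ sets", {
  wf <- icrp_weights("female")$w_t
  wm <- icrp_weights("male")$w_t
  expect_length(wf, 26)
  expect_length(wm, 25)
  expect_true(all(c("breast", "uterus") %in% names(wf)))
  expect_false("prostate" %in% names(wf))
  expect_false(any(c("breast", "uterus") %in% names(wm)))
  expect_equal(unname(wf["gonads"]), 0.08)
  expect_equal(unname(wf["spleen"]), 0.0092)
  expect_equal(icrp_weights("male")$w_r, 1)
})

test_that("whole-body dose is an order-independent sum over present organs", {
  vocab <- organ_vocabulary()
  set.seed(7)
  labels <- array(0L, c(6, 6, 6))
  organs <- c("lung", "liver", "colon", "thyroid", "spleen")
  for (i in seq_along(organs)) {
    labels[i, , ] <- vocab$label[vocab$organ == organs[i]]
  }
  m <- fake_dose_map(array(runif(216, 5, 20), c(6, 6, 6)))
  tab <- organ_dose_table(m, labels, "male")
  expect_equal(total_effective_dose(tab), sum(tab$effective_dose))
  perm <- tab[sample(nrow(tab)), ]
  class(perm) <- class(tab)
  expect_equal(total_effective_dose(perm), total_effective_dose(tab))
  # single-organ table
  solo <- tab[tab$organ == "lung", ]
  class(solo) <- class(tab)
  expect_equal(total_effective_dose(solo), solo$effective_dose)
  # absent organs are reported, not imputed
  expect_true("stomach" %in% attr(tab, "missing"))
  expect_false("stomach" %in% tab$organ)
})

test_that("organ contributions are exact fractions summing to one", {
  vocab <- organ_vocabulary()
  set.seed(8)
  labels <- array(0L, c(6, 6, 6))
  organs <- names(icrp_weights("male")$w_t)
  for (i in seq_along(organs)) {
    labels[((i - 1) %% 6) + 1, ((i - 1) %/% 6) + 1, ] <-
      vocab$label[vocab$organ == organs[i]]
  }
  m <- fake_dose_map(array(runif(216, 1, 25), c(6, 6, 6)))
  tab <- organ_dose_table(m, labels, "male")
  cont <- organ_contribution(tab)
  expect_equal(sum(cont), 1, tolerance = 1e-9)
  expect_equal(unname(cont), tab$effective_dose / sum(tab$effective_dose))
  solo <- tab[1, ]
  class(solo) <- class(tab)
  expect_equal(unname(organ_contribution(solo)), 1)
  zero <- tab
  zero$effective_dose[] <- 0
  class(zero) <- class(tab)
  expect_error(organ_contribution(zero), "zero")
})

test_that("scaling the dose map scales doses linearly, contributions not at all", {
  vocab <- organ_vocabulary()
  labels <- array(0L, c(5, 5, 5))
  labels[1:2, , ] <- vocab$label[vocab$organ == "lung"]
  labels[4:5, , ] <- vocab$label[vocab$organ == "liver"]
  set.seed(9)
  base <- array(runif(125, 2, 15), c(5, 5, 5))
  t1 <- organ_dose_table(fake_dose_map(base), labels, "male")
  t3 <- organ_dose_table(fake_dose_map(3 * base), labels, "male")
  expect_equal(t3$absorbed_dose, 3 * t1$absorbed_dose)
  expect_equal(total_effective_dose(t3), 3 * total_effective_dose(t1))
  expect_equal(t3$contribution, t1$contribution)
})

test_that("organ dose tables serialize at the documented precision", {
  vocab <- organ_vocabulary()
  labels <- array(0L, c(4, 4, 4))
  labels[1, , ] <- vocab$label[vocab$organ == "lung"]
  labels[2, , ] <- vocab$label[vocab$organ == "liver"]
  tab <- organ_dose_table(fake_dose_map(array(11.26371, c(4, 4, 4))), labels, "male")
  csv <- tempfile(fileext = ".csv")
  write_organ_dose_table(tab, csv)
  back <- read.csv(csv)
  expect_equal(back$absorbed_dose, c(11.3, 11.3))
  expect_equal(nchar(sub(".*\\.", "", as.character(back$contribution))) <= 3,
               c(TRUE, TRUE))
  js <- tempfile(fileext = ".json")
  write_organ_dose_table(tab, js)
  full <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(full$ed_mc, attr(tab, "ed_mc"), tolerance = 1e-12)
})
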