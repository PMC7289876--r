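test_that("patient generation is deterministic and self-consistent", {
  p1 <- generate_patient(1)
  p2 <- generate_patient(1)
  expect_identical(p1, p2)
  expect_false(identical(generate_patient(2), p1))
  expect_true(p1$sex %in% c("female", "male"))
  expect_gt(p1$age, 0)
  expect_lt(abs(p1$bmi - p1$weight / (p1$height / 100)^2), 0.5)
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohort_spec(age_sd = -1), "positive")
  expect_error(cohort_spec(age_range = c(60, 20)), "range")
  expect_error(cohort_spec(female_fraction = 1.5), "female_fraction")
  expect_error(patient_record("x", age = -5, sex = "male"), "age")
  expect_error(patient_record("x", 40, "male", height = 180, weight = 60,
                              bmi = 30), "inconsistent")
})

test_that("generated cohort recovers the specified age distribution", {
  spec <- cohort_spec()
  ages <- vapply(1:1000, function(s) generate_patient(s, spec)$age, numeric(1))
  # analytic mean of the truncated normal the generator draws from
  a <- (spec$age_range[1] - spec$age_mean) / spec$age_sd
  b <- (spec$age_range[2] - spec$age_mean) / spec$age_sd
  trunc_mean <- spec$age_mean + spec$age_sd * (dnorm(a) - dnorm(b)) /
    (pnorm(b) - pnorm(a))
  se <- spec$age_sd / sqrt(1000)
  expect_lt(abs(mean(ages) - trunc_mean), 3 * se)
  expect_lt(abs(mean(ages) - spec$age_mean), 2)
})

test_that("phantoms respect sex-conditional anatomy and omissions", {
  male <- generate_phantom(patient_record("m", 50, "male", 178, 82), 48, seed = 3)
  female <- generate_phantom(patient_record("f", 45, "female", 165, 60), 48, seed = 3)
  expect_false(any(c("uterus", "breast") %in% phantom_organs(male)))
  expect_true("prostate" %in% phantom_organs(male))
  expect_false("prostate" %in% phantom_organs(female))
  expect_true(all(c("uterus", "breast") %in% phantom_organs(female)))
  vocab <- organ_vocabulary()
  expect_setequal(phantom_organs(male), vocab$organ[vocab$sex %in% c("both", "male")])

  no_spleen <- generate_phantom(male$patient, 48, seed = 3, omit = "spleen")
  expect_false("spleen" %in% phantom_organs(no_spleen))
  expect_setequal(phantom_organs(no_spleen), setdiff(phantom_organs(male), "spleen"))
  expect_identical("spleen", no_spleen$omitted)
  expect_error(generate_phantom(male$patient, 48, omit = "gizzard"), "unknown organ")
})

test_that("phantom grids are congruent with plausible tissue HU", {
  ph <- generate_phantom(patient_record("m", 50, "male", 178, 82), 64, seed = 9)
  expect_identical(dim(ph$hu), dim(ph$labels))
  vocab <- organ_vocabulary()
  lung_hu <- ph$hu[ph$labels == vocab$label[vocab$organ == "lung"]]
  bone_hu <- ph$hu[ph$labels == vocab$label[vocab$organ == "bone_surface"]]
  liver_hu <- ph$hu[ph$labels == vocab$label[vocab$organ == "liver"]]
  expect_lt(mean(lung_hu), -500)
  expect_gt(mean(bone_hu), 700)
  expect_true(mean(liver_hu) > 0 && mean(liver_hu) < 150)
})

test_that("two seeds differ in geometry but share the class inventory", {
  pat <- patient_record("m", 50, "male", 178, 82)
  a <- generate_phantom(pat, 48, seed = 1)
  b <- generate_phantom(pat, 48, seed = 2)
  expect_false(identical(a$labels, b$labels))
  expect_setequal(phantom_organs(a), phantom_organs(b))
})

test_that("too-small resolutions fail explicitly", {
  pat <- patient_record("m", 50, "male", 178, 82)
  expect_error(generate_phantom(pat, 8), "at least 16")
  expect_error(generate_phantom(pat, 16), "resolution too small")
})

test_that("tube current modulation is monotone in BMI with a sane DLP scale", {
  lean <- patient_record("a", 50, "male", 175, 21.6 * 1.75^2)
  stout <- patient_record("b", 50, "male", 175, 30 * 1.75^2)
  r1 <- emulate_scanner_report(lean, seed = 5, noise_sd = 0)
  r2 <- emulate_scanner_report(stout, seed = 5, noise_sd = 0)
  expect_gt(r2$effective_mas, r1$effective_mas)
  expect_gt(r2$ctdi_vol, r1$ctdi_vol)
  expect_equal(r1$dlp, round(r1$ctdi_vol * r1$scan_length), tolerance = 0.01)
  # anchor: normal-weight adult near the reference DLP of ~675 mGy cm
  anchor <- patient_record("c", 30, "female", 163, 21.6 * 1.63^2)
  ra <- emulate_scanner_report(anchor, seed = 1, noise_sd = 0)
  expect_gt(ra$dlp, 675 / 2)
  expect_lt(ra$dlp, 675 * 2)
  expect_error(emulate_scanner_report(patient_record("d", 40, "male")), "BMI")
})

test_that("synthetic cohorts couple BMI tightly to scanner output", {
  co <- generate_cohort(100, seed = 11)
  expect_gt(as.numeric(spearman_cor(co$bmi, co$eff_mas)), 0.9)
  expect_gt(as.numeric(spearman_cor(co$bmi, co$dlp)), 0.9)
})

test_that("study configurations load from JSON with defaults filled in", {
  cfg_path <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(cohort = list(female_fraction = 0.5, age_mean = 40),
         scan = list(air_kerma = 20), seed = 9),
    cfg_path, auto_unbox = TRUE
  )
  cfg <- load_config(cfg_path)
  expect_equal(cfg$cohort$female_fraction, 0.5)
  expect_equal(cfg$cohort$age_mean, 40)
  expect_equal(cfg$cohort$age_sd, 14.3)  # default retained
  expect_equal(cfg$scan$air_kerma, 20)
  expect_equal(cfg$scan$pitch, 0.8)
  expect_equal(cfg$seed, 9L)
  expect_error(load_config(tempfile()), "not found")
})

test_that("the packaged cohort table loads faithfully and round-trips", {
  tab <- load_cohort_table()
  expect_equal(nrow(tab), 22)
  expect_equal(tab$age[1], 30)
  expect_equal(tab$sex[1], "female")
  expect_equal(tab$dlp[1], 675)
  expect_equal(tab$ed_mc[1], 11.1)
  tmp <- tempfile(fileext = ".csv")
  write.csv(tab, tmp, row.names = FALSE)
  expect_equal(load_cohort_table(tmp), tab)

  empty <- tempfile(fileext = ".csv")
  file.create(empty)
  expect_equal(nrow(load_cohort_table(empty)), 0)

  bad <- tab
  bad$dlp[3] <- -5
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(load_cohort_table(tmp), "row 3.*DLP")
  bad <- tab
  bad$ed_mc[7] <- -1
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(load_cohort_table(tmp), "row 7.*negative dose")
})
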