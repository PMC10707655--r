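test_that("scenario validation rejects impossible timings", {
  expect_error(scene_scenario(duration_s = 0), class = "bw_validation_error")
  expect_error(scene_scenario(duration_s = 10, fps = 0),
               class = "bw_validation_error")
  expect_error(scene_scenario(duration_s = 10, precursor_onset_s = 7,
                              bleed_onset_s = 4),
               class = "bw_validation_error")
})

test_that("rendering is deterministic and respects the time range", {
  sc <- scene_scenario(duration_s = 5, fps = 25, rng_seed = 31, size = 32)
  f1 <- render_frame(sc, 2.0)
  f2 <- render_frame(sc, 2.0)
  expect_identical(f1, f2)
  expect_error(render_frame(sc, 5.5), class = "bw_validation_error")
  expect_error(render_frame(sc, -0.1), class = "bw_validation_error")
})

test_that("frame content matches its label: blood area drives the class", {
  sc_clean <- scene_scenario(duration_s = 5, fps = 25, rng_seed = 8, size = 32)
  f <- render_frame(sc_clean, 1.0)
  expect_identical(f$blood_label, 0L)
  expect_identical(f$blood_area_px, 0L)
  expect_true(all(f$image >= 0 & f$image <= 1))
  expect_true(all(f$tool_mask %in% c(0L, 1L)))
  expect_identical(dim(f$tool_mask), dim(f$image)[1:2])
  expect_gt(sum(f$tool_mask), 0)  # instruments are present

  sc_bleed <- scene_scenario(duration_s = 10, fps = 25, bleed_onset_s = 2,
                             blob_growth_rate = 40, rng_seed = 8, size = 32)
  fb <- render_frame(sc_bleed, 5.0)
  expect_identical(fb$blood_label, 1L)
  expect_gte(fb$blood_area_px, sc_bleed$min_blob_frac * 32^2)
})

test_that("label is always consistent with the rendered visible blood area", {
  sc <- scene_scenario(duration_s = 10, fps = 25, precursor_onset_s = 3,
                       bleed_onset_s = 7, rng_seed = 12, size = 32)
  for (t in seq(0, 9.96, by = 0.48)) {
    f <- render_frame(sc, t)
    expect_identical(f$blood_label,
                     as.integer(f$blood_area_px >= sc$min_blob_frac * 32^2))
  }
})

test_that("sequences have the right length and temporal label structure", {
  sc <- scene_scenario(duration_s = 10, fps = 25, precursor_onset_s = 4,
                       bleed_onset_s = 7, rng_seed = 5, size = 32)
  seq10 <- generate_sequence(sc)
  expect_length(seq10$frames, 250)

  labels <- vapply(seq10$frames, `[[`, integer(1), "blood_label")
  times <- vapply(seq10$frames, `[[`, numeric(1), "timestamp_s")
  expect_true(all(labels[times < 4] == 0))
  frac_pre <- mean(labels[times >= 4 & times < 7])
  expect_gt(frac_pre, 0)
  expect_lt(frac_pre, 1)
  expect_true(all(labels[times >= 7] == 1))

  sc0 <- scene_scenario(duration_s = 2, fps = 25, rng_seed = 5, size = 32)
  labels0 <- vapply(generate_sequence(sc0)$frames, `[[`, integer(1),
                    "blood_label")
  expect_true(all(labels0 == 0))
})

test_that("identical seeds reproduce bit-identical frames across sequences", {
  sc <- scene_scenario(duration_s = 2, fps = 10, precursor_onset_s = 0.5,
                       bleed_onset_s = 1.5, rng_seed = 99, size = 32)
  s1 <- generate_sequence(sc)
  s2 <- generate_sequence(sc)
  expect_identical(s1, s2)
})

test_that("a trivial colour heuristic separates the generated classes", {
  ds <- make_frame_dataset(120, size = 64, seed = 77)
  labels <- vapply(ds, `[[`, integer(1), "blood_label")
  expect_equal(sum(labels), 60)
  red_excess <- vapply(ds, function(f) {
    keep <- f$tool_mask == 0
    mean(f$image[, , 1][keep] - f$image[, , 2][keep])
  }, numeric(1))
  # best single-threshold split on the 1-D heuristic
  acc <- max(vapply(sort(red_excess), function(thr) {
    mean((red_excess > thr) == (labels == 1))
  }, numeric(1)))
  expect_gt(acc, 0.95)
})

test_that("datasets round-trip through PNG frames and a JSON manifest", {
  dir1 <- withr::local_tempdir()
  sc <- scene_scenario(duration_s = 0.4, fps = 25, bleed_onset_s = 0.2,
                       rng_seed = 3, size = 32)
  seq1 <- generate_sequence(sc)
  man <- write_dataset(seq1$frames, file.path(dir1, "manifest.json"),
                       file.path(dir1, "img"), fps = 25,
                       bleed_onset_s = 0.2, seed = 3)
  expect_length(man$frames, 10)
  expect_length(list.files(file.path(dir1, "img"), pattern = "^frame_.*png$"),
                10)

  back <- read_manifest(file.path(dir1, "manifest.json"))
  expect_equal(back$fps, 25)
  expect_equal(back$bleed_onset_s, 0.2)
  expect_equal(vapply(back$frames, `[[`, integer(1), "label"),
               vapply(seq1$frames, `[[`, integer(1), "blood_label"))
  expect_equal(vapply(back$frames, `[[`, numeric(1), "t"),
               vapply(seq1$frames, `[[`, numeric(1), "timestamp_s"))

  frames <- load_frames(back)
  expect_length(frames, 10)
  # 8-bit PNG round trip: images equal up to quantisation, masks exactly
  expect_lt(max(abs(frames[[5]]$image - seq1$frames[[5]]$image)), 1 / 255)
  expect_equal(frames[[5]]$tool_mask + 0, seq1$frames[[5]]$tool_mask + 0)

  # degenerate: empty sample list
  man0 <- write_dataset(list(), file.path(dir1, "empty.json"),
                        file.path(dir1, "img0"))
  expect_length(man0$frames, 0)
  expect_silent(read_manifest(file.path(dir1, "empty.json")))
})

test_that("regenerating with the same seed gives byte-identical images", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  sc <- scene_scenario(duration_s = 0.2, fps = 25, bleed_onset_s = 0.1,
                       rng_seed = 21, size = 32)
  write_dataset(generate_sequence(sc)$frames, file.path(dir1, "m.json"),
                file.path(dir1, "img"))
  write_dataset(generate_sequence(sc)$frames, file.path(dir2, "m.json"),
                file.path(dir2, "img"))
  f1 <- file.path(dir1, "img", "frame_00003.png")
  f2 <- file.path(dir2, "img", "frame_00003.png")
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
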