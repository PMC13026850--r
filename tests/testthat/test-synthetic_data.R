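test_that("scene generation is a pure function of (spec, seed)", {
  spec <- small_scene_spec()
  a <- generate_scene(spec, seed = 4)
  b <- generate_scene(spec, seed = 4)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  c <- generate_scene(spec, seed = 5)
  expect_false(identical(a$image, c$image))
  # generation does not disturb the session RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_scene(spec, seed = 6)); after <- runif(1)
  expect_identical(before, after)
})

test_that("masks are clean labels with instruments well below half the frame", {
  spec <- small_scene_spec()
  fracs <- vapply(1:30, function(s) {
    p <- generate_scene(spec, seed = s)
    expect_true(all(p$mask %in% 0:1))
    expect_true(all(p$image >= 0 & p$image <= 1))
    mean(p$mask == 1)
  }, numeric(1))
  # severe-imbalance regime: instruments are thin structures
  expect_lt(max(fracs), 0.5)
  expect_gt(mean(fracs), 0.01) # but instruments do exist on average
  # no instruments requested -> all-background mask
  empty <- generate_scene(scene_spec(height = 32, width = 32,
                                     instrument_count_range = c(0, 0)), seed = 1)
  expect_true(all(empty$mask == 0L))
})

test_that("multi-class preset adds anatomy labels without losing instruments", {
  spec <- scene_spec(height = 48, width = 48, num_classes = 4,
                     instrument_width_range = c(4, 8),
                     instrument_length_range = c(20, 40))
  p <- generate_scene(spec, seed = 2)
  expect_true(all(p$mask %in% 0:3))
  expect_gt(sum(p$mask == 1), 0)
})

test_that("degradations are identity at zero strength and act as documented", {
  set.seed(10)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  for (art in c("blur", "glare", "occlusion", "smoke", "low_contrast")) {
    expect_identical(degrade(img, art, 0), img)
    out <- degrade(img, art, 0.5, seed = 3)
    expect_true(all(out >= 0 & out <= 1))
    expect_identical(dim(out), dim(img))
  }
  # blur strictly reduces high-frequency (Laplacian) energy on a checkerboard
  chk <- array(rep((outer(1:32, 1:32, "+") %% 2), 3), c(32, 32, 3))
  blurred <- degrade(chk, "blur", 1, seed = 1)
  lap_var <- function(im) {
    g <- 0.299 * im[, , 1] + 0.587 * im[, , 2] + 0.114 * im[, , 3]
    var(as.vector(apply_frozen_bank(array(g, c(32, 32, 1)))[, , 3]))
  }
  expect_lt(lap_var(blurred), lap_var(chk))
  # glare never reduces the maximum
  glared <- degrade(img, "glare", 0.6, seed = 2)
  expect_gte(max(glared), max(img))
  expect_error(degrade(img, "vignette", 0.5), "unknown artifact")
})

test_that("degradations never alter the mask", {
  spec <- small_scene_spec(artifact_probabilities = c(blur = 1, glare = 1,
                                                      occlusion = 1, smoke = 1,
                                                      low_contrast = 1))
  heavy <- generate_scene(spec, seed = 9)
  expect_setequal(heavy$applied_artifacts,
                  c("blur", "glare", "occlusion", "smoke", "low_contrast"))
  clean_spec <- small_scene_spec(artifact_probabilities = c(blur = 0, glare = 0,
                                                            occlusion = 0, smoke = 0,
                                                            low_contrast = 0))
  clean <- generate_scene(clean_spec, seed = 9)
  expect_identical(heavy$mask, clean$mask)
  expect_false(identical(heavy$image, clean$image))
})

test_that("rare-class merging relabels totally and conserves pixels", {
  set.seed(6)
  mask <- matrix(sample(0:12, 400, TRUE), 20, 20)
  idmap <- stats::setNames(0:12, as.character(0:12))
  expect_identical(merge_rare_classes(mask, idmap), mask)
  mapping <- stats::setNames(c(0:6, rep(6L, 6)), as.character(0:12))
  merged <- merge_rare_classes(mask, mapping)
  expect_true(all(merged %in% 0:6))
  expect_identical(dim(merged), dim(mask))
  expect_equal(sum(merged == 6), sum(mask >= 6))
  expect_error(merge_rare_classes(mask, mapping[-3]), "unmapped")
})

test_that("PNG pairs round-trip masks losslessly and images to 8-bit precision", {
  dir <- withr::local_tempdir()
  pair <- generate_scene(small_scene_spec(), seed = 12)
  ip <- file.path(dir, "img.png"); mp <- file.path(dir, "mask.png")
  write_pair(pair, ip, mp)
  back <- read_pair(ip, mp)
  expect_identical(back$mask, pair$mask)
  expect_lte(max(abs(back$image - pair$image)), 1 / 255)
  # size mismatch on disk is rejected
  small <- generate_scene(scene_spec(height = 32, width = 32), seed = 1)
  png::writePNG(matrix(0, 32, 32), mp)
  png::writePNG(pair$image, ip)
  expect_error(read_pair(ip, mp), "differ")
})

test_that("dataset generation writes a consistent manifest", {
  dir <- withr::local_tempdir()
  spec <- scene_spec(height = 32, width = 32,
                     instrument_width_range = c(3, 8),
                     instrument_length_range = c(12, 30))
  manifest <- generate_dataset(spec, 4, dir, seed = 8)
  expect_equal(nrow(manifest), 4)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  pairs <- load_dataset(dir)
  # per-class pixel totals in the manifest equal the stored masks'
  for (i in 1:4) {
    expect_equal(manifest$px_class1[i], sum(pairs[[i]]$mask == 1))
    expect_equal(manifest$px_class0[i], sum(pairs[[i]]$mask == 0))
  }
  # rerun with the same seed: identical manifest and identical files
  dir2 <- withr::local_tempdir()
  manifest2 <- generate_dataset(spec, 4, dir2, seed = 8)
  expect_equal(manifest, manifest2)
  expect_identical(readBin(file.path(dir, "img_0001.png"), "raw", 1e6),
                   readBin(file.path(dir2, "img_0001.png"), "raw", 1e6))
})
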