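test_that("image files round-trip through disk losslessly (PNG) and keep shape (JPEG)", {
  img <- random_patch(45, 45, seed = 3)
  path <- withr::local_tempfile(fileext = ".png")
  write_image_png(img, path)
  reloaded <- load_image(path)
  expect_identical(unclass(reloaded), unclass(img))

  white <- rgb_image(array(255L, dim = c(2, 2, 3)))
  wpath <- withr::local_tempfile(fileext = ".png")
  write_image_png(white, wpath)
  expect_true(all(unclass(load_image(wpath)) == 255L))

  jpath <- withr::local_tempfile(fileext = ".jpg")
  jpeg::writeJPEG(unclass(img) / 255, jpath)
  expect_equal(dim(load_image(jpath)), c(45L, 45L, 3L))
})

test_that("alpha channels are dropped and non-colour images rejected", {
  rgba <- withr::with_seed(5, array(runif(6 * 6 * 4), dim = c(6, 6, 4)))
  apath <- withr::local_tempfile(fileext = ".png")
  png::writePNG(rgba, apath)
  loaded <- load_image(apath)
  expect_equal(dim(loaded), c(6L, 6L, 3L))
  expect_identical(unclass(loaded), unname(round(rgba[, , 1:3] * 255)) |>
                     (\(a) {storage.mode(a) <- "integer"; a})())

  gray <- matrix(runif(16), 4, 4)
  gpath <- withr::local_tempfile(fileext = ".png")
  png::writePNG(gray, gpath)
  expect_error(load_image(gpath), class = "chromaquant_format_error")
  expect_error(load_image("does-not-exist.png"),
               class = "chromaquant_io_error")
})

test_that("ROI extraction honours the half-open window and image bounds", {
  img <- random_patch(100, 100, seed = 7)
  patch <- extract_roi(img, 0, 0, 45)
  expect_equal(dim(patch), c(45L, 45L, 3L))
  expect_identical(unclass(patch), unclass(img)[1:45, 1:45, ])

  expect_error(extract_roi(img, 60, 60, 45, label = "sample_A7"),
               "sample_A7", class = "chromaquant_bounds_error")

  flat <- rgb_image(array(77L, dim = c(50, 50, 3)))
  expect_true(all(unclass(extract_roi(flat, 2, 3, 10)) == 77L))
})

test_that("ROI extraction is translation-consistent", {
  img <- random_patch(80, 90, seed = 13)
  for (rc in list(c(0, 0), c(10, 25), c(35, 45))) {
    cropped <- rgb_image(unclass(img)[(rc[1] + 1):80, (rc[2] + 1):90, ,
                                      drop = FALSE])
    expect_identical(unclass(extract_roi(img, rc[1], rc[2], 20)),
                     unclass(extract_roi(cropped, 0, 0, 20)))
  }
})

test_that("histograms conserve pixel counts and match a brute-force tally", {
  flat <- rgb_image(array(rep(c(200L, 30L, 30L), each = 45 * 45),
                          dim = c(45, 45, 3)))
  h <- roi_histogram(flat)
  expect_equal(h$count[h$channel == "R" & h$intensity == 200], 2025L)
  expect_equal(h$count[h$channel == "G" & h$intensity == 30], 2025L)
  expect_equal(h$count[h$channel == "B" & h$intensity == 30], 2025L)
  expect_equal(sum(h$count), 3L * 2025L)

  for (seed in 1:4) {
    patch <- random_patch(5, 5, seed = seed)
    h <- roi_histogram(patch)
    # conservation per channel
    counts <- tapply(h$count, h$channel, sum)
    expect_true(all(counts == 25L))
    # exhaustive per-pixel tally oracle
    px <- unclass(patch)
    for (ch in 1:3) {
      lab <- c("R", "G", "B")[ch]
      tally <- integer(256)
      for (i in 1:5) for (j in 1:5) {
        v <- px[i, j, ch]
        tally[v + 1L] <- tally[v + 1L] + 1L
      }
      expect_identical(h$count[h$channel == lab], tally)
    }
  }
})

test_that("channel means match brute-force sums and the histogram-derived mean", {
  flat <- rgb_image(array(rep(c(10L, 20L, 30L), each = 4), dim = c(2, 2, 3)))
  expect_equal(unlist(channel_means(flat)[, -1]),
               c(mean_r = 10, mean_g = 20, mean_b = 30))

  two <- rgb_image(array(c(0L, 255L), dim = c(2, 1, 3)))
  expect_equal(unlist(channel_means(two)[, -1]),
               c(mean_r = 127.5, mean_g = 127.5, mean_b = 127.5))

  for (seed in 5:8) {
    patch <- random_patch(3, 3, seed = seed)
    m <- channel_means(patch)
    px <- unclass(patch)
    expect_equal(m$mean_r, sum(px[, , 1]) / 9)
    expect_equal(m$mean_g, sum(px[, , 2]) / 9)
    expect_equal(m$mean_b, sum(px[, , 3]) / 9)
    # histogram consistency: sum(value * count) / n equals the pixel mean
    h <- roi_histogram(patch)
    hm <- tapply(h$intensity * h$count, h$channel, sum) / 9
    expect_equal(as.numeric(hm[c("R", "G", "B")]),
                 c(m$mean_r, m$mean_g, m$mean_b), tolerance = 1e-9)
  }
})

test_that("reflectance referencing gives exact ratios and unit blank self-reflectance", {
  sig <- tibble::tibble(label = c("blank", "s1"),
                        mean_r = c(240, 120), mean_g = c(240, 60),
                        mean_b = c(250, 200))
  refl <- reflectance_signals(sig)
  expect_equal(unlist(refl[refl$label == "blank", c("refl_r", "refl_g", "refl_b")]),
               c(refl_r = 1, refl_g = 1, refl_b = 1))
  expect_equal(unlist(refl[refl$label == "s1", c("refl_r", "refl_g", "refl_b")]),
               c(refl_r = 0.5, refl_g = 0.25, refl_b = 0.8))

  zero <- tibble::tibble(label = c("blank", "s1"), mean_r = c(0, 1),
                         mean_g = c(10, 1), mean_b = c(10, 1))
  expect_error(reflectance_signals(zero), class = "chromaquant_blank_error")
  expect_error(reflectance_signals(sig, blank_label = "nope"),
               class = "chromaquant_blank_error")

  abs_sig <- reflectance_signals(sig, absorbance = TRUE)
  expect_equal(abs_sig$abs_r[2], -log10(0.5))
})

test_that("green reflectance decreases monotonically with dye concentration", {
  scene <- render_scene(default_calibration_scene(noise_sd = 0, seed = 1))
  sig <- extract_signals(scene$image, scene$layout)
  std <- sig[grepl("^std_", sig$label), ]
  std <- std[order(as.integer(sub("std_", "", std$label))), ]
  expect_true(all(diff(std$refl_g) < 0))
})

test_that("ROI layouts round-trip through JSON and YAML", {
  layout <- roi_grid(c("blank", "std_1", "std_2"), edge = 45)
  for (ext in c(".json", ".yaml")) {
    path <- withr::local_tempfile(fileext = ext)
    write_roi_layout(layout, path)
    expect_equal(as.data.frame(read_roi_layout(path)),
                 as.data.frame(layout))
  }
  expect_error(roi_layout(c("a", "a"), c(0, 0), c(0, 50)),
               class = "chromaquant_roi_error")
})
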