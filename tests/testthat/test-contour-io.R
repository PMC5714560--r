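test_that("contour_set enforces polygon validity and slice ordering", {
  expect_error(contour_set(list(list(y = 0, points = rbind(c(0, 0), c(1, 0))))),
               "at least 3 points")
  bow <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))   # self-crossing
  expect_error(contour_set(list(list(y = 0, points = bow))),
               "self-intersecting")
  cs <- contour_set(list(circle_slice(5), circle_slice(-5), circle_slice(0)))
  expect_equal(contour_slice_ys(cs), c(-5, 0, 5))
})

test_that("JSON interchange round-trips contours exactly", {
  cs <- sphere_contours(R = 20, spacing = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_contours_json(list(cs, cs), path)
  back <- read_contours_json(path)
  expect_length(back, 2)
  expect_equal(contour_points_3d(back[[1]]), contour_points_3d(cs),
               tolerance = 1e-12)
  expect_equal(back[[1]]$observer, cs$observer)
})

test_that("RT-STRUCT write/read round-trips coordinates within 1e-3 mm", {
  cs <- sphere_contours(R = 22, spacing = 5, center = c(10, -4, 65))
  path <- withr::local_tempfile(fileext = ".dcm")
  write_rtstruct(cs, path)
  back <- read_rtstruct(path, "prostate")
  expect_lt(max(abs(contour_points_3d(back) - contour_points_3d(cs))), 1e-3)
  expect_equal(length(back$slices), length(cs$slices))
})

test_that("RT-STRUCT reader errors name the available structures", {
  cs <- sphere_contours()
  path <- withr::local_tempfile(fileext = ".dcm")
  write_rtstruct(cs, path)
  expect_error(read_rtstruct(path, "bladder"), "available: prostate")
})

test_that("a hand-built minimal RT-STRUCT with one triangle decodes to a 3-point polygon", {
  # encoded from the DICOM data-element layout by an independent writer:
  # explicit VR little endian, one CLOSED_PLANAR triangle at z = 12.5
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  u32v <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
  el <- function(g, e, vr, chr) {
    v <- charToRaw(chr)
    if (length(v) %% 2) v <- c(v, if (vr == "UI") as.raw(0) else charToRaw(" "))
    c(u16(g), u16(e), charToRaw(vr), u16(length(v)), v)
  }
  sq <- function(g, e, item) c(u16(g), u16(e), charToRaw("SQ"), raw(2),
                               as.raw(c(0xFF, 0xFF, 0xFF, 0xFF)),
                               u16(0xFFFE), u16(0xE000),
                               as.raw(c(0xFF, 0xFF, 0xFF, 0xFF)), item,
                               u16(0xFFFE), u16(0xE00D), u32v(0),
                               u16(0xFFFE), u16(0xE0DD), u32v(0))
  roi <- c(el(0x3006, 0x0022, "IS", "1"),
           el(0x3006, 0x0024, "UI", "2.25.99"),
           el(0x3006, 0x0026, "LO", "tri"))
  contour <- c(el(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
               el(0x3006, 0x0046, "IS", "3"),
               el(0x3006, 0x0050, "DS",
                  "0\\0\\12.5\\10\\0\\12.5\\0\\10\\12.5"))
  rcs_item <- c(sq(0x3006, 0x0040, contour), el(0x3006, 0x0084, "IS", "1"))
  meta_body <- el(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  meta <- c(u16(0x0002), u16(0x0000), charToRaw("UL"), u16(4),
            u32v(length(meta_body)), meta_body)
  ds <- c(sq(0x3006, 0x0020, roi), sq(0x3006, 0x0039, rcs_item))
  path <- withr::local_tempfile(fileext = ".dcm")
  writeBin(c(raw(128), charToRaw("DICM"), meta, ds), path)

  cs <- read_rtstruct(path, "tri")
  expect_length(cs$slices, 1)
  expect_equal(cs$slices[[1]]$y, 12.5)
  expect_equal(cs$slices[[1]]$points,
               rbind(c(0, 0), c(10, 0), c(0, 10)), ignore_attr = TRUE)
  expect_equal(cs$frame_of_reference, "2.25.99")
})
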