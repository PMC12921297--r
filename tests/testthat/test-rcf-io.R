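random_map <- function(seed, nr = 12, nc = 20, px = 0.5, origin = c(-5, -3)) {
  set.seed(seed)
  # values exactly representable at 6 significant digits
  v <- matrix(signif(runif(nr * nc, 0, 60), 6), nr, nc)
  dose_map(v, pixel_size_mm = px, origin_mm = origin, plane = "RCF2")
}

test_that("dose maps round-trip losslessly through the text format", {
  path <- withr::local_tempfile(fileext = ".txt")
  for (s in 1:5) {
    m <- random_map(s)
    write_dose_map(m, path)
    m2 <- read_dose_map(path)
    expect_identical(m2$values, m$values)
    expect_identical(m2$pixel_size_mm, m$pixel_size_mm)
    expect_identical(m2$origin_mm, m$origin_mm)
    expect_identical(m2$plane, m$plane)
  }

  m <- dose_map(matrix(c(1, 3, 2, 4), 2, 2), 1, c(0, 0), "toy")
  write_dose_map(m, path)
  expect_equal(read_dose_map(path)$values, m$values)
})

test_that("malformed dose-map files raise parse errors naming the problem", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), path)
  expect_error(read_dose_map(path), "empty")

  writeLines(c("# pixel_size_mm=0.25", "# plane=x", "1 2"), path)
  expect_error(read_dose_map(path), "origin_mm")

  writeLines(c("# pixel_size_mm=0.25", "# origin_mm=0,0", "# plane=x",
               "1 foo"), path)
  expect_error(read_dose_map(path), "line 4")

  writeLines(c("# pixel_size_mm=0.25", "# origin_mm=0,0", "# plane=x",
               "1 -2"), path)
  expect_error(read_dose_map(path), "negative")
})

test_that("region statistics: uniform, two-pixel, and brute-force oracle", {
  u <- dose_map(matrix(10, 20, 20), 1, c(0, 0), "u")
  st <- region_stats(u, region_spec("r", 10, 10, 6, 6))
  expect_equal(st$mean_Gy, 10)
  expect_equal(st$rel_dev, 0)

  # two pixels {8, 12}: mean 10, half peak-to-peak over mean = 0.2
  m2 <- dose_map(matrix(c(8, 12), 1, 2), 1, c(0, 0), "t")
  st2 <- region_stats(m2, region_spec("r", 1, 0.5, 2, 1))
  expect_equal(st2$mean_Gy, 10)
  expect_equal(st2$rel_dev, 0.2)

  # random maps against an exhaustive pixel loop
  for (s in 1:5) {
    m <- random_map(s)
    reg <- region_spec("r", stats::runif(1, -3, 3), stats::runif(1, -2, 2),
                       stats::runif(1, 2, 6), stats::runif(1, 2, 4))
    inside <- c()
    for (i in seq_len(nrow(m$values))) {
      for (j in seq_len(ncol(m$values))) {
        x <- m$origin_mm[1] + (j - 0.5) * m$pixel_size_mm
        z <- m$origin_mm[2] + (i - 0.5) * m$pixel_size_mm
        if (x >= reg$cx_mm - reg$w_mm / 2 - 1e-9 &&
            x < reg$cx_mm + reg$w_mm / 2 - 1e-9 &&
            z >= reg$cz_mm - reg$h_mm / 2 - 1e-9 &&
            z < reg$cz_mm + reg$h_mm / 2 - 1e-9) {
          inside <- c(inside, m$values[i, j])
        }
      }
    }
    st <- region_stats(m, reg)
    expect_equal(st$mean_Gy, mean(inside))
    expect_equal(st$rel_dev, (max(inside) - min(inside)) / (2 * mean(inside)))
    expect_equal(st$n_pixels, length(inside))
  }

  expect_error(region_stats(u, region_spec("far", 100, 100, 2, 2)), "overlaps")
})

test_that("region mean is invariant under joint translation of map and region", {
  m <- random_map(3)
  reg <- region_spec("r", 0, 0, 4, 3)
  st <- region_stats(m, reg)
  shift <- c(7.25, -3.5)
  m_sh <- dose_map(m$values, m$pixel_size_mm, m$origin_mm + shift, m$plane)
  reg_sh <- region_spec("r", shift[1], shift[2], 4, 3)
  expect_equal(region_stats(m_sh, reg_sh)$mean_Gy, st$mean_Gy)
})

test_that("mean over a union of two disjoint equal-area regions nests", {
  m <- random_map(9, nr = 20, nc = 20, px = 1, origin = c(0, 0))
  a <- region_stats(m, region_spec("a", 5, 10, 4, 4))
  b <- region_stats(m, region_spec("b", 15, 10, 4, 4))
  ab <- region_stats(m, region_spec("ab", 10, 10, 14, 4))
  # the union region covers a, b plus the strip between; compare instead
  # the exact union of the two disjoint boxes via pixel counts
  expect_equal(a$n_pixels, b$n_pixels)
  union_mean <- (a$mean_Gy * a$n_pixels + b$mean_Gy * b$n_pixels) /
    (a$n_pixels + b$n_pixels)
  expect_equal(union_mean, (a$mean_Gy + b$mean_Gy) / 2)
  expect_true(is.finite(ab$mean_Gy))
})

test_that("blue-box mean is region_stats on the tank projection", {
  u <- dose_map(matrix(7.5, 48, 144), 0.25, c(-18, -6), "RCF2")
  expect_equal(blue_box_mean(u), 7.5)
  m <- random_map(4, nr = 48, nc = 60, px = 0.25, origin = c(-7.5, -6))
  box <- region_spec("blue-box", 0, 0, 5, 5)
  expect_equal(blue_box_mean(m, box), region_stats(m, box)$mean_Gy)
  expect_error(blue_box_mean(u, region_spec("out", 500, 0, 5, 5)), "overlaps")
})

test_that("two-compartment average reproduces the reported integer doses", {
  r1 <- two_compartment_average(85, 70)
  expect_equal(r1$d_av_Gy, 77.5)
  expect_equal(r1$d_av_reported_Gy, 78)
  r3 <- two_compartment_average(45, 32)
  expect_equal(r3$d_av_Gy, 38.5)
  expect_equal(r3$d_av_reported_Gy, 39)
  expect_equal(two_compartment_average(12.3, 12.3)$d_av_Gy, 12.3)
  expect_error(two_compartment_average(-1, 5))
})

test_that("round_half_away rounds ties away from zero at any digit", {
  expect_equal(round_half_away(0.315, 2), 0.32)
  expect_equal(round_half_away(-0.315, 2), -0.32)
  expect_equal(round_half_away(38.5, 0), 39)
  expect_equal(round_half_away(2.5, 0), 3)
})

test_that("region tables round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  regs <- default_regions(blue_box = TRUE)
  write_regions(regs, path)
  expect_equal(as.data.frame(read_regions(path)), as.data.frame(regs))
})
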