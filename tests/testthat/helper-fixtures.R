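# Shared fixtures: tiny layouts, solid/random images, and the independent
# brute-force / closed-form oracles the implementation is checked against.

# smallest legal layout: one control/analyte pair, DC1 under condition 1
tiny_layout <- function(roi = roi_spec("disk", 3), pitch = c(20, 20),
                        origin = c(15, 15)) {
  plate_layout(
    n_rows = 2, n_cols = 2, origin = origin, pitch = pitch, roi = roi,
    wells = data.frame(
      well = c("A1", "A2"), sensor = "DC1", condition = 1L,
      role = c("control", "analyte"), pair = "P01"
    )
  )
}

# 2 sensors x 2 conditions (12-digit codes), 8 wells in rows A-B
quad_layout <- function(roi = roi_spec("disk", 3)) {
  wells <- do.call(rbind, lapply(1:2, function(i) {
    data.frame(
      well = paste0(LETTERS[i], 1:4),
      sensor = paste0("DC", i),
      condition = c(1L, 1L, 2L, 2L),
      role = c("control", "analyte", "control", "analyte"),
      pair = paste0("DC", i, "c", c(1, 1, 2, 2))
    )
  }))
  plate_layout(2, 4, origin = c(15, 15), pitch = c(20, 20), roi = roi,
               wells = wells)
}

solid_image <- function(h, w, rgb, bit_depth = 8L) {
  px <- array(0L, dim = c(h, w, 3L))
  for (k in 1:3) px[, , k] <- as.integer(rgb[k])
  plate_image(px, bit_depth = bit_depth)
}

random_image <- function(h, w, seed, bit_depth = 8L) {
  maxval <- 2^bit_depth - 1
  px <- withr::with_seed(seed, {
    array(sample.int(maxval + 1L, h * w * 3L, replace = TRUE) - 1L,
          dim = c(h, w, 3L))
  })
  plate_image(px, bit_depth = bit_depth)
}

# independent double-loop pixel-sum oracle for per-well ROI totals
brute_totals <- function(img, layout) {
  d <- dim(img$pixels)
  wells <- layout$wells
  out <- matrix(0, nrow(wells), 4L)
  for (i in seq_len(nrow(wells))) {
    ctr <- well_center(layout, wells$well[i])
    r <- layout$roi$size
    for (y in 0:(d[1] - 1L)) {
      for (x in 0:(d[2] - 1L)) {
        inside <- if (layout$roi$shape == "disk") {
          (x - ctr["x"])^2 + (y - ctr["y"])^2 <= r^2
        } else {
          max(abs(x - ctr["x"]), abs(y - ctr["y"])) <= r
        }
        if (inside) {
          out[i, 4] <- out[i, 4] + 1
          for (k in 1:3) out[i, k] <- out[i, k] + img$pixels[y + 1, x + 1, k]
        }
      }
    }
  }
  colnames(out) <- c("red_total", "green_total", "blue_total", "pixel_count")
  out
}

# closed-form OLS via the normal equations (kept independent of stats::lm)
ols_closed_form <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}
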