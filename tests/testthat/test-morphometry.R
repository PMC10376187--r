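make_lm <- function(A, B, C, D, E, F, G) {
  lm <- rbind(A = A, B = B, C = C, D = D, E = E, F = F, G = G)
  colnames(lm) <- c("x", "y")
  lm
}

single_slice_series <- function(lm, spacing = 0.04) {
  knee_series(list(list(image = NULL, landmarks = lm)),
              pixel_spacing = spacing, image_size = 512)
}

base_lm <- make_lm(A = c(256, 200), B = c(200, 180), C = c(310, 182),
                   D = c(100, 256), E = c(400, 256), F = c(180, 330),
                   G = c(330, 320))

test_that("TEA slice selection takes the longest epicondylar span", {
  lm <- base_lm
  series <- single_slice_series(lm)
  tea <- select_tea_slice(series)
  # D = (100,256), E = (400,256) at 0.04 cm/px -> 300 px -> 12 cm
  expect_equal(tea$length_cm, 12)
  expect_equal(tea$extreme_landmarks, c("D", "E"))
  # argmax across slices: widths 7.9, 8.2, 8.0 cm -> middle slice
  mk <- function(w_cm) {
    l <- lm; w <- w_cm / 0.04
    l["D", ] <- c(256 - w / 2, 256); l["E", ] <- c(256 + w / 2, 256)
    list(image = NULL, landmarks = l)
  }
  s3 <- knee_series(list(mk(7.9), mk(8.2), mk(8.0)), pixel_spacing = 0.04,
                    image_size = 512)
  expect_equal(select_tea_slice(s3)$slice_index, 2)
  expect_equal(select_tea_slice(s3)$length_cm, 8.2)
})

test_that("extreme-landmark selection matches a brute-force x-span scan", {
  set.seed(10)
  for (i in 1:50) {
    lm <- base_lm + matrix(rnorm(14, 0, 15), 7, 2)
    series <- single_slice_series(lm)
    tea <- select_tea_slice(series)
    i_med <- which.min(lm[, 1]); i_lat <- which.max(lm[, 1])
    expect_equal(tea$extreme_landmarks,
                 rownames(lm)[c(i_med, i_lat)])
    expect_equal(tea$length_cm,
                 sqrt(sum((lm[i_lat, ] - lm[i_med, ])^2)) * 0.04,
                 tolerance = 1e-12)
  }
})

test_that("TEA-PFA angle matches the arctangent oracle and edge cases", {
  tea_line <- list(p = c(0, 0), d = c(1, 0))
  lm <- base_lm
  lm["F", ] <- c(0, 0); lm["G", ] <- c(10, 0.875)
  expect_equal(tea_pfa_angle(lm, tea_line), atan(0.0875) * 180 / pi,
               tolerance = 1e-12)
  lm["G", ] <- c(10, 0)     # parallel
  expect_equal(tea_pfa_angle(lm, tea_line), 0)
  lm["G", ] <- c(0, 12)     # perpendicular
  expect_equal(tea_pfa_angle(lm, tea_line), 90)
  lm["G", ] <- lm["F", ]    # degenerate
  expect_error(tea_pfa_angle(lm, tea_line), "degenerate")
})

test_that("trough slice selection minimizes point-line distance", {
  mk <- function(ay) {
    l <- base_lm; l["A", ] <- c(256, 256 - ay)
    list(image = NULL, landmarks = l)
  }
  series <- knee_series(list(mk(3), mk(1.2), mk(2.5)), pixel_spacing = 0.04,
                        image_size = 512)
  tea_line <- list(p = c(100, 256), d = c(1, 0))
  expect_equal(select_trough_slice(series, tea_line), 2)
  # point on the line has distance zero
  expect_equal(patellometry:::point_line_distance(c(42, 256), tea_line), 0)
  # oracle: |cross(E - D, A - D)| / |E - D| on random points and lines
  set.seed(11)
  for (i in 1:200) {
    D <- runif(2, 0, 512); E <- runif(2, 0, 512); A <- runif(2, 0, 512)
    d <- E - D
    if (sqrt(sum(d^2)) < 1) next
    line <- list(p = D, d = d / sqrt(sum(d^2)))
    oracle <- abs(d[1] * (A[2] - D[2]) - d[2] * (A[1] - D[1])) /
      sqrt(sum(d^2))
    expect_equal(patellometry:::point_line_distance(A, line), oracle,
                 tolerance = 1e-9)
  }
})

test_that("asymmetry ratio projects onto the TEA and is monotone in the trough", {
  tea_line <- list(p = c(0, 5), d = c(1, 0))
  lm <- base_lm
  lm["B", ] <- c(1, 40); lm["A", ] <- c(2, 60); lm["C", ] <- c(3, 38)
  expect_equal(asymmetry_ratio(lm, tea_line), 0.5)
  lm["A", ] <- c(3, 55)   # groove on the lateral aspect -> 0
  expect_equal(asymmetry_ratio(lm, tea_line), 0)
  lm["A", ] <- c(1, 55)   # groove on the medial aspect -> 1
  expect_equal(asymmetry_ratio(lm, tea_line), 1)
  # monotone as the trough projection moves from C toward B
  vals <- sapply(seq(3, 1, length.out = 11), function(ax) {
    lm["A", ] <- c(ax, 50); asymmetry_ratio(lm, tea_line)
  })
  expect_true(all(diff(vals) > 0))
  lm["B", ] <- c(2, 40); lm["C", ] <- c(2, 38)
  expect_error(asymmetry_ratio(lm, tea_line), "degenerate")
})

test_that("asymmetry ratio equals the rotated-frame oracle for oblique TEAs", {
  set.seed(12)
  for (i in 1:100) {
    theta <- runif(1, -pi / 3, pi / 3)
    d <- c(cos(theta), sin(theta))
    tea_line <- list(p = runif(2, 0, 100), d = d)
    lm <- base_lm + matrix(rnorm(14, 0, 10), 7, 2)
    # oracle: rotate the frame so the TEA is horizontal, use x-coordinates
    R <- rbind(c(cos(-theta), -sin(-theta)), c(sin(-theta), cos(-theta)))
    rot <- function(p) as.vector(R %*% (p - tea_line$p))
    xa <- rot(lm["A", ])[1]; xb <- rot(lm["B", ])[1]; xc <- rot(lm["C", ])[1]
    oracle <- abs(xc - xa) / abs(xc - xb)
    expect_equal(asymmetry_ratio(lm, tea_line), oracle, tolerance = 1e-9)
  }
})

test_that("sulcus angle matches the dot-product oracle and is symmetric", {
  lm <- base_lm
  lm["B", ] <- c(0, 0); lm["A", ] <- c(2, 2); lm["C", ] <- c(4, 0)
  expect_equal(sulcus_angle(lm), 90)
  lm["A", ] <- c(2, 0)   # collinear, A between -> flat groove
  expect_equal(sulcus_angle(lm), 180)
  lm["B", ] <- c(10, 40); lm["A", ] <- c(80, 95); lm["C", ] <- c(150, 42)
  u <- lm["B", ] - lm["A", ]; v <- lm["C", ] - lm["A", ]
  oracle <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  expect_equal(sulcus_angle(lm), oracle, tolerance = 1e-12)
  # symmetric in B <-> C
  lm2 <- lm
  lm2["B", ] <- lm["C", ]; lm2["C", ] <- lm["B", ]
  expect_equal(sulcus_angle(lm2), sulcus_angle(lm))
  lm2["B", ] <- lm2["A", ]
  expect_error(sulcus_angle(lm2), "degenerate")
})

test_that("measure_knee composes the chain and handles single-slice series", {
  series <- single_slice_series(base_lm)
  m <- measure_knee(series)
  expect_equal(m$tea_slice, 1)
  expect_equal(m$trough_slice, 1)
  expect_s3_class(m, "knee_measurements")
  df <- as.data.frame(m)
  expect_named(df, c("series_id", "tea_length_cm", "tea_pfa_angle_deg",
                     "asymmetry_ratio", "sulcus_angle_deg", "tea_slice",
                     "trough_slice"))
})

test_that("measurements are invariant under rigid rotation and translation", {
  series <- varied_phantom(8, n_slices = 5L)
  m0 <- measurement_vector(measure_knee(series))
  ctr <- c(256, 256)
  for (theta_deg in c(-15, 8, 20)) {
    th <- theta_deg * pi / 180
    R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
    rigid <- transform_landmarks(series, function(p)
      as.vector(R %*% (p - ctr)) + ctr + c(20, -10))
    m1 <- measurement_vector(measure_knee(rigid))
    expect_equal(m1, m0, tolerance = 1e-9)
  }
})

test_that("identical results for predictions passed as annotation tables", {
  series <- generate_phantom(small_spec(seed = 31))
  ann <- series_annotations(series)
  rebuilt <- series_from_annotations(ann, pixel_spacing = series$pixel_spacing)
  expect_equal(measurement_vector(measure_knee(rebuilt)),
               measurement_vector(measure_knee(series)), tolerance = 1e-12)
})
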