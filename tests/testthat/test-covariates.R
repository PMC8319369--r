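test_that("zonal mean matches a brute-force cell loop", {
  vals <- matrix(5, 4, 4)
  zones <- matrix(rep(c("a", "b"), each = 8), 4, 4)
  expect_equal(unname(zonal_mean(vals, zones)), c(5, 5))

  vals2 <- matrix(c(2, 4, NA, 10), 2, 2)
  zones2 <- matrix(c("z", "z", "z", "w"), 2, 2)
  zm <- zonal_mean(vals2, zones2)
  expect_equal(unname(zm), c(10, 3))

  set.seed(14)
  vals3 <- matrix(rnorm(400), 20, 20)
  vals3[sample(400, 40)] <- NA
  zones3 <- matrix(sample(c("k1", "k2", "k3"), 400, TRUE), 20, 20)
  zm3 <- zonal_mean(vals3, zones3)
  # independent loop oracle
  for (z in c("k1", "k2", "k3")) {
    acc <- 0; nn <- 0
    for (i in 1:20) for (j in 1:20) {
      if (zones3[i, j] == z && !is.na(vals3[i, j])) {
        acc <- acc + vals3[i, j]; nn <- nn + 1
      }
    }
    expect_equal(unname(zm3[z]), acc / nn, tolerance = 1e-12)
  }
  # invariance to relabeling and cell permutation
  perm <- sample(400)
  expect_equal(unname(zm3),
               unname(zonal_mean(matrix(vals3[perm], 20, 20),
                                 matrix(zones3[perm], 20, 20))))
  expect_error(zonal_mean(vals3, zones3[1:10, ]), "shape")
  zones_gap <- zones3
  zones_gap[is.na(vals3)] <- "k1"
  zones_gap[!is.na(vals3)] <- "k2"
  expect_warning(zonal_mean(vals3, zones_gap), "omitted")
})

test_that("plain-text grids round-trip through the reader", {
  f <- tempfile(fileext = ".grid")
  writeLines(c("2 3 -9999",
               "1.5 2.5 -9999",
               "4 5 6"), f)
  m <- read_grid(f)
  expect_equal(dim(m), c(2L, 3L))
  expect_true(is.na(m[1, 3]))
  expect_equal(m[1, 1:2], c(1.5, 2.5))
  fz <- tempfile(fileext = ".grid")
  writeLines(c("2 3 -9999", "a a -9999", "b b b"), fz)
  z <- read_grid(fz, character = TRUE)
  expect_true(is.na(z[1, 3]))
  expect_equal(unname(zonal_mean(m, z)), c(2, 5))
  unlink(c(f, fz))
})

test_that("urban population share is the urban-extent population fraction", {
  pop <- matrix(c(100, 300, 50, 50), 2, 2)
  zones <- matrix("c1", 2, 2)
  all_urban <- matrix("urban", 2, 2)
  all_rural <- matrix("rural", 2, 2)
  expect_equal(unname(urban_population_share(pop, all_urban, zones)), 1)
  expect_equal(unname(urban_population_share(pop, all_rural, zones)), 0)

  mixed <- matrix(c("urban", "rural", "rural", "rural"), 2, 2)
  expect_equal(unname(urban_population_share(
    matrix(c(100, 300, 0, 0), 2, 2), mixed, zones)), 0.25)
  # peri-urban counts as urban extent
  peri <- matrix(c("peri-urban", "rural", "rural", "rural"), 2, 2)
  expect_equal(unname(urban_population_share(
    matrix(c(100, 300, 0, 0), 2, 2), peri, zones)), 0.25)
  expect_error(urban_population_share(pop, matrix("suburb", 2, 2), zones),
               "unknown settlement")
  expect_warning(urban_population_share(matrix(0, 2, 2), all_urban, zones),
                 "zero total")
})

test_that("collinearity screen keeps temperature as the climate representative", {
  set.seed(31)
  n <- 500
  temperature <- runif(n, 15, 29)
  x <- data.frame(
    temperature = temperature,
    aridity = 250 - 8 * temperature + rnorm(n, 0, 5),
    precipitation = 300 - 10 * temperature + rnorm(n, 0, 8),
    evi = 5000 - 150 * temperature + rnorm(n, 0, 120),
    poverty = runif(n),
    school_holidays = sample(0:31, n, TRUE)
  )
  scr <- collinearity_screen(x)
  expect_setequal(scr$retained,
                  c("temperature", "poverty", "school_holidays"))
  expect_setequal(scr$dropped$variable,
                  c("aridity", "precipitation", "evi"))
  expect_true(all(scr$dropped$representative == "temperature"))
  expect_true(all(abs(scr$dropped$r) >= 0.7))

  # orthogonal covariates are all retained
  set.seed(32)
  ortho <- as.data.frame(matrix(rnorm(300), 100, 3))
  expect_setequal(collinearity_screen(ortho)$retained, names(ortho))

  # correlations match the hand-coded covariance formula
  a <- x$temperature; b <- x$aridity
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(scr$correlation["temperature", "aridity"], r_oracle,
               tolerance = 1e-12)

  # constant covariate flagged and excluded
  x$flat <- 1
  expect_warning(scr2 <- collinearity_screen(x), "constant")
  expect_equal(scr2$constant, "flat")
  expect_false("flat" %in% scr2$retained)
})

test_that("holiday-climate independence test controls its error rate", {
  # perfectly linear pair -> significant
  lin <- data.frame(school_holidays = 1:50, temperature = 2 * (1:50) + 3)
  expect_true(holiday_temperature_independence(lin)$significant)

  # Bonferroni: adjusted p = min(1, m p)
  set.seed(41)
  multi <- data.frame(school_holidays = rnorm(100),
                      temperature = rnorm(100), aridity = rnorm(100),
                      evi = rnorm(100))
  rep <- holiday_temperature_independence(multi)
  expect_equal(rep$p_adjusted, pmin(1, 3 * rep$p))

  # type-I error under independence: non-significant in >= 94% of replicates
  set.seed(42)
  hits <- vapply(1:100, function(i) {
    d <- data.frame(school_holidays = rnorm(1000), temperature = rnorm(1000))
    holiday_temperature_independence(d)$significant
  }, logical(1))
  expect_gte(mean(!hits), 0.94)
  expect_error(holiday_temperature_independence(
    data.frame(school_holidays = 1:2, temperature = 1:2)), "three")
})
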