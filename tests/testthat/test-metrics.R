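test_that("trip classification partitions flows into the three classes", {
  meta <- kenya_region_metadata()
  rec <- data.frame(origin_id = c("nairobi", "nairobi", "nairobi"),
                    dest_id = c("nairobi", "mombasa", "TZ"))
  expect_equal(classify_trip(rec, meta),
               c("within_county", "domestic", "international"))
  expect_error(classify_trip(data.frame(origin_id = "atlantis",
                                        dest_id = "nairobi"), meta),
               "unresolvable")
  # partition property: class totals sum to the panel total
  set.seed(9)
  panel <- data.frame(
    origin_id = sample(meta$region_id, 300, TRUE),
    dest_id = sample(c(meta$region_id, "TZ", "UG"), 300, TRUE),
    count = rpois(300, 50))
  cls <- classify_trip(panel, meta)
  expect_equal(sum(tapply(panel$count, cls, sum)), sum(panel$count))
})

test_that("total outward flow sums all destinations for the period", {
  panel <- data.frame(origin_id = "nairobi",
                      dest_id = c("mombasa", "kiambu"),
                      year = 2018, month = 3, count = c(200, 300))
  expect_equal(total_outward_flow(panel, "nairobi", 2018, 3), 500)
  expect_equal(total_outward_flow(panel[2:1, ], "nairobi", 2018, 3), 500)
  expect_warning(z <- total_outward_flow(panel, "nairobi", 2018, 4),
                 "no records")
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "no_records"))
  # within-county flows included by default, excludable by flag
  panel2 <- rbind(panel, data.frame(origin_id = "nairobi",
                                    dest_id = "nairobi", year = 2018,
                                    month = 3, count = 1000))
  expect_equal(total_outward_flow(panel2, "nairobi", 2018, 3), 1500)
  expect_equal(total_outward_flow(panel2, "nairobi", 2018, 3,
                                  include_within = FALSE), 500)
})

test_that("change ratios are flows relative to the January baseline", {
  # February flow double the January flow -> ratio exactly 2
  panel <- simple_panel("nairobi", 2019, c(1000, 2000))
  ch <- compute_change_ratios(panel)
  expect_identical(ch$ratio[ch$month == 2], 2)
  expect_identical(ch$ratio[ch$month == 1], 1)

  # all months equal -> all ratios 1
  flat <- compute_change_ratios(simple_panel("a", 2018, rep(700, 12)))
  expect_true(all(flat$ratio == 1))

  # scale invariance: multiplying a county's flows by k leaves ratios alone
  ch_scaled <- compute_change_ratios(
    transform(panel, count = count * 17.3))
  expect_equal(ch_scaled$ratio, ch$ratio)

  # zero baseline county-years are excluded and reported
  two <- rbind(simple_panel("a", 2018, c(100, 150)),
               simple_panel("b", 2018, c(0, 400)))
  expect_warning(ch2 <- compute_change_ratios(two), "baseline")
  expect_equal(unique(ch2$region_id), "a")
  expect_equal(attr(ch2, "excluded")$region_id, "b")
})

test_that("a complete 47-county two-year panel yields 1128 observations", {
  g <- kenya_graph()
  grid <- expand.grid(origin_id = g$region_ids, year = 2018:2019,
                      month = 1:12, stringsAsFactors = FALSE)
  grid$dest_id <- grid$origin_id
  set.seed(21)
  grid$count <- runif(nrow(grid), 1e4, 1e5)
  ch <- compute_change_ratios(grid)
  expect_equal(nrow(ch), 1128L)
  expect_equal(sum(ch$month == 1), 94L)
  expect_true(all(ch$ratio[ch$month == 1] == 1))
})

test_that("province OD matrix conserves totals and yields shares", {
  meta <- kenya_region_metadata()
  grouping <- data.frame(region_id = meta$region_id,
                         group_id = meta$province_id)
  one <- data.frame(origin_id = "kiambu", dest_id = "nyeri", year = 2018,
                    month = 1, count = 50)
  m1 <- od_matrix_by_region_group(one, grouping)
  expect_equal(dim(m1), c(8L, 8L))
  expect_equal(m1["central", "central"], 50)
  expect_equal(sum(m1), 50)

  set.seed(3)
  panel <- data.frame(
    origin_id = sample(meta$region_id, 500, TRUE),
    dest_id = sample(meta$region_id, 500, TRUE),
    year = 2018, month = 1, count = rpois(500, 40))
  m <- od_matrix_by_region_group(panel, grouping)
  expect_equal(sum(m), sum(panel$count))
  expect_error(od_matrix_by_region_group(
    data.frame(origin_id = "narnia", dest_id = "nyeri", count = 1),
    grouping), "not covered")

  sh <- outward_share(m, "nairobi")
  expect_equal(sum(sh), 1)
  tri <- matrix(c(50, 25, 25, 0, 80, 0, 0, 0, 1), 3, 3, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_equal(unname(outward_share(tri, "a")), c(0.5, 0.25, 0.25))
  expect_equal(unname(outward_share(tri, "b")), c(0, 1, 0))
  expect_equal(sh, outward_share(m * 3.7, "nairobi"))
  zero <- matrix(0, 2, 2, dimnames = list(c("p", "q"), c("p", "q")))
  expect_error(outward_share(zero, "p"), "undefined")
})
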