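make_ts <- function(start, n, res_min, value = 10, site = "s",
                    var = "doobs_nwis") {
  t <- as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1L) * res_min * 60
  stream_ts(site, var, t, rep_len(value, n))
}

test_that("resolution splitting separates persistent chunks only", {
  expect_length(split_by_resolution(make_ts("2015-01-01", 500, 15)), 1L)

  # hourly then 15-min (persistent change)
  t1 <- as.POSIXct("2015-01-01", tz = "UTC") + (0:(72 - 1)) * 3600
  t2 <- max(t1) + (1:192) * 900
  ts <- stream_ts("s", "doobs_nwis", c(t1, t2), rep(8, 72 + 192))
  ch <- split_by_resolution(ts)
  expect_length(ch, 2L)
  expect_equal(ch[[1]]$resolution, 60)
  expect_equal(ch[[2]]$resolution, 15)

  # 60/30/60 with known boundaries
  ta <- as.POSIXct("2015-01-01", tz = "UTC") + (0:47) * 3600
  tb <- max(ta) + (1:96) * 1800
  tc <- max(tb) + (1:48) * 3600
  ch3 <- split_by_resolution(stream_ts("s", "doobs_nwis", c(ta, tb, tc),
                                       rep(8, 48 + 96 + 48)))
  expect_length(ch3, 3L)
  expect_equal(vapply(ch3, function(x) x$resolution, numeric(1)),
               c(60, 30, 60))
  expect_equal(nrow(ch3[[1]]$data), 48L)
  expect_equal(nrow(ch3[[2]]$data), 96L)

  # an isolated missing timestamp does not define a new chunk
  tt <- as.POSIXct("2015-01-01", tz = "UTC") + (0:199) * 900
  tt <- tt[-50]
  expect_length(split_by_resolution(stream_ts("s", "doobs_nwis", tt,
                                              rep(8, 199))), 1L)
})

# a 4-day synthetic site is the base fixture for the merge/filter rules
base_site <- function(gaps = list(), seed = 11, ...) {
  generate_site(synthetic_site_config(seed = seed, n_days = 4, gaps = gaps,
                                      ...))
}

test_that("gap-free inputs yield all-valid days and exact interpolation at original points", {
  g <- base_site()
  prep <- prepare_model_input(g$site, g$raws)
  expect_length(prep, 1L)
  v <- prep[[1]]$validity
  expect_true(all(v$valid))
  expect_true(all(v$reason == "none"))
  inp <- prep[[1]]$input
  ti <- g$truth$input
  m <- match(as.numeric(inp$solar.time), as.numeric(ti$solar.time))
  expect_false(anyNA(m))
  for (cn in c("DO.obs", "DO.sat", "depth", "temp.water", "light",
               "discharge"))
    expect_equal(inp[[cn]], ti[[cn]][m], tolerance = 1e-12)
})

test_that("a 2-hour gap is filled but a 4-hour gap excludes the whole day", {
  g2 <- base_site(gaps = list(list(variable = "wtr", day = 2,
                                   start_hour = 10, duration_hours = 2)))
  v2 <- prepare_model_input(g2$site, g2$raws)[[1]]$validity
  expect_true(all(v2$valid))

  g4 <- base_site(gaps = list(list(variable = "disch", day = 3,
                                   start_hour = 9, duration_hours = 4)))
  v4 <- prepare_model_input(g4$site, g4$raws)[[1]]$validity
  expect_equal(v4$valid, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(v4$reason[3], "gap>3h")
})

test_that("oxygen gaps appear as missing rows and each invalid day has one primary reason", {
  g <- base_site(gaps = list(list(variable = "doobs", day = 2,
                                  start_hour = 12, duration_hours = 2)))
  prep <- prepare_model_input(g$site, g$raws)[[1]]
  expect_true(all(prep$validity$valid))
  d2 <- prep$input[prep$input$date == g$truth$daily$date[2], ]
  expect_equal(sum(is.na(d2$DO.obs)), 8L)  # 2 h at 15 min
  expect_false(anyNA(d2$temp.water))
  expect_true(all(table(prep$validity$date) == 1L))
})

test_that("merging conserves oxygen observations across valid and invalid days", {
  g <- base_site(gaps = list(list(variable = "sw", day = 2,
                                  start_hour = 8, duration_hours = 5)))
  prep <- prepare_model_input(g$site, g$raws)[[1]]
  expect_equal(prep$validity$reason[2], "gap>3h")
  expect_equal(sum(!is.na(prep$input$DO.obs)),
               nrow(g$raws$doobs$data))
})

test_that("merging an already-merged gap-free table returns it unchanged", {
  g <- base_site()
  ti <- g$truth$input
  lon <- g$site$longitude
  utc <- ti$solar.time - lon * 240
  as_ts <- function(v, var) stream_ts("s", var, utc, ti[[v]])
  merged <- merge_and_interpolate(
    as_ts("DO.obs", "doobs_nwis"),
    others = list(DO.sat = as_ts("DO.sat", "dosat"),
                  depth = as_ts("depth", "depth"),
                  temp.water = as_ts("temp.water", "wtr"),
                  light = as_ts("light", "par"),
                  discharge = as_ts("discharge", "disch")),
    longitude = lon)
  expect_true(all(merged$validity$valid))
  for (cn in c("DO.obs", "DO.sat", "depth", "temp.water", "light",
               "discharge"))
    expect_equal(merged$input[[cn]], ti[[cn]], tolerance = 1e-12)
})

test_that("days without entirely positive flow are excluded", {
  g <- base_site()
  prep <- prepare_model_input(g$site, g$raws)[[1]]
  v0 <- filter_positive_flow(prep$input, prep$validity)
  expect_equal(v0, prep$validity)  # all Q > 0: unchanged

  # one zero reading at 14:00 solar on day 2
  for (qval in c(0, -0.5)) {
    inp <- prep$input
    hit <- inp$date == prep$validity$date[2] &
      format(inp$solar.time, "%H:%M") == "14:00"
    expect_true(any(hit))
    inp$discharge[hit] <- qval
    v <- filter_positive_flow(inp, prep$validity)
    expect_equal(v$valid, c(TRUE, FALSE, TRUE, TRUE))
    expect_equal(v$reason[2], "nonpositive_flow")
  }
})

test_that("days at chunk edges with incomplete windows are flagged", {
  g <- base_site()
  o2 <- g$raws$doobs
  # drop the first 3 hours: the first day window is no longer complete
  keep <- o2$data$DateTime >= o2$data$DateTime[1] + 3 * 3600
  raws <- g$raws
  raws$doobs <- stream_ts(o2$site_id, o2$variable, o2$data$DateTime[keep],
                          o2$data$value[keep])
  v <- prepare_model_input(g$site, raws)[[1]]$validity
  expect_false(v$valid[1])
  expect_equal(v$reason[1], "incomplete_window")
  expect_true(all(v$valid[-1]))
})
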