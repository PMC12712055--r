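test_that("localization tables round-trip through the CSV dialect", {
  cfg <- synth_minflux_config(n_trimers = 4, seed = 31)
  ds <- generate_minflux_dataset(cfg)
  f <- tempfile(fileext = ".csv")
  write_localizations(ds$localizations, f)
  back <- read_localizations(f)
  expect_equal(nrow(back), nrow(ds$localizations))
  expect_equal(back, ds$localizations, tolerance = 1e-12)
})

test_that("malformed localization files produce informative errors", {
  f <- tempfile(fileext = ".csv")
  ok <- data.frame(tid = 1:5, x_nm = 1:5, y_nm = 1:5, z_nm = 1:5,
                   cfr = 0.1, efo = 50, t_s = 1:5)
  utils::write.csv(ok, f, row.names = FALSE)
  expect_equal(nrow(read_localizations(f)), 5)

  utils::write.csv(ok[setdiff(names(ok), "z_nm")], f, row.names = FALSE)
  expect_error(read_localizations(f), "z_nm")

  bad <- ok
  bad$x_nm <- as.character(bad$x_nm)
  bad$x_nm[3] <- "oops"
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(read_localizations(f), "x_nm.*line.*4")

  expect_error(read_localizations(tempfile()), "not found")
})

test_that("quality filter removes high-cfr and high-efo localizations", {
  locs <- make_locs(1:8, x = 1:8, y = 1:8, z = 1:8,
                    cfr = c(0.1, 0.9, 0.79, 0.81, 0.5, 0.2, 0.3, 0.0),
                    efo = c(50, 50, 50, 50, 900, 60, 70, 80))
  out <- filter_quality(locs, filter_config(efo_max = 100))
  # cfr 0.9 and 0.81 fail the 0.8 cutoff; efo 900 fails the absolute cutoff
  expect_equal(out$tid, c(1L, 3L, 6L, 7L, 8L))
  expect_equal(attr(out, "removed_cfr"), 2)
  expect_equal(attr(out, "removed_efo"), 1)

  clean <- make_locs(1:5, 1:5, 1:5, 1:5, cfr = 0, efo = 10)
  expect_equal(nrow(filter_quality(clean, filter_config(efo_max = 100))), 5)
})

test_that("default efo cutoff is the dataset 95th percentile", {
  locs <- make_locs(1:100, x = 1:100, y = 1:100, z = 1:100, cfr = 0.1,
                    efo = seq_len(100))
  out <- filter_quality(locs, filter_config())
  expect_equal(attr(out, "efo_cutoff"),
               unname(quantile(seq_len(100), 0.95)))
  expect_equal(nrow(out), sum(seq_len(100) <= quantile(seq_len(100), 0.95)))
})

test_that("trace grouping partitions by TID", {
  locs <- make_locs(c(2, 1, 2, 1, 2, 1), x = 1:6, y = 1:6, z = 1:6)
  tr <- group_traces(locs)
  expect_equal(n_traces(tr), 2)
  expect_equal(tr$tid, c(1, 1, 1, 2, 2, 2))

  expect_equal(n_traces(group_traces(locs[0, ])), 0)

  set.seed(1)
  rand <- make_locs(sample(1:37, 400, replace = TRUE), rnorm(400),
                    rnorm(400), rnorm(400))
  expect_equal(n_traces(group_traces(rand)), length(unique(rand$tid)))
})

test_that("trace filter excludes dispersed or under-sampled traces", {
  # trace 1: only 2 localizations -> excluded
  # trace 2: x-axis sample SD 10.5 -> excluded (any-axis rule)
  # trace 3: identical coordinates, SD 0 -> kept
  # trace 4: x-axis sample SD exactly 10 -> kept (strict >)
  locs <- rbind(
    make_locs(1, x = c(0, 1), y = c(0, 1), z = c(0, 1)),
    make_locs(2, x = c(-10.5, 0, 10.5), y = c(0, 0, 0), z = c(0, 0, 0)),
    make_locs(3, x = c(5, 5, 5), y = c(5, 5, 5), z = c(5, 5, 5)),
    make_locs(4, x = c(-10, 0, 10), y = c(0, 0, 0), z = c(0, 0, 0)))
  expect_equal(sd(c(-10, 0, 10)), 10)  # construction check for trace 4
  out <- filter_traces(group_traces(locs), filter_config())
  expect_setequal(unique(out$tid), c(3, 4))
  expect_equal(attr(out, "removed_short"), 1)
  expect_equal(attr(out, "removed_sd"), 1)
})

test_that("trimming drops the first localizations in time order", {
  locs <- make_locs(1, x = 1:5, y = 1:5, z = 1:5)
  locs$t_s <- c(3, 1, 2, 5, 4)  # scrambled acquisition times
  tr <- group_traces(locs)
  out <- trim_traces(tr, filter_config())
  # the two earliest (t = 1, 2, i.e. x = 2, 3) are dropped
  expect_equal(sort(out$x_nm), c(1, 4, 5))

  three <- group_traces(make_locs(7, x = 1:3, y = 1:3, z = 1:3))
  out3 <- trim_traces(three, filter_config())
  expect_equal(nrow(out3), 1)
  expect_equal(n_traces(out3), 1)  # trace retained with its last localization

  expect_equal(trim_traces(tr, filter_config(trim_head = 0)), tr)
})

test_that("z-scaling corrects only the axial coordinate", {
  locs <- group_traces(make_locs(1, x = 1:3, y = 4:6, z = c(10, 0, -20)))
  out <- apply_z_scaling(locs, filter_config())
  expect_equal(out$z_nm, c(7, 0, -14))
  expect_equal(out$x_nm, locs$x_nm)
  expect_equal(out$y_nm, locs$y_nm)
  expect_equal(apply_z_scaling(locs, filter_config(z_scale = 1)), locs)
})

test_that("trace centers equal the unweighted coordinate mean", {
  tr <- group_traces(make_locs(1, x = c(0, 2), y = c(0, 2), z = c(0, 2)))
  ct <- trace_centers(tr)
  expect_equal(unname(unlist(ct[, c("x_nm", "y_nm", "z_nm")])), c(1, 1, 1))
  expect_equal(ct$n_locs, 2L)

  single <- group_traces(make_locs(2, x = 3.3, y = -1, z = 0.5))
  expect_equal(unname(unlist(trace_centers(single)[, 2:4])), c(3.3, -1, 0.5))

  set.seed(4)
  pts <- make_locs(9, rnorm(10), rnorm(10), rnorm(10))
  ct <- trace_centers(group_traces(pts))
  expect_equal(unname(unlist(ct[, 2:4])),
               unname(colMeans(pts[, c("x_nm", "y_nm", "z_nm")])))
})

test_that("row permutations within a TID do not change trace centers", {
  cfg <- synth_minflux_config(n_trimers = 5, seed = 12)
  locs <- generate_minflux_dataset(cfg)$localizations
  set.seed(2)
  shuffled <- locs[sample(nrow(locs)), ]
  a <- filter_pipeline(locs)$centers
  b <- filter_pipeline(shuffled)$centers
  expect_equal(a[order(a$tid), ], b[order(b$tid), ], ignore_attr = TRUE)
})

test_that("tightening cutoffs never increases survivors", {
  cfg <- synth_minflux_config(n_trimers = 15, seed = 8)
  locs <- generate_minflux_dataset(cfg)$localizations
  n_locs <- function(cfr_max, max_sd) {
    nrow(filter_pipeline(locs, filter_config(cfr_max = cfr_max,
                                             max_axis_sd = max_sd))$localizations)
  }
  for (cfr in c(0.8, 0.6, 0.4, 0.2)) {
    expect_lte(n_locs(cfr, 10), n_locs(0.9, 10))
  }
  expect_lte(n_locs(0.8, 5), n_locs(0.8, 10))
  expect_lte(n_locs(0.8, 2), n_locs(0.8, 5))
})
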