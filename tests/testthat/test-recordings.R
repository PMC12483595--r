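test_that("sampling rate is derived from conversion time", {
  expect_equal(acquisition(0.060)$sampling_rate, 1 / 0.060)
  expect_equal(round(acquisition(0.060)$sampling_rate), 17)
  for (ct in c(0.001, 0.02, 0.060, 0.5, 3)) {
    expect_equal(acquisition(ct)$sampling_rate * ct, 1, tolerance = 1e-12)
  }
  expect_error(acquisition(0), "positive")
})

test_that("recording sets round-trip through the csv layout", {
  set.seed(42)
  rs <- recording_set(
    lapply(1:3, function(i) {
      x <- rnorm(50) * 1e-5
      x[c(7, 8, 31)] <- NA
      x
    }),
    channel_id = c("a", "b", "c"),
    inoculated = c(TRUE, TRUE, FALSE),
    treatment = c("voriconazole", "water_control", "none"),
    induction_time = c(1.2, 1.2, NA),
    acq = acquisition(0.060, start_time = 5),
    experiment_id = "rt-test"
  )
  f <- withr::local_tempfile(fileext = ".csv")
  write_recording_set(rs, f)
  back <- read_recording_set(f)

  expect_equal(back$channel_id, rs$channel_id)
  expect_equal(back$inoculated, rs$inoculated)
  expect_equal(back$treatment, rs$treatment)
  expect_equal(back$induction_time, rs$induction_time)
  expect_equal(experiment_id(back), "rt-test")
  expect_equal(acq(back)$conversion_time, 0.060)
  expect_equal(acq(back)$start_time, 5)
  expect_equal(sampling_rate(back), 1 / 0.060)
  for (i in 1:3) {
    expect_equal(which(is.na(back$samples[[i]])), which(is.na(rs$samples[[i]])))
    expect_equal(back$samples[[i]], rs$samples[[i]], tolerance = 1e-8)
  }
})

test_that("read-back sampling rate equals 1/conversion_time for any conversion time", {
  f <- withr::local_tempfile(fileext = ".csv")
  for (ct in c(0.01, 0.060, 0.25)) {
    rs <- recording_set(list(seq(0, 1e-4, length.out = 1000)), acq = acquisition(ct))
    write_recording_set(rs, f)
    expect_equal(sampling_rate(read_recording_set(f)), 1 / ct, tolerance = 1e-9)
  }
})

test_that("a constructed csv with an empty cell yields one missing marker", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "# mycovolt-recordings v1",
    "# experiment_id: tiny",
    "# conversion_time: 0.06",
    "# start_time: 0",
    "# channel: id=u inoculated=TRUE treatment=none induction_time=NA",
    "# channel: id=v inoculated=FALSE treatment=none induction_time=NA",
    "u,v",
    "1e-6,2e-6",
    "1e-6,",
    "1e-6,2e-6",
    "1e-6,2e-6",
    "1e-6,2e-6"
  ), f)
  rs <- read_recording_set(f)
  expect_equal(nrow(rs), 2)
  expect_equal(rs$n_samples, c(5L, 5L))
  expect_false(anyNA(rs$samples[[1]]))
  expect_equal(which(is.na(rs$samples[[2]])), 2L)
})

test_that("empty and eight-channel sets write and read back", {
  f <- withr::local_tempfile(fileext = ".csv")
  empty <- recording_set(list(), channel_id = character())
  write_recording_set(empty, f)
  expect_equal(nrow(read_recording_set(f)), 0)

  fpc <- recording_set(lapply(1:8, function(i) rep(i * 1e-6, 10)))
  write_recording_set(fpc, f)
  expect_equal(nrow(read_recording_set(f)), 8)
})

test_that("malformed layouts raise structured errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# mycovolt-recordings v1", "# experiment_id: x",
               "# start_time: 0"), f)
  expect_error(read_recording_set(f), "conversion_time")
  writeLines(c("a,b", "1,2"), f)
  expect_error(read_recording_set(f), "signature")
  expect_error(read_recording_set(tempfile()), "no such file")
  expect_error(read_recording_set(f, format = "hdf5"), "not supported")
})

test_that("construction enforces the container invariants", {
  expect_error(
    recording_set(list(a = 1:3 * 1e-6, b = 1:4 * 1e-6)),
    "inconsistent lengths.*a=3.*b=4"
  )
  expect_error(
    recording_set(list(rep(1e-6, 10)), induction_time = 100),
    "induction_time outside"
  )
  expect_error(
    recording_set(list(rep(1e-6, 10)), treatment = "bleach"),
    "unknown treatment"
  )
  expect_warning(
    recording_set(list(rep(2, 10))),
    "implausibly large"
  )
})

test_that("dplyr verbs and subsetting keep the acquisition metadata", {
  rs <- recording_set(list(a = rep(1e-6, 5), b = rep(2e-6, 5)),
                      inoculated = c(TRUE, FALSE), acq = acquisition(0.02))
  sub <- rs[rs$inoculated, ]
  expect_s3_class(sub, "myco_recordings")
  expect_equal(sampling_rate(sub), 50)
  filtered <- dplyr::filter(rs, !inoculated)
  expect_equal(sampling_rate(filtered), 50)
  expect_equal(filtered$channel_id, "b")
})
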