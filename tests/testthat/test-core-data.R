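test_that("Sorting enforces its invariants", {
  expect_error(Sorting(list(a = c(10, 10, 20)), 30000), "duplicate")
  expect_error(Sorting(list(a = c(10.5)), 30000), "integers")
  expect_error(Sorting(list(a = c(-1, 5)), 30000), "non-negative")
  expect_error(Sorting(list(a = 1, a = 2), 30000), "unique")
  expect_warning(s <- Sorting(list(a = c(100, 50)), 30000), "not sorted")
  expect_identical(spike_train(s, "a"), c(50, 100))
  sf <- Sorting(list(a = c(1, 2)), 30000,
                spike_features = list(a = list(amp = c(-80, -90))))
  expect_identical(sf$spike_features$a$amp, c(-80, -90))
  expect_error(Sorting(list(a = c(1, 2)), 30000,
                       spike_features = list(a = list(amp = 1))), "length")
})

test_that("sorting CSV and NPZ round-trips are the identity", {
  s <- Sorting(list(u1 = c(0, 100, 25000), u2 = c(5, 7), empty = numeric(0)),
               sampling_frequency = 30000)
  for (fmt in c("csv", "npz")) {
    p <- tempfile(fileext = paste0(".", fmt))
    write_sorting(s, p)
    s2 <- read_sorting(p)
    if (fmt == "npz") {
      expect_identical(unit_ids(s2), unit_ids(s))
      expect_identical(spike_train(s2, "empty"), numeric(0))
    } else {
      expect_identical(unit_ids(s2), unit_ids(s)[1:2])  # empty unit drops in csv
    }
    expect_identical(spike_train(s2, "u1"), spike_train(s, "u1"))
    expect_identical(spike_train(s2, "u2"), spike_train(s, "u2"))
    expect_equal(s2$sampling_frequency, 30000)
  }
})

test_that("sorting files are byte-stable and empty sortings are writable", {
  s <- Sorting(list(a = c(1, 2, 3)), 20000)
  p1 <- tempfile(fileext = ".npz"); p2 <- tempfile(fileext = ".npz")
  write_sorting(s, p1); write_sorting(s, p2)
  expect_identical(readBin(p1, raw(), file.size(p1)),
                   readBin(p2, raw(), file.size(p2)))
  e <- Sorting(list(), 10000)
  pe <- tempfile(fileext = ".csv")
  write_sorting(e, pe)
  expect_identical(n_units(read_sorting(pe)), 0L)
  pz <- tempfile(fileext = ".npz")
  write_sorting(e, pz)
  expect_identical(n_units(read_sorting(pz)), 0L)
})

test_that("unsorted CSV input is sorted with a warning, duplicates error", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("# sampling_frequency=30000", "unit_id,frame",
               "1,100", "1,50"), p)
  expect_warning(s <- read_sorting(p), "not sorted")
  expect_identical(spike_train(s, "1"), c(50, 100))
  writeLines(c("# sampling_frequency=30000", "unit_id,frame",
               "1,100", "1,100"), p)
  expect_error(suppressWarnings(read_sorting(p)), "unit '1': duplicate")
  expect_error(read_sorting(tempfile(fileext = ".csv")), "not found")
})

test_that("write/read round-trip is the identity on randomized sortings", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(0:6, 1)
    trains <- lapply(seq_len(n), function(j) random_train(sample(0:40, 1), 100000L))
    names(trains) <- if (n > 0) paste0("u", seq_len(n)) else character(0)
    s <- Sorting(trains, sampling_frequency = sample(c(10000, 30000), 1))
    p <- tempfile(fileext = sample(c(".csv", ".npz"), 1))
    write_sorting(s, p)
    s2 <- read_sorting(p)
    nonempty <- names(trains)[vapply(trains, length, 1L) > 0]
    if (grepl("npz$", p)) {
      expect_identical(s2$spike_trains, s$spike_trains)
    } else {
      expect_identical(s2$spike_trains[nonempty], s$spike_trains[nonempty])
    }
    expect_equal(s2$sampling_frequency, s$sampling_frequency)
  }
})

write_test_recording <- function(dir, values, nch = 4L, fs = 30000,
                                 dtype = "int16", gain = 1) {
  bin <- file.path(dir, "rec.bin")
  con <- file(bin, "wb")
  if (dtype == "int16") {
    writeBin(as.integer(values), con, size = 2L, endian = "little")
  } else {
    writeBin(as.numeric(values), con, size = 8L, endian = "little")
  }
  close(con)
  jsonlite::write_json(list(dtype = dtype, num_channels = nch,
                            sampling_frequency = fs, gain_to_uV = gain,
                            offset = 0),
                       paste0(bin, ".json"), auto_unbox = TRUE)
  probe <- file.path(dir, "probe.csv")
  writeLines(c("channel_id,x,y",
               paste0("ch", seq_len(nch), ",0,", seq_len(nch) * 20)), probe)
  list(bin = bin, probe = probe)
}

test_that("flat binary recordings read lazily and slice correctly", {
  dir <- tempfile(); dir.create(dir)
  f <- write_test_recording(dir, rep(0L, 4 * 1000))
  rec <- read_recording(f$bin, f$probe)
  expect_equal(rec$num_frames, 1000)
  expect_equal(unname(get_traces(rec, start_frame = 0, end_frame = 10)),
               matrix(0, 4, 10))

  # non-trivial values: frame-major layout, compare lazy slices to an eager
  # reference read of the whole file
  vals <- seq_len(4 * 50)
  f2 <- write_test_recording(dir, vals, gain = 0.5)
  rec2 <- read_recording(f2$bin, f2$probe)
  eager <- matrix(vals, 4, 50) * 0.5
  expect_equal(unname(get_traces(rec2)), eager)
  expect_equal(unname(get_traces(rec2, channel_ids = "ch2",
                                 start_frame = 10, end_frame = 20)),
               eager[2, 11:20, drop = FALSE])
  # disjoint ranges concatenate to the full read
  expect_equal(cbind(get_traces(rec2, start_frame = 0, end_frame = 17),
                     get_traces(rec2, start_frame = 17, end_frame = 50)),
               get_traces(rec2))
  # channel order preserved as requested
  expect_equal(unname(get_traces(rec2, channel_ids = c("ch3", "ch1"),
                                 start_frame = 0, end_frame = 5)),
               eager[c(3, 1), 1:5])
})

test_that("recording header/probe mismatches are rejected", {
  dir <- tempfile(); dir.create(dir)
  f <- write_test_recording(dir, rep(0L, 4 * 100))
  bad_probe <- file.path(dir, "bad_probe.csv")
  writeLines(c("channel_id,x,y", "a,0,0", "b,0,20", "c,0,40"), bad_probe)
  expect_error(read_recording(f$bin, bad_probe), "3 channels")
  hdr <- jsonlite::read_json(paste0(f$bin, ".json"), simplifyVector = TRUE)
  hdr$dtype <- "complex128"
  jsonlite::write_json(hdr, paste0(f$bin, ".json"), auto_unbox = TRUE)
  expect_error(read_recording(f$bin, f$probe), "dtype")
})

test_that("provenance dump/restore reproduces objects exactly", {
  s <- generate_gt_sorting(n_units = 3, duration = 10, seed = 7)
  rec1 <- restore_provenance(dump_provenance(s))
  expect_identical(rec1$spike_trains, s$spike_trains)

  # serialization round-trip through JSON
  p <- tempfile(fileext = ".json")
  write_provenance(dump_provenance(s), p)
  s2 <- restore_provenance(p)
  expect_identical(s2$spike_trains, s$spike_trains)

  # a processed chain records its stages in order
  gt <- generate_gt_sorting(n_units = 2, duration = 1, seed = 1)
  rec <- synthesize_recording(gt, noise_sd = 5, seed = 2)
  chain <- common_reference(bandpass_filter(rec, 300, 6000), "median")
  prov <- dump_provenance(chain)
  expect_identical(vapply(prov$operations, `[[`, "", "name"),
                   c("bandpass_filter", "common_reference"))
  restored <- restore_provenance(prov)
  expect_equal(get_traces(restored, start_frame = 100, end_frame = 200),
               get_traces(chain, start_frame = 100, end_frame = 200))
})

test_that("tampered schema versions and missing sources are rejected", {
  s <- generate_gt_sorting(n_units = 1, duration = 1, seed = 1)
  rec <- dump_provenance(s)
  rec$schema_version <- "99.0"
  expect_error(restore_provenance(rec), "unsupported provenance schema")

  p <- tempfile(fileext = ".csv")
  write_sorting(s, p)
  s2 <- read_sorting(p)
  prov <- dump_provenance(s2)
  file.remove(p)
  expect_error(restore_provenance(prov), "missing")

  expect_error(restore_provenance(dump_provenance(Sorting(list(a = 1), 1000))),
               "not restorable")
})
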