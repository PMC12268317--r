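write_csv_fixture <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

test_that("read_rt_table parses compounds, roles and missing cells", {
  f <- write_csv_fixture(c(
    "compound_id,role,rt_A,rt_B",
    "atrazine,calibrant,1.20,2.40",
    "diuron,calibrant,3.10,",
    "metolachlor,suspect,5.00,7.25"))
  tab <- read_rt_table(f)
  expect_s3_class(tab, "retention_table")
  expect_identical(table_systems(tab), c("A", "B"))
  expect_equal(sum(is.na(tab$rt_B)), 1)
  expect_equal(tab$rt_A, c(1.2, 3.1, 5.0))
})

test_that("read_rt_table rejects malformed input", {
  dup <- write_csv_fixture(c("compound_id,role,rt_A,rt_B",
                             "atrazine,calibrant,1,2",
                             "atrazine,calibrant,3,4"))
  expect_error(read_rt_table(dup), class = "rtbridge_validation_error")

  badrole <- write_csv_fixture(c("compound_id,role,rt_A,rt_B",
                                 "atrazine,standard,1,2",
                                 "diuron,calibrant,3,4"))
  expect_error(read_rt_table(badrole), class = "rtbridge_validation_error")

  badnum <- write_csv_fixture(c("compound_id,role,rt_A,rt_B",
                                "atrazine,calibrant,abc,2",
                                "diuron,calibrant,3,4"))
  expect_error(read_rt_table(badnum), class = "rtbridge_validation_error")

  onesys <- write_csv_fixture(c("compound_id,role,rt_A",
                                "atrazine,calibrant,1"))
  expect_error(read_rt_table(onesys), class = "rtbridge_validation_error")

  negrt <- write_csv_fixture(c("compound_id,role,rt_A,rt_B",
                               "atrazine,calibrant,-1,2",
                               "diuron,calibrant,3,4"))
  expect_error(read_rt_table(negrt), class = "rtbridge_validation_error")
})

test_that("write then read round-trips a retention table exactly", {
  tab <- tiny_rt_table()
  # awkward floats must survive at full double precision
  tab$rt_A[1] <- 1.23456789012345
  f <- tempfile(fileext = ".csv")
  write_rt_table(tab, f)
  back <- read_rt_table(f)
  expect_equal(back$compound_id, tab$compound_id)
  expect_equal(back$role, tab$role)
  expect_equal(back$rt_A, tab$rt_A, tolerance = 1e-15)
  expect_equal(back$rt_B, tab$rt_B, tolerance = 1e-15)
  # second round trip is the identity byte for byte
  f2 <- tempfile(fileext = ".csv")
  write_rt_table(back, f2)
  expect_identical(readBin(f, "raw", 1e6), readBin(f2, "raw", 1e6))
})

test_that("write_table is deterministic and refuses empty results", {
  rows <- data.frame(k = c("b", "a"), v = c(2.5, 1.5))
  f1 <- tempfile(); f2 <- tempfile()
  write_table(rows, f1, keys = "k")
  write_table(rows[2:1, ], f2, keys = "k")  # row order must not matter
  expect_identical(readBin(f1, "raw", 1e6), readBin(f2, "raw", 1e6))
  expect_error(write_table(rows[0, ], tempfile()),
               class = "rtbridge_validation_error")
})

test_that("chrom_system validates gradient segment geometry", {
  ok <- chrom_system(cs_id = "S1", run_time = 15,
                     gradient_segments = data.frame(
                       t_start = c(0, 2, 12), t_end = c(2, 12, 15),
                       phi_start = c(0.05, 0.05, 0.95),
                       phi_end = c(0.05, 0.95, 0.95)))
  expect_s3_class(ok, "chrom_system")

  expect_error(  # gap: segments end at 14 but the run is 15 min
    chrom_system(cs_id = "S2", run_time = 15,
                 gradient_segments = data.frame(
                   t_start = c(0, 2), t_end = c(2, 14),
                   phi_start = c(0.05, 0.05), phi_end = c(0.05, 0.95))),
    class = "rtbridge_validation_error")
  expect_error(  # overlapping segments
    chrom_system(cs_id = "S3", run_time = 15,
                 gradient_segments = data.frame(
                   t_start = c(0, 5), t_end = c(8, 15),
                   phi_start = c(0.05, 0.2), phi_end = c(0.2, 0.95))),
    class = "rtbridge_validation_error")
  expect_error(  # non-positive run time
    chrom_system(cs_id = "S4", run_time = 0,
                 gradient_segments = data.frame(
                   t_start = 0, t_end = 0, phi_start = 0, phi_end = 1)),
    class = "rtbridge_validation_error")
  expect_error(  # organic fraction above 1
    chrom_system(cs_id = "S5", run_time = 10,
                 gradient_segments = data.frame(
                   t_start = 0, t_end = 10, phi_start = 0.05, phi_end = 1.2)),
    class = "rtbridge_validation_error")
})

test_that("system metadata round-trips through CSV, at interlab scale", {
  # 37 reversed-phase systems, run times spanning 15-54 min
  systems <- lapply(seq_len(37), function(i) {
    linear_system(sprintf("DS%02d", i), run_time = 15 + (i - 1) * 39 / 36)
  })
  names(systems) <- vapply(systems, `[[`, character(1), "cs_id")
  f <- tempfile(fileext = ".csv")
  write_cs_metadata(systems, f)
  back <- read_cs_metadata(f)
  expect_length(back, 37)
  expect_s3_class(back[[1]], "chrom_system")
  expect_equal(back$DS01$run_time, 15)
  expect_equal(back$DS37$run_time, 54)
  expect_equal(back$DS05$gradient_segments, systems$DS05$gradient_segments)
})
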