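test_that("CSV ingestion normalizes axis order and validates metadata", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,replicate_id,label,600,602,604",
               "a,1,0,0.1,0.2,0.3",
               "a,2,0,0.2,0.3,0.4",
               "b,1,1,0.5,0.6,0.7"), path)
  s <- read_spectra_csv(path)
  expect_s3_class(s, "spectra_set")
  expect_equal(s$wavenumbers, c(600, 602, 604))
  expect_equal(dim(s$absorbance), c(3L, 3L))

  # same data with descending column order reads identically
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,replicate_id,label,604,602,600",
               "a,1,0,0.3,0.2,0.1",
               "a,2,0,0.4,0.3,0.2",
               "b,1,1,0.7,0.6,0.5"), path2)
  s2 <- read_spectra_csv(path2)
  expect_equal(s2$wavenumbers, s$wavenumbers)
  expect_equal(s2$absorbance, s$absorbance)

  # label outside {0,1} names the offending row
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,replicate_id,label,600,602",
               "a,1,0,0.1,0.2", "b,1,2,0.3,0.4"), path3)
  expect_error(read_spectra_csv(path3), "row.*2")

  # missing metadata column
  path4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,label,600", "a,0,0.1"), path4)
  expect_error(read_spectra_csv(path4), "replicate_id")

  # non-numeric absorbance names row and column
  path5 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,replicate_id,label,600,602",
               "a,1,0,0.1,oops"), path5)
  expect_error(read_spectra_csv(path5), "row 1.*602")
})

test_that("CSV write/read round-trips losslessly", {
  set.seed(41)
  s <- tiny_set(matrix(rnorm(100 * 50), 100, 50),
                wn = seq(600, 698, by = 2),
                label = rep(c(0L, 1L), 50))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(s, path)
  s2 <- read_spectra_csv(path)
  expect_equal(s2$wavenumbers, s$wavenumbers)
  expect_equal(s2$absorbance, s$absorbance, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(s2$label, s$label)
  expect_equal(s2$sample_id, s$sample_id)

  # descending layout on disk still round-trips to the ascending store
  write_spectra_csv(s, path, descending = TRUE)
  first_wn <- strsplit(readLines(path, n = 1L), ",")[[1]][4]
  expect_equal(as.numeric(first_wn), 698)
  expect_equal(read_spectra_csv(path)$absorbance, s$absorbance,
               tolerance = 1e-12, ignore_attr = TRUE)

  empty <- s
  expect_error(write_spectra_csv(subset_rows(s, integer(0)), path),
               "empty")
})

test_that("JCAMP reader handles XYPOINTS, implied-DELTAX XYDATA, and rejects bad input", {
  # 5-point XYPOINTS record
  path <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=test", "##JCAMP-DX=4.24", "##NPOINTS=5",
               "##XYPOINTS=(XY..XY)",
               "600.0, 0.10", "602.0, 0.20", "604.0, 0.15",
               "606.0, 0.30", "608.0, 0.25", "##END="), path)
  sp <- read_jcamp(path)
  expect_equal(sp$wavenumbers, seq(600, 608, by = 2))
  expect_equal(sp$absorbance, c(0.10, 0.20, 0.15, 0.30, 0.25))

  # AFFN XYDATA with DELTAX implied by line anchors matches expansion
  path2 <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=test", "##NPOINTS=6", "##XYDATA=(X++(Y..Y))",
               "600 0.1 0.2 0.3", "606 0.4 0.5 0.6", "##END="), path2)
  sp2 <- read_jcamp(path2)
  expect_equal(sp2$wavenumbers, seq(600, 610, by = 2))
  expect_equal(sp2$absorbance, c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))

  # truncated data is an error, not a silent short read
  path3 <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=test", "##NPOINTS=10", "##XYDATA=(X++(Y..Y))",
               "600 0.1 0.2 0.3", "##END="), path3)
  expect_error(read_jcamp(path3), "truncated|NPOINTS")

  # compressed dialects rejected explicitly
  path4 <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=test", "##XYDATA=(X++(Y..Y))",
               "600 A1B2C3", "##END="), path4)
  expect_error(read_jcamp(path4), "not supported")
})

test_that("replicate averaging matches a group-by oracle and checks labels", {
  s <- spectra_set(rbind(c(1, 1, 1), c(3, 3, 3), c(5, 5, 5)),
                   c(600, 602, 604),
                   sample_id = c("A", "A", "B"),
                   replicate_id = c(1L, 2L, 1L),
                   label = c(1L, 1L, 0L))
  avg <- average_replicates(s)
  expect_equal(nrow(avg$absorbance), 2L)
  expect_equal(unname(avg$absorbance["A" == avg$sample_id, ]), c(2, 2, 2))
  expect_equal(unname(avg$absorbance["B" == avg$sample_id, ]), c(5, 5, 5))
  expect_equal(avg$label, c(1L, 0L))

  # 10 samples x 3 replicates vs an aggregate() oracle
  set.seed(7)
  ids <- rep(sprintf("s%02d", 1:10), each = 3L)
  X <- matrix(rnorm(30 * 4), 30, 4)
  s2 <- spectra_set(X, 1:4, ids, rep(1:3, 10),
                    rep(rep(c(0L, 1L), 5), each = 3L))
  avg2 <- average_replicates(s2)
  oracle <- aggregate(X, by = list(id = ids), FUN = mean)
  oracle <- oracle[match(avg2$sample_id, oracle$id), -1L]
  expect_equal(unname(avg2$absorbance), unname(as.matrix(oracle)),
               tolerance = 1e-12)

  # conflicting labels within one sample
  bad <- spectra_set(matrix(0, 2, 2), 1:2, c("A", "A"), 1:2, c(0L, 1L))
  expect_error(average_replicates(bad), "conflicting labels")
})

test_that("region masking uses closed intervals and composes predictably", {
  s <- tiny_set(matrix(rnorm(3 * 2201), 3, 2201),
                wn = seq(600, 5000, by = 2))
  fp <- apply_region(s, region_spec(include = list(c(600, 1800))))
  expect_equal(length(fp$wavenumbers), 601L)   # closed-interval grid count
  expect_equal(range(fp$wavenumbers), c(600, 1800))

  # bounds in either order normalize identically
  r1 <- region_spec(include = list(c(600, 3000)),
                    exclude = list(c(2390, 2250)))
  r2 <- region_spec(include = list(c(600, 3000)),
                    exclude = list(c(2250, 2390)))
  expect_equal(apply_region(s, r1)$wavenumbers,
               apply_region(s, r2)$wavenumbers)
  expect_false(any(apply_region(s, r1)$wavenumbers >= 2250 &
                   apply_region(s, r1)$wavenumbers <= 2390))

  # excluding everything included is an error
  expect_error(apply_region(s, region_spec(include = list(c(600, 5000)),
                                           exclude = list(c(600, 5000)))),
               "no wavenumber")

  # idempotence
  r <- region_spec(include = list(c(900, 1700)))
  once <- apply_region(s, r)
  expect_equal(apply_region(once, r)$absorbance, once$absorbance)

  # commutes with replicate averaging
  reps <- spectra_set(matrix(rnorm(6 * 2201), 6, 2201),
                      seq(600, 5000, by = 2),
                      rep(c("A", "B"), each = 3L), rep(1:3, 2),
                      rep(c(0L, 1L), each = 3L))
  a <- apply_region(average_replicates(reps), r)
  b <- average_replicates(apply_region(reps, r))
  expect_equal(a$absorbance, b$absorbance, tolerance = 1e-12)
})

test_that("region specs load from YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("include:", "  - [600, 1800]",
               "exclude:", "  - [900, 1000]"), path)
  r <- read_region_yaml(path)
  s <- tiny_set(matrix(0, 1, 601), wn = seq(600, 1800, by = 2))
  out <- apply_region(s, r)
  expect_false(any(out$wavenumbers >= 900 & out$wavenumbers <= 1000))
})
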