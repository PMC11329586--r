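# Codec + private header + DICOM tree scanner. The codec has no external
# oracle in this environment, so it is held to structural and round-trip
# guarantees: what we write, we (and only a conforming explicit-LE parser)
# can read back bit-for-bit.

write_min_dicom <- function(path, patient = "sub-001", series = "1.2.3.4",
                            instance = 1, tr = 2300, extra = list()) {
  els <- c(list(
    mrcompliance:::dcm_element(0x0008L, 0x0070L, "LO", "SIEMENS"),
    mrcompliance:::dcm_element(0x0010L, 0x0020L, "LO", patient),
    mrcompliance:::dcm_element(0x0018L, 0x1030L, "LO", "anat_T1w"),
    mrcompliance:::dcm_element(0x0018L, 0x0080L, "DS", tr),
    mrcompliance:::dcm_element(0x0020L, 0x000DL, "UI", "1.2.3"),
    mrcompliance:::dcm_element(0x0020L, 0x000EL, "UI", series),
    mrcompliance:::dcm_element(0x0020L, 0x0013L, "IS", instance)),
    extra)
  mrcompliance:::dicom_write(path, els, paste0(series, ".", instance))
}

test_that("codec round-trips strings, decimals and multivalues", {
  f <- withr::local_tempfile(fileext = ".dcm")
  write_min_dicom(f, tr = 2300.5, extra = list(
    mrcompliance:::dcm_element(0x0020L, 0x0037L, "DS", c(1, 0, 0, 0, 1, 0)),
    mrcompliance:::dcm_element(0x0018L, 0x1312L, "CS", "AP")))
  expect_true(mrcompliance:::is_dicom_file(f))
  ds <- mrcompliance:::dicom_read(f)
  expect_identical(mrcompliance:::dcm_string(ds, "0010,0020"), "sub-001")
  expect_identical(mrcompliance:::dcm_numeric(ds, "0018,0080"), 2300.5)
  expect_identical(mrcompliance:::dcm_numeric(ds, "0020,0037"), c(1, 0, 0, 0, 1, 0))
  expect_identical(mrcompliance:::dcm_string(ds, "0018,1312"), "AP")
  expect_identical(mrcompliance:::dcm_string(ds, "0002,0010"), "1.2.840.10008.1.2.1")
})

test_that("non-DICOM and truncated files are recognized", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("not a scan", f)
  expect_false(mrcompliance:::is_dicom_file(f))
  expect_error(mrcompliance:::dicom_read(f), "DICOM|DICM")
})

test_that("Siemens ASCCONV block parses; malformed input degrades quietly", {
  blk <- mrcompliance:::ascconv_block(shim_mode = "standard",
                                      parallel_imaging = "GRAPPA",
                                      multi_slice_mode = "interleaved")
  got <- parse_siemens_private(blk)
  expect_identical(got$ParallelImaging$value, "GRAPPA")
  expect_identical(got$ShimMode$value, "standard")
  expect_identical(got$MultiSliceMode$value, "interleaved")
  expect_identical(got$ShimMode$source, "private-header")

  # truncated block: warning, empty map, no exception
  truncated <- substr(blk, 1, nchar(blk) - 25)
  expect_warning(out <- parse_siemens_private(truncated), "truncated")
  expect_length(out, 0L)
  expect_length(parse_siemens_private("no block here"), 0L)
  expect_length(parse_siemens_private(raw(0)), 0L)
})

test_that("GE/Philips private headers are skipped", {
  cfg <- fixture_config(n_subjects = 2, vendor_mix = c(GE = 0.5, PHILIPS = 0.5),
                        seed = 5)
  td <- withr::local_tempdir()
  generate_fixture(cfg, td, format = "dicom")
  h <- scan_dicom_tree(file.path(td, "dicom"))
  for (r in runs_for_all_pub(h)) {
    expect_false(r$parameters$ShimMode$present)
    expect_identical(r$parameters$ShimMode$source, "private-header")
  }
})

test_that("scanner builds one run per series and survives corrupt files", {
  cfg <- fixture_config(n_subjects = 3,
                        modalities = default_modalities()[1:2],
                        vendor_mix = c(SIEMENS = 1), seed = 9)
  td <- withr::local_tempdir()
  generate_fixture(cfg, td, format = "dicom")
  root <- file.path(td, "dicom")
  h <- scan_dicom_tree(root)
  expect_length(h$runs, 6L)
  expect_length(subjects(h), 3L)

  # corrupt DICOM (valid magic, garbage body) is skipped with a warning
  bad <- file.path(root, "corrupt.dcm")
  con <- file(bad, "wb")
  writeBin(c(raw(128), charToRaw("DICM"), as.raw(1:9)), con)
  close(con)
  expect_warning(h2 <- scan_dicom_tree(root), "skipping")
  expect_length(h2$runs, 6L)
  expect_identical(attr(h2, "n_corrupt"), 1L)

  expect_error(scan_dicom_tree(withr::local_tempdir()), "empty dataset")
})

test_that("hierarchy is invariant to file layout", {
  cfg <- fixture_config(n_subjects = 3, vendor_mix = c(SIEMENS = 1), seed = 13)
  td <- withr::local_tempdir()
  generate_fixture(cfg, td, format = "dicom")
  tidy <- file.path(td, "dicom")
  h_tidy <- scan_dicom_tree(tidy, dataset_name = "x")

  shuffled <- file.path(td, "shuffled")
  files <- list.files(tidy, recursive = TRUE, full.names = TRUE)
  set.seed(99)
  for (i in seq_along(files)) {
    dest <- file.path(shuffled, sample(letters[1:4], 1), sample(letters[1:4], 1))
    dir.create(dest, recursive = TRUE, showWarnings = FALSE)
    file.copy(files[i], file.path(dest, sprintf("f%03d.bin", i)))
  }
  h_shuf <- scan_dicom_tree(shuffled, dataset_name = "x")
  expect_identical(hierarchy_to_json(h_tidy), hierarchy_to_json(h_shuf))
})

test_that("representative instance is the lowest InstanceNumber", {
  td <- withr::local_tempdir()
  # same series, two instances, parameters differ: instance 1 must win
  write_min_dicom(file.path(td, "b.dcm"), instance = 2, tr = 9999)
  write_min_dicom(file.path(td, "a.dcm"), instance = 1, tr = 2300)
  h <- scan_dicom_tree(td)
  expect_length(h$runs, 1L)
  r <- runs_for(h, "ANAT_T1W")[[1]]
  expect_equal(r$parameters$RepetitionTime$value, 2300)
})
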