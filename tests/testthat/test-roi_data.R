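test_that("structural schema has the canonical 68+68+16 decomposition", {
  sch <- build_structural_schema()
  expect_equal(nrow(sch), 152)
  counts <- table(sch$measure)
  expect_equal(unname(counts[["thickness"]]), 68)
  expect_equal(unname(counts[["surface_area"]]), 68)
  expect_equal(unname(counts[["subcortical_volume"]]), 16)
  expect_equal(sum(sch$hemisphere == "left"), 76)
  expect_equal(anyDuplicated(sch[c("roi_name", "measure", "hemisphere")]), 0)
  expect_equal(anyDuplicated(sch$name), 0)
})

test_that("diffusion schema has 41 features with the three midline CC segments", {
  for (ms in c("FA", "RD")) {
    sch <- build_diffusion_schema(ms)
    expect_equal(nrow(sch), 41)
    expect_setequal(sch$roi_name[sch$hemisphere == "midline"],
                    c("BCC", "GCC", "SCC"))
    expect_equal(sum(sch$hemisphere == "left"), 19)
    expect_equal(sum(sch$hemisphere == "right"), 19)
  }
  fa <- build_diffusion_schema("FA")
  rd <- build_diffusion_schema("RD")
  expect_equal(fa$roi_name, rd$roi_name)         # schema symmetry
  expect_true(all(rd$measure == "RD"))
  # custom bilateral tract list is honored
  sch <- build_diffusion_schema("FA", bilateral_tracts = c("AAA", "BBB"))
  expect_equal(nrow(sch), 7)
})

test_that("load_cohort reads, reorders and validates", {
  co <- toy_cohort()
  path <- write_cohort_csv(co)
  got <- load_cohort(path, co$schema)
  expect_equal(got$X, co$X)
  expect_equal(got$subjects$subject_id, co$subjects$subject_id)

  # shuffled feature columns load identically to schema order
  dt <- utils::read.csv(path, check.names = FALSE)
  shuffled <- dt[, c(names(dt)[1:5], rev(co$schema$name))]
  path2 <- tempfile(fileext = ".csv")
  utils::write.csv(shuffled, path2, row.names = FALSE)
  expect_equal(load_cohort(path2, co$schema)$X, co$X)

  # missing feature column is a schema mismatch
  broken <- dt[, -ncol(dt)]
  path3 <- tempfile(fileext = ".csv")
  utils::write.csv(broken, path3, row.names = FALSE)
  expect_error(load_cohort(path3, co$schema), "schema mismatch")

  # unparseable numeric cell names row and column
  bad <- dt
  bad[[co$schema$name[2]]][3] <- "oops"
  path4 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, path4, row.names = FALSE)
  expect_error(load_cohort(path4, co$schema), "row 3")

  # TSV dialect round-trips bit-identically on values
  path5 <- tempfile(fileext = ".tsv")
  write_cohort(got, path5)
  expect_identical(load_cohort(path5, co$schema)$X, got$X)
})

test_that("filter_complete_cases removes exactly the incomplete rows", {
  co <- toy_cohort(M = 10)
  co$X[2, 1] <- NA
  co$X[7, 3] <- NA
  filt <- filter_complete_cases(co)
  expect_equal(n_subjects(filt), 8)
  expect_equal(filt$subjects$subject_id,
               co$subjects$subject_id[-c(2, 7)])   # order preserved
  expect_equal(filter_complete_cases(filt)$X, filt$X)  # idempotent
  clean <- toy_cohort(M = 5)
  expect_equal(filter_complete_cases(clean)$X, clean$X)
  allna <- toy_cohort(M = 3)
  allna$X[] <- NA
  expect_error(filter_complete_cases(allna), "empty cohort")
})

test_that("missingness outside the schema does not drop rows", {
  co <- toy_cohort()
  path <- write_cohort_csv(co)
  dt <- utils::read.csv(path, check.names = FALSE)
  dt$extra_qc_column <- NA
  path2 <- tempfile(fileext = ".csv")
  utils::write.csv(dt, path2, row.names = FALSE)
  got <- filter_complete_cases(load_cohort(path2, co$schema))
  expect_equal(n_subjects(got), n_subjects(co))
  expect_error(load_cohort(path2, co$schema, extra_columns = "error"),
               "extra column")
})

test_that("select_binary_groups labels, pools and preserves values", {
  groups <- c("HC", "HC", "HC", "TLE-HS-L", "TLE-HS-L", "TLE-HS-R",
              "TLE-HS-R", "TLE-HS-R", "HC", "TLE-NS-L")
  co <- toy_cohort(M = 10, groups = groups)
  sel <- select_binary_groups(co, "TLE-HS-L", "HC")
  expect_setequal(unique(sel$cohort$subjects$group), c("TLE-HS-L", "HC"))
  expect_equal(sum(sel$labels), 2)
  expect_equal(sel$cohort$X,
               co$X[groups %in% c("HC", "TLE-HS-L"), , drop = FALSE])

  pooled <- select_binary_groups(co, c("TLE-HS-L", "TLE-HS-R"), "HC")
  expect_equal(sum(pooled$labels), 5)

  lat <- select_binary_groups(co, "TLE-HS-L", "TLE-HS-R")
  expect_equal(length(lat$labels), 5)
  expect_equal(sum(lat$labels), 2)

  expect_error(select_binary_groups(co, "TLE-NS-R", "HC"), "empty")
  expect_error(select_binary_groups(co, "HC", "HC"), "overlap")
  expect_error(select_binary_groups(co, character(0), "HC"), "non-empty")
})
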