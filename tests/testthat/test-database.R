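test_that("the packaged database loads with every study validated", {
  db <- fixture_records()
  expect_equal(nrow(db), 49)
  expect_equal(db$strains[[1]], "LBA4404")
  expect_equal(db$od_wavelength_nm[1], 550L)
  expect_match(db$efficiency_pct[1], "^4.3")
  # absent antibiotic cells survive as "-", not as zero
  expect_true(any(db$kanamycin == "-"))
  # a trailing percent sign in one efficiency cell is tolerated
  shao <- db[db$reference == "shao_ref089", ]
  expect_equal(shao$efficiency_pct, "6.4%")
})

test_that("malformed cells are rejected with row and column named", {
  path <- withr::local_tempfile(fileext = ".csv")
  db <- utils::read.csv(transformation_db_path(), colClasses = "character",
                        fileEncoding = "UTF-8")
  db$kanamycin[3] <- "ten"
  utils::write.csv(db, path, row.names = FALSE, fileEncoding = "UTF-8")
  expect_error(load_database(path), "row 3.*kanamycin")

  db <- utils::read.csv(transformation_db_path(), colClasses = "character",
                        fileEncoding = "UTF-8")
  db$od_wavelength_nm[5] <- "620"
  utils::write.csv(db, path, row.names = FALSE, fileEncoding = "UTF-8")
  expect_error(load_database(path), "row 5.*wavelength")
})

test_that("range and multi-strain resolution follow the declared policies", {
  rows <- fixture_resolved()
  db <- fixture_records()
  # expansion conservation: one resolved row per listed strain
  expect_equal(nrow(rows), sum(lengths(db$strains)))
  # midpoint policy: "10-25" kanamycin in the de Jong 1994 study
  dejong <- rows[rows$reference == "dejong_ref041", ]
  expect_equal(unique(dejong$kanamycin), (10 + 25) / 2)
  expect_setequal(dejong$strain, c("LBA4404", "AGL0"))
  # expanded rows differ only in strain
  expect_equal(nrow(unique(dejong[, setdiff(names(dejong), "strain")])), 1)
  # absent antibiotic resolves to zero dose
  expect_equal(rows$cefotaxime[rows$reference == "ledger_ref059"], c(0, 0))
  # min and max policies bracket the midpoint
  lo <- resolve_records(db, "min")
  hi <- resolve_records(db, "max")
  expect_true(all(lo$efficiency_pct <= rows$efficiency_pct))
  expect_true(all(rows$efficiency_pct <= hi$efficiency_pct))
})

test_that("resolved rows survive a CSV round trip unchanged", {
  rows <- fixture_resolved()
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  back <- utils::read.csv(path, fileEncoding = "UTF-8")
  num <- vapply(rows, is.numeric, logical(1))
  for (col in names(rows)[num]) {
    expect_equal(back[[col]], rows[[col]], tolerance = 1e-12, info = col)
  }
})

test_that("encoding yields 11 scaled columns with a first-appearance codebook", {
  enc <- fixture_encoded()
  expect_equal(ncol(enc$features), 11)
  expect_equal(colnames(enc$features)[1:3], c("strain", "od", "ccp"))
  expect_true(all(enc$features >= 0 & enc$features <= 1))
  expect_false(anyNA(enc$features))
  expect_true(all(enc$targets >= 0 & enc$targets <= 100))
  # codes follow first appearance in the fixture and are injective
  expect_equal(enc$codebook[["LBA4404"]], 0L)
  expect_equal(enc$codebook[["A2002"]], 1L)
  expect_equal(anyDuplicated(enc$codebook), 0)
  # unseen strain at transform time is an encoding error
  rows <- fixture_resolved()
  rows$strain[1] <- "GV9999"
  expect_error(encode_features(rows, codebook = enc$codebook), "GV9999")
})

test_that("min-max scaling is invertible to machine precision", {
  enc <- fixture_encoded()
  raw <- chrysfoa:::unscale_features(enc$features, enc$scaling)
  rescaled <- chrysfoa:::scale_features(raw, enc$scaling)
  expect_equal(max(abs(rescaled - enc$features)), 0, tolerance = 1e-12)
  # a feature at the middle of its range scales to 0.5
  mid <- chrysfoa:::scale_features(
    matrix(250, 1, 1), tibble::tibble(feature = "k", min = 0, max = 500))
  expect_identical(as.numeric(mid), 0.5)
})

test_that("splits partition the rows at the stated sizes for any seed", {
  expect_equal(chrysfoa:::largest_remainder(10, c(0.7, 0.2, 0.1)), c(7L, 2L, 1L))
  expect_equal(chrysfoa:::largest_remainder(49, c(0.7, 0.2, 0.1)), c(34L, 10L, 5L))
  enc <- fixture_encoded()
  n <- nrow(enc$features)
  for (seed in 1:100) {
    sp <- split_dataset(enc, seed = seed)
    expect_identical(sort(c(sp$training, sp$testing, sp$validation)),
                     seq_len(n))
  }
  expect_identical(split_dataset(enc, seed = 42), split_dataset(enc, seed = 42))
  expect_error(split_dataset(enc, fractions = c(0.7, 0.2, 0.2)), "summing")
  expect_error(split_dataset(5), "at least 10")
})

test_that("encoding metadata round-trips through CSV and JSON", {
  enc <- fixture_encoded()
  rows_path <- withr::local_tempfile(fileext = ".csv")
  meta_path <- withr::local_tempfile(fileext = ".json")
  write_encoding(enc, rows_path, meta_path)
  meta <- read_encoding(meta_path)
  expect_identical(meta$codebook, enc$codebook)
  expect_equal(meta$scaling$min, enc$scaling$min, tolerance = 1e-12)
  expect_equal(meta$scaling$max, enc$scaling$max, tolerance = 1e-12)
  # re-encoding the written rows under the stored metadata is idempotent
  back <- utils::read.csv(rows_path, fileEncoding = "UTF-8")
  enc2 <- encode_features(back, codebook = meta$codebook,
                          scaling = meta$scaling)
  expect_equal(enc2$features, enc$features, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("member configs load from a YAML models section", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("models:",
               "  mlp: {hidden: 12, epochs: 300}",
               "  rbf: {centers: 20}",
               "  anfis: {rules: 5}"), path)
  cfgs <- read_model_config(path)
  expect_equal(cfgs$mlp$hidden, 12L)
  expect_equal(cfgs$mlp$epochs, 300L)
  expect_equal(cfgs$rbf$centers, 20L)
  expect_equal(cfgs$anfis$rules, 5L)
  writeLines("other: 1", path)
  expect_error(read_model_config(path), "models")
})
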