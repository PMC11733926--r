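test_that("CSV molecule tables read, validate and drop unparseable rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("smiles,y", "CCO,1.5", "c1ccccc1,0.2", "CC(=O)O,-0.7"), f)
  tab <- read_molecule_table(f, target_columns = "y")
  expect_s3_class(tab, "molecule_table")
  expect_equal(nrow(tab), 3)
  expect_equal(attr(tab, "target_names"), "y")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("smiles,y", "CCO,1", "not_a_smiles,2", "CCN,3", "C(,4",
               "CCC,5", "CCCC,6"), f2)
  expect_message(tab2 <- read_molecule_table(f2, target_columns = "y"),
                 "dropped 2")
  expect_equal(nrow(tab2), 4)
  expect_equal(attr(tab2, "n_dropped"), 2)
  expect_equal(tab2$y, c(1, 3, 5, 6))

  expect_error(read_molecule_table("no/such/file.csv"), "not found")
  expect_error(read_molecule_table(f, smiles_column = "smi"), "schema")
  expect_error(read_molecule_table(f, target_columns = "z"), "schema")
})

test_that("canonicalization collapses equivalent encodings and is idempotent", {
  can <- canonicalize_smiles(c("OCC", "CCO", "C(O)C"))
  expect_length(unique(can), 1)
  benz <- canonicalize_smiles("c1ccccc1")
  expect_identical(canonicalize_smiles(benz), benz)
  expect_error(canonicalize_smiles("C("), "unparseable")
  expect_error(canonicalize_smiles("not_a_smiles"), "unparseable")
})

test_that("random splits have the right sizes, are disjoint and seeded", {
  s <- random_split(10, test_fraction = 0.2, seed = 3)
  expect_length(s$train, 8)
  expect_length(test_indices(s, peek = TRUE), 2)
  expect_length(intersect(s$train, test_indices(s, peek = TRUE)), 0)

  big <- random_split(4200, test_fraction = 0.2, seed = 1)
  expect_length(test_indices(big, peek = TRUE), 840)

  s1 <- random_split(100, 0.25, 0.1, seed = 11)
  s2 <- random_split(100, 0.25, 0.1, seed = 11)
  expect_identical(s1$train, s2$train)
  expect_identical(s1$validation, s2$validation)
  expect_identical(test_indices(s1, peek = TRUE), test_indices(s2, peek = TRUE))
  s3 <- random_split(100, 0.25, 0.1, seed = 12)
  expect_false(identical(s1$train, s3$train))

  expect_error(random_split(10, test_fraction = 0), "config")
  expect_error(random_split(10, 0.6, 0.5), "config")
})

test_that("test-set access is counted by the guard", {
  s <- random_split(20, 0.2, seed = 1)
  expect_equal(test_access_count(s), 0L)
  invisible(test_indices(s, peek = TRUE))
  expect_equal(test_access_count(s), 0L)
  invisible(test_indices(s))
  expect_equal(test_access_count(s), 1L)
})

test_that("Murcko scaffolds strip side chains and group molecules", {
  benz <- canonicalize_smiles("c1ccccc1")
  expect_identical(murcko_scaffold("Cc1ccccc1"), benz)  # toluene -> benzene
  expect_identical(murcko_scaffold("c1ccccc1"), benz)
  expect_identical(murcko_scaffold("CCCC"), "")          # acyclic
  # molecules sharing a scaffold give identical strings
  expect_identical(murcko_scaffold("CCc1ccccc1"), murcko_scaffold("OCc1ccccc1"))
})

test_that("scaffold split assigns whole groups largest-first", {
  # 5 benzene derivatives, 3 pyridines, 2 naphthalenes -> group sizes 5,3,2
  smiles <- c("Cc1ccccc1", "CCc1ccccc1", "OCc1ccccc1", "NCc1ccccc1",
              "CCCc1ccccc1",
              "Cc1ccncc1", "CCc1ccncc1", "OCc1ccncc1",
              "Cc1ccc2ccccc2c1", "CCc1ccc2ccccc2c1")
  tab <- molecule_table(smiles)
  # with 10 molecules in 3 groups the tiny test tier can end up empty,
  # which the split reports as a warning by design
  sp <- suppressWarnings(scaffold_split(tab, c(0.8, 0.1, 0.1)))
  scaf <- murcko_scaffold(tab$smiles)
  te <- test_indices(sp, peek = TRUE)
  # the size-5 and size-3 groups fill the train set
  expect_true(all(which(scaf == scaf[1]) %in% sp$train))
  expect_true(all(which(scaf == scaf[6]) %in% sp$train))
  # no scaffold straddles two sets
  for (sc in unique(scaf)) {
    idx <- which(scaf == sc)
    sets <- c(all(idx %in% sp$train), all(idx %in% sp$validation),
              all(idx %in% te))
    expect_equal(sum(sets), 1)
  }
})

test_that("all-acyclic tables form one scaffold group with a warning", {
  tab <- molecule_table(c("CC", "CCC", "CCCC", "CCCCC"))
  w <- capture_warnings(sp <- scaffold_split(tab, c(0.8, 0.1, 0.1)))
  expect_true(any(grepl("acyclic", w)))
  expect_length(sp$train, 4)
})

test_that("splits serialize to 0-based JSON", {
  s <- random_split(10, 0.2, seed = 5)
  js <- jsonlite::fromJSON(split_to_json(s))
  expect_setequal(c(js$train, js$validation, js$test), 0:9)
  expect_equal(sort(js$test + 1), test_indices(s, peek = TRUE))
})
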