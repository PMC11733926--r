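test_that("count and bit blocks obey their value contracts", {
  tab <- tiny_table()
  mc <- featurize_block(tab, descriptor_block_spec("morgan_counts",
                                                   n_bits = 256))
  expect_true(all(mc >= 0))
  expect_true(all(mc == round(mc)))
  expect_equal(ncol(mc), 256)
  expect_match(colnames(mc)[1], "^fm3-")

  eb <- featurize_block(tab, descriptor_block_spec("ecfp_bits", n_bits = 128))
  expect_true(all(eb %in% c(0, 1)))

  mk <- featurize_block(tab, "maccs_keys")
  expect_equal(ncol(mk), 166)
  expect_true(all(mk %in% c(0, 1), na.rm = TRUE))
})

test_that("element fractions follow the molecular formula with implicit H", {
  tab <- tiny_table()
  ef <- featurize_block(tab, "element_fractions")
  # CCO = C2H6O: fractions 2/9, 6/9, 1/9
  expect_equal(unname(ef[1, c("frac-C", "frac-H", "frac-O")]),
               c(2, 6, 1) / 9)
  expect_equal(sum(ef[1, ]), 1)
})

test_that("physchem descriptors count functional groups from the graph", {
  tab <- tiny_table()
  pc <- featurize_block(tab, "physchem_descriptors")
  expect_equal(unname(pc[, "fr-COO"]), c(0, 1, 0, 1, 0, 0, 0))  # acids
  expect_equal(unname(pc[2, "fr-OH"]), 0)     # acid OH not counted as fr-OH
  expect_equal(unname(pc[3, "fr-Ar-OH"]), 1)  # phenol
  expect_equal(unname(pc[6, "fr-NH2"]), 1)    # ethylamine
  expect_equal(unname(pc[5, "NumRings"]), 1)
  expect_gt(pc[4, "MolWt"], 200)              # ibuprofen ~206
})

test_that("element property statistics match hand-computed compositions", {
  # water H2O: group numbers (1,1,16) -> mean 6
  w <- suppressMessages(molecule_table("O"))
  es <- element_property_stats(w)
  expect_equal(unname(es[1, "mean group number"]), 6)
  # methane CH4: (14 + 4*1)/5 = 3.6
  m <- suppressMessages(molecule_table("C"))
  expect_equal(unname(element_property_stats(m)[1, "mean group number"]), 3.6)
  # a single-element composition has zero spread
  expect_equal(unname(element_property_stats(m)[1, "std group number"]),
               sd_expected <- sqrt(mean((c(14, 1, 1, 1, 1) - 3.6)^2)))
  h2 <- suppressMessages(molecule_table("CC"))  # still two elements
  o2only <- element_property_stats(w)
  expect_equal(unname(o2only[1, "range period"]), 1)  # H period 1, O period 2
})

test_that("block concatenation is additive and repairs name collisions", {
  tab <- tiny_table()
  a <- featurize_block(tab, descriptor_block_spec("morgan_counts",
                                                  n_bits = 64))
  b <- featurize_block(tab, "maccs_keys")
  cc <- concat_blocks(list(a, b))
  expect_equal(ncol(cc), ncol(a) + ncol(b))
  expect_equal(colnames(cc), c(colnames(a), colnames(b)))
  dup <- b
  colnames(dup)[1] <- colnames(a)[1]
  expect_message(cc2 <- concat_blocks(list(a, dup)), "renamed")
  expect_false(anyDuplicated(colnames(cc2)) > 0)
  expect_error(concat_blocks(list(a, b[1:3, ])), "alignment")
})

test_that("the default block set reaches the expected base-vector scale", {
  tab <- cached("width_tab", suppressMessages(molecule_table(
    c("CCO", "CC(=O)Oc1ccccc1C(=O)O", "CCN(CC)CC"))))
  X <- featurize(tab, clean = FALSE)
  expect_gte(ncol(X), 9000)
  expect_lte(ncol(X), 13000)
})

test_that("cleaning drops unusable columns and imputes the rest", {
  X <- cbind(const = rep(1, 10), good = rnorm(10),
             holey = c(NA, rnorm(9)), dead = rep(NA_real_, 10))
  Xc <- clean_features(X, max_missing_fraction = 0.2)
  rep <- attr(Xc, "drop_report")
  expect_setequal(colnames(Xc), c("good", "holey"))
  expect_true("const" %in% rep$zero_variance)
  expect_true("dead" %in% rep$all_missing)
  expect_true("holey" %in% rep$imputed)
  expect_true(all(is.finite(Xc)))
  expect_equal(unname(Xc[1, "holey"]), median(X[-1, "holey"]))
  expect_error(clean_features(matrix(NA_real_, 5, 2)), "empty")
})

test_that("featurization is a pure function of the canonical molecule", {
  tab <- tiny_table()
  X1 <- featurize(tab, blocks = lean_blocks(), clean = FALSE)
  X2 <- featurize(tab, blocks = lean_blocks(), clean = FALSE)
  expect_identical(X1, X2)
  # permuting rows permutes the matrix identically
  perm <- c(3, 1, 2, 5, 4, 7, 6)
  tabp <- tab[perm, ]
  attributes(tabp)[c("task_type", "target_names", "n_dropped")] <-
    attributes(tab)[c("task_type", "target_names", "n_dropped")]
  Xp <- featurize(tabp, blocks = lean_blocks(), clean = FALSE)
  expect_equal(unname(Xp), unname(X1[perm, ]))
})

test_that("unknown blocks and parameters are rejected", {
  expect_error(descriptor_block_spec("quantum"), "unknown block")
  expect_error(descriptor_block_spec("morgan_counts", depth = 2),
               "unknown parameter")
})
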