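test_that("substructure sentences enumerate atom environments by radius", {
  expect_length(molecule_sentence("C", max_radius = 1), 1)   # isolated atom
  expect_length(molecule_sentence("CCO", max_radius = 1), 6) # 3 atoms x 2 radii
  expect_length(molecule_sentence("CCO", max_radius = 0), 3)
  # writing order of the same molecule does not change the token multiset
  expect_setequal(molecule_sentence("OCC", 1), molecule_sentence("CCO", 1))
  expect_equal(sort(table(molecule_sentence("OCC", 1))),
               sort(table(molecule_sentence("CCO", 1))))
  expect_error(molecule_sentence("C(", 1), "unparseable")
})

test_that("skip-gram training respects dimension, vocabulary and seed", {
  corpus <- c(rep(list(c("a", "b", "c", "a", "b")), 10),
              list(c("a", "c", "d")))
  m <- train_embeddings(corpus, dimension = 16, window = 2, min_count = 3,
                        epochs = 3, seed = 5)
  expect_equal(m$dimension, 16)
  expect_equal(ncol(m$vectors), 16)
  expect_false("d" %in% rownames(m$vectors))  # occurs once, min_count 3
  m2 <- train_embeddings(corpus, dimension = 16, window = 2, min_count = 3,
                         epochs = 3, seed = 5)
  expect_identical(m$vectors, m2$vectors)
  rare <- c(corpus, list(c("zz")))
  m3 <- train_embeddings(rare, dimension = 8, min_count = 2, epochs = 1)
  expect_false("zz" %in% rownames(m3$vectors))
  expect_error(train_embeddings(list(c("q")), min_count = 5), "vocabulary")
})

test_that("molecule vectors are sums of substructure vectors", {
  corpus <- rep(list(c("a", "b"), c("b", "c"), c("a", "c")), 5)
  m <- train_embeddings(corpus, dimension = 8, min_count = 1, epochs = 2,
                        seed = 1)
  va <- m$vectors["a", ]
  expect_equal(molecule_vector(m, "a"), unname(va))
  expect_equal(molecule_vector(m, c("a", "a")), unname(2 * va))
  expect_equal(molecule_vector(m, c("a", "b")),
               unname(va + m$vectors["b", ]))
  # out-of-vocabulary tokens contribute the UNK vector
  expect_equal(molecule_vector(m, c("xx", "yy")), unname(2 * m$unk_vector))
  expect_warning(z <- molecule_vector(m, character(0)), "empty")
  expect_equal(z, numeric(8))
})

test_that("embedding a table yields named columns and canonical invariance", {
  tab <- tiny_table()
  m <- train_embeddings(tab, dimension = 12, min_count = 1, epochs = 2,
                        max_radius = 1, seed = 2)
  E <- suppressWarnings(embed_table(m, tab))
  expect_equal(colnames(E), paste0("Mol2Vec-", 0:11))
  expect_equal(nrow(E), nrow(tab))
  # identical molecules embed identically
  tab2 <- suppressMessages(molecule_table(c("CCO", "OCC")))
  E2 <- embed_table(m, tab2)
  expect_equal(E2[1, ], E2[2, ], ignore_attr = TRUE)
})

test_that("co-occurring identifiers align more than disjoint-context ones", {
  # words a and b always share contexts; u and v live in a disjoint topic
  make_corpus <- function(seed) {
    set.seed(seed)
    lapply(1:60, function(i) {
      if (i %% 2 == 0) c("a", "b", sample(c("x", "y"), 2, TRUE))
      else c("u", "v", sample(c("p", "q"), 2, TRUE))
    })
  }
  cos <- function(m, w1, w2) {
    v1 <- m$vectors[w1, ]; v2 <- m$vectors[w2, ]
    sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  }
  diffs <- vapply(1:5, function(s) {
    m <- train_embeddings(make_corpus(s), dimension = 16, window = 3,
                          min_count = 1, epochs = 20, seed = s)
    cos(m, "a", "b") - cos(m, "a", "u")
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.6)
})

test_that("embedding models persist to a two-file artifact", {
  corpus <- rep(list(c("a", "b", "c")), 8)
  m <- train_embeddings(corpus, dimension = 6, min_count = 1, epochs = 2,
                        seed = 3)
  d <- withr::local_tempdir()
  save_embedding_model(m, d)
  m2 <- load_embedding_model(d)
  expect_equal(m2$vectors, m$vectors, tolerance = 1e-12)
  expect_equal(molecule_vector(m2, c("a", "b")),
               molecule_vector(m, c("a", "b")), tolerance = 1e-12)
})
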