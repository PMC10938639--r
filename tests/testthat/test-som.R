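test_that("fingerprints are deterministic and structure-sensitive", {
  pfoa <- "OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F"
  pfos <- "OS(=O)(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F"
  fps <- fingerprint_library(c(a = pfoa, b = pfoa, c = pfos),
                             n_bits = 1024)
  expect_identical(fps["a", ], fps["b", ])
  expect_false(identical(fps["a", ], fps["c", ]))
  expect_gte(sum(fps["a", ]), 1L)
  expect_equal(tanimoto(fps["a", ], fps["a", ]), 1)
  expect_lt(tanimoto(fps["a", ], fps["c", ]), 1)
})

test_that("tanimoto handles disjoint, overlapping and empty vectors", {
  expect_equal(tanimoto(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_equal(tanimoto(c(1, 1, 0), c(1, 0, 1)), 1 / 3)
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 1)
})

test_that("unparseable molecules are skipped with a warning", {
  expect_warning(
    fps <- fingerprint_library(c(ok = "OC(=O)C(F)(F)F", bad = "xx(("),
                               n_bits = 256),
    "skipping"
  )
  expect_equal(rownames(fps), "ok")
  expect_equal(attr(fps, "skipped"), "bad")
})

test_that("batch training is deterministic and rejects degenerate grids", {
  cl <- clustered_fps(n_per = 20, bits = 128)
  m1 <- train_som(cl$X, rows = 4, cols = 4, epochs = 10, seed = 3)
  m2 <- train_som(cl$X, rows = 4, cols = 4, epochs = 10, seed = 3)
  expect_identical(m1$codebook, m2$codebook)
  expect_error(train_som(cl$X, rows = 1, cols = 4, epochs = 5), "2x2")
  expect_error(train_som(cl$X, rows = 4, cols = 4, epochs = 0), "epochs")
})

test_that("identical inputs collapse onto a single best-matching unit", {
  X <- matrix(rep(c(1, 0, 1, 0), each = 30), nrow = 30)
  m <- train_som(X, rows = 3, cols = 3, epochs = 5, seed = 1)
  bmu <- best_matching_unit(m, X)$unit
  expect_equal(length(unique(bmu)), 1L)
})

test_that("quantization error is non-increasing across batch epochs", {
  set.seed(8)
  X <- matrix(stats::rbinom(150 * 256, 1, 0.1), 150, 256)
  m <- train_som(X, rows = 5, cols = 5, epochs = 25, seed = 8)
  expect_true(all(diff(m$qe_history) <= 1e-9))
  expect_equal(quantization_error(m, X),
               m$qe_history[length(m$qe_history)])
})

test_that("quantization error is zero when data sit on the codebook", {
  m <- train_som(matrix(stats::runif(40), 10, 4), rows = 2, cols = 2,
                 epochs = 3, seed = 1)
  expect_equal(quantization_error(m, m$codebook), 0)
  expect_equal(quantization_error(m, m$codebook[2, ]), 0)
  expect_error(quantization_error(m, m$codebook[0, , drop = FALSE]),
               "empty")
})

test_that("BMU matches an exhaustive-search oracle and breaks ties row-major", {
  cl <- clustered_fps(n_per = 15, bits = 64, seed = 12)
  m <- train_som(cl$X, rows = 3, cols = 4, epochs = 8, seed = 12)
  set.seed(13)
  for (i in 1:25) {
    q <- stats::runif(64)
    expect_equal(best_matching_unit(m, q)$unit, naive_bmu(m$codebook, q))
  }
  # two exactly equidistant units: lower row-major index wins
  m$codebook[5, ] <- m$codebook[9, ]
  got <- best_matching_unit(m, m$codebook[9, ])
  expect_equal(got$unit, 5L)
  expect_error(best_matching_unit(m, stats::runif(10)), "length")
})

test_that("well-separated clusters map to pure units", {
  cl <- clustered_fps(n_per = 60, bits = 512, seed = 5)
  m <- train_som(cl$X, rows = 6, cols = 6, epochs = 30, seed = 3)
  bmu <- best_matching_unit(m, cl$X)$unit
  purity <- vapply(split(cl$cluster, bmu),
                   function(g) max(table(g)) / length(g), numeric(1))
  expect_true(all(purity == 1))
  # each cluster occupies its own set of units
  expect_equal(length(unique(paste(bmu, cl$cluster))),
               length(unique(bmu)))
})

test_that("batch training is invariant to input row order", {
  cl <- clustered_fps(n_per = 20, bits = 128, seed = 6)
  m <- train_som(cl$X, rows = 4, cols = 4, epochs = 10, seed = 6)
  set.seed(7)
  perm <- sample(nrow(cl$X))
  mp <- train_som(cl$X[perm, ], rows = 4, cols = 4, epochs = 10, seed = 6)
  expect_identical(m$codebook, mp$codebook)
})

test_that("activity projection labels units by modal call", {
  cl <- clustered_fps(n_per = 20, bits = 128, seed = 9)
  ids <- sprintf("c%03d", seq_len(nrow(cl$X)))
  rownames(cl$X) <- ids
  m <- train_som(cl$X, rows = 4, cols = 4, epochs = 10, seed = 9)
  calls <- data.frame(
    chemical_id = ids, receptor = "AR",
    final_call = ifelse(cl$cluster == 1, "active_agonist", "inactive"),
    stringsAsFactors = FALSE
  )
  panel <- project_activity(m, cl$X, calls, "AR")
  expect_equal(nrow(panel), 16L)
  occupied <- panel$n > 0
  expect_true(any(is.na(panel$label[!occupied])) || all(occupied))
  bmu <- best_matching_unit(m, cl$X)$unit
  active_units <- sort(unique(bmu[cl$cluster == 1]))
  expect_true(all(panel$label[active_units] == "active_agonist"))

  all_inactive <- transform(calls, final_call = "inactive")
  p0 <- project_activity(m, cl$X, all_inactive, "AR")
  expect_true(all(p0$label[p0$n > 0] == "inactive"))
  expect_true(all(is.na(p0$label[p0$n == 0])))

  expect_error(project_activity(m, cl$X, calls[-1, ], "AR"), "c001")
})

test_that("models survive a JSON round-trip", {
  cl <- clustered_fps(n_per = 10, bits = 32, seed = 4)
  m <- train_som(cl$X, rows = 3, cols = 3, epochs = 4, seed = 4)
  f <- tempfile(fileext = ".json")
  write_som(m, f)
  back <- read_som(f)
  expect_equal(back$codebook, m$codebook, ignore_attr = TRUE)
  expect_equal(back$qe_history, m$qe_history)
  q <- stats::runif(32)
  expect_equal(best_matching_unit(back, q), best_matching_unit(m, q))
})
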