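test_that("parse_library reads CSV rows in order and never drops entries", {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(
    dtxsid = c("D1", "D2", "D3"),
    smiles = c("OC(=O)C(F)(F)F", "", "CCCC")
  ), f, row.names = FALSE)
  out <- parse_library(f, id_col = "dtxsid", smiles_col = "smiles")
  expect_equal(out$source_id, c("D1", "D2", "D3"))
  expect_equal(out$smiles[2], "") # empty SMILES kept, flagged downstream
  expect_error(parse_library(f, id_col = "nope", smiles_col = "smiles"),
               "nope")
  expect_error(parse_library(tempfile()), "not found")
})

test_that("parse_library reads SDF molecules with title or property ids", {
  sdf <- ChemmineR::smiles2sdf(c(X1 = "OC(=O)C(F)(F)F", X2 = "CCCC"))
  ChemmineR::datablock(sdf) <- list(c(dtxsid = "D001"), c(dtxsid = "D002"))
  f <- tempfile(fileext = ".sdf")
  ChemmineR::write.SDF(sdf, f)
  by_title <- parse_library(f)
  expect_equal(nrow(by_title), 2L)
  expect_equal(by_title$source_id, c("X1", "X2"))
  by_prop <- parse_library(f, id_prop = "dtxsid")
  expect_equal(by_prop$source_id, c("D001", "D002"))
})

test_that("fluorine counting covers acids, fluorocarbon chains and blanks", {
  expect_equal(count_fluorines("OC(=O)C(F)(F)F"), 3L)
  expect_equal(count_fluorines("CCCC"), 0L)
  pfoa <- "OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F"
  expect_equal(count_fluorines(pfoa), 15L)
  expect_error(count_fluorines("not_a_smiles"), "unparseable")
})

test_that("perfluorinated unit requires a carbon with two fluorines", {
  expect_true(has_perfluorinated_unit("OC(=O)C(F)(F)F"))
  expect_false(has_perfluorinated_unit("FCC(F)CF")) # one F per carbon
  expect_false(has_perfluorinated_unit("CCO"))
  expect_error(has_perfluorinated_unit("not_a_smiles"), "unparseable")
})

test_that("inclusion filters assign one deterministic reason per entry", {
  out <- suppressWarnings(apply_inclusion_filters(c(
    "OC(=O)C(F)(F)F", "CCCC", "FCC(F)CF", "OC(=O)C(F)(F)F", "not_a_smiles"
  )))
  expect_equal(out$exclusion_reason,
               c("none", "no_perfluoro_unit", "no_perfluoro_unit",
                 "duplicate", "unparseable"))
  expect_equal(out$included, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  audit <- curation_audit(out)
  expect_equal(sum(audit$n), 5L)

  empty <- apply_inclusion_filters(character(0))
  expect_equal(nrow(empty), 0L)
  expect_equal(sum(curation_audit(empty)$n), 0L)
})

test_that("deduplication keys are spelling-invariant and first-wins", {
  pfoa_a <- "OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F"
  pfoa_b <- "FC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(=O)O"
  out <- apply_inclusion_filters(c(pfoa_a, pfoa_b))
  expect_equal(out$structure_key[1], out$structure_key[2])
  expect_equal(out$exclusion_reason, c("none", "duplicate"))

  ten <- apply_inclusion_filters(rep(pfoa_a, 10))
  expect_equal(sum(ten$included), 1L)
  expect_equal(sum(ten$exclusion_reason == "duplicate"), 9L)
})

test_that("deduplicate keeps exactly the first record per key group", {
  rec <- data.frame(
    source_id = c("a", "b", "c"), smiles = NA, canonical_smiles = NA,
    structure_key = c("K1", "K2", "K1"), n_fluorine = 3L,
    has_perfluoro_unit = TRUE, included = TRUE, exclusion_reason = "none",
    stringsAsFactors = FALSE
  )
  out <- deduplicate(rec)
  expect_equal(out$included, c(TRUE, TRUE, FALSE))
  distinct <- deduplicate(transform(rec, structure_key = c("K1", "K2", "K3")))
  expect_true(all(distinct$included))
})

test_that("curation conserves entries and included records obey the rules", {
  fx <- small_library()
  rec <- fx$rec
  expect_equal(nrow(rec), nrow(fx$entries))
  expect_equal(sum(curation_audit(rec)$n), nrow(fx$entries))
  inc <- rec[rec$included, ]
  expect_true(all(inc$n_fluorine >= 3L))
  expect_true(all(inc$has_perfluoro_unit))
  expect_equal(anyDuplicated(inc$structure_key), 0L)
})

test_that("curation recovers the generator's planted labels exactly", {
  fx <- small_library()
  expect_equal(fx$rec$included, fx$truth$expect_included)
  expect_equal(fx$rec$exclusion_reason, fx$truth$expect_reason)
})

test_that("curation is idempotent on its own included output", {
  fx <- small_library()
  inc <- fx$rec[fx$rec$included, c("source_id", "smiles")]
  again <- apply_inclusion_filters(inc)
  expect_true(all(again$included))
  expect_equal(again$structure_key,
               fx$rec$structure_key[fx$rec$included])
})

test_that("the set of included structures is stable under input permutation", {
  fx <- small_library()
  set.seed(9)
  perm <- sample(nrow(fx$entries))
  rec_p <- suppressWarnings(apply_inclusion_filters(fx$entries[perm, ]))
  expect_setequal(rec_p$structure_key[rec_p$included],
                  fx$rec$structure_key[fx$rec$included])
})
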