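# Curation tests parse real SMILES through the chemistry backend; the
# fixture molecules are tiny so the whole file stays fast.

test_that("canonicalization unifies notation, is idempotent, flags junk", {
  expect_equal(canonicalize_smiles("OCC"), canonicalize_smiles("CCO"))
  s <- canonicalize_smiles("CC(=O)Oc1ccccc1C(=O)O")
  expect_equal(canonicalize_smiles(s), s)
  expect_true(is.na(canonicalize_smiles("C1CC")))   # unclosed ring
})

test_that("curation applies removal rules in order with full accounting", {
  recs <- molecule_records(
    smiles = c("CCO", "OCC",             # duplicates (same molecule+label)
               "C1CC",                   # unparseable
               "c1ccccc1", "c1ccccc1",   # overlap: two labels
               "CC(=O)O",
               # a 32-residue-scale peptide-like chain, far above 1000 Da
               paste0(rep("CC(N)C(=O)N", 15), collapse = ""),
               "CCN"),
    labels = c("inhibitor", "inhibitor", "inhibitor",
               "inhibitor", "non_inhibitor", "substrate",
               "inhibitor", "non_substrate"),
    ids = paste0("m", 1:8))
  cur <- curate(recs, mw_limit = 1000)
  expect_s3_class(cur, "curated_dataset")
  expect_equal(nrow(cur$records) + nrow(cur$removed), 8)
  reasons <- setNames(cur$removed$reason, cur$removed$id)
  expect_equal(unname(reasons["m3"]), "unparseable")
  expect_equal(unname(reasons["m7"]), "overweight")
  expect_equal(unname(reasons["m2"]), "duplicate")
  # both overlapping records discarded, under both labels
  expect_equal(unname(reasons[c("m4", "m5")]), rep("overlapping", 2))
  # first occurrence of the duplicate kept
  expect_true("m1" %in% cur$records$id)
  expect_equal(unname(cur$census[["total"]]), nrow(cur$records))

  # idempotence: curating the survivors removes nothing further
  cur2 <- curate(cur$records, mw_limit = 1000)
  expect_equal(nrow(cur2$removed), 0)
  expect_equal(cur2$census, cur$census)
})

test_that("census is order-invariant even when the kept duplicate differs", {
  recs <- molecule_records(c("CCO", "OCC", "CCN"),
                           c("inhibitor", "inhibitor", "substrate"),
                           ids = c("a", "b", "c"))
  cur_fwd <- curate(recs)
  cur_rev <- curate(recs[3:1, ])
  expect_equal(cur_fwd$census, cur_rev$census)
  expect_setequal(cur_fwd$removed$reason, cur_rev$removed$reason)
  # the kept representative follows input order
  expect_true("a" %in% cur_fwd$records$id)
  expect_true("b" %in% cur_rev$records$id)
})

test_that("census counts the four classes and sums to the total", {
  labels <- rep(pgp_classes(), times = c(13, 9, 2, 1))
  cen <- census(labels)
  expect_equal(unname(cen[["inhibitor"]]), 13)
  expect_equal(unname(cen[["total"]]), 25)
  expect_equal(unname(census(character(0))[["total"]]), 0)
  cen3 <- census(rep("inhibitor", 3))
  expect_equal(unname(cen3[["total"]]), 3)
  expect_equal(unname(cen3[["non_substrate"]]), 0)
})

test_that("reading compounds handles CSV and plain SMILES inputs", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("smiles,label,id", "CCO,inhibitor,x1",
               "CCN,non_inhibitor,x2"), csv)
  recs <- read_compounds(csv)
  expect_equal(recs$id, c("x1", "x2"))
  expect_equal(recs$label, c("inhibitor", "non_inhibitor"))

  smi <- tempfile(fileext = ".smi")
  writeLines(c("CCO mol1", "c1ccccc1 mol2"), smi)
  recs2 <- read_compounds(smi, label = "substrate")
  expect_equal(recs2$id, c("mol1", "mol2"))
  expect_equal(unique(recs2$label), "substrate")
  expect_error(read_compounds(smi), "label")
  expect_error(molecule_records("CCO", "bogus_class"), "unknown label")
})

test_that("curation artifacts are written and re-readable", {
  recs <- molecule_records(c("CCO", "CCN"), c("inhibitor", "non_inhibitor"))
  cur <- curate(recs)
  dir <- tempfile()
  paths <- write_curation(cur, dir)
  expect_true(all(file.exists(paths)))
  cen <- jsonlite::read_json(paths[["census"]])
  expect_equal(cen$total, 2)
  back <- utils::read.csv(paths[["curated"]])
  expect_equal(nrow(back), 2)
  expect_true("canonical" %in% names(back))
})
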