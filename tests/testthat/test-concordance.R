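test_that("diplotype strings normalize canonically at each level", {
  expect_identical(
    normalize_diplotype("*17.001/*38.003 + 94781616A>G", "major"), "*17/*38")
  expect_identical(normalize_diplotype("*1.002/*17.001", "major"), "*1/*17")
  # order-insensitive at minor level, whitespace-normalized
  expect_identical(
    normalize_diplotype("*2.001 + rs4986894/*1.002", "minor_exact"),
    normalize_diplotype("*1.002/*2.001 + rs4986894", "minor_exact"))
  # re-parsing a normalized token is idempotent
  tok <- normalize_diplotype("*1.002 +94842865C>T/*2.002", "minor_exact")
  expect_identical(normalize_diplotype(tok, "minor_exact"), tok)
  # the subtraction annotation stays a distinct token
  expect_false(identical(
    normalize_diplotype("*1.002 +94842865C>T/*2.002–94842865C>T", "minor_exact"),
    normalize_diplotype("*1.002/*2.002", "minor_exact")))
  expect_true(is.na(normalize_diplotype("garbage", "major")))
})

test_that("PharmCat-style bracketed alternates parse into a ranked list", {
  p <- parse_diplotype("*1/*4 (*1/*17)")
  expect_true(p$well_formed)
  expect_identical(normalize_diplotype(p, "major"), "*1/*4")
  expect_length(p$alternates, 1)
  expect_identical(normalize_diplotype(p$alternates[[1]], "major"), "*1/*17")
  # a trailing metabolizer code is a phenotype, not an alternate
  p2 <- parse_diplotype("*1.002/*17.001 (RM)")
  expect_identical(p2$phenotype, "RM")
  expect_length(p2$alternates, 0)
})

test_that("agreement counts normalized matches and flags malformed cells", {
  expect_equal(agreement(c("*1/*2", "*1/*17"), c("*2/*1", "*1/*17"),
                         "major")$percent, 100)
  toy <- agreement(c("*1/*2", "*1/*17", "*2/*2", "*1/*1"),
                   c("*1/*2", "*1/*17", "*2/*2", "*1/*3"), "major")
  expect_identical(toy$n_agree, 3L)
  expect_equal(toy$percent, 75)
  expect_identical(toy$disagreeing, "4")
  # malformed tool cell counts as disagreement, never dropped
  bad <- agreement("*1/*2", "not a diplotype", "major")
  expect_identical(bad$n_agree, 0L)
  expect_identical(bad$n_total, 1L)
  expect_error(agreement("*1/*2", c("*1/*2", "*1/*3"), "major"), "length")
  expect_error(agreement(c("*1/*2", "*1/*2"), c("*1/*2", "*1/*2"), "major",
                         sample_ids = c("a", "a")), "duplicate")
})

test_that("published comparison columns reproduce the printed agreement rates", {
  t2 <- table2_calls()
  aldy_minor <- agreement(t2$manual, t2$aldy, "minor_exact",
                          sample_ids = t2$sample)
  expect_identical(aldy_minor$n_agree, 21L)
  expect_equal(round(aldy_minor$percent, 1), 56.8)
  aldy_major <- agreement(t2$manual, t2$aldy, "major", sample_ids = t2$sample)
  expect_identical(aldy_major$n_agree, 30L)
  expect_equal(round(aldy_major$percent, 1), 81.1)
  pk <- agreement(t2$manual, t2$pharmaku, "major", sample_ids = t2$sample)
  expect_identical(pk$n_agree, 31L)
  expect_equal(round(pk$percent, 1), 83.8)
  pc_first <- agreement(t2$manual, t2$pharmcat, "major", sample_ids = t2$sample)
  expect_identical(pc_first$n_agree, 17L)
  expect_equal(round(pc_first$percent, 1), 45.9)
  pc_any <- agreement(t2$manual, t2$pharmcat, "major", any_listed = TRUE,
                      sample_ids = t2$sample)
  expect_identical(pc_any$n_agree, 32L)
  expect_equal(round(pc_any$percent, 1), 86.5)
})

test_that("coarsening the comparison level never lowers agreement", {
  t2 <- table2_calls()
  for (col in c("aldy", "pharmaku", "pharmcat")) {
    minor <- agreement(t2$manual, t2[[col]], "minor_exact")$percent
    major <- agreement(t2$manual, t2[[col]], "major")$percent
    major_any <- agreement(t2$manual, t2[[col]], "major", any_listed = TRUE)$percent
    expect_gte(major, minor)
    expect_gte(major_any, major)
  }
  # and on random synthetic columns drawn from the fixture diplotype space
  tab <- cyp2c19_table()
  subs <- names(tab$alleles)
  set.seed(11)
  for (rep in 1:5) {
    mk <- function() vapply(1:20, function(i) {
      paste(sample(subs, 2, replace = TRUE), collapse = "/")
    }, "")
    ref <- mk(); tool <- mk()
    expect_gte(agreement(ref, tool, "major")$percent,
               agreement(ref, tool, "minor_exact")$percent)
  }
})

test_that("agreement is symmetric when no list expansion is involved", {
  t2 <- table2_calls()
  for (lv in c("minor_exact", "major")) {
    expect_identical(agreement(t2$manual, t2$aldy, lv)$n_agree,
                     agreement(t2$aldy, t2$manual, lv)$n_agree)
  }
})

test_that("phenotype-level concordance matches the printed 100% agreements", {
  t2 <- table2_calls()
  expect_equal(phenotype_concordance(t2$manual, t2$aldy)$percent, 100)
  expect_equal(phenotype_concordance(t2$manual, t2$pharmaku)$percent, 100)
  # cells without printed phenotypes translate through the function map
  fmap <- load_function_map()
  res <- phenotype_concordance(c("*1/*17", "*2/*2"), c("*1/*17 (RM)", "*1/*1"),
                               fmap = fmap)
  expect_identical(res$n_agree, 1L)
  # a single flipped category reduces agreement by one sample
  flip <- phenotype_concordance(c("*1/*1 (NM)", "*1/*2 (IM)"),
                                c("*1/*1 (NM)", "*1/*2 (NM)"))
  expect_identical(flip$n_agree, 1L)
})
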