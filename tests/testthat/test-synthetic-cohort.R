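tab <- cyp2c19_table()

test_that("identical spec and seed give byte-identical VCF output", {
  spec <- table2_cohort_spec(tab, seed = 5)
  g1 <- generate_cohort(spec, tempfile("det1"))
  g2 <- generate_cohort(spec, tempfile("det2"))
  expect_identical(readLines(g1$vcf), readLines(g2$vcf))
  expect_identical(g1$truth_df, g2$truth_df)
  g3 <- generate_cohort(table2_cohort_spec(tab, seed = 6), tempfile("det3"))
  expect_false(identical(g3$coverage_df$fraction, g1$coverage_df$fraction))
})

test_that("per-sample streams make cohorts stable under sample reordering", {
  nz <- noise_model(p_unphase = 0.4, p_drop = 0.2, p_block_split = 0.3)
  samples <- data.frame(
    sample_id = c("alpha", "beta", "gamma"),
    diplotype = c("*1.002/*2.011", "*2.002/*17.001", "*1.005/*3.002"),
    stringsAsFactors = FALSE)
  g_fwd <- generate_cohort(cohort_spec(samples, tab, noise = nz, seed = 3),
                           tempfile("fwd"))
  g_rev <- generate_cohort(cohort_spec(samples[3:1, ], tab, noise = nz, seed = 3),
                           tempfile("rev"))
  cs_fwd <- read_phased_vcf(g_fwd$vcf)
  cs_rev <- read_phased_vcf(g_rev$vcf)
  for (s in samples$sample_id) {
    expect_identical(cs_fwd[[s]]$calls, cs_rev[[s]]$calls, info = s)
  }
})

test_that("a reference/reference sample emits no alt records", {
  spec <- cohort_spec(
    data.frame(sample_id = "REF", diplotype = "*38.001/*38.001"),
    tab, seed = 1)
  g <- generate_cohort(spec, tempfile("ref"))
  cs <- read_phased_vcf(g$vcf)[["REF"]]
  expect_identical(nrow(cs$calls), 0L)
  expect_identical(format(call_diplotype(cs, tab)), "*38.001/*38.001")
})

test_that("noise-free cohorts are fully phased for samples with two or more hets", {
  g <- generate_cohort(table2_cohort_spec(tab, seed = 2), tempfile("ph"))
  callsets <- read_phased_vcf(g$vcf)
  for (cs in callsets) {
    st <- phasing_stats(restrict_to_region(cs, cyp2c19_region(), TRUE))
    if (st$n_het >= 2) {
      expect_equal(st$phased_fraction, 100, info = cs$sample_id)
    }
  }
  sm <- cohort_phasing_summary(
    lapply(callsets, phasing_stats, region = cyp2c19_region()))
  expect_equal(sm$min_pct, 100)
})

test_that("truth table records the intended diplotypes and phenotypes", {
  g <- generate_cohort(table2_cohort_spec(tab, seed = 1), tempfile("tt"))
  t2 <- table2_calls()
  printed <- vapply(t2$manual, function(s) parse_diplotype(s)$phenotype, "",
                    USE.NAMES = FALSE)
  expect_identical(g$truth_df$phenotype, printed)
  expect_identical(nrow(g$truth_df), 37L)
  # the one subtraction-notation cell is recorded as dropped, not emitted
  s05 <- g$truth_df[g$truth_df$sample_id == "S05", ]
  expect_match(s05$dropped_notation, "94842865")
  expect_true(all(g$coverage_df$fraction >= 0.33 & g$coverage_df$fraction <= 0.96))
})

test_that("injected novel variants come from the reserved range and are novel", {
  nz <- noise_model(novel_rate = 3)
  g <- generate_cohort(cohort_spec(
    data.frame(sample_id = "N1", diplotype = "*1.002/*17.001"),
    tab, noise = nz, seed = 9), tempfile("nv"))
  cs <- read_phased_vcf(g$vcf)[["N1"]]
  injected <- setdiff(cs$calls$id, tab$variant_universe$id)
  expect_gt(length(injected), 0)
  pos <- as.integer(sub("^[^:]*:([0-9]+):.*$", "\\1", injected))
  expect_true(all(pos >= 94830000 & pos <= 94839999))
  expect_false(any(flag_known(injected, tab)))
})

test_that("full unphasing creates suballele-level ambiguity in the caller", {
  cs <- simulate_sample("*1.002/*2.011", tab,
                        noise = noise_model(p_unphase = 1), seed = 4)
  call <- call_diplotype(cs, tab, calling_policy(report_alternatives = 50L))
  alt_subs <- lapply(call$alternatives,
                     function(a) sort(c(a$a$suballele, a$b$suballele)))
  expect_true(any(vapply(alt_subs, function(s) "*2.001" %in% s, TRUE)) ||
                "*2.001" %in% diplotype_suballeles(call))
  expect_gt(length(call$alternatives), 0)
})

test_that("recovery is non-increasing in unphasing and dropout noise", {
  pairs <- all_diplotype_pairs(tab)
  set.seed(13)
  sel <- pairs[sample(seq_along(pairs), 15)]
  recovery <- function(noise, seed_base) {
    hits <- vapply(seq_along(sel), function(i) {
      cs <- simulate_sample(paste(sel[[i]], collapse = "/"), tab,
                            noise = noise, seed = seed_base + i)
      identical(sort(diplotype_suballeles(call_diplotype(cs, tab))),
                sort(sel[[i]]))
    }, TRUE)
    mean(hits)
  }
  for (sd in c(100, 200)) {
    r_up <- vapply(c(0, 0.7, 1), function(p) {
      recovery(noise_model(p_unphase = p), sd)
    }, 0)
    expect_equal(r_up[1], 1)               # zero noise recovers everything
    expect_true(all(diff(r_up) <= 0.15))   # non-increasing up to sampling error
    r_drop <- vapply(c(0, 0.5), function(p) {
      recovery(noise_model(p_drop = p), sd + 31)
    }, 0)
    expect_gte(r_drop[1], r_drop[2])
  }
})

test_that("unresolvable or contradictory specifications fail loudly", {
  expect_error(cohort_spec(
    data.frame(sample_id = "X", diplotype = "*9.001/*1.002"), tab),
    "not resolvable")
  expect_error(cohort_spec(
    data.frame(sample_id = c("A", "A"),
               diplotype = c("*1.002/*1.002", "*1.002/*1.002")), tab),
    "unique")
  # same position, different alt on one strand
  expect_error(cohort_spec(
    data.frame(sample_id = "Y", diplotype = "*2.011 + 94762608T>A/*1.002"), tab),
    "contradictory")
  expect_error(cohort_spec(
    data.frame(sample_id = "Z", diplotype = "*1.002 + rs999/*1.002"), tab),
    "unresolvable extra")
})
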