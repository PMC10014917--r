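tab <- cyp2c19_table()

test_that("haplotype-pair enumeration respects phase structure", {
  # two het variants phased in trans within one block: a single pair
  cs <- read_test_callset(rbind(
    rec(94781859, "0|1:1"),
    rec(94761900, "1|0:1", ref = "C", alt = "T")))
  pairs <- build_haplotype_pairs(cs)
  expect_length(pairs, 1)
  expect_identical(pairs[[1]]$strand_a, "10:94761900:C:T")
  expect_identical(pairs[[1]]$strand_b, "10:94781859:G:A")
  # the same two variants in separate blocks: cis and trans both enumerated
  cs2 <- read_test_callset(rbind(
    rec(94781859, "0|1:1"),
    rec(94761900, "1|0:2", ref = "C", alt = "T")))
  pairs2 <- build_haplotype_pairs(cs2)
  expect_length(pairs2, 2)
  sigs <- sapply(pairs2, function(p) paste(sort(p$strand_a), collapse = ","))
  expect_true(any(sigs == "") || any(grepl(",", sigs)))  # one cis arrangement
  # zero variants: one pair with empty strands
  empty <- read_test_callset(rec(100, "0|0", ref = "A", alt = "G"))
  p0 <- build_haplotype_pairs(empty)
  expect_length(p0, 1)
  expect_length(p0[[1]]$strand_a, 0)
  # hom-alt variants appear on both strands
  hom <- read_test_callset(rec(94781859, "1|1"))
  ph <- build_haplotype_pairs(hom)
  expect_identical(ph[[1]]$strand_a, ph[[1]]$strand_b)
})

test_that("strand matching ranks suballeles by core, defining, extras, name", {
  # *2 core + rs4986894: *2.011 beats *2.001 (one more defining matched)
  m <- match_strand(c("10:94781859:G:A", "10:94762608:T:C"), integer(), tab)
  expect_identical(m[[1]]$suballele, "*2.011")
  expect_identical(m[[2]]$suballele, "*2.001")
  # empty strand falls back to the reference allele
  m0 <- match_strand(character(), integer(), tab)
  expect_identical(m0[[1]]$suballele, "*38.001")
  # a lone unknown variant: reference allele plus one novel extra
  mx <- match_strand("10:94999999:A:G", integer(), tab)
  expect_identical(mx[[1]]$suballele, "*38.001")
  expect_identical(mx[[1]]$extra_novel, "10:94999999:A:G")
})

test_that("strict_missing keeps but flags candidates at unassayed positions", {
  strand <- "10:94781859:G:A"
  strict <- calling_policy(missing_mode = "strict_missing")
  # rs4986894's position unassayed: *2.011 retained with a flagged gap
  m <- match_strand(strand, observed_ref = integer(), tab, strict)
  subs <- vapply(m, `[[`, "", "suballele")
  expect_true("*2.011" %in% subs)
  m211 <- m[[which(subs == "*2.011")]]
  expect_identical(m211$missing_defining, "10:94762608:T:C")
  expect_identical(m[[1]]$suballele, "*2.001")  # no-gap candidate still wins
  # position assayed as reference: *2.011 is truly incompatible
  m_obs <- match_strand(strand, observed_ref = 94762608L, tab, strict)
  expect_false("*2.011" %in% vapply(m_obs, `[[`, "", "suballele"))
})

test_that("fully phased *1.002/*2.011 resolves the suballele via phase", {
  cs <- read_test_callset(rbind(
    rec(94842866, "0|1:1", ref = "A", alt = "G"),
    rec(94770001, "0|1:1", ref = "T", alt = "C"),
    rec(94781859, "1|0:1"),
    rec(94762608, "1|0:1", ref = "T", alt = "C")))
  call <- call_diplotype(cs, tab)
  expect_identical(format(call), "*1.002/*2.011")
  expect_length(call$alternatives, 0)
  expect_true(call$primary$a$phase_supported && call$primary$b$phase_supported)
})

test_that("unphasing rs4986894 yields the *2.001-plus-extra alternative", {
  cs <- read_test_callset(rbind(
    rec(94842866, "0|1:1", ref = "A", alt = "G"),
    rec(94770001, "0|1:1", ref = "T", alt = "C"),
    rec(94781859, "1|0:1"),
    rec(94762608, "0/1", ref = "T", alt = "C")))
  call <- call_diplotype(cs, tab)
  expect_identical(format(call), "*1.002/*2.011")  # most-variants-accounted ranking
  expect_length(call$alternatives, 1)
  alt <- call$alternatives[[1]]
  expect_setequal(c(alt$a$suballele, alt$b$suballele), c("*1.002", "*2.001"))
  expect_identical(alt$a$extra_known, "10:94762608:T:C")
})

test_that("no variants and observed-reference positions give reference/reference", {
  cs <- read_test_callset(rbind(rec(94781859, "0|0"),
                                rec(94842866, "0|0", ref = "A", alt = "G")))
  call <- call_diplotype(cs, tab)
  expect_identical(format(call), "*38.001/*38.001")
})

test_that("calling is invariant under strand swap and repeated runs", {
  base <- rbind(
    rec(94761900, "0|1:1", ref = "C", alt = "T"),
    rec(94772038, "1|0:1", ref = "A", alt = "C"),
    rec(94772039, "1|0:1", ref = "T", alt = "G"),
    rec(94781616, "1|0:1", ref = "A", alt = "G"))
  flip <- function(g) chartr("01", "10", g)
  swapped <- base; swapped$S1 <- ifelse(grepl("\\|", base$S1),
                                        paste0(flip(substr(base$S1, 1, 3)),
                                               substring(base$S1, 4)), base$S1)
  c1 <- call_diplotype(read_test_callset(base), tab)
  c2 <- call_diplotype(read_test_callset(swapped), tab)
  expect_identical(format(c1), format(c2))
  expect_identical(format(c1), format(call_diplotype(read_test_callset(base), tab)))
  expect_identical(format(c1), "*17.001/*38.003 + g.94781616A>G")
})

test_that("novel-suballele detection reports phased extras not in any sibling", {
  cs <- read_test_callset(rbind(
    rec(94761900, "0|1:1", ref = "C", alt = "T"),
    rec(94772038, "1|0:1", ref = "A", alt = "C"),
    rec(94772039, "1|0:1", ref = "T", alt = "G"),
    rec(94781616, "1|0:1", ref = "A", alt = "G")))
  call <- call_diplotype(cs, tab)
  nv <- detect_novel_suballeles(call, tab)
  expect_identical(nv$descriptor, "*38.003 + g.94781616A>G")
  expect_true(nv$confident)
  # no extras -> no candidates
  clean <- call_diplotype(read_test_callset(rec(94781859, "0|1:1")), tab)
  expect_identical(nrow(detect_novel_suballeles(clean, tab)), 0L)
  # extra unphased relative to the defining variants -> unconfirmed
  cs_u <- read_test_callset(rbind(
    rec(94772038, "1|0:1", ref = "A", alt = "C"),
    rec(94772039, "1|0:1", ref = "T", alt = "G"),
    rec(94781616, "0/1", ref = "A", alt = "G")))
  call_u <- call_diplotype(cs_u, tab)
  nv_u <- detect_novel_suballeles(call_u, tab)
  hit <- nv_u[grepl("94781616", nv_u$extras), , drop = FALSE]
  if (nrow(hit) > 0) expect_false(any(hit$confident))
})

test_that("every fixture diplotype is recovered exactly from a phased sample", {
  pairs <- all_diplotype_pairs(tab)
  for (p in pairs) {
    cs <- simulate_sample(paste(p, collapse = "/"), tab)
    call <- call_diplotype(cs, tab)
    expect_identical(sort(diplotype_suballeles(call)), sort(p),
                     info = paste(p, collapse = "/"))
  }
})

test_that("primary call matches the brute-force oracle under noise", {
  pairs <- all_diplotype_pairs(tab)
  set.seed(7)
  picks <- sample(seq_along(pairs), 12)
  noises <- list(noise_model(p_unphase = 0.5), noise_model(p_drop = 0.4),
                 noise_model(p_unphase = 1, p_block_split = 0.5))
  for (k in seq_along(picks)) {
    p <- pairs[[picks[k]]]
    nz <- noises[[(k %% length(noises)) + 1L]]
    cs <- simulate_sample(paste(p, collapse = "/"), tab, noise = nz, seed = k)
    if (sum(cs$calls$zygosity == "het") > 8) next
    got <- sort(diplotype_suballeles(call_diplotype(cs, tab)))
    oracle <- oracle_call(cs, tab)
    expect_true(paste(got, collapse = "/") %in% oracle$diplotypes,
                info = sprintf("%s under noise %d", paste(p, collapse = "/"), k))
  }
})

test_that("removing phase information never shrinks the alternatives list", {
  generous <- calling_policy(report_alternatives = 100L)
  for (d in c("*1.002/*2.011", "*2.002/*17.001", "*1.005/*3.002")) {
    phased <- call_diplotype(simulate_sample(d, tab), tab, generous)
    unphased <- call_diplotype(
      simulate_sample(d, tab, noise = noise_model(p_unphase = 1)), tab,
      generous)
    expect_gte(length(unphased$alternatives), length(phased$alternatives))
  }
})

test_that("enumeration cap truncates deterministically with a flag", {
  n <- 15
  recs <- do.call(rbind, lapply(seq_len(n), function(i) {
    rec(94800000 + i, "0/1", ref = "A", alt = "G")
  }))
  cs <- read_test_callset(recs)
  pol <- calling_policy(max_unphased_enumeration = 3L)
  call <- call_diplotype(cs, tab, pol)
  expect_true(call$truncated)
  expect_length(call$unassigned, n - 1 - 3)
  expect_identical(format(call, "major"), "*38/*38")
  rerun <- call_diplotype(cs, tab, pol)
  expect_identical(call$unassigned, rerun$unassigned)
})
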