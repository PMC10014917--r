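# Build a small VCF file from a record table and return its path.
# records: data.frame with chrom, pos, ref, alt and one genotype string
# column per sample (e.g. "0|1:100", "0/1", "1|1", "0|0", "./.").
write_test_vcf <- function(records, samples) {
  path <- tempfile(fileext = ".vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=10,length=133797422>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=PS,Number=1,Type=Integer,Description="Phase set">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(records)), function(i) {
    gts <- vapply(samples, function(s) {
      g <- records[[s]][i]
      if (!grepl(":", g, fixed = TRUE)) g <- paste0(g, ":.")
      g
    }, "")
    paste(c(records$chrom[i], records$pos[i], ".", records$ref[i],
            records$alt[i], ".", "PASS", ".", "GT:PS", gts), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  path
}

# Single-sample convenience wrapper returning the parsed callset.
read_test_callset <- function(records, sample = "S1") {
  read_phased_vcf(write_test_vcf(records, sample))[[sample]]
}

# Record-table row constructor.
rec <- function(pos, gt, ref = "G", alt = "A", chrom = "10") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, S1 = gt,
             stringsAsFactors = FALSE)
}

# A minimal two-allele table built in code (reference + one defined allele).
tiny_table <- function() {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    "gene\tsuballele\tmajor\tfunction\tchrom\tpos\tref\talt\trsid\tis_core",
    "GX\t*1.001\t*1\tnormal\t\t\t\t\t\tFALSE",
    "GX\t*1.001\t*1\t\t10\t100\tA\tG\t\tTRUE",
    "GX\t*5.001\t*5\tnormal\t\t\t\t\t\tFALSE"), tsv)
  load_allele_table(tsv)
}

# All unordered suballele pairs of an allele table.
all_diplotype_pairs <- function(table) {
  subs <- names(table$alleles)
  out <- list()
  for (i in seq_along(subs)) for (j in i:length(subs)) {
    out[[length(out) + 1L]] <- c(subs[i], subs[j])
  }
  out
}

# Generate a one-sample zero-noise (unless given) cohort for a diplotype
# string and return the parsed callset restricted to the CYP2C19 region.
simulate_sample <- function(diplotype, table = cyp2c19_table(),
                            noise = noise_model(), seed = 1L,
                            sample_id = "SIM") {
  spec <- cohort_spec(
    data.frame(sample_id = sample_id, diplotype = diplotype,
               stringsAsFactors = FALSE),
    table, noise = noise, seed = seed)
  g <- generate_cohort(spec, tempfile("sim"))
  cs <- read_phased_vcf(g$vcf)[[sample_id]]
  restrict_to_region(cs, cyp2c19_region(), TRUE)
}
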