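#' Published multi-caller comparison table
#'
#' Returns the bundled 37-sample comparison fixture: the manually curated
#' diplotype column (the phasing-aware reference assignment, with printed
#' phenotypes) alongside the verbatim output columns of three star-allele
#' callers (Aldy, PharmaKU, PharmCat). PharmCat cells carry the manually
#' confirmed diplotype in brackets when it appeared in the output list but
#' not first; PharmCat prints no phenotypes. All cells are kept verbatim,
#' including one manual cell using a `–variant` subtraction annotation.
#'
#' @return A data frame with columns `sample`, `manual`, `aldy`, `pharmaku`,
#'   `pharmcat`.
#' @export
table2_calls <- function() {
  path <- system.file("extdata", "table2_calls.tsv", package = "phasestar",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Cohort specification for the published comparison cohort
#'
#' Encodes the manual (reference) diplotype column of [table2_calls()] as a
#' synthetic-cohort specification, so the full calling pipeline can be run
#' against a phased VCF that realizes those 37 diplotypes.
#'
#' @param table An [allele_table] (default: bundled CYP2C19 fixture).
#' @param noise A [noise_model()] (default: noise-free).
#' @param seed Master seed.
#' @return A [cohort_spec()].
#' @export
table2_cohort_spec <- function(table = cyp2c19_table(), noise = noise_model(),
                               seed = 1L) {
  t2 <- table2_calls()
  samples <- data.frame(sample_id = sprintf("S%02d", t2$sample),
                        diplotype = t2$manual, stringsAsFactors = FALSE)
  cohort_spec(samples, table, noise = noise, seed = seed)
}
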