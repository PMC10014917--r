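#' phasestar: phasing-aware star-allele assignment for CYP2C19
#'
#' Diplotype calling from phased VCF genotypes against a PharmVar-like
#' allele-definition table, phenotype translation, phasing statistics,
#' variant cataloguing, caller concordance and synthetic phased-cohort
#' generation.
#'
#' @keywords internal
"_PACKAGE"

# Internal variant identity: "chrom:pos:ref:alt". rsid is decorative and never
# enters the key.
variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Construct a table of variant keys
#'
#' A variant key identifies a genomic change by `(chrom, pos, ref, alt)` in
#' 1-based GRCh38 coordinates; an optional dbSNP rsid may be attached but is
#' decorative (equality ignores it). Only SNVs and simple indels with
#' uppercase A/C/G/T ref/alt strings are accepted.
#'
#' @param chrom Chromosome label(s).
#' @param pos 1-based genomic position(s).
#' @param ref,alt Reference and alternate base strings.
#' @param rsid Optional dbSNP identifiers (`NA` when absent).
#' @return A `data.frame` with columns `id, chrom, pos, ref, alt, rsid`.
#' @examples
#' variant_keys("10", 94781859, "G", "A", "rs4244285")
#' @export
variant_keys <- function(chrom, pos, ref, alt, rsid = NA_character_) {
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  ref <- as.character(ref)
  alt <- as.character(alt)
  rsid <- rep_len(as.character(rsid), length(pos))
  rsid[!is.na(rsid) & rsid == ""] <- NA_character_
  if (any(is.na(pos)) || any(pos < 1L)) {
    stop("variant positions must be integers >= 1", call. = FALSE)
  }
  bad <- !grepl("^[ACGT]+$", ref) | !grepl("^[ACGT]+$", alt)
  if (any(bad)) {
    stop("ref/alt must be non-empty uppercase A/C/G/T strings (first offender: ",
         ref[bad][1], ">", alt[bad][1], ")", call. = FALSE)
  }
  if (any(ref == alt)) {
    stop("ref and alt must differ", call. = FALSE)
  }
  data.frame(
    id = variant_id(chrom, pos, ref, alt),
    chrom = chrom, pos = pos, ref = ref, alt = alt, rsid = rsid,
    stringsAsFactors = FALSE
  )
}

# Render a variant in HGVS-like g-dot shorthand, e.g. "g.94781616A>G".
gdot <- function(pos, ref, alt) paste0("g.", pos, ref, ">", alt)

# Parse "g.94781616A>G" / "94781616A>G" into (pos, ref, alt); NULL on failure.
parse_gdot <- function(s) {
  m <- regmatches(s, regexec("^(?:g\\.)?([0-9]+)([ACGT]+)>([ACGT]+)$", s))[[1]]
  if (length(m) == 0) return(NULL)
  list(pos = as.integer(m[2]), ref = m[3], alt = m[4])
}

# Natural ordering key for star-allele names: "*2.011" -> c(2, 11).
star_sort_key <- function(names) {
  core <- sub("^\\*", "", names)
  major_num <- suppressWarnings(as.numeric(sub("\\..*$", "", core)))
  minor_num <- suppressWarnings(ifelse(grepl("\\.", core),
                                       as.numeric(sub("^[^.]*\\.", "", core)), 0))
  order(major_num, minor_num, names)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
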