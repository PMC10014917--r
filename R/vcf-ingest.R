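#' Gene regions
#'
#' A gene region is a 1-based inclusive coordinate window plus a flank width
#' (the capture design targets ~10 kb up- and downstream of each gene).
#'
#' @param gene Gene symbol.
#' @param chrom Chromosome label as used in the VCF.
#' @param start,end 1-based inclusive gene body coordinates.
#' @param flank Bases added up- and downstream (default 10000).
#' @return A `gene_region` object.
#' @export
gene_region <- function(gene, chrom, start, end, flank = 10000L) {
  start <- as.integer(start); end <- as.integer(end); flank <- as.integer(flank)
  stopifnot(start <= end, flank >= 0L)
  structure(list(gene = gene, chrom = as.character(chrom),
                 start = start, end = end, flank = flank),
            class = "gene_region")
}

#' CYP2C19 gene region (GRCh38)
#'
#' Gene-body coordinates on chromosome 10 (NC_000010.11) with the default
#' 10 kb flanks used by the capture panel.
#' @param flank Flank width in bases.
#' @return A [gene_region].
#' @export
cyp2c19_region <- function(flank = 10000L) {
  gene_region("CYP2C19", "10", 94762681L, 94853205L, flank = flank)
}

new_sample_callset <- function(sample_id, calls, observed_ref) {
  calls <- calls[order(calls$pos, calls$id), , drop = FALSE]
  rownames(calls) <- NULL
  if (anyDuplicated(calls$id)) {
    stop("duplicate variant in callset for sample ", sample_id, call. = FALSE)
  }
  structure(list(sample_id = sample_id, calls = calls,
                 observed_ref = observed_ref),
            class = "sample_callset")
}

#' @export
print.sample_callset <- function(x, ...) {
  nh <- sum(x$calls$zygosity == "het")
  cat(sprintf("<sample_callset> %s: %d calls (%d het, %d phased), %d observed-ref positions\n",
              x$sample_id, nrow(x$calls), nh, sum(x$calls$phased),
              nrow(x$observed_ref)))
  invisible(x)
}

empty_calls <- function() {
  data.frame(id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(),
             a1 = integer(), a2 = integer(), phased = logical(),
             phase_set = character(), zygosity = character(),
             stringsAsFactors = FALSE)
}

#' Read a phased VCF into per-sample call sets
#'
#' Parses GT (and PS, when present) FORMAT fields of a VCF 4.2+ file into one
#' call set per sample. Multiallelic records are decomposed into per-alternate
#' variant keys. Hom-ref genotypes are dropped from `calls` but their
#' positions are recorded as *observed reference*, so downstream policies can
#' distinguish an assayed-reference position from a missing one. A `|`
#' genotype separator marks a phased call; phased heterozygous calls carry
#' their phase-set identifier.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param samples Optional character vector restricting which sample columns
#'   to read (error when a requested sample is absent).
#' @return A named list of `sample_callset` objects.
#' @export
read_phased_vcf <- function(path, samples = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix[, c("CHROM", "POS", "REF", "ALT"), drop = FALSE],
                       stringsAsFactors = FALSE)
  if (ncol(vcf@gt) < 2) {
    stop("VCF has no sample genotype columns", call. = FALSE)
  }
  fmt <- vcf@gt[, "FORMAT"]
  if (!all(grepl("(^|:)GT(:|$)", fmt))) {
    stop("malformed VCF record (line ", which(!grepl("(^|:)GT(:|$)", fmt))[1],
         " of body): missing GT in FORMAT", call. = FALSE)
  }
  all_samples <- setdiff(colnames(vcf@gt), "FORMAT")
  if (is.null(samples)) samples <- all_samples
  absent <- setdiff(samples, all_samples)
  if (length(absent) > 0) {
    stop("sample(s) not found in VCF: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ps <- tryCatch(suppressWarnings(vcfR::extract.gt(vcf, element = "PS")),
                 error = function(e) NULL)
  pos <- as.integer(fix$POS)

  out <- lapply(samples, function(s) {
    calls_list <- list()
    obs_chrom <- character(); obs_pos <- integer()
    for (i in seq_len(nrow(fix))) {
      g <- gt[i, s]
      if (is.na(g) || g %in% c(".", "./.", ".|.")) next
      phased <- grepl("|", g, fixed = TRUE)
      parts <- strsplit(g, "[/|]")[[1]]
      if (!all(grepl("^[0-9]+$", parts)) || !length(parts) %in% c(1L, 2L)) {
        stop("malformed genotype '", g, "' at VCF body line ", i,
             " sample ", s, call. = FALSE)
      }
      idx <- as.integer(parts)
      if (length(idx) == 1L) idx <- c(idx, idx)  # haploid treated as hom
      if (all(idx == 0L)) {
        obs_chrom <- c(obs_chrom, fix$CHROM[i]); obs_pos <- c(obs_pos, pos[i])
        next
      }
      alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
      if (any(idx > length(alts))) {
        stop("malformed record at VCF body line ", i,
             ": allele index exceeds ALT count", call. = FALSE)
      }
      ps_i <- if (!is.null(ps)) ps[i, s] else NA_character_
      if (!is.na(ps_i) && ps_i == ".") ps_i <- NA_character_
      for (k in sort(unique(idx[idx > 0L]))) {
        a1 <- as.integer(idx[1] == k); a2 <- as.integer(idx[2] == k)
        zyg <- if (a1 + a2 == 2L) "hom_alt" else "het"
        calls_list[[length(calls_list) + 1L]] <- data.frame(
          id = variant_id(fix$CHROM[i], pos[i], fix$REF[i], alts[k]),
          chrom = fix$CHROM[i], pos = pos[i], ref = fix$REF[i], alt = alts[k],
          a1 = a1, a2 = a2, phased = phased,
          phase_set = if (phased && zyg == "het") ps_i else NA_character_,
          zygosity = zyg, stringsAsFactors = FALSE)
      }
    }
    calls <- if (length(calls_list)) do.call(rbind, calls_list) else empty_calls()
    new_sample_callset(s, calls,
                       data.frame(chrom = obs_chrom, pos = obs_pos,
                                  stringsAsFactors = FALSE))
  })
  names(out) <- samples
  out
}

#' Phase blocks of a call set
#'
#' Groups the phased heterozygous calls of a sample by phase-set identifier.
#' @param callset A `sample_callset`.
#' @return A named list of call data frames, one per phase set.
#' @export
phase_blocks <- function(callset) {
  het <- callset$calls[callset$calls$zygosity == "het" & callset$calls$phased &
                         !is.na(callset$calls$phase_set), , drop = FALSE]
  split(het, het$phase_set)
}

#' Restrict a call set to a gene region
#'
#' Keeps calls (and observed-reference positions) inside the region window:
#' `[start - flank, end + flank]` with flanks, `[start, end]` without.
#'
#' @param callset A `sample_callset`.
#' @param region A [gene_region].
#' @param include_flanks Include the up/downstream flanks (default `TRUE`).
#' @return The restricted `sample_callset` (possibly empty).
#' @export
restrict_to_region <- function(callset, region, include_flanks = TRUE) {
  lo <- if (include_flanks) region$start - region$flank else region$start
  hi <- if (include_flanks) region$end + region$flank else region$end
  keep <- callset$calls$chrom == region$chrom &
    callset$calls$pos >= lo & callset$calls$pos <= hi
  keep_obs <- callset$observed_ref$chrom == region$chrom &
    callset$observed_ref$pos >= lo & callset$observed_ref$pos <= hi
  new_sample_callset(callset$sample_id,
                     callset$calls[keep, , drop = FALSE],
                     callset$observed_ref[keep_obs, , drop = FALSE])
}

#' Sample-level coverage QC policy
#'
#' Samples whose fraction of target bases at or above `depth_threshold` falls
#' strictly below `min_fraction` are excluded (the 10%-of-target-bases-at-30X
#' exclusion rule; a sample at exactly the threshold is retained).
#'
#' @param min_fraction Minimum fraction of target bases (default 0.10).
#' @param depth_threshold Coverage depth defining "covered" (default 30).
#' @return A `qc_policy` object.
#' @export
qc_policy <- function(min_fraction = 0.10, depth_threshold = 30L) {
  stopifnot(min_fraction >= 0, min_fraction <= 1, depth_threshold > 0)
  structure(list(min_fraction = min_fraction,
                 depth_threshold = as.integer(depth_threshold)),
            class = "qc_policy")
}

#' Apply the sample-level coverage filter
#'
#' @param coverage A data frame with columns `sample_id` and `fraction`
#'   (fraction of target bases reaching the policy's depth threshold), or the
#'   path to a two-column TSV of the same content.
#' @param policy A [qc_policy].
#' @return A list with character vectors `retained` and `excluded`.
#' @examples
#' cov <- data.frame(sample_id = c("a", "b"), fraction = c(0.09, 0.10))
#' sample_qc_filter(cov)  # "a" excluded, "b" retained (strict less-than)
#' @export
sample_qc_filter <- function(coverage, policy = qc_policy()) {
  if (is.character(coverage)) coverage <- read_coverage_table(coverage)
  stopifnot(all(c("sample_id", "fraction") %in% names(coverage)))
  f <- as.numeric(coverage$fraction)
  if (any(is.na(f)) || any(f < 0) || any(f > 1)) {
    stop("coverage fractions must lie in [0, 1]", call. = FALSE)
  }
  excluded <- f < policy$min_fraction
  list(retained = coverage$sample_id[!excluded],
       excluded = coverage$sample_id[excluded])
}

#' Read gene regions from a BED file
#'
#' BED coordinates are 0-based half-open; they are converted to the 1-based
#' inclusive convention used everywhere inside the package at this boundary.
#' Expected columns: chrom, start, end, name (the gene symbol).
#'
#' @param path BED file path.
#' @param flank Flank width applied to every region (default 10000).
#' @return A named list of [gene_region] objects keyed by gene symbol.
#' @export
read_gene_regions_bed <- function(path, flank = 10000L) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(bed) < 4) stop("BED file needs chrom, start, end, name columns",
                          call. = FALSE)
  out <- lapply(seq_len(nrow(bed)), function(i) {
    gene_region(bed[i, 4], bed[i, 1],
                start = as.integer(bed[i, 2]) + 1L,  # 0-based -> 1-based
                end = as.integer(bed[i, 3]),         # half-open -> inclusive
                flank = flank)
  })
  stats::setNames(out, bed[, 4])
}

#' Read a per-sample coverage summary TSV
#'
#' @param path TSV with columns `sample_id` and `fraction`.
#' @return A data frame.
#' @export
read_coverage_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
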