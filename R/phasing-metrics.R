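#' Per-sample phasing statistics
#'
#' Computes, for one sample, how many variants were phased to their allele of
#' origin *in relation to at least one other variant*: a heterozygous call
#' counts as phased-with-partner only when its phase block contains at least
#' two heterozygous calls (a phased call alone in its block carries no
#' relational phase information). The default denominator is heterozygous
#' calls only (homozygous calls need no phasing); `denominator = "all"` uses
#' every non-hom-ref call for sensitivity checks.
#'
#' @param callset A `sample_callset`.
#' @param region Optional [gene_region] to restrict to (flanks included).
#' @param denominator `"het"` (default) or `"all"`.
#' @return A `phasing_stats` object: `sample_id`, `n_het`, `n_denominator`,
#'   `n_phased_with_partner`, `phased_fraction` (percent, `NA` when the
#'   denominator is zero, with `defined = FALSE`), and `block_spans`, a data
#'   frame of per-block het counts and spans in bp (span includes the length
#'   of the rightmost reference allele).
#' @export
phasing_stats <- function(callset, region = NULL,
                          denominator = c("het", "all")) {
  denominator <- match.arg(denominator)
  if (!is.null(region)) callset <- restrict_to_region(callset, region, TRUE)
  calls <- callset$calls
  het <- calls[calls$zygosity == "het", , drop = FALSE]
  blocks <- phase_blocks(callset)
  block_n <- vapply(blocks, nrow, 0L)
  partnered <- if (length(blocks)) {
    sum(block_n[block_n >= 2L])
  } else 0L
  n_den <- if (denominator == "het") nrow(het) else nrow(calls)
  frac <- if (n_den > 0) 100 * partnered / n_den else NA_real_
  spans <- if (length(blocks)) {
    data.frame(
      phase_set = names(blocks),
      n_het = as.integer(block_n),
      span = vapply(blocks, function(b) {
        max(b$pos + nchar(b$ref) - 1L) - min(b$pos)
      }, 0L),
      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(phase_set = character(), n_het = integer(), span = integer(),
               stringsAsFactors = FALSE)
  }
  structure(list(sample_id = callset$sample_id,
                 n_het = nrow(het), n_denominator = n_den,
                 n_phased_with_partner = as.integer(partnered),
                 phased_fraction = frac,
                 defined = n_den > 0,
                 denominator = denominator,
                 block_spans = spans),
            class = "phasing_stats")
}

#' @export
print.phasing_stats <- function(x, ...) {
  cat(sprintf("<phasing_stats> %s: %d/%d phased with a partner (%s%%), %d block(s)\n",
              x$sample_id, x$n_phased_with_partner, x$n_denominator,
              ifelse(x$defined, sprintf("%.1f", x$phased_fraction), "NA"),
              nrow(x$block_spans)))
  invisible(x)
}

#' Cohort phasing summary
#'
#' Aggregates per-sample [phasing_stats()]: arithmetic mean, minimum and
#' maximum of the defined phased fractions (samples with an undefined
#' fraction are excluded from the mean and counted), plus mean phase-block
#' span and the span range.
#'
#' @param stats A list of `phasing_stats` objects.
#' @return A list with `mean_pct`, `min_pct`, `max_pct`, `n_samples`,
#'   `n_undefined`, `mean_block_span`, `span_range`.
#' @export
cohort_phasing_summary <- function(stats) {
  if (length(stats) == 0) stop("no phasing statistics supplied", call. = FALSE)
  frac <- vapply(stats, `[[`, 0, "phased_fraction")
  defined <- vapply(stats, `[[`, TRUE, "defined")
  if (!any(defined)) stop("no sample has a defined phased fraction", call. = FALSE)
  spans <- unlist(lapply(stats, function(s) s$block_spans$span))
  list(
    mean_pct = mean(frac[defined]),
    min_pct = min(frac[defined]),
    max_pct = max(frac[defined]),
    n_samples = length(stats),
    n_undefined = sum(!defined),
    mean_block_span = if (length(spans)) mean(spans) else NA_real_,
    span_range = if (length(spans)) range(spans) else c(NA_real_, NA_real_)
  )
}

#' Per-sample phasing report table
#'
#' @param stats A list of `phasing_stats`.
#' @return A data frame with one row per sample: `sample_id`, `n_het`,
#'   `n_phased_with_partner`, `phased_fraction`, `n_blocks`, `mean_span`.
#' @export
phasing_report <- function(stats) {
  do.call(rbind, lapply(stats, function(s) {
    data.frame(sample_id = s$sample_id, n_het = s$n_het,
               n_phased_with_partner = s$n_phased_with_partner,
               phased_fraction = s$phased_fraction,
               n_blocks = nrow(s$block_spans),
               mean_span = if (nrow(s$block_spans)) mean(s$block_spans$span) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
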