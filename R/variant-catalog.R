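#' Flag variants as known or novel
#'
#' A variant is *known* when it appears in the star-allele nomenclature (or an
#' optional extra clinical panel); everything else is *novel* in the sense of
#' "not part of current PGx nomenclature".
#'
#' @param variants A data frame of variant keys (from [variant_keys()]) or a
#'   character vector of `chrom:pos:ref:alt` ids.
#' @param nomenclature An [allele_table].
#' @param extra_panel Optional additional variant keys (data frame or id
#'   vector) counted as known.
#' @return A named logical vector, one entry per variant id.
#' @export
flag_known <- function(variants, nomenclature, extra_panel = NULL) {
  ids <- if (is.data.frame(variants)) variants$id else as.character(variants)
  panel <- nomenclature$variant_universe$id
  if (!is.null(extra_panel)) {
    panel <- union(panel,
                   if (is.data.frame(extra_panel)) extra_panel$id else extra_panel)
  }
  stats::setNames(ids %in% panel, ids)
}

#' Count unique variants and singletons across a cohort
#'
#' A *carrier* of a variant is a sample whose call set contains it in any
#' non-hom-ref genotype (het or hom-alt). A *singleton* is carried by exactly
#' one sample.
#'
#' @param cohort_calls A list of `sample_callset` objects.
#' @return A list: `n_unique`, `n_singletons`, and `carrier_counts`, a data
#'   frame of per-variant carrier counts.
#' @export
count_singletons <- function(cohort_calls) {
  if (length(cohort_calls) == 0) stop("empty cohort", call. = FALSE)
  per_sample <- lapply(cohort_calls, function(cs) unique(cs$calls$id))
  tab <- table(unlist(per_sample))
  counts <- data.frame(id = as.character(names(tab) %||% character()),
                       carriers = as.integer(tab),
                       stringsAsFactors = FALSE)
  list(n_unique = nrow(counts),
       n_singletons = sum(counts$carriers == 1L),
       carrier_counts = counts[order(-counts$carriers, counts$id), ])
}

#' Impact-threshold configuration
#'
#' @param cadd_threshold CADD score cutoff (default 10).
#' @param threshold_mode `"strict_greater"` (score > cutoff, the Methods
#'   wording) or `"greater_or_equal"` (score >= cutoff, the Discussion
#'   wording); both printed high scorers (16.4 and 10.4) pass either way.
#' @return An `annotation_config` object.
#' @export
annotation_config <- function(cadd_threshold = 10,
                              threshold_mode = c("strict_greater",
                                                 "greater_or_equal")) {
  stopifnot(cadd_threshold > 0)
  structure(list(cadd_threshold = cadd_threshold,
                 threshold_mode = match.arg(threshold_mode)),
            class = "annotation_config")
}

#' Classify variant impact from CADD scores
#'
#' @param cadd Numeric CADD scores (`NA` for unscored variants).
#' @param config An [annotation_config].
#' @return A character vector in `{"high_impact_candidate", "below_threshold",
#'   "unscored"}`.
#' @examples
#' classify_impact(c(16.4, 10.4, 3.1, NA))
#' @export
classify_impact <- function(cadd, config = annotation_config()) {
  if (any(!is.na(cadd) & cadd < 0)) stop("CADD scores must be >= 0", call. = FALSE)
  high <- if (config$threshold_mode == "strict_greater") {
    cadd > config$cadd_threshold
  } else {
    cadd >= config$cadd_threshold
  }
  ifelse(is.na(cadd), "unscored",
         ifelse(high, "high_impact_candidate", "below_threshold"))
}

#' Read a per-variant annotation TSV
#'
#' Columns: `chrom pos ref alt cadd consequence` (empty `cadd` means
#' unscored).
#' @param path Path to the TSV.
#' @return A data frame with an added `id` column.
#' @export
read_annotation_table <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(ann)))
  ann$id <- variant_id(ann$chrom, ann$pos, ann$ref, ann$alt)
  if (!"cadd" %in% names(ann)) ann$cadd <- NA_real_
  ann$cadd <- suppressWarnings(as.numeric(ann$cadd))
  if (!"consequence" %in% names(ann)) ann$consequence <- NA_character_
  ann
}

#' Cross-tabulate consequence classes by known/novel status
#'
#' @param annotations A data frame with columns `id` and `consequence`.
#' @param known_flags Named logical vector (from [flag_known()]).
#' @return A data frame cross-tabulating consequence class against
#'   known/novel, with totals preserved.
#' @export
consequence_breakdown <- function(annotations, known_flags) {
  if (nrow(annotations) == 0) {
    return(data.frame(consequence = character(), status = character(),
                      n = integer(), stringsAsFactors = FALSE))
  }
  status <- ifelse(known_flags[annotations$id], "known", "novel")
  tab <- as.data.frame(table(consequence = annotations$consequence,
                             status = status),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tab[tab$n > 0, , drop = FALSE]
}

#' Cohort variant catalog report
#'
#' One-stop per-gene characterization: unique variant count, known/novel
#' split, singleton count and high-impact count.
#'
#' @param cohort_calls A list of `sample_callset` objects.
#' @param nomenclature An [allele_table].
#' @param annotations Optional annotation data frame (see
#'   [read_annotation_table()]).
#' @param config An [annotation_config].
#' @return A one-row data frame: `n_unique, n_known, n_novel, n_singletons,
#'   n_high_impact`.
#' @export
variant_catalog <- function(cohort_calls, nomenclature, annotations = NULL,
                            config = annotation_config()) {
  singles <- count_singletons(cohort_calls)
  ids <- singles$carrier_counts$id
  known <- flag_known(ids, nomenclature)
  n_high <- if (!is.null(annotations)) {
    ann <- annotations[annotations$id %in% ids, , drop = FALSE]
    sum(classify_impact(ann$cadd, config) == "high_impact_candidate")
  } else NA_integer_
  data.frame(gene = nomenclature$gene,
             n_unique = singles$n_unique,
             n_known = sum(known), n_novel = sum(!known),
             n_singletons = singles$n_singletons,
             n_high_impact = n_high,
             stringsAsFactors = FALSE)
}
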