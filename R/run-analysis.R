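#' Run configuration
#'
#' Collects the paths and policy blocks for an end-to-end analysis run.
#' A configuration can also be loaded from a YAML file with the same field
#' names via [load_run_config()]; unset fields take these defaults.
#'
#' @param vcf Path to the phased VCF.
#' @param definitions Path to the allele-definition table (default: bundled
#'   CYP2C19 fixture).
#' @param annotations Optional per-variant annotation TSV.
#' @param coverage Optional per-sample coverage TSV for the QC filter.
#' @param compare Optional path to a call-comparison TSV whose first column
#'   is `sample`, second the reference column, and remaining columns tool
#'   calls.
#' @param region A [gene_region] (default CYP2C19).
#' @param include_flanks Use the flanked region (default `TRUE`).
#' @param qc A [qc_policy].
#' @param policy A [calling_policy].
#' @param annotation_cfg An [annotation_config].
#' @param guideline `"CPIC"` or `"DPWG"`.
#' @param out_dir Directory for per-stage TSV outputs.
#' @return A `run_config` object.
#' @export
run_config <- function(vcf, definitions = NULL, annotations = NULL,
                       coverage = NULL, compare = NULL,
                       region = cyp2c19_region(), include_flanks = TRUE,
                       qc = qc_policy(), policy = calling_policy(),
                       annotation_cfg = annotation_config(),
                       guideline = "CPIC",
                       out_dir = tempfile("phasestar_run")) {
  structure(list(vcf = vcf,
                 definitions = definitions %||%
                   system.file("extdata", "cyp2c19_alleles_synthetic.tsv",
                               package = "phasestar", mustWork = TRUE),
                 annotations = annotations, coverage = coverage,
                 compare = compare, region = region,
                 include_flanks = include_flanks,
                 qc = qc, policy = policy, annotation_cfg = annotation_cfg,
                 guideline = guideline, out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file; recognized scalar fields: `vcf, definitions,
#'   annotations, coverage, compare, guideline, out_dir, include_flanks`,
#'   plus nested blocks `qc: {min_fraction, depth_threshold}`,
#'   `policy: {missing_mode, max_unphased_enumeration, report_alternatives}`,
#'   `annotation: {cadd_threshold, threshold_mode}` and
#'   `region: {gene, chrom, start, end, flank}`.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$vcf)) stop("config: 'vcf' is required", call. = FALSE)
  run_config(
    vcf = y$vcf, definitions = y$definitions, annotations = y$annotations,
    coverage = y$coverage, compare = y$compare,
    region = if (!is.null(y$region)) {
      do.call(gene_region, y$region)
    } else cyp2c19_region(),
    include_flanks = y$include_flanks %||% TRUE,
    qc = do.call(qc_policy, y$qc %||% list()),
    policy = do.call(calling_policy, y$policy %||% list()),
    annotation_cfg = do.call(annotation_config, y$annotation %||% list()),
    guideline = y$guideline %||% "CPIC",
    out_dir = y$out_dir %||% tempfile("phasestar_run"))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes QC filtering, VCF ingestion, region restriction, phasing
#' statistics, variant cataloguing, diplotype calling, novel-suballele
#' detection, phenotype translation and (optionally) caller concordance, and
#' writes one TSV per stage plus a run log into `config$out_dir`. An empty
#' VCF yields a zero-sample bundle with warnings, not an error.
#'
#' @param config A [run_config()].
#' @return A `report_bundle` list with one element per stage.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- stage("definitions", load_allele_table(config$definitions))
  fmap <- stage("definitions", {
    f <- load_function_map(guideline = config$guideline)
    missing <- setdiff(unique(vapply(tab$alleles, `[[`, "", "major")),
                       names(f$map))
    if (length(missing)) stop("function map lacks major(s): ",
                              paste(missing, collapse = ", "))
    f
  })

  qc_result <- NULL
  if (!is.null(config$coverage)) {
    qc_result <- stage("qc", sample_qc_filter(config$coverage, config$qc))
  }

  callsets <- stage("ingest", read_phased_vcf(config$vcf))
  if (!is.null(qc_result)) callsets <- callsets[
    intersect(names(callsets), qc_result$retained)]
  if (length(callsets) == 0) warning("no samples to analyze")
  callsets <- stage("restrict", lapply(callsets, restrict_to_region,
                                       region = config$region,
                                       include_flanks = config$include_flanks))

  phasing <- stage("phasing", lapply(callsets, phasing_stats))
  phasing_tbl <- if (length(phasing)) phasing_report(phasing) else NULL

  ann <- if (!is.null(config$annotations)) {
    stage("catalog", read_annotation_table(config$annotations))
  } else NULL
  catalog <- if (length(callsets)) {
    stage("catalog", variant_catalog(callsets, tab, ann, config$annotation_cfg))
  } else NULL

  calls <- stage("call", lapply(callsets, call_diplotype, table = tab,
                                policy = config$policy))
  novel <- stage("call", do.call(rbind, c(
    lapply(calls, detect_novel_suballeles, table = tab),
    list(make.row.names = FALSE))))

  calls_tbl <- if (length(calls)) do.call(rbind, lapply(calls, function(cl) {
    findings <- length(c(cl$primary$a$extra_known, cl$primary$a$extra_novel,
                         cl$primary$b$extra_known, cl$primary$b$extra_novel,
                         cl$unassigned)) > 0
    ph <- assign_phenotype(c(cl$primary$a$major, cl$primary$b$major), fmap,
                           carries_findings = findings)
    data.frame(sample_id = cl$sample_id,
               diplotype_minor = format(cl, "minor"),
               diplotype_major = format(cl, "major"),
               phenotype = ph$phenotype, actionable = ph$actionable,
               n_alternatives = length(cl$alternatives),
               phase_supported = cl$primary$a$phase_supported &&
                 cl$primary$b$phase_supported,
               truncated = cl$truncated,
               stringsAsFactors = FALSE)
  })) else NULL
  if (!is.null(calls_tbl)) rownames(calls_tbl) <- NULL

  distribution <- if (!is.null(calls_tbl)) {
    cohort_phenotype_distribution(calls_tbl$phenotype, config$guideline)
  } else NULL

  concordance <- NULL
  if (!is.null(config$compare)) {
    concordance <- stage("concordance", {
      cmp <- utils::read.delim(config$compare, stringsAsFactors = FALSE,
                               fileEncoding = "UTF-8")
      ref_col <- names(cmp)[2]
      tools <- names(cmp)[-(1:2)]
      res <- list()
      for (tl in tools) {
        for (lv in c("minor_exact", "major")) {
          res[[paste(tl, lv, sep = ".")]] <-
            agreement(cmp[[ref_col]], cmp[[tl]], lv,
                      sample_ids = cmp[[1]],
                      label = paste(ref_col, "vs", tl))
        }
        res[[paste(tl, "major_any", sep = ".")]] <-
          agreement(cmp[[ref_col]], cmp[[tl]], "major", any_listed = TRUE,
                    sample_ids = cmp[[1]], label = paste(ref_col, "vs", tl))
      }
      res
    })
  }

  bundle <- structure(list(
    qc = qc_result, phasing = phasing_tbl, catalog = catalog,
    calls = calls_tbl, novel_suballeles = novel,
    phenotype_distribution = distribution, concordance = concordance,
    config = config), class = "report_bundle")

  wr <- function(df, f) if (!is.null(df) && nrow(df) > 0) {
    utils::write.table(df, file.path(config$out_dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wr(phasing_tbl, "phasing.tsv")
  wr(catalog, "catalog.tsv")
  wr(calls_tbl, "diplotypes.tsv")
  wr(novel, "novel_suballeles.tsv")
  wr(distribution, "phenotype_distribution.tsv")
  writeLines(c(paste("phasestar", as.character(utils::packageVersion("phasestar"))),
               paste("time:", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
               paste("missing_mode:", config$policy$missing_mode),
               paste("guideline:", config$guideline),
               paste("samples:", length(calls))),
             file.path(config$out_dir, "run_log.txt"))
  bundle
}

#' Render a report bundle as markdown
#'
#' @param bundle A `report_bundle` from [run_full_analysis()].
#' @return A character vector of markdown lines (one section per stage; the
#'   numbers are identical to the stage TSVs).
#' @export
render_report <- function(bundle) {
  stopifnot(inherits(bundle, "report_bundle"))
  out <- c("# phasestar analysis report", "")
  if (!is.null(bundle$qc)) {
    out <- c(out, "## Sample QC",
             sprintf("- retained: %d, excluded: %d",
                     length(bundle$qc$retained), length(bundle$qc$excluded)), "")
  }
  if (!is.null(bundle$phasing)) {
    out <- c(out, "## Phasing",
             sprintf("- mean phased fraction: %.1f%% over %d samples",
                     mean(bundle$phasing$phased_fraction, na.rm = TRUE),
                     nrow(bundle$phasing)), "")
  }
  if (!is.null(bundle$catalog)) {
    out <- c(out, "## Variant catalog",
             sprintf("- %d unique variants (%d known, %d novel), %d singletons",
                     bundle$catalog$n_unique, bundle$catalog$n_known,
                     bundle$catalog$n_novel, bundle$catalog$n_singletons), "")
  }
  if (!is.null(bundle$calls)) {
    out <- c(out, "## Diplotype calls",
             vapply(seq_len(nrow(bundle$calls)), function(i) {
               sprintf("- %s: %s (%s)", bundle$calls$sample_id[i],
                       bundle$calls$diplotype_minor[i],
                       bundle$calls$phenotype[i])
             }, ""), "")
  }
  if (!is.null(bundle$novel_suballeles) && nrow(bundle$novel_suballeles) > 0) {
    conf <- bundle$novel_suballeles[bundle$novel_suballeles$confident, ]
    out <- c(out, "## Candidate novel suballeles",
             if (nrow(conf)) sprintf("- %s: %s", conf$sample_id, conf$descriptor)
             else "- none confirmed", "")
  }
  if (!is.null(bundle$phenotype_distribution)) {
    d <- bundle$phenotype_distribution
    out <- c(out, "## Phenotype distribution",
             sprintf("- %s: %d (%.1f%%)", d$phenotype, d$n, d$percent), "")
  }
  if (!is.null(bundle$concordance)) {
    out <- c(out, "## Caller concordance",
             vapply(bundle$concordance, function(cc) {
               sprintf("- %s [%s]: %d/%d (%.1f%%)", cc$label, cc$level,
                       cc$n_agree, cc$n_total, cc$percent)
             }, ""), "")
  }
  out
}
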