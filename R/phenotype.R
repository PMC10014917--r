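#' Allele function map
#'
#' Loads the per-major-allele function classes for a gene (normal /
#' decreased / no_function / increased / unknown) together with the
#' function-combination rule table translating an unordered pair of function
#' classes into a metabolizer category. CPIC uses five categories (PM, IM,
#' NM, RM, UM); DPWG lacks RM, and the bundled default reports the
#' increased/normal combination as NM under DPWG (annotated as an
#' increased-function carrier).
#'
#' @param map_path Path to a `gene<TAB>major<TAB>function` TSV; default is the
#'   bundled CYP2C19 map.
#' @param rules_path Path to the combination-rule TSV with columns
#'   `function_a, function_b, CPIC, DPWG`; default bundled.
#' @param guideline `"CPIC"` (default) or `"DPWG"`.
#' @return A `function_map` object.
#' @export
load_function_map <- function(map_path = NULL, rules_path = NULL,
                              guideline = c("CPIC", "DPWG")) {
  guideline <- match.arg(guideline)
  map_path <- map_path %||%
    system.file("extdata", "cyp2c19_function_map.tsv", package = "phasestar",
                mustWork = TRUE)
  rules_path <- rules_path %||%
    system.file("extdata", "phenotype_rules.tsv", package = "phasestar",
                mustWork = TRUE)
  map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
  rules <- utils::read.delim(rules_path, stringsAsFactors = FALSE,
                             check.names = FALSE)
  bad <- !map$`function` %in% allele_functions
  if (any(bad)) stop("unknown function class in map: ", map$`function`[bad][1],
                     call. = FALSE)
  structure(list(gene = unique(map$gene),
                 map = stats::setNames(map$`function`, map$major),
                 rules = rules, guideline = guideline),
            class = "function_map")
}

phenotype_categories <- function(guideline) {
  if (guideline == "CPIC") c("PM", "IM", "NM", "RM", "UM") else c("PM", "IM", "NM", "UM")
}

major_of <- function(allele) sub("^(\\*[0-9]+).*$", "\\1", allele)

#' Assign a metabolizer phenotype to a diplotype
#'
#' Looks up each major allele's function class and translates the unordered
#' pair of classes through the combination rule table. The assignment is
#' symmetric in allele order. An unknown function class or an uncatalogued
#' combination yields the explicit category `"indeterminate"`, never a silent
#' default. A result is *actionable* when the phenotype differs from NM or
#' either allele carries a non-normal function class.
#'
#' @param diplotype A length-2 character vector of allele names, or a single
#'   `"A/B"` string; suballele suffixes and `+extra` annotations are stripped
#'   to the major allele (a `+extra` annotation sets `carries_findings`).
#' @param fmap A [load_function_map()] object.
#' @param carries_findings Set to `TRUE` when the call carries flagged
#'   variants beyond the assigned suballeles (in-cis extras); such a sample
#'   counts as actionable even when its phenotype is NM.
#' @return A one-row data frame: `diplotype` (major level, canonical order),
#'   `phenotype`, `guideline`, `actionable`, `note` (annotation for the
#'   increased-function carrier remap under DPWG, else `NA`).
#' @examples
#' fmap <- load_function_map()
#' assign_phenotype("*1.002/*17.001", fmap)$phenotype  # "RM"
#' @export
assign_phenotype <- function(diplotype, fmap, carries_findings = FALSE) {
  if (length(diplotype) == 1) {
    p <- parse_diplotype(diplotype)
    if (!p$well_formed) stop("unparseable diplotype: ", diplotype, call. = FALSE)
    if (any(vapply(p$alleles, function(a) length(a$extras) > 0, TRUE))) {
      carries_findings <- TRUE
    }
    diplotype <- vapply(p$alleles, `[[`, "", "allele")
  }
  if (length(diplotype) != 2) stop("a diplotype has exactly two alleles",
                                   call. = FALSE)
  majors <- major_of(trimws(diplotype))
  unknown <- setdiff(majors, names(fmap$map))
  if (length(unknown) > 0) {
    stop("major allele not in function map: ", unknown[1], call. = FALSE)
  }
  funs <- sort(unname(fmap$map[majors]))
  rules <- fmap$rules
  hit <- which((rules$function_a == funs[1] & rules$function_b == funs[2]) |
                 (rules$function_a == funs[2] & rules$function_b == funs[1]))
  phen <- if (any(funs == "unknown") || length(hit) == 0) {
    "indeterminate"
  } else {
    rules[[fmap$guideline]][hit[1]]
  }
  majors <- majors[star_sort_key(majors)]
  note <- if (fmap$guideline == "DPWG" && setequal(funs, c("increased", "normal"))) {
    "increased-function carrier"
  } else NA_character_
  data.frame(diplotype = paste(majors, collapse = "/"),
             phenotype = phen, guideline = fmap$guideline,
             actionable = !identical(phen, "NM") || any(funs != "normal") ||
               isTRUE(carries_findings),
             note = note,
             stringsAsFactors = FALSE)
}

#' Cohort phenotype distribution
#'
#' @param phenotypes Character vector of phenotype categories (or a data
#'   frame with a `phenotype` column).
#' @param guideline Category system used for zero-count rows.
#' @return A data frame with one row per category: `phenotype`, `n`,
#'   `percent` (0.1% precision), `percent_int` (integer display rounding).
#' @export
cohort_phenotype_distribution <- function(phenotypes, guideline = "CPIC") {
  if (is.data.frame(phenotypes)) phenotypes <- phenotypes$phenotype
  if (length(phenotypes) == 0) stop("no phenotype assignments", call. = FALSE)
  cats <- phenotype_categories(guideline)
  extra <- setdiff(unique(phenotypes), cats)
  cats <- c(cats, extra)
  n <- vapply(cats, function(ct) sum(phenotypes == ct), 0L)
  data.frame(phenotype = cats, n = unname(n),
             percent = round(100 * unname(n) / length(phenotypes), 1),
             percent_int = as.integer(round(100 * unname(n) / length(phenotypes))),
             stringsAsFactors = FALSE, row.names = NULL)
}
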