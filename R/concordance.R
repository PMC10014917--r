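#' Parse a printed diplotype string
#'
#' Handles the notation used in published comparison tables:
#' `"*1.002 + rs4986894/*2.001 (IM)"`. A trailing parenthesized metabolizer
#' code is the printed phenotype; any other parenthesized group containing a
#' `/` is a ranked alternate diplotype (the PharmCat convention of listing
#' the manually confirmed call in brackets after the first-listed call).
#' Each allele token is a star-allele name plus optional signed extra-variant
#' annotations (`+rs4986894`, `+94781616A>G`, and the `–`/`-` form,
#' preserved verbatim). Parsing is total: malformed strings are returned with
#' `well_formed = FALSE`, never dropped.
#'
#' @param s A diplotype string.
#' @return A list: `raw`, `alleles` (list of two token records with `allele`,
#'   `extras`, `token`), `phenotype` (`NA` when unprinted), `alternates`
#'   (list of parsed alternate diplotypes), `well_formed`.
#' @export
parse_diplotype <- function(s) {
  raw <- s
  work <- trimws(s)
  phen <- NA_character_
  m <- regmatches(work, regexec("\\((PM|IM|NM|RM|UM)\\)\\s*$", work))[[1]]
  if (length(m) > 0) {
    phen <- m[2]
    work <- trimws(sub("\\((PM|IM|NM|RM|UM)\\)\\s*$", "", work))
  }
  alternates <- list()
  alt_re <- "\\(([^()]*/[^()]*)\\)"
  while (grepl(alt_re, work)) {
    inner <- regmatches(work, regexec(alt_re, work))[[1]][2]
    alternates[[length(alternates) + 1L]] <- parse_diplotype(inner)
    work <- trimws(sub(alt_re, "", work))
  }
  parts <- strsplit(work, "/", fixed = TRUE)[[1]]
  ok <- length(parts) == 2
  alleles <- lapply(parts, parse_allele_token)
  if (ok) ok <- all(vapply(alleles, `[[`, TRUE, "well_formed"))
  list(raw = raw, alleles = alleles, phenotype = phen,
       alternates = alternates, well_formed = ok)
}

parse_allele_token <- function(tok) {
  tok <- trimws(tok)
  m <- regmatches(tok, regexec("^(\\*[0-9]+(?:\\.[0-9]+)?)(.*)$", tok))[[1]]
  if (length(m) == 0) {
    return(list(allele = NA_character_, extras = character(),
                token = gsub("\\s+", "", tok), well_formed = FALSE))
  }
  allele <- m[2]
  rest <- trimws(m[3])
  extras <- character()
  ok <- TRUE
  if (nzchar(rest)) {
    pieces <- regmatches(rest, gregexpr("[+–-][^+–-]*", rest))[[1]]
    consumed <- paste(pieces, collapse = "")
    if (gsub("\\s+", "", consumed) != gsub("\\s+", "", rest)) ok <- FALSE
    extras <- gsub("\\s+", "", pieces)
  }
  list(allele = allele, extras = extras,
       token = paste0(allele, paste(sort(extras), collapse = "")),
       well_formed = ok)
}

#' Normalize a diplotype string to a canonical comparison token
#'
#' @param s A diplotype string or a [parse_diplotype()] result.
#' @param level `"minor_exact"` (full suballele tokens including signed
#'   extra annotations, whitespace-normalized, order-insensitive) or
#'   `"major"` (suballele suffixes and extras stripped).
#' @return A canonical string, or `NA` for a malformed input.
#' @examples
#' normalize_diplotype("*2.001 + rs4986894/*1.002", "minor_exact")
#' normalize_diplotype("*17.001/*38.003 + 94781616A>G", "major")
#' @export
normalize_diplotype <- function(s, level = c("minor_exact", "major")) {
  level <- match.arg(level)
  p <- if (is.character(s)) parse_diplotype(s) else s
  if (!p$well_formed) return(NA_character_)
  toks <- if (level == "minor_exact") {
    vapply(p$alleles, `[[`, "", "token")
  } else {
    major_of(vapply(p$alleles, `[[`, "", "allele"))
  }
  paste(toks[star_sort_key(toks)], collapse = "/")
}

new_concordance_result <- function(label, level, n_total, n_agree,
                                   disagreeing) {
  structure(list(label = label, level = level,
                 n_total = n_total, n_agree = n_agree,
                 percent = 100 * n_agree / n_total,
                 disagreeing = disagreeing),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance> %s [%s]: %d/%d agree (%.1f%%)\n",
              x$label, x$level, x$n_agree, x$n_total, x$percent))
  invisible(x)
}

#' Agreement between a reference and a tool call column
#'
#' Compares two aligned columns of diplotype strings after
#' [normalize_diplotype()] at the requested level. With `any_listed = TRUE`
#' a sample agrees when the reference diplotype matches the tool's
#' first-listed call *or any* of its bracketed alternates (the reading under
#' which a ranked output list counts as containing the correct call).
#' Malformed strings are flagged and counted as disagreements.
#'
#' @param reference,tool Character vectors of diplotype strings, aligned by
#'   sample.
#' @param level `"minor_exact"` or `"major"`.
#' @param any_listed Accept a match against bracketed alternates.
#' @param sample_ids Optional sample labels (must be unique).
#' @param label Comparison label for reporting.
#' @return A `concordance_result`.
#' @export
agreement <- function(reference, tool, level = c("minor_exact", "major"),
                      any_listed = FALSE, sample_ids = NULL,
                      label = "reference vs tool") {
  level <- match.arg(level)
  if (length(reference) != length(tool)) {
    stop("reference and tool columns differ in length", call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- as.character(seq_along(reference))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  agree <- vapply(seq_along(reference), function(i) {
    r <- normalize_diplotype(reference[i], level)
    if (is.na(r)) return(FALSE)
    pt <- parse_diplotype(tool[i])
    cand <- normalize_diplotype(pt, level)
    if (any_listed) {
      cand <- c(cand, vapply(pt$alternates, normalize_diplotype, "", level = level))
    }
    r %in% cand[!is.na(cand)]
  }, TRUE)
  new_concordance_result(label, if (any_listed) paste0(level, "_any_listed") else level,
                         length(reference), sum(agree), sample_ids[!agree])
}

#' Phenotype-level concordance
#'
#' Compares the metabolizer categories of two call columns. Printed
#' phenotype annotations (e.g. `"(IM)"`) are used where present; otherwise,
#' when a function map is supplied, the major diplotype is translated with
#' [assign_phenotype()]. A sample with no resolvable phenotype on either
#' side counts as a disagreement (this is why columns without phenotypes,
#' like PharmCat's, are excluded from phenotype comparisons by default).
#'
#' @param reference,tool Character vectors of diplotype strings.
#' @param fmap Optional [load_function_map()] used for cells without printed
#'   phenotypes.
#' @param sample_ids Optional sample labels.
#' @param label Comparison label.
#' @return A `concordance_result` with level `"phenotype"`.
#' @export
phenotype_concordance <- function(reference, tool, fmap = NULL,
                                  sample_ids = NULL,
                                  label = "reference vs tool") {
  if (length(reference) != length(tool)) {
    stop("reference and tool columns differ in length", call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- as.character(seq_along(reference))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  get_phen <- function(s) {
    p <- parse_diplotype(s)
    if (!is.na(p$phenotype)) return(p$phenotype)
    if (!is.null(fmap) && p$well_formed) {
      majors <- major_of(vapply(p$alleles, `[[`, "", "allele"))
      if (all(majors %in% names(fmap$map))) {
        return(assign_phenotype(majors, fmap)$phenotype)
      }
    }
    NA_character_
  }
  rp <- vapply(reference, get_phen, "", USE.NAMES = FALSE)
  tp <- vapply(tool, get_phen, "", USE.NAMES = FALSE)
  agree <- !is.na(rp) & !is.na(tp) & rp == tp
  new_concordance_result(label, "phenotype", length(reference), sum(agree),
                         sample_ids[!agree])
}
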