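#' Diplotype calling policy
#'
#' @param missing_mode `"assume_reference"` (default; positions not called
#'   are treated as reference — appropriate for targeted capture with
#'   observed-reference tracking) or `"strict_missing"` (a defining variant at
#'   a position neither called nor observed as reference counts as missing
#'   and the candidate is retained but flagged — the behaviour that produces
#'   PharmCat-style ranked ambiguity).
#' @param max_unphased_enumeration Cap on the number of free orientation bits
#'   (phase blocks beyond the first plus unphased heterozygous calls) that are
#'   enumerated exhaustively (default 12). Beyond the cap, unphased variants
#'   are dropped from enumeration deterministically — novel variants first,
#'   then by descending position — and reported as unconfirmed extras.
#' @param report_alternatives Maximum number of alternative diplotypes kept.
#' @return A `calling_policy` object.
#' @export
calling_policy <- function(missing_mode = c("assume_reference", "strict_missing"),
                           max_unphased_enumeration = 12L,
                           report_alternatives = 10L) {
  stopifnot(max_unphased_enumeration >= 0)
  structure(list(missing_mode = match.arg(missing_mode),
                 max_unphased_enumeration = as.integer(max_unphased_enumeration),
                 report_alternatives = as.integer(report_alternatives)),
            class = "calling_policy")
}

#' Enumerate haplotype pairs consistent with the phase structure
#'
#' Reconstructs the two parental strands from a call set. Within a phase
#' block the genotype orientation fixes the relative strand assignment of its
#' heterozygous calls; across blocks, and for unphased heterozygous calls,
#' both orientations are enumerated (up to whole-pair strand swap, so the
#' first unit's orientation is pinned). Hom-alt variants sit on both strands.
#'
#' @param callset A `sample_callset`, restricted to one gene region.
#' @param policy A [calling_policy].
#' @param known_ids Optional character vector of nomenclature variant ids,
#'   used only to decide which variants are dropped first when the
#'   enumeration cap is exceeded.
#' @return A list of haplotype pairs; each has `strand_a`, `strand_b`
#'   (character vectors of variant ids), `unassigned` (ids dropped by
#'   truncation) and `truncated` (logical).
#' @export
build_haplotype_pairs <- function(callset, policy = calling_policy(),
                                  known_ids = character()) {
  calls <- callset$calls
  hom <- calls$id[calls$zygosity == "hom_alt"]
  het <- calls[calls$zygosity == "het", , drop = FALSE]

  phased <- het[het$phased & !is.na(het$phase_set), , drop = FALSE]
  loose <- het[!(het$phased & !is.na(het$phase_set)), , drop = FALSE]

  units <- list()
  if (nrow(phased) > 0) {
    for (b in split(phased, phased$phase_set)) {
      units[[length(units) + 1L]] <- list(
        a = b$id[b$a1 == 1L], b = b$id[b$a1 == 0L], single = FALSE)
    }
  }
  if (nrow(loose) > 0) {
    for (i in seq_len(nrow(loose))) {
      units[[length(units) + 1L]] <- list(
        a = loose$id[i], b = character(), single = TRUE)
    }
  }

  # deterministic truncation when the enumeration would be too large:
  # drop unphased singleton units, novel variants first, then descending pos
  unassigned <- character()
  truncated <- FALSE
  free_bits <- function(u) max(0L, length(u) - 1L)
  if (free_bits(units) > policy$max_unphased_enumeration) {
    singles <- which(vapply(units, `[[`, TRUE, "single"))
    ids <- vapply(units[singles], function(u) u$a, "")
    pos <- as.integer(sub("^[^:]*:([0-9]+):.*$", "\\1", ids))
    drop_order <- singles[order(ids %in% known_ids, pos,
                                decreasing = c(FALSE, TRUE), method = "radix")]
    while (free_bits(units) - length(unassigned) >
           policy$max_unphased_enumeration && length(drop_order) > 0) {
      unassigned <- c(unassigned,
                      vapply(units[drop_order[1]], function(u) u$a, ""))
      drop_order <- drop_order[-1]
    }
    units <- Filter(function(u) !u$single || !(u$a %in% unassigned), units)
    truncated <- TRUE
  }

  n_free <- free_bits(units)
  combos <- if (length(units) == 0) {
    matrix(logical(0), nrow = 1)
  } else {
    as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n_free)))
  }
  if (nrow(combos) == 0) combos <- matrix(logical(0), nrow = 1)

  lapply(seq_len(nrow(combos)), function(r) {
    flips <- c(FALSE, as.logical(combos[r, ]))  # first unit pinned
    a <- hom; b <- hom
    for (j in seq_along(units)) {
      u <- units[[j]]
      if (flips[j]) { a <- c(a, u$b); b <- c(b, u$a) }
      else          { a <- c(a, u$a); b <- c(b, u$b) }
    }
    list(strand_a = sort(unique(a)), strand_b = sort(unique(b)),
         unassigned = unassigned, truncated = truncated)
  })
}

#' Match one haplotype strand against the nomenclature
#'
#' Ranks candidate suballeles for a reconstructed strand by (1) most core
#' variants matched, (2) most defining variants matched, (3) fewest extra
#' known variants, (4) fewest extra novel variants, (5) star-allele name.
#' Under `assume_reference` a suballele is compatible only when its whole
#' defining set is present on the strand; under `strict_missing`, defining
#' variants at positions neither called nor observed as reference are counted
#' as `missing_defining` and the candidate is kept but flagged. The reference
#' allele (empty defining set) is the universal fallback, so the ranked list
#' is never empty.
#'
#' @param strand Character vector of variant ids on the strand.
#' @param observed_ref Integer vector of positions assayed as reference (plus
#'   called positions); used only by `strict_missing`.
#' @param table An [allele_table].
#' @param policy A [calling_policy].
#' @return A list of `star_match` records in rank order.
#' @export
match_strand <- function(strand, observed_ref = integer(), table,
                         policy = calling_policy()) {
  universe <- table$variant_universe$id
  matches <- list()
  for (a in table$alleles) {
    def <- a$defining$id
    matched <- intersect(def, strand)
    absent <- setdiff(def, strand)
    if (policy$missing_mode == "assume_reference") {
      if (length(absent) > 0) next
      missing_def <- character()
    } else {
      absent_pos <- a$defining$pos[match(absent, a$defining$id)]
      assayed <- absent_pos %in% observed_ref
      if (any(assayed)) next       # assayed and reference: truly incompatible
      missing_def <- absent
    }
    extras <- setdiff(strand, def)
    matches[[length(matches) + 1L]] <- structure(list(
      suballele = a$suballele, major = a$major,
      matched_defining = matched, missing_defining = missing_def,
      extra_known = intersect(extras, universe),
      extra_novel = setdiff(extras, universe),
      n_core = length(intersect(a$core, strand)),
      n_matched = length(matched),
      phase_supported = NA), class = "star_match")
  }
  nm <- vapply(matches, `[[`, "", "suballele")
  ord <- order(-vapply(matches, `[[`, 0L, "n_core"),
               -vapply(matches, `[[`, 0L, "n_matched"),
               vapply(matches, function(m) length(m$extra_known), 0L),
               vapply(matches, function(m) length(m$extra_novel), 0L),
               vapply(matches, function(m) length(m$missing_defining), 0L),
               star_sort_key_rank(nm),
               method = "radix")
  matches[ord]
}

# rank vector for star names in natural order (helper for radix ordering)
star_sort_key_rank <- function(names) {
  r <- integer(length(names))
  r[star_sort_key(names)] <- seq_along(names)
  r
}

# A strand's composition is phase-backed when every heterozygous variant on
# it is phased and all of them share one phase set (hom-alt variants need no
# phase; a lone unphased het is NOT backed — its strand assignment is
# arbitrary).
strand_phase_supported <- function(strand, callset) {
  het <- callset$calls[callset$calls$zygosity == "het" &
                         callset$calls$id %in% strand, , drop = FALSE]
  if (nrow(het) == 0L) return(TRUE)
  all(het$phased & !is.na(het$phase_set)) && length(unique(het$phase_set)) == 1L
}

match_token <- function(m) {
  paste0(m$suballele,
         if (length(c(m$extra_known, m$extra_novel)) > 0) {
           ids <- sort(c(m$extra_known, m$extra_novel))
           paste0(" + ", paste(vapply(ids, id_to_gdot, ""), collapse = " + "))
         } else "")
}

id_to_gdot <- function(id) {
  p <- strsplit(id, ":", fixed = TRUE)[[1]]
  gdot(p[2], p[3], p[4])
}

#' Call a star-allele diplotype for one sample
#'
#' Enumerates the haplotype pairs consistent with the sample's phase
#' structure ([build_haplotype_pairs()]), finds the best-matching suballele
#' for each strand ([match_strand()]), and reports the diplotype maximizing
#' the summed strand ranks as primary; distinct diplotypes arising from other
#' phase-consistent strand assignments are kept as ranked alternatives. With
#' complete phasing there is a single haplotype pair and suballele-level
#' resolution is exact. The pair is reported in canonical order
#' (natural star-allele order), so output is invariant under strand swap.
#'
#' @param callset A `sample_callset`.
#' @param table An [allele_table].
#' @param policy A [calling_policy].
#' @param region Optional [gene_region] restriction (flanks included).
#' @return A `diplotype_call`: `primary` (two `star_match` records with
#'   `phase_supported` filled), `alternatives`, `score`
#'   (`n_core_matched`, `n_defining_matched`, `n_extra`, `n_missing`),
#'   `unassigned`, `truncated`, `n_pairs`, `policy`.
#' @export
call_diplotype <- function(callset, table, policy = calling_policy(),
                           region = NULL) {
  if (!is.null(region)) callset <- restrict_to_region(callset, region, TRUE)
  known_ids <- table$variant_universe$id
  pairs <- build_haplotype_pairs(callset, policy, known_ids)
  assayed <- sort(unique(c(callset$calls$pos, callset$observed_ref$pos)))

  cand <- list()
  for (p in pairs) {
    ma <- match_strand(p$strand_a, assayed, table, policy)[[1]]
    mb <- match_strand(p$strand_b, assayed, table, policy)[[1]]
    ma$phase_supported <- strand_phase_supported(p$strand_a, callset)
    mb$phase_supported <- strand_phase_supported(p$strand_b, callset)
    # canonical order by natural star order (then token) => swap-invariant
    ord <- star_sort_key_rank(c(ma$suballele, mb$suballele))
    if (ord[1] > ord[2] ||
        (ord[1] == ord[2] && match_token(ma) > match_token(mb))) {
      tmp <- ma; ma <- mb; mb <- tmp
    }
    sig <- paste(match_token(ma), match_token(mb), sep = "/")
    score <- c(
      n_core = ma$n_core + mb$n_core,
      n_def = ma$n_matched + mb$n_matched,
      n_extra = length(c(ma$extra_known, mb$extra_known)) * 1000L +
        length(c(ma$extra_novel, mb$extra_novel)),
      n_missing = length(c(ma$missing_defining, mb$missing_defining)))
    if (is.null(cand[[sig]])) {
      cand[[sig]] <- list(a = ma, b = mb, score = score, sig = sig)
    }
  }
  ord <- order(-vapply(cand, function(x) x$score["n_core"], 0),
               -vapply(cand, function(x) x$score["n_def"], 0),
               vapply(cand, function(x) x$score["n_extra"], 0),
               vapply(cand, function(x) x$score["n_missing"], 0),
               vapply(cand, function(x) x$sig, ""),
               method = "radix")
  cand <- cand[ord]
  best <- cand[[1]]
  alternatives <- cand[-1]
  if (length(alternatives) > policy$report_alternatives) {
    alternatives <- alternatives[seq_len(policy$report_alternatives)]
  }
  structure(list(
    sample_id = callset$sample_id,
    primary = list(a = best$a, b = best$b),
    alternatives = alternatives,
    score = best$score,
    unassigned = pairs[[1]]$unassigned,
    truncated = pairs[[1]]$truncated,
    n_pairs = length(pairs),
    policy = policy), class = "diplotype_call")
}

#' @export
format.diplotype_call <- function(x, level = c("minor", "major"), ...) {
  level <- match.arg(level)
  if (level == "minor") {
    paste(match_token(x$primary$a), match_token(x$primary$b), sep = "/")
  } else {
    paste(x$primary$a$major, x$primary$b$major, sep = "/")
  }
}

#' @export
print.diplotype_call <- function(x, ...) {
  cat(sprintf("<diplotype_call> %s: %s (major %s)%s%s\n",
              x$sample_id, format(x), format(x, "major"),
              if (length(x$alternatives)) sprintf(", %d alternative(s)",
                                                  length(x$alternatives)) else "",
              if (x$truncated) " [enumeration truncated]" else ""))
  invisible(x)
}

#' Suballele pair of a diplotype call
#'
#' @param call A `diplotype_call`.
#' @return Character vector of the two primary suballele names, canonical
#'   order.
#' @export
diplotype_suballeles <- function(call) {
  c(call$primary$a$suballele, call$primary$b$suballele)
}

#' Detect candidate novel suballeles
#'
#' A strand matched to a known suballele but carrying phased extra variants
#' that no catalogued suballele of the same major allele contains is a
#' candidate novel (minor) star allele; it is reported as
#' `"<suballele> + <variant>"`. Extras whose phase relative to the defining
#' variants is not backed by a single phase block are reported with
#' `confident = FALSE` (unconfirmed).
#'
#' @param call A `diplotype_call`.
#' @param table The [allele_table] the call was made against.
#' @return A data frame with columns `sample_id`, `suballele`, `extras`,
#'   `descriptor`, `confident`; zero rows when no strand carries extras.
#' @export
detect_novel_suballeles <- function(call, table) {
  rows <- list()
  for (m in list(call$primary$a, call$primary$b)) {
    extras <- sort(c(m$extra_known, m$extra_novel))
    if (length(extras) == 0) next
    others <- Filter(function(x) x$suballele != m$suballele,
                     suballeles_of(table, m$major))
    explained <- any(vapply(others, function(o) all(extras %in% o$defining$id),
                            TRUE))
    if (explained) next
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = call$sample_id,
      suballele = m$suballele,
      extras = paste(extras, collapse = ";"),
      descriptor = paste(m$suballele, "+",
                         paste(vapply(extras, id_to_gdot, ""), collapse = " + ")),
      confident = isTRUE(m$phase_supported),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(sample_id = character(), suballele = character(),
                      extras = character(), descriptor = character(),
                      confident = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
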