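#' Star-allele nomenclature tables
#'
#' An `allele_table` holds a PharmVar-like star-allele nomenclature for one
#' gene: each suballele (e.g. `*2.011`) is defined by a set of variant keys, a
#' subset of which are flagged *core* (the defining lesion shared by every
#' suballele of the major allele, e.g. g.94781859G>A for `*2`). One suballele
#' with an empty defining set acts as the *reference allele*, assigned to a
#' haplotype on which no defining variants are observed.
#'
#' @name allele_table
#' @seealso [load_allele_table()], [suballeles_of()], [cyp2c19_table()]
NULL

new_allele_table <- function(gene, alleles, reference_allele) {
  universe_ids <- sort(unique(unlist(lapply(alleles, function(a) a$defining$id))))
  all_var <- do.call(rbind, lapply(alleles, function(a) a$defining))
  universe <- if (is.null(all_var) || nrow(all_var) == 0) {
    variant_keys(character(), integer(), character(), character())
  } else {
    all_var[!duplicated(all_var$id), , drop = FALSE]
  }
  universe <- universe[order(universe$pos, universe$id), , drop = FALSE]
  rownames(universe) <- NULL
  structure(
    list(gene = gene, alleles = alleles,
         reference_allele = reference_allele,
         variant_universe = universe),
    class = "allele_table"
  )
}

#' @export
print.allele_table <- function(x, ...) {
  cat(sprintf("<allele_table> gene %s: %d suballeles (%d majors), %d variants, reference %s\n",
              x$gene, length(x$alleles),
              length(unique(vapply(x$alleles, `[[`, "", "major"))),
              nrow(x$variant_universe), x$reference_allele))
  invisible(x)
}

allele_functions <- c("normal", "decreased", "no_function", "increased", "unknown")

#' Load a star-allele definition table
#'
#' Reads the allele-definition dialect: one row per (suballele, variant) pair
#' plus allele-level metadata rows (variant columns empty) declaring the
#' function class and, optionally, reference status. Columns:
#' `gene, suballele, major, function, chrom, pos, ref, alt, rsid, is_core`
#' (an optional `is_reference` column marks the reference suballele
#' explicitly; otherwise the unique suballele with an empty defining set is
#' taken as reference). A JSON mirror with identical field names is accepted.
#'
#' Validation enforces: unique suballele names; each suballele name extends
#' its major's name; core variants shared by all suballeles of a major;
#' core sets contained in defining sets; a reference allele present with an
#' empty defining set; and (in strict mode) pairwise-distinct defining sets.
#'
#' @param path Path to a TSV or JSON definition file.
#' @param format `"tsv"` or `"json"`; guessed from the file extension.
#' @param strict When `TRUE` (default), two suballeles with identical
#'   defining sets raise a `"non-unique defining set"` validation error.
#' @return An [allele_table] object.
#' @examples
#' tab <- cyp2c19_table()
#' tab$reference_allele
#' @export
load_allele_table <- function(path, format = c("auto", "tsv", "json"),
                              strict = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (!file.exists(path)) stop("allele definition file not found: ", path, call. = FALSE)
  raw <- if (format == "tsv") {
    utils::read.delim(path, colClasses = "character", na.strings = NULL,
                      fileEncoding = "UTF-8", check.names = FALSE)
  } else {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  }
  required <- c("gene", "suballele", "major", "function",
                "chrom", "pos", "ref", "alt", "rsid", "is_core")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("allele definition parse error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in names(raw)) raw[[col]] <- as.character(raw[[col]])
  raw[is.na(raw)] <- ""
  build_allele_table(raw, strict = strict)
}

build_allele_table <- function(raw, strict = TRUE) {
  n <- nrow(raw)
  is_meta <- raw$pos == "" & raw$ref == "" & raw$alt == ""
  # line numbers reported 1-based including the header line
  lineno <- seq_len(n) + 1L

  # parse variant rows
  vrows <- which(!is_meta)
  for (i in vrows) {
    if (!grepl("^[0-9]+$", raw$pos[i])) {
      stop(sprintf("parse error at line %d: non-numeric pos '%s'", lineno[i], raw$pos[i]),
           call. = FALSE)
    }
    if (!grepl("^[ACGT]+$", raw$ref[i]) || !grepl("^[ACGT]+$", raw$alt[i]) ||
        raw$ref[i] == raw$alt[i]) {
      stop(sprintf("parse error at line %d: bad ref/alt '%s>%s'",
                   lineno[i], raw$ref[i], raw$alt[i]), call. = FALSE)
    }
  }

  gene <- unique(raw$gene[raw$gene != ""])
  if (length(gene) != 1) {
    stop("validation error: expected exactly one gene symbol, got ",
         paste(gene, collapse = ", "), call. = FALSE)
  }

  meta <- raw[is_meta, , drop = FALSE]
  if (anyDuplicated(meta$suballele)) {
    stop("validation error: duplicate suballele metadata row for ",
         meta$suballele[duplicated(meta$suballele)][1], call. = FALSE)
  }
  # variant rows for a suballele lacking a metadata row get one implicitly
  # only if function is carried on the variant rows; otherwise it is an error
  subs <- unique(raw$suballele)
  alleles <- list()
  for (s in subs) {
    rows <- raw[raw$suballele == s, , drop = FALSE]
    major <- unique(rows$major)
    if (length(major) != 1 || major == "") {
      stop("validation error: suballele ", s, " has inconsistent or empty major",
           call. = FALSE)
    }
    if (!startsWith(s, major)) {
      stop("validation error: suballele ", s, " does not extend its major name ",
           major, call. = FALSE)
    }
    fun <- setdiff(unique(rows$`function`), "")
    if (length(fun) != 1) {
      stop("validation error: suballele ", s,
           " must declare exactly one function class", call. = FALSE)
    }
    if (!fun %in% allele_functions) {
      stop("validation error: unknown function class '", fun, "' for ", s,
           call. = FALSE)
    }
    vr <- rows[rows$pos != "", , drop = FALSE]
    defining <- if (nrow(vr) == 0) {
      variant_keys(character(), integer(), character(), character())
    } else {
      variant_keys(vr$chrom, as.integer(vr$pos), vr$ref, vr$alt, vr$rsid)
    }
    if (anyDuplicated(defining$id)) {
      stop("validation error: duplicate defining variant in ", s, call. = FALSE)
    }
    core_flag <- if (nrow(vr) == 0) logical(0) else toupper(vr$is_core) %in% c("TRUE", "T", "1", "YES")
    ref_flag <- if ("is_reference" %in% names(rows)) {
      any(toupper(rows$is_reference) %in% c("TRUE", "T", "1", "YES"))
    } else FALSE
    alleles[[s]] <- list(
      suballele = s, major = major, func = fun,
      defining = defining,
      core = defining$id[core_flag],
      is_reference = ref_flag
    )
  }
  alleles <- alleles[subs[star_sort_key(subs)]]

  # core variants shared across suballeles of one major
  majors <- unique(vapply(alleles, `[[`, "", "major"))
  for (m in majors) {
    members <- Filter(function(a) a$major == m, alleles)
    cores <- lapply(members, function(a) sort(a$core))
    if (length(unique(cores)) > 1) {
      bad <- names(members)[which(!vapply(cores, identical, TRUE, cores[[1]]))[1]]
      stop("validation error: suballele ", bad,
           " core set differs from its major's core set", call. = FALSE)
    }
  }

  # reference allele: explicit flag wins, else the unique empty defining set
  explicit_ref <- names(Filter(function(a) isTRUE(a$is_reference), alleles))
  empty <- names(Filter(function(a) nrow(a$defining) == 0, alleles))
  reference <- if (length(explicit_ref) == 1) {
    explicit_ref
  } else if (length(explicit_ref) > 1) {
    stop("validation error: multiple suballeles flagged is_reference", call. = FALSE)
  } else if (length(empty) == 1) {
    empty
  } else if (length(empty) == 0) {
    stop("validation error: no reference allele (empty defining set) present",
         call. = FALSE)
  } else {
    stop("validation error: several empty defining sets; flag one is_reference",
         call. = FALSE)
  }
  if (nrow(alleles[[reference]]$defining) != 0) {
    stop("validation error: reference allele ", reference,
         " must have an empty defining set", call. = FALSE)
  }

  if (strict) {
    sets <- vapply(alleles, function(a) paste(sort(a$defining$id), collapse = ";"), "")
    dup <- duplicated(sets)
    if (any(dup)) {
      twin <- names(alleles)[match(sets[dup][1], sets)]
      stop("validation error: non-unique defining set (", names(alleles)[dup][1],
           " duplicates ", twin, ")", call. = FALSE)
    }
  }

  new_allele_table(gene, alleles, reference)
}

#' Write an allele table in canonical form
#'
#' Emits the TSV (or JSON) dialect read by [load_allele_table()], rows sorted
#' in natural star-allele order with variant rows ordered by position, so that
#' `write_allele_table(load_allele_table(f))` is byte-stable under reloading.
#'
#' @param table An [allele_table].
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_allele_table <- function(table, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  rows <- list()
  for (a in table$alleles) {
    rows[[length(rows) + 1L]] <- data.frame(
      gene = table$gene, suballele = a$suballele, major = a$major,
      `function` = a$func, chrom = "", pos = "", ref = "", alt = "", rsid = "",
      is_core = "FALSE",
      is_reference = ifelse(a$suballele == table$reference_allele, "TRUE", "FALSE"),
      check.names = FALSE, stringsAsFactors = FALSE
    )
    if (nrow(a$defining) > 0) {
      d <- a$defining[order(a$defining$pos, a$defining$id), , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = table$gene, suballele = a$suballele, major = a$major,
        `function` = "", chrom = d$chrom, pos = as.character(d$pos),
        ref = d$ref, alt = d$alt,
        rsid = ifelse(is.na(d$rsid), "", d$rsid),
        is_core = ifelse(d$id %in% a$core, "TRUE", "FALSE"),
        is_reference = "FALSE",
        check.names = FALSE, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (format == "tsv") {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8", eol = "\n")
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", na = "string", pretty = TRUE)
  }
  invisible(path)
}

#' Suballeles of a major star allele
#'
#' @param table An [allele_table].
#' @param major Major allele name, e.g. `"*2"`.
#' @return The sub-list of suballele definitions belonging to `major`.
#' @examples
#' names(suballeles_of(cyp2c19_table(), "*2"))
#' @export
suballeles_of <- function(table, major) {
  stopifnot(inherits(table, "allele_table"))
  hits <- Filter(function(a) a$major == major, table$alleles)
  if (length(hits) == 0) {
    stop("unknown major allele: ", major, call. = FALSE)
  }
  hits
}

#' Bundled simplified CYP2C19 nomenclature
#'
#' Loads the package's simplified CYP2C19 allele-definition fixture. It
#' encodes the published relationships between the suballeles it covers
#' (for example `*2.011` = `*2.001` + rs4986894/g.94762608T>C, the `*2` core
#' g.94781859G>A, the `*11` core g.94775507G>A, g.94781616A>G on `*3.002`,
#' the `*1` core g.94842866A>G and the upstream `*17` core rs12248560) and
#' fills the remaining suballele-distinguishing positions with synthetic
#' placeholder variants (blank rsid). `*38.001` is the reference allele.
#' It is a self-contained stand-in for a PharmVar release, not a copy of one.
#'
#' @return An [allele_table] for CYP2C19.
#' @export
cyp2c19_table <- function() {
  load_allele_table(
    system.file("extdata", "cyp2c19_alleles_synthetic.tsv", package = "phasestar",
                mustWork = TRUE)
  )
}
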