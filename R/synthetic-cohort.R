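#' Noise model for synthetic phased cohorts
#'
#' Controls the degradation applied to the perfectly phased genotypes implied
#' by a diplotype: loss of phase on individual heterozygous calls, phase-set
#' breaks between consecutive heterozygous sites, position dropout (missing,
#' not hom-ref: dropped positions leave the observed-reference set too, so
#' both missing-position policies are exercised), injection of
#' non-nomenclature variants, and the per-sample coverage fraction used by
#' the QC filter. Defaults are noise-free with coverage fractions spanning
#' the 33%-96% range seen in real capture data.
#'
#' @param p_unphase Probability a heterozygous genotype loses its phase.
#' @param p_block_split Probability of a phase-set break between consecutive
#'   heterozygous sites.
#' @param p_drop Probability a position is omitted for a sample.
#' @param novel_rate Expected count (Poisson) of injected novel variants per
#'   sample; injected positions are drawn from a reserved range disjoint from
#'   all definition positions, so they are novel by construction.
#' @param qc_fraction_range Range the per-sample coverage fraction is drawn
#'   from (uniform).
#' @return A `noise_model` object.
#' @export
noise_model <- function(p_unphase = 0, p_block_split = 0, p_drop = 0,
                        novel_rate = 0, qc_fraction_range = c(0.33, 0.96)) {
  stopifnot(p_unphase >= 0, p_unphase <= 1, p_block_split >= 0,
            p_block_split <= 1, p_drop >= 0, p_drop <= 1, novel_rate >= 0,
            length(qc_fraction_range) == 2,
            all(qc_fraction_range >= 0 & qc_fraction_range <= 1))
  structure(list(p_unphase = p_unphase, p_block_split = p_block_split,
                 p_drop = p_drop, novel_rate = novel_rate,
                 qc_fraction_range = qc_fraction_range),
            class = "noise_model")
}

# Positions reserved for injected novel variants; disjoint from every
# definition position in the bundled table by construction.
novel_position_range <- c(94830000L, 94839999L)

resolve_allele_token <- function(token_record, table) {
  name <- token_record$allele
  if (is.na(name) || !name %in% names(table$alleles)) {
    stop("diplotype not resolvable in table: allele ", name, call. = FALSE)
  }
  def <- table$alleles[[name]]
  extras <- variant_keys(character(), integer(), character(), character())
  dropped <- character()
  for (e in token_record$extras) {
    sign <- substr(e, 1, 1)
    body <- substring(e, 2)
    if (sign != "+") { dropped <- c(dropped, e); next }  # "-" form unplaceable
    g <- parse_gdot(body)
    if (!is.null(g)) {
      extras <- rbind(extras, variant_keys(table$variant_universe$chrom[1] %||% "10",
                                           g$pos, g$ref, g$alt))
      next
    }
    hit <- which(!is.na(table$variant_universe$rsid) &
                   table$variant_universe$rsid == body)
    if (length(hit) == 1) {
      extras <- rbind(extras, table$variant_universe[hit, , drop = FALSE])
      next
    }
    stop("unresolvable extra variant '", e, "' on ", name, call. = FALSE)
  }
  list(definition = def, extras = extras, dropped = dropped)
}

#' Specify a synthetic phased cohort
#'
#' @param samples A data frame with columns `sample_id` and `diplotype`
#'   (strings in the printed notation, e.g.
#'   `"*1.002/*38.003 + 94781616A>G"`; a trailing phenotype annotation is
#'   ignored). Extras prefixed `+` are placed on that allele's strand;
#'   the `–` subtraction form cannot be emitted and is dropped with a record
#'   in the truth table.
#' @param table An [allele_table] resolving every diplotype.
#' @param gene Gene symbol.
#' @param noise A [noise_model].
#' @param seed Integer master seed; each sample derives its own stream from
#'   `(seed, sample_id)`, so cohorts are stable under sample reordering.
#' @return A `cohort_spec` object with per-sample resolved strand variant
#'   sets.
#' @export
cohort_spec <- function(samples, table, gene = table$gene,
                        noise = noise_model(), seed = 1L) {
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "diplotype") %in% names(samples)))
  if (anyDuplicated(samples$sample_id)) {
    stop("sample ids must be unique", call. = FALSE)
  }
  resolved <- lapply(seq_len(nrow(samples)), function(i) {
    p <- parse_diplotype(samples$diplotype[i])
    if (!p$well_formed) {
      stop("unparseable diplotype for ", samples$sample_id[i], ": ",
           samples$diplotype[i], call. = FALSE)
    }
    strands <- lapply(p$alleles, function(tok) {
      r <- resolve_allele_token(tok, table)
      vars <- rbind(r$definition$defining[, c("id", "chrom", "pos", "ref", "alt")],
                    r$extras[, c("id", "chrom", "pos", "ref", "alt")])
      if (anyDuplicated(vars$id)) vars <- vars[!duplicated(vars$id), ]
      if (anyDuplicated(vars$pos)) {
        stop("contradictory extras for ", samples$sample_id[i],
             ": two alts at one position on the ", r$definition$suballele,
             " strand", call. = FALSE)
      }
      list(suballele = r$definition$suballele, major = r$definition$major,
           variants = vars, extras = r$extras$id, dropped = r$dropped)
    })
    list(sample_id = samples$sample_id[i], diplotype = samples$diplotype[i],
         a = strands[[1]], b = strands[[2]])
  })
  structure(list(gene = gene, table = table, samples = resolved,
                 noise = noise, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Deterministic 31-bit stream seed from (master seed, sample id).
derive_seed <- function(seed, sample_id) {
  h <- 0
  for (ch in utf8ToInt(sample_id)) h <- (h * 131 + ch) %% 2147483629
  as.integer((seed %% 2147483629) * 48271 %% 2147483629 + h) %% 2147483629L
}

#' Generate a synthetic phased VCF cohort
#'
#' Emits a multi-sample VCF 4.2 (GT:PS) in which, before noise, each
#' sample's first allele's variants sit on strand A (`1|0`), the second
#' allele's on strand B (`0|1`), shared variants are hom-alt (`1|1`), and
#' all heterozygous calls share a single phase set. Noise (see
#' [noise_model()]) is then applied reproducibly from per-sample streams.
#' Alongside the VCF, a truth table of intended diplotypes and phenotypes
#' and a per-sample coverage TSV are written.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory (created if needed).
#' @return A list: `vcf`, `truth`, `coverage` (file paths), plus the truth
#'   and coverage data frames (`truth_df`, `coverage_df`).
#' @export
generate_cohort <- function(spec, out_dir = tempfile("phasestar_cohort")) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  noise <- spec$noise
  fmap <- load_function_map()
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }

  # per-sample genotype construction
  per_sample <- list()
  truth_rows <- list()
  cov_rows <- list()
  registry <- list()  # id -> (chrom,pos,ref,alt)
  for (s in spec$samples) {
    set.seed(derive_seed(spec$seed, s$sample_id))
    cov_rows[[s$sample_id]] <- stats::runif(1, noise$qc_fraction_range[1],
                                            noise$qc_fraction_range[2])
    a_vars <- s$a$variants; b_vars <- s$b$variants
    # injected novel variants from the reserved range
    n_novel <- if (noise$novel_rate > 0) stats::rpois(1, noise$novel_rate) else 0L
    if (n_novel > 0) {
      pos <- sample(seq(novel_position_range[1], novel_position_range[2]),
                    n_novel)
      nk <- variant_keys("10", pos, "A", "G")
      onto_a <- stats::runif(n_novel) < 0.5
      a_vars <- rbind(a_vars, nk[onto_a, c("id", "chrom", "pos", "ref", "alt")])
      b_vars <- rbind(b_vars, nk[!onto_a, c("id", "chrom", "pos", "ref", "alt")])
    }
    for (v in list(a_vars, b_vars)) {
      for (j in seq_len(nrow(v))) registry[[v$id[j]]] <- v[j, ]
    }
    a_ids <- a_vars$id; b_ids <- b_vars$id
    het_ids <- sort(setdiff(union(a_ids, b_ids), intersect(a_ids, b_ids)))
    het_pos <- as.integer(sub("^[^:]*:([0-9]+):.*$", "\\1", het_ids))
    het_ids <- het_ids[order(het_pos)]; het_pos <- sort(het_pos)
    # phase blocks: break between consecutive het sites with p_block_split
    block <- integer(length(het_ids))
    if (length(het_ids) > 0) {
      breaks <- if (length(het_ids) > 1) {
        stats::runif(length(het_ids) - 1) < noise$p_block_split
      } else logical(0)
      block <- cumsum(c(1L, as.integer(breaks)))
    }
    ps_of <- if (length(het_ids)) {
      stats::setNames(vapply(block, function(b) min(het_pos[block == b]), 0L),
                      het_ids)
    } else integer()
    unphased <- if (length(het_ids)) {
      stats::setNames(stats::runif(length(het_ids)) < noise$p_unphase, het_ids)
    } else logical()
    per_sample[[s$sample_id]] <- list(a = a_ids, b = b_ids, ps = ps_of,
                                      unphased = unphased)
    phen <- assign_phenotype(c(s$a$major, s$b$major), fmap)
    truth_rows[[s$sample_id]] <- data.frame(
      sample_id = s$sample_id, diplotype = s$diplotype,
      allele_a = s$a$suballele, allele_b = s$b$suballele,
      major_a = s$a$major, major_b = s$b$major,
      phenotype = phen$phenotype,
      extras_a = paste(s$a$extras, collapse = ";"),
      extras_b = paste(s$b$extras, collapse = ";"),
      dropped_notation = paste(c(s$a$dropped, s$b$dropped), collapse = ";"),
      stringsAsFactors = FALSE)
  }

  vars <- if (length(registry)) do.call(rbind, registry) else
    variant_keys(character(), integer(), character(), character())
  vars <- vars[order(vars$pos, vars$id), , drop = FALSE]

  # genotype strings, with per-sample dropout applied in a second seeded pass
  sample_ids <- names(per_sample)
  gt_mat <- matrix("0|0", nrow = nrow(vars), ncol = length(sample_ids),
                   dimnames = list(NULL, sample_ids))
  for (sid in sample_ids) {
    ss <- per_sample[[sid]]
    set.seed(derive_seed(spec$seed + 7L, sid))
    drop_mask <- stats::runif(nrow(vars)) < noise$p_drop
    for (j in seq_len(nrow(vars))) {
      id <- vars$id[j]
      in_a <- id %in% ss$a; in_b <- id %in% ss$b
      g <- if (in_a && in_b) "1|1"
      else if (in_a) paste0("1|0:", ss$ps[[id]])
      else if (in_b) paste0("0|1:", ss$ps[[id]])
      else "0|0"
      if ((in_a || in_b) && !(in_a && in_b) && isTRUE(ss$unphased[[id]])) {
        g <- "0/1"
      }
      if (drop_mask[j]) g <- "./."
      gt_mat[j, sid] <- g
    }
  }
  # pad PS field
  gt_mat[] <- ifelse(grepl(":", gt_mat, fixed = TRUE), gt_mat,
                     paste0(gt_mat, ":."))

  vcf_path <- file.path(out_dir, "cohort.vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=10,length=133797422>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=PS,Number=1,Type=Integer,Description="Phase set">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))
  body <- vapply(seq_len(nrow(vars)), function(j) {
    paste(c(vars$chrom[j], vars$pos[j], ".", vars$ref[j], vars$alt[j], ".",
            "PASS", ".", "GT:PS", gt_mat[j, ]), collapse = "\t")
  }, "")
  writeLines(c(header, body), vcf_path)

  truth_df <- do.call(rbind, truth_rows); rownames(truth_df) <- NULL
  truth_path <- file.path(out_dir, "truth.tsv")
  utils::write.table(truth_df, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  coverage_df <- data.frame(sample_id = sample_ids,
                            fraction = round(unlist(cov_rows[sample_ids]), 4),
                            stringsAsFactors = FALSE)
  coverage_path <- file.path(out_dir, "coverage.tsv")
  utils::write.table(coverage_df, coverage_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(vcf = vcf_path, truth = truth_path, coverage = coverage_path,
       truth_df = truth_df, coverage_df = coverage_df, dir = out_dir)
}
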