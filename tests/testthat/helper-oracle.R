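# Independent brute-force diplotype oracle: enumerates every assignment of
# heterozygous calls to the two strands (filtering those inconsistent with
# the phase blocks) and every ordered suballele pair, and maximizes
# (core matched, defining matched, -extra known, -extra novel) summed over
# the two strands, lexicographically. Deliberately naive and separate from
# the package's enumeration/matching code path.
oracle_call <- function(callset, table) {
  calls <- callset$calls
  hom <- calls$id[calls$zygosity == "hom_alt"]
  het <- calls[calls$zygosity == "het", , drop = FALSE]
  n <- nrow(het)
  universe <- table$variant_universe$id

  score_allele <- function(a, strand) {
    def <- a$defining$id
    if (!all(def %in% strand)) return(NULL)
    extras <- setdiff(strand, def)
    c(core = length(intersect(a$core, strand)),
      def = length(def),
      ek = -sum(extras %in% universe),
      en = -sum(!(extras %in% universe)))
  }
  better <- function(s1, s2) {  # is s1 strictly better than s2
    for (k in seq_along(s1)) {
      if (s1[k] != s2[k]) return(s1[k] > s2[k])
    }
    FALSE
  }

  best_score <- NULL
  best_sigs <- character()
  ph <- het[het$phased & !is.na(het$phase_set), , drop = FALSE]
  for (mask in 0:(2^n - 1)) {
    bits <- if (n > 0) as.logical(bitwAnd(mask, 2^(seq_len(n) - 1))) else logical(0)
    ok <- TRUE
    for (psid in unique(ph$phase_set)) {
      idx <- which(het$phased & !is.na(het$phase_set) & het$phase_set == psid)
      pat <- bits[idx]; orient <- het$a1[idx] == 1L
      if (!(all(pat == orient) || all(pat == !orient))) { ok <- FALSE; break }
    }
    if (!ok) next
    sa <- c(hom, het$id[bits]); sb <- c(hom, het$id[!bits])
    for (na in names(table$alleles)) {
      s1 <- score_allele(table$alleles[[na]], sa)
      if (is.null(s1)) next
      for (nb in names(table$alleles)) {
        s2 <- score_allele(table$alleles[[nb]], sb)
        if (is.null(s2)) next
        sc <- s1 + s2
        sig <- paste(sort(c(na, nb)), collapse = "/")
        if (is.null(best_score) || better(sc, best_score)) {
          best_score <- sc; best_sigs <- sig
        } else if (!better(best_score, sc)) {
          best_sigs <- union(best_sigs, sig)
        }
      }
    }
  }
  list(score = best_score, diplotypes = sort(best_sigs))
}
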