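# Independent brute-force oracles, deliberately written over codon strings
# and Biostrings::GENETIC_CODE only (no reuse of package lookup tables).

GC_MAP <- Biostrings::GENETIC_CODE
ALL_CODONS <- names(GC_MAP)
SENSE_CODONS <- ALL_CODONS[GC_MAP != "*"]

o_translate <- function(codon) unname(GC_MAP[codon])

o_synonyms <- function(codon) {
  SENSE_CODONS[GC_MAP[SENSE_CODONS] == GC_MAP[codon]]
}

o_is_degenerate <- function(codon) length(o_synonyms(codon)) > 1L

# RSCU by direct family loops
oracle_rscu <- function(codons) {
  counts <- table(factor(codons, levels = SENSE_CODONS))
  out <- stats::setNames(rep(NA_real_, length(SENSE_CODONS)), SENSE_CODONS)
  for (aa in unique(GC_MAP[SENSE_CODONS])) {
    fam <- SENSE_CODONS[GC_MAP[SENSE_CODONS] == aa]
    tot <- sum(counts[fam])
    if (tot > 0) out[fam] <- counts[fam] / (tot / length(fam))
  }
  out
}

oracle_gc3s <- function(codons) {
  elig <- codons[vapply(codons, o_is_degenerate, logical(1))]
  if (!length(elig)) return(NA_real_)
  mean(substr(elig, 3, 3) %in% c("G", "C"))
}

oracle_fop <- function(codons, optimal) {
  elig <- codons[vapply(codons, o_is_degenerate, logical(1))]
  if (!length(elig)) return(NA_real_)
  mean(elig %in% optimal)
}

# Nei-Gojobori synonymous potential sites for one codon, by enumerating all
# nine single-base changes (stop-creating changes dropped from denominators)
oracle_ng_syn <- function(codon) {
  bases <- c("A", "C", "G", "T")
  s_tot <- 0
  for (p in 1:3) {
    syn <- 0L
    valid <- 0L
    for (b in setdiff(bases, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      if (o_translate(mut) == "*") next
      valid <- valid + 1L
      if (o_translate(mut) == o_translate(codon)) syn <- syn + 1L
    }
    if (valid > 0L) s_tot <- s_tot + syn / valid
  }
  s_tot
}

# exhaustive per-column polarization for homozygous alignments where every
# ingroup codon differs from the outgroup codon at <= 1 position
oracle_branch_counts <- function(seq_list, outgroup, optimal = character(0)) {
  ingroup <- setdiff(names(seq_list), outgroup)
  n_cod <- nchar(seq_list[[1]]) / 3
  tally <- list()
  add <- function(branch, kind) {
    key <- paste(branch, kind)
    tally[[key]] <<- (if (is.null(tally[[key]])) 0 else tally[[key]]) + 1
  }
  for (j in seq_len(n_cod)) {
    get <- function(g) substr(seq_list[[g]], 3 * j - 2, 3 * j)
    anc <- get(outgroup)
    tips <- vapply(ingroup, get, character(1))
    for (d in setdiff(unique(tips), anc)) {
      carriers <- ingroup[tips == d]
      syn <- o_translate(anc) == o_translate(d)
      kind <- if (!syn) {
        "nonsyn"
      } else if (!(anc %in% optimal) && d %in% optimal) {
        "U2P"
      } else if (anc %in% optimal && !(d %in% optimal)) {
        "P2U"
      } else if (anc %in% optimal && d %in% optimal) {
        "P2P"
      } else {
        "U2U"
      }
      if (length(carriers) == length(ingroup)) {
        add("ancestral", kind)
      } else {
        for (b in carriers) add(b, kind)
      }
    }
  }
  tally
}

# random sense-codon gene
random_gene <- function(n, exclude_met_trp = FALSE) {
  pool <- SENSE_CODONS
  if (exclude_met_trp) pool <- setdiff(pool, c("ATG", "TGG"))
  sample(pool, n, replace = TRUE)
}

# random homozygous 4-genotype alignment: each ingroup genotype differs from
# the outgroup by <= 1 nucleotide per codon (no stops introduced)
random_polar_alignment <- function(n_cod = 10, p_mut = 0.4) {
  bases <- c("A", "C", "G", "T")
  og <- random_gene(n_cod)
  tips <- list(b1 = og, b2 = og, b3 = og)
  for (j in seq_len(n_cod)) {
    if (stats::runif(1) > p_mut) next
    # derive 1 or 2 alternative single-base variants of the outgroup codon
    for (k in sample(1:3, sample(1:3, 1))) {
      repeat {
        mut <- og[j]
        p <- sample(1:3, 1)
        substr(mut, p, p) <- sample(setdiff(bases, substr(mut, p, p)), 1)
        if (GC_MAP[mut] != "*") break
      }
      tips[[k]][j] <- mut
    }
  }
  seqs <- c(
    og = paste0(og, collapse = ""),
    vapply(tips, paste0, character(1), collapse = "")
  )
  names(seqs) <- c("og", "b1", "b2", "b3")
  seqs
}

tiny_alignment <- function(seqs, outgroup = "og", locus = "L1") {
  codon_alignment(locus, seqs, outgroup)
}
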