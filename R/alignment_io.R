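# Codon alignments, heterozygote handling and table readers.
#
# One locus = one CodonAlignment: an outgroup genotype plus >=1 ingroup
# genotypes, codon-aligned, reading frame 0. Unphased heterozygotes are
# encoded with two-base IUPAC codes (R,Y,S,W,K,M); any other non-ACGT symbol
# (N, 3-base codes, gaps) marks the codon ambiguous/excluded for that
# genotype. Gap columns are excluded for every genotype.

FLAG_PLAIN <- 0L
FLAG_HET <- 1L
FLAG_EXCL <- 2L

#' Construct a validated codon alignment for one locus
#'
#' @param locus locus identifier.
#' @param seqs named character vector of aligned nucleotide sequences (equal
#'   length, divisible by 3); names are genotype ids and must include
#'   `outgroup`.
#' @param outgroup genotype id of the outgroup sequence.
#' @param strip_terminal_stop drop the final codon column when any genotype
#'   carries a stop codon there (default TRUE).
#' @return An object of class `codon_alignment` with elements `locus`,
#'   `genotypes`, `outgroup`, `ingroup`, `n_codons`, `seqs` (the retained
#'   nucleotide strings), `codon` (genotype x codon integer matrix, NA where
#'   the codon is not plain A/C/G/T), `flags` (0 = plain, 1 = two-base
#'   heterozygote, 2 = excluded), `hets` (list keyed "genotype.codon" of
#'   resolution matrices with columns codon, w) and `gap_cols`.
#'   Validation failures (length mismatch, frameshift, internal stop,
#'   missing outgroup) signal an error of class `selcub_invalid_locus`.
#' @export
codon_alignment <- function(locus, seqs, outgroup, strip_terminal_stop = TRUE) {
  fail <- function(reason) {
    stop(structure(
      class = c("selcub_invalid_locus", "error", "condition"),
      list(message = sprintf("locus %s: %s", locus, reason), call = NULL,
           locus = locus, reason = reason)
    ))
  }
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    fail("sequences must be named by genotype")
  }
  if (!outgroup %in% names(seqs)) fail(sprintf("missing outgroup '%s'", outgroup))
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) fail("unequal sequence lengths")
  if (lens[1] %% 3L != 0L) fail("length not divisible by 3 (frameshift)")
  L <- unname(lens[1]) %/% 3L
  if (L < 1L) fail("empty alignment")

  tb <- genetic_code_tables()
  G <- length(seqs)
  genotypes <- names(seqs)

  codon_chr <- matrix("", G, L)
  for (g in seq_len(G)) {
    codon_chr[g, ] <- substring(seqs[g], 3L * seq_len(L) - 2L, 3L * seq_len(L))
  }
  cod <- matrix(match(codon_chr, tb$codons), G, L)

  # strip a terminal stop column if any genotype ends in a definite stop
  if (strip_terminal_stop && L > 1L) {
    last <- cod[, L]
    if (any(!is.na(last) & tb$aa[last] == "*")) {
      L <- L - 1L
      codon_chr <- codon_chr[, seq_len(L), drop = FALSE]
      cod <- cod[, seq_len(L), drop = FALSE]
      seqs <- substring(seqs, 1L, 3L * L)
    }
  }

  # internal definite stop -> locus excluded
  internal_stop <- !is.na(cod) & matrix(tb$aa[cod] == "*", nrow(cod), ncol(cod))
  if (any(internal_stop)) fail("internal stop codon")

  flags <- matrix(FLAG_PLAIN, G, L)
  flags[is.na(cod)] <- FLAG_EXCL
  is_het <- is.na(cod) & matrix(grepl("^[ACGTRYSWKM]{3}$", codon_chr), G, L) &
    matrix(grepl("[RYSWKM]", codon_chr), G, L)

  hets <- list()
  het_idx <- which(is_het)
  for (ii in het_idx) {
    g <- (ii - 1L) %% G + 1L
    j <- (ii - 1L) %/% G + 1L
    res <- expand_heterozygote(codon_chr[g, j])[[1L]]
    keep <- tb$aa[codon_index(res$codon)] != "*"
    if (!any(keep)) next # every phasing is a stop; stays excluded
    res <- res[keep, , drop = FALSE]
    res$weight <- res$weight / sum(res$weight)
    flags[g, j] <- FLAG_HET
    hets[[paste0(genotypes[g], ".", j)]] <-
      cbind(codon = codon_index(res$codon), w = res$weight)
  }

  gap_cols <- which(apply(
    matrix(grepl("-", codon_chr, fixed = TRUE), G, L), 2L, any
  ))
  if (length(gap_cols)) flags[, gap_cols] <- FLAG_EXCL

  structure(list(
    locus = locus, genotypes = genotypes, outgroup = outgroup,
    ingroup = setdiff(genotypes, outgroup), n_codons = L,
    seqs = seqs, codon = cod, flags = flags, hets = hets,
    gap_cols = gap_cols
  ), class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf(
    "<codon_alignment> locus %s: %d genotypes (outgroup %s), %d codons, %d het codons\n",
    x$locus, length(x$genotypes), x$outgroup, x$n_codons, length(x$hets)
  ))
  invisible(x)
}

#' Read per-locus codon alignments from FASTA
#'
#' Accepts either a directory of per-locus FASTA files (locus id = file name
#' without extension) or a single multi-FASTA file holding one locus.
#' Loci failing validation (frameshift, internal stop, length mismatch,
#' missing outgroup sequence within a file) are excluded and logged.
#'
#' @param path directory of FASTA files, or one FASTA file.
#' @param outgroup genotype id of the outgroup (must appear in every locus;
#'   a locus lacking it is excluded, but an input where no locus carries the
#'   outgroup raises an error).
#' @param ... passed to [codon_alignment()].
#' @return list with `alignments` (named list of `codon_alignment`) and
#'   `excluded` (data.frame locus/reason).
#' @export
read_codon_alignments <- function(path, outgroup, ...) {
  if (length(path) != 1L || !file.exists(path)) {
    stop("cannot read alignments: no such file or directory: ", path)
  }
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.(fa|fasta|fas)$", full.names = TRUE)
  } else {
    path
  }
  if (!length(files)) stop("no FASTA files found under ", path)

  alignments <- list()
  excluded <- list()
  for (f in files) {
    locus <- tools::file_path_sans_ext(basename(f))
    ss <- tryCatch(Biostrings::readBStringSet(f), error = function(e) {
      stop("unreadable FASTA file ", f, ": ", conditionMessage(e))
    })
    seqs <- as.character(ss)
    names(seqs) <- sub("\\s.*$", "", names(ss))
    aln <- tryCatch(
      codon_alignment(locus, seqs, outgroup, ...),
      selcub_invalid_locus = function(e) e
    )
    if (inherits(aln, "selcub_invalid_locus")) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(locus = locus, reason = aln$reason)
    } else {
      alignments[[locus]] <- aln
    }
  }
  excluded <- if (length(excluded)) {
    do.call(rbind, excluded)
  } else {
    data.frame(locus = character(), reason = character())
  }
  if (!length(alignments) &&
      any(grepl("missing outgroup", excluded$reason))) {
    stop("outgroup '", outgroup, "' absent from every locus under ", path)
  }
  if (nrow(excluded)) {
    message(sprintf(
      "excluded %d locus/loci: %s", nrow(excluded),
      paste(excluded$locus, "(", excluded$reason, ")", collapse = "; ")
    ))
  }
  list(alignments = alignments, excluded = excluded)
}

#' Write codon alignments back to per-locus FASTA files
#'
#' @param alignments named list of `codon_alignment` objects.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_codon_alignments <- function(alignments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (aln in alignments) {
    p <- file.path(dir, paste0(aln$locus, ".fasta"))
    ss <- Biostrings::BStringSet(aln$seqs)
    Biostrings::writeXStringSet(ss, p, width = 80L)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Expand two-base IUPAC heterozygote codons into weighted resolutions
#'
#' A codon with h heterozygous positions expands to its 2^h consistent
#' phasings with equal weight 2^-h (phase-agnostic expectation over the two
#' unphased haplotypes). A homozygous codon returns itself with weight 1.
#' Codons containing symbols other than A/C/G/T/R/Y/S/W/K/M return NULL
#' (ambiguous; excluded from counting).
#'
#' @param codons character vector of 3-letter codons.
#' @return list (one element per input codon) of data.frames with columns
#'   `codon` and `weight`, or NULL entries for non-expandable codons.
#' @export
expand_heterozygote <- function(codons) {
  lapply(toupper(codons), function(cd) {
    ch <- strsplit(cd, "")[[1L]]
    if (length(ch) != 3L || !all(ch %in% c(BASES, names(IUPAC_HET)))) {
      return(NULL)
    }
    opts <- lapply(ch, function(b) if (b %in% BASES) b else IUPAC_HET[[b]])
    grid <- expand.grid(opts, stringsAsFactors = FALSE)
    res <- apply(grid, 1L, paste0, collapse = "")
    data.frame(
      codon = res, weight = rep(1 / length(res), length(res)),
      stringsAsFactors = FALSE
    )
  })
}

#' Read a per-gene expression table
#'
#' Expects a TSV with header `gene_id` followed by one numeric column per
#' genotype (FPKM-like, non-negative).
#'
#' @param path TSV file.
#' @return data.frame of class `selcub_expression` with columns gene_id, one
#'   column per genotype, and `mean_expr` (cross-genotype mean).
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(df) || ncol(df) < 2L) {
    stop("expression table must have a gene_id column plus one column per genotype")
  }
  expression_table(df[, "gene_id"], df[, setdiff(names(df), "gene_id"), drop = FALSE])
}

#' Build an expression table from vectors
#'
#' @param gene_id character vector of gene ids (unique).
#' @param values data.frame or named list of non-negative expression values,
#'   one element per genotype.
#' @return data.frame of class `selcub_expression`.
#' @export
expression_table <- function(gene_id, values) {
  values <- as.data.frame(values, check.names = FALSE)
  if (anyDuplicated(gene_id)) {
    stop(
      "duplicate gene id(s): ",
      paste(unique(gene_id[duplicated(gene_id)]), collapse = ", ")
    )
  }
  for (cn in names(values)) {
    v <- values[[cn]]
    if (!is.numeric(v) || anyNA(v)) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("malformed expression value in column %s, row %d", cn, bad))
    }
    if (any(v < 0)) {
      stop(sprintf(
        "negative expression value in column %s, row %d",
        cn, which(v < 0)[1]
      ))
    }
  }
  out <- cbind(data.frame(gene_id = gene_id, stringsAsFactors = FALSE), values)
  out$mean_expr <- rowMeans(values)
  class(out) <- c("selcub_expression", "data.frame")
  out
}

#' Write an expression table to TSV
#' @param expr a `selcub_expression` data.frame.
#' @param path output path.
#' @export
write_expression_table <- function(expr, path) {
  utils::write.table(
    expr[, setdiff(names(expr), "mean_expr")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
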