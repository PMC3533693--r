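# Codon-usage statistics: codon counting with heterozygote weights, RSCU,
# GC3s, expression-decile delta-RSCU, optimal-codon inference, Fop and
# delta-RSCU+ (mean positive delta-RSCU, a genotype-level bias strength).

#' Count codon usage with heterozygote weights
#'
#' @param x a `codon_alignment`, a list of them, or a character vector of
#'   codons (two-base IUPAC heterozygote codons contribute fractional
#'   weights; other ambiguous codons contribute 0).
#' @param genotype genotype id (required for alignment input).
#' @return numeric(64) of (possibly fractional) codon counts, named by codon.
#' @export
count_codons <- function(x, genotype = NULL) {
  tb <- genetic_code_tables()
  counts <- numeric(64L)
  if (inherits(x, "codon_alignment")) x <- list(x)
  if (is.list(x) && length(x) && inherits(x[[1L]], "codon_alignment")) {
    if (is.null(genotype)) stop("genotype must be given for alignment input")
    for (aln in x) {
      g <- match(genotype, aln$genotypes)
      if (is.na(g)) stop("genotype ", genotype, " absent from locus ", aln$locus)
      fl <- aln$flags[g, ]
      plain <- aln$codon[g, fl == FLAG_PLAIN]
      counts <- counts + tabulate(plain, 64L)
      for (j in which(fl == FLAG_HET)) {
        res <- aln$hets[[paste0(genotype, ".", j)]]
        counts[res[, "codon"]] <- counts[res[, "codon"]] + res[, "w"]
      }
    }
  } else if (is.character(x)) {
    if (!length(x)) stop("empty codon input")
    idx <- codon_index(x)
    counts <- counts + tabulate(idx[!is.na(idx)], 64L)
    for (res in expand_heterozygote(x[is.na(idx)])) {
      if (is.null(res)) next
      ri <- codon_index(res$codon)
      ok <- tb$aa[ri] != "*"
      if (!any(ok)) next
      w <- res$weight[ok] / sum(res$weight[ok])
      counts[ri[ok]] <- counts[ri[ok]] + w
    }
  } else if (is.list(x) && !length(x)) {
    stop("empty codon input")
  } else {
    stop("unsupported input to count_codons")
  }
  names(counts) <- tb$codons
  counts
}

#' Per-gene codon count matrix for one genotype
#'
#' @param alignments named list of `codon_alignment` objects.
#' @param genotype genotype id.
#' @return numeric matrix, loci x 64 codons, rownames = locus ids.
#' @export
codon_counts_matrix <- function(alignments, genotype) {
  m <- matrix(0, length(alignments), 64L,
    dimnames = list(names(alignments), genetic_code_tables()$codons)
  )
  for (i in seq_along(alignments)) {
    m[i, ] <- count_codons(alignments[[i]], genotype)
  }
  m
}

#' Relative synonymous codon usage
#'
#' RSCU of codon i in a synonymous family of size k with counts X_j is
#' X_i / ((1/k) * sum_j X_j); 1 under uniform usage. Families with zero total
#' count are flagged undefined rather than set to 0.
#'
#' @param counts numeric(64) codon counts (see [count_codons()]).
#' @return data.frame with one row per sense codon: codon, aa, count, rscu,
#'   undefined.
#' @export
rscu <- function(counts) {
  tb <- genetic_code_tables()
  stopifnot(length(counts) == 64L, all(counts >= 0, na.rm = TRUE))
  val <- rep(NA_real_, 64L)
  undef <- rep(TRUE, 64L)
  for (fam in tb$families) {
    tot <- sum(counts[fam])
    if (tot > 0) {
      val[fam] <- counts[fam] / (tot / length(fam))
      undef[fam] <- FALSE
    }
  }
  s <- tb$sense
  data.frame(
    codon = tb$codons[s], aa = tb$aa[s], count = as.numeric(counts[s]),
    rscu = val[s], undefined = undef[s], stringsAsFactors = FALSE
  )
}

third_base_gc <- function() {
  i <- seq_len(64L)
  ((i - 1L) %% 4L + 1L) %in% c(2L, 3L) # C or G
}

#' GC content at synonymous third positions (GC3s)
#'
#' Fraction of G or C at third positions of codons belonging to degenerate
#' synonymous families (Met, Trp and stops excluded).
#'
#' @param x numeric(64) codon counts, or a character vector of codons.
#' @return fraction in \[0, 1\], or NA when the gene has no eligible codons.
#' @export
gc3s <- function(x) {
  if (is.character(x)) x <- count_codons(x)
  tb <- genetic_code_tables()
  denom <- sum(x[tb$degenerate])
  if (denom <= 0) return(NA_real_)
  sum(x[tb$degenerate & third_base_gc()]) / denom
}

#' Frequency of optimal codons (Fop)
#'
#' Weighted count of codons in the optimal set divided by the weighted count
#' of codons in degenerate synonymous families (Met, Trp and stops excluded
#' from the denominator).
#'
#' @param x numeric(64) codon counts, or a character vector of codons.
#' @param optimal character vector of optimal codons (or an
#'   `optimal_codon_table`, whose consensus set is used).
#' @return fraction in \[0, 1\], or NA when the denominator is 0.
#' @export
fop <- function(x, optimal) {
  if (is.character(x)) x <- count_codons(x)
  if (inherits(optimal, "optimal_codon_table")) optimal <- optimal$consensus
  if (!length(optimal)) stop("empty optimal codon set")
  tb <- genetic_code_tables()
  oi <- codon_index(optimal)
  if (anyNA(oi)) stop("unknown codon in optimal set")
  denom <- sum(x[tb$degenerate])
  if (denom <= 0) return(NA_real_)
  sum(x[intersect(oi, which(tb$degenerate))]) / denom
}

#' Split genes into high and low expression sets
#'
#' Top and bottom `quantile` fractions of genes ranked by expression,
#' deterministic tie-breaking by gene id.
#'
#' @param expr a `selcub_expression` table.
#' @param gene_ids genes to consider (default: all in `expr`).
#' @param quantile fraction in (0, 0.5); default 0.1 (expression deciles).
#' @param basis column of `expr` to rank by; default the cross-genotype mean.
#' @return list with `high`, `low` (character gene ids) and `degenerate`
#'   (TRUE when all expression values are tied).
#' @export
partition_by_expression <- function(expr, gene_ids = NULL, quantile = 0.1,
                                    basis = "mean_expr") {
  if (!is.numeric(quantile) || quantile <= 0 || quantile >= 0.5) {
    stop("quantile must lie in (0, 0.5)")
  }
  if (is.null(gene_ids)) gene_ids <- expr$gene_id
  miss <- setdiff(gene_ids, expr$gene_id)
  if (length(miss)) {
    warning(sprintf("%d gene(s) missing from expression table; dropped", length(miss)))
    gene_ids <- setdiff(gene_ids, miss)
  }
  v <- expr[[basis]][match(gene_ids, expr$gene_id)]
  n <- length(gene_ids)
  n_sel <- floor(quantile * n)
  if (n_sel < 1L) stop("expression partition is empty (too few genes)")
  if (n_sel < 10L) warning("fewer than 10 genes per expression set")
  high <- gene_ids[order(-v, gene_ids)][seq_len(n_sel)]
  low <- gene_ids[order(v, gene_ids)][seq_len(n_sel)]
  list(high = high, low = low, degenerate = length(unique(v)) == 1L)
}

# per-gene RSCU values for one codon family layout: genes x 61 matrix with NA
# where the gene's family total is zero.
per_gene_rscu <- function(count_matrix) {
  tb <- genetic_code_tables()
  out <- matrix(NA_real_, nrow(count_matrix), 64L,
    dimnames = dimnames(count_matrix)
  )
  for (fam in tb$families) {
    tot <- rowSums(count_matrix[, fam, drop = FALSE])
    sc <- length(fam) / tot
    sc[tot == 0] <- NA_real_
    out[, fam] <- count_matrix[, fam, drop = FALSE] * sc
  }
  out[, genetic_code_tables()$sense, drop = FALSE]
}

#' Expression-decile delta-RSCU with per-codon tests
#'
#' For each sense codon, delta-RSCU = mean per-gene RSCU among high-expression
#' genes minus the mean among low-expression genes (genes whose synonymous
#' family is absent are omitted for that codon). Departure from zero is
#' tested by one-way ANOVA on the per-gene RSCU values (two groups); codons
#' with significantly positive delta-RSCU are flagged putative optimal.
#'
#' @param count_matrix loci x 64 codon count matrix for one genotype
#'   (see [codon_counts_matrix()]).
#' @param high,low character vectors of gene ids (rownames of
#'   `count_matrix`), from [partition_by_expression()].
#' @param genotype genotype id recorded in the result.
#' @param alpha significance level for the optimal-codon call (default 0.05).
#' @param p_adjust multiple-testing adjustment across the 61 codons passed to
#'   [stats::p.adjust()]; default "BH". Use "none" for unadjusted calls.
#' @return data.frame of class `delta_rscu_table`: codon, aa, rscu_high,
#'   rscu_low, delta, n_high, n_low, statistic (ANOVA F), p, p_adj, optimal.
#' @export
delta_rscu <- function(count_matrix, high, low, genotype = NA_character_,
                       alpha = 0.05, p_adjust = "BH") {
  tb <- genetic_code_tables()
  if (!length(high) || !length(low)) stop("empty expression set")
  rh <- per_gene_rscu(count_matrix[high, , drop = FALSE])
  rl <- per_gene_rscu(count_matrix[low, , drop = FALSE])
  s <- tb$sense
  n_codon <- length(s)
  mh <- ml <- stat <- p <- rep(NA_real_, n_codon)
  nh <- nl <- integer(n_codon)
  for (k in seq_len(n_codon)) {
    vh <- rh[, k]; vh <- vh[!is.na(vh)]
    vl <- rl[, k]; vl <- vl[!is.na(vl)]
    nh[k] <- length(vh); nl[k] <- length(vl)
    if (!nh[k] || !nl[k]) next
    mh[k] <- mean(vh); ml[k] <- mean(vl)
    if (nh[k] >= 2L && nl[k] >= 2L && (stats::var(c(vh, vl)) > 0)) {
      fit <- anova_one_way(list(high = vh, low = vl))
      stat[k] <- fit$statistic; p[k] <- fit$p.value
    }
  }
  delta <- mh - ml
  p_adj <- stats::p.adjust(p, method = p_adjust)
  out <- data.frame(
    codon = tb$codons[s], aa = tb$aa[s],
    rscu_high = mh, rscu_low = ml, delta = delta,
    n_high = nh, n_low = nl, statistic = stat, p = p, p_adj = p_adj,
    optimal = !is.na(delta) & delta > 0 & !is.na(p_adj) & p_adj < alpha,
    stringsAsFactors = FALSE
  )
  attr(out, "genotype") <- genotype
  attr(out, "alpha") <- alpha
  class(out) <- c("delta_rscu_table", "data.frame")
  out
}

#' Consensus optimal codons across genotypes
#'
#' Intersects the per-genotype putative optimal sets and, within each amino
#' acid represented by more than one codon, keeps the codon with the greatest
#' mean delta-RSCU across genotypes (alphabetical tie-break), so the
#' consensus holds at most one codon per amino acid.
#'
#' @param tables named list of `delta_rscu_table`s, one per genotype.
#' @return object of class `optimal_codon_table`: list with `per_genotype`
#'   (named list of codon sets), `consensus` (character codons), and `table`
#'   (data.frame codon/aa/mean_delta for the consensus).
#' @export
consensus_optimal <- function(tables) {
  stopifnot(length(tables) >= 1L)
  per_genotype <- lapply(tables, function(t) t$codon[t$optimal])
  common <- Reduce(intersect, per_genotype)
  if (!length(common)) {
    warning("no codon is optimal in every genotype; consensus set is empty")
    res <- list(
      per_genotype = per_genotype, consensus = character(0),
      table = data.frame(
        codon = character(0), aa = character(0), mean_delta = numeric(0)
      )
    )
    class(res) <- "optimal_codon_table"
    return(res)
  }
  mean_delta <- rowMeans(matrix(
    vapply(
      tables, function(t) t$delta[match(common, t$codon)],
      numeric(length(common))
    ),
    nrow = length(common)
  ))
  aa <- tables[[1L]]$aa[match(common, tables[[1L]]$codon)]
  ord <- order(aa, -mean_delta, common)
  df <- data.frame(
    codon = common, aa = aa, mean_delta = mean_delta,
    stringsAsFactors = FALSE
  )[ord, ]
  keep <- !duplicated(df$aa)
  res <- list(
    per_genotype = per_genotype,
    consensus = df$codon[keep],
    table = df[keep, , drop = FALSE]
  )
  class(res) <- "optimal_codon_table"
  res
}

#' @export
print.optimal_codon_table <- function(x, ...) {
  cat(sprintf(
    "<optimal_codon_table> %d consensus codon(s) over %d amino acids; per-genotype sets: %s\n",
    length(x$consensus), length(unique(x$table$aa)),
    paste(sprintf("%s=%d", names(x$per_genotype),
                  lengths(x$per_genotype)), collapse = ", ")
  ))
  invisible(x)
}

#' Mean positive delta-RSCU (delta-RSCU+)
#'
#' Genotype-level codon-bias strength: the arithmetic mean of the codons with
#' positive delta-RSCU. The per-codon positive values (and their logs, used
#' by the downstream ANOVAs) are returned alongside the mean.
#'
#' @param table a `delta_rscu_table`.
#' @return list with `mean` (NA when no positive values), `values` (named
#'   positive delta-RSCU values) and `log_values`.
#' @export
delta_rscu_plus <- function(table) {
  pos <- !is.na(table$delta) & table$delta > 0
  vals <- stats::setNames(table$delta[pos], table$codon[pos])
  list(
    mean = if (length(vals)) mean(vals) else NA_real_,
    values = vals,
    log_values = log(vals)
  )
}

#' Per-gene usage summary (expression, length, Fop, GC3s)
#'
#' @param alignments named list of `codon_alignment` objects.
#' @param expr a `selcub_expression` table.
#' @param optimal optimal codon set (character or `optimal_codon_table`).
#' @param genotypes genotypes to summarise (default: all in first locus).
#' @param parts optional result of [partition_by_expression()] used to label
#'   expression classes high/low/mid.
#' @return data.frame: gene_id, genotype, expression, length_bp, fop, gc3s,
#'   expr_class.
#' @export
gene_usage_summary <- function(alignments, expr, optimal,
                               genotypes = NULL, parts = NULL) {
  if (is.null(genotypes)) genotypes <- alignments[[1L]]$genotypes
  rows <- vector("list", length(genotypes))
  for (gi in seq_along(genotypes)) {
    g <- genotypes[gi]
    cm <- codon_counts_matrix(alignments, g)
    ids <- rownames(cm)
    cls <- rep("mid", length(ids))
    if (!is.null(parts)) {
      cls[ids %in% parts$high] <- "high"
      cls[ids %in% parts$low] <- "low"
    }
    rows[[gi]] <- data.frame(
      gene_id = ids, genotype = g,
      expression = expr$mean_expr[match(ids, expr$gene_id)],
      length_bp = vapply(alignments, function(a) 3L * a$n_codons, integer(1)),
      fop = apply(cm, 1L, fop, optimal = optimal),
      gc3s = apply(cm, 1L, gc3s),
      expr_class = cls, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
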