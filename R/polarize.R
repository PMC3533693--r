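# Outgroup-parsimony polarization of codon changes onto branches of a
# three-ingroup star over an ancestral branch, classification of changes
# (synonymous / non-synonymous; preferred / unpreferred), Nei-Gojobori
# potential-site counting and diversity summaries.

#' Polarize codon changes against the outgroup
#'
#' The ancestral state of every codon column is taken to be the outgroup
#' state (columns where the outgroup is heterozygous, ambiguous or gapped are
#' skipped). A derived codon carried by every ingroup genotype is assigned to
#' the ancestral branch; a derived codon carried by a strict subset is
#' assigned to each carrying terminal branch. With heterozygotes, each
#' genotype carries a weighted set of codon states (weights from the 2^h
#' equal-weight phasings); the weight shared by all ingroup genotypes (the
#' minimum across genotypes) goes to the ancestral branch and each genotype's
#' residual weight to its terminal branch, which reduces to the plain rule
#' for homozygous data.
#'
#' @param alignments a `codon_alignment` or named list of them.
#' @return data.frame of polarized changes: locus, codon (1-based index),
#'   branch ("ancestral" or terminal genotype id), anc, der (integer codon
#'   codes), weight, het (TRUE when the change involves heterozygous
#'   weighting). Attribute `skipped` counts codon columns skipped because the
#'   outgroup state was unavailable.
#' @export
polarize <- function(alignments) {
  if (inherits(alignments, "codon_alignment")) {
    alignments <- stats::setNames(list(alignments), alignments$locus)
  }
  out <- vector("list", length(alignments))
  skipped <- 0L
  for (li in seq_along(alignments)) {
    aln <- alignments[[li]]
    og <- match(aln$outgroup, aln$genotypes)
    ing <- setdiff(seq_along(aln$genotypes), og)
    ing_ids <- aln$genotypes[ing]
    ok_out <- aln$flags[og, ] == FLAG_PLAIN
    skipped <- skipped + sum(!ok_out)
    simple <- ok_out &
      colSums(aln$flags[ing, , drop = FALSE] != FLAG_PLAIN) == 0L

    acc <- list()
    # fast path: fully plain columns
    js <- which(simple)
    if (length(js)) {
      anc <- aln$codon[og, js]
      tips <- aln$codon[ing, js, drop = FALSE]
      diff <- tips != matrix(anc, length(ing), length(js), byrow = TRUE)
      shared <- colSums(diff) == length(ing) &
        apply(tips, 2L, function(x) length(unique(x)) == 1L)
      if (any(shared)) {
        acc[[length(acc) + 1L]] <- data.frame(
          locus = aln$locus, codon = js[shared], branch = "ancestral",
          anc = anc[shared], der = tips[1L, shared], weight = 1,
          het = FALSE, stringsAsFactors = FALSE
        )
      }
      for (k in seq_along(ing)) {
        sel <- diff[k, ] & !shared
        if (any(sel)) {
          acc[[length(acc) + 1L]] <- data.frame(
            locus = aln$locus, codon = js[sel], branch = ing_ids[k],
            anc = anc[sel], der = tips[k, sel], weight = 1,
            het = FALSE, stringsAsFactors = FALSE
          )
        }
      }
    }
    # slow path: columns with heterozygous or excluded ingroup codons
    for (j in which(ok_out & !simple)) {
      anc <- aln$codon[og, j]
      states <- list()
      for (k in seq_along(ing)) {
        fl <- aln$flags[ing[k], j]
        if (fl == FLAG_PLAIN) {
          states[[ing_ids[k]]] <- cbind(codon = aln$codon[ing[k], j], w = 1)
        } else if (fl == FLAG_HET) {
          states[[ing_ids[k]]] <- aln$hets[[paste0(ing_ids[k], ".", j)]]
        } # FLAG_EXCL: genotype drops out of this column
      }
      if (!length(states)) next
      ders <- unique(unlist(lapply(states, function(s) s[, "codon"])))
      ders <- setdiff(ders, anc)
      for (d in ders) {
        w_g <- vapply(states, function(s) {
          sum(s[s[, "codon"] == d, "w"])
        }, numeric(1))
        m <- min(w_g)
        if (m > 0) {
          acc[[length(acc) + 1L]] <- data.frame(
            locus = aln$locus, codon = j, branch = "ancestral",
            anc = anc, der = d, weight = m, het = m < 1,
            stringsAsFactors = FALSE
          )
        }
        resid <- w_g - m
        for (gname in names(resid)[resid > 0]) {
          acc[[length(acc) + 1L]] <- data.frame(
            locus = aln$locus, codon = j, branch = gname,
            anc = anc, der = d, weight = resid[[gname]],
            het = resid[[gname]] < 1,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    out[[li]] <- if (length(acc)) do.call(rbind, acc) else NULL
  }
  out <- out[!vapply(out, is.null, logical(1))]
  res <- if (length(out)) {
    do.call(rbind, out)
  } else {
    data.frame(
      locus = character(), codon = integer(), branch = character(),
      anc = integer(), der = integer(), weight = numeric(), het = logical()
    )
  }
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

step_lookup <- function() {
  if (!is.null(.tbl_env$step_df)) {
    return(list(df = .tbl_env$step_df, idx = .tbl_env$step_idx))
  }
  tb <- genetic_code_tables()
  pairs <- which(!vapply(tb$steps, is.null, logical(1)))
  dfs <- lapply(pairs, function(p) {
    s <- tb$steps[[p]]
    cbind(pair = p, s)
  })
  df <- do.call(rbind, dfs)
  idx <- split(seq_len(nrow(df)), df[, "pair"])
  .tbl_env$step_df <- df
  .tbl_env$step_idx <- idx
  list(df = df, idx = idx)
}

#' Classify a polarized codon change
#'
#' Single-position differences are classified directly; multi-position
#' differences are decomposed over all minimal mutational paths avoiding stop
#' codons, steps averaged with equal path weights. The codon-bias class of a
#' synonymous step follows membership of its start/end codons in the optimal
#' set: U2P (unpreferred to preferred), P2U, P2P or U2U.
#'
#' @param anc,der ancestral and derived codons (strings or integer codes).
#' @param optimal character vector of preferred codons, an
#'   `optimal_codon_table`, or NULL (bias class then NA).
#' @return data.frame of single-nucleotide steps: from, to (codon strings),
#'   weight, class ("synonymous"/"non-synonymous"), bias. Zero rows when the
#'   change is excluded because every path crosses a stop codon.
#' @export
classify_change <- function(anc, der, optimal = NULL) {
  if (is.character(anc)) anc <- codon_index(anc)
  if (is.character(der)) der <- codon_index(der)
  ch <- data.frame(
    locus = "x", codon = 1L, branch = "b", anc = anc, der = der,
    weight = 1, het = FALSE, stringsAsFactors = FALSE
  )
  st <- classify_changes(ch, optimal)
  data.frame(
    from = codon_string(st$from), to = codon_string(st$to),
    weight = st$weight, class = st$class, bias = st$bias,
    stringsAsFactors = FALSE
  )
}

#' Expand polarized changes into classified mutation steps
#'
#' @param changes data.frame from [polarize()].
#' @param optimal preferred codon set (character, `optimal_codon_table`, or
#'   NULL).
#' @return data.frame with one row per single-nucleotide step: locus, codon,
#'   branch, from, to (integer codes), weight, het, class, bias. Attribute
#'   `n_excluded` counts changes dropped because all mutational paths cross a
#'   stop codon.
#' @export
classify_changes <- function(changes, optimal = NULL) {
  tb <- genetic_code_tables()
  lk <- step_lookup()
  if (inherits(optimal, "optimal_codon_table")) optimal <- optimal$consensus
  pref <- rep(FALSE, 64L)
  if (!is.null(optimal) && length(optimal)) pref[codon_index(optimal)] <- TRUE

  pair <- (changes$anc - 1L) * 64L + changes$der
  rows <- lk$idx[as.character(pair)]
  n_steps <- lengths(rows)
  excluded <- n_steps == 0L
  rep_i <- rep(seq_len(nrow(changes)), n_steps)
  srows <- unlist(rows, use.names = FALSE)
  st <- lk$df[srows, , drop = FALSE]
  out <- data.frame(
    locus = changes$locus[rep_i], codon = changes$codon[rep_i],
    branch = changes$branch[rep_i],
    from = st[, "from"], to = st[, "to"],
    weight = changes$weight[rep_i] * st[, "w"],
    het = changes$het[rep_i], stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  syn <- tb$syn_step[cbind(out$from, out$to)]
  out$class <- ifelse(syn, "synonymous", "non-synonymous")
  out$bias <- rep(NA_character_, nrow(out))
  if (!is.null(optimal)) {
    pf <- pref[out$from]
    pt <- pref[out$to]
    out$bias[syn & !pf & pt] <- "U2P"
    out$bias[syn & pf & !pt] <- "P2U"
    out$bias[syn & pf & pt] <- "P2P"
    out$bias[syn & !pf & !pt] <- "U2U"
  }
  attr(out, "n_excluded") <- sum(excluded)
  out
}

#' Per-branch change tallies and ratios
#'
#' @param steps classified steps from [classify_changes()].
#' @param branches branch ids to report (default: those present).
#' @param exclude_het drop heterozygous (polymorphic) changes before
#'   tallying.
#' @return data.frame of class `branch_change_counts`, one row per branch:
#'   n_syn, n_nonsyn, n_u2p, n_p2u, n_p2p, n_u2u, pn_ps, u2p_p2u (ratios NA
#'   when the denominator is 0), plus n_deleterious / n_nonsyn_classified /
#'   del_fraction columns (NA until filled by [label_deleterious()]).
#' @export
branch_counts <- function(steps, branches = NULL, exclude_het = FALSE) {
  if (exclude_het) steps <- steps[!steps$het, , drop = FALSE]
  if (is.null(branches)) branches <- sort(unique(steps$branch))
  agg <- function(sel) {
    v <- numeric(length(branches))
    if (any(sel)) {
      s <- rowsum(steps$weight[sel], steps$branch[sel])
      v[match(rownames(s), branches)] <- s[, 1]
    }
    v
  }
  syn <- steps$class == "synonymous"
  out <- data.frame(
    branch = branches,
    n_syn = agg(syn),
    n_nonsyn = agg(!syn),
    n_u2p = agg(!is.na(steps$bias) & steps$bias == "U2P"),
    n_p2u = agg(!is.na(steps$bias) & steps$bias == "P2U"),
    n_p2p = agg(!is.na(steps$bias) & steps$bias == "P2P"),
    n_u2u = agg(!is.na(steps$bias) & steps$bias == "U2U"),
    stringsAsFactors = FALSE
  )
  out$pn_ps <- ifelse(out$n_syn > 0, out$n_nonsyn / out$n_syn, NA_real_)
  out$u2p_p2u <- ifelse(out$n_p2u > 0, out$n_u2p / out$n_p2u, NA_real_)
  out$n_deleterious <- rep(NA_real_, nrow(out))
  out$n_nonsyn_classified <- rep(NA_real_, nrow(out))
  out$del_fraction <- rep(NA_real_, nrow(out))
  class(out) <- c("branch_change_counts", "data.frame")
  out
}

#' Deleterious fraction from classified counts
#'
#' @param n_deleterious,n_total (possibly fractional) counts of deleterious
#'   and total classified non-synonymous changes.
#' @param digits decimal places for the reported fraction (default 3,
#'   matching conventional reporting); use NA for no rounding.
#' @return numeric fraction(s); NA where the total is 0.
#' @export
deleterious_fraction <- function(n_deleterious, n_total, digits = 3) {
  stopifnot(all(n_deleterious <= n_total | n_total == 0, na.rm = TRUE))
  f <- ifelse(n_total > 0, n_deleterious / n_total, NA_real_)
  if (!is.na(digits)) f <- round(f, digits)
  f
}

#' Nei-Gojobori potential site counts
#'
#' Each codon contributes, per position, the fraction of non-stop single-base
#' changes that are synonymous; synonymous + non-synonymous sites = 3 per
#' fully counted codon.
#'
#' @param x numeric(64) codon counts, a character codon vector, a
#'   `codon_alignment` (with `genotype`), or a list of alignments.
#' @param genotype genotype id for alignment input.
#' @return list with `syn`, `nonsyn` (fractional site counts) and `codons`
#'   (total codons counted).
#' @export
nei_gojobori_sites <- function(x, genotype = NULL) {
  if (!is.numeric(x)) x <- count_codons(x, genotype)
  tb <- genetic_code_tables()
  s <- tb$sense
  syn <- sum(x[s] * tb$ng_syn[s])
  tot <- sum(x[s])
  list(syn = syn, nonsyn = 3 * tot - syn, codons = tot)
}

#' Watterson's theta
#'
#' @param S segregating sites.
#' @param n number of haplotypes sampled.
#' @param L number of sites surveyed.
#' @return S / (a_n * L) with a_n the (n-1)-th harmonic number.
#' @export
watterson_theta <- function(S, n, L) {
  stopifnot(n >= 2, L > 0)
  S / (sum(1 / seq_len(n - 1L)) * L)
}

.allele_map <- local({
  m <- NULL
  function() {
    if (!is.null(m)) return(m)
    mm <- c(as.list(stats::setNames(BASES, BASES)), IUPAC_HET)
    m <<- mm
    mm
  }
})

#' Nucleotide diversity and divergence summary
#'
#' Computes, per site class (synonymous / non-synonymous): Nei-Gojobori
#' potential-site totals (averaged over ingroup genotypes), segregating sites
#' S among the ingroup, divergent sites K (sites where the outgroup allele is
#' absent from the ingroup allele set), and per-locus Watterson's theta
#' reported as across-locus mean and SD. Also returns the pairwise
#' nucleotide-difference matrix across all genotypes (heterozygous
#' mismatches contribute fractional differences, e.g. 0.5 for a heterozygote
#' against a matching homozygote) and per-genotype observed heterozygosity.
#'
#' Variable and divergent sites are classified synonymous/non-synonymous in
#' the codon context of the outgroup; sites whose outgroup codon is
#' unavailable are left unclassified.
#'
#' @param alignments named list of `codon_alignment` objects.
#' @param n_haplotypes haplotype count for Watterson's theta; default 2 per
#'   ingroup (diploid) genotype.
#' @return list with `by_class` (data.frame class/n_sites/S/K/theta_mean/
#'   theta_sd), `pairwise` (symmetric matrix), `h_obs` (named fractions),
#'   `n_haplotypes`, `n_loci`.
#' @export
diversity_summary <- function(alignments, n_haplotypes = NULL) {
  tb <- genetic_code_tables()
  amap <- .allele_map()
  first <- alignments[[1L]]
  genotypes <- first$genotypes
  outgroup <- first$outgroup
  ingroup <- setdiff(genotypes, outgroup)
  if (length(ingroup) < 2L) stop("need at least 2 ingroup genotypes")
  if (is.null(n_haplotypes)) n_haplotypes <- 2L * length(ingroup)

  classes <- c("synonymous", "non-synonymous")
  nsites <- c(0, 0)
  S_tot <- c(0L, 0L)
  K_tot <- c(0L, 0L)
  theta <- list(numeric(0), numeric(0))
  G <- length(genotypes)
  pw <- matrix(0, G, G, dimnames = list(genotypes, genotypes))
  het_sites <- stats::setNames(numeric(G), genotypes)
  call_sites <- stats::setNames(numeric(G), genotypes)

  for (aln in alignments) {
    stopifnot(identical(aln$genotypes, genotypes))
    L3 <- 3L * aln$n_codons
    nt <- matrix("", G, L3)
    for (g in seq_len(G)) nt[g, ] <- strsplit(aln$seqs[g], "")[[1L]]
    known <- matrix(nt %in% names(amap), G, L3)
    # exclude sites in excluded codon columns for each genotype
    excl <- aln$flags == FLAG_EXCL
    known <- known & !excl[, rep(seq_len(aln$n_codons), each = 3L)]
    is_het <- matrix(nt %in% names(IUPAC_HET), G, L3) & known

    het_sites <- het_sites + rowSums(is_het)
    call_sites <- call_sites + rowSums(known)

    # allele frequency arrays per base for pairwise differences
    fr <- lapply(BASES, function(b) {
      m <- (nt == b) * 1
      for (code in names(IUPAC_HET)) {
        if (b %in% IUPAC_HET[[code]]) m <- m + (nt == code) * 0.5
      }
      m
    })
    names(fr) <- BASES
    for (i in seq_len(G - 1L)) for (j in (i + 1L):G) {
      ok <- known[i, ] & known[j, ]
      same <- rowSums(vapply(
        BASES, function(b) fr[[b]][i, ok] * fr[[b]][j, ok],
        numeric(sum(ok))
      ))
      pw[i, j] <- pw[j, i] <- pw[i, j] + sum(1 - same)
    }

    # potential sites per class: NG fractional counts averaged over ingroup
    ng <- vapply(ingroup, function(g) {
      v <- nei_gojobori_sites(count_codons(aln, g))
      c(v$syn, v$nonsyn)
    }, numeric(2))
    loc_sites <- rowMeans(ng)
    nsites <- nsites + loc_sites

    og <- match(outgroup, genotypes)
    ing_i <- match(ingroup, genotypes)
    loc_S <- c(0L, 0L)
    loc_K <- c(0L, 0L)

    # ingroup allele union per site (variable / divergence calls)
    ing_known <- colSums(known[ing_i, , drop = FALSE]) == length(ing_i)
    cand <- which(ing_known)
    for (s in cand) {
      alleles <- unique(unlist(amap[nt[ing_i, s]]))
      seg <- length(alleles) > 1L
      div <- known[og, s] && !(nt[og, s] %in% names(IUPAC_HET)) &&
        !(nt[og, s] %in% alleles)
      if (!seg && !div) next
      # classify in the outgroup codon context
      j <- (s - 1L) %/% 3L + 1L
      pos <- (s - 1L) %% 3L + 1L
      if (aln$flags[og, j] != FLAG_PLAIN) next
      ogc <- aln$codon[og, j]
      mut <- tb$mut_next[ogc, pos, ]
      aas <- tb$aa[mut[match(alleles, BASES)]]
      cls <- if (seg) {
        if (length(unique(aas)) == 1L && unique(aas) != "*") 1L else 2L
      } else {
        if (all(aas == tb$aa[ogc])) 1L else 2L
      }
      if (seg) loc_S[cls] <- loc_S[cls] + 1L
      if (div) {
        cls_d <- if (all(aas == tb$aa[ogc]) && length(unique(aas)) == 1L) 1L else 2L
        loc_K[cls_d] <- loc_K[cls_d] + 1L
      }
    }
    S_tot <- S_tot + loc_S
    K_tot <- K_tot + loc_K
    for (cl in 1:2) {
      if (loc_sites[cl] > 0) {
        theta[[cl]] <- c(
          theta[[cl]],
          watterson_theta(loc_S[cl], n_haplotypes, loc_sites[cl])
        )
      }
    }
  }

  list(
    by_class = data.frame(
      class = classes, n_sites = nsites, S = S_tot, K = K_tot,
      theta_mean = vapply(theta, mean, numeric(1)),
      theta_sd = vapply(theta, stats::sd, numeric(1)),
      stringsAsFactors = FALSE
    ),
    pairwise = pw,
    h_obs = het_sites / pmax(call_sites, 1),
    n_haplotypes = n_haplotypes,
    n_loci = length(alignments)
  )
}
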