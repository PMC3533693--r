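# Simplified physicochemical-constraint classifier for non-synonymous
# changes: each homolog-alignment column yields a deviation score D(a) for
# every candidate amino acid from six property scales; candidates scoring
# beyond a chi-square-referenced threshold are "bad" (incompatible), and
# derived residues falling in the bad set are labelled deleterious. This is
# an intentionally simplified stand-in for full constraint methods (no
# tree-weighted sequence contributions); externally computed good/bad tables
# can be supplied instead.

AA1 <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

#' Default physicochemical property scales
#'
#' Six scales over the 20 amino acids: Kyte-Doolittle hydropathy, Grantham
#' polarity, net side-chain charge at pH 7, Zamyatnin side-chain volume
#' (A^3), and Chou-Fasman alpha-helix and beta-sheet propensities.
#'
#' @return numeric matrix, 20 amino acids x 6 scales.
#' @export
default_property_scales <- function() {
  m <- cbind(
    hydropathy = c(
      1.8, -4.5, -3.5, -3.5, 2.5, -3.5, -3.5, -0.4, -3.2, 4.5,
      3.8, -3.9, 1.9, 2.8, -1.6, -0.8, -0.7, -0.9, -1.3, 4.2
    ),
    polarity = c(
      8.1, 10.5, 11.6, 13.0, 5.5, 10.5, 12.3, 9.0, 10.4, 5.2,
      4.9, 11.3, 5.7, 5.2, 8.0, 9.2, 8.6, 5.4, 6.2, 5.9
    ),
    charge = c(
      0, 1, 0, -1, 0, 0, -1, 0, 0.1, 0,
      0, 1, 0, 0, 0, 0, 0, 0, 0, 0
    ),
    volume = c(
      88.6, 173.4, 114.1, 111.1, 108.5, 143.8, 138.4, 60.1, 153.2, 166.7,
      166.7, 168.6, 162.9, 189.9, 112.7, 89.0, 116.1, 227.8, 193.6, 140.0
    ),
    helix = c(
      1.42, 0.98, 0.67, 1.01, 0.70, 1.11, 1.51, 0.57, 1.00, 1.08,
      1.21, 1.16, 1.45, 1.13, 0.57, 0.77, 0.83, 1.08, 0.69, 1.06
    ),
    sheet = c(
      0.83, 0.93, 0.89, 0.54, 1.19, 1.10, 0.37, 0.75, 0.87, 1.60,
      1.30, 0.74, 1.05, 1.38, 0.55, 0.75, 1.19, 1.37, 1.47, 1.70
    )
  )
  rownames(m) <- AA1
  m
}

#' Constraint profile of one alignment column
#'
#' For each candidate amino acid a, the deviation score is
#' D(a) = sum_p ((s_p(a) - mu_p) / max(sigma_p, floor_p))^2 over property
#' scales p, with mu_p and sigma_p the mean and SD of the scale over the
#' residues observed in the column. Candidates with D above `tau` form the
#' incompatible ("bad") set.
#'
#' @param column character vector of observed residues (one-letter); gaps
#'   ("-", ".") and unknowns ("X") are dropped.
#' @param scales property matrix (default [default_property_scales()]).
#' @param sigma_floor per-scale lower bound on sigma; default 0.1 x the
#'   scale's SD across all 20 amino acids, preventing invariant columns from
#'   making every substitution incompatible.
#' @param tau deviation threshold; default the 95th percentile of a
#'   chi-square distribution with df = number of scales.
#' @return object of class `constraint_profile`: list with `residues`, `D`
#'   (named numeric over 20 amino acids), `tau`, `good`, `bad`; or NULL when
#'   fewer than 2 scorable residues remain (column undefined).
#' @export
build_profile <- function(column, scales = default_property_scales(),
                          sigma_floor = NULL, tau = NULL) {
  column <- toupper(column)
  column <- column[column %in% rownames(scales)]
  if (length(column) < 2L) return(NULL)
  if (is.null(sigma_floor)) sigma_floor <- 0.1 * apply(scales, 2L, stats::sd)
  if (is.null(tau)) tau <- stats::qchisq(0.95, df = ncol(scales))
  obs <- scales[column, , drop = FALSE]
  mu <- colMeans(obs)
  sg <- pmax(apply(obs, 2L, stats::sd), sigma_floor)
  z <- sweep(sweep(scales, 2L, mu, "-"), 2L, sg, "/")
  D <- rowSums(z^2)
  structure(list(
    residues = column, D = D, tau = tau,
    good = names(D)[D <= tau], bad = names(D)[D > tau]
  ), class = "constraint_profile")
}

#' Homolog-alignment quality filter
#'
#' @param n_homologs number of homologous proteins in the alignment.
#' @param identity mean pairwise identity of the homologs to the focal
#'   sequence over aligned positions.
#' @param min_homologs minimum homolog count (default 5).
#' @param min_identity identity threshold, strict ">" (default 0.6).
#' @return TRUE to keep the locus, FALSE to drop it.
#' @export
apply_filters <- function(n_homologs, identity, min_homologs = 5L,
                          min_identity = 0.6) {
  n_homologs >= min_homologs & identity > min_identity
}

#' Mean identity of homologs to a focal sequence
#'
#' @param focal character vector of residues (or a string).
#' @param homologs character matrix (homologs x positions) or character
#'   vector of aligned sequences.
#' @return mean pairwise identity over positions where both sequences are
#'   ungapped.
#' @export
alignment_identity <- function(focal, homologs) {
  if (is.character(focal) && length(focal) == 1L) {
    focal <- strsplit(focal, "")[[1L]]
  }
  if (!is.matrix(homologs)) {
    homologs <- do.call(rbind, strsplit(homologs, ""))
  }
  ids <- apply(homologs, 1L, function(h) {
    ok <- focal != "-" & h != "-"
    if (!any(ok)) return(NA_real_)
    mean(h[ok] == focal[ok])
  })
  mean(ids, na.rm = TRUE)
}

# Build a good-set lookup: function(locus, position) -> character vector of
# compatible amino acids, or NULL when the column is undefined.
# `homologs` is a named list (locus -> residue matrix homologs x positions or
# character vector of aligned sequences); `external` is a data.frame
# locus/position/allowed (allowed = string of one-letter codes) overriding
# computation, e.g. output from a full constraint tool.
constraint_lookup <- function(homologs = NULL, external = NULL,
                              scales = default_property_scales(),
                              sigma_floor = NULL, tau = NULL) {
  cache <- new.env(parent = emptyenv())
  if (!is.null(external)) {
    key <- paste(external$locus, external$position)
    ext <- stats::setNames(strsplit(toupper(external$allowed), ""), key)
    return(function(locus, pos) ext[[paste(locus, pos)]])
  }
  function(locus, pos) {
    key <- paste0(locus, ".", pos)
    if (!is.null(cache[[key]])) {
      return(if (identical(cache[[key]], "")) NULL else cache[[key]])
    }
    h <- homologs[[locus]]
    if (is.null(h)) return(NULL)
    if (!is.matrix(h)) {
      h <- do.call(rbind, strsplit(h, ""))
      homologs[[locus]] <<- h
    }
    if (pos > ncol(h)) {
      cache[[key]] <- ""
      return(NULL)
    }
    pr <- build_profile(h[, pos], scales, sigma_floor, tau)
    cache[[key]] <- if (is.null(pr)) "" else pr$good
    if (is.null(pr)) NULL else pr$good
  }
}

#' Label polarized non-synonymous changes as deleterious
#'
#' Polarized mode of the deleterious-mutation analysis: each derived
#' non-synonymous change is labelled deleterious when the derived residue
#' falls in the incompatible set of its protein position's constraint
#' profile.
#'
#' @param steps classified steps from [classify_changes()].
#' @param homologs named list (locus -> homolog residue matrix or aligned
#'   sequences); columns are assumed to map 1:1 to codon positions.
#' @param external optional precomputed good/bad table
#'   (locus, position, allowed) used instead of computing profiles.
#' @param counts optional `branch_change_counts` to augment in place.
#' @param ... passed to [build_profile()] (scales, sigma_floor, tau).
#' @return list with `steps` (deleterious column added; NA where the
#'   position was unclassifiable), `counts` (per-branch
#'   n_deleterious / n_nonsyn_classified / del_fraction filled in) and
#'   `n_unclassified` (weight of non-synonymous changes at unmapped or
#'   undefined positions).
#' @export
label_deleterious <- function(steps, homologs, external = NULL,
                              counts = NULL, ...) {
  tb <- genetic_code_tables()
  lookup <- constraint_lookup(homologs, external, ...)
  del <- rep(NA, nrow(steps))
  ns <- which(steps$class == "non-synonymous")
  for (i in ns) {
    good <- lookup(steps$locus[i], steps$codon[i])
    if (is.null(good)) next
    del[i] <- !(tb$aa[steps$to[i]] %in% good)
  }
  steps$deleterious <- del
  if (is.null(counts)) counts <- branch_counts(steps)
  cls <- !is.na(del)
  for (b in seq_len(nrow(counts))) {
    sel <- steps$branch == counts$branch[b] & steps$class == "non-synonymous"
    counts$n_nonsyn_classified[b] <- sum(steps$weight[sel & cls])
    counts$n_deleterious[b] <- sum(steps$weight[sel & cls & del %in% TRUE])
  }
  counts$del_fraction <- deleterious_fraction(
    counts$n_deleterious, counts$n_nonsyn_classified, digits = NA
  )
  list(
    steps = steps, counts = counts,
    n_unclassified = sum(steps$weight[ns][is.na(del[ns])])
  )
}

#' Deleterious alleles at polymorphic non-synonymous sites
#'
#' Polymorphism mode of the deleterious-mutation analysis: at every codon
#' column where the ingroup genotypes segregate for amino acid, each
#' genotype's allele(s) are labelled against the column's constraint profile
#' (heterozygous alleles weighted 0.5 each), avoiding any dependence on
#' ancestral-state assignment.
#'
#' @param alignments named list of `codon_alignment` objects.
#' @param homologs named list of homolog alignments (see
#'   [label_deleterious()]).
#' @param external optional precomputed good/bad table.
#' @param ... passed to [build_profile()].
#' @return data.frame: genotype, n_deleterious, n_total, fraction
#'   (deleterious / total over classified alleles).
#' @export
polymorphic_deleterious <- function(alignments, homologs, external = NULL,
                                    ...) {
  tb <- genetic_code_tables()
  lookup <- constraint_lookup(homologs, external, ...)
  first <- alignments[[1L]]
  ingroup <- first$ingroup
  n_del <- stats::setNames(numeric(length(ingroup)), ingroup)
  n_tot <- stats::setNames(numeric(length(ingroup)), ingroup)
  for (aln in alignments) {
    ing_i <- match(ingroup, aln$genotypes)
    for (j in seq_len(aln$n_codons)) {
      fl <- aln$flags[ing_i, j]
      if (all(fl == FLAG_EXCL)) next
      states <- list()
      for (k in seq_along(ingroup)) {
        if (fl[k] == FLAG_PLAIN) {
          states[[ingroup[k]]] <- cbind(codon = aln$codon[ing_i[k], j], w = 1)
        } else if (fl[k] == FLAG_HET) {
          states[[ingroup[k]]] <- aln$hets[[paste0(ingroup[k], ".", j)]]
        }
      }
      if (length(states) < 2L) next
      aas <- unique(tb$aa[unlist(lapply(states, function(s) s[, "codon"]))])
      if (length(aas) < 2L) next # not an amino-acid polymorphism
      good <- lookup(aln$locus, j)
      if (is.null(good)) next
      for (g in names(states)) {
        s <- states[[g]]
        for (r in seq_len(nrow(s))) {
          a <- tb$aa[s[r, "codon"]]
          n_tot[g] <- n_tot[g] + s[r, "w"]
          if (!(a %in% good)) n_del[g] <- n_del[g] + s[r, "w"]
        }
      }
    }
  }
  data.frame(
    genotype = ingroup, n_deleterious = as.numeric(n_del),
    n_total = as.numeric(n_tot),
    fraction = deleterious_fraction(n_del, n_tot, digits = NA),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
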