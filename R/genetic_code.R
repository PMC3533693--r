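#' @keywords internal
"_PACKAGE"

# Internal codon machinery.
#
# Codons are represented as integers 1..64 with index
#   16*(b1-1) + 4*(b2-1) + b3,  bases ordered A,C,G,T.
# All downstream counting (RSCU, Fop, polarization, Nei-Gojobori sites,
# the simulator) works on these integer codes; strings only appear at I/O.

BASES <- c("A", "C", "G", "T")

.tbl_env <- new.env(parent = emptyenv())

#' Genetic-code lookup tables
#'
#' Builds (once per session) the standard-genetic-code tables the package
#' relies on: codon/amino-acid maps, synonymous families and degeneracy,
#' single-mutation neighbourhoods, Nei-Gojobori potential-site fractions per
#' codon, and the minimal-mutational-path step decomposition used to classify
#' multi-position codon differences.
#'
#' @return A list with elements:
#'   \describe{
#'     \item{codons}{character(64), codon strings in index order.}
#'     \item{aa}{character(64), one-letter amino acid per codon ("*" = stop).}
#'     \item{sense}{integer indices of the 61 sense codons.}
#'     \item{families}{named list, amino acid -> integer codon indices.}
#'     \item{fam_size}{integer(64), synonymous-family size of each codon's
#'       amino acid (NA for stops).}
#'     \item{degenerate}{logical(64), TRUE for sense codons whose family has
#'       more than one member (excludes Met, Trp and stops).}
#'     \item{ng_syn}{numeric(64), Nei-Gojobori synonymous potential sites per
#'       codon (stop-creating changes excluded from denominators); NA for
#'       stops. Non-synonymous sites are \code{3 - ng_syn}.}
#'     \item{mut_next}{64 x 3 x 4 integer array: codon obtained by setting
#'       position p to base b.}
#'     \item{steps}{list indexed by \code{(from-1)*64 + to} giving, for every
#'       ordered pair of distinct sense codons, a matrix of single-nucleotide
#'       steps (columns from, to, w) averaged over all minimal mutational
#'       paths that avoid stop codons; NULL where every path crosses a stop.}
#'     \item{syn_step}{64 x 64 logical, TRUE where the single-nucleotide pair
#'       (row -> col) is a synonymous change.}
#'   }
#' @export
genetic_code_tables <- function() {
  if (!is.null(.tbl_env$tables)) return(.tbl_env$tables)

  codons <- character(64)
  k <- 0L
  for (b1 in BASES) for (b2 in BASES) for (b3 in BASES) {
    k <- k + 1L
    codons[k] <- paste0(b1, b2, b3)
  }
  gc_map <- Biostrings::GENETIC_CODE
  aa <- unname(gc_map[codons])
  sense <- which(aa != "*")

  families <- split(seq_len(64L)[sense], aa[sense])
  fam_size <- rep(NA_integer_, 64L)
  for (a in names(families)) fam_size[families[[a]]] <- length(families[[a]])
  degenerate <- !is.na(fam_size) & fam_size > 1L

  b_idx <- function(b) match(b, BASES)
  mut_next <- array(NA_integer_, dim = c(64L, 3L, 4L))
  for (i in seq_len(64L)) {
    b <- c(
      (i - 1L) %/% 16L + 1L,
      ((i - 1L) %/% 4L) %% 4L + 1L,
      (i - 1L) %% 4L + 1L
    )
    for (p in 1:3) for (nb in 1:4) {
      bb <- b
      bb[p] <- nb
      mut_next[i, p, nb] <- 16L * (bb[1] - 1L) + 4L * (bb[2] - 1L) + bb[3]
    }
  }

  # Nei-Gojobori potential synonymous sites per codon: at each position, the
  # fraction of non-stop single-base changes that are synonymous; each
  # position contributes one full site split syn/non-syn.
  ng_syn <- rep(NA_real_, 64L)
  for (i in sense) {
    s_tot <- 0
    for (p in 1:3) {
      nbrs <- mut_next[i, p, ]
      nbrs <- nbrs[nbrs != i]
      ok <- aa[nbrs] != "*"
      if (!any(ok)) next # position counts as fully non-synonymous (no valid change)
      s_tot <- s_tot + sum(aa[nbrs[ok]] == aa[i]) / sum(ok)
    }
    ng_syn[i] <- s_tot
  }

  syn_step <- matrix(FALSE, 64L, 64L)
  for (i in sense) for (p in 1:3) for (nb in 1:4) {
    j <- mut_next[i, p, nb]
    if (j != i && aa[j] != "*") syn_step[i, j] <- aa[j] == aa[i]
  }

  steps <- .build_step_table(codons, aa, sense)

  .tbl_env$tables <- list(
    codons = codons, aa = aa, sense = sense,
    families = families, fam_size = fam_size, degenerate = degenerate,
    ng_syn = ng_syn, mut_next = mut_next,
    steps = steps, syn_step = syn_step
  )
  .tbl_env$tables
}

# Minimal mutational paths between codon pairs, stop-avoiding, equal path
# weights (Nei-Gojobori convention). Returns list over (from-1)*64+to.
.build_step_table <- function(codons, aa, sense) {
  base_of <- function(i) c(
    (i - 1L) %/% 16L + 1L,
    ((i - 1L) %/% 4L) %% 4L + 1L,
    (i - 1L) %% 4L + 1L
  )
  idx_of <- function(b) 16L * (b[1] - 1L) + 4L * (b[2] - 1L) + b[3]
  perms <- list(
    `1` = list(1L),
    `2` = list(c(1L, 2L), c(2L, 1L)),
    `3` = list(
      c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
      c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)
    )
  )
  steps <- vector("list", 64L * 64L)
  for (a in sense) {
    ba <- base_of(a)
    for (d in sense) {
      if (a == d) next
      diffp <- which(ba != base_of(d))
      nd <- length(diffp)
      bd <- base_of(d)
      paths <- list()
      for (ord in perms[[as.character(nd)]]) {
        cur <- ba
        path <- matrix(0L, nrow = nd, ncol = 2L)
        ok <- TRUE
        for (s in seq_len(nd)) {
          nxt <- cur
          p <- diffp[ord[s]]
          nxt[p] <- bd[p]
          i_cur <- idx_of(cur); i_nxt <- idx_of(nxt)
          if (aa[i_nxt] == "*") { ok <- FALSE; break }
          path[s, ] <- c(i_cur, i_nxt)
          cur <- nxt
        }
        if (ok) paths[[length(paths) + 1L]] <- path
      }
      if (!length(paths)) next # unreachable without crossing a stop
      w <- 1 / length(paths)
      all_steps <- do.call(rbind, paths)
      key <- paste(all_steps[, 1], all_steps[, 2])
      agg <- rowsum(rep(w, nrow(all_steps)), key)
      fromto <- matrix(as.integer(unlist(strsplit(rownames(agg), " "))),
        ncol = 2L, byrow = TRUE
      )
      steps[[(a - 1L) * 64L + d]] <- cbind(
        from = fromto[, 1], to = fromto[, 2], w = agg[, 1]
      )
    }
  }
  steps
}

#' Convert codon strings to integer codes
#'
#' @param x character vector of 3-letter codons over A/C/G/T.
#' @return integer codes in 1..64; NA for codons containing other symbols.
#' @export
codon_index <- function(x) {
  tb <- genetic_code_tables()
  match(toupper(x), tb$codons)
}

#' Convert integer codon codes back to strings
#' @param i integer codes in 1..64.
#' @return character codons.
#' @export
codon_string <- function(i) genetic_code_tables()$codons[i]

#' The standard genetic code as a data frame
#'
#' @return data.frame with columns codon, aa (one-letter, "*" for stop),
#'   family_size and degenerate flag; 64 rows.
#' @export
genetic_code_table <- function() {
  tb <- genetic_code_tables()
  data.frame(
    codon = tb$codons, aa = tb$aa,
    family_size = tb$fam_size, degenerate = tb$degenerate,
    stringsAsFactors = FALSE
  )
}

# Two-base IUPAC ambiguity codes (unphased heterozygotes); anything else
# non-ACGT marks the codon ambiguous/excluded.
IUPAC_HET <- list(
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
  W = c("A", "T"), K = c("G", "T"), M = c("A", "C")
)
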