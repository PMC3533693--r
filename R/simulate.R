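# Truth-known mutation-selection-drift simulator of coding-sequence
# evolution over a four-genotype tree: root -> outgroup tip, and
# root -> ingroup ancestor -> three terminal genotypes. Selection enters via
# Kimura relative fixation weights f(dS) = dS / (1 - exp(-dS)) applied to
# mutation proposals: synonymous proposals gain/lose the per-gene codon-bias
# benefit S_g for planted preferred codons, non-synonymous proposals that
# violate a planted physicochemical constraint draw a Gamma-distributed
# cost. Per-lineage efficacy multipliers nu scale every selective effect, so
# nu < 1 emulates the drift-dominated regime of selfing lineages. Every
# accepted change is recorded in a ledger that can be replayed exactly.

#' Simulation configuration
#'
#' @param n_genes number of orthologous loci.
#' @param n_codons codons per locus (constant length).
#' @param expr_meanlog,expr_sdlog log-normal law of mean expression (FPKM-like).
#' @param s_max maximal codon-bias selection intensity; a gene at expression
#'   rank q gets S_g = s_max * q, so bias is concentrated in highly
#'   expressed genes.
#' @param branch_lengths expected mutation proposals per codon, named
#'   "outgroup", "ancestral" and one entry per ingroup genotype.
#' @param nu selection-efficacy multipliers in (0, 1], same names as
#'   `branch_lengths`; selfing terminal branches get nu < 1.
#' @param p_del probability that a constraint-violating non-synonymous
#'   proposal (derived residue incompatible with the planted column
#'   consensus at a constrained position) carries a fitness cost.
#' @param del_shape,del_mean shape and mean of the Gamma law of that cost.
#' @param kappa transition:transversion mutation bias.
#' @param constrained_frac fraction of codon positions under planted
#'   physicochemical constraint.
#' @param het_rate per-genotype heterozygote injection rate per nucleotide
#'   site (unphased IUPAC codes; independent sites).
#' @param outgroup,ingroup genotype ids.
#' @param mating named map genotype -> "selfing"/"outcrossing".
#' @param n_homologs homologous proteins emitted per locus.
#' @param expr_noise_sd log-scale SD of per-genotype expression noise.
#' @param seed mandatory RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_codons = 200L,
                       expr_meanlog = 3,
                       expr_sdlog = 1.5,
                       s_max = 2,
                       branch_lengths = c(
                         outgroup = 0.2, ancestral = 0.1,
                         brazil = 0.12, jamaica = 0.12, nicaragua = 0.12
                       ),
                       nu = c(
                         outgroup = 1, ancestral = 1,
                         brazil = 1, jamaica = 0.2, nicaragua = 0.2
                       ),
                       p_del = 0.8,
                       del_shape = 0.6,
                       del_mean = 2,
                       kappa = 2,
                       constrained_frac = 0.7,
                       het_rate = c(
                         brazil = 9.8e-4, jamaica = 1.8e-4,
                         nicaragua = 0.8e-4, paradoxa = 0
                       ),
                       outgroup = "paradoxa",
                       ingroup = c("brazil", "jamaica", "nicaragua"),
                       mating = c(
                         brazil = "outcrossing", jamaica = "selfing",
                         nicaragua = "selfing", paradoxa = "selfing"
                       ),
                       n_homologs = 6L,
                       expr_noise_sd = 0.1,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("sim_config: seed is mandatory")
  cfg <- list(
    n_genes = as.integer(n_genes), n_codons = as.integer(n_codons),
    expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog, s_max = s_max,
    branch_lengths = branch_lengths, nu = nu, p_del = p_del,
    del_shape = del_shape, del_mean = del_mean, kappa = kappa,
    constrained_frac = constrained_frac, het_rate = het_rate,
    outgroup = outgroup, ingroup = ingroup, mating = mating,
    n_homologs = as.integer(n_homologs), expr_noise_sd = expr_noise_sd,
    seed = as.integer(seed)
  )
  branches <- c("outgroup", "ancestral", ingroup)
  stopifnot(
    cfg$n_genes >= 1L, cfg$n_codons >= 2L, cfg$s_max >= 0,
    all(branches %in% names(cfg$branch_lengths)),
    all(branches %in% names(cfg$nu)),
    all(cfg$nu > 0 & cfg$nu <= 1),
    all(cfg$branch_lengths >= 0),
    cfg$p_del >= 0, cfg$p_del <= 1,
    cfg$constrained_frac >= 0, cfg$constrained_frac <= 1,
    all(cfg$het_rate >= 0 & cfg$het_rate <= 1),
    all(c(ingroup, outgroup) %in% names(cfg$mating)),
    cfg$kappa > 0, cfg$del_shape > 0, cfg$del_mean > 0
  )
  class(cfg) <- "sim_config"
  cfg
}

base_at_table <- function() {
  i <- seq_len(64L)
  cbind(
    (i - 1L) %/% 16L + 1L,
    ((i - 1L) %/% 4L) %% 4L + 1L,
    (i - 1L) %% 4L + 1L
  )
}

# Kimura relative fixation weight, f(0) = 1.
kimura_weight <- function(ds) {
  out <- rep(1, length(ds))
  nz <- abs(ds) > 1e-12
  out[nz] <- ds[nz] / (1 - exp(-ds[nz]))
  out
}

# amino-acid compatibility under a fully conserved column of `cons`:
# 20 x 20 logical, [candidate, consensus]
compat_matrix <- function(n_homologs, scales = default_property_scales(),
                          sigma_floor = NULL, tau = NULL) {
  m <- matrix(FALSE, 20L, 20L, dimnames = list(AA1, AA1))
  for (cons in AA1) {
    pr <- build_profile(rep(cons, n_homologs), scales, sigma_floor, tau)
    m[pr$good, cons] <- TRUE
  }
  m
}

# One branch of sequence evolution over the concatenated codon vector.
# Proposals at positions hit only once are processed vectorized; positions
# proposed more than once fall back to a sequential loop so multiple hits
# compound correctly.
evolve_branch <- function(cod, S_gene, gene_of, constrained, cons_aa_idx,
                          len, nu, cfg, tb, compat, pref) {
  N <- length(cod)
  n_prop <- stats::rpois(1L, len * N)
  empty <- data.frame(
    pos = integer(), from = integer(), to = integer(),
    syn = logical(), deleterious = logical(), ord = integer()
  )
  if (n_prop == 0L) return(list(cod = cod, ledger = empty))
  base_at <- base_at_table()
  partner <- c(3L, 4L, 1L, 2L)
  aa_idx <- match(tb$aa, AA1)
  f_cap <- if (cfg$s_max > 0) kimura_weight(cfg$s_max) else 1

  pos <- sample.int(N, n_prop, replace = TRUE)
  p_in <- sample.int(3L, n_prop, replace = TRUE)
  u_base <- stats::runif(n_prop)
  u_acc <- stats::runif(n_prop)
  u_del <- stats::runif(n_prop)
  g_del <- stats::rgamma(n_prop, shape = cfg$del_shape,
                         rate = cfg$del_shape / cfg$del_mean)

  step <- function(idx, cur) {
    # shared proposal logic; cur = current codon at pos[idx]
    b_cur <- base_at[cbind(cur, p_in[idx])]
    w <- matrix(1, length(idx), 4L)
    w[cbind(seq_along(idx), b_cur)] <- 0
    w[cbind(seq_along(idx), partner[b_cur])] <- cfg$kappa
    tot <- cfg$kappa + 2
    u <- u_base[idx] * tot
    c1 <- w[, 1L]; c2 <- c1 + w[, 2L]; c3 <- c2 + w[, 3L]
    nb <- 1L + (u > c1) + (u > c2) + (u > c3)
    new <- tb$mut_next[cbind(cur, p_in[idx], nb)]
    ok <- tb$aa[new] != "*"
    syn <- tb$syn_step[cbind(cur, new)]
    nu_s <- nu * S_gene[gene_of[pos[idx]]]
    ds <- ifelse(syn, nu_s * (pref[new] - pref[cur]), 0)
    viol <- ok & !syn & constrained[pos[idx]] &
      !compat[cbind(
        ifelse(ok, aa_idx[new], 1L), cons_aa_idx[pos[idx]]
      )]
    del <- viol & (u_del[idx] < cfg$p_del)
    ds[del] <- -g_del[idx][del] * nu
    acc <- ok & (u_acc[idx] < kimura_weight(ds) / f_cap)
    list(new = new, syn = syn, del = del, acc = acc)
  }

  dup <- pos %in% pos[duplicated(pos)]
  led <- vector("list", 2L)

  v <- which(!dup)
  if (length(v)) {
    cur <- cod[pos[v]]
    st <- step(v, cur)
    a <- st$acc
    cod[pos[v[a]]] <- st$new[a]
    led[[1L]] <- data.frame(
      pos = pos[v[a]], from = cur[a], to = st$new[a],
      syn = st$syn[a], deleterious = st$del[a], ord = v[a]
    )
  }
  sq <- which(dup)
  if (length(sq)) {
    rows <- vector("list", length(sq))
    nr <- 0L
    for (i in sq) {
      cur <- cod[pos[i]]
      st <- step(i, cur)
      if (st$acc) {
        cod[pos[i]] <- st$new
        nr <- nr + 1L
        rows[[nr]] <- c(pos[i], cur, st$new, st$syn, st$del, i)
      }
    }
    if (nr) {
      m <- do.call(rbind, rows[seq_len(nr)])
      led[[2L]] <- data.frame(
        pos = m[, 1L], from = m[, 2L], to = m[, 3L],
        syn = as.logical(m[, 4L]), deleterious = as.logical(m[, 5L]),
        ord = m[, 6L]
      )
    }
  }
  ledger <- do.call(rbind, led[!vapply(led, is.null, logical(1))])
  if (is.null(ledger)) ledger <- empty
  ledger <- ledger[order(ledger$ord), , drop = FALSE]
  rownames(ledger) <- NULL
  list(cod = cod, ledger = ledger)
}

IUPAC_FROM_PAIR <- c(
  AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M"
)

# Fast internal constructor used by the simulator: builds a codon_alignment
# from integer codon matrices plus a het table without re-parsing strings.
# Structurally identical to codon_alignment() output (checked in tests).
new_codon_alignment_raw <- function(locus, genotypes, outgroup, cod_mat,
                                    hets_df, tb) {
  G <- nrow(cod_mat)
  L <- ncol(cod_mat)
  dimnames(cod_mat) <- NULL
  flags <- matrix(FLAG_PLAIN, G, L)
  base_at <- base_at_table()
  seqs <- stats::setNames(
    vapply(seq_len(G), function(g) {
      paste0(tb$codons[cod_mat[g, ]], collapse = "")
    }, character(1)),
    genotypes
  )
  cod <- cod_mat
  hets <- list()
  if (!is.null(hets_df) && nrow(hets_df)) {
    for (r in seq_len(nrow(hets_df))) {
      g <- match(hets_df$genotype[r], genotypes)
      j <- hets_df$codon[r]
      p <- hets_df$pos[r]
      c0 <- cod_mat[g, j]
      c1 <- tb$mut_next[c0, p, hets_df$base2[r]]
      pair <- paste0(sort(BASES[c(base_at[c0, p], hets_df$base2[r])]),
                     collapse = "")
      s <- seqs[[g]]
      substr(s, 3L * (j - 1L) + p, 3L * (j - 1L) + p) <- IUPAC_FROM_PAIR[[pair]]
      seqs[[g]] <- s
      flags[g, j] <- FLAG_HET
      cod[g, j] <- NA_integer_
      hets[[paste0(genotypes[g], ".", j)]] <-
        cbind(codon = c(c0, c1), w = c(0.5, 0.5))
    }
  }
  structure(list(
    locus = locus, genotypes = genotypes, outgroup = outgroup,
    ingroup = setdiff(genotypes, outgroup), n_codons = L,
    seqs = seqs, codon = cod, flags = flags, hets = hets,
    gap_cols = integer(0)
  ), class = "codon_alignment")
}

#' Simulate a truth-known orthologous-locus dataset
#'
#' Generates codon alignments (outgroup + three ingroup genotypes),
#' a per-genotype expression table, per-locus homolog protein alignments
#' reflecting the planted constrained positions, and a `truth` record
#' holding the planted preferred codons, per-gene selection strengths, the
#' per-branch ledger of accepted changes and the injected heterozygous
#' sites. Replaying the ledger from the root reproduces every tip exactly.
#'
#' @param config a `sim_config`.
#' @param out_dir optional directory; when given, writes `loci/*.fasta`,
#'   `expression.tsv`, `homologs/*.fasta` and `truth.json` there.
#' @return list of class `selcub_sim`: alignments (named list of
#'   `codon_alignment`), expression (`selcub_expression`), homologs (named
#'   list of character vectors of aligned homolog proteins), truth, config.
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  cfg <- if (inherits(config, "sim_config")) config else do.call(sim_config, config)
  set.seed(cfg$seed)
  tb <- genetic_code_tables()
  G <- cfg$n_genes
  L <- cfg$n_codons
  N <- G * L
  gene_ids <- sprintf("g%05d", seq_len(G))
  genotypes <- c(cfg$outgroup, cfg$ingroup)
  gene_of <- rep(seq_len(G), each = L)

  # planted preferred codon: one per degenerate amino acid, G/C-ending
  # members favoured (mirrors the GC-ending optimal codons seen in plants)
  pref <- rep(0, 64L)
  preferred <- integer(0)
  third_gc <- third_base_gc()
  for (fam in tb$families) {
    if (length(fam) < 2L) next
    cand <- fam[third_gc[fam]]
    if (!length(cand)) cand <- fam
    pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
    preferred <- c(preferred, pick)
    pref[pick] <- 1
  }

  # expression and per-gene selection intensity
  expr_mean <- stats::rlnorm(G, cfg$expr_meanlog, cfg$expr_sdlog)
  S_gene <- cfg$s_max * rank(expr_mean, ties.method = "first") / G

  # ancestral sequences at codon equilibrium pi ~ exp(S_g * preferred)
  aa_names <- names(tb$families)
  aa_pick <- sample(length(aa_names), N, replace = TRUE)
  cod0 <- integer(N)
  S_pos <- S_gene[gene_of]
  for (ai in seq_along(aa_names)) {
    fam <- tb$families[[ai]]
    sel <- which(aa_pick == ai)
    if (!length(sel)) next
    k <- length(fam)
    if (k == 1L) {
      cod0[sel] <- fam
      next
    }
    w <- matrix(1, length(sel), k)
    for (j in seq_len(k)) if (pref[fam[j]] > 0) w[, j] <- exp(S_pos[sel])
    cum <- t(apply(w, 1L, cumsum))
    u <- stats::runif(length(sel)) * cum[, k]
    pick <- rep(1L, length(sel))
    for (j in seq_len(k - 1L)) pick <- pick + (u > cum[, j])
    cod0[sel] <- fam[pick]
  }

  # planted constraint structure
  constrained <- stats::runif(N) < cfg$constrained_frac
  cons_aa_idx <- match(tb$aa[cod0], AA1)
  compat <- compat_matrix(cfg$n_homologs)

  run <- function(cod, branch) {
    evolve_branch(
      cod, S_gene, gene_of, constrained, cons_aa_idx,
      cfg$branch_lengths[[branch]], cfg$nu[[branch]], cfg, tb, compat, pref
    )
  }
  out_tip <- run(cod0, "outgroup")
  anc <- run(cod0, "ancestral")
  tips <- list()
  tips[[cfg$outgroup]] <- out_tip$cod
  ledgers <- list(outgroup = out_tip$ledger, ancestral = anc$ledger)
  for (g in cfg$ingroup) {
    r <- run(anc$cod, g)
    tips[[g]] <- r$cod
    ledgers[[g]] <- r$ledger
  }

  # heterozygote injection: unphased IUPAC codes at independent sites, one
  # per codon, skipping substitutions that would create a stop phase
  base_at <- base_at_table()
  het_rows <- list()
  for (g in genotypes) {
    h <- cfg$het_rate[[g]]
    if (is.null(h) || h <= 0) next
    n_h <- stats::rbinom(1L, 3L * N, h)
    if (!n_h) next
    sites <- sample.int(3L * N, n_h)
    cod_j <- (sites - 1L) %/% 3L + 1L
    keep <- !duplicated(cod_j)
    sites <- sites[keep]
    cod_j <- cod_j[keep]
    p_in <- (sites - 1L) %% 3L + 1L
    for (r in seq_along(sites)) {
      c0 <- tips[[g]][cod_j[r]]
      b0 <- base_at[c0, p_in[r]]
      alts <- setdiff(1:4, b0)
      alts <- alts[tb$aa[tb$mut_next[c0, p_in[r], alts]] != "*"]
      if (!length(alts)) next
      b1 <- if (length(alts) == 1L) alts else sample(alts, 1L)
      het_rows[[length(het_rows) + 1L]] <- data.frame(
        genotype = g, gene = gene_ids[gene_of[cod_j[r]]],
        codon = (cod_j[r] - 1L) %% L + 1L, pos = p_in[r],
        base1 = b0, base2 = b1, stringsAsFactors = FALSE
      )
    }
  }
  hets_df <- if (length(het_rows)) {
    do.call(rbind, het_rows)
  } else {
    data.frame(
      genotype = character(), gene = character(), codon = integer(),
      pos = integer(), base1 = integer(), base2 = integer()
    )
  }

  # per-locus alignments
  alignments <- vector("list", G)
  names(alignments) <- gene_ids
  for (gi in seq_len(G)) {
    rows <- ((gi - 1L) * L + 1L):(gi * L)
    cod_mat <- do.call(rbind, lapply(tips[genotypes], function(x) x[rows]))
    rownames(cod_mat) <- genotypes
    hd <- hets_df[hets_df$gene == gene_ids[gi], , drop = FALSE]
    alignments[[gi]] <- new_codon_alignment_raw(
      gene_ids[gi], genotypes, cfg$outgroup, cod_mat, hd, tb
    )
  }

  # expression table: per-genotype log-normal noise around the gene mean
  vals <- lapply(genotypes, function(g) {
    expr_mean * stats::rlnorm(G, 0, cfg$expr_noise_sd)
  })
  names(vals) <- genotypes
  expression <- expression_table(gene_ids, vals)

  # homolog protein alignments: conserved columns at constrained positions,
  # free columns elsewhere
  homologs <- vector("list", G)
  names(homologs) <- gene_ids
  for (gi in seq_len(G)) {
    rows <- ((gi - 1L) * L + 1L):(gi * L)
    root_aa <- tb$aa[cod0[rows]]
    hm <- matrix(root_aa, cfg$n_homologs, L, byrow = TRUE)
    free <- which(!constrained[rows])
    if (length(free)) {
      hm[, free] <- sample(AA1, cfg$n_homologs * length(free), replace = TRUE)
    }
    homologs[[gi]] <- apply(hm, 1L, paste0, collapse = "")
  }

  led <- do.call(rbind, lapply(names(ledgers), function(b) {
    ld <- ledgers[[b]]
    if (!nrow(ld)) return(NULL)
    data.frame(
      branch = if (b == "outgroup") "outgroup" else b,
      gene = gene_ids[gene_of[ld$pos]],
      codon = (ld$pos - 1L) %% L + 1L,
      from = ld$from, to = ld$to, syn = ld$syn,
      bias = ifelse(!ld$syn, NA_character_, ifelse(
        pref[ld$to] > pref[ld$from], "U2P",
        ifelse(pref[ld$from] > pref[ld$to], "P2U", "U2U")
      )),
      deleterious = ld$deleterious, ord = ld$ord,
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(led)) {
    led <- data.frame(
      branch = character(), gene = character(), codon = integer(),
      from = integer(), to = integer(), syn = logical(),
      bias = character(), deleterious = logical(), ord = integer()
    )
  }

  truth <- list(
    config = unclass(cfg),
    preferred = tb$codons[sort(preferred)],
    s_gene = stats::setNames(S_gene, gene_ids),
    root = cod0, ingroup_ancestor = anc$cod,
    ledger = led, hets = hets_df,
    constrained = constrained
  )

  sim <- structure(list(
    alignments = alignments, expression = expression,
    homologs = homologs, truth = truth, config = cfg
  ), class = "selcub_sim")

  if (!is.null(out_dir)) write_sim_dataset(sim, out_dir)
  sim
}

#' @export
print.selcub_sim <- function(x, ...) {
  cat(sprintf(
    "<selcub_sim> %d loci x %d codons, genotypes %s (outgroup %s), %d planted changes, seed %d\n",
    x$config$n_genes, x$config$n_codons,
    paste(c(x$config$outgroup, x$config$ingroup), collapse = "/"),
    x$config$outgroup, nrow(x$truth$ledger), x$config$seed
  ))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' @param sim a `selcub_sim`.
#' @param dir output directory; creates `loci/`, `homologs/`,
#'   `expression.tsv` and `truth.json`.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_codon_alignments(sim$alignments, file.path(dir, "loci"))
  write_expression_table(sim$expression, file.path(dir, "expression.tsv"))
  hdir <- file.path(dir, "homologs")
  dir.create(hdir, showWarnings = FALSE)
  for (id in names(sim$homologs)) {
    seqs <- sim$homologs[[id]]
    names(seqs) <- sprintf("%s_hom%d", id, seq_along(seqs))
    Biostrings::writeXStringSet(
      Biostrings::BStringSet(seqs), file.path(hdir, paste0(id, ".fasta")),
      width = 80L
    )
  }
  jsonlite::write_json(
    sim$truth, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(dir)
}

#' Replay the planted change ledger from the root
#'
#' Applies the ledger to the ancestral sequence branch by branch (in
#' recorded order) and re-applies the planted heterozygous sites, returning
#' the implied tip nucleotide sequences. Byte-identity with the emitted
#' alignments is the simulator's core consistency check.
#'
#' @param sim a `selcub_sim`.
#' @return named list genotype -> named character vector (locus -> sequence).
#' @export
replay_truth <- function(sim) {
  tb <- genetic_code_tables()
  cfg <- sim$config
  G <- cfg$n_genes
  L <- cfg$n_codons
  gene_ids <- names(sim$alignments)
  led <- sim$truth$ledger

  apply_branch <- function(cod, branch) {
    ld <- led[led$branch == branch, , drop = FALSE]
    if (!nrow(ld)) return(cod)
    ld <- ld[order(ld$ord), , drop = FALSE]
    pos <- (match(ld$gene, gene_ids) - 1L) * L + ld$codon
    for (r in seq_len(nrow(ld))) {
      if (cod[pos[r]] != ld$from[r]) {
        stop("ledger inconsistent at ", ld$gene[r], " codon ", ld$codon[r])
      }
      cod[pos[r]] <- ld$to[r]
    }
    cod
  }

  root <- sim$truth$root
  tips <- list()
  tips[[cfg$outgroup]] <- apply_branch(root, "outgroup")
  anc <- apply_branch(root, "ancestral")
  for (g in cfg$ingroup) tips[[g]] <- apply_branch(anc, g)

  hets <- sim$truth$hets
  out <- list()
  for (g in names(tips)) {
    seqs <- character(G)
    for (gi in seq_len(G)) {
      rows <- ((gi - 1L) * L + 1L):(gi * L)
      seqs[gi] <- paste0(tb$codons[tips[[g]][rows]], collapse = "")
    }
    names(seqs) <- gene_ids
    hd <- hets[hets$genotype == g, , drop = FALSE]
    for (r in seq_len(nrow(hd))) {
      s <- seqs[[hd$gene[r]]]
      at <- 3L * (hd$codon[r] - 1L) + hd$pos[r]
      pair <- paste0(sort(BASES[c(hd$base1[r], hd$base2[r])]), collapse = "")
      substr(s, at, at) <- IUPAC_FROM_PAIR[[pair]]
      seqs[[hd$gene[r]]] <- s
    }
    out[[g]] <- seqs
  }
  out
}
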