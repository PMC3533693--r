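# RSCU, GC3s, Fop, expression partition, delta-RSCU and optimal codons.

counts_for <- function(codons) count_codons(codons)

test_that("RSCU follows the family formula and flags empty families", {
  # uniform 4-fold usage -> 1.0 each
  r <- rscu(counts_for(rep(c("GCT", "GCC", "GCA", "GCG"), 10)))
  expect_equal(r$rscu[r$aa == "A"], rep(1, 4))
  # extreme 2-fold bias -> (2, 0)
  r <- rscu(counts_for(rep("GAC", 10)))
  expect_equal(r$rscu[r$codon == "GAC"], 2)
  expect_equal(r$rscu[r$codon == "GAT"], 0)
  # 6-fold Leu, one codon only -> 6
  r <- rscu(counts_for(rep("CTG", 6)))
  expect_equal(r$rscu[r$codon == "CTG"], 6)
  expect_true(all(r$undefined[r$aa == "K"]))
  expect_true(all(is.na(r$rscu[r$aa == "K"])))
})

test_that("RSCU values sum to family size for every non-empty family", {
  set.seed(42)
  for (rep_i in 1:5) {
    cts <- count_codons(random_gene(300))
    r <- rscu(cts)
    for (aa in unique(r$aa)) {
      rows <- r[r$aa == aa, ]
      if (any(rows$undefined)) next
      expect_equal(sum(rows$rscu), nrow(rows), info = aa)
    }
  }
})

test_that("RSCU, GC3s and Fop match brute-force oracles on random genes", {
  set.seed(7)
  opt <- c("GCC", "GAC", "CTG", "AAG", "TTC")
  for (i in 1:100) {
    gene <- random_gene(sample(20:60, 1))
    cts <- counts_for(gene)
    r <- rscu(cts)
    expect_equal(
      stats::setNames(r$rscu, r$codon)[SENSE_CODONS],
      oracle_rscu(gene)[SENSE_CODONS]
    )
    expect_equal(gc3s(cts), oracle_gc3s(gene))
    expect_equal(fop(cts, opt), oracle_fop(gene, opt))
  }
})

test_that("GC3s handles boundary cases", {
  expect_equal(gc3s(c("TTT", "TTC")), 0.5)
  expect_true(is.na(gc3s(c("ATG", "TGG"))))
  expect_equal(gc3s(c("GCC", "GGG", "CTC")), 1)
})

test_that("Fop is bounded and behaves as a weighted mean under concatenation", {
  opt <- c("GCC", "GAC")
  expect_equal(fop(rep(c("GCC", "GAC"), 5), opt), 1)
  expect_true(is.na(fop(c("ATG", "TGG"), opt)))
  expect_equal(fop(c("GCC", "GCT", "GCA", "GCG"), opt), 0.25)
  set.seed(11)
  for (i in 1:20) {
    g1 <- random_gene(30, exclude_met_trp = TRUE)
    g2 <- random_gene(50, exclude_met_trp = TRUE)
    f1 <- fop(g1, opt); f2 <- fop(g2, opt); f12 <- fop(c(g1, g2), opt)
    expect_gte(f12, min(f1, f2) - 1e-12)
    expect_lte(f12, max(f1, f2) + 1e-12)
  }
})

test_that("count_codons propagates heterozygote weights and is additive", {
  expect_equal(unname(count_codons("ARA")[c("AAA", "AGA")]), c(0.5, 0.5))
  g1 <- c("ATG", "AAA"); g2 <- c("AAA", "GGG")
  expect_equal(count_codons(c(g1, g2)), count_codons(g1) + count_codons(g2))
  expect_error(count_codons(character(0)), "empty")
})

test_that("expression partition is deterministic with id tie-breaking", {
  et <- expression_table(sprintf("g%03d", 1:100), list(a = 1:100, b = 1:100))
  parts <- partition_by_expression(et, quantile = 0.1)
  expect_length(parts$high, 10)
  expect_length(parts$low, 10)
  expect_setequal(parts$high, sprintf("g%03d", 91:100))
  expect_setequal(parts$low, sprintf("g%03d", 1:10))
  expect_false(parts$degenerate)

  et2 <- expression_table(sprintf("g%03d", 1:100), list(a = rep(1, 100)))
  parts2 <- partition_by_expression(et2, quantile = 0.1, basis = "a")
  expect_true(parts2$degenerate)
  expect_setequal(parts2$high, sprintf("g%03d", 1:10)) # id order under ties
  expect_error(partition_by_expression(et, quantile = 0.6), "quantile")
})

# toy count matrix helper: list gene -> codon character vector
toy_matrix <- function(genes) {
  m <- do.call(rbind, lapply(genes, count_codons))
  rownames(m) <- names(genes)
  m
}

test_that("delta-RSCU is zero under identical usage and antisymmetric", {
  genes <- list(
    h1 = c("GAC", "GAT", "AAA"), h2 = c("GAC", "GAT", "AAG"),
    h3 = c("GAC", "GAT", "AAA"),
    l1 = c("GAC", "GAT", "AAA"), l2 = c("GAC", "GAT", "AAG"),
    l3 = c("GAC", "GAT", "AAA")
  )
  m <- toy_matrix(genes)
  d <- delta_rscu(m, c("h1", "h2", "h3"), c("l1", "l2", "l3"))
  expect_true(all(d$delta[!is.na(d$delta)] == 0))
  expect_false(any(d$optimal))

  set.seed(3)
  genes2 <- lapply(1:8, function(i) random_gene(30))
  names(genes2) <- paste0("g", 1:8)
  m2 <- toy_matrix(genes2)
  d_fwd <- delta_rscu(m2, paste0("g", 1:4), paste0("g", 5:8))
  d_rev <- delta_rscu(m2, paste0("g", 5:8), paste0("g", 1:4))
  expect_equal(d_fwd$delta, -d_rev$delta)
  expect_equal(d_fwd$p, d_rev$p)
})

test_that("delta-RSCU on a hand-built contrast matches the formula", {
  # high genes use only GAC for Asp (per-gene RSCU 2), low only GAT (RSCU 0)
  genes <- list(
    h1 = c("GAC", "GAC", "AAA"), h2 = c("GAC", "AAA", "AAA"),
    h3 = c("GAC", "GAC", "GAC"),
    l1 = c("GAT", "GAT", "AAA"), l2 = c("GAT", "AAA", "AAA"),
    l3 = c("GAT", "GAT", "GAT")
  )
  m <- toy_matrix(genes)
  d <- delta_rscu(m, c("h1", "h2", "h3"), c("l1", "l2", "l3"),
    p_adjust = "none"
  )
  gac <- d[d$codon == "GAC", ]
  expect_equal(gac$delta, 2)
  expect_equal(gac$rscu_high, 2)
  expect_equal(gac$rscu_low, 0)
  expect_true(gac$optimal) # zero within-group variance, degenerate separation
  # permuting gene labels within a group changes nothing
  d2 <- delta_rscu(m, c("h3", "h1", "h2"), c("l2", "l3", "l1"),
    p_adjust = "none"
  )
  expect_equal(d$delta, d2$delta)
})

test_that("genes lacking a family are omitted from that codon's contrast", {
  genes <- list(
    h1 = c("GAC", "GAC"), h2 = c("AAA", "AAA"), h3 = c("GAC", "GAT"),
    l1 = c("GAT", "GAT"), l2 = c("GAT", "GAC"), l3 = c("AAG", "AAG")
  )
  m <- toy_matrix(genes)
  d <- delta_rscu(m, c("h1", "h2", "h3"), c("l1", "l2", "l3"))
  gac <- d[d$codon == "GAC", ]
  expect_equal(gac$n_high, 2L) # h2 has no Asp
  expect_equal(gac$n_low, 2L) # l3 has no Asp
  expect_equal(gac$delta, mean(c(2, 1)) - mean(c(0, 1)))
})

test_that("consensus optimal codons intersect genotypes and keep one per amino acid", {
  mk <- function(optimal, deltas) {
    tb <- genetic_code_table()
    tb <- tb[tb$aa != "*", ]
    d <- data.frame(
      codon = tb$codon, aa = tb$aa, delta = 0,
      optimal = tb$codon %in% optimal, stringsAsFactors = FALSE
    )
    d$delta[match(names(deltas), d$codon)] <- unlist(deltas)
    class(d) <- c("delta_rscu_table", "data.frame")
    d
  }
  t1 <- mk("GAC", c(GAC = 0.5))
  expect_equal(consensus_optimal(list(a = t1))$consensus, "GAC")

  # Ala: GCC (mean 0.3) beats GCG (0.2) in all genotypes
  tabs <- lapply(1:3, function(i) {
    mk(c("GCC", "GCG"), c(GCC = 0.3, GCG = 0.2))
  })
  names(tabs) <- paste0("g", 1:3)
  expect_equal(consensus_optimal(tabs)$consensus, "GCC")

  # optimal in 3 of 4 genotypes -> excluded
  tabs4 <- c(tabs, list(g4 = mk("GCG", c(GCG = 0.4))))
  res <- consensus_optimal(tabs4)
  expect_equal(res$consensus, "GCG")
  expect_false("GCC" %in% res$consensus)
  expect_warning(
    consensus_optimal(list(a = mk("GAC", c(GAC = 1)), b = mk("AAG", c(AAG = 1)))),
    "empty"
  )
})

test_that("delta-RSCU+ is the mean of positive values only", {
  tb <- genetic_code_table()
  tb <- tb[tb$aa != "*", ]
  d <- data.frame(
    codon = tb$codon, aa = tb$aa, delta = NA_real_, stringsAsFactors = FALSE
  )
  d$delta[1:2] <- c(0.2, 0.4)
  d$delta[3] <- -0.5
  class(d) <- c("delta_rscu_table", "data.frame")
  dp <- delta_rscu_plus(d)
  expect_equal(dp$mean, 0.3)
  expect_length(dp$values, 2)
  expect_equal(unname(dp$log_values), log(c(0.2, 0.4)))
  d$delta[1:2] <- NA
  expect_true(is.na(delta_rscu_plus(d)$mean))
})
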