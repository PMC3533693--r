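# Orchestration: run the full analysis over a dataset (simulated in memory
# or loaded from disk) and emit the table/figure analogues plus a
# machine-readable stats bundle.

#' Analysis run configuration
#'
#' @param outgroup,ingroup genotype ids; defaults match the simulator.
#' @param mating named genotype -> "selfing"/"outcrossing" map.
#' @param quantile expression quantile defining high/low classes (default
#'   0.1, i.e. deciles).
#' @param alpha significance level for optimal-codon calls and tests.
#' @param p_adjust multiple-testing adjustment for optimal-codon calls
#'   ("BH" default; "none" for unadjusted calls).
#' @param exclude_het drop heterozygous (polymorphic) changes from branch
#'   counts.
#' @param watterson_n haplotype count for Watterson's theta (default 2 per
#'   ingroup genotype).
#' @param min_homologs,min_identity homolog-alignment quality filters for
#'   the deleterious-change analysis.
#' @param tau,sigma_floor constraint-classifier knobs (see
#'   [build_profile()]).
#' @param optimal optional preferred-codon set overriding the inferred
#'   consensus (e.g. the simulator's planted truth).
#' @return list of class `run_config`.
#' @export
run_config <- function(outgroup = "paradoxa",
                       ingroup = c("brazil", "jamaica", "nicaragua"),
                       mating = c(
                         brazil = "outcrossing", jamaica = "selfing",
                         nicaragua = "selfing", paradoxa = "selfing"
                       ),
                       quantile = 0.1, alpha = 0.05, p_adjust = "BH",
                       exclude_het = FALSE, watterson_n = NULL,
                       min_homologs = 5L, min_identity = 0.6,
                       tau = NULL, sigma_floor = NULL, optimal = NULL) {
  structure(list(
    outgroup = outgroup, ingroup = ingroup, mating = mating,
    quantile = quantile, alpha = alpha, p_adjust = p_adjust,
    exclude_het = exclude_het, watterson_n = watterson_n,
    min_homologs = min_homologs, min_identity = min_identity,
    tau = tau, sigma_floor = sigma_floor, optimal = optimal
  ), class = "run_config")
}

#' Load a dataset directory
#'
#' Expects the layout written by [write_sim_dataset()]: `loci/*.fasta`,
#' `expression.tsv` and optionally `homologs/*.fasta`.
#'
#' @param dir dataset directory.
#' @param outgroup outgroup genotype id.
#' @return list with alignments, expression, homologs, excluded.
#' @export
load_dataset <- function(dir, outgroup) {
  loci_dir <- if (dir.exists(file.path(dir, "loci"))) file.path(dir, "loci") else dir
  rd <- read_codon_alignments(loci_dir, outgroup)
  expr_path <- file.path(dir, "expression.tsv")
  expression <- if (file.exists(expr_path)) read_expression_table(expr_path) else NULL
  hdir <- file.path(dir, "homologs")
  homologs <- NULL
  if (dir.exists(hdir)) {
    files <- list.files(hdir, pattern = "\\.(fa|fasta)$", full.names = TRUE)
    homologs <- lapply(files, function(f) as.character(Biostrings::readBStringSet(f)))
    names(homologs) <- tools::file_path_sans_ext(basename(files))
  }
  list(
    alignments = rd$alignments, expression = expression,
    homologs = homologs, excluded = rd$excluded
  )
}

# translate a genotype's plain codons to protein (X at het/excluded codons)
translate_genotype <- function(aln, genotype) {
  tb <- genetic_code_tables()
  g <- match(genotype, aln$genotypes)
  aa <- rep("X", aln$n_codons)
  ok <- aln$flags[g, ] == FLAG_PLAIN
  aa[ok] <- tb$aa[aln$codon[g, ok]]
  paste0(aa, collapse = "")
}

#' Run the full selection-efficacy analysis
#'
#' Stages: `diversity` (site-class summaries, Watterson's theta, pairwise
#' differences, observed heterozygosity), `codon_usage` (per-genotype
#' delta-RSCU tables, consensus optimal codons, delta-RSCU+), `changes`
#' (outgroup-polarized branch counts incl. U2P/P2U), `deleterious`
#' (constraint-classifier analyses, polarized and polymorphism modes) and
#' `models` (chi-square homogeneity tests, delta-RSCU+ ANOVAs, the Fop
#' covariate models).
#'
#' @param data a `selcub_sim`, a dataset directory path, or a list with
#'   elements alignments / expression / homologs.
#' @param config a [run_config()].
#' @param stages character subset of stages to run (later stages may need
#'   earlier ones; `codon_usage` is always run when `changes` is requested
#'   unless `config$optimal` is supplied).
#' @param out_dir optional directory for the TSV/JSON report bundle.
#' @return list of class `selcub_run` with one element per stage plus
#'   `manifest`.
#' @export
run_pipeline <- function(data, config = run_config(),
                         stages = c(
                           "diversity", "codon_usage", "changes",
                           "deleterious", "models"
                         ),
                         out_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (inherits(data, "selcub_sim")) {
    data <- list(
      alignments = data$alignments, expression = data$expression,
      homologs = data$homologs, excluded = NULL
    )
  } else if (is.character(data)) {
    data <- load_dataset(data, config$outgroup)
  }
  alignments <- data$alignments
  if (!length(alignments)) stop("input stage: no alignments")
  res <- list(config = config)

  if ("diversity" %in% stages) {
    res$diversity <- diversity_summary(alignments, config$watterson_n)
  }

  need_usage <- "codon_usage" %in% stages ||
    (("changes" %in% stages || "models" %in% stages) && is.null(config$optimal))
  if (need_usage) {
    if (is.null(data$expression)) {
      stop("codon_usage stage: expression table missing")
    }
    parts <- partition_by_expression(
      data$expression, names(alignments), config$quantile
    )
    genotypes <- alignments[[1L]]$genotypes
    cms <- lapply(genotypes, function(g) codon_counts_matrix(alignments, g))
    names(cms) <- genotypes
    tables <- lapply(genotypes, function(g) {
      delta_rscu(cms[[g]], parts$high, parts$low, g,
        alpha = config$alpha, p_adjust = config$p_adjust
      )
    })
    names(tables) <- genotypes
    opt <- consensus_optimal(tables)
    dplus <- lapply(tables, delta_rscu_plus)
    res$codon_usage <- list(
      parts = parts, counts = cms, delta_tables = tables,
      optimal = opt, delta_plus = dplus
    )
  }

  optimal_set <- if (!is.null(config$optimal)) {
    config$optimal
  } else if (!is.null(res$codon_usage)) {
    res$codon_usage$optimal$consensus
  } else {
    NULL
  }

  if ("changes" %in% stages || "deleterious" %in% stages) {
    changes <- polarize(alignments)
    steps <- classify_changes(changes, optimal_set)
    counts <- branch_counts(steps, exclude_het = config$exclude_het)
    res$changes <- list(
      steps = steps, counts = counts,
      n_skipped_columns = attr(changes, "skipped"),
      n_excluded_changes = attr(steps, "n_excluded")
    )
  }

  if ("deleterious" %in% stages && !is.null(data$homologs)) {
    filt <- vapply(names(alignments), function(id) {
      h <- data$homologs[[id]]
      if (is.null(h)) return(FALSE)
      focal <- translate_genotype(alignments[[id]], config$outgroup)
      apply_filters(
        length(h), alignment_identity(focal, h),
        config$min_homologs, config$min_identity
      )
    }, logical(1))
    kept <- names(alignments)[filt]
    sub_steps <- res$changes$steps[res$changes$steps$locus %in% kept, , drop = FALSE]
    lab <- label_deleterious(
      sub_steps, data$homologs[kept],
      sigma_floor = config$sigma_floor, tau = config$tau
    )
    polym <- polymorphic_deleterious(
      alignments[kept], data$homologs[kept],
      sigma_floor = config$sigma_floor, tau = config$tau
    )
    res$deleterious <- list(
      kept_loci = kept, polarized = lab$counts, polymorphic = polym,
      n_unclassified = lab$n_unclassified
    )
  }

  if ("models" %in% stages) {
    res$models <- list()
    cts <- res$changes$counts
    term <- cts[cts$branch %in% config$ingroup, , drop = FALSE]
    if (nrow(term) >= 2L && all(term$n_syn > 0)) {
      res$models$pn_ps_chi2 <- chi2_homogeneity(rbind(
        nonsyn = term$n_nonsyn, syn = term$n_syn
      ))
    }
    anc <- cts[cts$branch == "ancestral", , drop = FALSE]
    if (nrow(anc) == 1L) {
      res$models$u2p_p2u_vs_ancestral <- lapply(
        stats::setNames(config$ingroup, config$ingroup),
        function(g) {
          row <- cts[cts$branch == g, ]
          tab <- rbind(
            c(row$n_u2p, row$n_p2u),
            c(anc$n_u2p, anc$n_p2u)
          )
          if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NULL)
          suppressMessages(chi2_homogeneity(tab))
        }
      )
    }
    if (!is.null(res$deleterious)) {
      pm <- res$deleterious$polymorphic
      if (all(pm$n_total > 0) && sum(pm$n_deleterious) > 0) {
        res$models$deleterious_chi2 <- suppressMessages(chi2_homogeneity(rbind(
          deleterious = pm$n_deleterious,
          other = pm$n_total - pm$n_deleterious
        )))
      }
    }
    if (!is.null(res$codon_usage)) {
      vals <- lapply(res$codon_usage$delta_plus, function(d) d$values)
      if (all(lengths(vals) >= 2L)) {
        res$models$delta_plus_tests <- delta_rscu_plus_tests(
          vals, config$mating, config$alpha
        )
      }
      usage <- gene_usage_summary(
        alignments, data$expression, optimal_set,
        parts = res$codon_usage$parts
      )
      usage$mating_system <- unname(config$mating[usage$genotype])
      res$usage <- usage
      res$models$fop_model_genotype <- tryCatch(
        fop_model(usage, "genotype", include_gc3s = TRUE, alpha = config$alpha),
        error = function(e) e
      )
      res$models$fop_model_mating <- tryCatch(
        fop_model(usage, "mating_system", include_gc3s = TRUE, alpha = config$alpha),
        error = function(e) e
      )
      res$models$fop_model_mating_no_gc3s <- tryCatch(
        fop_model(usage, "mating_system", include_gc3s = FALSE, alpha = config$alpha),
        error = function(e) e
      )
    }
  }

  res$manifest <- list(
    n_loci = length(alignments),
    n_excluded_loci = if (is.null(data$excluded)) 0L else nrow(data$excluded),
    excluded = data$excluded,
    stages = stages,
    config = unclass(config)
  )
  class(res) <- "selcub_run"
  if (!is.null(out_dir)) write_run_bundle(res, out_dir)
  res
}

#' @export
print.selcub_run <- function(x, ...) {
  cat(sprintf(
    "<selcub_run> %d loci; stages: %s\n",
    x$manifest$n_loci, paste(x$manifest$stages, collapse = ", ")
  ))
  if (!is.null(x$changes)) {
    print(x$changes$counts[, c("branch", "n_syn", "n_nonsyn", "pn_ps", "u2p_p2u")])
  }
  invisible(x)
}

tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write the report bundle of a pipeline run
#'
#' Emits table1_site_class.tsv, table1_pairwise.tsv, table2.tsv,
#' delta_rscu.tsv, optimal_codons.tsv, fig1_counts.tsv, fig4_counts.tsv,
#' stats.json and manifest.json (stage availability permitting).
#'
#' @param res a `selcub_run`.
#' @param dir output directory.
#' @export
write_run_bundle <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(res$diversity)) {
    tsv(res$diversity$by_class, file.path(dir, "table1_site_class.tsv"))
    pw <- as.data.frame(res$diversity$pairwise)
    pw <- cbind(genotype = rownames(pw), pw)
    tsv(pw, file.path(dir, "table1_pairwise.tsv"))
    tsv(
      data.frame(
        genotype = names(res$diversity$h_obs),
        h_obs = as.numeric(res$diversity$h_obs)
      ),
      file.path(dir, "h_obs.tsv")
    )
  }
  if (!is.null(res$usage)) {
    agg <- stats::aggregate(
      res$usage[, c("expression", "length_bp", "fop", "gc3s")],
      by = list(
        expr_class = res$usage$expr_class, genotype = res$usage$genotype
      ), FUN = mean, na.rm = TRUE
    )
    tsv(agg, file.path(dir, "table2.tsv"))
  }
  if (!is.null(res$codon_usage)) {
    dt <- do.call(rbind, lapply(names(res$codon_usage$delta_tables), function(g) {
      t <- res$codon_usage$delta_tables[[g]]
      cbind(genotype = g, as.data.frame(t))
    }))
    tsv(dt, file.path(dir, "delta_rscu.tsv"))
    tsv(res$codon_usage$optimal$table, file.path(dir, "optimal_codons.tsv"))
  }
  if (!is.null(res$deleterious)) {
    tsv(
      as.data.frame(res$deleterious$polarized),
      file.path(dir, "fig1_counts.tsv")
    )
    tsv(res$deleterious$polymorphic, file.path(dir, "fig1_polymorphic.tsv"))
  }
  if (!is.null(res$changes)) {
    tsv(as.data.frame(res$changes$counts), file.path(dir, "fig4_counts.tsv"))
  }
  if (!is.null(res$models)) {
    strip <- function(x) {
      if (inherits(x, "fop_model")) {
        return(x[c("retained", "eliminated", "anova", "r_squared")])
      }
      if (inherits(x, "condition")) return(list(error = conditionMessage(x)))
      if (is.list(x)) return(lapply(x, strip))
      x
    }
    jsonlite::write_json(
      strip(res$models), file.path(dir, "stats.json"),
      auto_unbox = TRUE, digits = NA, null = "null", force = TRUE
    )
  }
  jsonlite::write_json(
    c(res$manifest[c("n_loci", "n_excluded_loci", "stages", "config")],
      list(generated_at = format(Sys.time(), tz = "UTC"))),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE
  )
  invisible(dir)
}
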