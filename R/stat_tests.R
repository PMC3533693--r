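# Inferential layer: chi-square homogeneity tests (plain Pearson, no
# continuity correction), one-way ANOVA, Tukey-Kramer HSD, the Fop covariate
# model with backward elimination, and the delta-RSCU+ contrasts.

#' Pearson chi-square homogeneity test
#'
#' Plain Pearson statistic without continuity correction. Fractional counts
#' (arising from heterozygote averaging) are accepted with a logged caveat.
#'
#' @param table r x c matrix of non-negative counts.
#' @return list of class `contingency_result`: observed, expected, statistic,
#'   df, p.value.
#' @export
chi2_homogeneity <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("chi-square homogeneity test undefined: zero margin")
  }
  if (any(table != round(table))) {
    message("chi2_homogeneity: fractional counts used as-is (heterozygote averaging)")
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  structure(list(
    observed = table, expected = ht$expected,
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p.value = unname(ht$p.value)
  ), class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf(
    "Pearson chi-square homogeneity: X2 = %.4g, df = %d, p = %.4g\n",
    x$statistic, x$df, x$p.value
  ))
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical equal-variance F test across labelled groups; for two groups
#' this equals the squared pooled-variance two-sample t statistic.
#'
#' @param groups named list of numeric vectors (>= 2 groups, every group
#'   non-empty, >= 2 total residual df unless separation is degenerate).
#' @return list: statistic (F), df (numerator, denominator), p.value,
#'   degenerate (TRUE when within-group variance is 0 but groups differ;
#'   statistic is then Inf and p 0).
#' @export
anova_one_way <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(!lengths(groups))) stop("every group needs at least one value")
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), lengths(groups)))
  within <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  means <- vapply(groups, mean, numeric(1))
  df1 <- length(groups) - 1L
  df2 <- length(value) - length(groups)
  if (within == 0 && stats::var(means) > 0) {
    return(list(
      statistic = Inf, df = c(df1, df2), p.value = 0, degenerate = TRUE
    ))
  }
  if (df2 < 1L) stop("not enough residual degrees of freedom")
  ht <- stats::oneway.test(value ~ grp, var.equal = TRUE)
  list(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter), p.value = unname(ht$p.value),
    degenerate = FALSE
  )
}

#' Tukey-Kramer HSD pairwise comparisons
#'
#' Studentized-range pairwise contrasts with the Tukey-Kramer unequal-n
#' correction (via [stats::TukeyHSD()]).
#'
#' @param groups named list of numeric vectors.
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame: pair, diff, lwr, upr, p_adj, significant.
#' @export
tukey_kramer <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) < 2L)) stop("every group needs at least two values")
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), lengths(groups)))
  fit <- stats::aov(value ~ grp)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$grp
  data.frame(
    pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
    upr = tk[, "upr"], p_adj = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Fop covariate model with backward elimination
#'
#' Least-squares model of per-gene Fop on GC3s, gene length, expression and
#' either genotype or mating system (the two cannot enter one model when
#' only one genotype is outcrossing), with all two-way interactions.
#' Terms are removed by backward elimination at level `alpha` when they are
#' not significant and not contained in a significant higher-order term
#' (elimination order: largest p first, ties by term name).
#'
#' @param data data.frame with columns fop, gc3s, length_bp, expression and
#'   the grouping column.
#' @param group "genotype" or "mating_system".
#' @param include_gc3s set FALSE for the GC3s-excluded variant (GC3s is not
#'   independent of Fop when all optimal codons are G/C-ending).
#' @param alpha elimination level (default 0.05).
#' @return list of class `fop_model`: formula, fit (lm), anova (per-term df,
#'   sum_sq, F, p, var_explained), retained, eliminated, r_squared.
#' @export
fop_model <- function(data, group = c("genotype", "mating_system"),
                      include_gc3s = TRUE, alpha = 0.05) {
  group <- match.arg(group)
  stopifnot(all(c("fop", "length_bp", "expression", group) %in% names(data)))
  data <- data[stats::complete.cases(
    data[, c("fop", "length_bp", "expression", group,
             if (include_gc3s) "gc3s")]
  ), ]
  data[[group]] <- factor(data[[group]])
  covars <- c(if (include_gc3s) "gc3s", "length_bp", "expression", group)
  form <- stats::as.formula(paste(
    "fop ~ (", paste(covars, collapse = " + "), ")^2"
  ))
  fit <- stats::lm(form, data = data)
  al <- stats::alias(fit)$Complete
  if (!is.null(al) && nrow(al)) {
    stop("rank-deficient model; collinear terms: ",
         paste(rownames(al), collapse = ", "))
  }
  eliminated <- character(0)
  repeat {
    dr <- stats::drop1(fit, test = "F")
    dr <- dr[rownames(dr) != "<none>", , drop = FALSE]
    cand <- rownames(dr)[!is.na(dr$`Pr(>F)`) & dr$`Pr(>F)` > alpha]
    if (!length(cand)) break
    ps <- dr[cand, "Pr(>F)"]
    drop_term <- cand[order(-ps, cand)][1L]
    eliminated <- c(eliminated, drop_term)
    fit <- stats::update(fit, stats::as.formula(paste(". ~ . -", drop_term)))
  }
  an <- stats::anova(fit)
  ss_tot <- sum(an$`Sum Sq`)
  terms_tab <- data.frame(
    term = rownames(an), df = an$Df, sum_sq = an$`Sum Sq`,
    statistic = an$`F value`, p = an$`Pr(>F)`,
    var_explained = an$`Sum Sq` / ss_tot,
    stringsAsFactors = FALSE
  )
  structure(list(
    formula = stats::formula(fit), fit = fit,
    anova = terms_tab,
    retained = setdiff(terms_tab$term, "Residuals"),
    eliminated = eliminated,
    r_squared = summary(fit)$r.squared
  ), class = "fop_model")
}

#' @export
print.fop_model <- function(x, ...) {
  cat("Fop covariate model:", deparse(x$formula), "\n")
  cat(sprintf(
    "retained: %s | R^2 = %.4f\n",
    if (length(x$retained)) paste(x$retained, collapse = ", ") else "(none)",
    x$r_squared
  ))
  invisible(x)
}

#' ANOVA and Tukey-Kramer contrasts of log delta-RSCU+
#'
#' Runs the two separate one-way ANOVAs of log-transformed per-codon positive
#' delta-RSCU values — among genotypes and between mating systems — plus the
#' Tukey-Kramer pairwise table over genotypes and the pooled-variance t
#' contrast of the selfing genotypes combined against the outcrosser.
#'
#' @param values named list (genotype -> positive delta-RSCU values, from
#'   [delta_rscu_plus()]).
#' @param mating named character vector genotype -> "selfing"/"outcrossing".
#' @param alpha significance level (default 0.05).
#' @return list: genotype_anova, mating_anova, tukey (data.frame),
#'   selfer_contrast (t statistic, df, p.value, means), means (per genotype,
#'   log scale).
#' @export
delta_rscu_plus_tests <- function(values, mating, alpha = 0.05) {
  if (any(unlist(values) <= 0)) stop("delta-RSCU+ values must be positive")
  lv <- lapply(values, log)
  mt <- mating[names(lv)]
  if (anyNA(mt)) stop("mating system missing for some genotype")
  by_mating <- split(
    unlist(lv, use.names = FALSE),
    rep(unname(mt), lengths(lv))
  )
  sel <- by_mating[["selfing"]]
  out <- by_mating[["outcrossing"]]
  tt <- stats::t.test(out, sel, var.equal = TRUE)
  list(
    genotype_anova = anova_one_way(lv),
    mating_anova = anova_one_way(by_mating),
    tukey = tukey_kramer(lv, alpha),
    selfer_contrast = list(
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p.value = unname(tt$p.value),
      mean_outcrosser = mean(out), mean_selfer = mean(sel)
    ),
    means = vapply(lv, mean, numeric(1))
  )
}
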