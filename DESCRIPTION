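Package: selcub
Title: Selection Efficacy and Codon Usage Bias in Selfing Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether evolutionary transitions from outcrossing to
    self-fertilization reduce the efficacy of natural selection, using
    codon-aligned orthologous coding sequences from one outgroup and several
    ingroup genotypes. Implements outgroup-parsimony polarization of derived
    mutations with unphased-heterozygote averaging, synonymous/non-synonymous
    change counting with Nei-Gojobori potential-site denominators, Watterson
    theta and pairwise-difference diversity summaries, relative synonymous
    codon usage (RSCU) statistics including expression-decile delta-RSCU,
    optimal-codon inference, Fop and delta-RSCU+, preferred/unpreferred
    (U2P/P2U) substitution counting, a simplified physicochemical-constraint
    classifier for deleterious amino-acid changes, the associated chi-square,
    ANOVA and Tukey-Kramer inferential layer, and a truth-known
    mutation-selection-drift simulator of coding-sequence evolution for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
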