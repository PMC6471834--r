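Package: parcon
Title: Parallel and Convergent Amino Acid Replacements in Protein Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies parallel and convergent amino acid replacements across
    independent branch pairs of a rooted phylogeny from ancestral-sequence
    records, computes expected counts under an empirical substitution model
    (by continuous-time Markov simulation along the tree or by an analytic
    calculation conditioning on inferred ancestral states), and tests observed
    against expected counts with a Poisson tail rule. Reads protein alignments
    in FASTA, trees in Newick, substitution models in PAML 'dat' format, and a
    tab-delimited ancestral-sequence record format; includes a synthetic
    fixture generator so the whole pipeline runs offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
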