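Package: famclade
Title: Evolutionary Classification of Plant Gene Families into Groups and
    Supergroups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying transporter-like plant gene families by
    their evolutionary history. From homolog hit tables and protein
    alignments, the package filters sequences and alignment columns, builds
    neighbor-joining trees from JTT or Poisson-corrected protein distances,
    maps bootstrap bipartition support, tests monophyly via clans on
    unrooted trees, roots trees on an outgroup, and reconciles rooted gene
    trees against the fixed land-plant rank ladder (green algae, bryophyte,
    lycophyte, monocot, eudicot) to emit named supergroups (letters) and
    groups (Roman numerals) with eudicot/monocot halves. A birth-death
    simulator of gene duplication and loss along the ranked species tree,
    with protein sequence evolution, provides ground-truth labels for
    end-to-end validation, and reporting helpers reproduce family
    member-count tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    phangorn,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
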