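Package: IMflow
Title: Multilocus Divergence and Introgression Analysis Under the
    Isolation-with-Migration Model
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for multilocus analyses of divergence and gene flow
    between closely related populations or sibling species from per-locus
    nuclear sequence alignments. Provides per-locus polymorphism and
    neutrality statistics (nucleotide diversity, Watterson's theta,
    Tajima's D, Fu's Fs, Ramos-Onsins and Rozas' R2) with coalescent null
    distributions, Hudson's FST with permutation significance,
    shared/fixed/exclusive polymorphism classification, Dxy, the
    multilocus HKA neutrality test, four-gamete non-recombining block
    extraction, neighbor-joining trees on mean-FST distances with locus
    bootstrap, sympatric-versus-allopatric differential-introgression
    statistics, a two-population isolation-with-migration coalescent
    simulator under the infinite-sites model, rejection-ABC demographic
    parameter estimation, and conversion of scaled parameters to
    demographic units. A synthetic-study generator produces complete
    four-population multilocus datasets with known ground truth. Ships a
    reference panel of published summary values for 21 nuclear loci in
    four Brazilian populations of the Lutzomyia longipalpis species
    complex.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: PopulationGenetics, Coalescent, Genetics, SNP, Software
RoxygenNote: 7.3.3
LinkingTo: Rcpp
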