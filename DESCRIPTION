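Package: SIPshift
Title: Detection of Isotope-Labelled Taxa from DNA-SIP Density Gradient Fractions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for DNA stable-isotope-probing (DNA-SIP) experiments in
    which CsCl density gradients are fractionated and each fraction is
    profiled by amplicon sequencing, TRFLP fingerprinting and 16S rRNA gene
    qPCR. Provides fraction-level normalization, TRF filtering and
    rarefaction; reconstruction of the unfractionated community from its
    fractions; labelled-versus-unlabelled difference profiles and
    buoyant-density centre-of-mass shift scores that classify taxa as having
    assimilated a 13C-labelled substrate; whole-community qPCR shift checks;
    stable-isotope arithmetic for chloroform-fumigation biomass delta-13C and
    qPCR standard-curve efficiency; and a seeded forward simulator of
    isopycnic gradients (GC- and 13C-dependent banding, Dirichlet-multinomial
    sequencing noise, lognormal qPCR noise) so that every inference step can
    be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Microbiome, Metagenomics, Sequencing, Software
RoxygenNote: 7.3.3
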