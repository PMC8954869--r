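Package: fregion
Title: Functional Linear Model Association Tests for Multi-Gene Regions
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Region-based association tests for quantitative traits that treat
    each gene region's genotype profile as a smooth function. Genotype rows are
    expanded on an orthonormal Fourier basis with a roughness penalty; regions
    are then tested jointly either by backward-stepwise AIC selection on the
    per-region coefficient blocks followed by block partial F tests (the Step
    and LW-Step methods), or by locally sparse functional regression with an
    fSCAD penalty that compresses effect functions of unassociated regions
    exactly to zero, followed by a degrees-of-freedom-adjusted partial F test
    (Multi-SLoS, W-SLoS and LW-SLoS). Includes per-locus Beta-density minor
    allele frequency weighting, readers for VCF/TSV inputs, a synthetic-data
    engine emulating haplotype-pool simulation designs (rare, common, hybrid
    and mixed layouts), and a replicate harness that estimates power and false
    positive rates across significance grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    splines,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
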