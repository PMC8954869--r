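# Shared fixtures: small simulated studies and quadrature oracles.

# Small multi-region study for fast unit tests.
toyStudy <- function(seed = 1, n = 200, M = 12, P = 25, layout = "common25",
                     assoc = NULL, scenario = "I") {
  des <- simulationDesign(layout, n = n, snpsPerRegion = M,
                          assocRegions = assoc, scenario = scenario)
  simulateStudy(des, seed = seed)
}

# Trapezoid-rule inner products of basis columns -- the quadrature oracle
# used to check exact orthonormality and roughness matrices.
trapezoidGram <- function(F1, F2, pts) {
  w <- c(diff(pts) / 2, 0) + c(0, diff(pts) / 2)
  crossprod(F1 * w, F2)
}

# Independent penalized-smoothing oracle: minimizes the penalized sum of
# squares by QR on the augmented system [Phi; sqrt(lambda) S], S'S = R2.
pensseOracle <- function(X, basis, lambda_x) {
  Phi <- basisMatrix(basis)
  R2 <- roughnessMatrix(basis, 2L)$R2
  S <- diag(sqrt(diag(R2)), nrow = ncol(Phi))   # R2 is diagonal for Fourier
  aug <- rbind(Phi, sqrt(lambda_x) * S)
  t(apply(X, 1L, function(xi) qr.solve(aug, c(xi, numeric(ncol(Phi))))))
}

# Hand-written VCF fixture: 3 samples x 4 biallelic sites in one region.
writeToyVCF <- function(dir) {
  vcf <- file.path(dir, "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "A", "B", "C", sep = "\t"),
    paste("1", "101", "s1", "A", "T", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "102", "s2", "G", "C", ".", "PASS", ".", "GT",
          "0/1", "0/1", "0/0", sep = "\t"),
    paste("1", "103", "s3", "T", "A", ".", "PASS", ".", "GT",
          "1/1", "0/0", "0/1", sep = "\t"),
    paste("1", "104", "s4", "C", "G", ".", "PASS", ".", "GT",
          "0/0", "0/0", "0/1", sep = "\t")), vcf)
  rmap <- file.path(dir, "toy.regions.tsv")
  writeLines(c("region_id\tchrom\tstart\tend", "g1\t1\t101\t105"), rmap)
  tr <- file.path(dir, "toy.traits.tsv")
  writeLines(c("sample_id\tvalue", "A\t0.5", "B\t-0.2", "C\t1.1"), tr)
  c(vcf = vcf, regions = rmap, traits = tr)
}
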