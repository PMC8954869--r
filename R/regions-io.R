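# Dataset plumbing: MAF computation, Beta-density locus weights, VCF/TSV
# readers and writers.

#' Folded minor allele frequency of each genotype column
#'
#' @param X `n x M` additive genotype matrix with entries in {0, 1, 2}.
#' @return numeric vector of M folded frequencies `min(p, 1 - p)` with
#'   `p = mean(column)/2`.
#' @examples
#' computeMAF(cbind(c(0, 1, 1, 2), c(2, 2, 2, 0)))
#' @export
computeMAF <- function(X) {
  X <- as.matrix(X)
  if (!length(X)) stop("empty genotype matrix")
  if (!all(X %in% c(0, 1, 2))) stop("genotypes must be coded 0/1/2")
  p <- colMeans(X) / 2
  pmin(p, 1 - p)
}

#' @rdname betaLocusWeights
#' @param a1,a2 Beta shape parameters.
#' @export
locusWeightScheme <- function(a1 = 1, a2 = 10)
  new("LocusWeightScheme", a1 = as.numeric(a1), a2 = as.numeric(a2))

#' Beta-density locus weights
#'
#' Diagonal `M x M` weight matrix Theta whose j-th diagonal entry is the
#' Beta(a1, a2) density evaluated at the j-th locus' folded minor allele
#' frequency. The default Beta(1, 10) strongly upweights rare loci;
#' Beta(1, 1) gives the identity (no weighting).
#'
#' @param maf numeric frequencies in [0, 0.5].
#' @param scheme a [LocusWeightScheme].
#' @return diagonal numeric matrix `M x M`.
#' @examples
#' diag(betaLocusWeights(c(0, 0.5), locusWeightScheme(1, 10)))
#' @export
betaLocusWeights <- function(maf, scheme = locusWeightScheme()) {
  if (any(maf < 0) || any(maf > 0.5)) stop("maf must lie in [0, 0.5]")
  if (scheme@a1 < 1 && any(maf == 0))
    stop("Beta density is infinite at 0 when a1 < 1")
  w <- dbeta(maf, scheme@a1, scheme@a2)
  diag(w, nrow = length(w))
}

#' Apply locus weights to a region's genotypes
#'
#' Scales genotype column j by the j-th diagonal weight: `X* = X Theta`.
#' Smoothing `X*` with the same basis and penalty yields the loci-weighted
#' functional representation used by the LW-Step and LW-SLoS tests.
#'
#' @param region a [MarkerRegion].
#' @param Theta diagonal nonnegative `M x M` weight matrix.
#' @return numeric matrix of weighted genotypes (no longer 0/1/2 coded).
#' @export
applyLocusWeights <- function(region, Theta) {
  X <- region@X
  if (!is.matrix(Theta) || nrow(Theta) != ncol(X) || ncol(Theta) != ncol(X))
    stop("Theta must be an M x M matrix matching the region")
  if (any(Theta[row(Theta) != col(Theta)] != 0))
    stop("Theta must be diagonal")
  if (any(diag(Theta) < 0)) stop("Theta must be nonnegative")
  X %*% Theta
}

#' Read a multi-region dataset from VCF + region map + trait files
#'
#' Assembles a [MultiRegionDataset] from a VCF of biallelic SNPs (additive
#' coding from the GT field), a tab-separated region map with columns
#' `region_id`, `chrom`, `start`, `end` (half-open `[start, end)` intervals,
#' 1-based positions as printed in the VCF), and a tab-separated trait file
#' with columns `sample_id`, `value`. Sample sets must agree exactly;
#' missing genotypes and empty regions are errors.
#'
#' @param vcfFile path to a VCF (plain text or bgzipped).
#' @param regionFile path to the region map TSV.
#' @param traitFile path to the trait TSV (optional).
#' @return a [MultiRegionDataset].
#' @export
readDataset <- function(vcfFile, regionFile, traitFile = NULL) {
  vcf <- vcfR::read.vcfR(vcfFile, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  fix <- vcfR::getFIX(vcf)
  chrom <- fix[, "CHROM"]
  pos <- as.numeric(fix[, "POS"])
  if (any(is.na(gt))) stop("missing genotypes are not supported")
  dose <- matrix(0, nrow = ncol(gt), ncol = nrow(gt),
                 dimnames = list(colnames(gt), NULL))
  for (j in seq_len(nrow(gt))) {
    alleles <- strsplit(gt[j, ], "[/|]")
    cnt <- vapply(alleles, function(a) sum(a == "1"), numeric(1))
    if (any(vapply(alleles, function(a) any(!a %in% c("0", "1")), logical(1))))
      stop("only biallelic GT fields coded 0/1 are supported")
    dose[, j] <- cnt
  }
  rmap <- utils::read.delim(regionFile, stringsAsFactors = FALSE)
  need <- c("region_id", "chrom", "start", "end")
  if (!all(need %in% names(rmap)))
    stop("region map must have columns region_id, chrom, start, end")
  regions <- lapply(seq_len(nrow(rmap)), function(i) {
    sel <- which(chrom == rmap$chrom[i] & pos >= rmap$start[i] &
                 pos < rmap$end[i])
    if (!length(sel))
      stop("region '", rmap$region_id[i], "' overlaps no variants")
    markerRegion(rmap$region_id[i], dose[, sel, drop = FALSE],
                 positions = pos[sel])
  })
  y <- numeric(0)
  if (!is.null(traitFile)) {
    tr <- utils::read.delim(traitFile, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "value") %in% names(tr)))
      stop("trait file must have columns sample_id, value")
    if (!setequal(tr$sample_id, rownames(dose)))
      stop("trait samples do not match VCF samples")
    y <- tr$value[match(rownames(dose), tr$sample_id)]
  }
  multiRegionDataset(regions, y)
}

#' Write a simulated dataset as VCF + region map + trait TSV
#'
#' Emits a minimal plain-text VCF v4.2 (one pseudo-chromosome, biallelic
#' sites, GT-only), a region-map TSV and a trait TSV so that simulated data
#' can be fed back through [readDataset] or the command-line interface
#' exactly like real data.
#'
#' @param dataset a [MultiRegionDataset].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the three file paths.
#' @export
writeDataset <- function(dataset, dir, prefix = "simulated") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nIndividuals(dataset)
  samples <- sprintf("S%04d", seq_len(n))
  vcf <- file.path(dir, paste0(prefix, ".vcf"))
  rmapf <- file.path(dir, paste0(prefix, ".regions.tsv"))
  trf <- file.path(dir, paste0(prefix, ".traits.tsv"))
  con <- file(vcf, "w")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=1>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  gtcode <- c("0/0", "0/1", "1/1")
  offset <- 0L
  rmap <- NULL
  for (r in dataset@regions) {
    M <- ncol(r@X)
    pos <- offset + seq_len(M)
    rmap <- rbind(rmap, data.frame(region_id = r@regionId, chrom = "1",
                                   start = pos[1L], end = pos[M] + 1L))
    for (j in seq_len(M)) {
      writeLines(paste(c("1", pos[j], paste0(r@regionId, "_", j), "A", "T",
                         ".", "PASS", ".", "GT",
                         gtcode[r@X[, j] + 1L]), collapse = "\t"), con)
    }
    offset <- offset + M
  }
  close(con)
  utils::write.table(rmap, rmapf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (length(dataset@y))
    utils::write.table(data.frame(sample_id = samples, value = dataset@y),
                       trf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(vcf = vcf, regions = rmapf, traits = trf))
}
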