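#' Linkage-disequilibrium parameter matrix for a pair of haplotypes
#'
#' For two phased haplotypes coded 0/1 over the same p loci, the
#' disequilibrium parameter between loci j and l is
#' D_jl = (h1_j - h2_j)(h1_l - h2_l) / 4,
#' i.e. 0.25 when the haplotypes differ at both loci in coupling phase,
#' -0.25 in repulsion phase, and 0 whenever they share an allele at either
#' locus. The diagonal entry D_jj is 0.25 exactly when the two haplotypes
#' differ at locus j (the cross would be heterozygous there), else 0.
#'
#' @param h1,h2 Integer/numeric vectors of 0/1 allele indicators with equal
#'   length.
#' @return A p x p symmetric matrix with entries in \{-0.25, 0, 0.25\}.
#' @export
pairwise_D <- function(h1, h2) {
  d <- haplotype_diff(h1, h2)
  tcrossprod(d) / 4
}

# validated difference vector h1 - h2; D = outer(d, d) / 4
haplotype_diff <- function(h1, h2) {
  if (length(h1) != length(h2))
    stop("haplotypes must have equal length")
  if (!all(h1 %in% c(0, 1)) || !all(h2 %in% c(0, 1)))
    stop("haplotypes must be biallelic with alleles coded 0/1")
  as.numeric(h1) - as.numeric(h2)
}
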