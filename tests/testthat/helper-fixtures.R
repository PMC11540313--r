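# Small fixture builders shared across tests.

# random map with p loci spread over n_chrom chromosomes
rand_map <- function(p, n_chrom = 1, max_len = 1) {
  chrom <- sort(rep_len(seq_len(n_chrom), p))
  pos <- unlist(lapply(split(seq_len(p), chrom), function(idx)
    sort(runif(length(idx), 0, max_len))))
  genetic_map(sprintf("L%02d", seq_len(p)), paste0("c", chrom), unname(pos))
}

# map with every locus on its own chromosome (all loci unlinked)
unlinked_map <- function(p) {
  genetic_map(sprintf("L%02d", seq_len(p)), paste0("c", seq_len(p)),
              rep(0, p))
}

rand_haplotypes <- function(p, N) {
  matrix(sample(0:1, p * N, replace = TRUE), p, N)
}

# N founders over N unlinked loci with pairwise allele sharing exactly 1/2
# (binary Sylvester-Hadamard rows): with equal effects this realises the
# infinitesimal ladder exactly.
hadamard_founders <- function(N = 16) {
  M <- matrix(1, 1, 1)
  while (ncol(M) < N) M <- rbind(cbind(M, M), cbind(M, -M))
  H <- (M + 1) / 2
  map <- unlinked_map(N)
  list(haplotypes = H, map = map,
       beta = rep(sqrt(2 / N), N))   # sigmaA2 = p * beta^2 / 2 = 1
}
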