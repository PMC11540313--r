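# Exhaustive enumeration oracle for small genomes (p <= ~5 loci).
#
# Computes the exact distribution of gametes founding the DH lines of a
# balanced bracket by brute-force probability propagation, independently of
# the Sigma-matrix algebra: gamete strand patterns are enumerated with
# their Markov transition probabilities (switch prob = adjacent-locus
# recombination fraction, fresh strand at each chromosome start), and
# group genotype distributions are propagated level by level (left gamete
# x right gamete, independent).

oracle_switch_prob <- function(map, mapping_function = haldane_c) {
  p <- nrow(map)
  new_chr <- c(TRUE, map$chrom[-1] != map$chrom[-p])
  s <- mapping_function(pmax(c(0, diff(map$pos)), 0))
  s[new_chr] <- 0.5
  s
}

# all 2^p strand patterns and their probabilities
oracle_strands <- function(sprob) {
  p <- length(sprob)
  S <- as.matrix(expand.grid(rep(list(0:1), p)))[, p:1, drop = FALSE]
  prob <- apply(S, 1, function(s) {
    pr <- 1
    prev <- 0
    for (j in seq_len(p)) {
      switch_j <- (s[j] != prev)
      pr <- pr * if (switch_j) sprob[j] else 1 - sprob[j]
      prev <- s[j]
    }
    pr
  })
  # strand at each chromosome start is symmetric: average over both initial
  # strands is already encoded by sprob[start] = 0.5
  list(S = S, prob = prob)
}

gamete_key <- function(g) paste(g, collapse = "")

# distribution of gametes from one genotype (h1, h2): named prob vector
oracle_gamete_dist <- function(h1, h2, strands) {
  out <- new.env()
  for (r in seq_len(nrow(strands$S))) {
    s <- strands$S[r, ]
    g <- ifelse(s == 0, h1, h2)
    k <- gamete_key(g)
    out[[k]] <- (if (is.null(out[[k]])) 0 else out[[k]]) + strands$prob[r]
  }
  unlist(as.list(out))
}

# genotype distribution of a group: data.frame(pat, mat keys, prob)
# gametes of a group: mixture over member genotypes
oracle_group <- function(H, slots, strands) {
  if (length(slots) == 2) {
    geno <- data.frame(pat = gamete_key(H[, slots[1]]),
                       mat = gamete_key(H[, slots[2]]), prob = 1,
                       stringsAsFactors = FALSE)
    return(geno)
  }
  half <- length(slots) / 2
  left <- oracle_group(H, slots[seq_len(half)], strands)
  right <- oracle_group(H, slots[half + seq_len(half)], strands)
  lg <- oracle_group_gametes(left, strands)
  rg <- oracle_group_gametes(right, strands)
  geno <- expand.grid(pat = names(lg), mat = names(rg),
                      stringsAsFactors = FALSE)
  geno$prob <- as.vector(outer(unname(lg), unname(rg)))
  geno
}

key_to_hap <- function(k) as.integer(strsplit(k, "")[[1]])

oracle_group_gametes <- function(geno, strands) {
  acc <- list()
  for (r in seq_len(nrow(geno))) {
    gd <- oracle_gamete_dist(key_to_hap(geno$pat[r]),
                             key_to_hap(geno$mat[r]), strands)
    for (k in names(gd)) {
      acc[[k]] <- (if (is.null(acc[[k]])) 0 else acc[[k]]) +
        geno$prob[r] * gd[[k]]
    }
  }
  unlist(acc)
}

# exact variance/covariance of BVs among DH lines of the bracket
oracle_dh_moments <- function(H, map, beta1, beta2 = beta1,
                              mapping_function = haldane_c) {
  strands <- oracle_strands(oracle_switch_prob(map, mapping_function))
  top <- oracle_group(H, seq_len(ncol(H)), strands)
  gam <- oracle_group_gametes(top, strands)
  stopifnot(abs(sum(gam) - 1) < 1e-12)
  G <- t(vapply(names(gam), key_to_hap, integer(nrow(H))))
  bv1 <- 2 * as.vector(G %*% beta1)     # DH doubles the gamete
  bv2 <- 2 * as.vector(G %*% beta2)
  w <- unname(gam)
  m1 <- sum(w * bv1); m2 <- sum(w * bv2)
  list(var1 = sum(w * (bv1 - m1)^2),
       var2 = sum(w * (bv2 - m2)^2),
       cov = sum(w * (bv1 - m1) * (bv2 - m2)))
}
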