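#' Genome presets
#'
#' Built-in genome layouts used throughout examples and validation:
#' `"corn"` has 10 chromosomes of 1.9 Morgan each with 500 loci placed
#' evenly; `"cattle"` triples the corn layout to 30 chromosomes (1500
#' loci), emulating a genome with three times as many effectively
#' independent loci.
#'
#' @param preset `"corn"` or `"cattle"`.
#' @param n_loci Total locus count (divisible by the chromosome number);
#'   default 500 for corn, 1500 for cattle.
#' @return List with `n_chromosomes`, `chromosome_length_morgan`,
#'   `n_loci`, `name`.
#' @export
genome_preset <- function(preset = c("corn", "cattle"), n_loci = NULL) {
  preset <- match.arg(preset)
  n_chr <- if (preset == "corn") 10L else 30L
  if (is.null(n_loci)) n_loci <- 50L * n_chr
  if (n_loci %% n_chr != 0)
    stop("n_loci must be divisible by the number of chromosomes")
  list(n_chromosomes = n_chr, chromosome_length_morgan = 1.9,
       n_loci = as.integer(n_loci), name = preset)
}

preset_map <- function(preset) {
  per <- preset$n_loci / preset$n_chromosomes
  genetic_map(
    locus_id = sprintf("chr%02d_l%03d", rep(seq_len(preset$n_chromosomes), each = per),
                       rep(seq_len(per), preset$n_chromosomes)),
    chrom = sprintf("chr%02d", rep(seq_len(preset$n_chromosomes), each = per)),
    pos = rep(seq(0, preset$chromosome_length_morgan, length.out = per),
              preset$n_chromosomes))
}

#' Generate synthetic fully inbred founders and their genetic map
#'
#' Draws `n_founders` fully inbred haplotypes over a preset genome: loci
#' are placed evenly along each chromosome and the frequency of the effect
#' allele at each locus is drawn uniformly from `maf_range`, then founder
#' alleles are sampled independently at that frequency. Stands in for a
#' real inbred diversity panel; reproducible from the RNG state.
#'
#' @param n_founders Number of inbred lines (>= 2).
#' @param preset A [genome_preset] or preset name.
#' @param maf_range Range of per-locus effect-allele frequencies; default
#'   `c(0.1, 0.5)`.
#' @param complementary If `TRUE` (with `n_founders = 2`), the second
#'   haplotype is the complement of the first so every locus segregates.
#' @return List with `haplotypes` (p x n 0/1 matrix) and `map`
#'   ([genetic_map]).
#' @export
generate_founders <- function(n_founders, preset = "corn",
                              maf_range = c(0.1, 0.5),
                              complementary = FALSE) {
  if (n_founders < 2) stop("need at least 2 founders")
  if (is.character(preset)) preset <- genome_preset(preset)
  map <- preset_map(preset)
  p <- nrow(map)
  q <- stats::runif(p, maf_range[1], maf_range[2])
  H <- matrix(stats::rbinom(p * n_founders, 1L, q), nrow = p,
              dimnames = list(map$locus_id, NULL))
  if (complementary) {
    if (n_founders != 2) stop("complementary founders require n_founders = 2")
    H[, 2] <- 1L - H[, 1]
  }
  list(haplotypes = H, map = map)
}

#' Generate correlated additive trait effects
#'
#' Draws allele-substitution effects for `n_traits` traits from a
#' multivariate normal with the requested pairwise correlation, then
#' rescales each trait so the realized genetic variance among the founder
#' lines (BV of each inbred line = 2 h' beta) matches `variances`. With
#' many loci the realized trait correlation tracks the target closely.
#'
#' @param founders Output of [generate_founders] (or a p x n haplotype
#'   matrix).
#' @param n_traits Number of traits (default 2).
#' @param target_correlation Common pairwise correlation of effects
#'   (|rho| <= 1; default 0.7).
#' @param variances Target genetic variances among founder lines, length
#'   `n_traits` (default `c(1, 100)` for two traits, else 1s).
#' @return p x n_traits matrix of effects with columns `trait1`, ...
#' @export
generate_effects <- function(founders, n_traits = 2,
                             target_correlation = 0.7, variances = NULL) {
  H <- if (is.list(founders)) founders$haplotypes else as.matrix(founders)
  p <- nrow(H)
  if (abs(target_correlation) > 1) stop("|target_correlation| must be <= 1")
  if (is.null(variances))
    variances <- if (n_traits == 2) c(1, 100) else rep(1, n_traits)
  if (length(variances) != n_traits)
    stop("variances must have one entry per trait")
  Z <- matrix(stats::rnorm(p * n_traits), p, n_traits)
  if (abs(target_correlation) == 1) {
    beta <- Z[, 1] %*% t(target_correlation^(seq_len(n_traits) - 1))
  } else {
    R <- matrix(target_correlation, n_traits, n_traits)
    diag(R) <- 1
    beta <- Z %*% chol(R)
  }
  bv <- 2 * crossprod(H, beta)             # founder-line BVs, n x T
  sds <- apply(bv, 2, stats::sd)
  if (any(sds == 0)) stop("degenerate founders: a trait has zero variance")
  beta <- sweep(beta, 2, sqrt(variances) / sds, "*")
  dimnames(beta) <- list(rownames(H), paste0("trait", seq_len(n_traits)))
  beta
}

#' Triple a corn-layout genome into a cattle-like genome
#'
#' Builds a 30-chromosome genome from 10-chromosome corn inputs:
#' chromosomes 1-10 are copied unchanged; for each of chromosomes 11-30
#' the founder assignment of the corresponding corn chromosome is
#' reshuffled (sampled without replacement across founders), which
#' preserves per-chromosome allele frequencies and within-chromosome LD
#' while avoiding artificial between-chromosome LD between copies of the
#' same corn locus. Allele-substitution effects are multiplied by 1/3 so
#' variance levels stay comparable to the corn genome.
#'
#' @param founders Output of [generate_founders] on the corn preset.
#' @param effects p x T effects matrix over the corn loci.
#' @return List with `haplotypes` (3p x n), `map` (30 chromosomes) and
#'   `effects` (3p x T, scaled by 1/3).
#' @export
cattle_from_corn <- function(founders, effects) {
  H <- founders$haplotypes
  map <- founders$map
  effects <- as.matrix(effects)
  chrs <- unique(map$chrom)
  if (length(chrs) != 10) stop("expected a 10-chromosome corn-layout input")
  n <- ncol(H)
  blocks <- list(); mrows <- list(); erows <- list()
  for (copy in 0:2) {
    for (ci in seq_along(chrs)) {
      idx <- which(map$chrom == chrs[ci])
      perm <- if (copy == 0) seq_len(n) else sample.int(n)
      blocks[[length(blocks) + 1L]] <- H[idx, perm, drop = FALSE]
      newchr <- sprintf("chr%02d", ci + 10 * copy)
      mrows[[length(mrows) + 1L]] <- data.frame(
        locus_id = if (copy == 0) map$locus_id[idx]
                   else sprintf("%s_c%d", map$locus_id[idx], copy),
        chrom = newchr, pos = map$pos[idx], stringsAsFactors = FALSE)
      erows[[length(erows) + 1L]] <- effects[idx, , drop = FALSE]
    }
  }
  m <- do.call(rbind, mrows)
  out_map <- genetic_map(m$locus_id, m$chrom, m$pos)
  H3 <- do.call(rbind, blocks)
  E3 <- do.call(rbind, erows) / 3
  rownames(H3) <- m$locus_id
  rownames(E3) <- m$locus_id
  # genetic_map sorts by (chrom, pos); align matrices to it
  ord <- match(out_map$locus_id, m$locus_id)
  list(haplotypes = H3[ord, , drop = FALSE], map = out_map,
       effects = E3[ord, , drop = FALSE])
}
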