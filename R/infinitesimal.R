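#' Expected gametic MSV under the infinitesimal model
#'
#' With many unlinked loci of equal effect, an individual's gametic
#' Mendelian sampling variance is fully determined by its inbreeding
#' coefficient F: MSV = 0.25 (1 - F) sigmaA2, with sigmaA2 the additive
#' variance of the random-mating non-inbred base population.
#'
#' @param F Inbreeding coefficient in `[0, 1]`, vectorised.
#' @param sigmaA2 Base-population additive genetic variance (>= 0).
#' @return Expected gametic MSV (trait units squared).
#' @export
gametic_msv_expected <- function(F, sigmaA2 = 1) {
  if (any(F < 0) || any(F > 1)) stop("inbreeding coefficient must be in [0, 1]")
  if (any(sigmaA2 < 0)) stop("sigmaA2 must be non-negative")
  0.25 * (1 - F) * sigmaA2
}

#' Genetic variance of the next generation
#'
#' Transmission of additive variance from parents to offspring: the
#' parent-average part (sire and dam group variances over 4 plus half their
#' BV covariance) plus both Mendelian sampling variances and twice the MS
#' covariance. Selfing corresponds to `cov_parents = sire_var` and
#' `cov_ms = 0` with identical parent pools (variance + 2 MSV); DH
#' production corresponds to a perfectly correlated MS term
#' (`cov_ms = msv`), giving variance + 4 MSV.
#'
#' @param sire_var,dam_var Genetic variances of the sire and dam groups.
#' @param cov_parents Covariance of BVs of mated sires and dams (0 under
#'   random mating).
#' @param sire_msv,dam_msv Gametic MSVs of the sire and dam groups.
#' @param cov_ms Covariance of the sire and dam Mendelian sampling terms
#'   (0 except for DH production, where it equals the gametic MSV).
#' @return Expected genetic variance of the offspring generation.
#' @export
next_gen_variance <- function(sire_var, dam_var, cov_parents = 0,
                              sire_msv = 0, dam_msv = 0, cov_ms = 0) {
  if (any(c(sire_var, dam_var, sire_msv, dam_msv) < 0))
    stop("variances must be non-negative")
  sire_var / 4 + dam_var / 4 + cov_parents / 2 +
    sire_msv + dam_msv + 2 * cov_ms
}

# mean coancestry between founder blocks x and y (cross pairs only)
block_mean_f <- function(f, x, y) mean(f[x, y])

#' Infinitesimal-model variance cascade for an N-way crossing plan
#'
#' Coancestry-based counterpart of [build_cascade]: expected genetic
#' variances of every F1 group and expected gametic MSVs of group members
#' along the balanced bracket, from founder coancestries alone. The MSV of
#' a group member is 0.25 (1 - F) sigmaA2 with F the mean coancestry
#' between the founder blocks of the group's two parents; generation-1
#' groups of fully inbred founders have F1 variance 0.
#'
#' @param N Number of founder slots, a power of 2.
#' @param coancestry N x N symmetric matrix of pairwise coancestries among
#'   the founder lines (default: all unrelated, 0).
#' @param sigmaA2 Base-population additive variance.
#' @return A data.frame with one row per generation: `generation`,
#'   `f1_variance` (within-group genetic variance), `gametic_msv` (of a
#'   group member), `dh_variance` (variance of DH lines the group would
#'   produce), averaged over groups of the generation.
#' @export
infinitesimal_cascade <- function(N, coancestry = NULL, sigmaA2 = 1) {
  check_power2(N)
  if (is.null(coancestry)) coancestry <- matrix(0, N, N)
  if (!is.matrix(coancestry) || any(dim(coancestry) != N))
    stop("coancestry must be an N x N matrix")
  L <- log2(N)
  walk <- function(slots) {
    n <- length(slots)
    half <- n / 2
    left <- slots[seq_len(half)]
    right <- slots[half + seq_len(half)]
    if (n == 2) {
      f1 <- 0
    } else {
      lw <- walk(left); rw <- walk(right)
      f1 <- lw$f1 / 4 + rw$f1 / 4 + lw$msv + rw$msv
    }
    msv <- gametic_msv_expected(block_mean_f(coancestry, left, right), sigmaA2)
    res <- list(f1 = f1, msv = msv)
    acc[[log2(n)]] <<- c(acc[[log2(n)]], list(res))
    res
  }
  acc <- vector("list", L)
  walk(seq_len(N))
  f1 <- vapply(acc, function(g) mean(vapply(g, `[[`, 0, "f1")), 0)
  msv <- vapply(acc, function(g) mean(vapply(g, `[[`, 0, "msv")), 0)
  data.frame(generation = seq_len(L), f1_variance = f1, gametic_msv = msv,
             dh_variance = f1 + 4 * msv)
}

#' Expected F1 and DH variances of an N-way cross (infinitesimal model)
#'
#' `expected_f1_variance` returns the expected genetic variance among the
#' top-level N-way F1 individuals; `expected_dh_variance` the expected
#' variance among DH lines made from their gametes. The DH variance is
#' evaluated as the closed-form sum over bracket levels,
#' sum_g 2^(2 - (L - g)) * 0.25 * (1 - mean f of level-g cross pairs) * sigmaA2
#' with L = log2(N): the gametic-MSV weight halves with every step from the
#' X-way F1 level (4) towards generation 1. With all coancestries 0 this
#' gives the ladder 1, 1.5, 1.75, 1.875, ... -> 2 for N = 2, 4, 8, 16, ...
#'
#' @inheritParams infinitesimal_cascade
#' @return A scalar expected variance (units of sigmaA2).
#' @export
expected_dh_variance <- function(N, coancestry = NULL, sigmaA2 = 1) {
  check_power2(N)
  if (is.null(coancestry)) coancestry <- matrix(0, N, N)
  if (!is.matrix(coancestry) || any(dim(coancestry) != N))
    stop("coancestry must be an N x N matrix")
  L <- log2(N)
  total <- 0
  for (g in seq_len(L)) {
    # level-g groups have size 2^g, split into two blocks of 2^(g-1)
    fbar <- numeric(0)
    for (start in seq(1, N, by = 2^g)) {
      left <- start:(start + 2^(g - 1) - 1)
      right <- (start + 2^(g - 1)):(start + 2^g - 1)
      fbar <- c(fbar, coancestry[left, right])
    }
    total <- total + 2^(2 - (L - g)) * 0.25 * (1 - mean(fbar)) * sigmaA2
  }
  total
}

#' @rdname expected_dh_variance
#' @export
expected_f1_variance <- function(N, coancestry = NULL, sigmaA2 = 1) {
  casc <- infinitesimal_cascade(N, coancestry, sigmaA2)
  casc$f1_variance[nrow(casc)]
}

#' Identity-by-state coancestry of fully inbred founder haplotypes
#'
#' For fully inbred lines represented by single haplotypes, the allele
#' sharing proportion between two haplotypes predicts the homozygosity of
#' their cross and serves as a marker-based coancestry:
#' f_ik = 1 - mean(|h_i - h_k|) = 1 - 4 * mean(diag(D^(ik))).
#'
#' @param panel A [founder_panel] (or plain p x N 0/1 matrix).
#' @return N x N symmetric matrix with unit diagonal.
#' @export
ibs_coancestry <- function(panel) {
  H <- if (inherits(panel, "founder_panel")) panel$haplotypes else as.matrix(panel)
  p <- nrow(H)
  # share_ik = fraction of loci with equal alleles
  M <- 2 * H - 1
  (crossprod(M) / p + 1) / 2
}

check_power2 <- function(N) {
  if (length(N) != 1 || N < 2 || N != round(N) ||
      bitwAnd(as.integer(N), as.integer(N) - 1L) != 0)
    stop("N must be a power of 2 (>= 2)")
  invisible(N)
}
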