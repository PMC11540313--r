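#' Standardized selection intensity for a selected proportion
#'
#' Mean of a standard normal truncated at its upper `p` quantile:
#' i = dnorm(qnorm(1 - p)) / p. Converts a selected proportion (e.g. 0.05)
#' into the intensity multiplying a within-group SD in a selection
#' differential.
#'
#' @param p Selected proportion in (0, 1].
#' @return Selection intensity (>= 0), vectorised.
#' @export
selection_intensity <- function(p) {
  if (any(p <= 0) || any(p > 1)) stop("selected proportion must be in (0, 1]")
  ifelse(p == 1, 0, stats::dnorm(stats::qnorm(1 - p)) / p)
}

#' Expected genetic level of selected F4 descendants (ExpBVSelGrGrGrOff)
#'
#' Criterion for ranking sets of 16 founder haplotypes by the expected mean
#' breeding value of selected great-great-grandoffspring: the mean BV of
#' the 8 founder pairs plus the per-generation selection differentials,
#' each the product of a selection intensity and the relevant group SD:
#'
#' mean(pair BVs) + i_F1 * mean(4 generation-2 group SDs)
#'               + i_F2 * mean(2 generation-3 group SDs)
#'               + i_F3 * generation-4 group SD
#'               + i_F4 * sqrt(2 * gametic MSV of the 16-way F1 group)
#'
#' The last generation's offspring variance is approximated as twice the
#' 16-way F1 gametic variance, i.e. the unknown mates are assumed to
#' produce gametes with the same variance. The criterion assumes normally
#' distributed BVs within groups.
#'
#' @param pair_bvs Numeric vector of 8 founder-pair BVs (BV of the
#'   genotype formed by the two slot haplotypes of each generation-1
#'   cross).
#' @param gen2_sd Numeric vector of the 4 generation-2 (4-way F1) group
#'   SDs.
#' @param gen3_sd Numeric vector of the 2 generation-3 (8-way F1) group
#'   SDs.
#' @param gen4_sd Scalar generation-4 (16-way F1) group SD.
#' @param gamete_msv Scalar gametic MSV of the 16-way F1 group (trait
#'   units squared).
#' @param intensities Numeric vector of 4 selection intensities
#'   (i_F1 .. i_F4), all >= 0; see [selection_intensity].
#' @return Expected genetic level of selected F4 individuals (trait
#'   units).
#' @export
exp_bv_sel_grgrgroff <- function(pair_bvs, gen2_sd, gen3_sd, gen4_sd,
                                 gamete_msv, intensities) {
  if (length(pair_bvs) != 8) stop("pair_bvs must have length 8")
  if (length(gen2_sd) != 4) stop("gen2_sd must have length 4")
  if (length(gen3_sd) != 2) stop("gen3_sd must have length 2")
  if (length(gen4_sd) != 1) stop("gen4_sd must be a scalar")
  if (length(intensities) != 4) stop("intensities must have length 4")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("intensities must be finite and non-negative")
  if (any(c(gen2_sd, gen3_sd, gen4_sd) < 0) || gamete_msv < 0)
    stop("SDs and the gametic MSV must be non-negative")
  mean(pair_bvs) +
    intensities[1] * mean(gen2_sd) +
    intensities[2] * mean(gen3_sd) +
    intensities[3] * gen4_sd +
    intensities[4] * sqrt(2 * gamete_msv)
}

#' Evaluate the criterion from a 16-slot panel and its cascade
#'
#' Convenience wrapper: founder-pair BVs are computed from the slot
#' haplotypes (dosage times effect, summed over loci), group SDs are square
#' roots of the cascade's F1 group variances, and the gametic MSV is the
#' top group's.
#'
#' @param panel A 16-slot [founder_panel].
#' @param cascade Cascade of the same panel from [build_cascade].
#' @param beta p-vector of effects of the trait under selection.
#' @param intensities Four selection intensities.
#' @param trait Trait id to pull from the cascade (default: its first).
#' @return The criterion value.
#' @export
criterion_from_cascade <- function(panel, cascade, beta, intensities,
                                   trait = NULL) {
  stopifnot(inherits(panel, "founder_panel"),
            inherits(cascade, "variance_cascade"))
  H <- panel$haplotypes
  if (ncol(H) != 16) stop("the criterion is defined for 16 founder slots")
  if (is.null(trait)) trait <- cascade$trait[1]
  cc <- cascade[cascade$trait == trait, , drop = FALSE]
  if (nrow(cc) == 0) stop("trait not found in cascade")
  beta <- as.numeric(beta)
  pair_bvs <- vapply(seq_len(8), function(t)
    sum((H[, 2 * t - 1] + H[, 2 * t]) * beta), 0)
  sd_gen <- function(g) sqrt(cc$f1_variance[cc$generation == g])
  exp_bv_sel_grgrgroff(pair_bvs,
                       gen2_sd = sd_gen(2), gen3_sd = sd_gen(3),
                       gen4_sd = sd_gen(4),
                       gamete_msv = cc$gametic_msv[cc$generation == 4],
                       intensities = intensities)
}
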