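#' Relative qPCR quantification by the delta-delta-Ct method
#'
#' `ddCt = (Ct_target,treated - Ct_ref,treated) - (Ct_target,control -
#' Ct_ref,control)`; fold change `= 2^(-ddCt)`, assuming amplification
#' efficiency exactly 2 per cycle. Each argument may be a vector of replicate
#' Ct values; replicates are reduced by their mean and the standard error of
#' ddCt is propagated as the root sum of squared standard errors of the four
#' means, giving a fold interval `2^-(ddCt +/- se)`.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   numeric Ct values (cycles), scalars or replicate vectors.
#' @return list: `ddct`, `fold`, and (when any input has replicates)
#'   `ddct_se`, `fold_lo`, `fold_hi`.
#' @export
ddct_fold_change <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  args <- list(ct_target_treated, ct_ref_treated, ct_target_control, ct_ref_control)
  if (any(!vapply(args, function(a) all(is.finite(a)), logical(1)))) {
    stop("Ct values must be finite")
  }
  m <- vapply(args, mean, numeric(1))
  ddct <- (m[1] - m[2]) - (m[3] - m[4])
  out <- list(ddct = ddct, fold = 2^(-ddct))
  if (any(lengths(args) > 1L)) {
    se2 <- vapply(args, function(a) {
      if (length(a) > 1L) stats::var(a) / length(a) else 0
    }, numeric(1))
    se <- sqrt(sum(se2))
    out$ddct_se <- se
    out$fold_lo <- 2^(-(ddct + se))
    out$fold_hi <- 2^(-(ddct - se))
  }
  out
}

#' Absolute qPCR quantification by the standard-curve method
#'
#' Fits the least-squares dilution line `Ct = slope * log10(q) + intercept`
#' and inverts it for the unknowns: `q = 10^((Ct - intercept) / slope)`.
#' Amplification efficiency is `10^(-1/slope) - 1` (1.0 means perfect
#' doubling, slope about -3.32).
#'
#' @param standards data.frame with columns `log10_quantity` and `ct`; at
#'   least 3 points spanning at least 2 log10 units.
#' @param unknowns numeric Ct values to quantify (optional).
#' @return list: `fit` (`slope`, `intercept`, `r_squared`, `efficiency`) and
#'   `quantities` for the unknowns (linear scale).
#' @export
standard_curve_quantify <- function(standards, unknowns = numeric(0)) {
  need <- c("log10_quantity", "ct")
  if (!all(need %in% names(standards))) stop("standards needs columns: log10_quantity, ct")
  if (nrow(standards) < 3L) stop("need at least 3 standards")
  if (diff(range(standards$log10_quantity)) < 2) {
    stop("standards must span at least 2 log10 units")
  }
  fit <- stats::lm(ct ~ log10_quantity, data = standards)
  slope <- unname(stats::coef(fit)[2]); intercept <- unname(stats::coef(fit)[1])
  if (slope >= 0) stop("invalid dilution series: slope must be negative")
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((standards$ct - mean(standards$ct))^2)
  list(fit = list(slope = slope, intercept = intercept,
                  r_squared = 1 - ss_res / ss_tot,
                  efficiency = 10^(-1 / slope) - 1),
       quantities = 10^((unknowns - intercept) / slope))
}

#' ChIP-qPCR enrichment as percent of the 2% input aliquot
#'
#' `%input = 100 * q_ip / q_input2pct`: the immunoprecipitated DNA relative
#' to the measured 2% input aliquot itself (not rescaled to total chromatin).
#' `rescale_total = TRUE` applies the alternative convention, multiplying by
#' 0.02 so the value is a percentage of total input chromatin.
#'
#' @param q_ip DNA quantity in the immunoprecipitate.
#' @param q_input2pct DNA quantity in the 2% input aliquot (> 0).
#' @param rescale_total logical, default `FALSE`.
#' @return percent value(s).
#' @export
chip_percent_input <- function(q_ip, q_input2pct, rescale_total = FALSE) {
  if (any(q_input2pct <= 0)) stop("input quantity must be > 0")
  pct <- 100 * q_ip / q_input2pct
  if (rescale_total) pct <- pct * 0.02
  pct
}

#' Fold enrichment of an antibody ChIP over the IgG control
#'
#' @param pct_input_ab,pct_input_igg percent-input values from
#'   [chip_percent_input()].
#' @return fold ratio.
#' @export
chip_fold_over_igg <- function(pct_input_ab, pct_input_igg) {
  if (any(pct_input_igg <= 0)) stop("IgG percent input must be > 0")
  pct_input_ab / pct_input_igg
}

#' Viral titre from a plaque assay
#'
#' `titre = plaques / (dilution * volume)` in PFU/ml. Zero plaques are
#' reported as 0 with the detection limit `1 / (dilution * volume)` attached
#' as attribute `detection_limit`.
#'
#' @param plaque_count plaques counted on the well.
#' @param dilution dilution fraction in (0, 1], e.g. `1e-5`.
#' @param inoculum_volume_ml plated volume in ml (> 0).
#' @return titre in PFU/ml.
#' @export
plaque_titre <- function(plaque_count, dilution, inoculum_volume_ml) {
  if (any(dilution <= 0 | dilution > 1)) stop("dilution must lie in (0, 1]")
  if (any(inoculum_volume_ml <= 0)) stop("inoculum volume must be > 0")
  titre <- plaque_count / (dilution * inoculum_volume_ml)
  if (any(plaque_count == 0)) {
    attr(titre, "detection_limit") <- 1 / (dilution * inoculum_volume_ml)
  }
  titre
}

#' Fold reduction between paired titres
#'
#' @param titre_control,titre_treated titres in PFU/ml (`titre_treated` > 0).
#' @return `titre_control / titre_treated`.
#' @export
titre_fold_reduction <- function(titre_control, titre_treated) {
  if (any(titre_treated <= 0)) stop("treated titre must be > 0 for a fold ratio")
  as.numeric(titre_control) / as.numeric(titre_treated)
}
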