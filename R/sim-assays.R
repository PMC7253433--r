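#' Simulate assay fixtures with known ground truth
#'
#' Builds tidy qPCR (ddCt), RIP-qPCR, polysome-fraction, reporter and
#' clonogenic tables by inverting the corresponding quantification
#' formulas, so each downstream operation recovers its construction
#' parameter exactly.
#'
#' @param seed Integer seed (randomizes nuisance Ct levels and fraction
#'   splits, never the planted truths).
#' @param ddct_fold Planted expression fold change (treated vs control).
#' @param rip_fold Planted RIP enrichment of the gene relative to the
#'   reference gene.
#' @param te,te_control Planted translational efficiencies (HP / total).
#' @param pe_treated,pe_control Planted plating efficiencies (percent).
#' @param reporter_ratio Planted Rluc/Fluc ratio relative to control.
#'
#' @return A list of data.frames `ct`, `rip`, `polysome`, `reporter`,
#'   `colony`, plus `truth` (the planted values).
#' @export
simulate_assays <- function(seed = 1L, ddct_fold = 2, rip_fold = 4,
                            te = 0.3, te_control = 0.2,
                            pe_treated = 40, pe_control = 80,
                            reporter_ratio = 1.5) {
  stopifnot(ddct_fold > 0, rip_fold > 0,
            te >= 0, te <= 1, te_control > 0, te_control <= 1,
            pe_treated >= 0, pe_control > 0, reporter_ratio > 0)
  with_seed(seed, {
    # ddCt: choose nuisance Cts, set treated target Ct so that
    # 2^-(ddCt) equals the planted fold
    ct_ref_control <- stats::runif(1, 18, 22)
    ct_ref_treated <- stats::runif(1, 18, 22)
    ct_target_control <- stats::runif(1, 20, 26)
    ct_target_treated <- ct_ref_treated +
      (ct_target_control - ct_ref_control) - log2(ddct_fold)
    ct <- data.frame(
      sample = c("treated", "treated", "control", "control"),
      gene = c("target", "reference", "target", "reference"),
      condition = c("treated", "treated", "control", "control"),
      ct = c(ct_target_treated, ct_ref_treated,
             ct_target_control, ct_ref_control))

    # RIP: reference gene flat (IP == IgG); planted gene IP enriched by
    # log2(rip_fold) cycles over IgG
    rip <- data.frame(
      gene = c("gene", "reference"),
      ct_ip = c(NA, NA), ct_igg = c(NA, NA), ct_input = c(NA, NA))
    rip$ct_input <- stats::runif(2, 14, 18)
    rip$ct_igg <- rip$ct_input + stats::runif(2, 6, 10)
    rip$ct_ip <- c(rip$ct_igg[1] - log2(rip_fold), rip$ct_igg[2])

    # polysome: split (1 - TE) of the total randomly between NP and LP
    mk_fracs <- function(te_val, total) {
      w <- stats::runif(1, 0.3, 0.7)
      data.frame(np = (1 - te_val) * total * w,
                 lp = (1 - te_val) * total * (1 - w),
                 hp = te_val * total)
    }
    polysome <- cbind(condition = c("treated", "control"),
                      rbind(mk_fracs(te, 100), mk_fracs(te_control, 80)))

    # reporter: control pair with an arbitrary ratio; condition pair
    # scaled so the normalized ratio is as planted
    ctrl_fluc <- stats::runif(1, 50, 200)
    ctrl_rluc <- ctrl_fluc * stats::runif(1, 0.5, 2)
    cond_fluc <- stats::runif(1, 50, 200)
    cond_rluc <- cond_fluc * (ctrl_rluc / ctrl_fluc) * reporter_ratio
    reporter <- data.frame(
      condition = c("condition", "control"),
      rluc = c(cond_rluc, ctrl_rluc),
      fluc = c(cond_fluc, ctrl_fluc))

    # clonogenic: plated chosen so colony counts are integral
    colony <- data.frame(
      condition = c("treated", "control"),
      colonies = c(pe_treated * 5, pe_control * 5),
      plated = c(500, 500))

    list(ct = ct, rip = rip, polysome = polysome, reporter = reporter,
         colony = colony,
         truth = list(ddct_fold = ddct_fold, rip_fold = rip_fold,
                      te = te, te_control = te_control,
                      pe_treated = pe_treated, pe_control = pe_control,
                      reporter_ratio = reporter_ratio))
  })
}
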