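#' Relative expression by the ddCt method
#'
#' Computes `dCt = ct_target - ct_ref` per condition, `ddCt =
#' dCt_treated - dCt_control`, and the fold change `2^(-ddCt)` (Livak
#' convention: a lower Ct means more template, so a target Ct dropping by
#' one cycle doubles the fold). Set `literal_sign = TRUE` for the literal
#' `2^(+ddCt)` form, which inverts fold directions.
#'
#' @param ct_target_treated,ct_ref_treated Target and reference-gene Ct in
#'   the treated condition; vectorized.
#' @param ct_target_control,ct_ref_control Same for the control condition.
#' @param literal_sign Use `2^(+ddCt)` instead of `2^(-ddCt)`.
#'
#' @return Numeric fold change(s).
#' @examples
#' ddct_expression(20, 18, 22, 18)  # 4
#' @export
ddct_expression <- function(ct_target_treated, ct_ref_treated,
                            ct_target_control, ct_ref_control,
                            literal_sign = FALSE) {
  cts <- c(ct_target_treated, ct_ref_treated,
           ct_target_control, ct_ref_control)
  if (any(!is.finite(cts)) || any(cts <= 0)) {
    stop("all Ct values must be finite and > 0", call. = FALSE)
  }
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  if (literal_sign) 2^ddct else 2^(-ddct)
}

#' RIP-qPCR enrichment normalized to IgG, input and a reference gene
#'
#' Per gene, enrichment over the mock IP is
#' `E = eff^(ct_input - ct_ip) / eff^(ct_input - ct_igg) =
#' eff^(ct_igg - ct_ip)`; the reported value is `E / E_reference`, i.e.
#' relative to a housekeeping mRNA (HPRT in the assays this reproduces).
#'
#' @param genes Character vector of gene identifiers.
#' @param ct_ip,ct_igg,ct_input Ct values of the IP, control IgG IP and
#'   input samples, parallel to `genes`.
#' @param reference_gene Gene used as the normalizer; must be in `genes`.
#' @param efficiency Amplification factor per cycle (default 2 = 100%
#'   primer efficiency).
#'
#' @return Named numeric vector of normalized enrichments (reference = 1).
#' @examples
#' rip_enrichment(c("g1", "hprt"), ct_ip = c(20, 24), ct_igg = c(23, 24),
#'                ct_input = c(15, 16), reference_gene = "hprt")  # g1 = 8
#' @export
rip_enrichment <- function(genes, ct_ip, ct_igg, ct_input,
                           reference_gene, efficiency = 2) {
  stopifnot(length(genes) == length(ct_ip),
            length(genes) == length(ct_igg),
            length(genes) == length(ct_input),
            efficiency > 1)
  if (any(is.na(ct_igg)) || any(is.na(ct_input))) {
    stop("missing IgG or input Ct", call. = FALSE)
  }
  if (!reference_gene %in% genes) {
    stop("reference gene '", reference_gene, "' not in table",
         call. = FALSE)
  }
  e <- efficiency^(ct_igg - ct_ip)
  names(e) <- genes
  e / e[[reference_gene]]
}

#' Translational efficiency from pooled polysome fractions
#'
#' TE is the heavy-polysome share of the total signal across the
#' non-polysomal (NP), light (LP) and heavy (HP) polysomal pools:
#' `TE = hp / (np + lp + hp)`.
#'
#' @param np,lp,hp Relative mRNA quantities per pooled fraction
#'   (non-negative); vectorized.
#'
#' @return Numeric TE in `[0, 1]`.
#' @examples
#' polysome_te(50, 20, 30)  # 0.3
#' @export
polysome_te <- function(np, lp, hp) {
  stopifnot(all(np >= 0), all(lp >= 0), all(hp >= 0))
  total <- np + lp + hp
  if (any(total <= 0)) stop("total fraction amount must be > 0",
                            call. = FALSE)
  hp / total
}

#' TE ratio between a condition and its paired control
#'
#' @param np,lp,hp Fractions of the condition of interest.
#' @param np_control,lp_control,hp_control Fractions of the control.
#' @return `TE_condition / TE_control`.
#' @export
polysome_te_ratio <- function(np, lp, hp,
                              np_control, lp_control, hp_control) {
  polysome_te(np, lp, hp) /
    polysome_te(np_control, lp_control, hp_control)
}

#' Renilla/Firefly reporter ratio
#'
#' `rluc / fluc`, optionally normalized to a control pair's ratio.
#'
#' @param rluc,fluc Renilla and Firefly luciferase readings; `fluc` must
#'   be positive.
#' @param rluc_control,fluc_control Optional control pair for
#'   normalization.
#' @return Numeric ratio.
#' @examples
#' reporter_ratio(200, 100)  # 2
#' @export
reporter_ratio <- function(rluc, fluc,
                           rluc_control = NULL, fluc_control = NULL) {
  if (any(fluc <= 0)) stop("fluc must be > 0", call. = FALSE)
  r <- rluc / fluc
  if (!is.null(rluc_control)) {
    if (is.null(fluc_control) || any(fluc_control <= 0)) {
      stop("control pair incomplete or fluc_control <= 0", call. = FALSE)
    }
    r <- r / (rluc_control / fluc_control)
  }
  r
}

#' Plating efficiency and clonogenic survival fraction
#'
#' `PE (%) = colonies / plated * 100`; the survival fraction is
#' `PE_treated / PE_control` when a control PE is supplied.
#'
#' @param colonies Colonies formed (>= 0); vectorized.
#' @param plated Cells plated (> 0).
#' @param control_pe Optional control plating efficiency (percent).
#'
#' @return A list with `pe` (percent) and `survival_fraction` (`NA` when
#'   no control is given).
#' @examples
#' clonogenic_survival(200, 500)$pe  # 40
#' @export
clonogenic_survival <- function(colonies, plated, control_pe = NULL) {
  stopifnot(all(colonies >= 0))
  if (any(plated <= 0)) stop("plated must be > 0", call. = FALSE)
  pe <- colonies / plated * 100
  sf <- if (is.null(control_pe)) NA_real_ else {
    if (any(control_pe <= 0)) stop("control_pe must be > 0", call. = FALSE)
    pe / control_pe
  }
  list(pe = pe, survival_fraction = sf)
}
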