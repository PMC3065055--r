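#' Vascular-targeting treatment protocol
#'
#' Describes which drugs run and how. The angiogenesis inhibitor (AI, a
#' bevacizumab-like antibody) is dosed every two weeks but its 20-day
#' half-life keeps it at therapeutic levels continuously, so it acts as a
#' sustained parameter change; the cytotoxic agent (temozolomide-like) acts
#' daily through a 6-week window; the vascular disrupting agent (VDA,
#' CA4P-like) is dosed every three weeks and acts only on the dose day.
#' Every drug starts on the first day the tumour radius reaches
#' `trigger_radius`.
#'
#' @param drugs subset of `c("AI", "CYTOTOXIC", "VDA")`.
#' @param T1 AI efficacy: the targeted parameter is scaled by `T1` (>= 1).
#' @param T2 daily kill probability of the cytotoxic agent for an actively
#'   dividing (proliferative) cell.
#' @param T3 per-sub-segment destruction probability of the VDA for
#'   angiogenic vessels on a dose day.
#' @param ai_mode what the AI targets: `"PRODUCTION"` divides the VEGF
#'   production rate `b_v` by `T1`; `"BINDING"` divides the VEGF/VEGFR-2
#'   association rate `k_0` by `T1`; `"SENSITIVITY"` multiplies the EC
#'   response threshold `rv_crit` by `T1`.
#' @param ai_interval,cytotoxic_window,vda_interval schedule constants in
#'   days (14 / 42 / 21).
#' @param trigger_radius tumour radius (mm) at which treatment starts.
#' @param ai_duration days of AI coverage after the trigger (`Inf` =
#'   indefinite); used for cessation experiments.
#' @param vda_duration days of VDA dosing after the trigger.
#' @export
treatment_protocol <- function(drugs = "AI", T1 = 100, T2 = 0.34, T3 = 0.6,
                               ai_mode = c("PRODUCTION", "BINDING",
                                           "SENSITIVITY"),
                               ai_interval = 14, cytotoxic_window = 42,
                               vda_interval = 21, trigger_radius = 4,
                               ai_duration = Inf, vda_duration = Inf) {
  drugs <- match.arg(drugs, c("AI", "CYTOTOXIC", "VDA"), several.ok = TRUE)
  ai_mode <- match.arg(ai_mode)
  if (T1 < 1) stop("invalid argument: T1 must be >= 1")
  if (T2 < 0 || T2 > 1 || T3 < 0 || T3 > 1) {
    stop("invalid argument: T2 and T3 must lie in [0, 1]")
  }
  if (ai_interval <= 0 || cytotoxic_window <= 0 || vda_interval <= 0) {
    stop("invalid argument: schedule durations must be positive")
  }
  structure(list(drugs = drugs, T1 = T1, T2 = T2, T3 = T3, ai_mode = ai_mode,
                 ai_interval = ai_interval,
                 cytotoxic_window = cytotoxic_window,
                 vda_interval = vda_interval,
                 trigger_radius = trigger_radius,
                 ai_duration = ai_duration, vda_duration = vda_duration),
            class = "treatment_protocol")
}

#' Apply the angiogenesis inhibitor to the model parameters
#'
#' Returns modified copies of the PDE and angiogenesis parameters according
#' to the protocol's `ai_mode`; re-applying to pristine copies when the AI
#' stops restores the exact pre-treatment values.
#'
#' @param pde a `pde_params`.
#' @param angio an `angiogenesis_params`.
#' @param protocol a `treatment_protocol`.
#' @return list with modified `pde` and `angio`.
#' @export
apply_ai <- function(pde, angio, protocol) {
  switch(protocol$ai_mode,
         PRODUCTION = { pde$b_v <- pde$b_v / protocol$T1 },
         BINDING = { pde$k_0 <- pde$k_0 / protocol$T1 },
         SENSITIVITY = { angio$rv_crit <- angio$rv_crit * protocol$T1 },
         stop("invalid argument: unknown ai_mode"))
  list(pde = pde, angio = angio)
}

#' Apply one day of cytotoxic chemotherapy
#'
#' Each proliferative (actively dividing) cell is independently destroyed
#' with probability `T2`; killed cells become necrotic, so they stay inside
#' the tumour area but leave the active area. Hypoxic and necrotic cells
#' are untouched -- the drug only reaches cycling cells.
#'
#' @param tumor a `tumor_state`.
#' @param protocol a `treatment_protocol`.
#' @param rng an [rng_stream()].
#' @param day day index (recorded only).
#' @return list: updated `tumor`, `n_killed`.
#' @export
apply_cytotoxic <- function(tumor, protocol, rng, day = 0) {
  prolif <- which(tumor$states == STATE_PROLIFERATIVE)
  if (length(prolif) == 0L) {
    return(list(tumor = tumor, n_killed = 0L))
  }
  u <- rng_draw(rng, function() runif(length(prolif)))
  killed <- prolif[u < protocol$T2]
  tumor$states[killed] <- STATE_NECROTIC
  list(tumor = tumor, n_killed = length(killed))
}

#' Apply one vascular-disrupting-agent dose
#'
#' Each alive angiogenic sub-segment is independently hit with probability
#' `T3` and removed together with its flow-dependency closure; native
#' (coopted) vessels are never touched -- the drug binds angiogenic
#' endothelium selectively. The upstream cascade is what makes the tumour
#' response insensitive to `T3` beyond moderate values.
#'
#' @param network a `vessel_network`.
#' @param protocol a `treatment_protocol`.
#' @param rng an [rng_stream()].
#' @param day day index (recorded only).
#' @return list: updated `network`, `n_removed` (including cascade),
#'   `removed` ids.
#' @export
apply_vda <- function(network, protocol, rng, day = 0) {
  angio <- which(network$alive & network$type == 2L)
  if (length(angio) == 0L) {
    return(list(network = network, n_removed = 0L, removed = integer(0)))
  }
  u <- rng_draw(rng, function() runif(length(angio)))
  doomed <- angio[u < protocol$T3]
  res <- remove_segments_with_cascade(network, doomed)
  list(network = res$network, n_removed = res$n_removed,
       removed = res$removed)
}

#' Daily fractional kill implied by a measured log cell kill
#'
#' Under the fractional-kill hypothesis, a course of `n_days` daily doses
#' each killing a fraction `f` of an exponentially growing population with
#' daily growth factor `g = 2^(1/doubling_time)` produces a net log10 kill
#' of `log_kill` when `(g (1 - f))^n_days = 10^(-log_kill)`, giving
#' `f = 1 - 10^(-log_kill / n_days) / g`. The temozolomide literature value
#' of 0.4 log units over five days with a four-day doubling time gives
#' f of about 0.30, close to the cytotoxic default `T2 = 0.34`.
#'
#' @param log_kill net population reduction in log10 units.
#' @param n_days number of daily doses over which it was measured.
#' @param doubling_time tumour doubling time in days (`Inf` = no growth).
#' @return the daily kill probability `f`.
#' @export
fractional_kill_from_log_kill <- function(log_kill, n_days, doubling_time) {
  if (log_kill < 0 || n_days <= 0 || doubling_time <= 0) {
    stop("invalid argument: all arguments must be positive")
  }
  g <- 2^(1 / doubling_time)
  f <- 1 - 10^(-log_kill / n_days) / g
  if (f < 0 || f >= 1) {
    stop(sprintf("domain error: implied daily kill fraction %.3f not in [0, 1)",
                 f))
  }
  f
}
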