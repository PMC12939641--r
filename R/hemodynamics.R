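#' Body surface area (Mosteller)
#'
#' @param height_cm height in cm
#' @param weight_kg weight in kg
#' @return BSA in m^2.
#' @export
bsa_mosteller <- function(height_cm, weight_kg) {
  if (any(height_cm <= 0) || any(weight_kg <= 0))
    stop("height_cm and weight_kg must be positive", call. = FALSE)
  sqrt(height_cm * weight_kg / 3600)
}

#' Estimated indexed oxygen consumption
#'
#' Age- and weight-based estimation equation for oxygen consumption in
#' children (linear in natural logs of age and weight, with single-ventricle
#' and critical-illness adjustments):
#' \deqn{VO_2 = 242.1 + 9.7\,\ln(age) - 34\,\ln(weight) - 9.6\,SV - 11.2\,CI}
#' Treated as indexed (mL O2/min/m^2), so the Fick step yields cardiac index
#' directly.
#'
#' @param age_years age in years (> 0)
#' @param weight_kg weight in kg (> 0)
#' @param single_ventricle 0/1 single-ventricle anatomy flag
#' @param critical_illness 0/1 critical-illness flag
#' @return Estimated VO2 in mL O2/min/m^2.
#' @export
estimate_vo2 <- function(age_years, weight_kg, single_ventricle = 0,
                         critical_illness = 0) {
  if (any(!is.finite(age_years)) || any(age_years <= 0))
    stop("age_years must be positive and finite", call. = FALSE)
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0))
    stop("weight_kg must be positive and finite", call. = FALSE)
  if (!all(single_ventricle %in% c(0, 1)) || !all(critical_illness %in% c(0, 1)))
    stop("single_ventricle and critical_illness must be 0 or 1", call. = FALSE)
  242.1 + 9.7 * log(age_years) - 34 * log(weight_kg) -
    9.6 * single_ventricle - 11.2 * critical_illness
}

#' Fick cardiac index with a NIRS venous surrogate
#'
#' Fick principle: flow = oxygen consumption / arteriovenous oxygen content
#' difference. Arterial content is `k_o2 * Hb * SaO2 * 10` mL O2 per litre of
#' blood (the factor 10 converts g/dL to g/L); venous saturation is taken
#' from the renal NIRS channel as a surrogate. Dissolved oxygen is ignored.
#' Rows where the venous surrogate meets or exceeds the arterial saturation
#' have an undefined arteriovenous difference and return `NA` (a flag, not an
#' error).
#'
#' @param vo2i indexed oxygen consumption, mL O2/min/m^2
#' @param sao2_frac arterial saturation as a fraction in (0, 1]
#' @param svo2_frac venous (surrogate) saturation as a fraction
#' @param hemoglobin_g_dl hemoglobin, g/dL (> 0)
#' @param k_o2 oxygen-carrying capacity of hemoglobin, mL O2/g (default 1.36)
#' @return Cardiac index, L/min/m^2; `NA` where undefined.
#' @export
fick_cardiac_index <- function(vo2i, sao2_frac, svo2_frac, hemoglobin_g_dl,
                               k_o2 = 1.36) {
  if (any(hemoglobin_g_dl <= 0, na.rm = TRUE))
    stop("hemoglobin_g_dl must be positive", call. = FALSE)
  avdiff <- sao2_frac - svo2_frac
  ci <- vo2i / (k_o2 * hemoglobin_g_dl * avdiff * 10)
  ci[!is.na(avdiff) & avdiff <= 0] <- NA_real_
  ci
}

#' Indexed systemic vascular resistance
#'
#' `(MAP - CVP) * 80 / CI`, in dyn s cm-5 m2 (the conventional x80 unit
#' conversion). Undefined (NA) where cardiac index is non-positive.
#'
#' @param map_mmHg mean arterial pressure, mmHg
#' @param cvp_mmHg central venous pressure, mmHg
#' @param ci cardiac index, L/min/m^2
#' @return SVRi; `NA` where `ci <= 0`.
#' @export
svri <- function(map_mmHg, cvp_mmHg, ci) {
  out <- (map_mmHg - cvp_mmHg) * 80 / ci
  out[!is.na(ci) & ci <= 0] <- NA_real_
  out
}

#' Mean circulatory filling pressure
#'
#' Bedside MCFP estimate as a fixed linear combination of central venous
#' pressure, mean arterial pressure and absolute cardiac output:
#' \deqn{MCFP = 0.96\,CVP + 0.04\,MAP + 0.2\,CO}
#' CO enters in L/min; the 0.2 coefficient carries the implied unit
#' conversion.
#'
#' @param cvp_mmHg central venous pressure, mmHg
#' @param map_mmHg mean arterial pressure, mmHg
#' @param co_L_min cardiac output, L/min
#' @return MCFP, mmHg.
#' @export
mcfp <- function(cvp_mmHg, map_mmHg, co_L_min) {
  0.96 * cvp_mmHg + 0.04 * map_mmHg + 0.2 * co_L_min
}

#' Venous resistance
#'
#' `(MCFP - CVP) / VR` in mmHg per L/min, where venous return VR equals
#' cardiac output at steady state. Undefined (NA) where the flow is
#' non-positive.
#'
#' @param mcfp_mmHg mean circulatory filling pressure, mmHg
#' @param cvp_mmHg central venous pressure, mmHg
#' @param vr_flow venous return (steady-state cardiac output), L/min
#' @return Venous resistance; `NA` where `vr_flow <= 0`.
#' @export
venous_resistance <- function(mcfp_mmHg, cvp_mmHg, vr_flow) {
  out <- (mcfp_mmHg - cvp_mmHg) / vr_flow
  out[!is.na(vr_flow) & vr_flow <= 0] <- NA_real_
  out
}

#' Regional oxygen extraction
#'
#' `(SaO2 - NIRS) / SaO2`. Scale-invariant, so percent or fraction inputs
#' give the same answer as long as both are on the same scale. Negative
#' values (NIRS exceeding arterial saturation) are allowed and returned
#' as-is; undefined (NA) where `sao2 <= 0`.
#'
#' @param sao2 arterial oxygen saturation
#' @param nirs regional NIRS saturation (same scale as `sao2`)
#' @return Extraction fraction; `NA` where `sao2 <= 0`.
#' @export
oxygen_extraction <- function(sao2, nirs) {
  out <- (sao2 - nirs) / sao2
  out[!is.na(sao2) & sao2 <= 0] <- NA_real_
  out
}

#' Derive all hemodynamic outcomes for one patient
#'
#' Row-wise composition of the derivation chain on an imputed vitals frame:
#' estimated VO2 -> Fick cardiac index (renal NIRS venous surrogate) ->
#' cardiac output (CI x BSA) -> SVRi -> MCFP -> venous resistance ->
#' cerebral/renal oxygen extraction. Rows with undefined intermediates (e.g.
#' renal NIRS at or above arterial saturation) carry `NA` through every
#' dependent column; no values are fabricated.
#'
#' @param profile one-row patient profile (needs `age_years`, `weight_kg`,
#'   `single_ventricle`, `critical_illness`, `bsa_m2`, `hemoglobin_g_dl`)
#' @param vitals imputed vitals frame with columns `time_s` and
#'   [vital_signals()]; saturations in percent
#' @param k_o2 oxygen-carrying constant, mL O2/g Hb
#' @param vo2_indexed if `TRUE` (default) the VO2 estimate is indexed and the
#'   Fick step yields CI directly; if `FALSE` it is treated as absolute and
#'   Fick yields CO, with CI = CO / BSA
#' @param vr_flow flow convention for the venous-resistance denominator:
#'   `"co"` (absolute cardiac output, default) or `"ci"` (indexed)
#' @return Data frame: `time_s`, `vo2i`, `ci`, `co`, `svri`, `mcfp`, `rv`,
#'   `coer`, `roer`.
#' @export
derive_all <- function(profile, vitals, k_o2 = 1.36, vo2_indexed = TRUE,
                       vr_flow = c("co", "ci")) {
  vr_flow <- match.arg(vr_flow)
  need <- c("time_s", "map", "sao2", "cvp", "cnirs", "rnirs")
  miss <- setdiff(need, names(vitals))
  if (length(miss))
    stop("vitals frame lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  vo2 <- estimate_vo2(profile$age_years, profile$weight_kg,
                      profile$single_ventricle, profile$critical_illness)
  sao2f <- vitals$sao2 / 100
  svo2f <- vitals$rnirs / 100
  ci_raw <- fick_cardiac_index(vo2, sao2f, svo2f, profile$hemoglobin_g_dl,
                               k_o2 = k_o2)
  if (vo2_indexed) {
    ci_v <- ci_raw
    co_v <- ci_v * profile$bsa_m2
  } else {
    co_v <- ci_raw
    ci_v <- co_v / profile$bsa_m2
  }
  svri_v <- svri(vitals$map, vitals$cvp, ci_v)
  mcfp_v <- mcfp(vitals$cvp, vitals$map, co_v)
  flow <- if (vr_flow == "co") co_v else ci_v
  rv_v <- venous_resistance(mcfp_v, vitals$cvp, flow)
  data.frame(
    time_s = vitals$time_s,
    vo2i = rep(vo2, nrow(vitals)),
    ci   = ci_v,
    co   = co_v,
    svri = svri_v,
    mcfp = mcfp_v,
    rv   = rv_v,
    coer = oxygen_extraction(vitals$sao2, vitals$cnirs),
    roer = oxygen_extraction(vitals$sao2, vitals$rnirs)
  )
}
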