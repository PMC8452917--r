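# Patient physiology and boundary-condition construction.

#' Read patient records from CSV
#'
#' Expects columns `patient_id`, `sbp`, `dbp`, `lv_mass` (one row per
#' patient); MBP is derived.
#'
#' @param path CSV file path.
#' @return A list of [patient_record()]s, named by patient id.
#' @export
read_patients <- function(path) {
  if (!file.exists(path))
    stop_coroflow("parse_error", "file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "sbp", "dbp", "lv_mass")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop_coroflow("parse_error", "%s: missing column(s) %s", path,
                  paste(miss, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    patient_record(df$sbp[i], df$dbp[i], df$lv_mass[i],
                   id = df$patient_id[i]))
  stats::setNames(out, df$patient_id)
}

#' Mean blood pressure from brachial cuff readings
#'
#' MBP = DBP + (SBP - DBP) / 3, the standard one-third pulse-pressure rule.
#'
#' @param sbp Systolic pressure (mmHg).
#' @param dbp Diastolic pressure (mmHg), strictly below `sbp`.
#' @return Mean blood pressure (mmHg). Vectorized.
#' @export
mean_blood_pressure <- function(sbp, dbp) {
  if (any(!is.finite(sbp)) || any(!is.finite(dbp)) || any(sbp <= dbp))
    stop_coroflow("domain_error", "require finite sbp > dbp")
  dbp + (sbp - dbp) / 3
}

#' Patient physiological record
#'
#' @param sbp Systolic brachial pressure (mmHg).
#' @param dbp Diastolic brachial pressure (mmHg).
#' @param lv_mass Left-ventricular myocardial mass (g).
#' @param mbp Mean pressure (mmHg); computed from `sbp`/`dbp` when omitted.
#' @param id Optional patient identifier.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(sbp, dbp, lv_mass, mbp = NULL, id = NULL) {
  if (!is.finite(lv_mass) || lv_mass <= 0)
    stop_coroflow("domain_error", "lv_mass must be positive")
  mbp <- mbp %||% mean_blood_pressure(sbp, dbp)
  structure(list(id = id, sbp = as.numeric(sbp), dbp = as.numeric(dbp),
                 mbp = as.numeric(mbp), lv_mass = as.numeric(lv_mass)),
            class = "patient_record")
}

#' Hemodynamic model parameters
#'
#' Defaults encode the physiological assumptions of the simulation:
#' Newtonian blood (density 1050 kg/m^3, viscosity 3.5 mPa s), resting total
#' coronary flow scaling with myocardial mass as `flow_coeff *
#' mass^flow_exponent` (mL/min with mass in g), hyperemic microvascular
#' resistance at 0.21 of the resting value (adenosine), inlet pressure 6.8
#' mmHg below the patient mean pressure, flow apportioned among outlets by
#' diameter to the Murray exponent, and a venous reference pressure `p0`.
#'
#' @param rho Blood density (kg/m^3).
#' @param mu Dynamic viscosity (Pa s).
#' @param flow_coeff Allometric coefficient c (mL min^-1 g^-0.75).
#' @param flow_exponent Allometric exponent of the mass-flow law.
#' @param hyperemia_factor Hyperemic/resting microvascular resistance ratio,
#'   in (0, 1].
#' @param inlet_offset Inlet pressure offset below MBP (mmHg).
#' @param murray_exponent Exponent k of the outlet-diameter flow weights.
#' @param p0 Reference (venous) pressure at the outlets (mmHg).
#' @return An object of class `hemo_params`.
#' @export
hemo_params <- function(rho = 1050, mu = 0.0035, flow_coeff = 2.6,
                        flow_exponent = 0.75, hyperemia_factor = 0.21,
                        inlet_offset = 6.8, murray_exponent = 3, p0 = 0) {
  p <- list(rho = rho, mu = mu, flow_coeff = flow_coeff,
            flow_exponent = flow_exponent, hyperemia_factor = hyperemia_factor,
            inlet_offset = inlet_offset, murray_exponent = murray_exponent,
            p0 = p0)
  if (any(!vapply(p, is.finite, logical(1))))
    stop_coroflow("domain_error", "hemo_params must all be finite")
  if (p$rho <= 0 || p$mu <= 0 || p$flow_coeff <= 0 || p$flow_exponent <= 0 ||
      p$inlet_offset < 0 || p$murray_exponent <= 0 || p$p0 < 0)
    stop_coroflow("domain_error", "hemo_params out of range")
  if (p$hyperemia_factor <= 0 || p$hyperemia_factor > 1)
    stop_coroflow("domain_error", "hyperemia_factor must be in (0, 1]")
  structure(p, class = "hemo_params")
}

#' Resting total coronary blood flow from myocardial mass
#'
#' Q_rest = c * mass^a (mL/min), the allometric perfusion law; defaults give
#' about 0.8 mL/min/g for a 114 g left ventricle.
#'
#' @param lv_mass Left-ventricular mass (g).
#' @param params A [hemo_params()] object.
#' @return Resting flow (mL/min).
#' @export
resting_flow <- function(lv_mass, params = hemo_params()) {
  if (any(!is.finite(lv_mass)) || any(lv_mass <= 0))
    stop_coroflow("domain_error", "lv_mass must be positive")
  params$flow_coeff * lv_mass^params$flow_exponent
}

#' Build inlet and outlet boundary conditions for a patient
#'
#' The inlet static pressure is set `inlet_offset` mmHg below the
#' patient-specific MBP (the systemic effect of adenosine). The hyperemic
#' flow target is `Q_rest / hyperemia_factor`. Each outlet receives a flow
#' weight proportional to its local diameter raised to the Murray exponent
#' (diameter = twice the mean of the last three radius samples), and an
#' initial downstream resistance `R_i = (P_in - p0) / Q_i*` where `Q_i*` is
#' the outlet's share of the hyperemic target. Calibration
#' ([calibrate_total_flow()]) subsequently rescales the `R_i` uniformly so
#' that total outflow matches the target through the actual (lossy)
#' geometry.
#'
#' @param tree A `coronary_tree`.
#' @param patient A [patient_record()].
#' @param params A [hemo_params()] object.
#' @return A list with `inlet_pressure` (mmHg), `bcs` (data.frame with
#'   columns `outlet_id`, `R` in mmHg min/mL, `p0` in mmHg) and
#'   `target_flow` (hyperemic total flow, mL/min).
#' @export
build_outlet_bcs <- function(tree, patient, params = hemo_params()) {
  outs <- outlet_ids(tree)
  if (length(outs) == 0L)
    stop_coroflow("topology_error", "tree has no outlets")
  p_in <- patient$mbp - params$inlet_offset
  if (p_in <= params$p0)
    stop_coroflow("domain_error",
                  "inlet pressure (%.1f mmHg) must exceed reference p0 (%.1f mmHg)",
                  p_in, params$p0)
  d <- vapply(outs, function(id) {
    r <- tree_branch(tree, id)$samples$r
    2 * mean(utils::tail(r, 3L))
  }, numeric(1))
  w <- d^params$murray_exponent
  w <- w / sum(w)
  q_rest <- resting_flow(patient$lv_mass, params)
  q_target <- q_rest / params$hyperemia_factor
  q_i <- w * q_target
  bcs <- data.frame(outlet_id = outs,
                    R = (p_in - params$p0) / q_i,
                    p0 = params$p0,
                    row.names = NULL)
  list(inlet_pressure = p_in, bcs = bcs, target_flow = q_target)
}
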