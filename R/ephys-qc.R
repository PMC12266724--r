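## Recording quality-control gates and rule-based excitatory subtype
## discrimination for intrinsic electrophysiology feature records.

#' Build an intrinsic-feature record
#'
#' @param access_resistance_MOhm,input_resistance_MOhm Access and input
#'   resistance, MOhm.
#' @param resting_Vm_mV Resting membrane potential, mV.
#' @param drift_mV Membrane-potential drift over the recording, mV.
#' @param holding_current_pA Holding current, pA.
#' @param threshold_AP_amplitude_mV Action-potential amplitude from spike
#'   onset, mV.
#' @param absolute_AP_peak_mV Absolute AP peak, mV.
#' @param adp_amplitude_mV Afterdepolarization amplitude, mV, or `NA` when
#'   absent.
#' @param amplitude_adaptation_profile Per-spike AP amplitudes normalized to
#'   the first spike (first element 1).
#' @param half_width_ms AP half-width, ms.
#' @param spiny Logical: dendritic spines in post-hoc histology (`NA` =
#'   unknown).
#' @return An `intrinsic_record` list.
#' @export
intrinsic_record <- function(access_resistance_MOhm = NA,
                             input_resistance_MOhm = NA,
                             resting_Vm_mV = NA, drift_mV = NA,
                             holding_current_pA = NA,
                             threshold_AP_amplitude_mV = NA,
                             absolute_AP_peak_mV = NA,
                             adp_amplitude_mV = NA,
                             amplitude_adaptation_profile = numeric(0),
                             half_width_ms = NA, spiny = NA) {
  prof <- amplitude_adaptation_profile
  if (length(prof) > 0 && abs(prof[1] - 1) > 1e-9) {
    stop("adaptation profile must be normalized to the first spike",
         call. = FALSE)
  }
  structure(list(
    access_resistance_MOhm = access_resistance_MOhm,
    input_resistance_MOhm = input_resistance_MOhm,
    resting_Vm_mV = resting_Vm_mV, drift_mV = drift_mV,
    holding_current_pA = holding_current_pA,
    threshold_AP_amplitude_mV = threshold_AP_amplitude_mV,
    absolute_AP_peak_mV = absolute_AP_peak_mV,
    adp_amplitude_mV = adp_amplitude_mV,
    amplitude_adaptation_profile = prof,
    half_width_ms = half_width_ms, spiny = spiny
  ), class = "intrinsic_record")
}

#' Recording quality-control gate
#'
#' A recording passes when all criteria hold, with strict inequalities
#' exactly as stated (boundary values fail): access resistance < 35 MOhm *or*
#' < 20% of input resistance; resting Vm < -50 mV; |drift| < 10 mV; threshold
#' AP amplitude > 50 mV; absolute AP peak > 0 mV; |holding current| < 30 pA.
#' A missing field makes its criterion unevaluable and fails the gate with a
#' `missing:` reason.
#'
#' @param record An [intrinsic_record()].
#' @return List with `pass` (logical) and `failed_criteria` (character,
#'   empty iff `pass`).
#' @export
#' @examples
#' qc_gate(intrinsic_record(40, 150, -60, 2, 10, 60, 20))$failed_criteria
qc_gate <- function(record) {
  stopifnot(inherits(record, "intrinsic_record"))
  failed <- character(0)
  crit <- function(value_names, ok, label) {
    vals <- unlist(record[value_names])
    if (anyNA(vals)) {
      failed <<- c(failed, paste0("missing:", label))
    } else if (!ok(vals)) {
      failed <<- c(failed, label)
    }
  }
  crit(c("access_resistance_MOhm", "input_resistance_MOhm"),
       function(v) v[1] < 35 || v[1] < 0.2 * v[2], "access_resistance")
  crit("resting_Vm_mV", function(v) v < -50, "resting_Vm")
  crit("drift_mV", function(v) abs(v) < 10, "Vm_drift")
  crit("threshold_AP_amplitude_mV", function(v) v > 50, "AP_amplitude")
  crit("absolute_AP_peak_mV", function(v) v > 0, "AP_peak")
  crit("holding_current_pA", function(v) abs(v) < 30, "holding_current")
  list(pass = length(failed) == 0, failed_criteria = failed)
}

#' Excitatory subtype from the amplitude-adaptation profile
#'
#' E1 cells show a monophasic (monotonically declining) spike-amplitude
#' profile and no afterdepolarization; E2 cells show a biphasic profile — an
#' initial decline followed by recovery above the running minimum — or an
#' ADP. Amplitude recoveries of at most `tolerance` (fraction of the
#' first-spike amplitude, default 2%) do not count as biphasic. Profiles with
#' fewer than three spikes are indeterminate.
#'
#' @param record An [intrinsic_record()].
#' @param tolerance Recovery tolerance as a fraction of the first-spike
#'   amplitude.
#' @return `"E1"`, `"E2"` or `"indeterminate"`.
#' @export
#' @examples
#' classify_excitatory_subtype(
#'   intrinsic_record(amplitude_adaptation_profile = c(1, 0.6, 0.65, 0.7)))
classify_excitatory_subtype <- function(record, tolerance = 0.02) {
  stopifnot(inherits(record, "intrinsic_record"))
  prof <- record$amplitude_adaptation_profile
  if (length(prof) < 3) return("indeterminate")
  has_adp <- !is.na(record$adp_amplitude_mV) && record$adp_amplitude_mV > 0
  biphasic <- FALSE
  run_min <- prof[1]
  for (i in 2:length(prof)) {
    if (prof[i] - run_min > tolerance * prof[1]) {
      biphasic <- TRUE
      break
    }
    run_min <- min(run_min, prof[i])
  }
  if (biphasic || has_adp) "E2" else "E1"
}

#' Excitatory/inhibitory call from intrinsic and histological criteria
#'
#' Scores the evaluable criteria — spiny dendrites, AP half-width >= 1.0 ms,
#' input resistance within 200–500 MOhm — toward the excitatory phenotype;
#' the majority of evaluable criteria decides, with ties or no evaluable
#' criterion giving `"unknown"`.
#'
#' @param record An [intrinsic_record()].
#' @return `"excitatory"`, `"inhibitory"` or `"unknown"`.
#' @export
classify_ei <- function(record) {
  stopifnot(inherits(record, "intrinsic_record"))
  votes <- c(
    spines = if (is.na(record$spiny)) NA else as.logical(record$spiny),
    half_width = if (is.na(record$half_width_ms)) NA
                 else record$half_width_ms >= 1.0,
    input_resistance = if (is.na(record$input_resistance_MOhm)) NA
                       else record$input_resistance_MOhm >= 200 &&
                            record$input_resistance_MOhm <= 500
  )
  votes <- votes[!is.na(votes)]
  if (length(votes) == 0) return("unknown")
  n_exc <- sum(votes)
  n_inh <- sum(!votes)
  if (n_exc > n_inh) "excitatory" else if (n_inh > n_exc) "inhibitory"
  else "unknown"
}

#' QC and subtype calls for a feature table
#'
#' Applies [qc_gate()], [classify_ei()] and [classify_excitatory_subtype()]
#' to each row of a feature table (columns named as in
#' [intrinsic_record()]; `amplitude_adaptation_profile` as a
#' semicolon-joined string).
#'
#' @param features Data frame, one row per cell.
#' @return Data frame with `cell`, `qc_pass`, `qc_reasons`, `ei_class`,
#'   `subtype`.
#' @export
qc_feature_table <- function(features) {
  out <- data.frame(cell = seq_len(nrow(features)), qc_pass = NA,
                    qc_reasons = "", ei_class = "", subtype = "")
  for (i in seq_len(nrow(features))) {
    row <- features[i, ]
    prof <- numeric(0)
    if (!is.null(row$amplitude_adaptation_profile) &&
        !is.na(row$amplitude_adaptation_profile) &&
        nzchar(row$amplitude_adaptation_profile)) {
      prof <- as.numeric(strsplit(row$amplitude_adaptation_profile, ";")[[1]])
    }
    rec <- intrinsic_record(
      access_resistance_MOhm = row$access_resistance_MOhm %||% NA,
      input_resistance_MOhm = row$input_resistance_MOhm %||% NA,
      resting_Vm_mV = row$resting_Vm_mV %||% NA,
      drift_mV = row$drift_mV %||% NA,
      holding_current_pA = row$holding_current_pA %||% NA,
      threshold_AP_amplitude_mV = row$threshold_AP_amplitude_mV %||% NA,
      absolute_AP_peak_mV = row$absolute_AP_peak_mV %||% NA,
      adp_amplitude_mV = row$adp_amplitude_mV %||% NA,
      amplitude_adaptation_profile = prof,
      half_width_ms = row$half_width_ms %||% NA,
      spiny = row$spiny %||% NA
    )
    g <- qc_gate(rec)
    out$qc_pass[i] <- g$pass
    out$qc_reasons[i] <- paste(g$failed_criteria, collapse = ";")
    out$ei_class[i] <- classify_ei(rec)
    out$subtype[i] <- classify_excitatory_subtype(rec)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
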