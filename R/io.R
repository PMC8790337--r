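# File interchange: pressure-trace CSVs with metadata sidecars, plate
# CSVs, and YAML transport parameter files.

#' Write a perfusion trace CSV with metadata sidecar
#'
#' Columns `time_min`, `pressure_mmHg`; the sidecar `<path>.yaml` carries
#' `eye_id`, `species` and `flow_ul_min`.
#'
#' @param record a [perfusion_record()].
#' @param path output CSV path.
#' @param sidecar also write the YAML sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(record, path, sidecar = TRUE) {
  stopifnot(inherits(record, "perfusion_record"))
  utils::write.csv(data.frame(time_min = record$times,
                              pressure_mmHg = record$pressures),
                   path, row.names = FALSE)
  if (sidecar) {
    yaml::write_yaml(list(eye_id = record$eye_id, species = record$species,
                          flow_ul_min = record$flow_rate),
                     paste0(path, ".yaml"))
  }
  invisible(path)
}

#' Read a perfusion trace CSV
#'
#' Accepts either a calibrated trace (`time_min`, `pressure_mmHg`) or a
#' raw one (`time_min`, `voltage_V`) together with a
#' [calibrate_transducer()] curve. Metadata comes from the `<path>.yaml`
#' sidecar when present, overridable by arguments.
#'
#' @param path CSV path.
#' @param calibration optional `calibration_curve` for raw voltage traces.
#' @param eye_id,species,flow_ul_min metadata overrides.
#' @return a [perfusion_record()].
#' @export
read_trace_csv <- function(path, calibration = NULL, eye_id = NULL,
                           species = NULL, flow_ul_min = NULL) {
  df <- utils::read.csv(path)
  if (!"time_min" %in% names(df)) stopf("trace CSV must have a time_min column")
  meta <- list()
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) meta <- yaml::read_yaml(sidecar)
  eye_id <- eye_id %||% meta$eye_id %||% basename(path)
  species <- species %||% meta$species %||% "pig"
  flow_ul_min <- flow_ul_min %||% meta$flow_ul_min %||%
    stopf("flow rate missing: supply flow_ul_min or a sidecar")
  pressures <- if ("pressure_mmHg" %in% names(df)) {
    df$pressure_mmHg
  } else if ("voltage_V" %in% names(df)) {
    if (is.null(calibration)) stopf("raw voltage trace needs a calibration curve")
    predict(calibration, df$voltage_V)
  } else stopf("trace CSV must have pressure_mmHg or voltage_V")
  perfusion_record(eye_id, species, flow_ul_min, df$time_min, pressures)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a plate CSV
#'
#' Long-format plate table: `well`, `channel`, `reading_au`, `role`
#' (`"standard"` or `"sample"`), `known_concentration` (standards only),
#' `eye_id` and `time_h` (samples only).
#'
#' @param plate data frame in the plate layout.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(plate, path) {
  needed <- c("well", "channel", "reading_au", "role")
  stopifnot(is.data.frame(plate), all(needed %in% names(plate)))
  utils::write.csv(plate, path, row.names = FALSE)
  invisible(path)
}

#' Read a plate CSV
#' @param path CSV path.
#' @return data frame in the plate layout.
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path)
  needed <- c("well", "channel", "reading_au", "role")
  if (!all(needed %in% names(df))) {
    stopf("plate CSV must have columns %s", paste(needed, collapse = ", "))
  }
  df
}

#' Quantify a plate table
#'
#' Fits a standard curve per channel from the `standard` rows and inverts
#' the `sample` rows to concentrations.
#'
#' @param plate plate data frame (see [read_plate_csv()]).
#' @return list with `curves` (per channel [fit_standard_curve()]) and
#'   `samples` (sample rows with `concentration` and `below_background`
#'   columns added).
#' @export
quantify_plate <- function(plate) {
  channels <- unique(plate$channel)
  curves <- list()
  out <- list()
  for (ch in channels) {
    std <- plate[plate$role == "standard" & plate$channel == ch, , drop = FALSE]
    smp <- plate[plate$role == "sample" & plate$channel == ch, , drop = FALSE]
    if (nrow(std) < 3) stopf("channel %s: need >= 3 standards", ch)
    curves[[ch]] <- fit_standard_curve(std$known_concentration, std$reading_au,
                                       channel = ch)
    if (nrow(smp)) {
      conc <- reading_to_concentration(curves[[ch]], smp$reading_au)
      smp$concentration <- as.numeric(conc)
      smp$below_background <- attr(conc, "below_background")
      out[[ch]] <- smp
    }
  }
  samples <- if (length(out)) do.call(rbind, out) else
    plate[0, , drop = FALSE]
  rownames(samples) <- NULL
  list(curves = curves, samples = samples)
}

#' Read a transport parameter file
#'
#' Flat key-value YAML with keys `f`, `R0_cm`, `kappa`, and either `a_cm`
#' or `injection_volume_ul`, and either `P0_dyn_cm2` or
#' `injection_volume_ul` (+ optional `rigidity_mmHg_per_ul`).
#'
#' @param path YAML path.
#' @return a [poroelastic_params()].
#' @export
read_transport_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  poroelastic_params(
    f = cfg$f %||% 1,
    R0 = cfg$R0_cm %||% 1.2,
    kappa = cfg$kappa %||% 8.4e-8,
    a = cfg$a_cm,
    P0 = cfg$P0_dyn_cm2,
    injection_volume_ul = cfg$injection_volume_ul,
    rigidity_mmhg_per_ul = cfg$rigidity_mmHg_per_ul %||% 1)
}
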