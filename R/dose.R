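#' Weight-adapted tube voltage selection
#'
#' The acquisition protocol selects the tube voltage from the patient's
#' body weight: 80 kV up to and including 70 kg, 100 kV above 70 up to and
#' including 80 kg, and 120 kV above 80 kg.
#'
#' @param weight patient body weight in kg (vectorized, all > 0).
#' @return Tube voltage(s) in kV, one of 80, 100, 120.
#' @export
select_kv <- function(weight) {
  if (!is.numeric(weight) || any(!is.finite(weight)) || any(weight <= 0))
    stop("`weight` must be positive", call. = FALSE)
  ifelse(weight <= 70, 80, ifelse(weight <= 80, 100, 120))
}

#' Dose-length product
#'
#' `DLP = CTDIvol * scan length`. Cohort-level calculations use a fixed
#' median scan length of 25 cm so exams remain comparable across
#' protocols.
#'
#' @param ctdi_vol volume CT dose index in mGy (>= 0, vectorized).
#' @param scan_length scan length in cm (>= 0, default 25).
#' @return DLP in mGy*cm.
#' @export
dlp <- function(ctdi_vol, scan_length = 25) {
  if (any(!is.finite(ctdi_vol)) || any(ctdi_vol < 0))
    stop("`ctdi_vol` must be >= 0", call. = FALSE)
  if (any(!is.finite(scan_length)) || any(scan_length < 0))
    stop("`scan_length` must be >= 0", call. = FALSE)
  ctdi_vol * scan_length
}

#' Effective dose from DLP
#'
#' `E = DLP * k` with the ICRP anatomical conversion factor; the default
#' `k = 0.0058` mSv/(mGy*cm) is the head-and-neck factor.
#'
#' @param dlp dose-length product in mGy*cm (>= 0, vectorized).
#' @param k_factor conversion factor in mSv/(mGy*cm).
#' @return Effective dose in mSv (full precision; reports round to 2
#'   decimals).
#' @export
effective_dose <- function(dlp, k_factor = 0.0058) {
  if (any(!is.finite(dlp)) || any(dlp < 0))
    stop("`dlp` must be >= 0", call. = FALSE)
  dlp * k_factor
}

#' Percent dose reduction against a reference
#'
#' `100 * (1 - reduced / reference)`; negative when the "reduced" dose
#' exceeds the reference. Reports round to 1 decimal.
#'
#' @param reference reference dose (> 0).
#' @param reduced compared dose (>= 0).
#' @return Reduction in percent.
#' @export
percent_reduction <- function(reference, reduced) {
  if (any(!is.finite(reference)) || any(reference <= 0))
    stop("`reference` must be > 0", call. = FALSE)
  100 * (1 - reduced / reference)
}

#' Read exam dose records from CSV
#'
#' Expected columns: `patient_id`, `weight_kg`, `kv`, `ctdi_vol_mgy`,
#' optional `scan_length_cm` (missing values default to 25 cm with a
#' message) and optional `protocol_label`. The returned table is augmented
#' with the derived chain (`dlp`, `effective_dose`), the protocol-expected
#' tube voltage `kv_expected = select_kv(weight)` and a
#' `protocol_deviation` flag where the recorded kV disagrees.
#'
#' @param path CSV file path.
#' @param k_factor effective-dose conversion factor (default 0.0058).
#' @return A `data.frame` of augmented dose records.
#' @examples
#' exams <- system.file("extdata", "example_exams.csv", package = "ctiq")
#' cohort_summary(read_dose_records(exams))
#' @export
read_dose_records <- function(path, k_factor = 0.0058) {
  if (!file.exists(path)) stop("dose CSV not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("weight_kg", "ctdi_vol_mgy")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("dose CSV is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!nrow(df)) stop("dose CSV has no records", call. = FALSE)
  if (is.null(df$scan_length_cm)) df$scan_length_cm <- NA_real_
  n_default <- sum(is.na(df$scan_length_cm))
  if (n_default) {
    message(n_default, " record(s) without scan length; using 25 cm")
    df$scan_length_cm[is.na(df$scan_length_cm)] <- 25
  }
  if (is.null(df$protocol_label)) df$protocol_label <- "all"
  augment_dose_records(df, k_factor)
}

#' @rdname read_dose_records
#' @param records data.frame with at least `weight_kg` and `ctdi_vol_mgy`
#'   (plus optional `kv`, `scan_length_cm`, `protocol_label`).
#' @export
augment_dose_records <- function(records, k_factor = 0.0058) {
  if (!nrow(records)) stop("no dose records", call. = FALSE)
  records$scan_length_cm <- records$scan_length_cm %||% 25
  records$dlp <- dlp(records$ctdi_vol_mgy, records$scan_length_cm)
  records$effective_dose <- effective_dose(records$dlp, k_factor)
  records$k_factor <- k_factor
  records$kv_expected <- select_kv(records$weight_kg)
  if (!is.null(records$kv)) {
    records$protocol_deviation <- records$kv != records$kv_expected
  } else {
    records$protocol_deviation <- FALSE
  }
  records
}

#' Cohort dose summary
#'
#' Per-protocol mean and standard deviation of CTDIvol, DLP and effective
#' dose (mean +/- SD reporting convention), with the number of records
#' whose recorded kV deviates from the weight-adapted rule.
#'
#' @param records augmented dose records, see [read_dose_records()] /
#'   [augment_dose_records()].
#' @return A `data.frame` with one row per protocol label.
#' @export
cohort_summary <- function(records) {
  if (is.null(records) || !nrow(records))
    stop("no dose records to summarize", call. = FALSE)
  if (is.null(records$dlp)) records <- augment_dose_records(records)
  lab <- records$protocol_label %||% rep("all", nrow(records))
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  out <- do.call(rbind, lapply(split(records, lab), function(g) {
    data.frame(protocol = g$protocol_label[1L] %||% "all",
               n = nrow(g),
               ctdi_vol_mean = mean(g$ctdi_vol_mgy),
               ctdi_vol_sd = sd0(g$ctdi_vol_mgy),
               dlp_mean = mean(g$dlp),
               dlp_sd = sd0(g$dlp),
               effective_dose_mean = round(mean(g$effective_dose), 2),
               effective_dose_sd = round(sd0(g$effective_dose), 2),
               n_protocol_deviation = sum(g$protocol_deviation))
  }))
  rownames(out) <- NULL
  out
}
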