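#' Baseline imputation of masked ECG samples
#'
#' Reference imputations the learned reconstructors are compared against:
#' `"zero"` leaves masked entries at zero; `"linear"` interpolates each lead
#' linearly in time across its gaps (constant extrapolation at the record
#' edges).
#'
#' @param record an [ecg_record()] with masked entries zeroed.
#' @param mask binary observation mask.
#' @param method `"linear"` or `"zero"`.
#' @return The imputed [ecg_record()].
#' @export
impute_baseline <- function(record, mask, method = c("linear", "zero")) {
  method <- match.arg(method)
  out <- record$signal
  if (method == "linear") {
    for (l in seq_len(ncol(out))) {
      obs <- which(mask[, l] == 1)
      mis <- which(mask[, l] == 0)
      if (length(mis) == 0) next
      if (length(obs) < 2) {
        out[mis, l] <- if (length(obs)) out[obs[1], l] else 0
        next
      }
      out[mis, l] <- stats::approx(obs, out[obs, l], xout = mis,
                                   rule = 2)$y
    }
  }
  ecg_record(out, record$fs, record$lead_names, record$patient_id,
             record$label, normalized = record$normalized,
             scale_info = record$scale_info)
}
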