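#' Average daily gain (g/day)
#'
#' @param bw_start,bw_end body weights (g) at the start and end of the
#'   interval.
#' @param days interval length in days (> 0).
#' @export
compute_adg <- function(bw_start, bw_end, days) {
  if (any(days <= 0)) stop("days must be positive")
  (bw_end - bw_start) / days
}

#' Feed conversion ratio
#'
#' Total feed intake divided by weight gain over the interval.  Records
#' with zero or negative gain are returned as `NA` with a warning (they are
#' excluded from downstream analyses).
#'
#' @param feed_intake_total total feed intake over the interval (g).
#' @inheritParams compute_adg
#' @export
compute_fcr <- function(feed_intake_total, bw_start, bw_end) {
  gain <- bw_end - bw_start
  bad <- gain <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with nonpositive gain set to NA")
    gain[bad] <- NA_real_
  }
  feed_intake_total / gain
}

#' Residual feed intake by linear regression
#'
#' Regresses daily feed intake on metabolic mid-body-weight and average
#' daily gain, \eqn{FI_i = \mu + \alpha\, midBW_i^{0.75} + \beta\, ADG_i +
#' RFI_i}, where \eqn{midBW} is the arithmetic mean of the start and end
#' weights and FI is expressed in g/day.  RFI is the OLS residual (mean
#' zero, orthogonal to both regressors).
#'
#' @param records data frame with columns `bw_start`, `bw_end`, `days`,
#'   `feed_intake_total` (and optionally `animal_id`).
#' @param exponent metabolic body-weight exponent (default 0.75).
#' @return object of class `rfi_fit`: list with `mu`, `alpha`, `beta`,
#'   `rfi` (named residuals, g/day), `fitted`, `model` (the `lm` fit).
#' @export
compute_rfi <- function(records, exponent = 0.75) {
  stopifnot(all(c("bw_start", "bw_end", "days", "feed_intake_total")
                %in% names(records)))
  if (nrow(records) < 3) stop("at least 3 records are needed to fit RFI")
  fi <- records$feed_intake_total / records$days
  midbw <- ((records$bw_start + records$bw_end) / 2)^exponent
  adg <- compute_adg(records$bw_start, records$bw_end, records$days)
  X <- cbind(1, midbw, adg)
  qx <- qr(X)
  if (qx$rank < 3) {
    kappa_x <- kappa(X)
    stop("collinear RFI regressors (condition number ",
         format(kappa_x, digits = 4), ")")
  }
  fit <- stats::lm(fi ~ midbw + adg)
  rfi <- stats::residuals(fit)
  names(rfi) <- if ("animal_id" %in% names(records))
    as.character(records$animal_id) else as.character(seq_along(rfi))
  structure(list(mu = unname(stats::coef(fit)[1]),
                 alpha = unname(stats::coef(fit)[2]),
                 beta = unname(stats::coef(fit)[3]),
                 rfi = rfi, fitted = stats::fitted(fit), model = fit),
            class = "rfi_fit")
}

#' Outlier mask by the median absolute deviation rule
#'
#' Keeps value v iff \eqn{|v - \mathrm{median}| \le k \cdot MAD}, with the
#' raw (unscaled) MAD \eqn{= \mathrm{median}(|v - \mathrm{median}|)}.  A
#' zero MAD (e.g. constant data) keeps every value.  `NA`s are kept as
#' `NA` in the mask.
#'
#' @param values numeric vector (at least one finite value).
#' @param k multiplier (default 3.5).
#' @param scaled if `TRUE` use the normal-consistent MAD (x 1.4826);
#'   default `FALSE`, the literal median absolute deviation.
#' @return logical keep-mask of the same length as `values`.
#' @export
mad_outlier_filter <- function(values, k = 3.5, scaled = FALSE) {
  if (!any(is.finite(values))) stop("no finite values")
  med <- stats::median(values, na.rm = TRUE)
  mad_raw <- stats::median(abs(values - med), na.rm = TRUE)
  if (scaled) mad_raw <- mad_raw * 1.4826
  if (mad_raw == 0) return(ifelse(is.na(values), NA, TRUE))
  abs(values - med) <= k * mad_raw
}

#' Derive growth and feed-efficiency traits from raw records
#'
#' Computes ADG, FCR and RFI for one age interval, applying the MAD
#' outlier rule to each input trait (FI, weights, ADG) before the RFI
#' regression and then to RFI itself, mirroring per-trait outlier removal.
#'
#' @inheritParams compute_rfi
#' @param mad_k MAD multiplier for outlier removal; `Inf` disables it.
#' @return data frame with `animal_id`, `adg`, `fcr`, `rfi` (NA where the
#'   record was filtered or invalid).
#' @export
derive_traits <- function(records, mad_k = 3.5, exponent = 0.75) {
  ids <- as.character(records$animal_id)
  adg <- compute_adg(records$bw_start, records$bw_end, records$days)
  fcr <- suppressWarnings(
    compute_fcr(records$feed_intake_total, records$bw_start, records$bw_end))
  fi <- records$feed_intake_total / records$days
  keep <- !is.na(fcr)
  if (is.finite(mad_k)) {
    for (v in list(fi, records$bw_start, records$bw_end, adg))
      keep <- keep & mad_outlier_filter(v, mad_k) %in% TRUE
  }
  rfi <- rep(NA_real_, nrow(records))
  if (sum(keep) >= 3) {
    fit <- compute_rfi(records[keep, , drop = FALSE], exponent = exponent)
    rfi[keep] <- fit$rfi
    if (is.finite(mad_k)) {
      ok <- mad_outlier_filter(rfi[keep], mad_k) %in% TRUE
      rfi[keep][!ok] <- NA_real_
    }
  }
  adg_out <- ifelse(is.finite(mad_k) & !mad_outlier_filter(adg, mad_k) %in% TRUE,
                    NA_real_, adg)
  fcr_out <- fcr
  if (is.finite(mad_k)) {
    fbad <- !is.na(fcr) & !(mad_outlier_filter(fcr, mad_k) %in% TRUE)
    fcr_out[fbad] <- NA_real_
  }
  data.frame(animal_id = ids, adg = adg_out, fcr = fcr_out, rfi = rfi,
             stringsAsFactors = FALSE)
}
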