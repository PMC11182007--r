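# Reporter-assay quantification: Miller units and heat induction profiles.
#
# The Miller-unit convention is the standard
#   1000 * (A420 - 1.75 * A550) / (time_min * volume_mL * OD600)
# with both coefficients configurable, since protocol variants differ.
# Heat induction is the ratio of mean Miller units at an elevated
# temperature to the mean at the reference temperature (25 C by default),
# with the ratio's standard error by first-order propagation.

#' Compute Miller units for one measurement
#'
#' @param m a list/row with fields `construct_id`, `temperature`,
#'   `replicate`, `A420`, `A550` (optional, default 0), `OD600`, `time`
#'   (minutes), `volume` (mL).
#' @param correction A550 scattering correction coefficient (default 1.75).
#' @param scale overall scale (default 1000).
#' @return a list of class `miller_result` with `construct_id`,
#'   `temperature`, `replicate`, `miller_units`.
#' @export
miller_units <- function(m, correction = 1.75, scale = 1000) {
  a550 <- m$A550 %||% 0
  if (is.na(a550)) a550 <- 0
  if (!is.finite(m$OD600) || m$OD600 <= 0)
    ts_error("bad_measurement", "OD600 must be positive")
  if (!is.finite(m$time) || m$time <= 0)
    ts_error("bad_measurement", "time must be positive")
  if (!is.finite(m$volume) || m$volume <= 0)
    ts_error("bad_measurement", "volume must be positive")
  mu <- scale * (m$A420 - correction * a550) / (m$time * m$volume * m$OD600)
  structure(list(construct_id = m$construct_id, temperature = m$temperature,
                 replicate = m$replicate, miller_units = mu),
            class = "miller_result")
}

#' Compute Miller units for a table of measurements
#'
#' @param df data.frame with columns `construct_id`, `temperature_C`,
#'   `replicate`, `A420`, `A550`, `OD600`, `time_min`, `volume_mL` (the
#'   assay CSV schema; `A550` may be absent).
#' @inheritParams miller_units
#' @return data.frame with `construct_id`, `temperature`, `replicate`,
#'   `miller_units`.
#' @export
miller_units_table <- function(df, correction = 1.75, scale = 1000) {
  need <- c("construct_id", "temperature_C", "replicate", "A420", "OD600",
            "time_min", "volume_mL")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    ts_error("bad_measurement",
             sprintf("assay table lacks column(s): %s",
                     paste(missing, collapse = ", ")))
  if (is.null(df$A550)) df$A550 <- 0
  out <- lapply(seq_len(nrow(df)), function(i)
    miller_units(list(construct_id = df$construct_id[i],
                      temperature = df$temperature_C[i],
                      replicate = df$replicate[i], A420 = df$A420[i],
                      A550 = df$A550[i], OD600 = df$OD600[i],
                      time = df$time_min[i], volume = df$volume_mL[i]),
                 correction = correction, scale = scale))
  data.frame(construct_id = vapply(out, `[[`, character(1), "construct_id"),
             temperature = vapply(out, function(x) as.numeric(x$temperature),
                                  numeric(1)),
             replicate = vapply(out, function(x) as.integer(x$replicate),
                                integer(1)),
             miller_units = vapply(out, `[[`, numeric(1), "miller_units"),
             stringsAsFactors = FALSE)
}

#' Heat induction profile of a construct
#'
#' Per-temperature mean and SD of Miller units over replicates, and the
#' induction ratio mean(T) / mean(reference) with its standard error by
#' first-order (delta-method) propagation:
#' `se_r = r * sqrt((se_T/mean_T)^2 + (se_ref/mean_ref)^2)`.
#'
#' Because replicate counts are small (triplicates in the usual design),
#' the relative variance is pooled across temperatures before propagation:
#' reporter noise is multiplicative (approximately constant CV), so every
#' temperature estimates the same relative variance and pooling gives the
#' SE more degrees of freedom than the 2 available per temperature.
#'
#' @param results data.frame with columns `construct_id`, `temperature`,
#'   `replicate`, `miller_units` (see [miller_units_table()]), for a
#'   single construct.
#' @param reference_temp reference temperature in degrees C (default 25).
#' @return an object of class `heat_induction_profile`: `construct_id`,
#'   `temperatures`, `mean_mu`, `sd_mu`, `n`, `induction`, `induction_se`,
#'   `reference_temp`. `induction[as.character(reference_temp)]` is 1.
#' @export
heat_induction_profile <- function(results, reference_temp = 25) {
  if (length(unique(results$construct_id)) > 1L)
    ts_error("bad_measurement",
             "heat_induction_profile expects a single construct")
  temps <- sort(unique(results$temperature))
  if (!(reference_temp %in% temps))
    ts_error("missing_reference",
             sprintf("no measurements at reference temperature %g", reference_temp))
  stat <- function(t) {
    x <- results$miller_units[results$temperature == t]
    c(mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else 0,
      n = length(x))
  }
  st <- vapply(temps, stat, numeric(3))
  colnames(st) <- as.character(temps)
  m_ref <- st["mean", as.character(reference_temp)]
  if (m_ref == 0)
    ts_error("missing_reference", "reference-temperature mean is zero")
  induction <- st["mean", ] / m_ref
  # pooled relative variance (constant-CV noise model)
  df_t <- st["n", ] - 1
  relvar <- ifelse(st["mean", ] != 0, (st["sd", ] / st["mean", ])^2, 0)
  pooled <- if (sum(df_t) > 0) sum(df_t * relvar) / sum(df_t) else 0
  se_rel <- sqrt(pooled / st["n", ])
  se_rel_ref <- se_rel[[as.character(reference_temp)]]
  induction_se <- abs(induction) * sqrt(se_rel^2 + se_rel_ref^2)
  induction_se[as.character(reference_temp)] <- 0
  structure(list(construct_id = results$construct_id[1],
                 temperatures = temps,
                 mean_mu = st["mean", ], sd_mu = st["sd", ],
                 n = as.integer(st["n", ]),
                 induction = induction, induction_se = induction_se,
                 reference_temp = reference_temp),
            class = "heat_induction_profile")
}

#' @export
print.heat_induction_profile <- function(x, ...) {
  cat(sprintf("heat induction profile for %s (reference %g C)\n",
              x$construct_id, x$reference_temp))
  for (t in as.character(x$temperatures))
    cat(sprintf("  %5s C: %8.1f +/- %.1f M.U. (n=%d)  induction %.2f-fold (se %.2f)\n",
                t, x$mean_mu[[t]], x$sd_mu[[t]], x$n[[which(as.character(x$temperatures) == t)]],
                x$induction[[t]], x$induction_se[[t]]))
  invisible(x)
}

#' Classify a construct as a thermometer or not
#'
#' A construct is called a thermometer when its maximal induction over
#' non-reference temperatures reaches the fold threshold; when a negative
#' control profile is supplied the induction must also exceed the
#' negative control's at the same temperature.
#'
#' @param profile a [heat_induction_profile()].
#' @param threshold fold-change threshold (default 2.0).
#' @param controls optional list with elements `negative` and/or
#'   `positive`, each a `heat_induction_profile`.
#' @return `"thermometer"` or `"no_induction"`.
#' @export
classify_construct <- function(profile, threshold = 2.0, controls = NULL) {
  temps <- as.character(profile$temperatures)
  temps <- temps[temps != as.character(profile$reference_temp)]
  if (length(temps) == 0L) return("no_induction")
  ok <- vapply(temps, function(t) {
    ind <- profile$induction[[t]]
    if (ind < threshold) return(FALSE)
    neg <- controls$negative
    if (!is.null(neg) && t %in% as.character(neg$temperatures) &&
        ind <= neg$induction[[t]]) return(FALSE)
    TRUE
  }, logical(1))
  if (any(ok)) "thermometer" else "no_induction"
}
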