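#' Mean threshold ratio between two waveforms
#'
#' Ratios are formed per matched (subject, carrier, AMF) record and then
#' summarized as mean +/- SEM over the pooled set of pairs ("on average
#' across frequencies"). `pooling = "frequency_means"` instead averages
#' within frequency first and summarizes over the per-frequency means.
#'
#' @param data A threshold table containing both waveforms.
#' @param numerator,denominator Waveform labels.
#' @param pooling `"pairs"` (default) or `"frequency_means"`.
#' @return A list with `mean`, `sem`, `n`, and the per-pair `ratios`.
#' @export
threshold_ratios <- function(data, numerator, denominator,
                             pooling = c("pairs", "frequency_means")) {
  pooling <- match.arg(pooling)
  for (w in c(numerator, denominator))
    if (!any(data$waveform == w))
      stop(sprintf("waveform '%s' is absent from the data", w))
  num <- data[data$waveform == numerator, ]
  den <- data[data$waveform == denominator, ]
  key <- function(d) paste(d$subject, d$carrier_hz, d$amf_hz, sep = "\r")
  m <- match(key(num), key(den))
  ok <- !is.na(m)
  if (!any(ok))
    stop("no matched (subject, frequency) pairs between the two waveforms")
  ratios <- num$threshold_ma[ok] / den$threshold_ma[m[ok]]
  carrier <- num$carrier_hz[ok]
  if (pooling == "frequency_means") {
    ratios <- as.numeric(tapply(ratios, carrier, mean))
  }
  n <- length(ratios)
  list(mean = mean(ratios),
       sem = if (n > 1) stats::sd(ratios) / sqrt(n) else 0,
       n = n, ratios = ratios, pooling = pooling)
}

#' Normalize an AMF threshold curve per subject
#'
#' Divides each subject's thresholds by that subject's minimum threshold
#' (i / i_min), then averages the normalized values across subjects per
#' AMF. Because different subjects reach their minima at different AMFs,
#' the averaged curve generally stays above 1 everywhere.
#'
#' @param data A threshold table from an AMF design; every subject needs
#'   at least 2 AMF points.
#' @return A data frame with `amf_hz`, `mean_i_over_imin`, `sem`, `n`.
#' @export
normalize_amf_curve <- function(data) {
  counts <- table(data$subject)
  if (any(counts < 2))
    stop("every subject needs at least 2 AMF points: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  imin <- tapply(data$threshold_ma, data$subject, min)
  norm <- data$threshold_ma / as.numeric(imin[as.character(data$subject)])
  agg <- aggregate(norm, list(amf_hz = data$amf_hz),
                   function(v) c(mean = mean(v),
                                 sem = if (length(v) > 1)
                                   stats::sd(v) / sqrt(length(v)) else 0,
                                 n = length(v)))
  out <- data.frame(amf_hz = agg$amf_hz, mean_i_over_imin = agg$x[, "mean"],
                    sem = agg$x[, "sem"], n = agg$x[, "n"])
  out[order(out$amf_hz), ]
}

#' Run a complete synthetic threshold study
#'
#' Generates a strength-frequency dataset from the configuration, fits
#' the Reilly equation to the pooled per-waveform mean log thresholds,
#' computes threshold ratios of every waveform against the unmodulated
#' sine, and (optionally) generates and normalizes an AMF design. The
#' report is a pure function of the configuration (and its seed).
#'
#' @param config A [study_config()].
#' @param amf_hz Optional AMF grid; if non-NULL an AMF design is also
#'   generated and normalized.
#' @return An object of class `study_report` with elements `fits`
#'   (per-waveform I0 and R^2), `ratios` (vs sine), `amf_curve` (or NULL),
#'   `data`, `amf_data`, and `provenance`.
#' @export
run_study <- function(config, amf_hz = NULL) {
  stopifnot(inherits(config, "study_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  data <- stage("generate", generate_sf_dataset(config))

  fits <- stage("fit", {
    out <- list()
    for (w in config$waveforms) {
      sub <- data[data$waveform == w, ]
      mu <- aggregate(log(sub$threshold_ma),
                      list(carrier_hz = sub$carrier_hz), mean)
      fit <- fit_reilly(data.frame(carrier_hz = mu$carrier_hz,
                                   threshold_ma = exp(mu$x)))
      out[[w]] <- list(i0 = fit$params$i0, r_squared = fit$r_squared)
    }
    out
  })

  ratios <- stage("ratios", {
    out <- list()
    for (w in setdiff(config$waveforms, "sine")) {
      r <- threshold_ratios(data, w, "sine")
      out[[paste0(w, "_over_sine")]] <-
        list(mean = r$mean, sem = r$sem, n = r$n)
    }
    out
  })

  amf_curve <- NULL
  amf_data <- NULL
  if (!is.null(amf_hz)) {
    amf_data <- stage("amf_generate", generate_amf_dataset(config, amf_hz))
    amf_curve <- stage("amf_normalize", normalize_amf_curve(amf_data))
  }

  cfg_string <- paste(deparse(unclass(config)), collapse = "")
  structure(list(fits = fits, ratios = ratios, amf_curve = amf_curve,
                 data = data, amf_data = amf_data,
                 provenance = list(model = config$model, seed = config$seed,
                                   config_hash = sum(utf8ToInt(cfg_string)))),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>", x$provenance$model,
      sprintf("(seed %d)\n", x$provenance$seed))
  for (w in names(x$fits))
    cat(sprintf("  %-6s I0 = %.4g mA, R^2 = %.4f\n", w, x$fits[[w]]$i0,
                x$fits[[w]]$r_squared))
  for (r in names(x$ratios))
    cat(sprintf("  %-16s %.3f +/- %.3f (n = %d)\n", r, x$ratios[[r]]$mean,
                x$ratios[[r]]$sem, x$ratios[[r]]$n))
  if (!is.null(x$amf_curve))
    cat(sprintf("  AMF curve: minimum %.3f at %g Hz\n",
                min(x$amf_curve$mean_i_over_imin),
                x$amf_curve$amf_hz[which.min(x$amf_curve$mean_i_over_imin)]))
  invisible(x)
}

#' Write a study report as JSON
#'
#' @param report A `study_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- list(fits = report$fits, ratios = report$ratios,
              provenance = report$provenance)
  if (!is.null(report$amf_curve))
    out$amf_curve <- report$amf_curve
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
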