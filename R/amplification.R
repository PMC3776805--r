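#' Estimate the baseline fluorescence of an amplification curve
#'
#' Background fluorescence is taken as the mean reading over an early cycle
#' window that precedes the exponential phase (cycles 3-10 by default, the
#' usual ground-phase region of a 40-cycle run).
#'
#' @param curve an [amp_curve()].
#' @param early_window integer cycles to average over.
#' @return A list with `baseline` (mean RFU) and `noise_sd` (SD of the window
#'   readings, n-1 denominator; 0 for a single-cycle window).
#' @export
estimate_baseline <- function(curve, early_window = 3:10) {
  stopifnot(inherits(curve, "amp_curve"))
  if (length(early_window) == 0L) stop("empty baseline window", call. = FALSE)
  idx <- match(early_window, curve$cycles)
  if (anyNA(idx)) stop("baseline window outside the curve's cycles", call. = FALSE)
  f <- curve$fluorescence[idx]
  list(baseline = mean(f),
       noise_sd = if (length(f) > 1L) stats::sd(f) else 0)
}

#' Call the quantification cycle (Cq) of an amplification curve
#'
#' Cq is the fractional cycle at which baseline-subtracted fluorescence first
#' crosses a fixed threshold (30 RFU by default), linearly interpolated
#' between the flanking cycles. More template gives a smaller Cq.
#'
#' @param curve an [amp_curve()].
#' @param threshold RFU threshold (> 0), applied to baseline-subtracted
#'   fluorescence.
#' @param baseline background RFU to subtract; `NULL` estimates it with
#'   [estimate_baseline()].
#' @return The fractional Cq, or `NA` with attribute `reason = "no-crossing"`
#'   when the curve never reaches the threshold (such reactions are excluded
#'   downstream).
#' @export
call_cq <- function(curve, threshold = 30, baseline = NULL) {
  stopifnot(inherits(curve, "amp_curve"))
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  if (is.null(baseline)) baseline <- estimate_baseline(curve)$baseline
  f <- curve$fluorescence - baseline
  above <- which(f >= threshold)
  if (length(above) == 0L)
    return(structure(NA_real_, reason = "no-crossing"))
  i <- above[1L]
  if (i == 1L) return(curve$cycles[1L])
  c0 <- curve$cycles[i - 1L]; c1 <- curve$cycles[i]
  f0 <- f[i - 1L]; f1 <- f[i]
  c0 + (threshold - f0) / (f1 - f0) * (c1 - c0)
}

#' Fit single-curve amplification efficiency (window of linearity)
#'
#' Slides windows of 5, then 4, then 3 consecutive cycles over the
#' exponential phase of the baseline-subtracted curve and fits ordinary least
#' squares of log10(fluorescence) on cycle. The largest window size with any
#' fit reaching `r2_min` is accepted, tie-broken by the highest r-squared.
#' The efficiency follows from the slope via `(1 + E) = 10^slope`.
#'
#' The exponential phase is bounded below by 3x the baseline noise SD and
#' above by `plateau_frac` of the maximum baseline-subtracted fluorescence.
#'
#' @param curve an [amp_curve()].
#' @param r2_min minimum r-squared for an acceptable window (default 0.998).
#' @param window_sizes window lengths tried in order of preference.
#' @param baseline,baseline_sd background RFU and its noise SD; `NULL`
#'   estimates both from the early cycles.
#' @param plateau_frac upper bound of the exponential phase, as a fraction of
#'   the curve's maximum baseline-subtracted fluorescence.
#' @return A one-row data frame (`gene`, `reaction_id`, `E`,
#'   `amplification_factor`, `window_start`, `window_end`, `n_points`, `r2`,
#'   `slope`, `ok`); `ok = FALSE` with `E = NA` when no window qualifies
#'   (the reaction is then excluded from the gene's mean efficiency).
#' @export
fit_efficiency <- function(curve, r2_min = 0.998, window_sizes = c(5L, 4L, 3L),
                           baseline = NULL, baseline_sd = NULL,
                           plateau_frac = 0.8) {
  stopifnot(inherits(curve, "amp_curve"))
  if (is.null(baseline) || is.null(baseline_sd)) {
    bl <- estimate_baseline(curve)
    if (is.null(baseline)) baseline <- bl$baseline
    if (is.null(baseline_sd)) baseline_sd <- bl$noise_sd
  }
  f <- curve$fluorescence - baseline
  lo <- max(3 * baseline_sd, 0)
  hi <- plateau_frac * max(f)
  usable <- which(f > lo & f <= hi)

  fail <- data.frame(gene = curve$gene, reaction_id = curve$reaction_id,
                     E = NA_real_, amplification_factor = NA_real_,
                     window_start = NA_real_, window_end = NA_real_,
                     n_points = NA_integer_, r2 = NA_real_, slope = NA_real_,
                     ok = FALSE, stringsAsFactors = FALSE)
  if (length(usable) < min(window_sizes)) return(fail)

  logf <- ifelse(f > 0, log10(pmax(f, .Machine$double.xmin)), NA_real_)
  for (w in sort(window_sizes, decreasing = TRUE)) {
    best <- NULL
    for (s in usable) {
      idx <- s:(s + w - 1L)
      if (idx[w] > length(f) || !all(idx %in% usable)) next
      x <- curve$cycles[idx]; y <- logf[idx]
      fit <- stats::lm.fit(cbind(1, x), y)
      ssr <- sum(fit$residuals^2)
      sst <- sum((y - mean(y))^2)
      r2 <- if (sst > 0) 1 - ssr / sst else 0
      if (r2 >= r2_min && (is.null(best) || r2 > best$r2))
        best <- list(slope = fit$coefficients[2L], r2 = r2,
                     start = x[1L], end = x[w])
    }
    if (!is.null(best)) {
      slope <- unname(best$slope)
      return(data.frame(gene = curve$gene, reaction_id = curve$reaction_id,
                        E = 10^slope - 1, amplification_factor = 10^slope,
                        window_start = best$start, window_end = best$end,
                        n_points = w, r2 = best$r2, slope = slope,
                        ok = TRUE, stringsAsFactors = FALSE))
    }
  }
  fail
}

#' Summarize per-reaction efficiency fits into a per-gene efficiency set
#'
#' Accepted fits are averaged per gene (arithmetic mean with SEM across
#' reactions). A warning is issued when a gene's mean efficiency falls
#' outside \[0.85, 1.10\], the span typical of acceptable qPCR assays; genes
#' with no accepted fit are reported with a missing efficiency.
#'
#' @param fits a data frame of [fit_efficiency()] rows (rbind-ed).
#' @param warn_range numeric length-2; warn when a mean E falls outside it.
#' @return An `efficiency_set`: data frame with `gene`, `E`, `sem`,
#'   `amplification_factor`, `n_reactions`.
#' @export
summarize_efficiencies <- function(fits, warn_range = c(0.85, 1.10)) {
  stopifnot(is.data.frame(fits), all(c("gene", "E", "ok") %in% names(fits)))
  out <- do.call(rbind, lapply(split(fits, fits$gene), function(d) {
    e <- d$E[d$ok]
    n <- length(e)
    data.frame(gene = d$gene[1L],
               E = if (n > 0) mean(e) else NA_real_,
               sem = if (n > 1) stats::sd(e) / sqrt(n) else if (n == 1) 0 else NA_real_,
               amplification_factor = if (n > 0) 1 + mean(e) else NA_real_,
               n_reactions = n, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  bad <- !is.na(out$E) & (out$E < warn_range[1L] | out$E > warn_range[2L])
  if (any(bad))
    warning(sprintf("mean efficiency outside [%.2f, %.2f] for: %s",
                    warn_range[1L], warn_range[2L],
                    paste(out$gene[bad], collapse = ", ")))
  miss <- is.na(out$E)
  if (any(miss))
    warning(sprintf("no accepted efficiency fit for: %s",
                    paste(out$gene[miss], collapse = ", ")))
  class(out) <- c("efficiency_set", "data.frame")
  out
}

#' Build an efficiency set directly from known per-gene efficiencies
#'
#' Convenience constructor used when efficiencies come from an external table
#' rather than from curve fitting.
#'
#' @param E named numeric vector of per-gene efficiencies.
#' @return An `efficiency_set` data frame.
#' @export
efficiency_set <- function(E) {
  stopifnot(!is.null(names(E)), all(E > 0))
  out <- data.frame(gene = names(E), E = as.numeric(E), sem = 0,
                    amplification_factor = 1 + as.numeric(E),
                    n_reactions = NA_integer_, stringsAsFactors = FALSE)
  class(out) <- c("efficiency_set", "data.frame")
  out
}
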