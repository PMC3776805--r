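#' Present-call filtering of a count panel
#'
#' Two detection filters used in digital screening of sequencing libraries:
#' `min_calls` keeps unigenes detected (count >= 1) in at least `k` of the
#' libraries; `min_reads_all` keeps unigenes with at least `r` reads in every
#' library. Both conventions occur in the literature, so both are exposed and
#' neither is privileged.
#'
#' @param panel a [count_panel()].
#' @param mode `"min_calls"` or `"min_reads_all"`.
#' @param k minimum number of libraries with a present call (`min_calls`).
#' @param r minimum reads required in every library (`min_reads_all`).
#' @return Character vector of retained unigene ids.
#' @export
present_filter <- function(panel, mode = c("min_calls", "min_reads_all"),
                           k = 7, r = 7) {
  stopifnot(inherits(panel, "count_panel"))
  mode <- match.arg(mode)
  n_lib <- ncol(panel$counts)
  if (mode == "min_calls") {
    if (k > n_lib || k < 1) stop("k must lie in [1, number of libraries]", call. = FALSE)
    keep <- rowSums(panel$counts >= 1) >= k
  } else {
    if (r < 1) stop("r must be >= 1", call. = FALSE)
    keep <- apply(panel$counts >= r, 1L, all)
  }
  rownames(panel$counts)[keep]
}

#' Digital (virtual) fold expression between two libraries
#'
#' The read-count analogue of a fold change: `fold = m / (n * (M / N))`,
#' where `m` and `n` are the unigene's reads in the query and reference
#' libraries and `M`, `N` the corresponding whole-library totals. The fold is
#' 1 when the unigene occupies the same fraction of both libraries, and is
#' invariant to uniform scaling of a library.
#'
#' @param m,n unigene read counts in the query and reference libraries.
#' @param M,N total reads of the query and reference libraries.
#' @return The fold expression (vectorized). `n = 0` yields `NA` with a
#'   warning: the profile is undefined relative to that reference.
#' @export
virtual_expression <- function(m, n, M, N) {
  if (any(M <= 0) || any(N <= 0)) stop("library totals must be positive", call. = FALSE)
  if (any(m < 0) || any(n < 0)) stop("counts must be non-negative", call. = FALSE)
  out <- m / (n * (M / N))
  if (any(n == 0)) {
    warning("zero reads in the reference library: fold undefined (NA)")
    out[n == 0] <- NA_real_
  }
  out
}

#' Digital expression profile of every retained unigene
#'
#' Per unigene: fold expression in each library relative to a reference
#' library, plus the mean (MV), SD and coefficient of variation CV = SD/MV of
#' the unigene's library proportions. CV is computed on proportions
#' (count/total), which equals the CV of the folds wherever the folds are
#' defined, and does not depend on the reference library.
#'
#' @param panel a [count_panel()].
#' @param unigenes unigene ids to profile (default: all).
#' @param ref_library reference library (default: first column); its fold is
#'   1 by construction. Unigenes with zero reads in the reference library get
#'   `NA` folds and are flagged.
#' @return Data frame with `unigene`, one `fold.<library>` column per
#'   library, `mv`, `sd`, `cv`, `flagged`.
#' @export
digital_profile <- function(panel, unigenes = rownames(panel$counts),
                            ref_library = colnames(panel$counts)[1L]) {
  stopifnot(inherits(panel, "count_panel"))
  cnt <- panel$counts[unigenes, , drop = FALSE]
  tot <- panel$lib_totals
  prop <- sweep(cnt, 2L, tot, "/")
  ref_prop <- prop[, ref_library]
  folds <- sweep(prop, 1L, ref_prop, "/")
  flagged <- ref_prop == 0
  folds[flagged, ] <- NA_real_
  mv <- rowMeans(prop)
  sdv <- apply(prop, 1L, stats::sd)
  cv <- ifelse(mv > 0, sdv / mv, NA_real_)
  out <- data.frame(unigene = unigenes, stringsAsFactors = FALSE)
  ff <- as.data.frame(folds)
  names(ff) <- paste0("fold.", colnames(cnt))
  out <- cbind(out, ff, mv = unname(mv), sd = unname(sdv), cv = unname(cv),
               flagged = unname(flagged))
  rownames(out) <- NULL
  out
}

#' Coefficient of variation of one unigene's digital expression
#'
#' SD/mean (n-1 denominator) of the unigene's normalized expression
#' (count/total) over the chosen libraries; invariant to rescaling all
#' chosen totals by a common factor.
#'
#' @param panel a [count_panel()].
#' @param unigene one unigene id.
#' @param libraries libraries to use (default: all; at least two).
#' @return The CV, or `NA` with a warning when the mean is zero.
#' @export
unigene_cv <- function(panel, unigene, libraries = colnames(panel$counts)) {
  stopifnot(inherits(panel, "count_panel"), length(libraries) >= 2L)
  prop <- panel$counts[unigene, libraries] / panel$lib_totals[libraries]
  mv <- mean(prop)
  if (mv == 0) {
    warning("zero mean expression: CV undefined")
    return(NA_real_)
  }
  stats::sd(prop) / mv
}

#' Library-omission analysis of digital CVs
#'
#' Recomputes each unigene's CV after omitting a library subset and reports
#' the change `dCV = CV(remaining) - CV(all)`. A negative change means the
#' omitted libraries were driving the unigene's variability. The summary
#' counts decreasing / increasing / unchanged unigenes and gives mean +/- SEM
#' of dCV separately for the decreasing and increasing sets.
#'
#' @param panel a [count_panel()].
#' @param unigenes retained unigene ids (e.g. from [present_filter()]).
#' @param omit libraries to omit, given as column names or as a panel
#'   annotation value (e.g. `"fruit"`); at least two libraries must remain.
#' @return List with `per_unigene` (unigene, cv_all, cv_omitted, dcv) and
#'   `summary` (n_decrease, n_increase, n_unchanged, and mean/sem of dCV for
#'   each direction).
#' @export
omission_analysis <- function(panel, unigenes, omit) {
  stopifnot(inherits(panel, "count_panel"))
  libs <- colnames(panel$counts)
  omit_libs <- if (all(omit %in% libs)) omit else libs[panel$panels %in% omit]
  if (length(omit_libs) == 0L) stop("no libraries match 'omit'", call. = FALSE)
  keep_libs <- setdiff(libs, omit_libs)
  if (length(keep_libs) < 2L)
    stop("omission must leave at least two libraries", call. = FALSE)
  cv_all <- vapply(unigenes, function(u) unigene_cv(panel, u, libs), 0)
  cv_om <- vapply(unigenes, function(u) unigene_cv(panel, u, keep_libs), 0)
  dcv <- cv_om - cv_all
  per <- data.frame(unigene = unigenes, cv_all = unname(cv_all),
                    cv_omitted = unname(cv_om), dcv = unname(dcv),
                    stringsAsFactors = FALSE)
  dn <- dcv[dcv < 0]; up <- dcv[dcv > 0]
  msem <- function(x) if (length(x) == 0L) c(mean = NA_real_, sem = NA_real_)
    else c(mean = mean(x),
           sem = if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0)
  list(per_unigene = per,
       summary = list(n_decrease = length(dn), n_increase = length(up),
                      n_unchanged = sum(dcv == 0),
                      decrease = msem(dn), increase = msem(up),
                      omitted = omit_libs))
}
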