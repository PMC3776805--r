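#' Collapse technical replicates to per-(sample, gene) mean Cq
#'
#' Replicates are averaged on the Cq scale (arithmetic mean) before any
#' transformation to relative quantities. SD uses the n-1 denominator;
#' SE = SD / sqrt(n). A singleton replicate yields SE = 0 with a warning.
#'
#' @param data a long Cq data frame with columns `sample`, `group`, `gene`,
#'   `replicate`, `cq` (as produced by [simulate_cq()] or [read_cq_table()]).
#' @return Data frame with one row per (sample, gene): `sample`, `group`,
#'   `gene`, `n`, `cq`, `sd`, `se`.
#' @export
collapse_replicates <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("sample", "gene", "cq") %in% names(data)))
  if (!"group" %in% names(data)) data$group <- "all"
  keep <- !is.na(data$cq)
  data <- data[keep, , drop = FALSE]
  if (nrow(data) == 0L) stop("no non-missing Cq values", call. = FALSE)
  key <- interaction(data$sample, data$gene, drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(split(data, key), function(d) {
    n <- nrow(d)
    data.frame(sample = d$sample[1L], group = d$group[1L], gene = d$gene[1L],
               n = n, cq = mean(d$cq),
               sd = if (n > 1) stats::sd(d$cq) else NA_real_,
               se = if (n > 1) stats::sd(d$cq) / sqrt(n) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (any(out$n == 1L))
    warning(sprintf("%d (sample, gene) pairs have a single replicate; their SE is 0",
                    sum(out$n == 1L)))
  out
}

#' Transform mean Cq values into efficiency-corrected relative quantities
#'
#' For each gene the calibrator is the sample with the lowest mean Cq (ties
#' broken by sample-label order), whose relative quantity is 1; every other
#' sample gets `RQ = (1 + E)^(Cq_cal - Cq)`, so RQ lies in (0, 1]. The
#' standard error follows the delta method on the exponent:
#' `SE(RQ) = RQ * ln(1 + E) * SE(Cq)`.
#'
#' @param mean_cq output of [collapse_replicates()] (needs a complete
#'   gene x sample grid; samples missing any gene are dropped with a message).
#' @param efficiencies an [efficiency_set()] covering every gene.
#' @return An object of class `rq_matrix`: list with `rq` and `se`
#'   (gene x sample matrices), `calibrator` (named per gene), `groups`
#'   (named per sample), `efficiency` (named per gene).
#' @export
cq_to_rq <- function(mean_cq, efficiencies) {
  stopifnot(is.data.frame(mean_cq),
            all(c("sample", "gene", "cq") %in% names(mean_cq)))
  if (!inherits(efficiencies, "efficiency_set"))
    stop("efficiencies must be an efficiency_set", call. = FALSE)
  genes <- sort(unique(mean_cq$gene))
  missE <- setdiff(genes, efficiencies$gene[!is.na(efficiencies$E)])
  if (length(missE))
    stop("no efficiency for gene(s): ", paste(missE, collapse = ", "),
         call. = FALSE)
  samples <- sort(unique(mean_cq$sample))
  cq <- matrix(NA_real_, length(genes), length(samples),
               dimnames = list(genes, samples))
  se <- cq
  cq[cbind(mean_cq$gene, mean_cq$sample)] <- mean_cq$cq
  if ("se" %in% names(mean_cq)) {
    se[cbind(mean_cq$gene, mean_cq$sample)] <- mean_cq$se
  } else se[] <- 0
  ## geNorm-style analyses need a complete grid: drop incomplete samples
  incomplete <- colnames(cq)[colSums(is.na(cq)) > 0]
  if (length(incomplete)) {
    message("dropping samples with missing genes: ",
            paste(incomplete, collapse = ", "))
    cq <- cq[, setdiff(samples, incomplete), drop = FALSE]
    se <- se[, setdiff(samples, incomplete), drop = FALSE]
    samples <- colnames(cq)
    if (length(samples) < 2L) stop("fewer than 2 complete samples", call. = FALSE)
  }
  E <- stats::setNames(efficiencies$E, efficiencies$gene)[genes]
  cal_idx <- apply(cq, 1L, which.min) # ties: first in sample-label order
  cal_cq <- cq[cbind(seq_along(genes), cal_idx)]
  rq <- (1 + E)^(cal_cq - cq)
  se_rq <- rq * log(1 + E) * se
  grp <- if ("group" %in% names(mean_cq)) {
    g <- mean_cq$group[match(samples, mean_cq$sample)]
    stats::setNames(as.character(g), samples)
  } else stats::setNames(rep("all", length(samples)), samples)
  structure(list(rq = rq, se = se_rq,
                 calibrator = stats::setNames(samples[cal_idx], genes),
                 groups = grp, efficiency = E),
            class = "rq_matrix")
}

#' Construct a relative-quantity matrix directly
#'
#' @param rq gene x sample matrix of positive relative quantities.
#' @param se matching matrix of standard errors (default 0).
#' @param groups optional named per-sample group labels.
#' @return An `rq_matrix` object.
#' @export
rq_matrix <- function(rq, se = NULL, groups = NULL) {
  rq <- as.matrix(rq)
  if (any(rq <= 0)) stop("relative quantities must be positive", call. = FALSE)
  if (is.null(rownames(rq))) rownames(rq) <- sprintf("g%d", seq_len(nrow(rq)))
  if (is.null(colnames(rq))) colnames(rq) <- sprintf("S%02d", seq_len(ncol(rq)))
  if (is.null(se)) se <- array(0, dim(rq), dimnames(rq))
  if (is.null(groups)) groups <- stats::setNames(rep("all", ncol(rq)), colnames(rq))
  cal <- colnames(rq)[apply(rq, 1L, which.max)]
  structure(list(rq = rq, se = as.matrix(se),
                 calibrator = stats::setNames(cal, rownames(rq)),
                 groups = groups[colnames(rq)],
                 efficiency = stats::setNames(rep(NA_real_, nrow(rq)), rownames(rq))),
            class = "rq_matrix")
}

#' Per-sample normalization factor from a reference-gene set
#'
#' The normalization factor of sample s is the geometric mean of the
#' reference genes' relative quantities,
#' `NF_s = (prod RQ_gs)^(1/f)` for f reference genes, with the delta-method
#' error `SE(NF) = NF * (1/f) * sqrt(sum (SE(RQ)/RQ)^2)`.
#'
#' @param rq an `rq_matrix`.
#' @param ref_genes character vector of reference genes (subset of rows of
#'   `rq`; at least one).
#' @return A `normalization_factor`: list with `nf`, `se` (named per sample),
#'   `ref_genes`.
#' @export
normalization_factor <- function(rq, ref_genes) {
  stopifnot(inherits(rq, "rq_matrix"))
  if (length(ref_genes) < 1L) stop("need at least one reference gene", call. = FALSE)
  miss <- setdiff(ref_genes, rownames(rq$rq))
  if (length(miss)) stop("reference gene(s) not in matrix: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  f <- length(ref_genes)
  sub <- rq$rq[ref_genes, , drop = FALSE]
  sub_se <- rq$se[ref_genes, , drop = FALSE]
  nf <- exp(colMeans(log(sub)))
  se <- nf * (1 / f) * sqrt(colSums((sub_se / sub)^2))
  structure(list(nf = nf, se = se, ref_genes = ref_genes),
            class = "normalization_factor")
}

#' Normalized relative quantities of a target gene
#'
#' Divides the target's relative quantities by the sample-specific
#' normalization factor and rescales so the chosen group's mean NRQ is 1.
#' Relative errors add in quadrature:
#' `SE(NRQ)/NRQ = sqrt((SE(RQ)/RQ)^2 + (SE(NF)/NF)^2)`.
#'
#' @param rq an `rq_matrix` containing the target gene.
#' @param target the target gene (one row of `rq`).
#' @param nf a [normalization_factor()] over the same samples.
#' @param rescale_group group label whose mean NRQ is set to 1; `NULL`
#'   skips rescaling.
#' @return Data frame with `sample`, `group`, `nrq`, `se`; attribute
#'   `rescale_group`.
#' @export
normalized_rq <- function(rq, target, nf, rescale_group = NULL) {
  stopifnot(inherits(rq, "rq_matrix"), inherits(nf, "normalization_factor"))
  if (!target %in% rownames(rq$rq)) stop("target gene not in matrix", call. = FALSE)
  samples <- colnames(rq$rq)
  if (!all(samples %in% names(nf$nf)))
    stop("normalization factor does not cover all samples", call. = FALSE)
  t_rq <- rq$rq[target, ]
  t_se <- rq$se[target, ]
  nrq <- t_rq / nf$nf[samples]
  rel_se <- sqrt((t_se / t_rq)^2 + (nf$se[samples] / nf$nf[samples])^2)
  grp <- rq$groups[samples]
  if (!is.null(rescale_group)) {
    in_grp <- grp == rescale_group
    if (!any(in_grp)) stop("rescale group not present: ", rescale_group, call. = FALSE)
    nrq <- nrq / mean(nrq[in_grp])
  }
  out <- data.frame(sample = samples, group = unname(grp),
                    nrq = unname(nrq), se = unname(nrq * rel_se),
                    stringsAsFactors = FALSE)
  attr(out, "rescale_group") <- rescale_group
  out
}

#' Efficiency-corrected single-reference fold ratio (Pfaffl model)
#'
#' The fold change of a target gene between two sample groups, normalized to
#' one reference gene, computed from group-mean Cq values:
#' `ratio = (1+E_t)^(Cq_t,cal - Cq_t,grp) / (1+E_r)^(Cq_r,cal - Cq_r,grp)`.
#' At E = 1 for both genes this reduces to the classical 2^-ddCq.
#'
#' @param mean_cq output of [collapse_replicates()].
#' @param target,reference gene labels.
#' @param sample_group group whose expression is quantified.
#' @param calibrator_group group relative to which it is expressed.
#' @param efficiencies an [efficiency_set()] with both genes.
#' @return The (positive) fold ratio.
#' @export
pfaffl_ratio <- function(mean_cq, target, reference, sample_group,
                         calibrator_group, efficiencies) {
  stopifnot(is.data.frame(mean_cq), inherits(efficiencies, "efficiency_set"))
  E <- stats::setNames(efficiencies$E, efficiencies$gene)
  for (g in c(target, reference))
    if (!g %in% names(E) || is.na(E[g]))
      stop("missing efficiency for gene: ", g, call. = FALSE)
  grp_cq <- function(gene, group) {
    sel <- mean_cq$gene == gene & mean_cq$group == group
    if (!any(sel)) stop(sprintf("no Cq for gene %s in group %s", gene, group),
                        call. = FALSE)
    mean(mean_cq$cq[sel])
  }
  d_t <- grp_cq(target, calibrator_group) - grp_cq(target, sample_group)
  d_r <- grp_cq(reference, calibrator_group) - grp_cq(reference, sample_group)
  unname((1 + E[target])^d_t / (1 + E[reference])^d_r)
}
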