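#' geNorm expression-stability measure M
#'
#' For genes j and k, the pairwise variation `V_jk` is the standard deviation
#' (n-1 denominator) over samples of `log2(RQ_j / RQ_k)`. A gene's stability
#' `M_j` is the mean of `V_jk` over all other genes k. Lower M means more
#' stable expression; M is invariant to rescaling any gene or any sample by a
#' constant, and to the choice of log base up to a common factor (base 2 is
#' the geNorm convention, used here).
#'
#' @param rq an `rq_matrix` with positive entries.
#' @param genes genes to include (default: all rows); at least two.
#' @return Named numeric vector of M values.
#' @export
genorm_m <- function(rq, genes = rownames(rq$rq)) {
  stopifnot(inherits(rq, "rq_matrix"))
  m <- rq$rq[genes, , drop = FALSE]
  if (nrow(m) < 2L) stop("geNorm M needs at least 2 genes", call. = FALSE)
  if (any(m <= 0)) stop("relative quantities must be positive", call. = FALSE)
  lg <- log2(m)
  n <- nrow(lg)
  V <- matrix(0, n, n)
  for (j in seq_len(n - 1L)) {
    for (k in (j + 1L):n) {
      V[j, k] <- V[k, j] <- stats::sd(lg[j, ] - lg[k, ])
    }
  }
  stats::setNames(rowSums(V) / (n - 1L), rownames(lg))
}

#' Rank reference genes by stepwise geNorm elimination
#'
#' Recomputes M on the retained gene set and removes the least stable gene
#' (largest M) until two remain; those two share the best rank, as geNorm
#' cannot separate the final pair. Each gene's reported M is its value at the
#' step of its elimination. Ties are broken deterministically by gene-label
#' order (the later label is eliminated first) and recorded.
#'
#' @param rq an `rq_matrix` with at least 3 genes (with exactly 2, a
#'   degenerate report with both genes at rank 1 is returned).
#' @param m_threshold geNorm's default acceptability cutoff on M (1.5);
#'   retained-set M values above it are flagged.
#' @return Data frame with `gene`, `M` (at elimination), `rank` (1 = most
#'   stable; the final pair shares rank 1), `step`, `flagged`; attributes
#'   `elimination_order` and `ties` (character vector of logged tie-breaks).
#' @export
genorm_rank <- function(rq, m_threshold = 1.5) {
  stopifnot(inherits(rq, "rq_matrix"))
  genes <- rownames(rq$rq)
  ties <- character(0)
  if (length(genes) < 2L) stop("need at least 2 genes", call. = FALSE)
  if (length(genes) == 2L) {
    M <- genorm_m(rq, genes)
    out <- data.frame(gene = genes, M = unname(M), rank = c(1L, 1L),
                      step = c(0L, 0L), flagged = unname(M) > m_threshold,
                      stringsAsFactors = FALSE)
    attr(out, "elimination_order") <- character(0)
    attr(out, "ties") <- ties
    return(out)
  }
  retained <- genes
  elim <- character(0)
  m_at_elim <- stats::setNames(numeric(length(genes)), genes)
  flagged <- stats::setNames(logical(length(genes)), genes)
  step <- 0L
  while (length(retained) > 2L) {
    step <- step + 1L
    M <- genorm_m(rq, retained)
    flagged[retained] <- flagged[retained] | (M > m_threshold)
    worst_val <- max(M)
    cand <- retained[abs(M - worst_val) < 1e-15]
    if (length(cand) > 1L) {
      cand <- sort(cand, decreasing = TRUE) # later label eliminated first
      ties <- c(ties, sprintf("step %d: tie among {%s}; eliminated %s",
                              step, paste(sort(cand), collapse = ", "), cand[1L]))
    }
    out_gene <- cand[1L]
    m_at_elim[out_gene] <- M[out_gene]
    elim <- c(elim, out_gene)
    retained <- setdiff(retained, out_gene)
  }
  M <- genorm_m(rq, retained)
  flagged[retained] <- flagged[retained] | (M > m_threshold)
  m_at_elim[retained] <- M
  ranks <- stats::setNames(integer(length(genes)), genes)
  ranks[retained] <- 1L
  ranks[rev(elim)] <- seq_along(elim) + 2L
  out <- data.frame(gene = genes, M = unname(m_at_elim[genes]),
                    rank = unname(ranks[genes]), step = NA_integer_,
                    flagged = unname(flagged[genes]), stringsAsFactors = FALSE)
  out$step[match(elim, out$gene)] <- seq_along(elim)
  out <- out[order(out$rank, out$gene), ]
  rownames(out) <- NULL
  attr(out, "elimination_order") <- elim
  attr(out, "ties") <- ties
  out
}

#' qBase coefficient of variation of normalized relative quantities
#'
#' Each candidate reference gene is normalized by the factor built from the
#' full candidate set (including the gene itself); its CV is the SD/mean of
#' the resulting normalized relative quantities across samples, and the
#' panel-level figure is the arithmetic mean of the per-gene CVs. A single
#' reference normalizes to itself exactly, so its CV is 0; the mean CV is 0
#' precisely when all candidates are mutually proportional.
#'
#' @param rq an `rq_matrix`.
#' @param ref_genes candidate reference genes (non-empty).
#' @return List with `cv` (named per gene), `mean_cv`, and the
#'   `normalization_factor` used.
#' @export
qbase_cv <- function(rq, ref_genes = rownames(rq$rq)) {
  stopifnot(inherits(rq, "rq_matrix"))
  if (length(ref_genes) < 1L) stop("need at least one reference gene", call. = FALSE)
  nf <- normalization_factor(rq, ref_genes)
  nrq <- sweep(rq$rq[ref_genes, , drop = FALSE], 2L, nf$nf, "/")
  cv <- apply(nrq, 1L, function(x) stats::sd(x) / mean(x))
  list(cv = cv, mean_cv = mean(cv), normalization_factor = nf)
}

#' Classify reference genes and sets by stability thresholds
#'
#' A gene is acceptable when its M value is strictly below `m_max`; a
#' candidate set is acceptable when both its mean M and its mean CV are
#' strictly below the thresholds (defaults M < 0.5 and CV < 25%, the usual
#' bounds for a homogeneous sample panel).
#'
#' @param M named per-gene M values.
#' @param cv named per-gene CVs (same genes).
#' @param m_max,cv_max acceptability thresholds (strict inequalities).
#' @return List with `gene` (data frame: gene, M, cv, accepted) and `set`
#'   (list: mean_m, mean_cv, accepted).
#' @export
classify_acceptability <- function(M, cv, m_max = 0.5, cv_max = 0.25) {
  genes <- names(M)
  stopifnot(!is.null(genes), setequal(genes, names(cv)))
  cv <- cv[genes]
  gene_tab <- data.frame(gene = genes, M = unname(M), cv = unname(cv),
                         accepted = unname(M < m_max), stringsAsFactors = FALSE)
  list(gene = gene_tab,
       set = list(mean_m = mean(M), mean_cv = mean(cv),
                  accepted = mean(M) < m_max && mean(cv) < cv_max))
}

#' Fit a reference-gene stability report
#'
#' The main entry point of the package: from replicate-level Cq data and
#' per-gene amplification efficiencies it computes efficiency-corrected
#' relative quantities, the geNorm stepwise elimination ranking (M values),
#' qBase CVs of normalized relative quantities, and acceptability calls.
#' Tissue panels with distinct transcriptomes (e.g. floral buds vs fruits)
#' should be fitted separately.
#'
#' @param data either a long Cq data frame (`sample`, `group`, `gene`,
#'   `replicate`, `cq`) or a ready-made `rq_matrix`.
#' @param efficiencies an [efficiency_set()]; required when `data` is a Cq
#'   data frame, ignored for an `rq_matrix`.
#' @param m_max,cv_max acceptability thresholds on M and CV.
#' @param m_threshold geNorm's default cutoff (1.5) used to flag unstable
#'   retained-set M values.
#' @return An object of class `stability_report`: list with `ranking`
#'   (gene, M, rank, cv, accepted, flagged), `mean_m`, `mean_cv`,
#'   `set_accepted`, `best_pair`, `elimination_order`, `ties`, `thresholds`,
#'   and the underlying `rq` matrix.
#' @seealso [genorm_rank()], [qbase_cv()], [compare_reference_sets()]
#' @examples
#' spec <- cq_sim_spec(
#'   genes = lapply(1:4, function(i)
#'     gene_sim_spec(paste0("g", i), bio_sd = 0.1)),
#'   groups = rep(c("a", "b"), each = 3), loading_sd = 0.5, tech_sd = 0.1,
#'   seed = 42)
#' sim <- simulate_cq(spec)
#' eff <- efficiency_set(setNames(rep(1, 4), paste0("g", 1:4)))
#' fit <- gene_stability(sim$data, eff)
#' print(fit)
#' @export
gene_stability <- function(data, efficiencies = NULL, m_max = 0.5,
                           cv_max = 0.25, m_threshold = 1.5) {
  rq <- if (inherits(data, "rq_matrix")) {
    data
  } else {
    if (is.null(efficiencies))
      stop("efficiencies are required with Cq input", call. = FALSE)
    cq_to_rq(collapse_replicates(data), efficiencies)
  }
  rk <- genorm_rank(rq, m_threshold = m_threshold)
  qb <- qbase_cv(rq, rownames(rq$rq))
  M <- stats::setNames(rk$M, rk$gene)
  cls <- classify_acceptability(M, qb$cv[rk$gene], m_max = m_max, cv_max = cv_max)
  ranking <- rk
  ranking$cv <- unname(qb$cv[rk$gene])
  ranking$accepted <- cls$gene$accepted
  structure(list(ranking = ranking,
                 mean_m = cls$set$mean_m, mean_cv = qb$mean_cv,
                 set_accepted = cls$set$accepted,
                 best_pair = rk$gene[rk$rank == 1L],
                 elimination_order = attr(rk, "elimination_order"),
                 ties = attr(rk, "ties"),
                 thresholds = c(m_max = m_max, cv_max = cv_max,
                                m_threshold = m_threshold),
                 rq = rq),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, digits = 4, ...) {
  cat("Reference-gene stability report\n")
  cat(sprintf("  %d genes x %d samples; best pair: %s (M = %s)\n",
              nrow(x$ranking), ncol(x$rq$rq),
              paste(x$best_pair, collapse = " & "),
              format(x$ranking$M[1L], digits = digits)))
  cat(sprintf("  mean M = %s, mean CV = %s, set %s (M < %g, CV < %g)\n",
              format(x$mean_m, digits = digits),
              format(x$mean_cv, digits = digits),
              if (x$set_accepted) "accepted" else "rejected",
              x$thresholds["m_max"], x$thresholds["cv_max"]))
  print(x$ranking[, c("gene", "M", "rank", "cv", "accepted")],
        digits = digits, row.names = FALSE)
  if (length(x$ties)) cat("  tie-breaks:", paste(x$ties, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.stability_report <- function(object, ...) {
  r <- object$ranking
  structure(list(n_genes = nrow(r), n_samples = ncol(object$rq$rq),
                 best_pair = object$best_pair,
                 best_m = r$M[1L],
                 n_accepted = sum(r$accepted),
                 mean_m = object$mean_m, mean_cv = object$mean_cv,
                 set_accepted = object$set_accepted,
                 elimination_order = object$elimination_order),
            class = "summary.stability_report")
}

#' @export
print.summary.stability_report <- function(x, ...) {
  cat(sprintf(paste0("Stability fit: %d genes, %d samples\n",
                     "  most stable pair: %s (M = %.4f)\n",
                     "  %d gene(s) individually accepted; set mean M = %.4f, ",
                     "mean CV = %.4f (%s)\n"),
              x$n_genes, x$n_samples, paste(x$best_pair, collapse = " & "),
              x$best_m, x$n_accepted, x$mean_m, x$mean_cv,
              if (x$set_accepted) "accepted" else "rejected"))
  cat("  elimination order:", paste(x$elimination_order, collapse = " > "), "\n")
  invisible(x)
}

#' @export
coef.stability_report <- function(object, ...) {
  stats::setNames(object$ranking$M, object$ranking$gene)
}

#' Plot a stability ranking as a bar chart
#'
#' Bars show M values from least to most stable (the geNorm presentation),
#' with per-gene CVs printed above and accepted genes highlighted.
#'
#' @param x a `stability_report`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.stability_report <- function(x, ...) {
  r <- x$ranking[order(-x$ranking$rank, x$ranking$gene), ]
  bp <- graphics::barplot(r$M, names.arg = r$gene, las = 2,
                          col = ifelse(r$accepted, "orange", "grey70"),
                          ylab = "geNorm M value",
                          main = "Expression stability (lower = more stable)",
                          ...)
  graphics::text(bp, r$M, labels = sprintf("%.2f", r$cv), pos = 3,
                 cex = 0.7, xpd = NA)
  graphics::abline(h = x$thresholds["m_max"], lty = 2)
  invisible(x)
}

#' Compare the normalization factors of two reference-gene sets
#'
#' Per sample, the fold difference `NF_A / NF_B` is computed and rescaled so
#' its geometric mean over the panel is 1; the summary gives the mean fold
#' with SEM and the maximum absolute deviation from unity (also as
#' |log2 fold|). When target genes are supplied, their normalized relative
#' quantities under both sets are reported together with whether the peak
#' (argmax) group differs — the signature of a normalization artifact caused
#' by an unstable reference.
#'
#' @param rq an `rq_matrix`.
#' @param set_a,set_b non-empty reference-gene sets (may overlap).
#' @param targets optional character vector of target genes.
#' @param rescale_group optional group for rescaling target NRQs.
#' @return List with `fold` (per-sample data frame), `mean_fold`, `sem_fold`,
#'   `max_abs_log2_fold`, `max_fold_deviation`, and (with targets) `targets`:
#'   per gene, NRQ under each set and `peak_shifted`.
#' @export
compare_reference_sets <- function(rq, set_a, set_b, targets = NULL,
                                   rescale_group = NULL) {
  stopifnot(inherits(rq, "rq_matrix"))
  nfa <- normalization_factor(rq, set_a)
  nfb <- normalization_factor(rq, set_b)
  fold <- nfa$nf / nfb$nf
  fold <- fold / exp(mean(log(fold))) # geometric-mean centring
  res <- list(fold = data.frame(sample = names(fold), fold = unname(fold),
                                stringsAsFactors = FALSE),
              mean_fold = mean(fold),
              sem_fold = if (length(fold) > 1)
                stats::sd(fold) / sqrt(length(fold)) else 0,
              max_abs_log2_fold = max(abs(log2(fold))),
              max_fold_deviation = max(abs(fold - 1)))
  if (!is.null(targets)) {
    res$targets <- lapply(stats::setNames(targets, targets), function(tg) {
      na <- normalized_rq(rq, tg, nfa, rescale_group = rescale_group)
      nb <- normalized_rq(rq, tg, nfb, rescale_group = rescale_group)
      peak <- function(d) {
        gm <- tapply(d$nrq, d$group, mean)
        names(gm)[which.max(gm)]
      }
      list(nrq_a = na, nrq_b = nb, peak_a = peak(na), peak_b = peak(nb),
           peak_shifted = peak(na) != peak(nb))
    })
  }
  res
}
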