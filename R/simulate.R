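#' @keywords internal
"_PACKAGE"

## Seeded evaluation that does not clobber the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Specify a simulated qPCR assay (one gene)
#'
#' Describes one gene of a synthetic Cq panel: its expression level at the
#' calibrator (`base_cq`, in cycles), its amplification efficiency, its
#' per-sample biological noise on the log2-expression scale, and its
#' regulation across the ordered sample groups.
#'
#' Regulation is either a geometric trend (`trend_fold`, the total fold
#' change from the first to the last group; 1 = unregulated) or an explicit
#' multiplicative `profile` with one fold per group (first group = 1), which
#' takes precedence and permits non-monotone profiles such as `c(1, 2, 8, 4)`.
#'
#' @param gene_id character label.
#' @param base_cq Cq at the calibrator, in cycles; must lie in (5, 40).
#' @param efficiency amplification efficiency E in (0, 1.2].
#' @param bio_sd SD of per-sample biological log2-expression noise.
#' @param trend_fold total fold change across the ordered groups (> 0).
#' @param profile optional numeric vector of per-group folds, first element 1.
#' @return An object of class `gene_sim_spec`.
#' @export
gene_sim_spec <- function(gene_id, base_cq = 25, efficiency = 1,
                          bio_sd = 0, trend_fold = 1, profile = NULL) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  if (!is.finite(efficiency) || efficiency <= 0)
    stop("efficiency must be positive", call. = FALSE)
  if (efficiency > 1.2)
    stop("efficiency must not exceed 1.2", call. = FALSE)
  if (base_cq <= 5 || base_cq >= 40)
    stop("base_cq must lie in (5, 40)", call. = FALSE)
  if (trend_fold <= 0) stop("trend_fold must be positive", call. = FALSE)
  if (bio_sd < 0) stop("bio_sd must be non-negative", call. = FALSE)
  if (!is.null(profile)) {
    if (any(profile <= 0)) stop("profile folds must be positive", call. = FALSE)
    if (abs(profile[1L] - 1) > 1e-12)
      stop("profile must start at 1 (first group is the reference)", call. = FALSE)
  }
  structure(list(gene_id = gene_id, base_cq = base_cq, efficiency = efficiency,
                 bio_sd = bio_sd, trend_fold = trend_fold, profile = profile),
            class = "gene_sim_spec")
}

#' Specify a simulated Cq panel
#'
#' A panel of samples in ordered groups (e.g. four developmental stages with
#' replicates), assayed for a set of genes with graded stability. Each sample
#' carries a loading factor (log2-normal, SD `loading_sd`) shared by all its
#' genes — the cDNA-input variation that reference-gene normalization is meant
#' to remove — and each well has additive Gaussian technical noise on the Cq
#' scale (`tech_sd`, cycles).
#'
#' @param genes list of [gene_sim_spec()] objects.
#' @param groups character vector, one ordered group label per sample.
#' @param n_replicates technical replicates per (sample, gene) well.
#' @param loading_sd SD (log2 units) of the per-sample loading factor.
#' @param tech_sd SD (cycles) of replicate-level Cq noise.
#' @param seed integer RNG seed; a fixed seed gives identical output.
#' @return An object of class `cq_sim_spec`.
#' @export
cq_sim_spec <- function(genes, groups, n_replicates = 3,
                        loading_sd = 0, tech_sd = 0, seed = 1) {
  if (inherits(genes, "gene_sim_spec")) genes <- list(genes)
  stopifnot(length(genes) >= 1L, all(vapply(genes, inherits, TRUE, "gene_sim_spec")))
  if (length(groups) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (tech_sd < 0 || loading_sd < 0)
    stop("noise SDs must be non-negative", call. = FALSE)
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  ids <- vapply(genes, `[[`, "", "gene_id")
  if (anyDuplicated(ids)) stop("duplicate gene_id", call. = FALSE)
  g_levels <- unique(as.character(groups))
  for (g in genes)
    if (!is.null(g$profile) && length(g$profile) != length(g_levels))
      stop("profile length must equal the number of groups", call. = FALSE)
  structure(list(genes = genes, groups = as.character(groups),
                 n_samples = length(groups), n_replicates = as.integer(n_replicates),
                 loading_sd = loading_sd, tech_sd = tech_sd, seed = seed),
            class = "cq_sim_spec")
}

## log2 fold of a gene in each group (vector over group index 1..G)
gene_log2_profile <- function(gene, n_groups) {
  if (!is.null(gene$profile)) return(log2(gene$profile))
  if (n_groups == 1L) return(0)
  log2(gene$trend_fold) * (seq_len(n_groups) - 1L) / (n_groups - 1L)
}

#' Simulate a replicate-level Cq dataset with known ground truth
#'
#' For sample *i*, gene *g*, replicate *r*, the true log2 expression is
#' `x_ig = log2(profile at group of i) + N(0, bio_sd_g) + loading_i`, with
#' `loading_i ~ N(0, loading_sd)`, and
#' `Cq_igr = base_cq_g - x_ig / log2(1 + E_g) + N(0, tech_sd)`.
#' One extra unit of log2 expression therefore lowers Cq by exactly one cycle
#' when E = 1 (one doubling per cycle).
#'
#' @param spec a [cq_sim_spec()].
#' @return A list with components:
#'   \describe{
#'     \item{data}{long data frame `(sample, group, gene, replicate, cq)`.}
#'     \item{truth}{list with `loadings` (named, log2 units), `log2_expression`
#'       (gene x sample matrix of true x_ig), `profiles` (gene x group log2
#'       folds), `bio_sd` and `efficiency` (named per gene).}
#'   }
#' @export
simulate_cq <- function(spec) {
  stopifnot(inherits(spec, "cq_sim_spec"))
  n <- spec$n_samples
  g_levels <- unique(spec$groups)
  g_idx <- match(spec$groups, g_levels)
  samples <- sprintf("S%02d", seq_len(n))
  genes <- spec$genes
  ids <- vapply(genes, `[[`, "", "gene_id")

  with_seed(spec$seed, {
    loadings <- stats::rnorm(n, 0, spec$loading_sd)
    names(loadings) <- samples
    xmat <- matrix(NA_real_, length(genes), n, dimnames = list(ids, samples))
    prof <- matrix(NA_real_, length(genes), length(g_levels),
                   dimnames = list(ids, g_levels))
    rows <- vector("list", length(genes))
    for (j in seq_along(genes)) {
      gn <- genes[[j]]
      lp <- gene_log2_profile(gn, length(g_levels))
      prof[j, ] <- lp
      x <- lp[g_idx] + stats::rnorm(n, 0, gn$bio_sd) + loadings
      xmat[j, ] <- x
      cq_mean <- gn$base_cq - x / log2(1 + gn$efficiency)
      cq <- rep(cq_mean, each = spec$n_replicates) +
        stats::rnorm(n * spec$n_replicates, 0, spec$tech_sd)
      rows[[j]] <- data.frame(
        sample = rep(samples, each = spec$n_replicates),
        group = rep(spec$groups, each = spec$n_replicates),
        gene = gn$gene_id,
        replicate = rep(seq_len(spec$n_replicates), times = n),
        cq = cq, stringsAsFactors = FALSE)
    }
    data <- do.call(rbind, rows)
    rownames(data) <- NULL
    list(data = data,
         truth = list(
           loadings = loadings,
           log2_expression = xmat,
           profiles = prof,
           bio_sd = stats::setNames(vapply(genes, `[[`, 0, "bio_sd"), ids),
           efficiency = stats::setNames(vapply(genes, `[[`, 0, "efficiency"), ids)))
  })
}

#' Specify simulated amplification curves
#'
#' Sigmoid-like curves built from a constant baseline plus exponential growth
#' `start_fluorescence * (1 + E)^cycle`, capped at the plateau, with additive
#' Gaussian read noise. All fluorescence is in relative fluorescence units
#' (RFU).
#'
#' @param efficiency amplification efficiency E in (0, 1.2].
#' @param start_fluorescence RFU of template-derived signal at cycle 0;
#'   a proxy for template amount.
#' @param baseline constant background RFU.
#' @param plateau saturation RFU cap; must exceed the baseline.
#' @param noise_sd SD of additive RFU noise per cycle reading.
#' @param n_cycles number of cycles.
#' @param seed integer RNG seed.
#' @return An object of class `curve_sim_spec`.
#' @export
curve_sim_spec <- function(efficiency = 0.95, start_fluorescence = 1e-2,
                           baseline = 50, plateau = 1000, noise_sd = 0,
                           n_cycles = 40, seed = 1) {
  if (!is.finite(efficiency) || efficiency <= 0 || efficiency > 1.2)
    stop("efficiency must lie in (0, 1.2]", call. = FALSE)
  if (baseline >= plateau) stop("baseline must be below plateau", call. = FALSE)
  if (start_fluorescence <= 0) stop("start_fluorescence must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  structure(list(efficiency = efficiency, start_fluorescence = start_fluorescence,
                 baseline = baseline, plateau = plateau, noise_sd = noise_sd,
                 n_cycles = as.integer(n_cycles), seed = seed),
            class = "curve_sim_spec")
}

#' Construct an amplification curve object
#'
#' @param cycles strictly increasing integer cycle numbers.
#' @param fluorescence finite RFU readings, one per cycle.
#' @param reaction_id,gene,sample labels attached to the reaction.
#' @return An object of class `amp_curve`.
#' @export
amp_curve <- function(cycles, fluorescence, reaction_id = "rxn1",
                      gene = NA_character_, sample = NA_character_) {
  cycles <- as.numeric(cycles)
  if (length(cycles) != length(fluorescence))
    stop("cycles and fluorescence lengths differ", call. = FALSE)
  if (any(diff(cycles) <= 0)) stop("cycles must be strictly increasing", call. = FALSE)
  if (!all(is.finite(fluorescence))) stop("fluorescence must be finite", call. = FALSE)
  structure(list(reaction_id = reaction_id, gene = gene, sample = sample,
                 cycles = cycles, fluorescence = as.numeric(fluorescence)),
            class = "amp_curve")
}

#' Simulate a set of amplification curves
#'
#' Fluorescence at cycle c is
#' `baseline + min(start_fluorescence * (1+E)^c, plateau - baseline) + noise`,
#' clipped at the plateau. With default parameters the exponential phase spans
#' well over six cycles between baseline and plateau.
#'
#' @param spec a [curve_sim_spec()].
#' @param n_reactions number of replicate reactions to draw.
#' @param threshold RFU threshold later used for Cq calling; a warning is
#'   issued when the plateau cannot reach it (no crossing possible).
#' @param gene,sample labels attached to each reaction.
#' @return A list of [amp_curve()] objects.
#' @export
simulate_curves <- function(spec, n_reactions = 1, threshold = 30,
                            gene = NA_character_, sample = NA_character_) {
  stopifnot(inherits(spec, "curve_sim_spec"))
  if (spec$plateau - spec$baseline <= threshold)
    warning("plateau is at or below the Cq threshold: curves cannot cross it")
  cyc <- seq_len(spec$n_cycles)
  growth <- pmin(spec$start_fluorescence * (1 + spec$efficiency)^cyc,
                 spec$plateau - spec$baseline)
  with_seed(spec$seed, {
    lapply(seq_len(n_reactions), function(r) {
      f <- spec$baseline + growth + stats::rnorm(spec$n_cycles, 0, spec$noise_sd)
      amp_curve(cyc, pmin(f, spec$plateau),
                reaction_id = sprintf("rxn%d", r), gene = gene, sample = sample)
    })
  })
}

#' Specify simulated read-count libraries
#'
#' Unigene read counts across sequencing libraries, the substrate of the
#' digital expression-stability screen. Counts are Poisson with mean
#' `library_size * base_proportion * multiplier`; a unigene whose multipliers
#' are all 1 is stably expressed by construction.
#'
#' @param library_sizes total reads per library (default eight libraries:
#'   four bud and four fruit stages).
#' @param unigene_ids character labels.
#' @param base_proportions per-unigene base proportion of reads (>= 0).
#' @param multipliers unigene x library matrix of expression multipliers
#'   (default all 1).
#' @param panels per-library panel annotation (e.g. "bud"/"fruit").
#' @param seed integer RNG seed.
#' @return An object of class `count_sim_spec`.
#' @export
count_sim_spec <- function(library_sizes = rep(1e5, 8), unigene_ids,
                           base_proportions,
                           multipliers = NULL,
                           panels = rep(c("bud", "fruit"), each = length(library_sizes) / 2),
                           seed = 1) {
  n_lib <- length(library_sizes)
  if (n_lib < 2L || any(library_sizes < 1)) stop("need >= 2 libraries of size >= 1", call. = FALSE)
  stopifnot(length(unigene_ids) == length(base_proportions))
  if (any(base_proportions < 0)) stop("proportions must be >= 0", call. = FALSE)
  if (is.null(multipliers))
    multipliers <- matrix(1, length(unigene_ids), n_lib)
  multipliers <- as.matrix(multipliers)
  stopifnot(nrow(multipliers) == length(unigene_ids), ncol(multipliers) == n_lib)
  if (any(multipliers < 0)) stop("multipliers must be >= 0", call. = FALSE)
  if (length(panels) != n_lib) stop("one panel label per library", call. = FALSE)
  structure(list(n_libraries = n_lib, library_sizes = library_sizes,
                 unigene_ids = as.character(unigene_ids),
                 base_proportions = base_proportions,
                 multipliers = multipliers, panels = as.character(panels),
                 seed = seed),
            class = "count_sim_spec")
}

#' Construct a unigene x library count panel
#'
#' @param counts integer matrix, unigenes in rows, libraries in columns.
#' @param lib_totals whole-library total read counts (may exceed the column
#'   sums: totals refer to the full library, not just retained unigenes).
#' @param panels per-library panel annotation.
#' @return An object of class `count_panel`.
#' @export
count_panel <- function(counts, lib_totals, panels = rep("all", ncol(counts))) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (length(lib_totals) != ncol(counts))
    stop("one total per library", call. = FALSE)
  if (any(lib_totals < colSums(counts) - 1e-9))
    stop("library totals below the column sums: inconsistent totals", call. = FALSE)
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("L%d", seq_len(ncol(counts)))
  structure(list(counts = counts,
                 lib_totals = stats::setNames(as.numeric(lib_totals), colnames(counts)),
                 panels = stats::setNames(as.character(panels), colnames(counts))),
            class = "count_panel")
}

#' Simulate a read-count panel with known ground truth
#'
#' @param spec a [count_sim_spec()].
#' @return A list with `panel` (a [count_panel()]) and `truth` (list with
#'   logical `stable` — multipliers all equal to 1 — and the expected
#'   proportion matrix `proportion`).
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "count_sim_spec"))
  mu <- spec$multipliers * outer(spec$base_proportions, spec$library_sizes)
  counts <- with_seed(spec$seed, {
    matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
  })
  nm <- sprintf("%s%d", spec$panels, stats::ave(seq_along(spec$panels),
                                               spec$panels, FUN = seq_along))
  dimnames(counts) <- list(spec$unigene_ids, nm)
  prop <- sweep(mu, 2, spec$library_sizes, "/")
  dimnames(prop) <- dimnames(counts)
  stable <- apply(abs(spec$multipliers - 1) < 1e-12, 1, all)
  names(stable) <- spec$unigene_ids
  list(panel = count_panel(counts, spec$library_sizes, spec$panels),
       truth = list(stable = stable, proportion = prop))
}
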