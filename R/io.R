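#' Read a long-format Cq table
#'
#' Expects a CSV with header `sample,group,gene,replicate,cq`. Duplicate
#' (sample, gene, replicate) rows are an error (their line numbers are
#' reported); non-numeric Cq entries such as "ND" are flagged as missing with
#' a warning rather than coerced to zero, and Cq values outside (0, 45) draw
#' a warning.
#'
#' @param path CSV file path.
#' @return Data frame with columns `sample`, `group`, `gene`, `replicate`,
#'   `cq` (numeric, `NA` for non-detects).
#' @export
read_cq_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("sample", "group", "gene", "replicate", "cq")
  if (!all(need %in% names(raw)))
    stop("Cq table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  key <- paste(raw$sample, raw$gene, raw$replicate, sep = "\r")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(duplicated(key)))
    stop("duplicate (sample, gene, replicate) rows at line(s): ",
         paste(which(dup) + 1L, collapse = ", "), call. = FALSE)
  cq <- suppressWarnings(as.numeric(raw$cq))
  nd <- is.na(cq) & !is.na(raw$cq) & nzchar(raw$cq)
  if (any(nd))
    warning(sprintf("%d non-numeric Cq entries flagged as missing (e.g. '%s')",
                    sum(nd), raw$cq[which(nd)[1L]]))
  out_of_range <- !is.na(cq) & (cq <= 0 | cq >= 45)
  if (any(out_of_range))
    warning(sprintf("%d Cq values outside (0, 45)", sum(out_of_range)))
  data.frame(sample = raw$sample, group = raw$group, gene = raw$gene,
             replicate = as.integer(raw$replicate), cq = cq,
             stringsAsFactors = FALSE)
}

#' Write a long-format Cq table
#'
#' @param data Cq data frame (`sample`, `group`, `gene`, `replicate`, `cq`).
#' @param path output CSV path.
#' @param digits significant digits for numeric output (default 6, for
#'   diffable regression files).
#' @export
write_cq_table <- function(data, path, digits = 6) {
  d <- data
  d$cq <- signif(d$cq, digits)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a unigene x library count panel
#'
#' The count matrix is a TSV with unigene ids in the first column and one
#' column per library; library metadata (whole-library total reads and panel
#' annotation) come from a second TSV with columns `library`, `total`,
#' `panel`. Totals are taken from the metadata — they refer to the entire
#' library, not just the retained unigenes — and must be at least the column
#' sums.
#'
#' @param path count-matrix TSV path.
#' @param meta_path library-metadata TSV path.
#' @return A [count_panel()].
#' @export
read_count_table <- function(path, meta_path) {
  cnt <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  if (!all(c("library", "total", "panel") %in% names(meta)))
    stop("metadata must have columns library, total, panel", call. = FALSE)
  miss <- setdiff(colnames(cnt), meta$library)
  if (length(miss))
    stop("libraries missing from metadata: ", paste(miss, collapse = ", "),
         call. = FALSE)
  meta <- meta[match(colnames(cnt), meta$library), ]
  m <- as.matrix(cnt)
  if (any(m < 0)) stop("negative read counts", call. = FALSE)
  count_panel(m, meta$total, meta$panel)
}

#' Write a count panel (matrix + metadata) as TSV
#'
#' @param panel a [count_panel()].
#' @param path count-matrix TSV path.
#' @param meta_path library-metadata TSV path.
#' @export
write_count_table <- function(panel, path, meta_path) {
  stopifnot(inherits(panel, "count_panel"))
  df <- data.frame(unigene = rownames(panel$counts), panel$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- data.frame(library = colnames(panel$counts),
                     total = unname(panel$lib_totals),
                     panel = unname(panel$panels))
  utils::write.table(meta, meta_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a stability report as CSV
#'
#' One row per gene: `gene`, `M`, `rank`, `cv`, `accepted`.
#'
#' @param fit a [gene_stability()] report.
#' @param path output CSV path.
#' @param digits significant digits (default 6).
#' @export
write_stability_report <- function(fit, path, digits = 6) {
  stopifnot(inherits(fit, "stability_report"))
  d <- fit$ranking[, c("gene", "M", "rank", "cv", "accepted")]
  d$M <- signif(d$M, digits)
  d$cv <- signif(d$cv, digits)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Analysis run configuration
#'
#' Bundles every named constant of the pipeline in one validated object:
#' the Cq-calling RFU threshold, the minimum r-squared of the efficiency
#' fit, the M and CV acceptability bounds, geNorm's default M cutoff, the
#' RNA-integrity cutoff, the present-filter mode and its k/r parameters,
#' and the RNG seed.
#'
#' @param rfu_threshold Cq-calling threshold (RFU), default 30.
#' @param r2_min efficiency-fit minimum r-squared, default 0.998.
#' @param m_max,cv_max stability acceptability bounds (0.5, 0.25).
#' @param genorm_cutoff geNorm default M cutoff (1.5).
#' @param integrity_max 3':5'-ratio cutoff (4.43).
#' @param present_mode,present_k,present_r digital-screen filter settings.
#' @param seed RNG seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(rfu_threshold = 30, r2_min = 0.998, m_max = 0.5,
                       cv_max = 0.25, genorm_cutoff = 1.5,
                       integrity_max = 4.43,
                       present_mode = c("min_calls", "min_reads_all"),
                       present_k = 7, present_r = 7, seed = 1) {
  num <- c(rfu_threshold = rfu_threshold, r2_min = r2_min, m_max = m_max,
           cv_max = cv_max, genorm_cutoff = genorm_cutoff,
           integrity_max = integrity_max, present_k = present_k,
           present_r = present_r)
  if (any(num <= 0)) stop("all thresholds must be positive", call. = FALSE)
  structure(c(as.list(num),
              list(present_mode = match.arg(present_mode),
                   seed = as.integer(seed))),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  for (nm in names(x)) cat(sprintf("  %s = %s\n", nm, format(x[[nm]])))
  invisible(x)
}
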