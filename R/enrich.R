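#' Gene-level enrichment from peak-level differential accessibility
#'
#' Aggregates peak-level differential-accessibility results to genes using
#' a precomputed peak-to-gene link table (e.g. co-accessibility
#' predictions). For each (gene, topic), an empirical-Bayes mixture prior is
#' refit on the linked peaks' LFC estimates — on the global scale grid, with
#' a Dirichlet weights prior anchored at the globally fitted "default"
#' weights — and a log Bayes factor measures support for at least one peak
#' being differentially accessible against the all-null model.
#'
#' @name enrich
NULL

#' Read a peak-to-gene link table
#'
#' TSV with columns `peak_id`, `gene_id` and optionally a link `score`.
#' A peak may link to many genes and vice versa; duplicate
#' (peak, gene) rows are tolerated and de-duplicated downstream.
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `peak_id`, `gene_id` (and `score` when
#'   present).
#' @export
read_peak_gene_links <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  need <- c("peak_id", "gene_id")
  if (!all(need %in% names(dt)))
    stop("link table must have columns peak_id and gene_id: ", path)
  dt
}

#' Gene enrichment analysis of differentially accessible linked peaks
#'
#' @param de A `de_table` from [de_analysis()] run on the peak matrix. Per
#'   the method's design, this should be the unshrunk analysis
#'   (`shrink = FALSE`): the per-gene shrinkage performed here is the only
#'   shrinkage applied, which avoids overshrinking genes with strong
#'   patterns. Uses the `postmean_mcmc` and `se` columns.
#' @param links Peak-to-gene link data frame (`peak_id`, `gene_id`).
#' @param n0 Prior sample size anchoring per-gene mixture weights at the
#'   default (globally fitted) weights; the Dirichlet parameters are
#'   `1.01 + n0 * w_default`. As `n0` grows, per-gene weights converge to
#'   the default weights.
#' @param default_prior Optional pre-fitted `shrink_prior` on ALL
#'   (peak, topic) estimates with normal components; fitted here when
#'   `NULL`.
#' @param lfsr_thresh Peaks with per-gene-shrunken lfsr below this enter the
#'   mean l.e. LFC (default 0.05).
#' @param verbose Report genes excluded for having no linked peaks.
#' @return A data frame with one row per (gene, topic): `gene_id`, `topic`,
#'   `log_bf`, `mean_lelfc` (NA when no linked peak passes the lfsr
#'   threshold), `n_peaks`, `n_signif_peaks`. Attribute `n_excluded_genes`
#'   counts genes with no resolvable linked peaks.
#' @export
gene_enrichment <- function(de, links, n0 = 20, default_prior = NULL,
                            lfsr_thresh = 0.05, verbose = FALSE) {
  stopifnot(is.data.frame(de), n0 >= 0)
  links <- unique(links[, c("peak_id", "gene_id")])
  beta_all <- de$postmean_mcmc
  se_all <- de$se
  ok <- is.finite(beta_all) & is.finite(se_all) & se_all > 0
  if (is.null(default_prior))
    default_prior <- fit_mixture_prior(beta_all[ok], se_all[ok],
                                       family = "normal")
  scales <- default_prior$scales
  alpha <- 1.01 + n0 * default_prior$weights
  topics <- sort(unique(de$topic))
  # index the de table by (peak, topic)
  row_by_peak <- split(seq_len(nrow(de)), de$feature_id)
  genes <- unique(links$gene_id)
  linked <- split(links$peak_id, links$gene_id)
  out <- list()
  excluded <- 0L
  for (g in genes) {
    peaks <- intersect(unique(linked[[g]]), names(row_by_peak))
    if (length(peaks) == 0) {
      excluded <- excluded + 1L
      next
    }
    rows <- unlist(row_by_peak[peaks], use.names = FALSE)
    sub <- de[rows, , drop = FALSE]
    for (k in topics) {
      sk <- sub[sub$topic == k, , drop = FALSE]
      usable <- is.finite(sk$postmean_mcmc) & is.finite(sk$se) & sk$se > 0
      sk <- sk[usable, , drop = FALSE]
      if (nrow(sk) == 0)
        next
      prior_gk <- fit_mixture_prior(sk$postmean_mcmc, sk$se,
                                    family = "normal", scales = scales,
                                    weights_prior = alpha)
      sr <- shrink_estimates(sk$postmean_mcmc, sk$se, prior_gk)
      sig <- sr$lfsr < lfsr_thresh
      out[[length(out) + 1]] <- data.frame(
        gene_id = g, topic = k,
        log_bf = log_lr(sk$postmean_mcmc, sk$se, prior_gk),
        mean_lelfc = if (any(sig)) mean(sr$postmean[sig]) else NA_real_,
        n_peaks = nrow(sk), n_signif_peaks = sum(sig),
        stringsAsFactors = FALSE)
    }
  }
  if (verbose && excluded > 0)
    message("gene_enrichment: ", excluded,
            " genes excluded (no linked peaks in the DE table)")
  res <- if (length(out) == 0)
    data.frame(gene_id = character(0), topic = integer(0),
               log_bf = numeric(0), mean_lelfc = numeric(0),
               n_peaks = integer(0), n_signif_peaks = integer(0))
  else do.call(rbind, out)
  structure(res, n_excluded_genes = excluded,
            default_prior = default_prior)
}

#' Export differentially accessible peaks as BED
#'
#' Writes peaks with unmoderated two-sided p-value below the threshold to a
#' BED file, for downstream motif analysis. Peak ids must be BED-style
#' `"chr:start-end"` (0-based half-open); ids that do not parse are skipped
#' with a warning.
#'
#' @param de A `de_table` from an unshrunk [de_analysis()] run (`pval`
#'   column populated).
#' @param path Output BED path.
#' @param topic Restrict to one topic (default: all topics, peaks pooled).
#' @param pval_thresh p-value threshold (default 0.05).
#' @return Number of peaks written, invisibly.
#' @export
export_bed <- function(de, path, topic = NULL, pval_thresh = 0.05) {
  stopifnot(is.data.frame(de))
  sub <- de
  if (!is.null(topic))
    sub <- sub[sub$topic == topic, , drop = FALSE]
  if (all(is.na(sub$pval)))
    stop("de table has no p-values; run de_analysis with shrink = FALSE")
  sub <- sub[!is.na(sub$pval) & sub$pval < pval_thresh, , drop = FALSE]
  ids <- unique(sub$feature_id)
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  parsed <- vapply(m, length, integer(1)) == 4
  if (any(!parsed) && length(ids) > 0)
    warning(sum(!parsed), " peak ids are not 'chr:start-end' and were ",
            "skipped")
  rows <- t(vapply(m[parsed], function(z) z[2:4], character(3)))
  if (length(rows) == 0) {
    writeLines(character(0), path)
    return(invisible(0L))
  }
  df <- data.frame(chrom = rows[, 1], start = as.integer(rows[, 2]),
                   end = as.integer(rows[, 3]))
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(nrow(df))
}
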