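#' On-disk bundle for topic model fits
#'
#' A fit bundle is a directory with TSV matrices `W.tsv`, `H.tsv` (and the
#' derived `L.tsv`, `F.tsv`, `s.tsv` for convenience) plus `metadata.json`
#' recording K, the seed and iteration counts. Plain text throughout, so
#' bundles diff and version cleanly.
#'
#' @param fit A `poisson_nmf_fit`.
#' @param dir Output directory (created if missing).
#' @param meta Named list of extra metadata fields to record.
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir, meta = list()) {
  stopifnot(inherits(fit, "poisson_nmf_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(M, f) data.table::fwrite(data.table::as.data.table(M),
                                          file.path(dir, f), sep = "\t")
  wm(fit$W, "W.tsv")
  wm(fit$H, "H.tsv")
  tm <- poisson2multinom(fit)
  wm(tm$L, "L.tsv")
  wm(tm$F, "F.tsv")
  data.table::fwrite(data.table::data.table(s = tm$s),
                     file.path(dir, "s.tsv"), sep = "\t")
  md <- c(list(K = fit$K,
               n = nrow(fit$H), m = nrow(fit$W),
               final_loglik = if (length(fit$loglik_trace) > 0)
                 unname(utils::tail(fit$loglik_trace, 1)) else NA,
               n_recorded_updates = length(fit$loglik_trace)),
          meta)
  jsonlite::write_json(md, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(paste(fit$loglik_trace, collapse = "\n"),
             file.path(dir, "loglik_trace.txt"))
  invisible(dir)
}

#' Read a topic model fit bundle
#'
#' @param dir Bundle directory written by [write_fit()].
#' @return A `poisson_nmf_fit`.
#' @export
read_fit <- function(dir) {
  rm_ <- function(f) as.matrix(data.table::fread(file.path(dir, f),
                                                 sep = "\t"))
  W <- rm_("W.tsv")
  H <- rm_("H.tsv")
  tracefile <- file.path(dir, "loglik_trace.txt")
  trace <- if (file.exists(tracefile)) {
    lines <- readLines(tracefile)
    as.numeric(lines[nzchar(lines)])
  } else numeric(0)
  new_poisson_nmf_fit(W, H, trace)
}

#' Write a DE results table as TSV
#'
#' Column layout: feature_id, topic, map, postmean, hpd_lo, hpd_hi, se, z,
#' lfsr, svalue (plus postmean_mcmc, pval, p0).
#'
#' @param de A `de_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  cols <- c("feature_id", "topic", "map", "postmean", "hpd_lo", "hpd_hi",
            "se", "z", "lfsr", "svalue", "postmean_mcmc", "pval", "p0")
  data.table::fwrite(as.data.frame(de)[, cols], path, sep = "\t")
  invisible(path)
}

#' Read a DE results table
#' @param path TSV written by [write_de_table()].
#' @return A data frame with class `de_table`.
#' @export
read_de_table <- function(path) {
  out <- data.table::fread(path, sep = "\t", data.table = FALSE)
  class(out) <- c("de_table", "data.frame")
  out
}
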