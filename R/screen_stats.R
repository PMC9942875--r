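## Screen enrichment statistics: QC filters, RPM normalization, log2 fold
## changes, empirical-Bayes guide z-scores (DrugZ-style), element-level
## aggregation and LOF/GOF/SOF classification.

#' Guide count matrix with sample metadata
#'
#' @param counts non-negative integer matrix, rows = guides (unique
#'   rownames), columns = samples
#' @param samples data.frame with one row per column of `counts`: `sample`
#'   (matching colnames), `assay` (one of `plasmid`, `T0`, `control`,
#'   `IFNg`, `FACS_sorted`) and `replicate`
#' @return object of class `CountMatrix`
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts must have unique guide rownames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  req <- c("sample", "assay", "replicate")
  if (!all(req %in% names(samples)))
    stop("sample sheet needs columns: ", paste(req, collapse = ", "))
  if (!identical(as.character(samples$sample), colnames(counts)))
    stop("sample sheet rows must match count columns (same order)")
  ok_assays <- c("plasmid", "T0", "control", "IFNg", "FACS_sorted")
  if (!all(samples$assay %in% ok_assays))
    stop("assay must be one of: ", paste(ok_assays, collapse = ", "))
  structure(list(counts = counts, samples = samples), class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d guides x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$assay), collapse = ", ")))
  invisible(x)
}

#' Quality-control filter on a count matrix
#'
#' Applies, in order: (1) drop guides with 0 reads in any control/reference
#' sample; (2) drop guides with fewer than `min_reads` reads in any sample
#' (the minimum-count rule of base-editing screens, off via
#' `min_reads = NULL`); (3) drop guides over-represented in the plasmid
#' library (> `max_plasmid_reads`); (4) optionally drop guides whose
#' control counts differ more than `max_control_fold`-fold between
#' replicates. Each removal is logged with its triggering rule.
#'
#' @param cm a [count_matrix()]
#' @param reference_assays assays counting as control/reference for the
#'   zero-count rule (default `c("control", "T0")`)
#' @param min_reads minimum reads per guide in every sample (default 100);
#'   `NULL` disables
#' @param max_plasmid_reads plasmid over-representation cutoff (default
#'   50000); `NULL` disables
#' @param max_control_fold maximum fold difference of control counts
#'   between replicates; `NULL` (default) disables
#' @return list with `counts` (filtered `CountMatrix`) and `log`
#'   (data.frame `guide_id`, `rule`)
#' @export
qc_filter <- function(cm, reference_assays = c("control", "T0"),
                      min_reads = 100, max_plasmid_reads = 50000,
                      max_control_fold = NULL) {
  counts <- cm$counts
  samples <- cm$samples
  log <- data.frame(guide_id = character(), rule = character(),
                    stringsAsFactors = FALSE)
  drop_guides <- function(bad, rule) {
    if (any(bad)) {
      log <<- rbind(log, data.frame(guide_id = rownames(counts)[bad],
                                    rule = rule, stringsAsFactors = FALSE))
      counts <<- counts[!bad, , drop = FALSE]
    }
  }
  ref_cols <- samples$assay %in% reference_assays
  if (any(ref_cols))
    drop_guides(apply(counts[, ref_cols, drop = FALSE] == 0, 1L, any),
                "zero_in_control")
  if (!is.null(min_reads))
    drop_guides(apply(counts < min_reads, 1L, any), "min_reads")
  plasmid_cols <- samples$assay == "plasmid"
  if (!is.null(max_plasmid_reads) && any(plasmid_cols))
    drop_guides(apply(counts[, plasmid_cols, drop = FALSE] > max_plasmid_reads,
                      1L, any), "plasmid_overrepresented")
  if (!is.null(max_control_fold)) {
    ctrl <- counts[, samples$assay == "control", drop = FALSE]
    if (ncol(ctrl) >= 2L) {
      fold <- apply(ctrl, 1L, function(x) (max(x) + 1) / (min(x) + 1))
      drop_guides(fold > max_control_fold, "control_fold_difference")
    }
  }
  if (nrow(counts) == 0L) stop("qc_filter removed every guide")
  list(counts = count_matrix(counts, samples), log = log)
}

#' Reads-per-million normalization with pseudocount
#'
#' `norm_rpm = reads / total reads for the sample * 1e6 + 1`, applied
#' column-wise. The +1 pseudocount makes every normalized value >= 1, so
#' `sum(norm_rpm - 1)` is exactly 1e6 per sample.
#'
#' @param cm a [count_matrix()] (or plain matrix)
#' @return matrix of normalized values
#' @export
normalize_rpm <- function(cm) {
  counts <- if (inherits(cm, "CountMatrix")) cm$counts else as.matrix(cm)
  totals <- colSums(counts)
  if (any(totals == 0)) stop("sample with zero total reads")
  sweep(counts, 2L, totals, "/") * 1e6 + 1
}

#' Log2 fold change of normalized guide abundance
#'
#' @param cm a [count_matrix()]
#' @param treated,reference sample names (columns of `cm`)
#' @return data.frame `guide_id`, `norm_treated`, `norm_reference`, `l2fc`
#' @export
normalize_and_l2fc <- function(cm, treated, reference) {
  norm <- normalize_rpm(cm)
  if (!all(c(treated, reference) %in% colnames(norm)))
    stop("treated/reference sample not found in count matrix")
  data.frame(guide_id = rownames(norm),
             norm_treated = norm[, treated],
             norm_reference = norm[, reference],
             l2fc = log2(norm[, treated] / norm[, reference]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Empirical-Bayes guide z-scores
#'
#' DrugZ-style moderation: fold changes are centered on the mean of the
#' control guides (non-targeting / intergenic / non-essential), then each
#' guide's standard deviation is estimated from a sliding window of
#' `window` guides of similar reference abundance and forced monotone
#' non-increasing in abundance, so sparsely counted guides never receive a
#' smaller sd than well-counted ones. `z = centered l2fc / sd`.
#'
#' @param l2fc numeric vector of guide log2 fold changes
#' @param abundance reference-sample abundance used to order guides
#' @param is_control logical vector marking control guides
#' @param window sliding-window size in guides (default 800, clipped to the
#'   library size)
#' @param min_controls minimum number of control guides (default 20)
#' @param robust estimate the window sd as the normal-consistent scaled
#'   MAD (default), so that genuinely enriched or depleted guides do not
#'   inflate the noise estimate of their abundance neighbours; `FALSE`
#'   uses the plain sample sd
#' @return numeric vector of z-scores, same order as `l2fc`
#' @export
eb_zscore <- function(l2fc, abundance, is_control, window = 800L,
                      min_controls = 20L, robust = TRUE) {
  n <- length(l2fc)
  stopifnot(length(abundance) == n, length(is_control) == n)
  nc <- sum(is_control)
  if (nc < min_controls)
    stop("eb_zscore needs at least ", min_controls, " control guides (got ",
         nc, ")")
  centered <- l2fc - mean(l2fc[is_control])
  ord <- order(abundance, decreasing = TRUE)
  x <- centered[ord]
  w <- max(2L, min(as.integer(window), n))
  half <- w %/% 2L
  est <- if (robust) function(v) stats::mad(v) else sd
  sds <- vapply(seq_len(n), function(i) {
    lo <- min(max(1L, i - half), n - w + 1L)
    est(x[lo:(lo + w - 1L)])
  }, numeric(1))
  sds <- cummax(sds)  # abundance decreases along ord: sd never shrinks
  z <- numeric(n)
  z[ord] <- x / sds
  z
}

#' Aggregate guide z-scores to element scores
#'
#' Elements are genes or predicted amino-acid positions/variants. For each
#' element `normZ = sum(z) / sqrt(n)`, converted to a two-sided normal
#' p-value and Benjamini-Hochberg FDR across all elements of the run.
#'
#' @param guide_z data.frame with `guide_id` and `z`
#' @param mapping data.frame with `guide_id` and `element`; guides absent
#'   from the mapping are ignored
#' @return data.frame `element`, `n_guides`, `normZ`, `p`, `fdr`, ordered
#'   by `element`
#' @export
aggregate_elements <- function(guide_z, mapping) {
  m <- merge(guide_z, mapping, by = "guide_id")
  if (nrow(m) == 0L)
    return(data.frame(element = character(), n_guides = integer(),
                      normZ = numeric(), p = numeric(), fdr = numeric(),
                      stringsAsFactors = FALSE))
  agg <- do.call(rbind, lapply(split(m$z, m$element), function(z)
    data.frame(n_guides = length(z), normZ = sum(z) / sqrt(length(z)))))
  res <- data.frame(element = rownames(agg), agg, row.names = NULL,
                    stringsAsFactors = FALSE)
  res$p <- 2 * pnorm(-abs(res$normZ))
  res$fdr <- p.adjust(res$p, method = "BH")
  res[order(res$element), ]
}

#' Classify elements as LOF / GOF / SOF / neutral
#'
#' Thresholds are set from benchmark guide sets of known effect (the
#' screen's validation cohort): the LOF threshold is the
#' `benchmark_quantile` quantile (default the 5th percentile) of the
#' benchmark-LOF guide |z| in the proliferation assay, the GOF threshold
#' likewise from the benchmark-GOF guides, and the FACS support threshold
#' from the benchmark-LOF guide |z| in the FACS assay. An element is LOF
#' when enriched beyond the threshold in the proliferation (IFN-gamma
#' selection) assay with FACS support when a FACS screen exists; SOF
#' (separation-of-function) when proliferation-significant but below the
#' FACS threshold; GOF when depleted beyond the GOF threshold in
#' proliferation (FACS support is not required: a sort for non-responders
#' cannot recover GOF variants); otherwise neutral. Without FACS scores
#' classification degrades to proliferation-only calls, with a message.
#'
#' @param prolif data.frame `element`, `normZ` from the proliferation assay
#' @param facs same for the FACS assay, or `NULL`
#' @param benchmark_lof,benchmark_gof benchmark guide z-scores: numeric
#'   vectors (proliferation assay), or lists with components `prolif` and
#'   (for `benchmark_lof`) `facs`
#' @param benchmark_quantile quantile of benchmark |z| used as threshold
#'   (default 0.05)
#' @return data.frame `element`, `z_prolif`, `z_facs`, `call`, plus the
#'   thresholds as attributes
#' @export
classify_variants <- function(prolif, facs, benchmark_lof, benchmark_gof,
                              benchmark_quantile = 0.05) {
  if (is.numeric(benchmark_lof)) benchmark_lof <- list(prolif = benchmark_lof)
  if (is.numeric(benchmark_gof)) benchmark_gof <- list(prolif = benchmark_gof)
  stopifnot(length(benchmark_lof$prolif) > 0L,
            length(benchmark_gof$prolif) > 0L)
  zp <- setNames(prolif$normZ, prolif$element)
  thr_lof <- unname(quantile(abs(benchmark_lof$prolif), benchmark_quantile))
  thr_gof <- unname(quantile(abs(benchmark_gof$prolif), benchmark_quantile))
  have_facs <- !is.null(facs)
  if (have_facs) {
    if (is.null(benchmark_lof$facs))
      stop("FACS scores supplied but no benchmark-LOF FACS guide z-scores")
    zf <- setNames(facs$normZ, facs$element)[names(zp)]
    thr_facs <- unname(quantile(abs(benchmark_lof$facs), benchmark_quantile))
  } else {
    message("no FACS scores supplied: classification degrades to ",
            "proliferation-only calls")
    zf <- rep(NA_real_, length(zp))
    thr_facs <- NA_real_
  }
  call <- vapply(seq_along(zp), function(i) {
    if (zp[i] >= thr_lof) {
      if (!have_facs || is.na(zf[i])) "LOF"
      else if (zf[i] >= thr_facs) "LOF"
      else "SOF"
    } else if (zp[i] <= -thr_gof) "GOF" else "neutral"
  }, character(1))
  res <- data.frame(element = names(zp), z_prolif = unname(zp),
                    z_facs = unname(zf), call = call,
                    stringsAsFactors = FALSE)
  attr(res, "thresholds") <- c(lof = thr_lof, gof = thr_gof, facs = thr_facs)
  res
}

#' Score a screen end to end
#'
#' Per replicate: log2 fold change of each treated sample against the
#' matched reference sample, empirical-Bayes z-scores; guide z averaged
#' across replicates; element aggregation via [aggregate_elements()].
#' Replicates are matched by their `replicate` label in the sample sheet.
#'
#' @param cm a [count_matrix()]
#' @param treated_assay,reference_assay assay labels to compare
#' @param control_guides character vector of control guide ids used for
#'   centering and sd moderation
#' @param mapping guide-to-element mapping (see [aggregate_elements()]);
#'   `NULL` skips aggregation
#' @param window,min_controls passed to [eb_zscore()]
#' @return list with `guide_scores` (per replicate l2fc and z plus the
#'   cross-replicate mean `z_mean`) and `element_scores`
#' @export
run_screen <- function(cm, treated_assay, reference_assay, control_guides,
                       mapping = NULL, window = 800L, min_controls = 20L) {
  samples <- cm$samples
  treated <- samples[samples$assay == treated_assay, ]
  reference <- samples[samples$assay == reference_assay, ]
  reps <- intersect(treated$replicate, reference$replicate)
  if (length(reps) == 0L)
    stop("no shared replicates between '", treated_assay, "' and '",
         reference_assay, "'")
  is_control <- rownames(cm$counts) %in% control_guides
  per_rep <- lapply(reps, function(r) {
    tr <- treated$sample[treated$replicate == r][1L]
    rf <- reference$sample[reference$replicate == r][1L]
    fc <- normalize_and_l2fc(cm, tr, rf)
    fc$replicate <- r
    fc$z <- eb_zscore(fc$l2fc, fc$norm_reference, is_control,
                      window = window, min_controls = min_controls)
    fc
  })
  guide_scores <- do.call(rbind, per_rep)
  zbar <- tapply(guide_scores$z, guide_scores$guide_id, mean)
  zmean <- data.frame(guide_id = names(zbar), z = as.numeric(zbar),
                      stringsAsFactors = FALSE)
  element_scores <- if (!is.null(mapping))
    aggregate_elements(zmean, mapping) else NULL
  list(guide_scores = guide_scores, guide_z_mean = zmean,
       element_scores = element_scores)
}
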