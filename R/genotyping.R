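## Genotype verification: amplicon VAF profiles, single-cell guide
## assignment from UMI matrices, zygosity and consensus-edit calling, and
## screen error-rate estimation.

#' Per-guide editing profile from amplicon variant observations
#'
#' Computes variant allele frequency (`VAF = alt_reads / total_reads`),
#' removes entries below `min_vaf` (default 1%, an absolute filter), maps
#' each variant to its protospacer position through the guide table, and
#' summarizes per guide: VAF by protospacer position, the fraction of edit
#' observations inside the editor window, and — when a `consequence`
#' column is present — the co-occurrence rate of non-synonymous window
#' edits with synonymous edits in the same sample.
#'
#' @param observations data.frame with `sample`, `contig`, `pos` (1-based),
#'   `ref`, `alt`, `alt_reads`, `total_reads`, `guide_id`, optional
#'   `consequence`; rows with `total_reads = 0` are skipped with a warning
#' @param guides guide table (for protospacer-position mapping)
#' @param editor an [editor_config()]
#' @param min_vaf absolute VAF filter (default 0.01)
#' @return list with `observations` (filtered, with `vaf` and
#'   `protospacer_position` columns), `by_position` (per guide/position
#'   mean VAF and count), `per_guide` (in-window fraction and synonymous
#'   co-occurrence rate)
#' @export
vaf_profile <- function(observations, guides, editor, min_vaf = 0.01) {
  obs <- observations
  zero <- obs$total_reads == 0
  if (any(zero)) {
    warning(sum(zero), " observation(s) with zero total reads skipped")
    obs <- obs[!zero, ]
  }
  stopifnot(all(obs$alt_reads >= 0), all(obs$alt_reads <= obs$total_reads))
  obs$vaf <- obs$alt_reads / obs$total_reads
  obs <- obs[obs$vaf >= min_vaf, ]
  gidx <- match(obs$guide_id, guides$guide_id)
  pp <- genomic_to_protospacer(guides$start[gidx], guides$strand[gidx],
                               obs$pos - 1L)
  obs$protospacer_position <- ifelse(!is.na(pp) & pp >= 1L & pp <= 20L,
                                     pp, NA_integer_)
  win <- editor$window
  by_pos <- if (nrow(obs)) {
    key <- interaction(obs$guide_id, obs$protospacer_position, drop = TRUE)
    do.call(rbind, lapply(split(obs, key), function(d)
      data.frame(guide_id = d$guide_id[1L],
                 protospacer_position = d$protospacer_position[1L],
                 n = nrow(d), mean_vaf = mean(d$vaf),
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(guide_id = character(), protospacer_position = integer(),
               n = integer(), mean_vaf = numeric(), stringsAsFactors = FALSE)
  }
  per_guide <- do.call(rbind, lapply(split(obs, obs$guide_id), function(d) {
    inw <- !is.na(d$protospacer_position) &
      d$protospacer_position >= win[1L] & d$protospacer_position <= win[2L]
    syn_rate <- NA_real_
    if ("consequence" %in% names(d)) {
      by_sample <- split(d, d$sample)
      has_ns <- vapply(by_sample, function(s)
        any(s$consequence != "synonymous" & !is.na(s$protospacer_position) &
              s$protospacer_position >= win[1L] &
              s$protospacer_position <= win[2L]), logical(1))
      has_syn <- vapply(by_sample, function(s)
        any(s$consequence == "synonymous"), logical(1))
      if (any(has_ns)) syn_rate <- mean(has_syn[has_ns])
    }
    data.frame(guide_id = d$guide_id[1L], n_edits = nrow(d),
               in_window_fraction = mean(inw),
               synonymous_co_rate = syn_rate, stringsAsFactors = FALSE)
  }))
  if (is.null(per_guide))
    per_guide <- data.frame(guide_id = character(), n_edits = integer(),
                            in_window_fraction = numeric(),
                            synonymous_co_rate = numeric(),
                            stringsAsFactors = FALSE)
  rownames(by_pos) <- rownames(per_guide) <- NULL
  list(observations = obs, by_position = by_pos, per_guide = per_guide)
}

## P(>=1) and P(>=2) present guides from per-guide posteriors, assuming
## independence across guides within a cell (Poisson-binomial tails)
presence_tails <- function(p) {
  q <- 1 - p
  p_any <- 1 - prod(q)
  if (any(q == 0)) {
    ones <- sum(p == 1)
    p_one <- if (ones == 1L) prod(q[p < 1]) else 0
  } else {
    p_one <- prod(q) * sum(p / q)
  }
  c(p_any = p_any, p_multi = max(0, p_any - p_one))
}

#' Assign guides to cells from a UMI matrix
#'
#' Normalizes each cell's guide UMI counts by the cell's total UMI count
#' (pseudocount 0.5 keeps zeros finite), log-transforms, and fits one
#' pooled two-component skew-t mixture over all cell-by-guide entries.
#' Per-entry posteriors of the "present" component give, per cell,
#' P(at least one guide) and P(multiple guides) under cross-guide
#' independence. A cell is assigned its maximum-posterior guide iff
#' `P(>=1) >= p_any_min` (default 0.99) and `P(>=2) <= p_multi_max`
#' (default 0.01).
#'
#' @param umi non-negative cells x guides count matrix with dimnames
#' @param cell_totals per-cell total UMI counts used for normalization
#'   (default row sums of `umi`)
#' @param p_any_min,p_multi_max inclusion thresholds
#' @param pseudocount added to counts before the log transform
#' @param ... passed to [fit_skewt_mixture()]
#' @return data.frame `cell`, `p_any`, `p_multi`, `assigned_guide` (`NA`
#'   when thresholds are not met), `max_posterior`; the mixture fit is
#'   attached as attribute `"fit"`. If EM fails to converge all cells are
#'   excluded (assignments `NA`) with a warning.
#' @export
assign_guides <- function(umi, cell_totals = NULL, p_any_min = 0.99,
                          p_multi_max = 0.01, pseudocount = 0.5, ...) {
  umi <- as.matrix(umi)
  if (any(umi < 0)) stop("UMI counts must be non-negative")
  totals <- cell_totals %||% rowSums(umi)
  if (any(totals <= 0)) stop("every cell must have a positive total UMI count")
  x <- log(sweep(umi + pseudocount, 1L, totals, "/"))
  fit <- fit_skewt_mixture(as.vector(x), ...)
  post <- matrix(posterior_present(fit, as.vector(x)), nrow = nrow(umi),
                 dimnames = dimnames(umi))
  res <- do.call(rbind, lapply(seq_len(nrow(umi)), function(i) {
    tails <- presence_tails(post[i, ])
    best <- which.max(post[i, ])
    ok <- fit$converged && tails["p_any"] >= p_any_min &&
      tails["p_multi"] <= p_multi_max
    data.frame(cell = rownames(umi)[i] %||% as.character(i),
               p_any = unname(tails["p_any"]),
               p_multi = unname(tails["p_multi"]),
               assigned_guide = if (ok) colnames(umi)[best] else NA_character_,
               max_posterior = unname(post[i, best]),
               stringsAsFactors = FALSE)
  }))
  if (!fit$converged)
    warning("skew-t mixture EM did not converge; all cells excluded")
  attr(res, "fit") <- fit
  res
}

#' Ploidy-aware zygosity call from a cell's allele fraction
#'
#' For the default triploid setting, an allele fraction above
#' `homo_threshold` (0.60, i.e. two or three of three alleles edited) is
#' called `homo` (high confidence); a nonzero fraction at or below the
#' threshold is `het`; zero is `wt`. Vectorized over `af`.
#'
#' @param af allele fraction(s) in `[0, 1]`
#' @param ploidy integer >= 1 (recorded, and used for the penetrance
#'   string)
#' @param homo_threshold AF above which the call is homozygous
#' @return data.frame `af`, `zygosity`, `penetrance` (e.g. `"0/1/1"` for a
#'   triploid het)
#' @export
call_zygosity <- function(af, ploidy = 3L, homo_threshold = 0.60) {
  if (any(!is.finite(af)) || any(af < 0) || any(af > 1))
    stop("allele fractions must lie in [0, 1]")
  stopifnot(ploidy >= 1L)
  zyg <- ifelse(af > homo_threshold, "homo", ifelse(af > 0, "het", "wt"))
  ## display convention: homo = all alleles edited ("1/1/1" at ploidy 3),
  ## het = one unedited allele ("0/1/1"), wt = none
  n_alt <- ifelse(zyg == "homo", ploidy,
                  ifelse(zyg == "het", max(ploidy - 1L, 1L), 0L))
  pen <- vapply(n_alt, function(k)
    paste(c(rep(0L, ploidy - k), rep(1L, k)), collapse = "/"), character(1))
  data.frame(af = af, zygosity = zyg, penetrance = pen,
             stringsAsFactors = FALSE)
}

#' Consensus edits per guide across assigned cells
#'
#' Guides with at least `min_cells` uniquely assigned cells are reported;
#' an edit is retained for a guide iff it is observed in at least
#' `min_cells` cells and in at least `min_fraction` of the guide's cells.
#'
#' @param assignments data.frame `cell`, `assigned_guide` (as from
#'   [assign_guides()]); unassigned cells are ignored
#' @param cell_edits data.frame `cell`, `edit` (one row per edit observed
#'   in a cell)
#' @param min_cells minimum supporting cells (default 3)
#' @param min_fraction minimum fraction of the guide's cells (default 0.25)
#' @return data.frame `guide_id`, `edit`, `n_cells`, `n_guide_cells`,
#'   `fraction`, `retained`
#' @export
consensus_edits <- function(assignments, cell_edits, min_cells = 3L,
                            min_fraction = 0.25) {
  asg <- assignments[!is.na(assignments$assigned_guide), ]
  merged <- merge(asg[, c("cell", "assigned_guide")], cell_edits, by = "cell")
  n_cells_per_guide <- table(asg$assigned_guide)
  guides <- names(n_cells_per_guide)[n_cells_per_guide >= min_cells]
  res <- do.call(rbind, lapply(guides, function(g) {
    sub <- merged[merged$assigned_guide == g, ]
    ng <- as.integer(n_cells_per_guide[[g]])
    if (nrow(sub) == 0L) return(NULL)
    tab <- table(sub$edit)
    data.frame(guide_id = g, edit = names(tab), n_cells = as.integer(tab),
               n_guide_cells = ng, fraction = as.integer(tab) / ng,
               retained = as.integer(tab) >= min_cells &
                 as.integer(tab) / ng >= min_fraction,
               stringsAsFactors = FALSE)
  }))
  if (is.null(res))
    res <- data.frame(guide_id = character(), edit = character(),
                      n_cells = integer(), n_guide_cells = integer(),
                      fraction = numeric(), retained = logical(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Estimate the screen false-negative rate
#'
#' Guides for which no edited cells were detected are first excused when
#' their editability profile predicts failure (no target base in the
#' window, exclusively GC-context targets, or a poly-T tract); the
#' remaining undetected guides, divided by the number of detected guides,
#' give the false-negative rate as a percentage.
#'
#' @param n_detected number of guides with detected edits (> 0)
#' @param undetected_profiles data.frame of [profile_guides()] rows for the
#'   undetected guides (columns `no_target`, `exclusively_gc_context`,
#'   `polyT`), or an integer count of undetected guides together with
#'   `n_excluded`
#' @param n_excluded number of undetected guides excused by flags (used
#'   only when `undetected_profiles` is a count)
#' @return list with `fnr_percent`, `n_detected`, `n_undetected`,
#'   `n_excluded`, `n_unexplained`
#' @export
estimate_rates <- function(n_detected, undetected_profiles, n_excluded = 0L) {
  if (n_detected <= 0L) stop("false-negative rate undefined with 0 detected guides")
  if (is.data.frame(undetected_profiles)) {
    n_undetected <- nrow(undetected_profiles)
    n_excluded <- sum(undetected_profiles$no_target |
                        undetected_profiles$exclusively_gc_context |
                        undetected_profiles$polyT)
  } else {
    n_undetected <- as.integer(undetected_profiles)
  }
  unexplained <- n_undetected - n_excluded
  list(fnr_percent = 100 * unexplained / n_detected,
       n_detected = as.integer(n_detected), n_undetected = n_undetected,
       n_excluded = as.integer(n_excluded),
       n_unexplained = as.integer(unexplained))
}

#' Control-guide misassignment rate
#'
#' Fraction (as a percentage) of control guides — guides that do not
#' target the gene — whose assigned cells nevertheless carry a target-gene
#' edit, an index of guide-to-cell assignment accuracy.
#'
#' @param n_misassigned control guides assigned a target-gene edit
#' @param n_controls total control guides
#' @return percentage
#' @export
control_misassignment <- function(n_misassigned, n_controls) {
  stopifnot(n_controls > 0L, n_misassigned >= 0L, n_misassigned <= n_controls)
  100 * n_misassigned / n_controls
}
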