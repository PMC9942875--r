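## Seeded generators emulating the statistical structure of every pipeline
## input: a toy locus and tiling library with planted variant effects,
## negative-binomial screen counts with arm structure, single-cell
## guide-UMI matrices drawn from a skew-t mixture, and amplicon variant
## tables with window-focused editing and a het/homo zygosity mix.

#' Simulation configuration
#'
#' Returns the default configuration, with any component overridden via
#' named arguments (partial lists are merged into the defaults). Defaults
#' describe a desk-scale screen: a ~0.4 kb CDS over three exons, a tiling
#' CBE library with planted loss-, gain- and separation-of-function
#' elements of 2 log2-unit effect, 500x sequencing depth with
#' negative-binomial dispersion 0.1 over two replicates, 500 cells with
#' well-separated present/background skew-t components and a 5% doublet
#' rate, and amplicon editing peaked inside the editor window.
#'
#' @param seed master seed; all generators derive their streams from it
#' @param gene,library,screen,single_cell,amplicon partial override lists
#' @return list of class `SimulationConfig`
#' @export
sim_config <- function(seed = 1L, gene = list(), library = list(),
                       screen = list(), single_cell = list(),
                       amplicon = list()) {
  defaults <- list(
    seed = as.integer(seed),
    gene = list(n_exons = 3L, cds_len = 900L, intron_len = 150L,
                utr5 = 60L, utr3 = 90L, pad = 400L),
    library = list(editor = "BE3-NGG", guides_per_element = 4L,
                   n_lof = 6L, n_gof = 3L, n_sof = 3L,
                   n_nontargeting = 30L, n_intergenic = 15L,
                   effect_lof = 2.0, effect_gof = -2.0, effect_sof = 2.0),
    screen = list(depth = 500, dispersion = 0.1, replicates = 2L,
                  abundance_sdlog = 0.5, facs_capture_bg = 0.02,
                  facs_capture_lof = 0.8, essential_dropout = -2.0),
    single_cell = list(n_cells = 500L, n_guides = 20L, doublet_rate = 0.05,
                       total_meanlog = log(8000), total_sdlog = 0.4,
                       present = list(location = -1.2, scale = 0.3,
                                      df = 6, alpha = -1),
                       background = list(location = -7.0, scale = 0.5,
                                         df = 5, alpha = 1.5)),
    amplicon = list(peak_efficiency = 0.35, background_efficiency = 0.01,
                    joint_rate = 0.3, synonymous_co_rate = 0.25,
                    bulk_depth = 1000L, cells_per_guide = 10L,
                    cell_depth = 200L, cell_edit_rate = 0.8,
                    het_fraction = 0.5, ploidy = 3L))
  over <- list(gene = gene, library = library, screen = screen,
               single_cell = single_cell, amplicon = amplicon)
  for (nm in names(over))
    defaults[[nm]] <- utils::modifyList(defaults[[nm]], over[[nm]])
  structure(defaults, class = "SimulationConfig")
}

SENSE_CODONS <- local({
  bases <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

#' Simulate a toy locus and tiling guide library
#'
#' Builds a contig carrying one plus-strand target gene (CDS split over
#' `n_exons` exons with canonical GT/AG introns and flanking UTRs) and two
#' small auxiliary genes (one "essential", one "non-essential") used for
#' stop-codon control guides. Tiling guides are enumerated over the target
#' gene's exons (padded to capture splice windows), grouped positionally
#' into elements of `guides_per_element`, and element classes (LOF / GOF /
#' SOF / neutral) are planted to match the configured counts. Control
#' guides: non-targeting 20-mers absent from the contig, intergenic guides
#' from the padding, and stop controls from [design_controls()] on the
#' auxiliary genes. Identical config and seed give identical output.
#'
#' @param config a [sim_config()]
#' @return list with `seqs` (DNAStringSet), `genes` (target gene first),
#'   `library` (guide table with `category`), `truth` (per-guide `element`,
#'   `class`, `effect_prolif`, `facs_lof`, `dropout`), `editor`
#' @export
simulate_locus_and_library <- function(config = sim_config()) {
  set.seed(child_seed(config$seed, 101))
  gc <- config$gene
  lc <- config$library
  editor <- editor_config(lc$editor)

  ## --- target gene ---------------------------------------------------
  n_cod <- gc$cds_len %/% 3L
  cds_seq <- paste0("ATG",
                    paste(sample(SENSE_CODONS, n_cod - 2L, replace = TRUE),
                          collapse = ""),
                    sample(c("TAA", "TAG", "TGA"), 1L))
  cds_split <- sort(sample(seq(3L, gc$cds_len - 3L, by = 3L), gc$n_exons - 1L))
  piece_len <- diff(c(0L, cds_split, gc$cds_len))
  pieces <- substring(cds_seq, cumsum(c(1L, piece_len[-gc$n_exons])),
                      cumsum(piece_len))
  intron <- function() {
    body <- random_dna(gc$intron_len - 4L)
    paste0("GT", body, "AG")
  }
  ## assemble: pad | utr5+exon1 | intron | ... | exonN+utr3 | pad
  parts <- character(0)
  exon_bounds <- list()
  cursor <- 0L
  add <- function(s) { parts <<- c(parts, s); cursor <<- cursor + nchar(s) }
  add(random_dna(gc$pad))
  utr5 <- random_dna(gc$utr5)
  for (i in seq_len(gc$n_exons)) {
    exon_seq <- pieces[i]
    if (i == 1L) exon_seq <- paste0(utr5, exon_seq)
    if (i == gc$n_exons) exon_seq <- paste0(exon_seq, random_dna(gc$utr3))
    exon_bounds[[i]] <- c(cursor, cursor + nchar(exon_seq))
    add(exon_seq)
    if (i < gc$n_exons) add(intron())
  }
  gene_end <- cursor
  add(random_dna(gc$pad))

  ## --- auxiliary stop-control genes ----------------------------------
  aux <- lapply(c("ESS1", "NONESS1"), function(id) {
    ## short single-exon genes rich in CAA/CAG codons so CBE stop controls exist
    n_aux <- 40L
    codons <- sample(c(SENSE_CODONS, rep(c("CAA", "CAG", "CGA"), 12L)),
                     n_aux - 2L, replace = TRUE)
    aux_cds <- paste0("ATG", paste(codons, collapse = ""),
                      sample(c("TAA", "TAG", "TGA"), 1L))
    start <- cursor
    add(aux_cds)
    add(random_dna(60L))
    gene_model(id, "chrSim", "+",
               exons = matrix(c(start, start + nchar(aux_cds)), ncol = 2L),
               cds = c(start, start + nchar(aux_cds)))
  })

  contig <- paste(parts, collapse = "")
  seqs <- Biostrings::DNAStringSet(c(chrSim = contig))
  exons <- do.call(rbind, exon_bounds)
  cds_start <- exon_bounds[[1L]][1L] + gc$utr5
  cds_end <- exon_bounds[[gc$n_exons]][2L] - gc$utr3
  target <- gene_model("TARGET1", "chrSim", "+", exons,
                       c(cds_start, cds_end), seqs = seqs)
  for (g in aux) validate_gene_model(g, seqs)

  ## --- tiling guides over the target gene ----------------------------
  pad_win <- 10L
  tiling <- do.call(rbind, lapply(seq_len(nrow(exons)), function(i)
    enumerate_guides(seqs, "chrSim",
                     c(max(0L, exons[i, 1L] - pad_win),
                       min(nchar(contig), exons[i, 2L] + pad_win)),
                     editor$pam_pattern)))
  tiling <- tiling[!duplicated(tiling$guide_id), ]
  tiling <- tiling[order(tiling$start, tiling$strand), ]
  prof <- profile_guides(tiling, editor)
  tiling <- tiling[!prof$no_target, ]          # only guides that can edit
  tiling$category <- "targeting"

  ## --- elements and planted classes ----------------------------------
  n_elements <- nrow(tiling) %/% lc$guides_per_element
  n_planted <- lc$n_lof + lc$n_gof + lc$n_sof
  if (n_planted > n_elements)
    stop("requested ", n_planted, " planted elements but only ", n_elements,
         " are available; enlarge the gene or reduce the class counts")
  tiling <- tiling[seq_len(n_elements * lc$guides_per_element), ]
  element <- paste0("E", rep(seq_len(n_elements), each = lc$guides_per_element))
  classes <- rep("neutral", n_elements)
  planted <- sample(n_elements, n_planted)
  classes[planted] <- rep(c("LOF", "GOF", "SOF"),
                          c(lc$n_lof, lc$n_gof, lc$n_sof))
  cls <- classes[rep(seq_len(n_elements), each = lc$guides_per_element)]

  ## --- control guides -------------------------------------------------
  nt <- character(0)
  while (length(nt) < lc$n_nontargeting) {
    cand <- random_dna(20L)
    if (protospacer_match_count(cand, seqs) == 0L) nt <- c(nt, cand)
  }
  nt_tab <- data.frame(guide_id = sprintf("NT_%03d", seq_along(nt)),
                       protospacer = nt, pam = NA_character_,
                       contig = NA_character_, start = NA_integer_,
                       strand = NA_character_, unique_in_input = NA,
                       category = "non_targeting", stringsAsFactors = FALSE)
  inter <- enumerate_guides(seqs, "chrSim", c(0L, gc$pad), editor$pam_pattern)
  inter <- head(inter, lc$n_intergenic)
  if (nrow(inter)) inter$category <- "intergenic"
  stops <- design_controls(aux, seqs, editor)
  stop_tab <- if (nrow(stops)) {
    data.frame(stops[, c("guide_id", "protospacer", "pam", "contig", "start",
                         "strand", "unique_in_input")],
               category = ifelse(stops$gene_id == "ESS1",
                                 "stop_control_essential",
                                 "stop_control_nonessential"),
               stringsAsFactors = FALSE)
  } else NULL
  stop_tab <- stop_tab[!duplicated(stop_tab$guide_id), ]

  library <- rbind(tiling[, names(nt_tab)[1:7]],
                   inter[, names(nt_tab)[1:7]],
                   if (!is.null(stop_tab)) stop_tab[, names(nt_tab)[1:7]],
                   nt_tab[, names(nt_tab)[1:7]])
  library$category <- c(tiling$category, inter$category,
                        if (!is.null(stop_tab)) stop_tab$category,
                        nt_tab$category)
  library <- library[!duplicated(library$guide_id), ]
  rownames(library) <- NULL

  ## --- truth table ----------------------------------------------------
  eff <- c(LOF = lc$effect_lof, GOF = lc$effect_gof, SOF = lc$effect_sof,
           neutral = 0)
  truth <- data.frame(
    guide_id = library$guide_id, category = library$category,
    element = NA_character_, class = "control", effect_prolif = 0,
    facs_lof = FALSE, dropout = 0, stringsAsFactors = FALSE)
  ti <- match(tiling$guide_id, truth$guide_id)
  truth$element[ti] <- element
  truth$class[ti] <- cls
  truth$effect_prolif[ti] <- eff[cls]
  truth$facs_lof[ti] <- cls == "LOF"
  ess <- truth$category == "stop_control_essential"
  truth$dropout[ess] <- config$screen$essential_dropout

  list(seqs = seqs, genes = c(list(target), aux), library = library,
       truth = truth, editor = editor)
}

#' Simulate screen count matrices with arm structure
#'
#' Guide abundances are drawn log-normal around the configured depth from
#' a common plasmid pool; each arm's expected counts modulate that
#' abundance and counts are negative-binomial. Arms: `plasmid` (one
#' sample), and per replicate `T0`, `control`, `IFNg` (expected counts
#' multiplied by `2^effect_prolif`) and `FACS_sorted`. The FACS arm models
#' a sort for IFN-gamma non-responders as binomial capture: LOF guides are
#' captured with probability `facs_capture_lof`, everything else at the
#' background rate, and the sorted pool is resequenced to the library
#' depth — so only LOF guides enrich there. Essential stop controls carry
#' a `dropout` log2 effect in every post-T0 arm.
#'
#' @param truth truth table from [simulate_locus_and_library()] (only
#'   `guide_id`, `effect_prolif`, `facs_lof`, `dropout` are used)
#' @param config a [sim_config()]
#' @return a [count_matrix()]
#' @export
simulate_screen_counts <- function(truth, config = sim_config()) {
  sc <- config$screen
  set.seed(child_seed(config$seed, 202))
  n <- nrow(truth)
  size <- 1 / sc$dispersion
  abundance <- rlnorm(n, meanlog = log(sc$depth), sdlog = sc$abundance_sdlog)
  nb <- function(mu) rnbinom(n, mu = pmax(mu, 1e-8), size = size)

  cols <- list(plasmid = nb(abundance))
  meta <- data.frame(sample = "plasmid", assay = "plasmid", replicate = "R0",
                     stringsAsFactors = FALSE)
  post <- abundance * 2^truth$dropout
  capture <- ifelse(truth$facs_lof, sc$facs_capture_lof, sc$facs_capture_bg)
  mu_facs <- post * capture
  mu_facs <- mu_facs / sum(mu_facs) * n * sc$depth
  for (r in seq_len(sc$replicates)) {
    rep_id <- paste0("R", r)
    arm <- list(T0 = nb(abundance),
                control = nb(post),
                IFNg = nb(post * 2^truth$effect_prolif),
                FACS_sorted = nb(mu_facs))
    for (a in names(arm)) {
      nm <- paste0(a, "_", rep_id)
      cols[[nm]] <- arm[[a]]
      meta <- rbind(meta, data.frame(sample = nm, assay = a,
                                     replicate = rep_id,
                                     stringsAsFactors = FALSE))
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- truth$guide_id
  count_matrix(counts, meta)
}

#' Simulate a single-cell guide-UMI matrix
#'
#' Each cell receives one truth guide (two at the doublet rate); the
#' log normalized UMI fraction of present entries is drawn from the
#' "present" skew-t component and background entries from the background
#' component, then converted to counts against a log-normal per-cell total.
#'
#' @param config a [sim_config()]
#' @return list with `umi` (cells x guides matrix), `truth` (data.frame
#'   `cell`, `guides` comma-separated), `totals`
#' @export
simulate_umi_matrix <- function(config = sim_config()) {
  cc <- config$single_cell
  set.seed(child_seed(config$seed, 303))
  n <- cc$n_cells; g <- cc$n_guides
  guides <- sprintf("g%03d", seq_len(g))
  cells <- sprintf("cell%04d", seq_len(n))
  totals <- round(rlnorm(n, cc$total_meanlog, cc$total_sdlog))
  bg <- cc$background; pr <- cc$present
  x <- matrix(rskewt(n * g, bg$location, bg$scale, bg$df, bg$alpha),
              nrow = n, dimnames = list(cells, guides))
  truth_guides <- vector("list", n)
  for (i in seq_len(n)) {
    k <- 1L + (runif(1) < cc$doublet_rate)
    mine <- sample(g, k)
    x[i, mine] <- rskewt(k, pr$location, pr$scale, pr$df, pr$alpha)
    truth_guides[[i]] <- guides[sort(mine)]
  }
  umi <- round(exp(x) * totals)
  list(umi = umi,
       truth = data.frame(cell = cells,
                          guides = vapply(truth_guides, paste,
                                          character(1), collapse = ","),
                          stringsAsFactors = FALSE),
       totals = setNames(totals, cells))
}

#' Simulate amplicon variant observations (bulk and per cell)
#'
#' Per guide, the edited position set of each observation is drawn from
#' the outcome support of [enumerate_outcomes()] (all editable window
#' positions jointly at `joint_rate`, otherwise one single position,
#' weighted by a per-position efficiency profile peaked inside the editor
#' window). Bulk rows carry binomial alt/total read counts at the
#' position's efficiency; per-cell rows draw a zygosity (het vs homo at
#' the configured mix and ploidy) and binomial allele counts around the
#' implied allele fraction. With probability `synonymous_co_rate` an
#' edited sample also carries a planted synonymous co-edit.
#'
#' @param library guide table (targeting guides with genomic coordinates)
#' @param editor an [editor_config()]
#' @param config a [sim_config()]
#' @return list with `bulk` and `cells` observation data.frames (columns
#'   of [vaf_profile()] plus `consequence` and, for cells, `true_zygosity`)
#' @export
simulate_amplicon_calls <- function(library, editor, config = sim_config()) {
  ac <- config$amplicon
  set.seed(child_seed(config$seed, 404))
  targeting <- library[!is.na(library$start), ]
  prof <- profile_guides(targeting, editor)
  bulk <- list(); cells <- list()
  for (i in seq_len(nrow(targeting))) {
    gd <- targeting[i, ]
    ed <- as.integer(strsplit(prof$editable_positions[i], ",")[[1L]])
    if (length(ed) == 0L) next
    on_plus <- gd$strand == "+"
    ref <- if (on_plus) editor$source_base else revcomp(editor$source_base)
    alt <- if (on_plus) editor$product_base else revcomp(editor$product_base)
    eff <- ifelse(ed >= editor$window[1L] & ed <= editor$window[2L],
                  ac$peak_efficiency, ac$background_efficiency)
    can_edit <- any(eff > 0)
    pick_positions <- function() {
      if (length(ed) == 1L) return(ed)
      if (runif(1) < ac$joint_rate) ed
      else ed[sample.int(length(ed), 1L, prob = eff)]
    }
    emit <- function(sample_id, positions, alt_reads, total_reads, zyg = NULL) {
      data.frame(sample = sample_id, contig = gd$contig,
                 pos = protospacer_to_genomic(gd$start, gd$strand,
                                              positions) + 1L,
                 ref = ref, alt = alt, alt_reads = alt_reads,
                 total_reads = total_reads, guide_id = gd$guide_id,
                 consequence = "missense",
                 true_zygosity = zyg %||% NA_character_,
                 stringsAsFactors = FALSE)
    }
    ## bulk: one pooled sample per guide, per-position efficiency
    bsample <- paste0("bulk_", gd$guide_id)
    balt <- rbinom(length(ed), ac$bulk_depth, eff)
    bulk[[length(bulk) + 1L]] <- emit(bsample, ed, balt, ac$bulk_depth)
    ## cells
    for (ci in seq_len(ac$cells_per_guide)) {
      cid <- sprintf("%s_c%02d", gd$guide_id, ci)
      ## unedited cell (or inert guide at zero efficiency): no variant rows
      if (!can_edit || runif(1) >= ac$cell_edit_rate) next
      pos <- pick_positions()
      het <- runif(1) < ac$het_fraction
      af <- if (het) 1 / ac$ploidy
            else sample(c((ac$ploidy - 1) / ac$ploidy, 1), 1L)
      calt <- rbinom(length(pos), ac$cell_depth, af)
      rows <- emit(cid, pos, calt, ac$cell_depth,
                   zyg = if (het) "het" else "homo")
      if (runif(1) < ac$synonymous_co_rate) {
        syn_pos <- protospacer_to_genomic(gd$start, gd$strand,
                                          sample(setdiff(1:20, ed), 1L)) + 1L
        rows <- rbind(rows, data.frame(
          sample = cid, contig = gd$contig, pos = syn_pos, ref = ref,
          alt = alt, alt_reads = rbinom(1L, ac$cell_depth, af),
          total_reads = ac$cell_depth, guide_id = gd$guide_id,
          consequence = "synonymous",
          true_zygosity = if (het) "het" else "homo",
          stringsAsFactors = FALSE))
      }
      cells[[length(cells) + 1L]] <- rows
    }
  }
  list(bulk = do.call(rbind, bulk) %||% NULL,
       cells = do.call(rbind, cells) %||% NULL)
}
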