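# Fixture builders. All contigs are constructed in code at test time.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

rand_sense_codons <- function(n) {
  bases <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense <- setdiff(all, c("TAA", "TAG", "TGA"))
  paste(sample(sense, n, replace = TRUE), collapse = "")
}

# A random toy gene with UTR exonic flanks, canonical GT/AG introns and a
# valid CDS, on either strand. Coordinates are built by explicit string
# concatenation so the fixture is independent of the package's readers.
random_toy_gene <- function(seed, n_exons = sample(1:3, 1), strand = NULL,
                            n_codons = 12L, id = "toy") {
  set.seed(seed)
  strand <- strand %||% sample(c("+", "-"), 1)
  cds <- paste0("ATG", rand_sense_codons(n_codons - 2L),
                sample(c("TAA", "TAG", "TGA"), 1))
  gcds <- if (strand == "-") oracle_revcomp(cds) else cds
  cds_len <- nchar(gcds)
  cuts <- if (n_exons > 1)
    sort(sample(seq_len(cds_len - 1L), n_exons - 1L)) else integer(0)
  piece_len <- diff(c(0L, cuts, cds_len))
  starts <- cumsum(c(1L, piece_len[-n_exons]))
  pieces <- substring(gcds, starts, starts + piece_len - 1L)

  pad <- 12L; utr_l <- 6L; utr_r <- 7L; intron_len <- 11L
  parts <- character(0); cursor <- 0L
  exons <- matrix(0L, n_exons, 2L)
  add <- function(s) { parts <<- c(parts, s); cursor <<- cursor + nchar(s) }
  add(rand_dna(pad))
  for (i in seq_len(n_exons)) {
    ex <- pieces[i]
    if (i == 1L) ex <- paste0(rand_dna(utr_l), ex)
    if (i == n_exons) ex <- paste0(ex, rand_dna(utr_r))
    exons[i, ] <- c(cursor, cursor + nchar(ex))
    add(ex)
    if (i < n_exons) add(paste0("GT", rand_dna(intron_len - 4L), "AG"))
  }
  add(rand_dna(pad))
  contig <- paste(parts, collapse = "")
  cds_span <- c(exons[1L, 1L] + utr_l, exons[n_exons, 2L] - utr_r)
  seqs <- Biostrings::DNAStringSet(c(chrT = contig))
  gene <- gene_model(id, "chrT", strand, exons, cds_span, seqs = seqs)
  list(seqs = seqs, gene = gene, contig = contig, cds = cds)
}

# Hand-built single-exon plus-strand gene around a given CDS string
flat_gene <- function(cds, pad5 = 10L, pad3 = 10L, utr5 = 4L, utr3 = 5L,
                      id = "flat", seed = 99, strand = "+") {
  set.seed(seed)
  genomic_cds <- if (strand == "-") oracle_revcomp(cds) else cds
  contig <- paste0(rand_dna(pad5), rand_dna(utr5), genomic_cds, rand_dna(utr3),
                   rand_dna(pad3))
  exons <- matrix(c(pad5, pad5 + utr5 + nchar(cds) + utr3), 1L, 2L)
  cds_span <- c(pad5 + utr5, pad5 + utr5 + nchar(cds))
  seqs <- Biostrings::DNAStringSet(setNames(contig, "chrF"))
  gene <- gene_model(id, "chrF", strand, exons, cds_span, seqs = seqs)
  list(seqs = seqs, gene = gene, cds_span = cds_span, exons = exons)
}

# truth table for screen simulations without a locus (element structure only)
flat_truth <- function(n_elements, guides_per_element = 4L, n_lof = 0L,
                       n_gof = 0L, n_sof = 0L, n_controls = 100L,
                       effect = 2.0, seed = 1) {
  set.seed(seed)
  cls <- rep("neutral", n_elements)
  planted <- sample(n_elements, n_lof + n_gof + n_sof)
  cls[planted] <- rep(c("LOF", "GOF", "SOF"), c(n_lof, n_gof, n_sof))
  eff <- c(LOF = effect, GOF = -effect, SOF = effect, neutral = 0)
  per <- guides_per_element
  tg <- data.frame(
    guide_id = sprintf("t%04d", seq_len(n_elements * per)),
    element = rep(sprintf("E%03d", seq_len(n_elements)), each = per),
    class = rep(cls, each = per),
    effect_prolif = rep(unname(eff[cls]), each = per),
    facs_lof = rep(cls == "LOF", each = per),
    dropout = 0, stringsAsFactors = FALSE)
  ctrl <- data.frame(
    guide_id = sprintf("c%03d", seq_len(n_controls)),
    element = NA_character_, class = "control", effect_prolif = 0,
    facs_lof = FALSE, dropout = 0, stringsAsFactors = FALSE)
  rbind(tg, ctrl)
}

# score + classify a simulated screen; returns calls merged with truth
score_and_classify <- function(truth, config, n_benchmark_lof = 10L,
                               n_benchmark_gof = 5L) {
  cm <- simulate_screen_counts(truth, config)
  ctrl <- truth$guide_id[truth$class == "control"]
  mapping <- stats::na.omit(truth[, c("guide_id", "element")])
  pro <- run_screen(cm, "IFNg", "control", ctrl, mapping)
  fac <- run_screen(cm, "FACS_sorted", "control", ctrl, mapping)
  el_cls <- unique(truth[!is.na(truth$element), c("element", "class")])
  bl_el <- head(el_cls$element[el_cls$class == "LOF"], n_benchmark_lof)
  bg_el <- head(el_cls$element[el_cls$class == "GOF"], n_benchmark_gof)
  zp <- setNames(pro$guide_z_mean$z, pro$guide_z_mean$guide_id)
  zf <- setNames(fac$guide_z_mean$z, fac$guide_z_mean$guide_id)
  blg <- truth$guide_id[truth$element %in% bl_el]
  bgg <- truth$guide_id[truth$element %in% bg_el]
  calls <- classify_variants(pro$element_scores, fac$element_scores,
                             list(prolif = zp[blg], facs = zf[blg]),
                             list(prolif = zp[bgg]))
  list(merged = merge(calls, el_cls), prolif = pro, facs = fac,
       counts = cm)
}
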