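## Predicted edited alleles and their protein consequences.
##
## Outcome space per guide: each single editable window position alone,
## plus the joint edit of all editable positions when two or more exist —
## the allele set base-editing screens are scored against. An optional
## combinatorial mode enumerates every non-empty subset for small numbers
## of editable bases.

CONSEQUENCE_LEVELS <- c("stop_gained", "start_lost", "splice_variant",
                        "missense", "UTR", "synonymous", "intron",
                        "intergenic")

#' Prioritize consequence labels
#'
#' Collapses a multiset of per-position consequence labels to the most
#' deleterious under the total order stop gain > start loss > splice
#' variant > missense > UTR > synonymous > intron > intergenic.
#'
#' @param labels non-empty character vector of consequence labels
#' @return single most-deleterious label
#' @export
prioritize <- function(labels) {
  if (length(labels) == 0L) stop("prioritize() needs at least one label")
  bad <- setdiff(labels, CONSEQUENCE_LEVELS)
  if (length(bad)) stop("unknown consequence label(s): ",
                        paste(bad, collapse = ", "))
  CONSEQUENCE_LEVELS[min(match(labels, CONSEQUENCE_LEVELS))]
}

#' Enumerate predicted editing outcomes for a guide
#'
#' @param guide single-row guide data.frame (or list) with `guide_id`,
#'   `protospacer`, `contig`, `start`, `strand`
#' @param editor an [editor_config()]; the guide's PAM is expected to match
#'   the editor's pattern
#' @param combinatorial if `TRUE`, enumerate all non-empty subsets of
#'   editable positions (only sensible for small windows); default is
#'   singles plus the all-positions joint edit
#' @return list of `PredictedOutcome` objects, each with `guide_id`,
#'   `edited_positions` (protospacer coordinates) and `variants`, a
#'   data.frame of reference-strand substitutions (`contig`, `pos` 0-based,
#'   `ref`, `alt`). Empty list when the guide has no editable base.
#' @export
enumerate_outcomes <- function(guide, editor, combinatorial = FALSE) {
  guide <- as.list(guide)
  bases <- strsplit(guide$protospacer, "")[[1L]]
  win <- editor$window[1L]:editor$window[2L]
  editable <- win[bases[win] == editor$source_base]
  k <- length(editable)
  if (k == 0L) return(list())
  sets <- if (combinatorial) {
    unlist(lapply(seq_len(k), function(m)
      utils::combn(editable, m, simplify = FALSE)), recursive = FALSE)
  } else {
    c(lapply(editable, identity),
      if (k >= 2L) list(editable))
  }
  on_plus <- guide$strand == "+"
  ref <- if (on_plus) editor$source_base else revcomp(editor$source_base)
  alt <- if (on_plus) editor$product_base else revcomp(editor$product_base)
  lapply(sets, function(ps) {
    structure(list(
      guide_id = guide$guide_id,
      edited_positions = as.integer(ps),
      variants = data.frame(
        contig = guide$contig,
        pos = protospacer_to_genomic(guide$start, guide$strand, as.integer(ps)),
        ref = ref, alt = alt, stringsAsFactors = FALSE)),
      class = "PredictedOutcome")
  })
}

## apply reference-strand substitutions; returns a named character vector
## (accepted everywhere a contig set is, via contig_string())
apply_variants <- function(seqs, variants) {
  chars <- if (is.character(seqs)) seqs else
    stats::setNames(as.character(seqs), names(seqs))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    cur <- substr(chars[[v$contig]], v$pos + 1L, v$pos + 1L)
    if (cur != v$ref)
      stop("variant ref base mismatch at ", v$contig, ":", v$pos + 1L,
           " (expected ", v$ref, ", genome has ", cur,
           "; guide and genome out of sync)")
    substr(chars[[v$contig]], v$pos + 1L, v$pos + 1L) <- v$alt
  }
  chars
}

#' Annotate a predicted outcome against gene models
#'
#' Applies the outcome's variants to a copy of the genome, re-splices and
#' re-translates each gene, and derives per-position labels via [locate()]:
#' CDS positions become `start_lost` (edit in the annotated start codon),
#' `stop_gained`, `missense` or `synonymous` from the codon-level diff;
#' intronic positions within the splice window become `splice_variant`;
#' UTR/intron/intergenic label as such. The outcome's `consequence` is the
#' prioritized label over all edited positions and all genes (ties across
#' genes broken by gene id order); `protein_changes` lists every residue
#' whose amino acid differs after editing, for the gene that supplied the
#' prioritized consequence.
#'
#' @param outcome a `PredictedOutcome` from [enumerate_outcomes()]
#' @param genes a [gene_model()] or list of them
#' @param seqs contig sequences
#' @param splice_window passed to [locate()]
#' @return the outcome with `consequence`, `protein_changes` (data.frame
#'   `residue`, `ref_aa`, `alt_aa`) and per-gene `labels` filled in
#' @export
annotate_outcome <- function(outcome, genes, seqs, splice_window = 2L) {
  if (inherits(genes, "GeneModel")) genes <- list(genes)
  genes <- genes[order(vapply(genes, `[[`, character(1), "id"))]
  if (!is.character(seqs))
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  edited_seqs <- apply_variants(seqs, outcome$variants)

  per_gene <- lapply(genes, function(gene) {
    if (!identical(gene$chrom, outcome$variants$contig[1L]))
      return(list(labels = rep("intergenic", nrow(outcome$variants)),
                  changes = empty_protein_changes()))
    orig <- spliced_cds_and_protein(gene, seqs, check = FALSE)
    new <- spliced_cds_and_protein(gene, edited_seqs, check = FALSE)
    po <- strsplit(orig$protein, "")[[1L]]
    pn <- strsplit(new$protein, "")[[1L]]
    diff <- which(po != pn)
    changes <- data.frame(residue = diff, ref_aa = po[diff], alt_aa = pn[diff],
                          stringsAsFactors = FALSE)
    labels <- vapply(outcome$variants$pos, function(pos) {
      lab <- locate(gene, pos, splice_window = splice_window)
      switch(lab$category,
        CDS = {
          if (lab$codon_index == 0L) "start_lost"
          else {
            i <- lab$codon_index + 1L
            if (i > length(po)) "synonymous"      # edit in a trailing partial codon
            else if (pn[i] == po[i]) "synonymous"
            else if (pn[i] == "*") "stop_gained"
            else "missense"
          }
        },
        five_prime_UTR = "UTR", three_prime_UTR = "UTR",
        splice_region = "splice_variant",
        intron = "intron", intergenic = "intergenic")
    }, character(1))
    list(labels = labels, changes = changes)
  })

  best <- prioritize(unlist(lapply(per_gene, `[[`, "labels")))
  ## first gene (id order) attaining the prioritized consequence
  which_gene <- which(vapply(per_gene, function(pg) best %in% pg$labels,
                             logical(1)))[1L]
  outcome$consequence <- best
  outcome$protein_changes <- per_gene[[which_gene]]$changes
  outcome$labels <- per_gene[[which_gene]]$labels
  outcome
}

empty_protein_changes <- function() {
  data.frame(residue = integer(), ref_aa = character(), alt_aa = character(),
             stringsAsFactors = FALSE)
}

## residue index of the CDS base nearest a genomic position (for splice
## outcomes, which touch no codon directly)
nearest_cds_residue <- function(gene, pos) {
  pieces <- cds_pieces(gene)
  cand <- unlist(lapply(seq_len(nrow(pieces)), function(i) {
    c(pieces[i, 1L], pieces[i, 2L] - 1L)
  }))
  nearest <- cand[which.min(abs(cand - pos))]
  locate(gene, nearest)$codon_index + 1L
}

#' Amino-acid mutagenesis coverage of a gene
#'
#' Fraction of protein residues touched by at least one predicted
#' non-synonymous outcome, per guide set and for the union of all sets.
#' A residue is covered when it appears in an outcome's protein changes,
#' when a start-loss touches residue 1, or when a splice outcome implicates
#' the codon nearest the affected boundary. The denominator is the protein
#' length excluding the terminal stop.
#'
#' @param gene a [gene_model()]
#' @param seqs contig sequences
#' @param guide_sets named list; each element a list with `guides` (guide
#'   data.frame) and `editor` (an [editor_config()])
#' @return list with `per_set` (named numeric coverages), `union`
#'   (numeric), `residues` (list of covered residue index vectors) and
#'   `protein_length`
#' @export
aa_coverage <- function(gene, seqs, guide_sets) {
  if (!is.character(seqs))
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  protein <- spliced_cds_and_protein(gene, seqs, check = FALSE)$protein
  L <- nchar(protein) - (substr(protein, nchar(protein), nchar(protein)) == "*")
  covered <- lapply(guide_sets, function(set) {
    res <- integer()
    for (i in seq_len(nrow(set$guides))) {
      for (oc in enumerate_outcomes(set$guides[i, ], set$editor)) {
        ann <- annotate_outcome(oc, gene, seqs)
        res <- c(res, ann$protein_changes$residue)
        if (ann$consequence == "start_lost") res <- c(res, 1L)
        if (ann$consequence == "splice_variant") {
          sp <- ann$variants$pos[ann$labels == "splice_variant"]
          res <- c(res, vapply(sp, nearest_cds_residue, integer(1), gene = gene))
        }
      }
    }
    sort(unique(res[res >= 1L & res <= L]))
  })
  per_set <- vapply(covered, function(r) length(r) / L, numeric(1))
  union_res <- sort(unique(unlist(covered)))
  list(per_set = per_set, union = length(union_res) / L,
       residues = covered, protein_length = L)
}

#' Flatten annotated outcomes to a table
#'
#' One row per outcome with 1-based `chrom:pos:ref:alt` variant strings and
#' HGVS-like `p.Q123*` protein-change shorthand.
#'
#' @param outcomes list of annotated `PredictedOutcome` objects
#' @return data.frame
#' @export
outcomes_table <- function(outcomes) {
  do.call(rbind, lapply(outcomes, function(oc) {
    data.frame(
      guide_id = oc$guide_id,
      edited_positions = paste(oc$edited_positions, collapse = ","),
      variants = paste(sprintf("%s:%d:%s:%s", oc$variants$contig,
                               oc$variants$pos + 1L, oc$variants$ref,
                               oc$variants$alt), collapse = ";"),
      consequence = oc$consequence %||% NA_character_,
      protein_changes = if (!is.null(oc$protein_changes) &&
                            nrow(oc$protein_changes))
        paste(sprintf("p.%s%d%s", oc$protein_changes$ref_aa,
                      oc$protein_changes$residue,
                      oc$protein_changes$alt_aa), collapse = ";")
      else "", stringsAsFactors = FALSE)
  }))
}
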