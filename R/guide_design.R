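## Tiling-guide enumeration, editability profiling and stop-control design.
##
## Guide coordinate frame: protospacer positions 1-20 with the PAM at
## 21-23. `start` is the 0-based leftmost genomic coordinate of the 20-nt
## protospacer on either strand; on "+" the PAM occupies [start+20,
## start+23), on "-" it occupies [start-3, start) (reference strand), the
## protospacer-strand sequence being the reverse complement.

#' Enumerate candidate guides over a region
#'
#' Scans both strands of a contig for 20-mers whose adjacent 3-mer matches
#' the PAM pattern (IUPAC). Uniqueness (`unique_in_input`) counts exact
#' protospacer matches over both strands of all supplied contigs — a
#' desk-scale stand-in for a genome-wide uniqueness search.
#'
#' @param seqs named [Biostrings::DNAStringSet] of contigs
#' @param contig contig to scan
#' @param region optional 0-based half-open interval to scan (default the
#'   whole contig); regions shorter than 23 nt yield an empty table
#' @param pam_pattern IUPAC PAM triplet (default `"NGG"`)
#' @return data.frame with columns `guide_id`, `protospacer`, `pam`,
#'   `contig`, `start`, `strand`, `unique_in_input`
#' @export
enumerate_guides <- function(seqs, contig, region = NULL, pam_pattern = "NGG") {
  if (!contig %in% names(seqs)) stop("contig '", contig, "' not in sequences")
  len <- length(seqs[[contig]])
  region <- as.integer(region %||% c(0L, len))
  stopifnot(length(region) == 2L, region[1L] >= 0L, region[2L] <= len)
  empty <- data.frame(guide_id = character(), protospacer = character(),
                      pam = character(), contig = character(),
                      start = integer(), strand = character(),
                      unique_in_input = logical(), stringsAsFactors = FALSE)
  if (region[2L] - region[1L] < 23L) return(empty)
  s <- as.character(Biostrings::subseq(seqs[[contig]], region[1L] + 1L, region[2L]))
  n <- nchar(s)
  offs <- seq_len(n - 22L)  # 1-based offset of the 23-mer within the region
  sites23 <- substring(s, offs, offs + 22L)

  ## plus strand: protospacer = 23mer[1:20], PAM = 23mer[21:23]
  pam_p <- substring(sites23, 21L, 23L)
  hit_p <- pam_matches(pam_p, pam_pattern)
  plus <- data.frame(
    protospacer = substring(sites23[hit_p], 1L, 20L),
    pam = pam_p[hit_p],
    start = region[1L] + offs[hit_p] - 1L,
    strand = rep("+", sum(hit_p)), stringsAsFactors = FALSE)

  ## minus strand: reference PAM is the first 3 bases of the 23-mer,
  ## protospacer-strand sequence is the reverse complement
  rc23 <- revcomp(sites23)
  pam_m <- substring(rc23, 21L, 23L)
  hit_m <- pam_matches(pam_m, pam_pattern)
  minus <- data.frame(
    protospacer = substring(rc23[hit_m], 1L, 20L),
    pam = pam_m[hit_m],
    start = region[1L] + offs[hit_m] - 1L + 3L,
    strand = rep("-", sum(hit_m)), stringsAsFactors = FALSE)

  g <- rbind(plus, minus)
  if (nrow(g) == 0L) return(empty)
  g$contig <- contig
  g$guide_id <- sprintf("%s_%d_%s", g$contig, g$start, g$strand)
  g$unique_in_input <- protospacer_match_count(g$protospacer, seqs) == 1L
  rownames(g) <- NULL
  g[, c("guide_id", "protospacer", "pam", "contig", "start", "strand",
        "unique_in_input")]
}

## exact occurrences of each 20-mer over both strands of all contigs
protospacer_match_count <- function(protospacers, seqs) {
  strs <- if (is.character(seqs)) seqs else as.character(seqs)
  both <- c(strs, revcomp_chr(strs))
  count_in <- function(p, s) {
    m <- gregexpr(p, s, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) 0L else length(m)
  }
  vapply(protospacers, function(p)
    sum(vapply(both, count_in, integer(1), p = p)),
    integer(1), USE.NAMES = FALSE)
}

#' Reconstruct protospacer+PAM from the genome
#'
#' The invariant check behind every guide table: slicing the genome at
#' `(start, strand)` must reproduce `protospacer + pam`.
#'
#' @param guides guide data.frame as from [enumerate_guides()]
#' @param seqs contig sequences
#' @return character vector of 23-mers (protospacer-strand orientation)
#' @export
guide_site_sequence <- function(guides, seqs) {
  vapply(seq_len(nrow(guides)), function(i) {
    g <- guides[i, ]
    contig <- seqs[[g$contig]]
    if (g$strand == "+") {
      as.character(Biostrings::subseq(contig, g$start + 1L, g$start + 23L))
    } else {
      revcomp(as.character(Biostrings::subseq(contig, g$start - 2L, g$start + 20L)))
    }
  }, character(1))
}

## 0-based reference coordinate of protospacer position p (1..20)
protospacer_to_genomic <- function(start, strand, p) {
  ifelse(strand == "+", start + p - 1L, start + 20L - p)
}

## inverse: protospacer position of a 0-based reference coordinate
genomic_to_protospacer <- function(start, strand, pos) {
  ifelse(strand == "+", pos - start + 1L, start + 20L - pos)
}

#' Profile guides for editor-specific editability and QC flags
#'
#' For each guide: the editable positions (window positions whose
#' protospacer base equals the editor's source base; IUPAC ambiguity codes
#' never count as editable), `no_target` (no editable position),
#' `exclusively_gc_context` (cytidine editors only: every window C sits
#' immediately 3' of a G on the protospacer strand, the context disfavoured
#' by APOBEC deaminases), and `polyT` (a TTTT tract anywhere in the
#' protospacer, a potential U6 termination signal).
#'
#' @param guides guide data.frame
#' @param editor an [editor_config()]
#' @return data.frame with `guide_id`, `editable_positions`
#'   (comma-separated), `n_editable`, `no_target`,
#'   `exclusively_gc_context`, `polyT`
#' @export
profile_guides <- function(guides, editor) {
  win <- editor$window[1L]:editor$window[2L]
  res <- lapply(guides$protospacer, function(sp) {
    bases <- strsplit(sp, "")[[1L]]
    ed <- win[bases[win] == editor$source_base]
    gc <- if (editor$source_base == "C" && length(ed) > 0L)
      all(ed > 1L & bases[pmax(ed - 1L, 1L)] == "G") else FALSE
    list(ed = ed, gc = gc)
  })
  data.frame(
    guide_id = guides$guide_id,
    editable_positions = vapply(res, function(r) paste(r$ed, collapse = ","),
                                character(1)),
    n_editable = vapply(res, function(r) length(r$ed), integer(1)),
    no_target = vapply(res, function(r) length(r$ed) == 0L, logical(1)),
    exclusively_gc_context = vapply(res, function(r) r$gc, logical(1)),
    polyT = grepl("TTTT", guides$protospacer, fixed = TRUE),
    stringsAsFactors = FALSE)
}

#' Select stop-introducing control guides
#'
#' Enumerates guides over each gene's span (padded so windows flanking the
#' terminal exons are included), predicts edited alleles under the editor
#' model, and keeps every guide with at least one outcome whose prioritized
#' consequence is `stop_gained` in the target gene.
#'
#' @param genes list of [gene_model()] objects
#' @param seqs contig sequences
#' @param editor an [editor_config()]
#' @param pad bases added on each side of the gene span before enumeration
#' @return data.frame of stop-control guides with columns of
#'   [enumerate_guides()] plus `gene_id`, `edited_positions` and
#'   `protein_change` of the stop-introducing outcome
#' @export
design_controls <- function(genes, seqs, editor, pad = 30L) {
  seqs_chr <- stats::setNames(as.character(seqs), names(seqs))
  out <- lapply(genes, function(gene) {
    len <- length(seqs[[gene$chrom]])
    region <- c(max(0L, gene$exons[1L, 1L] - pad),
                min(len, gene$exons[nrow(gene$exons), 2L] + pad))
    guides <- enumerate_guides(seqs, gene$chrom, region, editor$pam_pattern)
    if (nrow(guides) == 0L) return(NULL)
    hits <- lapply(seq_len(nrow(guides)), function(i) {
      outcomes <- enumerate_outcomes(guides[i, ], editor)
      for (oc in outcomes) {
        ann <- tryCatch(annotate_outcome(oc, gene, seqs_chr),
                        error = function(e) NULL)
        if (!is.null(ann) && ann$consequence == "stop_gained") {
          pc <- ann$protein_changes
          return(data.frame(
            guides[i, ], gene_id = gene$id,
            edited_positions = paste(oc$edited_positions, collapse = ","),
            protein_change = paste(sprintf("p.%s%d%s", pc$ref_aa, pc$residue,
                                           pc$alt_aa), collapse = ";"),
            stringsAsFactors = FALSE))
        }
      }
      NULL
    })
    do.call(rbind, hits)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(guide_id = character(), protospacer = character(),
                      pam = character(), contig = character(),
                      start = integer(), strand = character(),
                      unique_in_input = logical(), gene_id = character(),
                      edited_positions = character(),
                      protein_change = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Write / read a guide library TSV
#'
#' Columns: `guide_id`, `protospacer`, `pam`, `contig`, `start` (0-based),
#' `strand`, `category` (one of `targeting`, `stop_control_essential`,
#' `stop_control_nonessential`, `non_targeting`, `intergenic`).
#'
#' @param library guide library data.frame
#' @param path output TSV path
#' @export
write_library <- function(library, path) {
  write.table(library, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
}
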