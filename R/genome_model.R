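## Gene-model containers, readers/writers, coordinate mapping and translation.
##
## Conventions: all internal genomic coordinates are 0-based half-open
## intervals; emitted variant tables are 1-based (VCF convention).

#' Construct and validate a gene model
#'
#' A `GeneModel` holds the transcript anatomy needed for consequence
#' annotation: exons, the genomic CDS span and the strand, all on a single
#' contig. Exons are stored as a two-column matrix of 0-based half-open
#' `[start, end)` intervals sorted by start. The CDS span must lie within
#' the exon union and, once spliced and strand-oriented, yield a sequence
#' whose length is a positive multiple of 3 and which begins with ATG.
#' Sequence-level checks run only when `seqs` is supplied.
#'
#' @param id gene/transcript identifier
#' @param chrom contig name
#' @param strand `"+"` or `"-"`
#' @param exons two-column matrix (or coercible) of 0-based half-open
#'   exon intervals
#' @param cds length-2 vector, 0-based half-open genomic CDS span
#' @param seqs optional named [Biostrings::DNAStringSet] of contig
#'   sequences used to validate the spliced CDS
#' @param permissive logical; if `TRUE`, CDS length/start-codon violations
#'   downgrade from errors to warnings
#' @return an object of class `GeneModel`
#' @export
gene_model <- function(id, chrom, strand, exons, cds, seqs = NULL,
                       permissive = FALSE) {
  exons <- matrix(as.integer(as.matrix(exons)), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] - exons[, 1L] < 1L))
    stop("gene ", id, ": every exon must have length >= 1")
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("gene ", id, ": exons overlap")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  cds <- as.integer(cds)
  if (length(cds) != 2L || cds[2L] <= cds[1L])
    stop("gene ", id, ": cds span must be a non-empty interval")
  if (cds[1L] < exons[1L, 1L] || cds[2L] > exons[nrow(exons), 2L])
    stop("gene ", id, ": cds span outside exon union")
  gene <- structure(
    list(id = as.character(id), chrom = as.character(chrom), strand = strand,
         exons = exons, cds = cds),
    class = "GeneModel")
  if (!is.null(seqs)) validate_gene_model(gene, seqs, permissive = permissive)
  gene
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s  %s%s  %d exon(s), CDS [%d,%d)\n",
              x$id, x$chrom, x$strand, nrow(x$exons), x$cds[1L], x$cds[2L]))
  invisible(x)
}

## sequence-level invariants; called at load time when sequences are known
validate_gene_model <- function(gene, seqs, permissive = FALSE) {
  if (!gene$chrom %in% names(seqs))
    stop("gene ", gene$id, ": contig '", gene$chrom, "' missing from sequences")
  cds <- spliced_cds_and_protein(gene, seqs, check = FALSE)$cds
  complain <- if (permissive) warning else stop
  if (nchar(cds) == 0L || nchar(cds) %% 3L != 0L)
    complain("gene ", gene$id, ": spliced CDS length ", nchar(cds),
             " is not a positive multiple of 3", call. = FALSE)
  if (substr(cds, 1L, 3L) != "ATG")
    complain("gene ", gene$id, ": spliced CDS does not begin with a start codon",
             call. = FALSE)
  invisible(gene)
}

## exon intervals clipped to the CDS span, genomic order, 0-based half-open
cds_pieces <- function(gene) {
  s <- pmax(gene$exons[, 1L], gene$cds[1L])
  e <- pmin(gene$exons[, 2L], gene$cds[2L])
  keep <- e > s
  cbind(start = s[keep], end = e[keep])
}

#' Spliced CDS and protein sequence of a gene model
#'
#' Concatenates the exonic sequence within the CDS span in genomic order,
#' reverse-complements for minus-strand genes, and translates with the
#' standard genetic code. The terminal stop is rendered as `"*"`. An
#' internal stop before the final codon triggers a warning but the
#' translation is still returned (edited alleles legitimately gain stops).
#'
#' @param gene a [gene_model()] object
#' @param seqs named [Biostrings::DNAStringSet] (or named character vector)
#'   holding the gene's contig
#' @param check logical; warn on internal stop codons (default `TRUE`)
#' @return list with elements `cds` and `protein` (character scalars)
#' @export
spliced_cds_and_protein <- function(gene, seqs, check = TRUE) {
  contig <- contig_string(seqs, gene$chrom)
  pieces <- cds_pieces(gene)
  parts <- substring(contig, pieces[, 1L] + 1L, pieces[, 2L])
  cds <- paste(parts, collapse = "")
  if (gene$strand == "-") cds <- revcomp_chr(cds)
  n_cod <- nchar(cds) %/% 3L
  protein <- translate_chr(cds)
  if (check && n_cod > 1L) {
    internal <- substr(protein, 1L, n_cod - 1L)
    if (grepl("*", internal, fixed = TRUE))
      warning("gene ", gene$id, ": internal stop codon in CDS", call. = FALSE)
  }
  list(cds = cds, protein = protein)
}

#' Classify a genomic position relative to a gene model
#'
#' Returns a site label with category `CDS`, `five_prime_UTR`,
#' `three_prime_UTR`, `splice_region`, `intron` or `intergenic`. The splice
#' region is the `splice_window` intronic bases flanking each exon
#' (default 2, the canonical GT/AG dinucleotides) and takes precedence over
#' plain intron. For CDS positions, `cds_offset` is the 0-based offset into
#' the spliced, strand-oriented CDS and `codon_index = cds_offset %/% 3`.
#'
#' @param gene a [gene_model()] object
#' @param pos 0-based genomic position
#' @param seqs optional contig sequences; when given, positions outside the
#'   contig raise an error
#' @param splice_window intronic bases on each side of an exon counted as
#'   splice region (default 2)
#' @return list of class `SiteLabel` with `category`, `cds_offset`,
#'   `codon_index` (the latter two `NA` outside the CDS)
#' @export
locate <- function(gene, pos, seqs = NULL, splice_window = 2L) {
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 0L) stop("position must be a non-negative integer")
  if (!is.null(seqs)) {
    if (pos >= contig_length(seqs, gene$chrom))
      stop("position ", pos, " outside contig ", gene$chrom)
  }
  ex <- gene$exons
  label <- function(category, cds_offset = NA_integer_, codon_index = NA_integer_)
    structure(list(category = category, cds_offset = cds_offset,
                   codon_index = codon_index), class = "SiteLabel")

  if (pos < ex[1L, 1L] || pos >= ex[nrow(ex), 2L]) return(label("intergenic"))
  in_exon <- any(pos >= ex[, 1L] & pos < ex[, 2L])
  if (!in_exon) {
    ## intronic: distance to flanking exon boundaries
    donor <- pos - ex[, 2L]      # >= 0 just 3' of an exon end (genomic)
    accept <- ex[, 1L] - pos - 1L # >= 0 just 5' of an exon start
    near <- any(donor >= 0L & donor < splice_window) ||
      any(accept >= 0L & accept < splice_window)
    return(label(if (near) "splice_region" else "intron"))
  }
  cds <- gene$cds
  if (pos >= cds[1L] && pos < cds[2L]) {
    pieces <- cds_pieces(gene)
    inside <- pos >= pieces[, 1L] & pos < pieces[, 2L]
    if (any(inside)) {
      before <- sum(pmax(0L, pmin(pieces[, 2L], pos) - pieces[, 1L]))
      cds_len <- sum(pieces[, 2L] - pieces[, 1L])
      off <- if (gene$strand == "+") before else cds_len - 1L - before
      return(label("CDS", off, off %/% 3L))
    }
    ## exonic position inside the genomic CDS span cannot fall between
    ## pieces (pieces are exon intersections), so this is unreachable
  }
  upstream <- pos < cds[1L]
  five <- (gene$strand == "+") == upstream
  label(if (five) "five_prime_UTR" else "three_prime_UTR")
}

#' Read a FASTA file of contig sequences
#'
#' @param path FASTA file (multi-record allowed); record ids must be unique
#' @return named [Biostrings::DNAStringSet], uppercased, ambiguity codes
#'   preserved
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) stop("duplicate FASTA record ids in ", path)
  Biostrings::DNAStringSet(toupper(seqs))
}

#' Read gene models from JSON, GTF or GFF3
#'
#' The JSON dialect is the canonical fixture format:
#' `{"genes": [{"id", "chrom", "strand", "exons": [[start, end], ...],
#' "cds": [start, end]}]}` with 0-based half-open coordinates. GTF/GFF3
#' files are read through [rtracklayer::import()]; only `exon` and `CDS`
#' features are used and coordinates are converted from 1-based inclusive.
#' One model per transcript (grouped by `transcript_id`, `Parent` or
#' `gene_id`, whichever is present).
#'
#' @param path model file (`.json`, `.gtf`, `.gff`, `.gff3`)
#' @param seqs optional contig sequences; when supplied every model is
#'   validated against them at load time
#' @param permissive passed to [gene_model()]
#' @return list of `GeneModel` objects
#' @export
read_gene_models <- function(path, seqs = NULL, permissive = FALSE) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "json") {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    genes <- doc$genes %||% doc
    return(lapply(genes, function(g) {
      exons <- do.call(rbind, lapply(g$exons, function(e) as.integer(unlist(e))))
      gene_model(g$id, g$chrom, g$strand, exons, as.integer(unlist(g$cds)),
                 seqs = seqs, permissive = permissive)
    }))
  }
  gr <- rtracklayer::import(path)
  md <- as.data.frame(gr)
  type <- as.character(md$type)
  key <- if ("transcript_id" %in% names(md) && !all(is.na(md$transcript_id))) {
    as.character(md$transcript_id)
  } else if ("Parent" %in% names(md)) {
    vapply(md$Parent, function(p) if (length(p)) as.character(p[[1]]) else NA_character_,
           character(1))
  } else {
    as.character(md$gene_id)
  }
  keep <- type %in% c("exon", "CDS") & !is.na(key)
  md <- md[keep, ]; type <- type[keep]; key <- key[keep]
  groups <- split(seq_len(nrow(md)), key)
  unname(Map(function(id, idx) {
    sub <- md[idx, ]
    ty <- type[idx]
    ex <- sub[ty == "exon", ]
    cd <- sub[ty == "CDS", ]
    if (nrow(ex) == 0L) ex <- cd
    if (nrow(cd) == 0L) stop("model '", id, "' without CDS features in ", path)
    exons <- cbind(ex$start - 1L, ex$end)  # 1-based inclusive -> 0-based half-open
    gene_model(id = id, chrom = as.character(sub$seqnames[1L]),
               strand = as.character(sub$strand[1L]),
               exons = exons, cds = c(min(cd$start) - 1L, max(cd$end)),
               seqs = seqs, permissive = permissive)
  }, names(groups), groups))
}

#' Write gene models to the JSON dialect
#'
#' Inverse of the JSON branch of [read_gene_models()]: a write/read
#' round-trip is field-identical on the retained fields.
#'
#' @param genes list of `GeneModel` objects
#' @param path output path
#' @export
write_gene_models <- function(genes, path) {
  doc <- list(genes = lapply(genes, function(g) {
    list(id = g$id, chrom = g$chrom, strand = g$strand,
         exons = lapply(seq_len(nrow(g$exons)),
                        function(i) as.integer(g$exons[i, ])),
         cds = as.integer(g$cds))
  }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read reference sequences and gene models together
#'
#' Convenience loader: reads the FASTA, reads the model file, and validates
#' every model against the loaded contigs (missing contigs and invalid CDS
#' are fatal unless `permissive`).
#'
#' @inheritParams read_gene_models
#' @param fasta_path FASTA file of contig sequences
#' @param model_path gene-model file (JSON/GTF/GFF3)
#' @return list with `seqs` (DNAStringSet) and `genes` (list of GeneModel)
#' @export
read_inputs <- function(fasta_path, model_path, permissive = FALSE) {
  seqs <- read_genome(fasta_path)
  genes <- read_gene_models(model_path, seqs = seqs, permissive = permissive)
  list(seqs = seqs, genes = genes)
}
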