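#' @keywords internal
"_PACKAGE"

#' @importFrom stats dt pt pnorm quantile sd median optim rnbinom rlnorm rnorm
#'   rchisq rbinom runif p.adjust setNames
#' @importFrom utils read.delim write.table head
NULL

IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of DNA strings
#'
#' Thin vectorized wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (may contain IUPAC codes)
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## vectorized IUPAC triplet match: pams is a character vector of 3-mers,
## pattern a single IUPAC triplet (e.g. "NGG")
pam_matches <- function(pams, pattern) {
  stopifnot(nchar(pattern) == 3L)
  ok <- rep(TRUE, length(pams))
  for (i in 1:3) {
    allowed <- IUPAC_MAP[[substr(pattern, i, i)]]
    if (is.null(allowed)) stop("unknown IUPAC code in PAM pattern: ", pattern)
    ok <- ok & substr(pams, i, i) %in% allowed
  }
  ok
}

## standard genetic code on character codons, independent of sequence classes
CODON_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  ## fill via Biostrings' GENETIC_CODE to avoid transcription slips
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  setNames(aa, codons)
})

`%||%` <- function(a, b) if (is.null(a)) b else a

## contig sequence as a plain character scalar; `seqs` may be a
## DNAStringSet or a named character vector (fast path for annotation)
contig_string <- function(seqs, chrom) {
  if (is.character(seqs)) {
    if (!chrom %in% names(seqs)) stop("contig '", chrom, "' missing")
    seqs[[chrom]]
  } else {
    if (!chrom %in% names(seqs)) stop("contig '", chrom, "' missing")
    as.character(seqs[[chrom]])
  }
}

contig_length <- function(seqs, chrom) nchar(contig_string(seqs, chrom))

## character-level reverse complement (keeps IUPAC codes as N-ish via chartr)
revcomp_chr <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGTRYKMBDHVN", "TGCAYRMKVHDBN", s), "")[[1L]]),
          collapse = ""), character(1), USE.NAMES = FALSE)
}

## standard-code translation on a character CDS; unknown codons become X
translate_chr <- function(cds) {
  n <- nchar(cds) %/% 3L
  if (n == 0L) return("")
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- CODON_TABLE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

## deterministic child seed; keeps values < 2^31
child_seed <- function(seed, offset) {
  (as.numeric(seed) * 48271 + offset) %% 2147483629
}
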