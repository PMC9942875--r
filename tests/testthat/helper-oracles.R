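# Independent oracles: deliberately naive re-implementations used to check
# the package's fast paths. They share no code with R/.

ORACLE_CODONS <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_translate <- function(cds) {
  n <- nchar(cds) %/% 3L
  paste(vapply(seq_len(n), function(i) {
    codon <- substr(cds, 3L * i - 2L, 3L * i)
    if (codon %in% names(ORACLE_CODONS)) ORACLE_CODONS[[codon]] else "X"
  }, character(1)), collapse = "")
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1L]]), collapse = "")
}

# spliced CDS of a gene directly from coordinate arithmetic on the contig
# string (0-based half-open everywhere)
oracle_spliced_cds <- function(contig_chars, exons, cds, strand) {
  pieces <- character(0)
  for (i in seq_len(nrow(exons))) {
    s <- max(exons[i, 1], cds[1]); e <- min(exons[i, 2], cds[2])
    if (e > s) pieces <- c(pieces, paste(contig_chars[(s + 1):e], collapse = ""))
  }
  out <- paste(pieces, collapse = "")
  if (strand == "-") oracle_revcomp(out) else out
}

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T", R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_pam_ok <- function(pam, pattern) {
  all(vapply(1:3, function(i)
    substr(pam, i, i) %in% ORACLE_IUPAC[[substr(pattern, i, i)]], logical(1)))
}

# brute-force guide scan over one contig, both strands; returns a data.frame
# of (start, strand, protospacer, pam) in the package's coordinate frame
oracle_scan_guides <- function(seq, pam_pattern) {
  n <- nchar(seq)
  rows <- list()
  for (i in seq_len(max(0, n - 22L))) {          # 1-based leftmost of 23-mer
    site <- substr(seq, i, i + 22L)
    if (oracle_pam_ok(substr(site, 21L, 23L), pam_pattern))
      rows[[length(rows) + 1L]] <- data.frame(
        start = i - 1L, strand = "+",
        protospacer = substr(site, 1L, 20L), pam = substr(site, 21L, 23L),
        stringsAsFactors = FALSE)
    rc <- oracle_revcomp(site)
    if (oracle_pam_ok(substr(rc, 21L, 23L), pam_pattern))
      rows[[length(rows) + 1L]] <- data.frame(
        start = i + 2L, strand = "-",
        protospacer = substr(rc, 1L, 20L), pam = substr(rc, 21L, 23L),
        stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(), strand = character(),
                      protospacer = character(), pam = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  running_min <- Inf
  for (k in n:1) {
    running_min <- min(running_min, p[ord[k]] * n / k)
    adj[ord[k]] <- min(running_min, 1)
  }
  adj
}
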