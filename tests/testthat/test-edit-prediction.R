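mk_guide <- function(protospacer, contig = "chrF", start = 0L, strand = "+",
                     id = "g1") {
  data.frame(guide_id = id, protospacer = protospacer, contig = contig,
             start = start, strand = strand, stringsAsFactors = FALSE)
}

test_that("outcome space is singles plus the all-window joint edit", {
  be3 <- editor_config("BE3-NGG")
  # Cs at protospacer 5 and 8: outcomes {5}, {8}, {5,8}
  oc <- enumerate_outcomes(mk_guide("AAAACAACAAAAAAAAAAAA"), be3)
  expect_length(oc, 3L)
  expect_setequal(vapply(oc, function(o) paste(o$edited_positions,
                                               collapse = ","), character(1)),
                  c("5", "8", "5,8"))
  # single editable C: one outcome
  expect_length(enumerate_outcomes(mk_guide("AAAACAAAAAAAAAAAAAAA"), be3), 1L)
  # no editable base: none
  expect_length(enumerate_outcomes(mk_guide("AAAAAAAAAAAAAAAAAAAA"), be3), 0L)
  # outcome count is k + [k >= 2] for k editable bases
  for (k in 1:5) {
    proto <- paste0(strrep("A", 3), strrep("C", k), strrep("A", 17 - k))
    n <- length(enumerate_outcomes(mk_guide(proto), be3))
    expect_equal(n, k + (k >= 2))
  }
})

test_that("the narrowed YE1 window never touches position 8", {
  ye1 <- editor_config("YE1-BE4max-NGN")
  oc <- enumerate_outcomes(mk_guide("AAAACAACAAAAAAAAAAAA"), ye1)
  expect_length(oc, 1L)
  expect_equal(oc[[1]]$edited_positions, 5L)
})

test_that("variants land on the reference strand with correct complementation", {
  be3 <- editor_config("BE3-NGG")
  oc <- enumerate_outcomes(mk_guide("AAAACAAAAAAAAAAAAAAA", start = 100L), be3)
  expect_equal(oc[[1]]$variants$pos, 104L)      # 0-based: start + 5 - 1
  expect_equal(oc[[1]]$variants$ref, "C")
  expect_equal(oc[[1]]$variants$alt, "T")
  ocm <- enumerate_outcomes(mk_guide("AAAACAAAAAAAAAAAAAAA", start = 100L,
                                     strand = "-"), be3)
  expect_equal(ocm[[1]]$variants$pos, 115L)     # 0-based: start + 20 - 5
  expect_equal(ocm[[1]]$variants$ref, "G")      # C on protospacer = G on ref
  expect_equal(ocm[[1]]$variants$alt, "A")
})

test_that("prioritize respects the published deleteriousness order", {
  expect_equal(prioritize(c("synonymous", "missense")), "missense")
  expect_equal(prioritize(c("missense", "stop_gained")), "stop_gained")
  expect_equal(prioritize("UTR"), "UTR")
  order <- c("stop_gained", "start_lost", "splice_variant", "missense",
             "UTR", "synonymous")
  for (i in seq_along(order))
    for (j in seq_along(order))
      expect_equal(prioritize(c(order[i], order[j])), order[min(i, j)])
  expect_equal(prioritize(c("intergenic", "synonymous")), "synonymous")
  expect_error(prioritize(character(0)), "at least one")
  expect_error(prioritize("frameshift"), "unknown")
})

test_that("prioritize is associative over multiset union", {
  set.seed(30)
  for (rep in 1:20) {
    a <- sample(bescan:::CONSEQUENCE_LEVELS, 3, replace = TRUE)
    b <- sample(bescan:::CONSEQUENCE_LEVELS, 2, replace = TRUE)
    expect_equal(prioritize(c(a, b)),
                 prioritize(c(prioritize(a), prioritize(b))))
  }
})

test_that("a CAA codon edited in-window annotates as stop gained", {
  # CAA at codon 2; place its C at protospacer position 5 via start offset
  cds <- paste0("ATG", "CAA", "GAA", "ACT", "GAG", "GAA", "TAA")
  f <- flat_gene(cds, pad5 = 20L, pad3 = 20L)
  c_pos <- f$cds_span[1] + 3L               # genomic 0-based position of the C
  guide <- mk_guide(as.character(Biostrings::subseq(f$seqs[["chrF"]],
                                                    c_pos - 4L + 1L,
                                                    c_pos - 4L + 20L)),
                    start = c_pos - 4L)
  be3 <- editor_config("BE3-NGG")
  oc <- enumerate_outcomes(guide, be3)
  hit <- Filter(function(o) c_pos %in% o$variants$pos, oc)
  expect_gt(length(hit), 0L)
  ann <- annotate_outcome(hit[[1]], f$gene, f$seqs)
  expect_equal(ann$consequence, "stop_gained")
  pc <- ann$protein_changes
  expect_true(any(pc$residue == 2L & pc$ref_aa == "Q" & pc$alt_aa == "*"))
})

test_that("an edit at the intron donor +1 position is a splice variant", {
  toy <- random_toy_gene(91, n_exons = 2, strand = "+")
  g <- toy$gene
  donor_g <- g$exons[1, 2]                  # first intronic base, the G of GT
  expect_equal(substr(toy$contig, donor_g + 1L, donor_g + 1L), "G")
  # reference G->A, as a minus-strand guide would install
  oc <- structure(list(guide_id = "sp", edited_positions = 5L,
                       variants = data.frame(contig = "chrT", pos = donor_g,
                                             ref = "G", alt = "A",
                                             stringsAsFactors = FALSE)),
                  class = "PredictedOutcome")
  ann <- annotate_outcome(oc, g, toy$seqs)
  expect_equal(ann$consequence, "splice_variant")
})

test_that("an edit in the annotated start codon is start_lost", {
  cds <- paste0("ATG", "GAA", "ACT", "GAG", "GAA", "TAA")
  f <- flat_gene(cds, pad5 = 20L, pad3 = 20L, strand = "-")
  # on "-" the start codon occupies the last 3 CDS bases genomically as
  # CAT (revcomp of ATG); editing that C -> T turns the start into ATA
  c_of_cat <- f$cds_span[2] - 3L
  expect_equal(substr(as.character(f$seqs[["chrF"]]), c_of_cat + 1L,
                      c_of_cat + 1L), "C")
  oc <- structure(list(guide_id = "st", edited_positions = 5L,
                       variants = data.frame(contig = "chrF",
                                             pos = c_of_cat,
                                             ref = "C", alt = "T",
                                             stringsAsFactors = FALSE)),
                  class = "PredictedOutcome")
  ann <- annotate_outcome(oc, f$gene, f$seqs)
  expect_equal(ann$consequence, "start_lost")
})

test_that("a ref-base mismatch between outcome and genome is fatal", {
  f <- flat_gene("ATGGAAACTTAA", pad5 = 20L, pad3 = 20L)
  oc <- structure(list(guide_id = "bad", edited_positions = 5L,
                       variants = data.frame(contig = "chrF", pos = 0L,
                                             ref = "Z", alt = "T",
                                             stringsAsFactors = FALSE)),
                  class = "PredictedOutcome")
  expect_error(annotate_outcome(oc, f$gene, f$seqs), "out of sync")
})

test_that("protein changes match an independent apply-and-retranslate oracle", {
  be3 <- editor_config("BE3-NGG")
  abe <- editor_config("ABE8e-NGN")
  n_checked <- 0L
  seed <- 0L
  while (n_checked < 200L) {
    seed <- seed + 1L
    toy <- random_toy_gene(seed + 4000, n_codons = 15L)
    guides <- enumerate_guides(toy$seqs, "chrT", pam_pattern = "NGN")
    if (nrow(guides) == 0L) next
    for (i in seq_len(min(4L, nrow(guides)))) {
      editor <- if (i %% 2L) be3 else abe
      if (!bescan:::pam_matches(guides$pam[i], editor$pam_pattern)) next
      for (oc in enumerate_outcomes(guides[i, ], editor)) {
        ann <- annotate_outcome(oc, toy$gene, toy$seqs)
        # oracle: edit the contig string directly, re-splice, re-translate
        chars <- strsplit(toy$contig, "")[[1L]]
        stopifnot(all(chars[oc$variants$pos + 1L] == oc$variants$ref))
        chars[oc$variants$pos + 1L] <- oc$variants$alt
        new_cds <- oracle_spliced_cds(chars, toy$gene$exons, toy$gene$cds,
                                      toy$gene$strand)
        p_old <- strsplit(oracle_translate(toy$cds), "")[[1L]]
        p_new <- strsplit(oracle_translate(new_cds), "")[[1L]]
        diff <- which(p_old != p_new)
        expect_identical(ann$protein_changes$residue, diff)
        expect_identical(ann$protein_changes$ref_aa, p_old[diff])
        expect_identical(ann$protein_changes$alt_aa, p_new[diff])
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gte(n_checked, 200L)
})

test_that("amino-acid coverage is monotone under editor union and matches brute force", {
  set.seed(50)
  toy <- random_toy_gene(61, n_exons = 1, strand = "+", n_codons = 10L)
  guides <- enumerate_guides(toy$seqs, "chrT", pam_pattern = "NGN")
  be3 <- editor_config("BE3.9max-NGN")
  abe <- editor_config("ABE8e-NGN")
  cov <- aa_coverage(toy$gene, toy$seqs,
                     list(CBE = list(guides = guides, editor = be3),
                          ABE = list(guides = guides, editor = abe)))
  expect_gte(cov$union, max(cov$per_set))
  expect_true(all(cov$per_set >= 0 & cov$per_set <= 1))
  # brute-force residue set for the CBE arm
  expected <- integer(0)
  for (i in seq_len(nrow(guides))) {
    for (oc in enumerate_outcomes(guides[i, ], be3)) {
      ann <- annotate_outcome(oc, toy$gene, toy$seqs)
      expected <- c(expected, ann$protein_changes$residue)
      if (ann$consequence == "start_lost") expected <- c(expected, 1L)
    }
  }
  L <- cov$protein_length
  expected <- sort(unique(expected[expected >= 1 & expected <= L]))
  expect_identical(cov$residues$CBE, expected)
  # empty guide list covers nothing
  cov0 <- aa_coverage(toy$gene, toy$seqs,
                      list(none = list(guides = guides[0, ], editor = be3)))
  expect_equal(unname(cov0$per_set), 0)
})

test_that("annotated outcomes flatten to a well-formed table", {
  f <- flat_gene(paste0("ATG", "CAA", "GAA", "TAA"), pad5 = 20L, pad3 = 20L)
  guides <- enumerate_guides(f$seqs, "chrF", pam_pattern = "NGN")
  be3 <- editor_config("BE3.9max-NGN")
  ocs <- list()
  for (i in seq_len(nrow(guides)))
    for (oc in enumerate_outcomes(guides[i, ], be3))
      ocs[[length(ocs) + 1L]] <- annotate_outcome(oc, f$gene, f$seqs)
  tab <- outcomes_table(ocs)
  expect_equal(nrow(tab), length(ocs))
  expect_true(all(grepl("^chrF:\\d+:[A-Z]:[A-Z]", tab$variants)))
  expect_true(all(tab$consequence %in% bescan:::CONSEQUENCE_LEVELS))
})
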