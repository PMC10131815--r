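test_that("FASTA parsing normalizes whitespace, case, and T->U", {
  s <- parse_fasta(">x\nAUG CCC\n", "rna")
  expect_length(s, 1)
  expect_equal(as.character(s[[1]]), "AUGCCC")
  expect_equal(length(s[[1]]), 6)

  expect_equal(as.character(parse_fasta(">x\natgccc", "rna")[[1]]), "AUGCCC")

  multi <- parse_fasta(">a desc\nAUGC\n>b\nGG\nCC\n", "rna")
  expect_equal(vapply(multi, attr, "", "name"), c("a", "b"))
  expect_equal(as.character(multi[[2]]), "GGCC")

  # headerless plain paste is one anonymous record
  expect_equal(as.character(parse_fasta("AUG CCC", "rna")[[1]]), "AUGCCC")
})

test_that("FASTA parsing rejects malformed and off-alphabet input", {
  expect_error(parse_fasta(">x\n", "rna"), "no sequence")
  expect_error(parse_fasta("", "rna"), "malformed")
  expect_error(parse_fasta(">x\nAUGN\n", "rna"), "position 4")
  expect_error(parse_fasta(">x\nMXZB\n", "protein"), "position 2")
  expect_error(rna_sequence("AUG-CCC"), "position 4")
})

test_that("FASTA reader agrees with Biostrings on a clean fixture", {
  skip_if_not_installed("Biostrings")
  path <- system.file("extdata", "vegfa_mrna_cds.fasta",
                      package = "vesikin", mustWork = TRUE)
  ours <- read_fasta(path, "rna")[[1]]
  ref <- as.character(Biostrings::readRNAStringSet(path)[[1]])
  expect_identical(as.character(ours), ref)
})

test_that("composition counts match a brute-force tally", {
  expect_equal(composition(rna_sequence("AUGC"))$counts,
               c(A = 1L, U = 1L, G = 1L, C = 1L))
  expect_equal(unname(composition(rna_sequence("AUGC"))$fractions),
               rep(0.25, 4))

  set.seed(42)
  for (i in 1:10) {
    s <- random_rna(200)
    comp <- composition(rna_sequence(s))
    expect_equal(comp$counts, tally_oracle(s, c("A", "U", "G", "C")))
    expect_equal(sum(comp$counts), 200)
    expect_equal(sum(comp$fractions), 1, tolerance = 1e-9)
  }
  p <- random_protein(150)
  pc <- composition(protein_sequence(p))
  expect_equal(sum(pc$counts), 150)
})

test_that("RNA molecular weight follows the per-nucleotide formula", {
  expect_equal(rna_molecular_weight(rna_sequence("A")), 329.2 + 159)
  expect_equal(rna_molecular_weight(rna_sequence("A"), triphosphate = FALSE),
               329.2)
  # independently summed: 157*329.2 + 118*306.2 + 143*305.2 + 158*345.2 + 159
  expect_equal(rna_molecular_weight(vegfa_cds()), 186160.2)

  # additivity and permutation invariance
  set.seed(7)
  s1 <- random_rna(40); s2 <- random_rna(25)
  mw <- function(s) rna_molecular_weight(rna_sequence(s),
                                         triphosphate = FALSE)
  expect_equal(mw(paste0(s1, s2)), mw(s1) + mw(s2))
  perm <- paste(sample(strsplit(s1, "")[[1]]), collapse = "")
  expect_equal(mw(perm), mw(s1))
})

test_that("molecular weights are strictly increasing in length", {
  set.seed(11)
  s <- random_rna(30)
  expect_gt(rna_molecular_weight(rna_sequence(paste0(s, "U"))),
            rna_molecular_weight(rna_sequence(s)))
  p <- random_protein(30)
  expect_gt(protein_molecular_weight(protein_sequence(paste0(p, "G"))),
            protein_molecular_weight(protein_sequence(p)))
})

test_that("protein molecular weight uses average residue masses plus water", {
  # glycine residue 57.0519 + water 18.01524
  expect_equal(protein_molecular_weight(protein_sequence("G")),
               75.06714, tolerance = 1e-6)
  # dipeptide: two independent residue-mass terms summed by hand
  expect_equal(protein_molecular_weight(protein_sequence("GA")),
               57.0519 + 71.0788 + 18.01524, tolerance = 1e-9)
})

test_that("translation follows the standard genetic code", {
  expect_equal(as.character(translate_rna(rna_sequence("AUGUGA"))), "M")
  expect_error(translate_rna(rna_sequence("AUGC")), "multiple of 3")
  expect_error(translate_rna(rna_sequence("UUGAAAUGA")), "start codon")
  expect_warning(out <- translate_rna(rna_sequence("AUGUGAUUU")),
                 "internal stop|dropped")
  expect_equal(as.character(out), "M")
  expect_warning(full <- translate_rna(rna_sequence("AUGAAA")), "no stop")
  expect_equal(as.character(full), "MK")
})

test_that("translation matches an independent codon-table oracle", {
  skip_if_not_installed("Biostrings")
  set.seed(99)
  for (i in 1:50) {
    cds <- random_cds(sample(3:30, 1))
    ours <- as.character(translate_rna(rna_sequence(cds)))
    ref <- as.character(Biostrings::translate(Biostrings::RNAString(cds)))
    expect_identical(ours, sub("\\*$", "", ref))
  }
})

test_that("translating the bundled CDS reproduces the bundled protein", {
  prot <- translate_rna(vegfa_cds())
  expect_identical(as.character(prot), as.character(vegfa_protein()))
  # round trip: MW identical whichever string it is computed from
  expect_identical(protein_molecular_weight(prot),
                   protein_molecular_weight(vegfa_protein()))
})
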