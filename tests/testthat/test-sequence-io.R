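test_that("FASTA reading preserves records and normalizes RNA and case", {
  path <- tmp_fasta(c("geneA some description", "geneB"),
                    c("ATGAAATTTCCCTAA", "augaaauaa"))
  seqs <- read_cds(path, format = "fasta")
  expect_length(seqs, 2L)
  expect_identical(names(seqs), c("geneA", "geneB"))
  expect_identical(unname(seqs["geneA"]), "ATGAAATTTCCCTAA")
  expect_identical(unname(seqs["geneB"]), "ATGAAATAA")

  expect_error(read_cds(tempfile(), format = "fasta"), "not found")
})

test_that("GenBank two-exon minus-strand CDS is spliced and reverse-complemented", {
  genome <- "AAACCCGGGTTTAAACCCGGGTTTAAACCC"
  gb <- c(
    "LOCUS       TOY30                  30 bp    DNA     circular PLN",
    "FEATURES             Location/Qualifiers",
    "     source          1..30",
    "     CDS             complement(join(4..9,16..24))",
    "                     /gene=\"toyA\"",
    "     CDS             2..7",
    "                     /gene=\"toyB\"",
    "ORIGIN",
    "        1 aaacccgggt ttaaacccgg gtttaaaccc",
    "//")
  path <- tempfile(fileext = ".gb")
  writeLines(gb, path)
  seqs <- read_cds(path, format = "genbank")

  # oracle: manual splice + reverse complement with base string ops
  splice <- paste0(substr(genome, 4, 9), substr(genome, 16, 24))
  oracle <- paste(rev(strsplit(chartr("ACGT", "TGCA", splice), "")[[1]]),
                  collapse = "")
  expect_identical(names(seqs), c("toyA", "toyB"))
  expect_identical(unname(seqs["toyA"]), oracle)
  expect_identical(unname(seqs["toyB"]), substr(genome, 2, 7))

  # record without CDS features: empty result plus warning
  gb2 <- c("LOCUS       EMPTY                  12 bp    DNA",
           "FEATURES             Location/Qualifiers",
           "     source          1..12",
           "ORIGIN", "        1 aaacccgggttt", "//")
  path2 <- tempfile(fileext = ".gb")
  writeLines(gb2, path2)
  expect_warning(empty <- read_cds(path2, format = "genbank"), "no CDS")
  expect_length(empty, 0L)
})

test_that("CDS filtering applies all five rules plus ambiguity and duplicates", {
  good300 <- paste0("ATG", strrep("AAA", 98), "TAA")  # 303 nt
  cand <- c(
    ok = good300,
    short = "ATGAAATAA",                                    # < 300 nt
    internal = paste0("ATG", "TAA", strrep("AAA", 97), "TAA"),
    nostart = paste0("GTG", strrep("AAA", 98), "TAA"),      # alt start rejected
    nostop = paste0("ATG", strrep("AAA", 100)),
    frame = paste0("ATG", strrep("AAA", 97), "TAAA"),
    ambig = paste0("ATG", "AAN", strrep("AAA", 97), "TAA"),
    ok2 = good300
  )
  attr(cand, "gene") <- c("g1", "g2", "g3", "g4", "g5", "g6", "g7", "g1")
  res <- filter_cds(cand, min_len = 300, species = "toy")

  expect_identical(names(res$set$seq), "ok")
  rep <- res$report
  expect_identical(attr(rep, "accepted") + attr(rep, "rejected"), nrow(rep))
  got <- stats::setNames(rep$reason, rep$gene_id)
  expect_identical(unname(got[c("short", "internal", "nostart", "nostop",
                                "frame", "ambig", "ok2")]),
                   c("length", "internal_stop", "start", "stop", "frame",
                     "ambiguous_base", "duplicate"))
  # reason counts sum to the rejection total
  expect_identical(sum(table(rep$reason[rep$reason != ""])),
                   attr(rep, "rejected"))
  # dedupe off keeps the second copy
  res2 <- filter_cds(cand, min_len = 300, dedupe = FALSE)
  expect_identical(names(res2$set$seq), c("ok", "ok2"))
  # empty input: empty set, zero-count report, no error
  res0 <- filter_cds(character(0))
  expect_identical(attr(res0$report, "accepted"), 0L)
  expect_length(res0$set$seq, 0L)
})

test_that("filtering is idempotent and accepted genes translate cleanly", {
  sim <- simulate_cds_set(15, c(100, 160), seed = 11, species = "prop")
  pass1 <- filter_cds(sim$set$seq, species = "prop")
  expect_identical(attr(pass1$report, "rejected"), 0L)
  pass2 <- filter_cds(pass1$set$seq, species = "prop")
  expect_identical(attr(pass2$report, "accepted"),
                   attr(pass1$report, "accepted"))
  for (s in pass1$set$seq) {
    prot <- translate_cds(s)  # errors on internal stop
    expect_identical(nchar(prot), as.integer(nchar(s) / 3) - 1L)  # stop dropped
  }
})

test_that("FASTA writing round-trips a set and refuses an empty one", {
  sim <- simulate_cds_set(41, 110, seed = 7, species = "spx")
  path <- tempfile(fileext = ".fasta")
  write_cds_fasta(sim$set, path)
  lines <- readLines(path)
  expect_identical(sum(startsWith(lines, ">")), 41L)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60))
  back <- read_cds(path, format = "fasta")
  expect_identical(as.vector(back), unname(sim$set$seq))
  expect_identical(names(back), names(sim$set$seq))

  expect_error(write_cds_fasta(cds_set(character(0), "empty"), tempfile()),
               "empty")
})
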