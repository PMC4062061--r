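# FASTA / GTF / VCF boundary conversions and variant normalization.

test_that("FASTA reading uppercases and preserves multiple records", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "acgt", ">chr2", "NNacgtACGT"), f)
  g <- read_genome(f)
  expect_equal(unclass(g), c(chr1 = "ACGT", chr2 = "NNACGTACGT"))
})

test_that("genome construction rejects bad input", {
  expect_error(genome_sequence(c(chr1 = "ACGT", chr1 = "AC")), "duplicate")
  expect_error(genome_sequence(c(chr1 = "ACXT")), "non-ACGTN")
  expect_error(genome_sequence(setNames("ACGT", "")), "non-empty")
})

test_that("a synthetic 10 kb genome survives a write/read round trip", {
  set.seed(9)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
             collapse = "")
  g <- genome_sequence(c(chrA = s))
  f <- withr::local_tempfile(fileext = ".fa")
  write_genome(g, f)
  expect_identical(unclass(read_genome(f)), unclass(g))
})

test_that("GTF coordinates convert to 0-based half-open with CDS split", {
  f <- withr::local_tempfile(fileext = ".gtf")
  at <- 'gene_id "g1"; transcript_id "t1";'
  writeLines(c(
    paste("chr1", "src", "exon", 101, 200, ".", "+", ".", at, sep = "\t"),
    paste("chr1", "src", "exon", 301, 400, ".", "+", ".", at, sep = "\t"),
    paste("chr1", "src", "CDS", 151, 200, ".", "+", ".", at, sep = "\t"),
    paste("chr1", "src", "CDS", 301, 349, ".", "+", ".", at, sep = "\t")), f)
  ts <- read_transcripts(f, "setX")
  tx <- ts$transcripts[["t1"]]
  expect_equal(tx$exons, rbind(c(100L, 200L), c(300L, 400L)),
               ignore_attr = TRUE)
  expect_equal(tx$cds, rbind(c(150L, 200L), c(300L, 349L)),
               ignore_attr = TRUE)
  expect_equal(tx$biotype, "coding")
  expect_false(tx$cds_incomplete)   # 50 + 49 = 99 bp, a codon multiple
})

test_that("noncoding transcripts and bad CDS records are handled", {
  f <- withr::local_tempfile(fileext = ".gtf")
  a1 <- 'gene_id "g1"; transcript_id "nc1";'
  a2 <- 'gene_id "g2"; transcript_id "bad1";'
  writeLines(c(
    paste("chr1", "src", "exon", 11, 50, ".", "-", ".", a1, sep = "\t"),
    paste("chr1", "src", "exon", 101, 150, ".", "+", ".", a2, sep = "\t"),
    paste("chr1", "src", "CDS", 201, 230, ".", "+", ".", a2, sep = "\t")), f)
  expect_warning(ts <- read_transcripts(f, "setX"), "rejected")
  expect_equal(names(ts$transcripts), "nc1")
  expect_equal(ts$transcripts[["nc1"]]$biotype, "noncoding")
})

test_that("transcript sets survive a GTF write/read round trip", {
  sim <- get_sim()
  f <- withr::local_tempfile(fileext = ".gtf")
  write_transcripts(sim$set_a, f)
  back <- read_transcripts(f, "setA")
  expect_setequal(names(back$transcripts), names(sim$set_a$transcripts))
  for (id in names(sim$set_a$transcripts)) {
    a <- sim$set_a$transcripts[[id]]; b <- back$transcripts[[id]]
    expect_equal(a$exons, b$exons, ignore_attr = TRUE)
    expect_equal(a$cds, b$cds, ignore_attr = TRUE)
    expect_equal(a$strand, b$strand)
    expect_equal(a$gene_id, b$gene_id)
  }
})

test_that("VCF records convert to minimal left-aligned 0-based variants", {
  g <- genome_sequence(c(chr1 = "TTTTACGTACGTAAAAACGT"))
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1,length=20>",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t5\tv1\tA\tG\t.\t.\t.",
               "chr1\t5\tv2\tA\tAT\t.\t.\t.",
               "chr1\t7\tv3\tGTA\tG\t.\t.\t.",
               "chr1\t5\t.\tAC\tGC,TC\t.\t.\t."), f)
  v <- read_variants(f, g)
  expect_equal(nrow(v), 5)
  v1 <- v[v$variant_id == "v1", ]
  expect_equal(c(v1$pos, v1$ref, v1$alt, v1$var_class),
               c("4", "A", "G", "SNV"))
  v2 <- v[v$variant_id == "v2", ]           # anchor trimmed, pure insertion
  expect_equal(c(v2$pos, v2$ref, v2$alt, v2$var_class),
               c("5", "", "T", "insertion"))
  v3 <- v[v$variant_id == "v3", ]           # deletion of TA after the anchor
  expect_equal(c(v3$ref, v3$alt, v3$var_class), c("TA", "", "deletion"))
  expect_equal(sum(v$var_class == "SNV"), 3)  # multi-allelic split into SNVs
})

test_that("REF mismatches error and symbolic alleles are skipped", {
  g <- genome_sequence(c(chr1 = "ACGTACGTAC"))
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1,length=10>",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t2\tv1\tG\tA\t.\t.\t."), f)
  expect_error(read_variants(f, g), "REF mismatch")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1,length=10>",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t2\tv1\tC\t<DEL>\t.\t.\t.",
               "chr1\t3\tv2\tG\tT\t.\t.\t."), f)
  expect_warning(v <- read_variants(f, g), "symbolic")
  expect_equal(v$variant_id, "v2")
})

test_that("indel normalization left-aligns through homopolymers", {
  g <- genome_sequence(c(chr1 = "ACGTTTTTACGT"))
  # deleting any one T of the run left-aligns to the first T (pos 3)
  nv <- normalize_variant("chr1", 6L, "T", "", g)
  expect_equal(nv$pos, 3L)
  expect_equal(nv$var_class, "deletion")
  # inserting a T anywhere in the run left-aligns to the run start
  nv2 <- normalize_variant("chr1", 8L, "", "T", g)
  expect_equal(nv2$pos, 3L)
  # anchor-base representation trims to the same minimal form
  nv3 <- normalize_variant("chr1", 2L, "GT", "G", g)
  expect_equal(nv3[c("pos", "ref", "alt")], list(pos = 3L, ref = "T", alt = ""))
  expect_error(normalize_variant("chr1", 2L, "GT", "GT", g), "monomorphic")
})

test_that("normalization is idempotent and never monomorphic", {
  sim <- get_sim()
  vt <- get_truth_run()$vt
  for (i in seq_len(nrow(vt$variants))) {
    v <- vt$variants[i, ]
    nv <- normalize_variant(v$chrom, v$pos, v$ref, v$alt, sim$genome)
    expect_identical(nv[c("pos", "ref", "alt")],
                     list(pos = v$pos, ref = v$ref, alt = v$alt))
    expect_false(nv$ref == nv$alt)
  }
})
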