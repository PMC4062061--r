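# Synthetic genome/transcript/variant generation: structural guarantees,
# determinism, truth recovery and the transcript-set asymmetry.

test_that("generated coding transcripts are well-formed ORFs", {
  sim <- get_sim()
  for (ts in list(sim$set_a, sim$set_b)) {
    for (tx in ts$transcripts) {
      if (tx$biotype != "coding") next
      ii <- tx_cds_info(tx, sim$genome)
      expect_equal(nchar(ii$cds) %% 3, 0)
      expect_false(tx$cds_incomplete)
      expect_equal(substr(ii$cds, 1, 3), "ATG")
      aa <- bio_translate(ii$cds)   # independent translation route
      expect_equal(match("*", aa), length(aa),
                   info = tx$transcript_id)   # stop only at the end
    }
  }
})

test_that("set B is a superset of set A with extra genes in A-intergenic space", {
  sim <- get_sim()
  expect_true(all(names(sim$set_a$transcripts) %in%
                    names(sim$set_b$transcripts)))
  extra <- setdiff(names(sim$set_b$transcripts),
                   names(sim$set_a$transcripts))
  expect_gt(length(extra), 0)
  a_spans <- t(vapply(sim$set_a$transcripts, tx_span, integer(2)))
  for (id in extra) {
    sp <- tx_span(sim$set_b$transcripts[[id]])
    gapdist <- min(pmax(a_spans[, 1] - sp[2], sp[1] - a_spans[, 2]))
    expect_gt(gapdist, 1000)   # intergenic under set A, beyond the flank
  }
})

test_that("a zero-extra configuration yields structurally identical sets", {
  sim0 <- simulate_genome_and_transcripts(
    sim_config(seed = 11, n_genes = 6L, extra_transcript_fraction = 0))
  expect_identical(names(sim0$set_a$transcripts),
                   names(sim0$set_b$transcripts))
})

test_that("identical seeds give byte-identical FASTA/GTF/VCF", {
  cfg <- sim_config(seed = 33, n_genes = 8L,
                    class_mix = setNames(rep(2L, 16L),
                                         names(sim_config()$class_mix)))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_genome_and_transcripts(cfg, outdir = d1)
  simulate_variants(s1, outdir = d1)
  s2 <- simulate_genome_and_transcripts(cfg, outdir = d2)
  simulate_variants(s2, outdir = d2)
  for (f in c("genome.fa", "setA.gtf", "setB.gtf", "variants.vcf",
              "truth.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
})

test_that("the engine recovers every designed consequence", {
  run <- get_truth_run()
  vt <- run$vt
  expect_gte(nrow(vt$variants), 200)
  expect_gte(length(unique(vt$truth$class)), 16)
  ta <- vt$truth$expected_a[match(run$calls_a$variant_id,
                                  vt$truth$variant_id)]
  tv <- vt$truth$expected_v[match(run$calls_v$variant_id,
                                  vt$truth$variant_id)]
  expect_identical(run$calls_a$term, ta)
  expect_identical(run$calls_v$term, tv)
})

test_that("truth recovery survives a VCF round trip", {
  run <- get_truth_run()
  d <- withr::local_tempdir()
  write_vcf(run$vt$variants, run$sim$genome, file.path(d, "v.vcf"))
  back <- read_variants(file.path(d, "v.vcf"), run$sim$genome)
  calls <- annotate_variants(back, run$sim$set_a, run$sim$genome,
                             a_style_regime())
  exp <- run$vt$truth$expected_a[match(calls$variant_id,
                                       run$vt$truth$variant_id)]
  expect_identical(calls$term, exp)
})

test_that("SNVs never receive a frameshift term", {
  run <- get_truth_run()
  for (calls in list(run$calls_a, run$calls_v)) {
    snvs <- calls[calls$var_class == "SNV", ]
    expect_false(any(grepl("frameshift", snvs$term)))
  }
})

test_that("CDS indels with non-codon-multiple length change are never
          missense/synonymous", {
  run <- get_truth_run()
  vt <- run$vt
  fs_classes <- c("frameshift_indel", "stopgain_via_indel")
  for (calls in list(run$calls_a, run$calls_v)) {
    sub <- calls[calls$variant_id %in%
                   vt$truth$variant_id[vt$truth$class %in% fs_classes], ]
    expect_false(any(sub$term %in% c("synonymous_SNV", "nonsynonymous_SNV",
                                     "synonymous_variant",
                                     "missense_variant")))
    expect_true(all(grepl("frameshift|stopgain|stop_gained", sub$term)))
  }
})

test_that("the superset yields more severe annotations (asymmetry)", {
  sc <- get_scenario()$sc
  run <- get_scenario()$run
  rk <- severity_ranking("A_style")
  ra <- match(run$calls_a$term, rk$terms)
  rb <- match(run$calls_b$term[match(run$calls_a$variant_id,
                                     run$calls_b$variant_id)], rk$terms)
  expect_true(all(rb <= ra))     # severity monotone under set growth
  expect_true(any(rb < ra))      # strictly more severe somewhere
  grp <- function(terms) sum(rollup_group(terms, "A_style") %in%
                               c("LOF", "MISSENSE"))
  expect_gt(grp(run$calls_b$term), grp(run$calls_a$term))
  expect_equal(grp(run$calls_b$term) - grp(run$calls_a$term),
               sc$expected$n_bonly_variants)
})
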