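panel <- synthetic_assay_panel()
gq <- panel$GNAQ_Q209

make_read <- function(assay, barcode, insert, stem = assay$stem_seq,
                      anchor = assay$anchor_seq, id = "r1") {
  s <- paste0(anchor, barcode, stem, insert)
  data.frame(read_id = id, sequence = s, qualities = strrep("I", nchar(s)),
             stringsAsFactors = FALSE)
}

test_that("tagging extracts the barcode when the stem sits at its expected position", {
  bc <- "ACGTACGTACGT"
  rd <- make_read(gq, bc, gq$reference_seq)
  tg <- tag_reads(rd, panel)
  expect_true(tg$valid)
  expect_equal(tg$assay, "GNAQ_Q209")
  expect_equal(tg$barcode, bc)
  expect_equal(tg$insert, gq$reference_seq)
})

test_that("a single stem substitution invalidates the read at zero tolerance", {
  stem_bad <- sub("G", "T", gq$stem_seq)
  tg <- tag_reads(make_read(gq, "ACGTACGTACGT", gq$reference_seq,
                            stem = stem_bad), panel)
  expect_false(tg$valid)
  # but passes with one mismatch allowed
  tg1 <- tag_reads(make_read(gq, "ACGTACGTACGT", gq$reference_seq,
                             stem = stem_bad), panel, max_stem_mismatch = 1L)
  expect_true(tg1$valid)
})

test_that("ambiguous barcode bases and unmatched anchors invalidate reads", {
  tg <- tag_reads(make_read(gq, "ACGTACGTACGN", gq$reference_seq), panel)
  expect_false(tg$valid)
  tg2 <- tag_reads(make_read(gq, "ACGTACGTACGT", gq$reference_seq,
                             anchor = "NNNNNNNN"), panel)
  expect_false(tg2$valid)
  expect_true(is.na(tg2$assay))
})

test_that("malformed records with unequal sequence/quality lengths are rejected", {
  rd <- make_read(gq, "ACGTACGTACGT", gq$reference_seq)
  rd$qualities <- "II"
  expect_error(tag_reads(rd, panel), "malformed")
})

test_that("valid-read count matches simulator stem-corruption bookkeeping", {
  spec <- read_sim_spec(gq, true_vaf = 0.05, n_molecules = 100,
                        per_base_error = 0, stem_corruption_prob = 0.05,
                        seed = 11L)
  sim <- simulate_reads(spec)
  tg <- tag_reads(sim$reads, panel)
  expect_equal(sum(tg$valid), sim$stats$n_reads - sim$stats$n_stem_corrupted)
})

test_that("families partition valid reads by (amplicon, barcode)", {
  rds <- do.call(rbind, list(
    make_read(gq, "AAAAAAAAAAAA", gq$reference_seq, id = "a1"),
    make_read(gq, "AAAAAAAAAAAA", gq$reference_seq, id = "a2"),
    make_read(gq, "AAAAAAAAAAAA", gq$reference_seq, id = "a3"),
    make_read(gq, "CCCCCCCCCCCC", gq$reference_seq, id = "b1"),
    make_read(gq, "CCCCCCCCCCCC", gq$reference_seq, id = "b2"),
    make_read(gq, "GGGGGGGGGGGG", gq$reference_seq, id = "c1")))
  fams <- build_families(tag_reads(rds, panel))
  expect_length(fams, 3L)
  expect_setequal(vapply(fams, `[[`, integer(1), "size"), c(3L, 2L, 1L))
  # the same barcode on two assays forms two distinct families
  g11 <- panel$GNA11_Q209
  rds2 <- rbind(make_read(gq, "AAAAAAAAAAAA", gq$reference_seq, id = "x1"),
                make_read(g11, "AAAAAAAAAAAA", g11$reference_seq,
                          id = "x2"))
  fams2 <- build_families(tag_reads(rds2, panel))
  expect_length(fams2, 2L)
  expect_setequal(vapply(fams2, `[[`, character(1), "assay"),
                  c("GNAQ_Q209", "GNA11_Q209"))
  expect_length(build_families(tag_reads(rds[0, ], panel)), 0L)
})

test_that("family count equals molecules with distinct barcodes (simulator oracle)", {
  spec <- read_sim_spec(gq, true_vaf = 0.1, n_molecules = 100,
                        per_base_error = 0, seed = 5L)
  sim <- simulate_reads(spec)
  fams <- build_families(tag_reads(sim$reads, panel))
  expect_length(fams, length(unique(sim$truth$barcode)))
  # partition: family sizes sum to the number of valid tagged reads
  expect_equal(sum(vapply(fams, `[[`, integer(1), "size")),
               sum(tag_reads(sim$reads, panel)$valid))
})

test_that("consensus thresholds are exact at the family-size boundaries", {
  alt_ins <- insert_with_allele(gq, "T")
  ref_ins <- gq$reference_seq
  target <- gq$target_position + 1L

  # 3-20 reads: any discordant read defeats the nonreference call
  for (s in c(3L, 10L, 20L)) {
    all_mut <- consensus_call(make_family(gq, rep(alt_ins, s)), gq)
    expect_equal(all_mut$bases[target], "T")
    one_wt <- consensus_call(
      make_family(gq, c(rep(alt_ins, s - 1L), ref_ins)), gq)
    expect_equal(one_wt$bases[target], "A")
  }
  # >20 reads: 90% rule; at size 21, 19 concordant suffice, 18 do not
  s21_19 <- consensus_call(make_family(gq, c(rep(alt_ins, 19), rep(ref_ins, 2))), gq)
  expect_equal(s21_19$bases[target], "T")
  s21_18 <- consensus_call(make_family(gq, c(rep(alt_ins, 18), rep(ref_ins, 3))), gq)
  expect_equal(s21_18$bases[target], "A")
  # size 25: 23 mutant (92%) called, 22 (88%) not
  s25_23 <- consensus_call(make_family(gq, c(rep(alt_ins, 23), rep(ref_ins, 2))), gq)
  expect_equal(s25_23$bases[target], "T")
  s25_22 <- consensus_call(make_family(gq, c(rep(alt_ins, 22), rep(ref_ins, 3))), gq)
  expect_equal(s25_22$bases[target], "A")
  # families below the minimum size are excluded
  expect_null(consensus_call(make_family(gq, rep(alt_ins, 2)), gq))
})

test_that("competing nonreference alleles apply the threshold to the modal one", {
  altT <- insert_with_allele(gq, "T")
  altC <- insert_with_allele(gq, "C")
  target <- gq$target_position + 1L
  # size 25, 20 T + 5 C: modal nonref T at 80% < 90% and no reference
  # support -> no call
  cs <- consensus_call(make_family(gq, c(rep(altT, 20), rep(altC, 5))), gq)
  expect_true(is.na(cs$bases[target]))
  expect_true(target %in% cs$no_call)
  # size 25, 23 T + 2 C: T at 92% -> called
  cs2 <- consensus_call(make_family(gq, c(rep(altT, 23), rep(altC, 2))), gq)
  expect_equal(cs2$bases[target], "T")
  # mixed family below total unanimity with reference present -> reference
  cs3 <- consensus_call(
    make_family(gq, c(rep(altT, 4), rep(gq$reference_seq, 6))), gq)
  expect_equal(cs3$bases[target], "A")
})

test_that("consensus errors on unequal read lengths", {
  fam <- make_family(gq, c(gq$reference_seq, substr(gq$reference_seq, 1, 10),
                           gq$reference_seq))
  expect_error(consensus_call(fam, gq), "unequal")
})

test_that("VAF counts mutant vs wildtype families and excludes no-calls", {
  altT <- insert_with_allele(gq, "T")
  wt <- lapply(1:3, function(i) consensus_call(
    make_family(gq, rep(gq$reference_seq, 5)), gq))
  mut <- list(consensus_call(make_family(gq, rep(altT, 5)), gq))
  vc <- quantify_vaf(c(wt, mut), gq)
  expect_equal(vc$mutant_families, 1L)
  expect_equal(vc$wildtype_families, 3L)
  expect_equal(vc$vaf, 0.25)
  expect_equal(vc$position, gq$target_position + 1L)
  # zero mutant families give VAF exactly 0
  vc0 <- quantify_vaf(wt, gq)
  expect_equal(vc0$vaf, 0)
  # zero classifiable families: VAF is NA (undetectable), not 0
  altX <- insert_with_allele(gq, "G")   # not among target_alts
  ncs <- list(consensus_call(make_family(gq, rep(altX, 5)), gq))
  expect_warning(vcn <- quantify_vaf(ncs, gq), "undetectable")
  expect_true(is.na(vcn$vaf))
  expect_equal(vcn$nocall_families, 1L)
})

test_that("end-to-end VAF estimate tracks simulated truth on a VAF grid", {
  vafs <- c(0.01, 0.05, 0.2)
  est <- truth <- numeric(0)
  for (i in seq_along(vafs)) {
    spec <- read_sim_spec(gq, true_vaf = vafs[i], n_molecules = 2000,
                          per_base_error = 1e-3, seed = 100L + i)
    sim <- simulate_reads(spec)
    vc <- call_variants(sim$reads, gq)
    est <- c(est, vc$vaf)
    truth <- c(truth, mean(sim$truth$allele != "ref"))
  }
  # estimates recover the realized molecule-level mutant fractions
  expect_true(all(abs(est - truth) < 0.01))
  slope <- coef(lm(est ~ truth))[2]
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
})

test_that("variant tables round-trip through the TSV exporter", {
  spec <- read_sim_spec(gq, true_vaf = 0.1, n_molecules = 200, seed = 2L)
  sim <- simulate_reads(spec)
  vc <- call_variants(sim$reads, gq)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_calls(vc, path)
  back <- read.delim(path)
  expect_equal(back$mutant_families, vc$mutant_families)
  expect_equal(back$vaf_percent, vc$vaf_percent, tolerance = 1e-10)
  expect_equal(back$position, vc$position)
})

test_that("FASTQ writing and reading preserve reads byte for byte", {
  sim <- simulate_reads(read_sim_spec(gq, 0.1, 30, seed = 9L))
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(sim$reads, path)
  back <- read_fastq(path)
  expect_identical(back, sim$reads)
})
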