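# Format round trips, allele harmonization rules, manifest determinism.

test_that("VCF write/read round trip preserves dosages and metadata", {
  G <- randomPanel(30, 25, seed = 2)
  # inject fractional and missing dosages to exercise DS and ./.
  D <- dosages(G) * 1.0
  D[1, 1] <- 1.7
  D[2, 2] <- NA
  G2 <- GenotypeMatrix(D, variantInfo(G), sampleIDs(G))
  f <- tempfile(fileext = ".vcf")
  writeGenotypes(G2, f, "vcf")
  back <- readGenotypes(f, "vcf")
  expect_equal(unname(dosages(back)), unname(dosages(G2)), tolerance = 1e-6)
  expect_identical(S4Vectors::mcols(variantInfo(back))$a1,
                   S4Vectors::mcols(variantInfo(G2))$a1)
})

test_that("GT is used when DS is absent and DS wins when present", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"d\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    paste("1", "100", "rs1", "G", "A", ".", "PASS", ".", "GT:DS",
          "0/1:.", "1/1:1.7", sep = "\t")), f)
  G <- readGenotypes(f, "vcf")
  expect_equal(unname(dosages(G)[1, ]), c(1, 1.7))
})

test_that("dosage TSV round trips and honours keep_samples", {
  G <- randomPanel(20, 10, seed = 3)
  f <- tempfile(fileext = ".tsv")
  writeGenotypes(G, f, "dosage_tsv")
  keep <- sampleIDs(G)[c(3, 1, 7)]
  back <- readGenotypes(f, "dosage_tsv", keep_samples = keep)
  expect_identical(sampleIDs(back), keep)
  expect_equal(unname(dosages(back)), unname(dosages(G)[, keep]))
  expect_error(readGenotypes(f, "dosage_tsv", keep_samples = "nope"),
               "absent")
})

test_that("readSumstats converts OR to log scale and clamps p = 0", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("CHR\tBP\tSNP\tA1\tA2\tOR\tSE\tP",
               "19\t45411941\trs_apoe\tC\tT\t3.44\t0.05\t5.64E-212",
               "1\t100\trs1\tA\tG\t1.0\t0.1\t0.5",
               "1\t200\trs2\tA\tG\t0.9\t0.1\t0",
               "1\t300\trs3\tA\tG\tnot_a_number\t0.1\t0.5"), f)
  expect_message(ss <- readSumstats(f), "dropped 1")
  tb <- statsTable(ss)
  expect_equal(nrow(tb), 3)
  expect_equal(tb$beta[tb$id == "rs_apoe"], log(3.44), tolerance = 1e-12)
  expect_equal(tb$beta[tb$id == "rs_apoe"], 1.2355, tolerance = 1e-4)
  expect_equal(tb$beta[tb$id == "rs1"], 0)
  expect_equal(tb$p[tb$id == "rs2"], .Machine$double.xmin)
  expect_true(tb$flagged[tb$id == "rs2"])
  # beta-less, OR-less file is rejected
  f2 <- tempfile()
  writeLines(c("CHR\tBP\tA1\tA2\tP", "1\t1\tA\tG\t0.5"), f2)
  expect_error(readSumstats(f2), "beta nor an OR")
})

test_that("harmonization matches, flips, and drops with reason codes", {
  G <- manualG(matrix(1, 4, 6), pos = c(100L, 200L, 300L, 400L),
               a1 = c("A", "C", "A", "C"), a2 = c("G", "T", "T", "T"))
  # cohort alleles: v1 A/G, v2 C/T, v3 A/T (ambiguous), v4 C/T
  ss <- SummaryStats(data.frame(
    chrom = "1", pos = c(100, 200, 300, 400, 500),
    id = paste0("r", 1:5),
    effect_allele = c("A", "T", "A", "G", "A"),
    other_allele  = c("G", "C", "T", "T", "G"),
    beta = 0.1, se = 0.1, p = 0.5, freq = 0.2, n = 100))
  h <- harmonizeAlleles(ss, G)
  expect_equal(h$ss_idx, 1:2)
  expect_equal(h$sign_flip, c(FALSE, TRUE))
  expect_setequal(h$dropped$reason[h$dropped$ss_idx == 3],
                  "ambiguous_strand")
  expect_setequal(h$dropped$reason[h$dropped$ss_idx == 4],
                  "allele_mismatch")
  expect_setequal(h$dropped$reason[h$dropped$ss_idx == 5],
                  "missing_in_cohort")
  # keeping ambiguous pairs is possible
  h2 <- harmonizeAlleles(ss, G, drop_ambiguous = FALSE)
  expect_true(3 %in% h2$ss_idx)
  # idempotence: re-harmonizing the matched subset changes nothing
  h3 <- harmonizeAlleles(ss[h$ss_idx], G)
  expect_equal(h3$g_idx, h$g_idx)
  expect_equal(h3$sign_flip, h$sign_flip)
  expect_equal(nrow(h3$dropped), 0)
  # a build mismatch gives zero matches and a clear error
  ss_wrong <- SummaryStats(data.frame(
    chrom = "9", pos = 1, id = "x", effect_allele = "A",
    other_allele = "G", beta = 0, se = 0.1, p = 0.5, freq = 0.2, n = 10))
  expect_error(harmonizeAlleles(ss_wrong, G), "build mismatch")
})

test_that("duplicate positions are dropped with reason duplicate", {
  G <- manualG(matrix(1, 2, 4), pos = c(100L, 200L))
  ss <- SummaryStats(data.frame(
    chrom = "1", pos = c(100, 100, 200), id = c("a", "b", "c"),
    effect_allele = c("A", "A", "C"), other_allele = c("G", "G", "T"),
    beta = 0.1, se = 0.1, p = 0.5, freq = 0.2, n = 100))
  h <- harmonizeAlleles(ss, G)
  expect_true(all(h$dropped$reason[h$dropped$ss_idx %in% 1:2] ==
                  "duplicate"))
  expect_false(any(1:2 %in% h$ss_idx))
})

test_that("writeResults emits headers, counts, and is byte-stable", {
  d1 <- tempfile(); d2 <- tempfile()
  tabs <- list(empty = data.frame(a = integer(0), b = character(0)),
               hits = data.frame(id = c("x", "y"), p = c(0.1, 0.2)))
  m <- writeResults(tabs, d1, seed = 3, config = list(q = 0.05))
  expect_identical(readLines(file.path(d1, "empty.tsv")), "a\tb")
  expect_equal(m$tables$hits$rows, 2)
  expect_error(writeResults(tabs, d1), "overwrite")
  writeResults(tabs, d2, seed = 3, config = list(q = 0.05))
  for (f in c("empty.tsv", "hits.tsv", "manifest.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("BED and GMT round trips preserve genes and sets", {
  ann <- simulateAnnotation("1", 1, 1e6, n_genes = 10, n_sets = 3, seed = 5)
  fb <- tempfile(fileext = ".bed")
  writeGeneBed(ann$genes, fb)
  back <- readGeneBed(fb)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(ann$genes))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(ann$genes))
  expect_identical(back$gene_id, ann$genes$gene_id)
  fg <- tempfile(fileext = ".gmt")
  writeGmt(ann$sets, fg)
  expect_identical(lapply(readGmt(fg), sort), lapply(ann$sets, sort))
})
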