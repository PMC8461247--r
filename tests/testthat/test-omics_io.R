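test_that("matrix TSV round-trips value-identically, preserving missing cells", {
  m <- matrix(c(1.25, 0, NA, 3.5, 2.125, 7), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("sA", "sB")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_omics_matrix(m, path)
  back <- read_omics_matrix(path, "expression")
  expect_identical(unclass(back)[, ], m[, ])
  expect_equal(dim(back), c(3L, 2L))
})

test_that("malformed matrices are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "gA\t1\t2", "gA\t3\t4"), path)
  expect_error(read_omics_matrix(path), "duplicate feature IDs.*gA")

  writeLines(c("gene_id\ts1\ts2", "gA\t1\tx", "gB\t3\t4"), path)
  expect_error(read_omics_matrix(path), "non-numeric cell.*gA.*s2")

  # empty cells and the NA token both read as missing
  writeLines(c("gene_id\ts1\ts2", "gA\t\t2", "gB\tNA\t4"), path)
  m <- read_omics_matrix(path)
  expect_true(is.na(m["gA", "s1"]) && is.na(m["gB", "s1"]))
})

test_that("sample matching intersects and sorts deterministically", {
  mk <- function(samples) matrix(1, 1, length(samples),
                                 dimnames = list("g", samples))
  expect_message(
    common <- match_samples(list(a = mk(c("C", "A", "B")), b = mk(c("B", "C", "D")),
                                 c = mk(c("B", "C")))),
    "dropped per layer")
  expect_identical(common, c("B", "C"))

  suppressMessages({
    same <- match_samples(list(mk(c("z", "y")), mk(c("y", "z"))))
  })
  expect_identical(same, c("y", "z"))

  expect_error(suppressMessages(match_samples(list(mk("A"), mk("B")))),
               "no samples shared")
  expect_error(match_samples(list(mk("A"))), ">= 2")
})

test_that("label attribute screening applies class-count and bias rules", {
  lab <- function(counts) {
    rep(paste0("c", seq_along(counts)), counts)
  }
  ok <- filter_label_attribute(setNames(lab(c(50, 30, 20)), paste0("s", 1:100)))
  expect_true(ok$accepted)

  # the class-count bound is exclusive: exactly max_classes classes fail
  five <- filter_label_attribute(setNames(lab(c(20, 20, 20, 20, 20)), paste0("s", 1:100)),
                                 max_classes = 5)
  expect_false(five$accepted)
  expect_match(five$reason, "5 classes")

  biased <- filter_label_attribute(setNames(lab(c(99, 1)), paste0("s", 1:100)))
  expect_false(biased$accepted)
  expect_match(biased$reason, "bias")

  single <- filter_label_attribute(setNames(rep("x", 10), paste0("s", 1:10)))
  expect_false(single$accepted)

  # pure predicate: identical verdicts on identical input
  expect_identical(ok, filter_label_attribute(setNames(lab(c(50, 30, 20)), paste0("s", 1:100))))
})

test_that("gene annotation reads from TSV and BED with consistent TSS", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\tstrand\ttss\tbiotype",
               "gA\tchr1\t+\t1001\tprotein_coding",
               "gB\tchr1\t-\t5000\tlincRNA"), tsv)
  a1 <- read_gene_annotation(tsv)
  expect_equal(a1$tss, c(1001L, 5000L))

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t1000\t2000\tgA\tprotein_coding\t+",
               "chr1\t4000\t5000\tgB\tlincRNA\t-"), bed)
  a2 <- read_gene_annotation(bed)
  expect_equal(a2$tss, a1$tss)
  expect_equal(a2$gene_id, a1$gene_id)

  writeLines(c("gene_id\tchrom\tstrand\ttss\tbiotype",
               "gA\tchr1\t*\t100\tprotein_coding"), tsv)
  expect_error(read_gene_annotation(tsv), "strand")
})

test_that("miRNA target maps and label tables parse", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mirna_id\tgene_id", "mir-1\tgA", "mir-1\tgB", "mir-2\tgA"), tf)
  tm <- read_mirna_targets(tf)
  expect_setequal(tm[["mir-1"]], c("gA", "gB"))
  expect_identical(tm[["mir-2"]], "gA")

  writeLines("mirna_id\tgene_id", tf)
  expect_error(read_mirna_targets(tf), "empty")

  lf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tlabel", "s1\tLumA", "s2\tBasal"), lf)
  labs <- read_labels(lf)
  expect_identical(labs, c(s1 = "LumA", s2 = "Basal"))
})
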