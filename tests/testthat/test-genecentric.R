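test_that("quantile normalization matches the order-statistic oracle", {
  # oracle: sort each column, average order statistics, re-assign by rank
  m <- matrix(c(1, 3, 4, 2), 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, 1]), c(1.5, 3.5))
  expect_equal(unname(qn[, 2]), c(3.5, 1.5))

  # columns already identical -> unchanged
  ident <- matrix(c(2, 5, 9, 2, 5, 9), 3, 2,
                  dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(quantile_normalize(ident), ident)

  # all-zero matrix stays zero through the log2 wrapper
  z <- matrix(0, 3, 2, dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_true(all(log2_quantile_normalize(z) == 0))

  expect_error(log2_quantile_normalize(matrix(-1, 2, 2, dimnames = list(1:2, 1:2))),
               "non-negative")
})

test_that("after quantile normalization all columns share one multiset of values", {
  set.seed(11)
  for (i in 1:50) {
    m <- matrix(rexp(20 * 4), 20, 4, dimnames = list(paste0("g", 1:20), paste0("s", 1:4)))
    qn <- quantile_normalize(m)
    sorted <- apply(qn, 2, sort)
    expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
  }
})

test_that("promoter methylation aggregates strand-aware window means", {
  ann <- data.frame(gene_id = c("gPlus", "gMinus", "gBare"),
                    chrom = "chr1", strand = c("+", "-", "+"),
                    tss = c(10000L, 30000L, 50000L),
                    biotype = "protein_coding")
  manifest <- data.frame(
    probe_id = c("p1", "p2", "p_out", "p3", "p4_out", "p_allna"),
    chrom = "chr1",
    pos = c(9500L, 8200L, 12500L,   # gPlus: [8000,10000]; p_out downstream
            30600L, 29500L,         # gMinus: [30000,32000]; p4_out upstream
            9900L))
  probes <- matrix(c(0.2, 0.4, 0.9, 0.6, 0.9, NA,
                     0.1, NA, 0.9, 0.8, 0.9, NA),
                   nrow = 6, dimnames = list(manifest$probe_id, c("sA", "sB")))
  gm <- methylation_to_gene(probes, manifest, ann)

  expect_equal(gm["gPlus", "sA"], mean(c(0.2, 0.4)))
  # probe missing in sample B -> mean over the remaining probe
  expect_equal(gm["gPlus", "sB"], 0.1)
  expect_equal(gm["gMinus", "sA"], 0.6)
  # gene with no probe in its window is absent
  expect_false("gBare" %in% rownames(gm))
  expect_error(methylation_to_gene(probes * 3, manifest, ann), "0,1")
})

test_that("miRNA bundles aggregate by geometric or arithmetic mean", {
  mirna <- matrix(c(2, 8, 5, 0,
                    2, 8, 7, 0), nrow = 4,
                  dimnames = list(c("m1", "m2", "m3", "mdead"), c("sA", "sB")))
  tmap <- list(m1 = "gBoth", m2 = "gBoth", m3 = "gSolo", mdead = "gDead")

  # geometric oracle without pseudocount distortion: exp(mean(log(x+1)))-1
  gm <- mirna_to_gene(mirna, tmap, gene_ids = c("gBoth", "gSolo", "gNone", "gDead"))
  expect_equal(gm["gBoth", "sA"], exp(mean(log(c(2, 8) + 1))) - 1)
  # single-miRNA bundle is the identity
  expect_equal(gm["gSolo", "sB"], 7)
  # untargeted gene and gene targeted only by an all-zero miRNA -> 0
  expect_true(all(gm[c("gNone", "gDead"), ] == 0))

  am <- mirna_to_gene(mirna, tmap, gene_ids = "gBoth", mode = "arithmetic")
  expect_equal(am["gBoth", "sA"], 5)

  expect_error(mirna_to_gene(mirna, list(), "gBoth"), "empty")
})

test_that("pure geometric mean of (2, 8) is 4 without pseudocount", {
  # the exported aggregation uses log1p; verify its limiting behaviour on
  # large values where the pseudocount is negligible
  big <- matrix(c(2e6, 8e6), 2, 1, dimnames = list(c("m1", "m2"), "s"))
  g <- mirna_to_gene(big, list(m1 = "g", m2 = "g"), "g")
  expect_equal(g["g", "s"] / 4e6, 1, tolerance = 1e-5)
})

test_that("gene filtering enforces biotype, presence and missingness rules", {
  ann <- data.frame(gene_id = c("gOK", "gMiss", "gLinc", "gAbsent"),
                    chrom = "chr1", strand = "+", tss = 1:4 * 1000L,
                    biotype = c("protein_coding", "protein_coding", "lincRNA",
                                "protein_coding"))
  samples <- paste0("s", 1:100)
  ge <- matrix(1, 4, 100, dimnames = list(ann$gene_id, samples))
  me <- ge
  me["gMiss", 1:81] <- NA  # missing in 81% of samples
  mi <- ge[c("gOK", "gMiss", "gLinc"), ]  # gAbsent not in all layers
  kept <- filter_genes(list(GE = ge, ME = me, MI = mi), ann)
  expect_identical(kept, "gOK")

  # exactly 80% missing is still tolerated
  me2 <- ge
  me2["gMiss", 1:80] <- NA
  kept2 <- filter_genes(list(GE = ge, ME = me2, MI = mi), ann)
  expect_setequal(kept2, c("gOK", "gMiss"))
})

test_that("min-max scaling uses the global slice range", {
  m <- matrix(c(2, 6, 10, 4), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  sc <- minmax_scale_slice(m)
  expect_equal(sc["b", "x"], 0.5)  # (6-2)/(10-2)
  expect_equal(min(sc), 0)
  expect_equal(max(sc), 1)
  cst <- minmax_scale_slice(matrix(7, 2, 2, dimnames = list(1:2, 1:2)))
  expect_true(all(cst == 0))
})

test_that("tensor assembly stacks slices, imputes and preserves values", {
  genes <- paste0("g", 1:10); samples <- paste0("s", 1:4)
  mk <- function(seed) {
    set.seed(seed)
    omics_matrix(matrix(runif(40), 10, 4, dimnames = list(genes, samples)), "x")
  }
  ms <- list(GE = mk(1), ME = mk(2), MI = mk(3))
  tens <- assemble_tensor(ms)
  expect_equal(dim(tens), c(10L, 4L, 3L))
  # slices recoverable and in [0,1], no NA
  expect_true(all(tens >= 0 & tens <= 1))
  expect_false(anyNA(tens))
  expect_equal(tens[, , "ME"], minmax_scale_slice(unclass(ms$ME)), ignore_attr = TRUE)

  # one missing cell -> its gene's row mean
  holey <- unclass(mk(4)); holey[2, 3] <- NA
  ms$GE <- omics_matrix(holey, "GE")
  tens2 <- assemble_tensor(ms, scale = FALSE)
  expect_equal(tens2[2, 3, "GE"], mean(holey[2, -3]))

  bad <- ms
  bad$ME <- omics_matrix(unclass(bad$ME)[, c(2, 1, 3, 4)], "ME")
  expect_error(assemble_tensor(bad), "identical gene and sample axes")
})

test_that("tensor write/read round-trips through TSV slices", {
  set.seed(9)
  ms <- lapply(c(GE = 1, ME = 2), function(s) {
    set.seed(s)
    omics_matrix(matrix(runif(12), 4, 3,
                        dimnames = list(paste0("g", 1:4), paste0("s", 1:3))), "x")
  })
  tens <- assemble_tensor(ms)
  dir <- withr::local_tempdir()
  write_tensor(tens, dir)
  back <- read_tensor(dir)
  expect_equal(unclass(back)[, , ], unclass(tens)[, , ], tolerance = 1e-12)
})

test_that("the normalization pipeline is deterministic", {
  set.seed(21)
  raw <- matrix(rexp(50), 10, 5, dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
  a <- normalize_layer(raw, TRUE)
  b <- normalize_layer(raw, TRUE)
  expect_identical(a, b)
})
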