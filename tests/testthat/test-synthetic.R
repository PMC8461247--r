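test_that("the generator is reproducible and respects its contract", {
  a <- generate_cohort(n_genes = 50, n_samples = 24, seed = 3)
  b <- generate_cohort(n_genes = 50, n_samples = 24, seed = 3)
  expect_identical(a$tensor[, , ], b$tensor[, , ])
  expect_identical(a$labels, b$labels)
  expect_identical(a$truth$G, b$truth$G)

  expect_true(all(a$tensor >= 0 & a$tensor <= 1))
  expect_false(anyNA(a$tensor))
  expect_error(generate_cohort(rank_true = 3, n_labels = 4), "rank_true")
})

test_that("every label owns at least one planted feature", {
  co <- generate_cohort(n_genes = 40, n_samples = 20, rank_true = 8,
                        n_labels = 4, seed = 2)
  lf <- co$truth$label_features
  expect_setequal(names(lf), paste0("L", 1:4))
  expect_true(all(lengths(lf) >= 1))
  expect_setequal(unlist(lf), 1:8)
})

test_that("a noise-free cohort equals the scaled planted sum exactly", {
  co <- generate_cohort(n_genes = 40, n_samples = 20, noise_sd = 0, seed = 6)
  clean <- reconstruct(co$truth$G, co$truth$P, co$truth$O)
  for (k in 1:3) {
    expect_equal(co$tensor[, , k], minmax_scale_slice(clean[, , k]),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("omics routing concentrates signal in the requested layers", {
  co <- generate_cohort(n_genes = 40, n_samples = 20, seed = 4,
                        omics_routing = "GE")
  O <- co$truth$O
  expect_true(all(O["GE", ] == 1))
  expect_true(all(O[c("ME", "MI"), ] < 0.1))

  sp <- generate_cohort(n_genes = 40, n_samples = 20, seed = 4,
                        omics_routing = "split_GE_ME")
  Os <- sp$truth$O
  first <- sp$truth$owner %in% c("L1", "L2")
  expect_true(all(Os["GE", first] == 1) && all(Os["ME", !first] == 1))
  expect_true(all(Os["GE", !first] < 0.1) && all(Os["ME", first] < 0.1))

  expect_error(generate_cohort(omics_routing = "bogus"), "routing")
})

test_that("fixture files parse cleanly and invert exactly before normalization", {
  fx <- small_fixture_dir(seed = 5)
  expect_no_warning({
    cfg <- fixture_config(fx$files)
    gc_data <- suppressMessages(build_gene_centric(cfg))
  })
  g <- gc_data$genes; s <- gc_data$samples
  direct <- fx$cohort$tensor
  expect_length(g, 60)

  # aggregation inverts the encoding exactly (normalization comes later)
  expect_equal(log2(gc_data$raw$GE + 1) / 10, direct[g, s, "GE"],
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(gc_data$raw$ME, direct[g, s, "ME"],
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(log2(gc_data$raw$MI + 1) / 10, direct[g, s, "MI"],
               ignore_attr = TRUE, tolerance = 1e-12)

  # probe manifest positions sit inside the strand-aware promoter windows
  ann <- read_gene_annotation(fx$files$annotation)
  man <- read_probe_manifest(fx$files$probe_manifest)
  gene_of <- sub("^cg_(.*)_[ab]$", "\\1", man$probe_id)
  ai <- match(gene_of, ann$gene_id)
  lo <- ifelse(ann$strand[ai] == "+", ann$tss[ai] - 2000L, ann$tss[ai])
  hi <- ifelse(ann$strand[ai] == "+", ann$tss[ai], ann$tss[ai] + 2000L)
  expect_true(all(man$pos >= lo & man$pos <= hi))
})

test_that("the normalized round-trip tensor stays close to the generated one", {
  # quantile normalization recalibrates each sample's marginal to the
  # cross-sample average, so the round trip is not an identity; the
  # distortion below was measured once on the default construction and
  # frozen (absolute, and after per-slice least-squares rescaling).
  fx <- small_fixture_dir(seed = 5, n_genes = 120, n_samples = 40)
  cfg <- fixture_config(fx$files)
  gc_data <- suppressMessages(build_gene_centric(cfg))
  slices <- list(GE = normalize_layer(gc_data$raw$GE, TRUE),
                 ME = normalize_layer(gc_data$raw$ME, FALSE),
                 MI = normalize_layer(gc_data$raw$MI, TRUE))
  direct <- fx$cohort$tensor
  num <- den <- num_sc <- 0
  for (o in names(slices)) {
    a <- slices[[o]]; b <- direct[rownames(a), colnames(a), o]
    num <- num + sum((a - b)^2)
    sc <- sum(a * b) / sum(a * a)
    num_sc <- num_sc + sum((sc * a - b)^2)
    den <- den + sum(b^2)
  }
  expect_lt(sqrt(num / den), 0.65)      # frozen: measured 0.587 at this size
  expect_lt(sqrt(num_sc / den), 0.25)   # frozen: measured 0.199 scale-free
})

test_that("lower noise gives better factor recovery", {
  cos_at <- function(noise) {
    co <- generate_cohort(n_genes = 100, n_samples = 40, rank_true = 4,
                          noise_sd = noise, seed = 8)
    dec <- parafac_nn(co$tensor, 4, seed = 1, n_starts = 3)
    match_factors(dec$C_g, co$truth$G)$mean_cosine
  }
  cosines <- vapply(c(0.15, 0.05, 0), cos_at, numeric(1))
  expect_true(all(diff(cosines) >= -1e-6))  # non-decreasing as noise drops
  expect_gt(cosines[3], 0.99)
})
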