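toy_catalog <- function(G, chrom = 1L, pos = NULL, classes = NULL) {
  m <- ncol(G)
  data.frame(variant_id = colnames(G), chrom = chrom,
             pos = pos %||% (seq_len(m) * 1000L),
             ref = "A", alt = "C", n_alleles = 2L,
             maf = unname(column_maf(G)),
             classes = classes %||% rep("", m),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the QC cascade reproduces hand-computed survivors on a 5-variant toy", {
  n <- 100
  set.seed(42)
  good <- rbinom(n, 2L, 0.5)
  # HWE-conforming common variant, distinct from `good`
  good2 <- rbinom(n, 2L, 0.4)
  rare <- c(rep(0L, n - 2L), 1L, 1L)          # MAF 0.01: fails MAF filter
  holes <- rbinom(n, 2L, 0.3)
  holes[1:80] <- NA                            # 80% missing: fails call rate
  G <- cbind(v1 = rare, v2 = holes, v3 = good, v4 = good, v5 = good2)
  rownames(G) <- sprintf("i%04d", seq_len(n))
  catal <- toy_catalog(G)
  # v4 duplicates v3 (r^2 = 1): pruned, keeping the earlier position v3.
  # Survivors must be v3 and v5, provided both pass the exact HWE test.
  stopifnot(hwe_exact_test(sum(good == 0), sum(good == 1), sum(good == 2)) >= 0.15,
            hwe_exact_test(sum(good2 == 0), sum(good2 == 1), sum(good2 == 2)) >= 0.15)
  panel <- benchmark_qc_filter(G, catal)
  expect_setequal(panel$variant_ids, c("v3", "v5"))
})

test_that("pruning collapses identical variants to a single survivor", {
  n <- 80
  set.seed(43)
  d <- rbinom(n, 2L, 0.5)
  while (hwe_exact_test(sum(d == 0), sum(d == 1), sum(d == 2)) < 0.15) {
    d <- rbinom(n, 2L, 0.5)
  }
  G <- matrix(rep(d, 4), ncol = 4,
              dimnames = list(sprintf("i%03d", 1:n), paste0("v", 1:4)))
  panel <- benchmark_qc_filter(G, toy_catalog(G))
  expect_length(panel$variant_ids, 1L)
  expect_equal(panel$variant_ids, "v1")  # earliest position wins
})

test_that("the exact mid-p HWE test removes about 15% of conforming variants", {
  set.seed(44)
  m <- 400; n <- 500
  G <- vapply(runif(m, 0.15, 0.5), function(p) rbinom(n, 2L, p), numeric(n))
  pv <- apply(G, 2, function(d) hwe_exact_test(sum(d == 0), sum(d == 1),
                                               sum(d == 2)))
  frac <- mean(pv < 0.15)
  b <- binom_bounds(m, 0.15)
  expect_gte(frac, b[1]); expect_lte(frac, b[2])
  # gross HWE violation is caught
  expect_lt(hwe_exact_test(50, 0, 50), 1e-6)
})

test_that("LD block assignment equals brute-force transitive closure", {
  pop <- shared_pop()
  ids <- pop$catalog$variant_id[pop$catalog$chrom == 1][1:60]
  keep <- ids[apply(pop$genotypes[, ids], 2, stats::sd) > 0]
  G <- pop$genotypes[, keep]
  blocks <- assign_ld_blocks(pop$genotypes, pop$catalog, candidates = keep,
                             r2_threshold = 0.9, window_bp = NULL)
  oracle <- closure_blocks(G, 0.9)
  got <- as.integer(factor(blocks$assignment[keep],
                           levels = unique(blocks$assignment[keep])))
  want <- as.integer(factor(oracle, levels = unique(oracle)))
  expect_equal(got, want)
})

test_that("LD block edge cases: unattainable threshold and exact duplicates", {
  ig <- independent_genotypes(100, 10, seed = 45)
  b1 <- assign_ld_blocks(ig$genotypes, ig$catalog, r2_threshold = 1.01)
  expect_length(b1$blocks, 10L)

  G <- ig$genotypes
  G[, "v00002"] <- G[, "v00001"]
  b2 <- assign_ld_blocks(G, ig$catalog, r2_threshold = 0.98)
  blk <- b2$assignment[c("v00001", "v00002")]
  expect_equal(blk[[1]], blk[[2]])
  expect_length(b2$blocks, 9L)
})

test_that("block representatives follow the annotation priority tiers", {
  G <- matrix(rbinom(300, 2, 0.4), ncol = 3,
              dimnames = list(sprintf("i%03d", 1:100), c("a", "b", "c")))
  catal <- toy_catalog(G, classes = c("ATACQTL", "coding", ""))
  blocks <- structure(list(assignment = c(a = "b1", b = "b1", c = "b2"),
                           blocks = list(b1 = c("a", "b"), b2 = "c")),
                      class = "ld_blocks")
  reps <- select_block_representatives(blocks, catal)
  expect_equal(unname(reps), c("b", "c"))  # coding beats ATACQTL; singleton

  catal2 <- toy_catalog(G, classes = c("eeQTL", "coding", "GWAS"))
  blocks2 <- structure(list(assignment = c(a = "b1", b = "b1", c = "b1"),
                            blocks = list(b1 = c("a", "b", "c"))),
                       class = "ld_blocks")
  expect_equal(unname(select_block_representatives(blocks2, catal2)), "a")
})

test_that("MAF bins are half-open with a closed top bin", {
  G <- matrix(0, nrow = 2, ncol = 3,
              dimnames = list(c("i1", "i2"), c("a", "b", "c")))
  catal <- toy_catalog(G)
  catal$maf <- c(0.049, 0.05, 0.5)
  h <- maf_bin_histogram(c("a", "b", "c"), catal)
  expect_equal(unname(h[1]), 1L)   # 0.049 in [0.00, 0.05)
  expect_equal(unname(h[2]), 1L)   # 0.05 in [0.05, 0.10)
  expect_equal(unname(h[10]), 1L)  # 0.5 in the closed top bin
  expect_equal(sum(maf_bin_histogram(character(), catal)), 0L)
  catal$maf[1] <- 0.6
  expect_error(maf_bin_histogram("a", catal), "0.5")
})

test_that("uniform MAFs fill bins within multinomial bounds", {
  set.seed(47)
  m <- 1000
  catal <- data.frame(variant_id = sprintf("u%04d", 1:m), chrom = 1L,
                      pos = 1:m, ref = "A", alt = "C", n_alleles = 2L,
                      maf = runif(m, 0, 0.4999), classes = "",
                      stringsAsFactors = FALSE)
  h <- maf_bin_histogram(catal$variant_id, catal)
  expect_equal(sum(h), m)
  b <- stats::qbinom(c(0.0005, 0.9995), m, 0.1)  # ~99% family-wise over 10 bins
  expect_true(all(h >= b[1] & h <= b[2]))
})

test_that("MAF-spectrum matching reproduces the reference histogram exactly", {
  m <- 400
  set.seed(46)
  catal <- data.frame(variant_id = sprintf("c%04d", 1:m), chrom = 1L,
                      pos = 1:m, ref = "A", alt = "C", n_alleles = 2L,
                      maf = rep(seq(0.025, 0.475, by = 0.05), each = 40),
                      classes = sample(c("", "GWAS", "GWAS;eeQTL"), m,
                                       replace = TRUE),
                      stringsAsFactors = FALSE)
  reference <- stats::setNames(rep(20L, 10),
                               names(maf_bin_histogram(character(), catal)))
  out <- match_maf_spectrum(catal$variant_id, reference, catal, seed = 3)
  expect_equal(unname(maf_bin_histogram(out, catal)), unname(reference))

  # reference equal to the candidate histogram returns the candidates
  full <- maf_bin_histogram(catal$variant_id, catal)
  all_out <- match_maf_spectrum(catal$variant_id, full, catal, seed = 3)
  expect_setequal(all_out$variant_ids, catal$variant_id)

  # all-zero reference gives an empty panel; shortfalls warn
  zero <- stats::setNames(rep(0L, 10), names(reference))
  expect_length(match_maf_spectrum(catal$variant_id, zero, catal,
                                   seed = 3)$variant_ids, 0L)
  big <- stats::setNames(rep(100L, 10), names(reference))
  expect_warning(match_maf_spectrum(catal$variant_id[1:100], big, catal,
                                    seed = 3), "shortfall")
})

test_that("the final filter keeps biallelic variants with MAF at least 0.1", {
  m <- 10
  catal <- data.frame(variant_id = paste0("f", 1:m), chrom = 1L, pos = 1:m,
                      ref = "A", alt = "C",
                      n_alleles = c(2L, 2L, 3L, 2L, 2L, 2L, 2L, 2L, 2L, 2L),
                      maf = c(0.09, 0.10, 0.30, 0.05, 0.25, 0.30, 0.35,
                              0.40, 0.45, 0.20),
                      classes = "", stringsAsFactors = FALSE)
  out <- final_filter(catal$variant_id, catal)
  expect_false("f1" %in% out$variant_ids)  # MAF 0.09 removed
  expect_true("f2" %in% out$variant_ids)   # MAF 0.10 kept
  expect_false("f3" %in% out$variant_ids)  # triallelic removed
  expect_length(out$variant_ids, 7L)       # 3 of 10 fail
})

test_that("matched random baselines are deterministic and bounded", {
  m <- 50
  catal <- data.frame(variant_id = paste0("p", 1:m), chrom = 1L, pos = 1:m,
                      ref = "A", alt = "C", n_alleles = 2L,
                      maf = runif(m, 0.1, 0.5), classes = "",
                      stringsAsFactors = FALSE)
  cur <- new_panel("current", catal$variant_id, catal)
  expect_equal(sample_matched_random_panel(cur, m, seed = 1)$variant_ids,
               cur$variant_ids)
  expect_length(sample_matched_random_panel(cur, 0, seed = 1)$variant_ids, 0L)
  a <- sample_matched_random_panel(cur, 20, seed = 1)
  b <- sample_matched_random_panel(cur, 20, seed = 1)
  c <- sample_matched_random_panel(cur, 20, seed = 2)
  expect_identical(a$variant_ids, b$variant_ids)
  expect_false(identical(a$variant_ids, c$variant_ids))
  expect_error(sample_matched_random_panel(cur, m + 1, seed = 1), "more variants")
})

test_that("panel construction composes with non-increasing size after tagging", {
  pop <- shared_pop()
  catal <- pop$catalog
  cand <- catal$variant_id[nzchar(catal$classes)]
  blocks <- assign_ld_blocks(pop$genotypes, catal, candidates = cand)
  reps <- select_block_representatives(blocks, catal)
  expect_lte(length(reps), length(cand))
  ref_hist <- pmin(maf_bin_histogram(reps, catal), 15L)
  matched <- suppressWarnings(match_maf_spectrum(reps, ref_hist, catal, seed = 4))
  expect_lte(length(matched$variant_ids), length(reps))
  final <- final_filter(matched, catal)
  expect_lte(length(final$variant_ids), length(matched$variant_ids))
})
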