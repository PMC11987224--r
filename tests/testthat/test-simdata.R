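test_that("population generation is deterministic under a fixed seed", {
  cfg <- sim_config(n_individuals = 120, n_chromosomes = 2,
                    variants_per_chromosome = 60, seed = 11)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$catalog, b$catalog)
  ca <- assign_functional_classes(a$catalog, cfg)
  cb <- assign_functional_classes(b$catalog, cfg)
  expect_identical(ca$classes, cb$classes)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(variants_per_chromosome = 1), "integer >= 2")
  expect_error(sim_config(trait_heritabilities = c(fat_pct = 1.2, prot_pct = 0.5,
                                                   volume = 0.3)),
               "heritabilities")
  expect_error(sim_config(class_proportions = c(bogus = 0.1)), "unknown")
  expect_error(sim_config(class_proportions = c(GWAS = 0.9, coding = 0.3)),
               "sum to <= 1")
  expect_error(sim_config(recombination_rate = -1), "recombination_rate")
})

test_that("no recombination with a two-haplotype pool forces complete linkage", {
  m <- 30
  h1 <- rep(c(0L, 1L), length.out = m)
  pool <- rbind(h1, 1L - h1)
  cfg <- sim_config(n_individuals = 100, n_chromosomes = 2,
                    variants_per_chromosome = m, haplotype_pool_size = 2,
                    recombination_rate = 0, seed = 3)
  pop <- simulate_population(cfg, base_haplotypes = list(pool, pool))
  for (ch in 1:2) {
    G <- pop$genotypes[, pop$catalog$variant_id[pop$catalog$chrom == ch]]
    poly <- apply(G, 2, stats::sd) > 0
    r2 <- stats::cor(G[, poly])^2
    expect_true(all(abs(r2 - 1) < 1e-12))
  }
})

test_that("the MAF spectrum is U-shaped and the catalog MAF matches the dosages", {
  cfg <- sim_config(n_individuals = 500, n_chromosomes = 2,
                    variants_per_chromosome = 500, seed = 7)
  pop <- simulate_population(cfg)
  expect_gte(mean(pop$catalog$maf < 0.1), 0.30)
  expect_lt(max(abs(column_maf(pop$genotypes) - pop$catalog$maf)), 1e-12)
  expect_true(all(diff(pop$catalog$pos[pop$catalog$chrom == 1]) > 0))
  expect_false(anyDuplicated(pop$catalog$variant_id) > 0)
})

test_that("class annotation respects zero, saturation and proportion contracts", {
  catalog <- data.frame(variant_id = sprintf("v%05d", 1:10000),
                        chrom = 1L, pos = 1:10000, ref = "A", alt = "C",
                        n_alleles = 2L, maf = runif(10000, 0, 0.5),
                        classes = "", stringsAsFactors = FALSE)
  cfg0 <- sim_config(class_proportions = stats::setNames(numeric(0), character(0)))
  out0 <- assign_functional_classes(catalog, cfg0)
  expect_true(all(out0$classes == ""))

  cfg1 <- sim_config(class_proportions = c(coding = 1.0), seed = 2)
  out1 <- assign_functional_classes(catalog, cfg1)
  expect_true(all(grepl("coding", out1$classes)))

  cfg4 <- sim_config(class_proportions = c(GWAS = 0.1, eeQTL = 0.2,
                                           ATACQTL = 0.1), seed = 3)
  out4 <- assign_functional_classes(catalog, cfg4)
  frac <- mean(nzchar(out4$classes))
  bounds <- binom_bounds(10000, 0.4)
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
})

test_that("trait simulation hits the degenerate heritability limits", {
  cfg <- sim_config(n_individuals = 200, n_chromosomes = 1,
                    variants_per_chromosome = 80,
                    trait_heritabilities = c(fat_pct = 0, prot_pct = 0,
                                             volume = 0),
                    seed = 13)
  pop <- simulate_population(cfg)
  ph <- simulate_traits(pop$genotypes, pop$catalog, cfg)
  truth <- attr(ph, "truth")
  expect_equal(stats::var(truth$fat_pct), 0)

  no_fx <- list(n_contemporary_groups = 2, cg_sd = 0, n_breeds = 2,
                breed_sd = 0, heterosis_coef = 0, inbreeding_coef = 0)
  cfg1 <- sim_config(n_individuals = 200, n_chromosomes = 1,
                     variants_per_chromosome = 80,
                     trait_heritabilities = c(fat_pct = 1, prot_pct = 1,
                                              volume = 1),
                     yield_noise_cv = 0, fixed_effect_spec = no_fx, seed = 13)
  pop1 <- simulate_population(cfg1)
  ph1 <- simulate_traits(pop1$genotypes, pop1$catalog, cfg1)
  t1 <- attr(ph1, "truth")
  expect_equal(ph1$fat_pct, cfg1$trait_means[["fat_pct"]] + t1$fat_pct,
               tolerance = 1e-12)
  expect_equal(ph1$fat_yield, ph1$fat_pct * ph1$volume, tolerance = 1e-12)
})

test_that("realized genetic signal matches the target heritability at n = 2000", {
  cfg <- sim_config(n_individuals = 2000, n_chromosomes = 2,
                    variants_per_chromosome = 150,
                    trait_heritabilities = c(fat_pct = 0.5, prot_pct = 0.5,
                                             volume = 0.35),
                    seed = 17)
  pop <- simulate_population(cfg)
  ph <- simulate_traits(pop$genotypes, pop$catalog, cfg)
  truth <- attr(ph, "truth")
  fx <- attr(ph, "fixed_part")
  biological <- ph$fat_pct - fx$fat_pct
  slope <- stats::coef(stats::lm(biological ~ truth$fat_pct))[2]
  expect_gte(slope, 0.9); expect_lte(slope, 1.1)
  realized_h2 <- stats::var(truth$fat_pct) / stats::var(biological)
  expect_lt(abs(realized_h2 - 0.5), 0.1)
})

test_that("yield traits carry a larger non-genetic variance share than percents", {
  cfg <- sim_config(n_individuals = 2000, n_chromosomes = 2,
                    variants_per_chromosome = 150, seed = 19)
  pop <- simulate_population(cfg)
  ph <- simulate_traits(pop$genotypes, pop$catalog, cfg)
  truth <- attr(ph, "truth")
  for (pt in cfg$percent_trait_names) {
    yt <- sub("_pct$", "_yield", pt)
    share_pct <- stats::cor(ph[[pt]], truth[[pt]])^2
    share_yield <- stats::cor(ph[[yt]], truth[[yt]])^2
    expect_lt(share_yield, share_pct)
  }
})

two_variant_genotypes <- function(n, d1, d2) {
  G <- cbind(v1 = d1, v2 = d2)
  rownames(G) <- sprintf("i%04d", seq_len(n))
  catalog <- data.frame(variant_id = c("v1", "v2"), chrom = 1L,
                        pos = c(1000L, 2000L), ref = "A", alt = "C",
                        n_alleles = 2L, maf = unname(column_maf(G)),
                        classes = "", stringsAsFactors = FALSE)
  list(G = G, catalog = catalog)
}

test_that("allelic counts reflect the configured skew in heterozygous carriers", {
  n <- 200
  tv <- two_variant_genotypes(n, rep(1L, n), rep(1L, n))
  base <- sim_config(n_ase_features = 1, ase_depth = 100,
                     prop_active_features = 1, seed = 23)

  base$ase_effect <- 0.2  # p = 0.7 for every carrier
  ac <- simulate_allelic_counts(tv$G, tv$catalog, base)
  expect_equal(nrow(ac), n)  # all heterozygous at the transcribed marker
  frac <- mean(ac$maternal_count / (ac$maternal_count + ac$paternal_count))
  expect_gte(frac, 0.66); expect_lte(frac, 0.74)

  base$ase_effect <- 0
  ac0 <- simulate_allelic_counts(tv$G, tv$catalog, base)
  pooled <- sum(ac0$maternal_count) / sum(ac0$maternal_count + ac0$paternal_count)
  b <- binom_bounds(n * 100, 0.5)
  expect_gte(pooled, b[1]); expect_lte(pooled, b[2])

  base$ase_effect <- 0.5  # p = 1: all reads maternal
  ac1 <- simulate_allelic_counts(tv$G, tv$catalog, base)
  expect_true(all(ac1$paternal_count == 0))
})

test_that("splice counts follow a logit dose-response in regulatory dosage", {
  n <- 371
  set.seed(31)
  d <- rbinom(n, 2L, 0.4)
  tv <- two_variant_genotypes(n, d, d)
  cfg <- sim_config(n_splice_features = 1, splice_depth = 200,
                    splice_base_logit = 0.5, splice_logit_effect = 0.5,
                    prop_active_features = 1, seed = 37)
  sc <- simulate_splice_counts(tv$G, tv$catalog, cfg)
  reg <- attr(sc, "features")$regulatory_variant[1]
  dos <- tv$G[sc$individual_id, reg]
  lg <- qlogis((sc$spliced_count + 0.5) /
                 (sc$spliced_count + sc$unspliced_count + 1))
  slope <- stats::coef(stats::lm(lg ~ dos))[2]
  expect_gte(slope, 0.4); expect_lte(slope, 0.6)

  cfg0 <- cfg; cfg0$prop_active_features <- 0; cfg0$seed <- 41
  sc0 <- simulate_splice_counts(tv$G, tv$catalog, cfg0)
  lg0 <- qlogis((sc0$spliced_count + 0.5) /
                  (sc0$spliced_count + sc0$unspliced_count + 1))
  d0 <- tv$G[sc0$individual_id, attr(sc0, "features")$regulatory_variant[1]]
  expect_lt(abs(stats::cor(lg0, d0)), 2.58 / sqrt(n))

  cfg1 <- cfg; cfg1$splice_base_logit <- 0; cfg1$splice_logit_effect <- 40
  sc1 <- simulate_splice_counts(tv$G, tv$catalog, cfg1)
  hom <- tv$G[sc1$individual_id, attr(sc1, "features")$regulatory_variant[1]] == 2
  expect_true(all(sc1$unspliced_count[hom] == 0))
})
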