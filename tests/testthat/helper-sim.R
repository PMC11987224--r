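# Shared fixtures, built in code.

# two-sided 99% binomial bounds on a proportion
binom_bounds <- function(n, p, conf = 0.99) {
  a <- (1 - conf) / 2
  stats::qbinom(c(a, 1 - a), n, p) / n
}

# independent-variant dosage matrix with a catalog (no LD), for statistic
# calibration tests where binomial error bounds assume independence
independent_genotypes <- function(n, m, maf_range = c(0.1, 0.5), seed = 1,
                                  chrom = 1L) {
  set.seed(seed)
  p <- runif(m, maf_range[1], maf_range[2])
  G <- vapply(p, function(pp) rbinom(n, 2L, pp), numeric(n))
  dimnames(G) <- list(sprintf("i%05d", seq_len(n)), sprintf("v%05d", seq_len(m)))
  catalog <- data.frame(variant_id = colnames(G),
                        chrom = chrom,
                        pos = seq_len(m) * 1000L,
                        ref = "A", alt = "C", n_alleles = 2L,
                        maf = unname(column_maf(G)), classes = "",
                        stringsAsFactors = FALSE)
  list(genotypes = G, catalog = catalog)
}

# small cached LD-structured population shared across tests
.pop_cache <- new.env(parent = emptyenv())
shared_pop <- function() {
  if (is.null(.pop_cache$pop)) {
    cfg <- sim_config(n_individuals = 600, n_chromosomes = 3,
                      variants_per_chromosome = 200, seed = 5)
    pop <- simulate_population(cfg)
    pop$catalog <- assign_functional_classes(pop$catalog, cfg)
    pop$config <- cfg
    .pop_cache$pop <- pop
  }
  .pop_cache$pop
}

# brute-force transitive closure over an r^2 adjacency matrix (test oracle
# for LD block assignment, independent of the union-find implementation)
closure_blocks <- function(G, threshold) {
  m <- ncol(G)
  A <- (stats::cor(G)^2 >= threshold)
  diag(A) <- TRUE
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  comp <- integer(m)
  cid <- 0L
  for (j in seq_len(m)) {
    if (comp[j] == 0L) {
      cid <- cid + 1L
      comp[A[j, ]] <- cid
    }
  }
  comp
}
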