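#' Functional annotation classes recognised by the simulator
#'
#' Variant classes mirror the functional-variant discovery streams of a
#' dairy-cattle functional genomics programme: production-trait GWAS tags,
#' RNA-seq derived molecular QTL (exon expression, allele-specific
#' expression, intron expression, splicing efficiency), histone ChIP-seq
#' and allele-specific binding QTL, chromatin accessibility QTL, and
#' predicted-deleterious coding variants.
#'
#' @export
FUNCTIONAL_CLASSES <- c("GWAS", "eeQTL", "aseQTL", "ieQTL", "seQTL",
                        "asbQTL", "ChIPseqQTL", "ATACQTL", "coding")

# Gene-expression QTL classes used for block-representative prioritisation.
EXPRESSION_CLASSES <- c("eeQTL", "aseQTL", "ieQTL", "seQTL")

#' Simulation configuration
#'
#' Defines the synthetic population: genome layout, haplotype-pool LD
#' structure, functional-class annotation rates, trait architecture
#' (heritabilities, causal-variant counts, class enrichment of causals),
#' fixed-effect structure, and molecular count data settings.
#'
#' Percent traits and the volume trait are simulated as primary traits with
#' additive genetic values; yield traits are formed downstream as
#' percent x volume with multiplicative measurement noise, so yields carry
#' compounded error relative to their parent percent trait.
#'
#' @param n_individuals number of diploid individuals.
#' @param n_chromosomes number of chromosomes.
#' @param variants_per_chromosome number of biallelic variants per chromosome
#'   (must be >= 2).
#' @param chromosome_length_bp chromosome length in base pairs.
#' @param haplotype_pool_size number of founder haplotypes per chromosome from
#'   which individuals are drawn.
#' @param n_base_haplotypes number of independent base haplotypes; the rest of
#'   the pool is built as gene-conversion-style mosaics of two base
#'   haplotypes, which is what creates block-wise LD.
#' @param mosaic_segments expected number of mosaic segments per pool
#'   haplotype.
#' @param recombination_rate expected crossovers per chromosome per meiosis
#'   (Poisson); 0 transmits pool haplotypes intact.
#' @param maf_shape shape parameter of the symmetric Beta distribution from
#'   which target allele frequencies are drawn; values < 1 give the
#'   U-shaped spectrum typical of sequence variants.
#' @param class_proportions named numeric vector, fraction of variants whose
#'   primary annotation is each functional class; must sum to <= 1, the
#'   remainder being unannotated.
#' @param multi_label_rate scale of the probability that an annotated variant
#'   additionally carries another class label.
#' @param causal_enrichment named numeric vector of relative odds that a
#'   variant carrying a class label is causal for a trait (unannotated
#'   variants have odds 1); odds multiply across labels.
#' @param n_causal_per_trait number of causal variants per primary trait.
#' @param trait_heritabilities named vector of narrow-sense h2 in `[0, 1]`
#'   for the primary traits.
#' @param trait_means named vector of trait means (percent units for percent
#'   traits, litres for volume); primary traits have unit biological
#'   (genetic + residual) variance around these means.
#' @param volume_trait_name,percent_trait_names trait labels.
#' @param yield_noise_cv coefficient of variation of the multiplicative
#'   lognormal measurement noise applied when forming yield traits.
#' @param fixed_effect_spec list with elements `n_contemporary_groups`,
#'   `cg_sd`, `n_breeds`, `breed_sd`, `heterosis_coef`, `inbreeding_coef`.
#' @param n_ase_features,ase_depth,ase_effect allele-specific count data:
#'   number of features, total read depth per informative individual, and the
#'   shift of the maternal read fraction away from 0.5 in heterozygous
#'   carriers of an active regulatory variant.
#' @param n_splice_features,splice_depth,splice_base_logit,splice_logit_effect
#'   splice-junction count data: number of junctions, read depth, baseline
#'   logit of the spliced proportion, and the additive logit shift per alt
#'   allele at an active regulatory variant.
#' @param prop_active_features fraction of molecular features whose linked
#'   regulatory variant has a nonzero effect.
#' @param seed integer root seed for all generators.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals = 1000,
                       n_chromosomes = 3,
                       variants_per_chromosome = 400,
                       chromosome_length_bp = 5e7,
                       haplotype_pool_size = 30,
                       n_base_haplotypes = 8,
                       mosaic_segments = 5,
                       recombination_rate = 1,
                       maf_shape = 0.4,
                       class_proportions = c(GWAS = 0.02, eeQTL = 0.06,
                                             aseQTL = 0.05, ieQTL = 0.02,
                                             seQTL = 0.01, asbQTL = 0.05,
                                             ChIPseqQTL = 0.05, ATACQTL = 0.10,
                                             coding = 0.03),
                       multi_label_rate = 0.25,
                       causal_enrichment = c(GWAS = 8, eeQTL = 6, aseQTL = 4,
                                             ieQTL = 4, seQTL = 4, asbQTL = 3,
                                             ChIPseqQTL = 3, ATACQTL = 2,
                                             coding = 5),
                       n_causal_per_trait = 30,
                       trait_heritabilities = c(fat_pct = 0.55,
                                                prot_pct = 0.50,
                                                volume = 0.35),
                       trait_means = c(fat_pct = 5, prot_pct = 4,
                                       volume = 20),
                       volume_trait_name = "volume",
                       percent_trait_names = c("fat_pct", "prot_pct"),
                       yield_noise_cv = 0.05,
                       fixed_effect_spec = list(n_contemporary_groups = 25,
                                                cg_sd = 0.5,
                                                n_breeds = 3,
                                                breed_sd = 0.3,
                                                heterosis_coef = 0.3,
                                                inbreeding_coef = -0.5),
                       n_ase_features = 100,
                       ase_depth = 80,
                       ase_effect = 0.15,
                       n_splice_features = 100,
                       splice_depth = 120,
                       splice_base_logit = 1.5,
                       splice_logit_effect = 0.5,
                       prop_active_features = 0.5,
                       seed = 1) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  .assert_count(cfg$n_individuals, "n_individuals")
  .assert_count(cfg$n_chromosomes, "n_chromosomes")
  .assert_count(cfg$variants_per_chromosome, "variants_per_chromosome", min = 2L)
  .assert_count(cfg$chromosome_length_bp, "chromosome_length_bp")
  .assert_count(cfg$haplotype_pool_size, "haplotype_pool_size")
  if (cfg$recombination_rate < 0)
    stop("recombination_rate must be >= 0", call. = FALSE)
  cp <- cfg$class_proportions
  if (length(cp)) {
    unknown <- setdiff(names(cp), FUNCTIONAL_CLASSES)
    if (length(unknown))
      stop("unknown functional class in class_proportions: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (any(cp < 0) || sum(cp) > 1 + 1e-12)
      stop("class_proportions must be non-negative and sum to <= 1",
           call. = FALSE)
  }
  if (length(cfg$causal_enrichment)) {
    unknown <- setdiff(names(cfg$causal_enrichment), FUNCTIONAL_CLASSES)
    if (length(unknown))
      stop("unknown functional class in causal_enrichment: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  h2 <- cfg$trait_heritabilities
  if (any(h2 < 0 | h2 > 1))
    stop("all heritabilities must lie in [0, 1]", call. = FALSE)
  need <- c(cfg$percent_trait_names, cfg$volume_trait_name)
  if (!all(need %in% names(h2)))
    stop("trait_heritabilities must name every percent trait and the volume trait",
         call. = FALSE)
  if (cfg$yield_noise_cv < 0) stop("yield_noise_cv must be >= 0", call. = FALSE)
  invisible(cfg)
}

# Build the founder haplotype pool for one chromosome:
# independent base haplotypes drawn at target allele frequencies, padded
# with mosaics that copy alternating segments from two random base
# haplotypes (gene-conversion-style), which induces block LD.
.build_pool <- function(m, pool_size, n_base, target_freq, mosaic_segments) {
  n_base <- min(n_base, pool_size)
  base <- matrix(rbinom(n_base * m, 1L, rep(target_freq, each = n_base)),
                 nrow = n_base, ncol = m)
  if (pool_size <= n_base) return(base[seq_len(pool_size), , drop = FALSE])
  extra <- pool_size - n_base
  switch_prob <- min(1, mosaic_segments / m)
  mos <- matrix(0L, nrow = extra, ncol = m)
  for (i in seq_len(extra)) {
    src <- sample.int(n_base, 2L)
    cur <- sample(c(1L, 2L), 1L)
    switches <- runif(m) < switch_prob
    state <- cur
    track <- integer(m)
    for (j in seq_len(m)) {
      if (switches[j]) state <- 3L - state
      track[j] <- state
    }
    mos[i, ] <- ifelse(track == 1L, base[src[1L], ], base[src[2L], ])
  }
  rbind(base, mos)
}

# One gamete: recombinant mosaic of two pool haplotypes with a Poisson
# number of crossovers placed uniformly between adjacent variants.
.make_gamete <- function(pool, recombination_rate) {
  m <- ncol(pool)
  idx <- sample.int(nrow(pool), 2L, replace = TRUE)
  if (recombination_rate == 0) return(pool[idx[1L], ])
  n_xo <- rpois(1L, recombination_rate)
  if (n_xo == 0L) return(pool[idx[1L], ])
  cuts <- sort(sample.int(m - 1L, min(n_xo, m - 1L)))
  seg <- cumsum(c(0L, as.integer(seq_len(m - 1L) %in% cuts))) %% 2L
  ifelse(seg == 0L, pool[idx[1L], ], pool[idx[2L], ])
}

#' Simulate a diploid population with block-wise LD
#'
#' Builds, per chromosome, a founder haplotype pool (random base haplotypes
#' plus gene-conversion-style mosaics) and forms each individual as a pair
#' of recombinant gametes drawn from the pool.  This haplotype-mosaic scheme
#' is a deliberately lightweight stand-in for imputed sequence data: it
#' reproduces block LD and a U-shaped MAF spectrum without coalescent
#' machinery.
#'
#' @param config a [sim_config()].
#' @param base_haplotypes optional list (one 0/1 matrix per chromosome,
#'   haplotypes in rows) overriding the generated pool; useful for
#'   constructing extreme LD configurations.
#' @return list with `genotypes` (individuals x variants dosage matrix with
#'   dimnames) and `catalog` (variant catalog `data.frame` with columns
#'   `variant_id`, `chrom`, `pos`, `ref`, `alt`, `n_alleles`, `maf`,
#'   `classes`).
#' @export
simulate_population <- function(config, base_haplotypes = NULL) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "population"))
  n <- config$n_individuals
  m <- config$variants_per_chromosome
  geno <- vector("list", config$n_chromosomes)
  cats <- vector("list", config$n_chromosomes)
  bases <- c("A", "C", "G", "T")
  for (chrom in seq_len(config$n_chromosomes)) {
    pos <- sort(sample.int(config$chromosome_length_bp, m))
    f <- rbeta(m, config$maf_shape, config$maf_shape)
    f <- pmin(pmax(f, 0.02), 0.98)
    if (is.null(base_haplotypes)) {
      pool <- .build_pool(m, config$haplotype_pool_size,
                          config$n_base_haplotypes, f,
                          config$mosaic_segments)
    } else {
      pool <- base_haplotypes[[chrom]]
      storage.mode(pool) <- "integer"
      if (ncol(pool) != m)
        stop("base_haplotypes[[", chrom, "]] must have ", m, " columns")
    }
    G <- matrix(0L, nrow = n, ncol = m)
    for (i in seq_len(n)) {
      G[i, ] <- .make_gamete(pool, config$recombination_rate) +
        .make_gamete(pool, config$recombination_rate)
    }
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    cats[[chrom]] <- data.frame(
      variant_id = sprintf("c%d_p%d", chrom, pos),
      chrom = chrom,
      pos = pos,
      ref = ref,
      alt = unname(alt),
      n_alleles = 2L,
      stringsAsFactors = FALSE
    )
    geno[[chrom]] <- G
  }
  catalog <- do.call(rbind, cats)
  rownames(catalog) <- NULL
  G <- do.call(cbind, geno)
  dimnames(G) <- list(sprintf("ind%05d", seq_len(n)), catalog$variant_id)
  catalog$maf <- unname(column_maf(G))
  catalog$classes <- ""
  list(genotypes = G, catalog = catalog)
}

#' Introduce missing genotype calls
#'
#' Sets a random fraction of dosage entries (or whole variants' worth of
#' entries, via per-variant rates) to `NA`, emulating imperfect call rates.
#'
#' @param genotypes dosage matrix.
#' @param rate overall probability that a call is missing, or a vector of
#'   per-variant rates (recycled over columns).
#' @param seed integer seed.
#' @return the matrix with `NA`s inserted.
#' @export
add_missingness <- function(genotypes, rate = 0.02, seed = 1) {
  set.seed(derive_seed(seed, "missing"))
  n <- nrow(genotypes)
  rate <- rep_len(rate, ncol(genotypes))
  for (j in seq_len(ncol(genotypes))) {
    if (rate[j] <= 0) next
    miss <- runif(n) < rate[j]
    genotypes[miss, j] <- NA
  }
  genotypes
}

#' Assign functional-class annotations to catalog variants
#'
#' Each variant receives at most one primary class by a multinomial draw
#' over `class_proportions` (remainder unannotated); annotated variants may
#' then pick up additional labels, reflecting that real tag variants often
#' carry signals in several discovery streams.
#'
#' @param catalog variant catalog with `maf` filled.
#' @param config a [sim_config()].
#' @return the catalog with the `classes` column populated
#'   (semicolon-delimited labels, `""` = unannotated).
#' @export
assign_functional_classes <- function(catalog, config) {
  validate_sim_config(config)
  if (any(is.na(catalog$maf))) stop("catalog maf must be filled", call. = FALSE)
  set.seed(derive_seed(config$seed, "classes"))
  cp <- config$class_proportions
  m <- nrow(catalog)
  classes <- character(m)
  if (length(cp) && sum(cp) > 0) {
    labels <- names(cp)
    cuts <- cumsum(cp)
    u <- runif(m)
    primary <- rep(NA_character_, m)
    for (k in rev(seq_along(labels))) primary[u < cuts[k]] <- labels[k]
    extra_p <- config$multi_label_rate * cp / sum(cp)
    for (i in which(!is.na(primary))) {
      lab <- primary[i]
      others <- labels[labels != lab & runif(length(labels)) < extra_p]
      classes[i] <- paste(sort(unique(c(lab, others))), collapse = ";")
    }
  }
  catalog$classes <- classes
  catalog
}

# Split a semicolon-delimited classes string into a character vector.
split_classes <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

# Causal-sampling weight: product of class enrichment odds over carried
# labels; unannotated variants have weight 1.
causal_weights <- function(catalog, enrichment) {
  cls <- split_classes(catalog$classes)
  vapply(cls, function(v) {
    if (!length(v)) return(1)
    prod(vapply(v, function(l) enrichment[[l]] %||% 1, 1))
  }, 1)
}

#' Simulate raw phenotypes with fixed effects and additive genetics
#'
#' For each primary trait (the percent traits and the volume trait) causal
#' variants are drawn with class-enrichment odds, effects are Normal and
#' rescaled so the additive genetic variance hits the target h2 on a unit
#' biological-variance scale, and the raw phenotype is
#' `mean + fixed effects + genetic value + Normal residual`.  Yield traits
#' are then formed as percent x volume with multiplicative lognormal noise
#' of coefficient of variation `yield_noise_cv`, so yields carry compounded
#' measurement error, mirroring how fat and protein yields are derived from
#' mid-infrared percent predictions and metered milk volumes.
#'
#' @param genotypes dosage matrix from [simulate_population()].
#' @param catalog annotated variant catalog.
#' @param config a [sim_config()].
#' @return a `data.frame` with columns `individual_id`, fixed-effect factors
#'   and covariates (`contemporary_group`, `breed`, `heterosis`,
#'   `inbreeding`), and one column per trait.  Attributes: `truth` (per
#'   individual true genetic value per trait) and `causal` (per primary
#'   trait, a `data.frame` of causal variant ids and effects).
#' @export
simulate_traits <- function(genotypes, catalog, config) {
  validate_sim_config(config)
  stopifnot(identical(colnames(genotypes), catalog$variant_id))
  set.seed(derive_seed(config$seed, "traits"))
  n <- nrow(genotypes)
  fes <- config$fixed_effect_spec
  cg <- factor(sample.int(fes$n_contemporary_groups, n, replace = TRUE))
  breed <- factor(sample(LETTERS[seq_len(fes$n_breeds)], n, replace = TRUE))
  heterosis <- runif(n)
  inbreeding <- runif(n, 0, 0.2)

  primary <- c(config$percent_trait_names, config$volume_trait_name)
  w <- causal_weights(catalog, config$causal_enrichment)
  pheno <- data.frame(individual_id = rownames(genotypes),
                      contemporary_group = cg, breed = breed,
                      heterosis = heterosis, inbreeding = inbreeding,
                      stringsAsFactors = FALSE)
  truth <- data.frame(individual_id = rownames(genotypes),
                      stringsAsFactors = FALSE)
  causal <- list()
  xb <- list()
  for (tr in primary) {
    h2 <- config$trait_heritabilities[[tr]]
    nc <- min(config$n_causal_per_trait, nrow(catalog))
    idx <- sample.int(nrow(catalog), nc, prob = w)
    eff <- rnorm(nc)
    g <- as.vector(genotypes[, idx, drop = FALSE] %*% eff)
    if (h2 > 0 && stats::var(g) > 0) {
      sc <- sqrt(h2 / stats::var(g))
      eff <- eff * sc
      g <- g * sc
    } else {
      eff <- rep(0, nc)
      g <- rep(0, n)
    }
    e <- rnorm(n, sd = sqrt(1 - h2))
    cg_eff <- rnorm(nlevels(cg), sd = fes$cg_sd)
    breed_eff <- rnorm(nlevels(breed), sd = fes$breed_sd)
    fx <- cg_eff[as.integer(cg)] + breed_eff[as.integer(breed)] +
      fes$heterosis_coef * heterosis + fes$inbreeding_coef * inbreeding
    pheno[[tr]] <- config$trait_means[[tr]] + fx + g + e
    truth[[tr]] <- g
    xb[[tr]] <- fx
    causal[[tr]] <- data.frame(variant_id = catalog$variant_id[idx],
                               effect = eff, stringsAsFactors = FALSE)
  }
  vol <- config$volume_trait_name
  sigma_ln <- sqrt(log(1 + config$yield_noise_cv^2))
  for (pt in config$percent_trait_names) {
    yt <- if (grepl("_pct$", pt)) sub("_pct$", "_yield", pt)
          else paste0(pt, "_yield")
    noise <- exp(rnorm(n, -sigma_ln^2 / 2, sigma_ln))
    pheno[[yt]] <- pheno[[pt]] * pheno[[vol]] * noise
    # genetic part of the product, ignoring fixed effects and noise
    truth[[yt]] <- (config$trait_means[[pt]] + truth[[pt]]) *
      (config$trait_means[[vol]] + truth[[vol]]) -
      config$trait_means[[pt]] * config$trait_means[[vol]]
  }
  attr(pheno, "truth") <- truth
  attr(pheno, "causal") <- causal
  attr(pheno, "fixed_part") <- xb
  pheno
}

# Pick regulatory/transcribed variant pairs for molecular features.
.pick_features <- function(catalog, n_features, maf_min = 0.1) {
  elig <- which(catalog$maf >= maf_min)
  if (length(elig) < 2L) stop("too few common variants for features")
  reg <- sample(elig, n_features, replace = n_features > length(elig))
  trans <- vapply(reg, function(i) {
    same <- which(catalog$chrom == catalog$chrom[i] & seq_len(nrow(catalog)) != i &
                    catalog$maf >= maf_min)
    if (!length(same)) return(NA_integer_)
    same[which.min(abs(catalog$pos[same] - catalog$pos[i]))]
  }, 1L)
  keep <- !is.na(trans)
  data.frame(feature_id = sprintf("feat%04d", seq_len(n_features))[keep],
             chrom = catalog$chrom[reg[keep]],
             pos = catalog$pos[reg[keep]],
             regulatory_variant = catalog$variant_id[reg[keep]],
             transcribed_variant = catalog$variant_id[trans[keep]],
             stringsAsFactors = FALSE)
}

#' Simulate allele-specific read counts
#'
#' Each feature is linked to one regulatory variant and one nearby
#' transcribed marker.  Rows exist only for individuals heterozygous at the
#' transcribed marker (the requirement for distinguishing parental reads).
#' Heterozygous carriers of an active regulatory variant have their maternal
#' read fraction shifted to `0.5 + effect` (parental phase is known in
#' simulation and the alt allele sits on the maternal haplotype by
#' convention, as in an F2 cross with breed-differentiated founders);
#' homozygotes are balanced at 0.5.
#'
#' @param genotypes dosage matrix.
#' @param catalog variant catalog.
#' @param config a [sim_config()]; uses `n_ase_features`, `ase_depth`,
#'   `ase_effect`, `prop_active_features`.
#' @return `data.frame` with `individual_id`, `feature_id`, `maternal_count`,
#'   `paternal_count`; attribute `features` holds per-feature metadata
#'   including the linked regulatory variant and its true effect.
#' @export
simulate_allelic_counts <- function(genotypes, catalog, config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "ase"))
  feats <- .pick_features(catalog, config$n_ase_features)
  feats$effect <- ifelse(runif(nrow(feats)) < config$prop_active_features,
                         config$ase_effect, 0)
  rows <- vector("list", nrow(feats))
  for (k in seq_len(nrow(feats))) {
    d_t <- genotypes[, feats$transcribed_variant[k]]
    d_r <- genotypes[, feats$regulatory_variant[k]]
    het_t <- which(!is.na(d_t) & d_t == 1)
    if (!length(het_t)) next
    p <- ifelse(!is.na(d_r[het_t]) & d_r[het_t] == 1,
                0.5 + feats$effect[k], 0.5)
    p <- pmin(pmax(p, 0), 1)
    maternal <- rbinom(length(het_t), config$ase_depth, p)
    rows[[k]] <- data.frame(individual_id = rownames(genotypes)[het_t],
                            feature_id = feats$feature_id[k],
                            maternal_count = maternal,
                            paternal_count = config$ase_depth - maternal,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "features") <- feats
  out
}

#' Simulate spliced/unspliced junction read counts
#'
#' Every individual contributes one row per splice junction; the spliced
#' proportion follows a logistic dose-response in the alt-allele count of
#' the junction's regulatory variant:
#' `p = plogis(base_logit + effect * dosage)`.
#'
#' @inheritParams simulate_allelic_counts
#' @return `data.frame` with `individual_id`, `feature_id`, `spliced_count`,
#'   `unspliced_count`; attribute `features` as in
#'   [simulate_allelic_counts()].
#' @export
simulate_splice_counts <- function(genotypes, catalog, config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "splice"))
  feats <- .pick_features(catalog, config$n_splice_features)
  feats$effect <- ifelse(runif(nrow(feats)) < config$prop_active_features,
                         config$splice_logit_effect, 0)
  n <- nrow(genotypes)
  rows <- vector("list", nrow(feats))
  for (k in seq_len(nrow(feats))) {
    d <- genotypes[, feats$regulatory_variant[k]]
    d[is.na(d)] <- mean(d, na.rm = TRUE)
    p <- plogis(config$splice_base_logit + feats$effect[k] * d)
    total <- rpois(n, config$splice_depth)
    spliced <- rbinom(n, total, p)
    keep <- total > 0
    rows[[k]] <- data.frame(individual_id = rownames(genotypes)[keep],
                            feature_id = feats$feature_id[k],
                            spliced_count = spliced[keep],
                            unspliced_count = (total - spliced)[keep],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "features") <- feats
  out
}
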