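#' Simulation configuration
#'
#' Bundles the parameters of the synthetic genotype generator and the
#' phenotype simulator. Defaults describe a desk-scale GWAS panel:
#' 1307 samples, 5000 variants on one synthetic chromosome, minor
#' allele frequencies uniform on \[0.05, 0.5\], mild local linkage
#' disequilibrium (adjacent-variant latent correlation 0.2), 20 causal
#' variants positioned by a Gaussian positional law, heritability 0.7.
#'
#' @param n_samples number of samples.
#' @param n_variants number of variants.
#' @param maf_range allele-frequency range `(low, high)`, within
#'   (0, 0.5].
#' @param ld_rho latent correlation between adjacent variants in
#'   \[0, 1).
#' @param distribution positional law for causal variants: `"gaussian"`
#'   (indices drawn around a random anchor with Gaussian weights) or
#'   `"gamma"` (anchor plus cumulative Gamma-distributed gaps).
#' @param n_causal number of causal variants.
#' @param h2 heritability: fraction of phenotypic variance explained by
#'   the causal genetic component, in \[0, 1\].
#' @param position_spread scale of the positional law, as a fraction of
#'   the panel length.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 1307L, n_variants = 5000L,
                              maf_range = c(0.05, 0.5), ld_rho = 0.2,
                              distribution = c("gaussian", "gamma"),
                              n_causal = 20L, h2 = 0.7,
                              position_spread = 0.02, seed = NULL) {
  distribution <- match.arg(distribution)
  stopifnot(n_causal <= n_variants, h2 >= 0, h2 <= 1,
            maf_range[1] > 0, maf_range[1] <= maf_range[2],
            maf_range[2] <= 0.5, ld_rho >= 0, ld_rho < 1,
            position_spread > 0)
  structure(list(n_samples = as.integer(n_samples),
                 n_variants = as.integer(n_variants),
                 maf_range = maf_range, ld_rho = ld_rho,
                 distribution = distribution,
                 n_causal = as.integer(n_causal), h2 = h2,
                 position_spread = position_spread, seed = seed),
            class = "simulation_config")
}

#' Named simulation presets
#'
#' `scenario_I`: Gaussian positional law, 20 causal variants,
#' heritability 0.7. `scalability`: the same setting with the gamma
#' positional law. Both default to 1307 samples by 5000 variants;
#' override any field via `...`.
#'
#' @param name preset name.
#' @param ... overrides passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
scenario_preset <- function(name, ...) {
  presets <- list(
    scenario_I = list(distribution = "gaussian", n_causal = 20L, h2 = 0.7),
    scalability = list(distribution = "gamma", n_causal = 20L, h2 = 0.7))
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  args <- utils::modifyList(presets[[name]], list(...))
  do.call(simulation_config, args)
}

#' Simulate a genotype dosage matrix
#'
#' Each variant gets an allele frequency drawn uniformly from
#' `maf_range`. Haplotypes come from a stationary AR(1) latent-Gaussian
#' process along the chromosome with adjacent-variant correlation
#' `ld_rho`, thresholded at the frequency quantile; the dosage is the
#' sum of two independent haplotypes. Variants are placed on one
#' synthetic chromosome at 1 kb spacing.
#'
#' @param cfg a [simulation_config()].
#' @param seed overrides `cfg$seed` when given.
#' @return A [genotype_matrix] with attribute `"maf"` (the drawn
#'   frequencies).
#' @export
simulate_genotypes <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_samples
  m <- cfg$n_variants
  maf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  thr <- stats::qnorm(maf)
  rho <- cfg$ld_rho
  haplotype <- function() {
    Z <- matrix(stats::rnorm(n * m), n, m)
    if (rho > 0 && m > 1) {
      s <- sqrt(1 - rho^2)
      for (j in 2:m) Z[, j] <- rho * Z[, j - 1] + s * Z[, j]
    }
    Z < rep(thr, each = n)
  }
  dos <- haplotype() + haplotype()
  storage.mode(dos) <- "double"
  g <- genotype_matrix(dos,
                       sample_ids = paste0("s", seq_len(n)),
                       variants = data.frame(id = paste0("v", seq_len(m)),
                                             chromosome = "1",
                                             position = 1000L * seq_len(m),
                                             stringsAsFactors = FALSE))
  attr(g, "maf") <- maf
  g
}

#' Draw causal variant indices by position
#'
#' `gaussian` mode: a uniform random anchor index is drawn and causal
#' indices are sampled without replacement with weights proportional to
#' a Normal density centred at the anchor with standard deviation
#' `position_spread * n_variants` (clustered causal loci). `gamma`
#' mode: successive gaps from the anchor follow
#' `Gamma(shape = 2, scale = position_spread * n_variants / n_causal)`,
#' wrapped around the panel and deduplicated to the nearest unused
#' index.
#'
#' @param cfg a [simulation_config()].
#' @param seed overrides `cfg$seed` when given.
#' @return Integer vector of `n_causal` distinct variant indices.
#' @export
choose_causal_positions <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  m <- cfg$n_variants
  k <- cfg$n_causal
  if (k == m) return(seq_len(m))
  if (cfg$distribution == "gaussian") {
    anchor <- stats::runif(1, 1, m)
    w <- stats::dnorm(seq_len(m), mean = anchor, sd = cfg$position_spread * m)
    w <- pmax(w, 1e-300)  # keep every index selectable for large k
    sort(sample.int(m, k, prob = w))
  } else {
    anchor <- sample.int(m, 1)
    gaps <- stats::rgamma(k, shape = 2, scale = cfg$position_spread * m / k)
    pos <- round(anchor + cumsum(gaps) - 1) %% m + 1
    taken <- logical(m)
    out <- integer(k)
    for (i in seq_len(k)) {
      p <- as.integer(pos[i])
      if (!taken[p]) {
        out[i] <- p
      } else {
        free <- which(!taken)
        # wrapped circular distance to the nearest unused index
        d <- pmin(abs(free - p), m - abs(free - p))
        out[i] <- free[which.min(d)]
      }
      taken[out[i]] <- TRUE
    }
    sort(out)
  }
}

#' Simulate a phenotype with known causal truth
#'
#' Effect sizes are drawn `Normal(0, 1)` per causal variant; the
#' genetic value is `g = Xc %*% beta` on centred dosages. For
#' `0 < h2 < 1`, Gaussian noise with variance
#' `var(g) * (1 - h2) / h2` is added so the genetic component explains
#' a fraction `h2` of the phenotypic variance (calibrated to the
#' realized `var(g)`). `h2 = 1` gives `y = g` exactly; `h2 = 0` gives
#' pure standard-normal noise (effects recorded but inert).
#'
#' @param g a [genotype_matrix] or numeric matrix.
#' @param causal integer vector of causal variant indices.
#' @param h2 heritability in \[0, 1\].
#' @param seed optional integer seed.
#' @return `list(phenotype = phenotype_vector, truth = simulation_truth)`
#'   where the truth holds `causal_indices`, `beta`, `genetic_values`,
#'   `h2`, and the realized `h2_realized = var(g)/var(y)`.
#' @export
simulate_phenotype <- function(g, causal, h2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- dosage_matrix(g)
  stopifnot(h2 >= 0, h2 <= 1, all(causal >= 1), all(causal <= ncol(X)))
  n <- nrow(X)
  beta <- stats::rnorm(length(causal))
  Xc <- scale(X[, causal, drop = FALSE], center = TRUE, scale = FALSE)
  gv <- as.numeric(Xc %*% beta)
  vg <- stats::var(gv)
  if (vg <= 0 && h2 > 0) {
    stop("causal set has zero genetic variance (monomorphic causal variants?)")
  }
  y <- if (h2 == 1) {
    gv
  } else if (h2 == 0) {
    stats::rnorm(n)
  } else {
    gv + stats::rnorm(n, sd = sqrt(vg * (1 - h2) / h2))
  }
  truth <- structure(list(causal_indices = as.integer(causal), beta = beta,
                          genetic_values = gv, h2 = h2,
                          h2_realized = if (stats::var(y) > 0) vg / stats::var(y) else NA_real_),
                     class = "simulation_truth")
  list(phenotype = phenotype_vector(y, "continuous"), truth = truth)
}

#' Simulate a complete GWAS dataset
#'
#' Convenience wrapper chaining [simulate_genotypes()],
#' [choose_causal_positions()], and [simulate_phenotype()] under one
#' seed.
#'
#' @param cfg a [simulation_config()].
#' @param seed overrides `cfg$seed` when given.
#' @return `list(genotypes =, phenotype =, truth =)`.
#' @export
simulate_gwas <- function(cfg, seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  g <- simulate_genotypes(cfg, seed = NULL)
  causal <- choose_causal_positions(cfg, seed = NULL)
  sim <- simulate_phenotype(g, causal, cfg$h2, seed = NULL)
  list(genotypes = g, phenotype = sim$phenotype, truth = sim$truth)
}
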