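#' Packaged marginal statistics of the study variables
#'
#' Per-variable maximum, minimum, mean and sample standard deviation for the
#' 16 environmental factors and 12 fruit-quality traits of the 99-orchard
#' survey. These drive the synthetic generator's truncated-normal marginals
#' and the default optimization bounds.
#'
#' @return Data frame with columns \code{code}, \code{mean}, \code{std},
#'   \code{min}, \code{max}.
#' @export
default_marginals <- function() {
  path <- system.file("extdata", "marginal_stats.csv", package = "navelopt",
                      mustWork = TRUE)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(m$min <= m$mean), all(m$mean <= m$max), all(m$std > 0))
  m
}

#' Default correlation structure of the environmental factors
#'
#' Identity except for a moderate (r = 0.4) exchangeable block among the ten
#' soil-nutrient variables (SOM, hydrolyzed N, total P, Olsen P, CEC,
#' available K/B/Zn, exchangeable Ca/Mg), mirroring the reported pattern of
#' highly significant positive correlations within that block. Only the
#' structure is emulated; the survey publishes no numeric correlation matrix.
#'
#' @param r within-block correlation (default 0.4).
#' @return 16x16 correlation matrix with factor codes as dimnames.
#' @export
default_factor_correlation <- function(r = 0.4) {
  fac <- factor_codes()
  R <- diag(length(fac))
  dimnames(R) <- list(fac, fac)
  block <- paste0("S", 3:12)
  R[block, block] <- r
  diag(R) <- 1
  R
}

#' Generator configuration
#'
#' @param n_samples number of orchards to simulate (study default 99).
#' @param seed integer seed; every stochastic draw is a deterministic
#'   function of it.
#' @param factor_correlation 16x16 positive-semidefinite correlation matrix
#'   for the Gaussian copula over the factors.
#' @param noise_sd per-trait residual standard deviation for the modeled
#'   traits: \code{NULL} (default) calibrates each trait's noise so the OLS F
#'   statistic at the study size n = 99 is near the packaged equation system's
#'   F value; a single number applies to all traits; a named vector sets
#'   traits individually.
#' @param equations generating \code{equation_system} (default: packaged).
#' @param marginals marginal statistics table (default packaged).
#' @return A list of class \code{generator_config}.
#' @export
generator_config <- function(n_samples = 99, seed = 1,
                             factor_correlation = default_factor_correlation(),
                             noise_sd = NULL,
                             equations = table4_equations(),
                             marginals = default_marginals()) {
  stopifnot(n_samples >= 1, is.matrix(factor_correlation),
            all(dim(factor_correlation) == 16))
  if (is.null(dimnames(factor_correlation)))
    dimnames(factor_correlation) <- list(factor_codes(), factor_codes())
  if (!isTRUE(all.equal(unname(diag(factor_correlation)),
                        rep(1, ncol(factor_correlation)))))
    stop("factor_correlation must have unit diagonal")
  ev <- eigen(factor_correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("factor_correlation is not positive semidefinite")
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 factor_correlation = factor_correlation, noise_sd = noise_sd,
                 equations = equations, marginals = marginals),
            class = "generator_config")
}

# internal: inverse-CDF draw from N(mean, sd) truncated to [lo, hi],
# given uniforms u in (0,1)
qtruncnorm <- function(u, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

#' Draw environmental factors from a Gaussian copula
#'
#' Each factor's marginal is a normal with the target mean and standard
#' deviation truncated to the target \code{[min, max]}; dependence comes from
#' a Gaussian copula with the configured correlation matrix. Deterministic
#' for a fixed seed.
#'
#' @param config a \code{generator_config}.
#' @param marginals marginal table covering all 16 factor codes (default:
#'   the config's).
#' @return An \code{orchard_dataset} with the 16 factor columns.
#' @export
sample_factors <- function(config, marginals = config$marginals) {
  fac <- factor_codes()
  m <- marginals[match(fac, marginals$code), ]
  if (anyNA(m$code)) stop("marginals must cover all 16 factor codes")
  if (any(m$min > m$max)) stop("inconsistent marginal: min > max")
  n <- config$n_samples
  R <- config$factor_correlation[fac, fac]
  L <- tryCatch(chol(R), error = function(e) {
    # PSD but rank-deficient: symmetric square root via eigendecomposition
    e2 <- eigen(R, symmetric = TRUE)
    t(e2$vectors %*% diag(sqrt(pmax(e2$values, 0))) %*% t(e2$vectors))
  })
  set.seed(config$seed)
  z <- matrix(stats::rnorm(n * length(fac)), nrow = n) %*% L
  u <- stats::pnorm(z)
  x <- matrix(NA_real_, nrow = n, ncol = length(fac),
              dimnames = list(NULL, fac))
  for (j in seq_along(fac))
    x[, j] <- qtruncnorm(u[, j], m$mean[j], m$std[j], m$min[j], m$max[j])
  orchard_dataset(x)
}

# internal: target R^2 implied by an F statistic with k regressors at size n
r2_from_f <- function(f, k, n) (f * k) / (f * k + n - k - 1)

# internal: resolve per-trait noise SD for the generating equations
resolve_noise_sd <- function(config, mu_by_trait) {
  traits <- names(mu_by_trait)
  out <- stats::setNames(numeric(length(traits)), traits)
  spec <- config$noise_sd
  for (tr in traits) {
    if (is.null(spec)) {
      eq <- config$equations$equations[[tr]]
      k <- length(eq$coefficients)
      r2 <- r2_from_f(eq$F, k, 99)
      s <- stats::sd(mu_by_trait[[tr]])
      out[tr] <- if (s == 0) 0 else s * sqrt((1 - r2) / r2)
    } else if (length(spec) == 1 && is.null(names(spec))) {
      out[tr] <- spec
    } else {
      if (!tr %in% names(spec)) stop("noise_sd has no entry for trait ", tr)
      out[tr] <- spec[[tr]]
    }
  }
  out
}

#' Generate quality traits from environmental factors
#'
#' Each modeled trait is its generating equation evaluated on the factors
#' plus independent homoscedastic Gaussian noise. TSS is generated as a pure
#' noise trait (truncated normal around its marginal), unlinked to the
#' factors. Seeded and reproducible: the trait stream uses the config seed
#' offset by one so factors and traits can be regenerated independently.
#'
#' @param factors an \code{orchard_dataset} holding the 16 factor columns.
#' @param config a \code{generator_config}.
#' @return An \code{orchard_dataset} with the factor columns plus the 12
#'   quality columns.
#' @export
generate_traits <- function(factors, config) {
  v <- factors$values
  n <- nrow(v)
  eqs <- config$equations$equations
  mu <- lapply(eqs, function(eq) {
    missing <- setdiff(names(eq$coefficients), colnames(v))
    if (length(missing) > 0)
      stop("equation for ", eq$trait, " references unknown code(s): ",
           paste(missing, collapse = ", "))
    drop(eq$intercept + v[, names(eq$coefficients), drop = FALSE] %*%
           eq$coefficients)
  })
  noise_sd <- resolve_noise_sd(config, mu)
  set.seed(config$seed + 1L)
  traits <- matrix(NA_real_, nrow = n, ncol = length(eqs) + 1L,
                   dimnames = list(NULL, c(names(eqs), "TSS")))
  for (tr in names(eqs))
    traits[, tr] <- mu[[tr]] + stats::rnorm(n, sd = noise_sd[tr])
  tss <- config$marginals[config$marginals$code == "TSS", ]
  traits[, "TSS"] <- qtruncnorm(stats::runif(n), tss$mean, tss$std,
                                tss$min, tss$max)
  orchard_dataset(cbind(v, traits), registry = factors$registry,
                  sample_ids = factors$sample_ids)
}

#' Simulate a complete study-like orchard dataset
#'
#' One call bundles the packaged marginals, factor correlation structure and
#' generating equation system: factors from the Gaussian copula, traits from
#' the equations plus calibrated noise.
#'
#' @param n number of orchards (study size: 99).
#' @param seed integer seed.
#' @param noise_sd optional noise override, as in [generator_config()].
#' @return An \code{orchard_dataset} with all 28 columns.
#' @examples
#' d <- make_study_like_dataset(n = 99, seed = 42)
#' summary(d$values[, "Y1"])
#' @export
make_study_like_dataset <- function(n = 99, seed = 1, noise_sd = NULL) {
  cfg <- generator_config(n_samples = n, seed = seed, noise_sd = noise_sd)
  generate_traits(sample_factors(cfg), cfg)
}
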