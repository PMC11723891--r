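#' Simulation configuration for a synthetic camouflage study
#'
#' Bundles and validates the parameters of the generative model used to
#' emulate a field study of background-matched coloration across a clade:
#' a pure-birth phylogeny, lambda-scaled Brownian trait evolution on the
#' natural-log scale, a controllable linear animal-on-background
#' dependence, sex linkage with a controllable divergence-rate ratio, and
#' log-normal precipitation covariates.
#'
#' @param n_taxa number of species (default 17, a typical small clade).
#' @param seed integer seed fixing every stochastic draw.
#' @param lambda_true phylogenetic signal of all simulated fields in
#'   \[0, 1\] (default 1, full Brownian motion).
#' @param slope_bg ln-scale slope of animal trait on its background
#'   counterpart (1 = perfect proportional background matching).
#' @param sigma_bm Brownian rate (ln-scale tip standard deviation on the
#'   unit-depth tree) of the background fields.
#' @param sigma_resid rate of the animal residual field around the
#'   background-driven expectation.
#' @param rate_ratio_male_female male/female divergence-rate ratio; male
#'   deviations scale as `sqrt(rate_ratio)` times the female deviations.
#' @param sigma_sex rate of the independent male increment (0 = males
#'   perfectly correlated with females).
#' @param climate_effect ln-scale loading of precipitation on the
#'   environment field shared with background brightness.
#' @param sigma_climate independent ln-scale noise of the precipitation
#'   covariates.
#' @param dominant_wavelength_px marking wavelength of generated texture
#'   images.
#' @param image_size side length (pixels) of generated texture images.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 17L, seed = 1L, lambda_true = 1,
                       slope_bg = 1, sigma_bm = 0.3, sigma_resid = 0.1,
                       rate_ratio_male_female = 1, sigma_sex = 0.1,
                       climate_effect = 0.5, sigma_climate = 0.3,
                       dominant_wavelength_px = 16, image_size = 256L) {
  cfg <- list(n_taxa = as.integer(n_taxa), seed = as.integer(seed),
              lambda_true = lambda_true, slope_bg = slope_bg,
              sigma_bm = sigma_bm, sigma_resid = sigma_resid,
              rate_ratio_male_female = rate_ratio_male_female,
              sigma_sex = sigma_sex, climate_effect = climate_effect,
              sigma_climate = sigma_climate,
              dominant_wavelength_px = dominant_wavelength_px,
              image_size = as.integer(image_size))
  if (cfg$n_taxa < 2L) stop("n_taxa must be >= 2")
  if (cfg$lambda_true < 0 || cfg$lambda_true > 1)
    stop("lambda_true must be in [0, 1]")
  for (nm in c("sigma_bm", "rate_ratio_male_female",
               "dominant_wavelength_px"))
    if (!(cfg[[nm]] > 0)) stop(nm, " must be positive")
  for (nm in c("sigma_resid", "sigma_sex", "sigma_climate"))
    if (cfg[[nm]] < 0) stop(nm, " must be non-negative")
  structure(cfg, class = "sim_config")
}

#' Simulate a pure-birth phylogeny with unit depth
#'
#' A Yule (pure-birth) tree with `n` tips, rescaled so every root-to-tip
#' path has length 1 (ultrametric); reproducible from the seed.
#'
#' @param n number of tips (>= 2).
#' @param seed integer RNG seed.
#' @return an [ape::phylo] tree with tips `sp01 ... spNN`.
#' @export
sim_tree <- function(n, seed = 1L) {
  if (n < 2L) stop("a tree needs at least 2 tips")
  set.seed(seed)
  tree <- ape::rphylo(n, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%02d", seq_len(n))
  tree
}

#' Simulate a trait under lambda-scaled Brownian motion
#'
#' One multivariate-normal draw with mean 0 and covariance
#' `sigma2 * lambda_transform(V, lambda)` where `V` is the Brownian
#' covariance of the tree, via Cholesky factorization.
#'
#' @param tree an [ape::phylo] tree (or a precomputed covariance matrix).
#' @param lambda phylogenetic signal in \[0, 1\].
#' @param sigma2 Brownian rate (> 0).
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return named numeric vector of tip values.
#' @export
sim_bm_trait <- function(tree, lambda = 1, sigma2 = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (sigma2 <= 0) stop("sigma2 must be positive")
  V <- if (is.matrix(tree)) tree else phylo_covariance(tree)
  Vl <- lambda_transform(V, lambda) * sigma2
  R <- tryCatch(chol(Vl), error = function(e)
    stop("covariance is not positive-definite: ", conditionMessage(e)))
  x <- as.numeric(t(R) %*% stats::rnorm(nrow(Vl)))
  names(x) <- rownames(V)
  x
}

# Baseline (ln-scale) levels of each simulated trait family; values are
# typical magnitudes for reflectance-derived metrics.
trait_baselines <- c(brightness = log(0.30), saturation = log(1.20),
                     hue1 = log(1.10), hue2 = log(2.20),
                     overall_contrast = log(0.010),
                     dominant_size_px = log(16), diversity = log(0.30))

#' Simulate a full two-sex trait table and its phylogeny
#'
#' For each trait family the generative model on the natural-log scale is:
#' background `ln B = t0 + g` with `g` a lambda-scaled Brownian field of
#' rate `sigma_bm^2`; female animal `ln F = t0 + slope_bg * g + e_f` with
#' residual field `e_f` of rate `sigma_resid^2`; male animal
#' `ln M = t0 + sqrt(rate_ratio) * (ln F - t0) + d` with an independent
#' increment `d` of rate `sigma_sex^2` (so male ln-deviations are
#' `sqrt(rate_ratio)` times the female ones, plus independent evolution).
#' Both sexes share the locality backgrounds.  Precipitation covariates
#' are log-normal, loaded on the background-brightness field through
#' `climate_effect`.  Exponentiating guarantees the strictly positive
#' values required by downstream ln-scale analyses.
#'
#' @param config a [sim_config()].
#' @return list with `traits` (data frame: taxon, sex, seven animal trait
#'   columns, seven `bg_` columns, `pdt`, `pwt`) and `tree`.
#' @export
sim_study_traits <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  tree <- sim_tree(config$n_taxa, config$seed)
  V <- phylo_covariance(tree)
  set.seed(config$seed + 1L)

  taxa <- tree$tip.label
  n <- length(taxa)
  bg <- list(); female <- list(); male <- list()
  g_brightness <- NULL
  for (tr in names(trait_baselines)) {
    t0 <- trait_baselines[[tr]]
    g <- sim_bm_trait(V, config$lambda_true, config$sigma_bm^2)
    if (tr == "brightness") g_brightness <- g
    e_f <- if (config$sigma_resid > 0)
      sim_bm_trait(V, config$lambda_true, config$sigma_resid^2)
    else rep(0, n)
    d_m <- if (config$sigma_sex > 0)
      sim_bm_trait(V, config$lambda_true, config$sigma_sex^2)
    else rep(0, n)
    ln_bg <- t0 + g
    ln_f <- t0 + config$slope_bg * g + e_f
    ln_m <- t0 + sqrt(config$rate_ratio_male_female) * (ln_f - t0) + d_m
    bg[[tr]] <- exp(ln_bg)
    female[[tr]] <- exp(ln_f)
    male[[tr]] <- exp(ln_m)
  }
  pdt <- exp(log(50) + config$climate_effect * g_brightness +
               stats::rnorm(n, 0, config$sigma_climate))
  pwt <- exp(log(600) + config$climate_effect * g_brightness +
               stats::rnorm(n, 0, config$sigma_climate))

  one_sex <- function(sex, animal) {
    df <- data.frame(taxon = taxa, sex = sex, stringsAsFactors = FALSE)
    for (tr in names(trait_baselines)) df[[tr]] <- animal[[tr]]
    for (tr in names(trait_baselines)) df[[paste0("bg_", tr)]] <- bg[[tr]]
    df$pdt <- pdt
    df$pwt <- pwt
    df
  }
  traits <- rbind(one_sex("female", female), one_sex("male", male))
  rownames(traits) <- NULL
  list(traits = traits, tree = tree)
}

#' Simulate a band-limited texture image with known marking wavelength
#'
#' An isotropic Gaussian random field whose spectral mass lies in a
#' half-octave annulus centred on the target wavelength is added to a
#' uniform mean color.  The red and green channels carry the pattern
#' (those are the channels granularity analysis averages); blue is
#' constant.  The field has exactly zero mean, so region means recover
#' `mean_rgb`, and its peak deviation equals `amplitude`.
#'
#' @param size image side in pixels.
#' @param wavelength_px target dominant marking wavelength (0 < w < size).
#' @param mean_rgb length-3 mean reflectance of the texture.
#' @param amplitude peak deviation added to R and G; `mean_rgb` +/-
#'   `amplitude` must stay inside \[0, 1\].
#' @param seed integer RNG seed.
#' @param px_per_mm pixel scale recorded on the image (default 20).
#' @return a [reflectance_image] with a full-frame `"animal"` mask.
#' @export
sim_pattern_image <- function(size = 256L, wavelength_px = 16,
                              mean_rgb = c(0.4, 0.5, 0.3), amplitude = 0.2,
                              seed = 1L, px_per_mm = 20) {
  size <- as.integer(size)
  if (!(wavelength_px > 0) || wavelength_px >= size)
    stop("require 0 < wavelength_px < size")
  if (length(mean_rgb) != 3L || any(mean_rgb < 0) || any(mean_rgb > 1))
    stop("mean_rgb must be three values in [0, 1]")
  if (amplitude < 0 ||
      any(mean_rgb[1:2] + amplitude > 1) || any(mean_rgb[1:2] - amplitude < 0))
    stop("amplitude pushes R/G channels out of the [0, 1] gamut")
  field <- matrix(0, size, size)
  if (amplitude > 0) {
    set.seed(seed)
    noise <- matrix(stats::rnorm(size * size), size, size)
    wl <- fft_wavelengths(size, size)
    f0 <- 1 / wavelength_px
    keep <- (1 / wl) >= f0 / 2^0.25 & (1 / wl) <= f0 * 2^0.25
    keep[1, 1] <- FALSE
    spec <- stats::fft(noise)
    spec[!keep] <- 0
    field <- Re(stats::fft(spec, inverse = TRUE)) / (size^2)
    field <- field * (amplitude / max(abs(field)))
  }
  px <- array(0, dim = c(size, size, 3))
  px[, , 1] <- mean_rgb[1] + field
  px[, , 2] <- mean_rgb[2] + field
  px[, , 3] <- mean_rgb[3]
  reflectance_image(px, px_per_mm = px_per_mm,
                    masks = list(animal = matrix(TRUE, size, size)))
}
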