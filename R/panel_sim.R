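#' Phenotype names used throughout the package
#'
#' The six biofilm-related phenotypes scored in the assay panel: complex
#' colony morphology, complex mat formation, flocculation (settling),
#' agar invasion, polystyrene (crystal violet) adhesion, and filamentous
#' growth.
#' @export
BIOFILM_PHENOTYPES <- c("colony", "mat", "flocculation", "invasion",
                        "adhesion", "filamentous")

#' Default inter-phenotype latent correlation
#'
#' A correlation structure for per-strain latent propensities reflecting the
#' relationships observed among biofilm phenotypes in natural isolates:
#' colony and mat complexity strongly correlated; flocculation and adhesion
#' moderately correlated; invasion moderately correlated with adhesion and
#' colony complexity; flocculation nearly independent of invasion.
#'
#' @param phenotypes Phenotype names (order defines the matrix).
#' @return A symmetric unit-diagonal correlation matrix.
#' @export
default_latent_correlation <- function(phenotypes = BIOFILM_PHENOTYPES) {
  p <- length(phenotypes)
  r <- diag(p)
  dimnames(r) <- list(phenotypes, phenotypes)
  set_r <- function(a, b, v) {
    if (a %in% phenotypes && b %in% phenotypes) {
      r[a, b] <<- v; r[b, a] <<- v
    }
  }
  set_r("colony", "mat", 0.80)
  set_r("colony", "invasion", 0.50)
  set_r("colony", "adhesion", 0.40)
  set_r("colony", "flocculation", 0.15)
  set_r("mat", "invasion", 0.45)
  set_r("mat", "adhesion", 0.35)
  set_r("mat", "flocculation", 0.15)
  set_r("flocculation", "adhesion", 0.65)
  set_r("flocculation", "invasion", 0.20)
  set_r("invasion", "adhesion", 0.55)
  set_r("filamentous", "invasion", 0.45)
  set_r("filamentous", "colony", 0.25)
  set_r("filamentous", "mat", 0.25)
  r
}

#' Default per-phenotype diploid effect
#'
#' Multiplicative factors applied to the haploid latent propensity for
#' diploids. The defaults encode the attenuation pattern seen across ploidy
#' in natural isolates: flocculation strongly attenuated, adhesion roughly
#' halved, colony and mat complexity mildly reduced, invasion nearly
#' unchanged, filamentous growth unaffected.
#'
#' @param phenotypes Phenotype names.
#' @return Named numeric vector of factors.
#' @export
default_diploid_effect <- function(phenotypes = BIOFILM_PHENOTYPES) {
  eff <- c(colony = 0.7, mat = 0.8, flocculation = 0.2, invasion = 0.9,
           adhesion = 0.5, filamentous = 1.0)
  out <- rep(1, length(phenotypes))
  names(out) <- phenotypes
  known <- intersect(phenotypes, names(eff))
  out[known] <- eff[known]
  out
}

#' Specification of a simulated multi-strain phenotype panel
#'
#' Per-strain latent phenotype propensities are multivariate Gaussian with
#' the given inter-phenotype correlation, mapped to a nonnegative
#' quantitative scale by the softplus function `log(1 + exp(z))`. The diploid
#' latent value is the haploid latent value times the per-phenotype
#' `diploid_effect` factor (with optional per-strain exception overrides),
#' after which independent Gaussian technical-replicate noise is added and
#' values are clamped at zero. Ordinal 0-5 scores come from thresholding the
#' noise-free latent value, so they are monotone in it.
#'
#' @param n_strains Number of strains.
#' @param phenotypes Character vector of phenotype names.
#' @param latent_correlation Unit-diagonal positive semi-definite correlation
#'   matrix (`phenotypes` x `phenotypes`).
#' @param diploid_effect Named per-phenotype multiplicative factor (< 1
#'   attenuates, > 1 amplifies the diploid latent value).
#' @param exception_strains Optional named list `strain -> named numeric
#'   (phenotype -> factor)` overriding `diploid_effect` for single strains.
#' @param replicate_sd Technical replicate noise standard deviation.
#' @param n_technical Technical replicates per strain/ploidy/phenotype.
#' @param ordinal_thresholds Ascending cut points (at most 5) mapping the
#'   latent value to ordinal scores 0-5; either a numeric vector shared by all
#'   phenotypes or a named list per phenotype.
#' @param latent_shift Optional numeric vector (length `n_strains`) added to
#'   every latent Gaussian before the softplus map; used to build panels with
#'   distinct strain groups.
#' @param seed Integer seed.
#' @return A `panel_spec` object.
#' @export
panel_spec <- function(n_strains = 30, phenotypes = BIOFILM_PHENOTYPES,
                       latent_correlation = default_latent_correlation(phenotypes),
                       diploid_effect = default_diploid_effect(phenotypes),
                       exception_strains = NULL,
                       replicate_sd = 0.1, n_technical = 3,
                       ordinal_thresholds = c(0.25, 0.5, 0.7, 1.0, 1.55),
                       latent_shift = NULL, seed = 1L) {
  check_count(n_strains, "n_strains")
  p <- length(phenotypes)
  if (p < 1L) abort_validation("at least one phenotype required")
  if (!is.matrix(latent_correlation) ||
      any(dim(latent_correlation) != c(p, p))) {
    abort_validation("latent_correlation must be a %d x %d matrix", p, p)
  }
  if (max(abs(diag(latent_correlation) - 1)) > 1e-8) {
    abort_validation("latent_correlation must have unit diagonal")
  }
  if (max(abs(latent_correlation - t(latent_correlation))) > 1e-8) {
    abort_validation("latent_correlation must be symmetric")
  }
  ev <- eigen(latent_correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort_validation("latent_correlation is not positive semi-definite")
  }
  if (is.null(names(diploid_effect))) names(diploid_effect) <- phenotypes
  if (!all(phenotypes %in% names(diploid_effect))) {
    abort_validation("diploid_effect must name every phenotype")
  }
  check_scalar(replicate_sd, "replicate_sd", lower = 0)
  check_count(n_technical, "n_technical")
  thr <- ordinal_thresholds
  if (!is.list(thr)) thr <- stats::setNames(rep(list(thr), p), phenotypes)
  for (ph in phenotypes) {
    tv <- thr[[ph]]
    if (is.null(tv) || length(tv) > 5L || is.unsorted(tv, strictly = TRUE)) {
      abort_validation("ordinal_thresholds for '%s' must be at most 5 strictly ascending cut points", ph)
    }
  }
  if (!is.null(latent_shift) && length(latent_shift) != n_strains) {
    abort_validation("latent_shift must have length n_strains")
  }
  structure(list(n_strains = as.integer(n_strains), phenotypes = phenotypes,
                 latent_correlation = latent_correlation,
                 diploid_effect = diploid_effect[phenotypes],
                 exception_strains = exception_strains,
                 replicate_sd = replicate_sd,
                 n_technical = as.integer(n_technical),
                 ordinal_thresholds = thr,
                 latent_shift = latent_shift,
                 seed = as.integer(seed)),
            class = "panel_spec")
}

softplus <- function(z) {
  # numerically stable log(1 + exp(z))
  ifelse(z > 30, z, log1p(exp(pmin(z, 30))))
}

#' Simulate a multi-strain phenotype panel
#'
#' Draws the panel described by a [panel_spec()]: one haploid and one diploid
#' stratum per strain and phenotype, each with `n_technical` technical
#' replicate quantitative values and an ordinal 0-5 score. Sample
#' inter-phenotype correlations converge to `latent_correlation` as
#' `n_strains` grows, and a fixed seed gives byte-identical output.
#'
#' @param spec A [panel_spec()].
#' @return A long-format data frame (a phenotype panel) with columns
#'   `strain`, `ploidy`, `phenotype`, `replicate_type`, `replicate_id`,
#'   `value`, `ordinal_score`.
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  set.seed(spec$seed)
  n <- spec$n_strains
  phenos <- spec$phenotypes
  p <- length(phenos)
  strains <- sprintf("S%03d", seq_len(n))

  # correlated latent Gaussians via eigendecomposition (PSD-safe)
  ed <- eigen(spec$latent_correlation, symmetric = TRUE)
  l <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), p) %*% t(ed$vectors)
  z <- matrix(stats::rnorm(n * p), n, p) %*% l
  if (!is.null(spec$latent_shift)) z <- z + spec$latent_shift
  lat_hap <- softplus(z)
  dimnames(lat_hap) <- list(strains, phenos)

  eff <- matrix(rep(spec$diploid_effect, each = n), n, p,
                dimnames = list(strains, phenos))
  for (s in names(spec$exception_strains)) {
    if (!s %in% strains) abort_validation("exception strain '%s' not in panel", s)
    ov <- spec$exception_strains[[s]]
    eff[s, names(ov)] <- ov
  }
  lat_dip <- lat_hap * eff

  score_of <- function(lat, ph) findInterval(lat, spec$ordinal_thresholds[[ph]])

  blocks <- vector("list", 2L * p)
  k <- 0L
  for (ploidy in c("haploid", "diploid")) {
    lat <- if (ploidy == "haploid") lat_hap else lat_dip
    for (j in seq_len(p)) {
      k <- k + 1L
      vals <- rep(lat[, j], each = spec$n_technical) +
        stats::rnorm(n * spec$n_technical, sd = spec$replicate_sd)
      blocks[[k]] <- data.frame(
        strain = rep(strains, each = spec$n_technical),
        ploidy = ploidy,
        phenotype = phenos[j],
        replicate_type = "technical",
        replicate_id = rep(seq_len(spec$n_technical), times = n),
        value = pmax(vals, 0),
        ordinal_score = rep(score_of(lat[, j], phenos[j]),
                            each = spec$n_technical),
        stringsAsFactors = FALSE)
    }
  }
  panel <- do.call(rbind, blocks)
  rownames(panel) <- NULL
  attr(panel, "latent_haploid") <- lat_hap
  attr(panel, "latent_diploid") <- lat_dip
  panel
}
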