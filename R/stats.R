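#' Kendall tau-b rank correlation
#'
#' Rank correlation between two ordinal (or continuous) score vectors, with
#' tie correction (tau-b): ordinal 0-5 phenotype grades guarantee heavy ties.
#' The two-sided p-value uses the tie-corrected normal approximation when
#' ties are present and the exact null distribution otherwise; `exact = TRUE`
#' forces exhaustive enumeration (only sensible for small n).
#'
#' @param x,y Equal-length numeric vectors, n >= 2, neither all-tied.
#' @param exact Force an exact p-value (requires untied data).
#' @return A `correlation_result`: list with `method`, `statistic` (tau),
#'   `p_value` and `n`.
#' @examples
#' kendall_tau(c(0, 0, 1, 2), c(0, 1, 1, 2))
#' @export
kendall_tau <- function(x, y, exact = NULL) {
  if (length(x) != length(y)) {
    abort_validation("vectors differ in length (%d vs %d)", length(x), length(y))
  }
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) abort_validation("need at least 2 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    abort_validation("correlation undefined: all values tied in one vector")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall",
                                         exact = exact,
                                         alternative = "two.sided"))
  structure(list(method = "kendall_tau_b",
                 statistic = unname(ct$estimate),
                 p_value = ct$p.value,
                 n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<%s: statistic %.4f%s%s, n %d>\n", x$method, x$statistic,
              if (!is.null(x$p_value)) sprintf(", p %.3g", x$p_value) else "",
              if (!is.null(x$r_squared)) sprintf(", R^2 %.3f", x$r_squared) else "",
              x$n))
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Two-sided unequal-variance comparison of two replicate sets, the test
#' applied to haploid versus diploid technical replicates:
#' `t = (mean_a - mean_b) / sqrt(s2_a/n_a + s2_b/n_b)` with
#' Welch-Satterthwaite degrees of freedom. Two zero-variance samples with
#' equal means give `t = 0, p = 1`; zero pooled variance with unequal means
#' gives infinite `t` and `p = 0`.
#'
#' @param a,b Numeric replicate vectors, each of length >= 2.
#' @return List with `t`, `df` and `p_value`.
#' @examples
#' welch_test(c(1, 2, 3), c(2, 3, 4))  # t = -1.2247, df = 4
#' @export
welch_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    abort_validation("each sample needs at least 2 values")
  }
  if (stats::var(a) + stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2,
                                        p_value = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p_value = 0))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values (used as q-values) with enforced monotonicity;
#' a test is significant when its q-value is at most `alpha`.
#'
#' @param p_values Numeric p-values in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return List with `q_values` and logical `significant` flags.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04))$q_values  # all 0.04
#' @export
fdr_adjust <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L) abort_validation("no p-values supplied")
  ok <- is.na(p_values) | (p_values >= 0 & p_values <= 1)
  if (!all(ok)) abort_validation("p-values outside [0, 1]")
  check_scalar(alpha, "alpha", 0, 1)
  q <- stats::p.adjust(p_values, method = "BH")
  list(q_values = q, significant = !is.na(q) & q <= alpha)
}

#' Ordinary least-squares fit of y on x
#'
#' Slope, intercept and coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot` for the scatter comparisons between
#' quantitative phenotypes (and between haploid and diploid values of one
#' phenotype). A constant response is fit as slope 0 with `R^2 = 0` by
#' convention.
#'
#' @param x,y Numeric vectors, n >= 2, `x` not constant.
#' @return A `correlation_result` with `method = "ols"`, `statistic` (slope),
#'   `intercept`, `r_squared` and `n`.
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y)) {
    abort_validation("vectors differ in length (%d vs %d)", length(x), length(y))
  }
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) abort_validation("need at least 2 complete pairs")
  if (stats::var(x) == 0) abort_validation("x is constant; slope undefined")
  if (stats::var(y) == 0) {
    return(structure(list(method = "ols", statistic = 0,
                          intercept = mean(y), r_squared = 0,
                          n = length(x)),
                     class = "correlation_result"))
  }
  fit <- stats::lm(y ~ x)
  structure(list(method = "ols",
                 statistic = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 n = length(x)),
            class = "correlation_result")
}

#' Classify haploid-to-diploid phenotype changes per strain
#'
#' For each strain and phenotype, compares diploid against haploid technical
#' replicate quantitative values with [welch_test()], pools the p-values
#' across strains within each phenotype for Benjamini-Hochberg FDR
#' adjustment, and calls `decrease` / `increase` by the sign of
#' (diploid mean - haploid mean) when the q-value is at most `alpha`, else
#' `no_change`. Strains missing one ploidy (or with fewer than two replicates
#' on either side) are excluded with a warning naming them — mirroring the
#' per-phenotype strain denominators of the assay panel.
#'
#' With `paired_on_means = TRUE` a paired t-test on the per-strain haploid and
#' diploid means across all strains is also returned (one test per
#' phenotype), for the reading of the protocol in which pairing is across
#' strains rather than replicates.
#'
#' @param panel A valid phenotype panel containing haploid and diploid
#'   technical replicates.
#' @param phenotypes Phenotypes to classify (default: the quantitative
#'   assays flocculation, invasion, adhesion).
#' @param alpha FDR level (default 0.05).
#' @param paired_on_means Also compute the per-phenotype paired-on-means
#'   variant.
#' @return A `ploidy_change_calls` data frame with one row per strain and
#'   phenotype: `strain`, `phenotype`, `haploid_mean`, `diploid_mean`,
#'   `t_statistic`, `df`, `p_value`, `q_value`, `call`. The per-phenotype
#'   paired tests, if requested, are in `attr(, "paired_on_means")`.
#' @export
classify_ploidy_changes <- function(panel,
                                    phenotypes = c("flocculation", "invasion",
                                                   "adhesion"),
                                    alpha = 0.05,
                                    paired_on_means = FALSE) {
  validate_panel(panel)
  check_scalar(alpha, "alpha", 0, 1)
  tech <- panel[panel$replicate_type == "technical" &
                  panel$phenotype %in% phenotypes &
                  panel$ploidy %in% c("haploid", "diploid"), , drop = FALSE]
  if (nrow(tech) == 0L) {
    abort_validation("panel has no technical replicates for the requested phenotypes")
  }
  rows <- list()
  excluded <- character(0)
  for (ph in phenotypes) {
    sub <- tech[tech$phenotype == ph, , drop = FALSE]
    strains <- sort(unique(sub$strain))
    for (s in strains) {
      a <- sub$value[sub$strain == s & sub$ploidy == "haploid"]
      b <- sub$value[sub$strain == s & sub$ploidy == "diploid"]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 2L || length(b) < 2L) {
        excluded <- c(excluded, sprintf("%s/%s", s, ph))
        next
      }
      wt <- welch_test(b, a)  # diploid minus haploid
      rows[[length(rows) + 1L]] <- data.frame(
        strain = s, phenotype = ph,
        haploid_mean = mean(a), diploid_mean = mean(b),
        t_statistic = wt$t, df = wt$df, p_value = wt$p_value,
        stringsAsFactors = FALSE)
    }
  }
  if (length(excluded)) {
    warning(sprintf("excluded strain/phenotype pairs lacking >=2 replicates per ploidy: %s",
                    paste(excluded, collapse = ", ")), call. = FALSE)
  }
  if (length(rows) == 0L) {
    abort_validation("no strain has >=2 haploid and >=2 diploid replicates")
  }
  calls <- do.call(rbind, rows)
  calls$q_value <- NA_real_
  for (ph in unique(calls$phenotype)) {
    i <- calls$phenotype == ph
    calls$q_value[i] <- fdr_adjust(calls$p_value[i], alpha)$q_values
  }
  delta <- calls$diploid_mean - calls$haploid_mean
  calls$call <- ifelse(calls$q_value > alpha, "no_change",
                       ifelse(delta < 0, "decrease", "increase"))
  class(calls) <- c("ploidy_change_calls", class(calls))
  if (paired_on_means) {
    paired <- lapply(stats::setNames(nm = unique(calls$phenotype)), function(ph) {
      i <- calls$phenotype == ph
      tt <- stats::t.test(calls$diploid_mean[i], calls$haploid_mean[i],
                          paired = TRUE)
      list(t = unname(tt$statistic), df = unname(tt$parameter),
           p_value = tt$p.value)
    })
    attr(calls, "paired_on_means") <- paired
  }
  calls
}

#' Per-phenotype summary of ploidy-change calls
#'
#' Counts decreases, no-changes and increases per phenotype — the
#' three-row summary table of diploid-versus-haploid outcomes.
#'
#' @param calls Output of [classify_ploidy_changes()].
#' @return Data frame with columns `phenotype`, `n_strains`, `n_decrease`,
#'   `n_no_change`, `n_increase`.
#' @export
ploidy_change_summary <- function(calls) {
  stopifnot(inherits(calls, "ploidy_change_calls"))
  phs <- unique(calls$phenotype)
  do.call(rbind, lapply(phs, function(ph) {
    cc <- calls$call[calls$phenotype == ph]
    data.frame(phenotype = ph, n_strains = length(cc),
               n_decrease = sum(cc == "decrease"),
               n_no_change = sum(cc == "no_change"),
               n_increase = sum(cc == "increase"),
               stringsAsFactors = FALSE)
  }))
}
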