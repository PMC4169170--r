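# Independent oracles used across the suite. These deliberately use brute
# force or closed forms, never the code paths they check.

# Kendall tau-b by exhaustive pair counting with tie correction.
brute_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  tie_term <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  (conc - disc) / sqrt((n0 - tie_term(x)) * (n0 - tie_term(y)))
}

# Welch statistic and Welch-Satterthwaite df from the printed formulas.
brute_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df)
}

# OLS slope/intercept/R^2 from the normal equations.
brute_ols <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  pred <- intercept + slope * x
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Average-linkage agglomeration by direct Lance-Williams recursion on the
# full distance matrix (fine for <= 6 leaves).
brute_average_heights <- function(d) {
  d <- as.matrix(d)
  sizes <- rep(1, nrow(d))
  heights <- numeric(0)
  while (nrow(d) > 1) {
    du <- d; diag(du) <- Inf
    k <- which(du == min(du), arr.ind = TRUE)[1, ]
    i <- min(k); j <- max(k)
    heights <- c(heights, d[i, j])
    new_row <- (sizes[i] * d[i, ] + sizes[j] * d[j, ]) / (sizes[i] + sizes[j])
    d[i, ] <- new_row; d[, i] <- new_row; d[i, i] <- 0
    d <- d[-j, -j, drop = FALSE]
    sizes[i] <- sizes[i] + sizes[j]; sizes <- sizes[-j]
  }
  heights
}

# A hard-step tube image built directly, bypassing the renderer.
step_image <- function(h = 100, w = 20, boundary_row = 50,
                       low = 0, high = 200) {
  m <- matrix(high, h, w)
  if (boundary_row > 0) m[seq_len(boundary_row), ] <- low
  gray_image(m)
}

# Mean intensity over the ROI complement, pixel by pixel.
brute_background <- function(img, mask) {
  mean(unclass(img)[!mask])
}

# Proportion of a null panel's strain/phenotype tests called significant.
null_panel_calls <- function(n_strains, seed, alpha = 0.05) {
  eff <- setNames(rep(1, length(BIOFILM_PHENOTYPES)), BIOFILM_PHENOTYPES)
  pan <- simulate_panel(panel_spec(n_strains = n_strains,
                                   diploid_effect = eff, seed = seed))
  classify_ploidy_changes(pan, alpha = alpha)
}

# Accuracy of the top dendrogram split on a panel with two strain groups
# whose latent means sit at -2 and +2 latent SD.
top_split_accuracy <- function(n_strains = 30, seed = 1) {
  shift <- rep(c(-2, 2), length.out = n_strains)
  pan <- simulate_panel(panel_spec(n_strains = n_strains,
                                   latent_shift = shift, seed = seed))
  pm <- phenotype_matrix(pan, ploidy = "haploid")
  tree <- hcluster(euclidean_distances(pm))
  cl <- stats::cutree(tree, k = 2)
  truth <- shift[match(names(cl), sprintf("S%03d", seq_len(n_strains)))] > 0
  acc <- mean((cl == cl[1]) == (truth == truth[1]))
  max(acc, 1 - acc)
}
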