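#' Build a strain x phenotype matrix from a panel
#'
#' Collapses technical replicates of one ploidy set by their mean, linearly
#' normalizes each phenotype to the 0-5 scale with [linear_normalize()], and
#' returns the complete strain x phenotype matrix used as clustering input.
#' Strains missing any phenotype are excluded with a warning naming them
#' (no imputation).
#'
#' @param panel A valid phenotype panel.
#' @param ploidy Which ploidy set to use (default haploid).
#' @param normalize Apply the 0-5 linear normalization per phenotype.
#' @return Numeric matrix, strains as rows (sorted), phenotypes as columns.
#' @export
phenotype_matrix <- function(panel, ploidy = "haploid", normalize = TRUE) {
  validate_panel(panel)
  sub <- panel[panel$ploidy == ploidy & panel$replicate_type == "technical", ,
               drop = FALSE]
  if (nrow(sub) == 0L) abort_validation("no technical rows for ploidy '%s'", ploidy)
  strains <- sort(unique(sub$strain))
  phenos <- unique(sub$phenotype)
  m <- matrix(NA_real_, length(strains), length(phenos),
              dimnames = list(strains, phenos))
  agg <- tapply(sub$value,
                list(factor(sub$strain, strains), factor(sub$phenotype, phenos)),
                mean, na.rm = TRUE)
  m[] <- agg
  incomplete <- rownames(m)[apply(m, 1L, function(r) any(!is.finite(r)))]
  if (length(incomplete)) {
    warning(sprintf("excluding strains with missing phenotypes: %s",
                    paste(incomplete, collapse = ", ")), call. = FALSE)
    m <- m[setdiff(rownames(m), incomplete), , drop = FALSE]
  }
  if (normalize) m <- apply(m, 2L, linear_normalize)
  m
}

#' Pairwise Euclidean distances between strain phenotype vectors
#'
#' @param m Numeric strain x phenotype matrix with no missing cells.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
euclidean_distances <- function(m) {
  if (!is.matrix(m) || nrow(m) < 2L) {
    abort_validation("need a matrix with at least 2 strains")
  }
  if (anyNA(m) || any(!is.finite(m))) {
    bad <- rownames(m)[apply(m, 1L, function(r) any(!is.finite(r)))]
    abort_validation("missing phenotype values for strains: %s",
                     paste(bad, collapse = ", "))
  }
  as.matrix(stats::dist(m, method = "euclidean"))
}

#' Agglomerative hierarchical clustering of strains
#'
#' Clusters strains by their pairwise distances. Rows are ordered
#' lexicographically by strain identifier before clustering, which makes
#' tie-breaking (and therefore the dendrogram) invariant to the input order.
#'
#' @param d Symmetric distance matrix (from [euclidean_distances()]) or a
#'   `dist` object.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return An `hclust` tree with merge heights in nondecreasing order.
#' @export
hcluster <- function(d, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    abort_validation("expected a square distance matrix")
  }
  if (nrow(d) < 2L) abort_validation("need at least 2 strains to cluster")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- sprintf("S%03d", seq_len(nrow(d)))
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  stats::hclust(stats::as.dist(d), method = linkage)
}

#' Write TreeView-compatible clustering output
#'
#' Writes the clustered phenotype matrix in the Cluster/TreeView file
#' dialect: a tab-delimited CDT with GID/ORF/NAME/GWEIGHT header and rows in
#' dendrogram leaf order, a GTR listing the merges as NODEnX records with
#' heights mapped to the similarity scale `1 - d / d_max` that TreeView
#' expects, a Newick file with branch lengths on the original distance scale,
#' and a plain leaf-order listing. All files use Unix line endings.
#'
#' @param m Strain x phenotype matrix (the clustering input).
#' @param tree `hclust` output of [hcluster()] on the same strains.
#' @param prefix Output path prefix; writes `<prefix>.cdt`, `<prefix>.gtr`,
#'   `<prefix>.nwk` and `<prefix>.leaves.txt`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_treeview <- function(m, tree, prefix) {
  stopifnot(inherits(tree, "hclust"))
  if (!setequal(rownames(m), tree$labels)) {
    abort_validation("matrix strains and tree leaves differ")
  }
  m <- m[tree$labels, , drop = FALSE]
  n <- nrow(m)
  gid <- sprintf("GENE%dX", seq_len(n))

  cdt_path <- paste0(prefix, ".cdt")
  con <- file(cdt_path, open = "wb")
  on.exit(close(con), add = TRUE)
  wline <- function(...) writeLines(paste(..., sep = "\t"), con, sep = "\n")
  wline(paste(c("GID", "ORF", "NAME", "GWEIGHT", colnames(m)), collapse = "\t"))
  wline(paste(c("EWEIGHT", "", "", "", rep("1", ncol(m))), collapse = "\t"))
  leaf_order <- tree$order  # indices into tree$labels
  for (i in leaf_order) {
    wline(paste(c(gid[i], rownames(m)[i], rownames(m)[i], "1",
                  format(m[i, ], trim = TRUE, digits = 10)), collapse = "\t"))
  }
  close(con); on.exit()

  # GTR: one NODE line per merge; negative ids are leaves, positive are nodes
  d_max <- max(tree$height)
  node_id <- function(j) {
    if (j < 0) gid[-j] else sprintf("NODE%dX", j)
  }
  gtr_lines <- vapply(seq_len(n - 1L), function(k) {
    sim <- if (d_max > 0) 1 - tree$height[k] / d_max else 1
    paste(sprintf("NODE%dX", k), node_id(tree$merge[k, 1L]),
          node_id(tree$merge[k, 2L]),
          format(sim, trim = TRUE, digits = 10), sep = "\t")
  }, character(1))
  gtr_path <- paste0(prefix, ".gtr")
  writeLines(gtr_lines, gtr_path, sep = "\n")

  nwk_path <- paste0(prefix, ".nwk")
  ape::write.tree(ape::as.phylo(tree), file = nwk_path)

  leaves_path <- paste0(prefix, ".leaves.txt")
  writeLines(tree$labels[leaf_order], leaves_path, sep = "\n")

  invisible(c(cdt = cdt_path, gtr = gtr_path, nwk = nwk_path,
              leaves = leaves_path))
}

#' Read values back from a CDT file
#'
#' Parses the tab-delimited CDT dialect written by [write_treeview()],
#' returning the numeric matrix (rows in the file's leaf order).
#'
#' @param path Path to a `.cdt` file.
#' @return Numeric matrix with strain rownames and phenotype colnames.
#' @export
read_cdt <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) abort_validation("CDT file too short: %s", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  phenos <- header[-(1:4)]
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  m <- t(vapply(body, function(f) as.numeric(f[-(1:4)]),
                numeric(length(phenos))))
  rownames(m) <- vapply(body, `[[`, character(1), 2L)
  colnames(m) <- phenos
  m
}
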