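#' Transform normalized counts for network construction
#'
#' Applies \code{log2(normalized + 1)} and removes genes with zero variance
#' across samples (a message reports how many). Correlation-based network
#' statistics downstream are robust to the exact choice of
#' variance-stabilizing transform, so the simple log transform is used.
#'
#' @param normalized genes x samples normalized count matrix with rownames.
#' @return transformed genes x samples matrix containing only variable genes.
#' @export
transform_expression <- function(normalized) {
  normalized <- as.matrix(normalized)
  if (ncol(normalized) < 3) stop("need >= 3 samples")
  x <- log2(normalized + 1)
  v <- apply(x, 1, stats::var)
  if (all(v == 0)) stop("no variable genes")
  if (any(v == 0)) {
    message(sum(v == 0), " zero-variance gene(s) removed")
  }
  x[v > 0, , drop = FALSE]
}

#' Signed weighted adjacency matrix
#'
#' Soft-thresholded signed adjacency
#' \deqn{a_{ij} = ((1 + cor(x_i, x_j)) / 2)^\beta}
#' with Pearson correlation, so perfectly anticorrelated genes get weight 0
#' and perfectly correlated genes weight 1. The diagonal is set to zero so
#' that row sums are connectivities.
#'
#' @param expr genes x samples matrix (no zero-variance genes).
#' @param beta soft-threshold power (>= 1).
#' @return symmetric genes x genes adjacency matrix in \eqn{[0, 1]}, zero
#'   diagonal.
#' @export
signed_adjacency <- function(expr, beta = 16) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3) stop("need >= 3 samples")
  if (beta < 1) stop("beta must be >= 1")
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) stop("zero-variance gene present; transform first")
  a <- ((1 + stats::cor(t(expr))) / 2)^beta
  a[a > 1] <- 1  # guard against rounding just above 1
  diag(a) <- 0
  a
}

#' Scale-free soft-threshold selection
#'
#' For each candidate power, builds the signed adjacency, computes the
#' connectivity distribution, and measures the scale-free topology fit as
#' the R-squared of the regression of log10(frequency) on log10(mean
#' connectivity) over binned connectivities, signed negatively when the
#' log-log slope is positive. Returns the smallest power whose signed
#' R-squared reaches \code{rsq_cut}, otherwise the power maximizing it; if
#' every fit is degenerate the configured default is returned with a
#' warning.
#'
#' @param expr genes x samples matrix.
#' @param powers candidate powers.
#' @param rsq_cut signed R-squared threshold (default 0.8).
#' @param nbins number of connectivity bins (default 10).
#' @param default fallback power for degenerate fits (default 16).
#' @return list with \code{beta} (chosen power) and \code{fit_table}
#'   (power, signed R-squared, slope, mean connectivity).
#' @export
pick_soft_threshold <- function(expr, powers = c(1:10, 12, 14, 16, 18, 20),
                                rsq_cut = 0.8, nbins = 10, default = 16) {
  if (length(powers) < 2) stop("need >= 2 candidate powers")
  s <- (1 + stats::cor(t(as.matrix(expr)))) / 2
  diag(s) <- 0
  rows <- lapply(powers, function(b) {
    k <- rowSums(s^b)
    fit <- scale_free_fit(k, nbins)
    data.frame(power = b, rsq_signed = fit$rsq_signed, slope = fit$slope,
               mean_k = mean(k))
  })
  tab <- do.call(rbind, rows)
  ok <- is.finite(tab$rsq_signed)
  if (!any(ok)) {
    warning("all scale-free fits degenerate; falling back to power ", default)
    return(list(beta = default, fit_table = tab))
  }
  pass <- ok & tab$rsq_signed >= rsq_cut
  beta <- if (any(pass)) min(tab$power[pass]) else
    tab$power[ok][which.max(tab$rsq_signed[ok])]
  list(beta = beta, fit_table = tab)
}

# log10-log10 regression of binned connectivity frequency; R^2 signed
# negative when the slope is positive (scale-free fits have negative slope).
scale_free_fit <- function(k, nbins = 10) {
  k <- k[is.finite(k)]
  if (length(unique(k)) < 3 || max(k) <= 0) {
    return(list(rsq_signed = NA_real_, slope = NA_real_))
  }
  bins <- cut(k, nbins)
  freq <- tapply(k, bins, length)
  kmean <- tapply(k, bins, mean)
  keep <- !is.na(freq) & freq > 0 & kmean > 0
  if (sum(keep) < 3) return(list(rsq_signed = NA_real_, slope = NA_real_))
  x <- log10(kmean[keep]); y <- log10(freq[keep])
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  list(rsq_signed = unname(-sign(slope) * r2), slope = unname(slope))
}

#' Topological overlap matrix
#'
#' Similarity augmenting direct adjacency with shared-neighbor agreement:
#' \deqn{TOM_{ij} = \frac{\sum_u a_{iu} a_{uj} + a_{ij}}
#'                       {\min(k_i, k_j) + 1 - a_{ij}}, \quad TOM_{ii} = 1}
#' with \eqn{k_i = \sum_u a_{iu}}.
#'
#' @param adjacency symmetric matrix in \eqn{[0, 1]} with zero diagonal.
#' @return symmetric TOM in \eqn{[0, 1]} with unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isSymmetric(unname(a), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(a < 0 | a > 1)) stop("adjacency must lie in [0, 1]")
  diag(a) <- 0
  k <- rowSums(a)
  shared <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (shared + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

# conventional module color order, largest module first
module_colors <- function(n) {
  base <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
            "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
            "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
            "lightyellow", "royalblue")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, paste0("module", seq_len(n - length(base))))
}

#' Detect coexpression modules
#'
#' Average-linkage hierarchical clustering on the dissimilarity
#' \code{1 - TOM}, cut statically. By default (\code{cut_height = NULL})
#' the cut is placed automatically in the widest gap of the upper quarter
#' of the merge-height distribution, which separates the within-module
#' merge regime from the joins between unrelated branches; a numeric
#' \code{cut_height} instead cuts at that fraction of the maximum merge
#' height. Clusters smaller than \code{min_module_size} are relabeled
#' \code{"grey"} (unassigned); surviving modules are named by size rank in
#' the conventional color order (turquoise largest, then blue, brown, ...).
#' When \code{expr} is supplied, modules whose eigengenes correlate above
#' \code{merge_threshold} are merged iteratively (closest pair first) before
#' naming.
#'
#' @param tom topological overlap matrix from [topological_overlap()].
#' @param expr optional genes x samples matrix enabling eigengene merging.
#' @param min_module_size smallest retained module (default 30).
#' @param cut_height NULL for the automatic largest-gap cut (default), or a
#'   fraction of the maximum dendrogram height at which to cut.
#' @param merge_threshold eigengene-correlation merge cutoff (default 0.75).
#' @return character vector of module labels, named by gene.
#' @export
detect_modules <- function(tom, expr = NULL, min_module_size = 30,
                           cut_height = NULL, merge_threshold = 0.75) {
  n <- nrow(tom)
  genes <- rownames(tom)
  if (is.null(genes)) genes <- paste0("g", seq_len(n))
  if (n < min_module_size) {
    warning("fewer genes than min_module_size; all genes unassigned")
    return(stats::setNames(rep("grey", n), genes))
  }
  diss <- stats::as.dist(1 - tom)
  tree <- stats::hclust(diss, method = "average")
  h_cut <- if (is.null(cut_height)) gap_cut_height(tree$height) else
    cut_height * max(tree$height)
  cl <- stats::cutree(tree, h = h_cut)
  if (!is.null(expr)) cl <- merge_close_modules(cl, expr, merge_threshold,
                                                min_module_size)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- rep("grey", n)
  if (length(keep)) {
    ordered <- keep[order(-sizes[keep])]
    cols <- module_colors(length(ordered))
    for (i in seq_along(ordered)) labels[cl == ordered[i]] <- cols[i]
  }
  stats::setNames(labels, genes)
}

# place the cut in the widest gap among the upper quarter of merge heights;
# the joins between unrelated branches concentrate near the maximum, while
# within-module merging finishes well below it. When no clearly dominant
# gap exists (a homogeneous tree) the cut sits above the last merge, giving
# a single cluster.
gap_cut_height <- function(heights, min_gap = 0.01) {
  h <- sort(heights)
  upper <- h[h >= stats::quantile(h, 0.75)]
  if (length(upper) < 2) return(max(h) + 1e-9)
  gaps <- diff(upper)
  i <- which.max(gaps)
  if (gaps[i] < min_gap) return(max(h) + 1e-9)
  (upper[i] + upper[i + 1]) / 2
}

# iteratively merge clusters whose eigengenes correlate above the threshold
merge_close_modules <- function(cl, expr, merge_threshold, min_module_size) {
  repeat {
    sizes <- table(cl)
    ids <- names(sizes)[sizes >= 2]
    if (length(ids) < 2) return(cl)
    labels <- stats::setNames(ifelse(as.character(cl) %in% ids,
                                     as.character(cl), "grey"), names(cl))
    mes <- module_eigengene(expr, labels)
    mes <- mes[setdiff(rownames(mes), "grey"), , drop = FALSE]
    if (nrow(mes) < 2) return(cl)
    cm <- stats::cor(t(mes))
    diag(cm) <- -Inf
    if (max(cm) <= merge_threshold) return(cl)
    pair <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    from <- rownames(cm)[pair[2]]; to <- rownames(cm)[pair[1]]
    cl[as.character(cl) == from] <- as.integer(to)
  }
}

#' Module eigengenes
#'
#' First principal component of the standardized expression of each module's
#' genes, oriented so that its average correlation with the member genes is
#' positive, and scaled to unit variance. A singleton module's eigengene is
#' its standardized profile.
#'
#' @param expr genes x samples matrix.
#' @param labels module label per gene (named or in row order).
#' @return modules x samples matrix of eigengene profiles (one row per
#'   module label present, including \code{"grey"} if any).
#' @export
module_eigengene <- function(expr, labels) {
  expr <- as.matrix(expr)
  mods <- sort(unique(labels))
  out <- matrix(NA_real_, length(mods), ncol(expr),
                dimnames = list(mods, colnames(expr)))
  for (m in mods) {
    sub <- expr[labels == m, , drop = FALSE]
    zs <- t(scale(t(sub)))
    if (nrow(zs) == 1) {
      me <- zs[1, ]
    } else {
      pc <- stats::prcomp(t(zs), center = FALSE, scale. = FALSE)
      me <- pc$x[, 1]
    }
    if (mean(stats::cor(me, t(sub))) < 0) me <- -me
    out[m, ] <- me / stats::sd(me)
  }
  out
}

#' Module membership (kME)
#'
#' Pearson correlation of every gene's profile with every module eigengene,
#' with the correlation t-test p-value (\eqn{df = n_{samples} - 2}).
#'
#' @param expr genes x samples matrix.
#' @param eigengenes modules x samples matrix from [module_eigengene()].
#' @return list with matrices \code{kme} and \code{p} (genes x modules).
#' @export
module_membership <- function(expr, eigengenes) {
  expr <- as.matrix(expr)
  n <- ncol(expr)
  if (n < 3) stop("need >= 3 samples")
  kme <- stats::cor(t(expr), t(eigengenes))
  r <- pmin(pmax(kme, -1), 1)
  t_stat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  list(kme = kme, p = p)
}

#' Total and intramodular connectivity
#'
#' \code{k_total} is each gene's adjacency row sum; \code{k_within} sums
#' adjacency only over co-members of the gene's module (unassigned "grey"
#' genes are summed over grey co-members).
#'
#' @param adjacency symmetric adjacency with zero diagonal.
#' @param labels module label per gene.
#' @return data.frame with \code{gene}, \code{module}, \code{k_within},
#'   \code{k_total}.
#' @export
intramodular_connectivity <- function(adjacency, labels) {
  a <- as.matrix(adjacency)
  diag(a) <- 0
  genes <- rownames(a)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(a)))
  k_total <- rowSums(a)
  k_within <- vapply(seq_len(nrow(a)), function(i) {
    same <- labels == labels[i]
    same[i] <- FALSE
    sum(a[i, same])
  }, numeric(1))
  data.frame(gene = genes, module = unname(labels), k_within = k_within,
             k_total = k_total, stringsAsFactors = FALSE)
}

#' Identify hub genes
#'
#' A gene is a hub of its module when its intramodular connectivity is at or
#' above the module's 90th percentile (linear-interpolation quantile;
#' modules with fewer than 10 genes take only their single best-connected
#' gene), its module membership exceeds \code{kme_min} strictly, and the
#' membership p-value is below \code{p_max}. Unassigned (grey) genes are
#' never hubs.
#'
#' @param connectivity data.frame from [intramodular_connectivity()].
#' @param kme own-module membership per gene (same order).
#' @param kme_p membership p-value per gene.
#' @param top_fraction fraction of each module counted as highly connected
#'   (default 0.10).
#' @param kme_min strict membership threshold (default 0.9).
#' @param p_max membership significance threshold (default 0.01).
#' @return logical hub flag per gene.
#' @export
identify_hubs <- function(connectivity, kme, kme_p, top_fraction = 0.10,
                          kme_min = 0.9, p_max = 0.01) {
  hub <- rep(FALSE, nrow(connectivity))
  for (m in setdiff(unique(connectivity$module), "grey")) {
    sel <- which(connectivity$module == m)
    kw <- connectivity$k_within[sel]
    top <- if (length(sel) < 10) kw >= max(kw) else
      kw >= stats::quantile(kw, 1 - top_fraction)
    hub[sel] <- top & kme[sel] > kme_min & kme_p[sel] < p_max
  }
  hub
}

#' Module-trait association
#'
#' Pearson correlation of each module eigengene with a per-sample trait
#' (e.g. the relative fitness of the sample's genotype at a given
#' temperature), with the correlation t-test p-value.
#'
#' @param eigengenes modules x samples matrix.
#' @param trait numeric trait value per sample.
#' @return data.frame with \code{module}, \code{cor}, \code{p}; a constant
#'   trait yields NA with a warning.
#' @export
module_trait_association <- function(eigengenes, trait) {
  if (length(trait) != ncol(eigengenes)) stop("one trait value per sample")
  n <- length(trait)
  if (stats::sd(trait) == 0) {
    warning("constant trait: association undefined")
    return(data.frame(module = rownames(eigengenes), cor = NA_real_,
                      p = NA_real_, stringsAsFactors = FALSE))
  }
  r <- as.vector(stats::cor(t(eigengenes), trait))
  t_stat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  data.frame(module = rownames(eigengenes), cor = r,
             p = 2 * stats::pt(-abs(t_stat), df = n - 2),
             stringsAsFactors = FALSE)
}

#' Full coexpression-network analysis
#'
#' Runs the whole network stage: signed adjacency at the given (or
#' automatically selected) power, topological overlap, module detection with
#' eigengene merging, eigengenes, module membership, intramodular
#' connectivity and hub identification.
#'
#' @param expr transformed genes x samples matrix (see
#'   [transform_expression()]).
#' @param beta soft-threshold power, or NULL to select with
#'   [pick_soft_threshold()].
#' @param min_module_size,cut_height,merge_threshold see [detect_modules()].
#' @param hub_top_fraction,hub_kme_min,hub_p_max see [identify_hubs()].
#' @return list of class \code{"coexpression_network"} with \code{beta},
#'   \code{adjacency}, \code{tom}, \code{labels}, \code{eigengenes} and a
#'   per-gene \code{genes} data.frame (module, k_within, k_total, kme,
#'   kme_p, hub).
#' @export
coexpression_network <- function(expr, beta = 16, min_module_size = 30,
                                 cut_height = NULL, merge_threshold = 0.75,
                                 hub_top_fraction = 0.10, hub_kme_min = 0.9,
                                 hub_p_max = 0.01) {
  expr <- as.matrix(expr)
  if (is.null(beta)) beta <- pick_soft_threshold(expr)$beta
  adj <- signed_adjacency(expr, beta)
  tom <- topological_overlap(adj)
  labels <- detect_modules(tom, expr, min_module_size, cut_height,
                           merge_threshold)
  mes <- module_eigengene(expr, labels)
  mm <- module_membership(expr, mes)
  conn <- intramodular_connectivity(adj, labels)
  own <- cbind(seq_len(nrow(conn)), match(conn$module, colnames(mm$kme)))
  kme_own <- mm$kme[own]
  kme_p_own <- mm$p[own]
  conn$kme <- kme_own
  conn$kme_p <- kme_p_own
  conn$hub <- identify_hubs(conn, kme_own, kme_p_own, hub_top_fraction,
                            hub_kme_min, hub_p_max)
  structure(list(beta = beta, adjacency = adj, tom = tom, labels = labels,
                 eigengenes = mes, genes = conn),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  sizes <- sort(table(x$labels), decreasing = TRUE)
  cat("Signed coexpression network (beta =", x$beta, "):",
      nrow(x$genes), "genes,", sum(names(sizes) != "grey"), "modules,",
      sum(x$genes$hub), "hubs\n")
  print(sizes)
  invisible(x)
}
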