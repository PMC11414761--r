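#' Additive gene-expression epistasis score
#'
#' With expression changes measured as log2 fold changes versus the common
#' ancestral reference, the additive (Fisher) null expects the double
#' mutant's change to equal the sum of the singles'; the per-gene epistatic
#' score is the deviation
#' \deqn{\epsilon_{exp} = GE_{xy} - (GE_x + GE_y)}
#'
#' @param ge_x,ge_y,ge_xy log2 fold changes of the two single mutants and
#'   the double mutant versus the ancestor (vectorized).
#' @return numeric vector of epistatic scores.
#' @export
epsilon_exp <- function(ge_x, ge_y, ge_xy) {
  ge_xy - (ge_x + ge_y)
}

#' Genome-wide standardization of epistatic scores
#'
#' Z-score of each gene's epistatic score against the distribution of scores
#' over all genes of the same double mutant.
#'
#' @param eps numeric vector of epistatic scores (>= 3 genes).
#' @return vector of z-scores (mean 0, sample SD 1).
#' @export
standardize_epsilon <- function(eps) {
  if (length(eps) < 3) stop("need >= 3 genes to standardize")
  s <- stats::sd(eps)
  if (s == 0) stop("zero genome-wide SD: cannot standardize")
  (eps - mean(eps)) / s
}

#' Assemble per-gene expression-epistasis records for one double mutant
#'
#' Merges the three mutant-versus-ancestor DE tables (rho single, rpoB
#' single, double mutant, all at the stressed temperature), computes the
#' additive epistatic score and its genome-wide z-score, and applies the two
#' significance tiers:
#' \itemize{
#'   \item tier A: differentially expressed (q < \code{q_threshold}) in at
#'     least one of the three contrasts;
#'   \item tier B: q < \code{q_threshold} AND |log2fc| > \code{lfc_threshold}
#'     in at least one contrast, AND |z| > \code{z_threshold}.
#' }
#' Genes missing a log2 fold change in any contrast are skipped (a message
#' reports how many); genes absent from a table only for the significance
#' columns are treated as non-significant in that contrast.
#'
#' @param de_x,de_y,de_xy DE record data.frames (columns \code{gene},
#'   \code{log2fc}, \code{q}) for the rho single, rpoB single and double
#'   mutant contrasts versus the ancestor.
#' @param double_id label for the double mutant.
#' @param q_threshold,lfc_threshold,z_threshold tier gates; defaults 0.001,
#'   2 and 2.
#' @return data.frame with \code{gene}, \code{double_id}, \code{ge_x},
#'   \code{ge_y}, \code{ge_xy}, \code{epsilon_exp}, \code{z},
#'   \code{tier_a}, \code{tier_b}.
#' @export
expression_epistasis <- function(de_x, de_y, de_xy, double_id = "double",
                                 q_threshold = 0.001, lfc_threshold = 2,
                                 z_threshold = 2) {
  genes <- Reduce(intersect, list(de_x$gene, de_y$gene, de_xy$gene))
  n_all <- length(unique(c(de_x$gene, de_y$gene, de_xy$gene)))
  if (length(genes) < n_all) {
    message(n_all - length(genes),
            " gene(s) missing from at least one contrast skipped (",
            double_id, ")")
  }
  if (length(genes) < 3) stop("fewer than 3 genes shared across contrasts")
  gx <- de_x[match(genes, de_x$gene), ]
  gy <- de_y[match(genes, de_y$gene), ]
  gxy <- de_xy[match(genes, de_xy$gene), ]
  eps <- epsilon_exp(gx$log2fc, gy$log2fc, gxy$log2fc)
  z <- standardize_epsilon(eps)
  rec <- data.frame(gene = genes, double_id = double_id,
                    ge_x = gx$log2fc, ge_y = gy$log2fc, ge_xy = gxy$log2fc,
                    epsilon_exp = eps, z = z, stringsAsFactors = FALSE)
  flags <- flag_significant(
    q = cbind(gx$q, gy$q, gxy$q),
    lfc = cbind(gx$log2fc, gy$log2fc, gxy$log2fc),
    z = z, q_threshold = q_threshold, lfc_threshold = lfc_threshold,
    z_threshold = z_threshold)
  rec$tier_a <- flags$tier_a
  rec$tier_b <- flags$tier_b
  rec
}

#' Two-tier significance flags for expression epistasis
#'
#' @param q matrix of q-values, one column per mutant-versus-ancestor
#'   contrast (NA = gene absent from that table, treated non-significant).
#' @param lfc matching matrix of log2 fold changes.
#' @param z genome-wide z-score per gene.
#' @param q_threshold,lfc_threshold,z_threshold gates (defaults 0.001, 2, 2).
#' @return list with logical vectors \code{tier_a} and \code{tier_b}.
#' @export
flag_significant <- function(q, lfc, z, q_threshold = 0.001,
                             lfc_threshold = 2, z_threshold = 2) {
  q <- as.matrix(q); lfc <- as.matrix(lfc)
  sig <- !is.na(q) & q < q_threshold
  tier_a <- rowSums(sig) > 0
  strong <- sig & abs(lfc) > lfc_threshold
  tier_b <- rowSums(strong) > 0 & abs(z) > z_threshold
  list(tier_a = tier_a, tier_b = unname(tier_b))
}

#' Sign-balance binomial test
#'
#' Two-sided exact binomial test of whether positively and negatively
#' epistatic genes are equally frequent among the qualifying set.
#'
#' @param eps epistatic scores of the qualifying genes, or pass counts
#'   directly via \code{n_pos}/\code{n_neg}.
#' @param n_pos,n_neg optional explicit counts.
#' @return list with \code{n_pos}, \code{n_neg}, \code{binomial_p} (NA with
#'   a \code{degenerate} flag when no gene qualifies).
#' @export
sign_balance <- function(eps = NULL, n_pos = NULL, n_neg = NULL) {
  if (is.null(n_pos)) {
    n_pos <- sum(eps > 0)
    n_neg <- sum(eps < 0)
  }
  n <- n_pos + n_neg
  if (n < 1) {
    return(list(n_pos = n_pos, n_neg = n_neg, binomial_p = NA_real_,
                degenerate = TRUE))
  }
  p <- stats::binom.test(n_pos, n, 0.5)$p.value
  list(n_pos = n_pos, n_neg = n_neg, binomial_p = p, degenerate = FALSE)
}

#' Distribution moments of epistatic scores
#'
#' Mean, median, Pearson skewness \eqn{\gamma_1 = m_3 / m_2^{3/2}} and
#' Pearson (non-excess) kurtosis \eqn{\gamma_2 = m_4 / m_2^2} with
#' population-style central moments (divisor n), plus a one-sample two-tailed
#' t-test of the mean against zero.
#'
#' @param eps numeric vector of epistatic scores (n >= 4, nonzero variance).
#' @param double_id label carried in the output.
#' @return list with \code{double_id}, \code{n}, \code{mean_eps},
#'   \code{median_eps}, \code{skewness}, \code{kurtosis}, \code{t_vs_zero},
#'   \code{p}.
#' @export
epistasis_moments <- function(eps, double_id = "double") {
  n <- length(eps)
  if (n < 4) stop("need n >= 4 for moments")
  m <- mean(eps)
  d <- eps - m
  m2 <- mean(d^2)
  if (m2 == 0) stop("zero variance: moments undefined")
  tt <- stats::t.test(eps)
  list(double_id = double_id, n = n, mean_eps = m,
       median_eps = stats::median(eps),
       skewness = mean(d^3) / m2^1.5,
       kurtosis = mean(d^4) / m2^2,
       t_vs_zero = unname(tt$statistic), p = tt$p.value)
}

#' Gene-set summary of expression epistasis
#'
#' Summarizes epistatic behavior inside a gene set (e.g. heat-shock,
#' stress-response or Rho-terminated genes): counts of significantly
#' epistatic members, positive/negative sign counts with a two-sided
#' binomial test, a two-sided Wilcoxon rank-sum test of in-set versus
#' out-of-set scores, a two-sided F-test of their variances, and the
#' fraction of the set that is differentially expressed (tier A).
#'
#' @param records data.frame from [expression_epistasis()].
#' @param gene_set character vector of gene names.
#' @param set_name label for the set.
#' @return list with \code{set_name}, \code{double_id}, \code{n_in_set},
#'   \code{n_sig_epistatic}, \code{n_pos}, \code{n_neg}, \code{binomial_p},
#'   \code{wilcoxon_p}, \code{f_test_p}, \code{de_fraction}. The Wilcoxon
#'   and F tests are NA when the out-of-set complement is empty.
#' @export
geneset_summary <- function(records, gene_set, set_name = "set") {
  inset <- records$gene %in% gene_set
  if (!any(inset)) stop("gene set '", set_name,
                        "' has empty intersection with the analysis universe")
  eps_in <- records$epsilon_exp[inset]
  eps_out <- records$epsilon_exp[!inset]
  sb <- sign_balance(eps_in)
  if (length(eps_out) >= 2 && length(eps_in) >= 2) {
    wp <- stats::wilcox.test(eps_in, eps_out, exact = length(records$gene) <= 50
                             )$p.value
    fp <- stats::var.test(eps_in, eps_out)$p.value
  } else {
    wp <- NA_real_; fp <- NA_real_
  }
  list(set_name = set_name, double_id = records$double_id[1],
       n_in_set = sum(inset), n_sig_epistatic = sum(records$tier_b[inset]),
       n_pos = sb$n_pos, n_neg = sb$n_neg, binomial_p = sb$binomial_p,
       wilcoxon_p = wp, f_test_p = fp,
       de_fraction = mean(records$tier_a[inset]))
}

#' Read a gene set file
#'
#' Accepts either a plain list (one gene per line) or GMT format (set name,
#' description, then members, tab-separated). A GMT file may hold several
#' sets; a named list is returned in that case.
#'
#' @param file path to the gene-set file.
#' @return character vector (plain list) or named list of character vectors
#'   (GMT).
#' @export
read_gene_set <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (!any(grepl("\t", lines))) return(trimws(lines))
  sets <- lapply(strsplit(lines, "\t"), function(f) {
    if (length(f) < 3) stop("malformed GMT line: ", paste(f, collapse = "\t"))
    stats::setNames(list(f[-(1:2)]), f[1])
  })
  do.call(c, sets)
}
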