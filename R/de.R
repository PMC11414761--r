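#' Median-of-ratios size factors
#'
#' Per-sample scale factors after the median-of-ratios method: each gene's
#' geometric mean across samples is a pseudo-reference; a sample's factor is
#' the median, over genes expressed in every sample, of its count divided by
#' the reference.
#'
#' @param counts numeric matrix of nonnegative counts, genes x samples.
#' @return named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no gene has nonzero counts in all samples")
  log_ref <- rowMeans(log(counts[pos, , drop = FALSE]))
  f <- apply(counts[pos, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - log_ref))
  })
  if (any(f <= 0)) stop("degenerate size factor")
  f
}

#' Normalize a count matrix by size factors
#'
#' @param counts genes x samples matrix.
#' @param factors per-sample positive factors (default: computed with
#'   [size_factors()]).
#' @return matrix of counts divided column-wise by the factors.
#' @export
normalize_counts <- function(counts, factors = size_factors(counts)) {
  counts <- as.matrix(counts)
  if (length(factors) != ncol(counts)) stop("one factor per sample required")
  if (any(factors <= 0)) stop("size factors must be positive")
  sweep(counts, 2, factors, "/")
}

#' Minimal per-gene differential-expression test
#'
#' A simple internal DE engine so the whole pipeline runs end-to-end on
#' synthetic data: per-gene Welch t-test on \code{log2(normalized + pseudo)}
#' with the log2 fold change defined as group-b mean minus group-a mean on
#' that scale, and Benjamini-Hochberg adjustment across the genes of the
#' contrast. For real data, externally produced DE tables can be supplied
#' through [ingest_de_table()] instead.
#'
#' Genes with zero counts in every sample of the contrast are dropped (a
#' message reports how many).
#'
#' @param normalized genes x samples normalized matrix with rownames.
#' @param group_a,group_b column names or indices of the two groups
#'   (>= 2 samples each). The fold change is b relative to a.
#' @param contrast_id label stored with each record.
#' @param pseudocount added before the log2 transform (default 1).
#' @return data.frame of DE records: \code{gene}, \code{contrast_id},
#'   \code{log2fc}, \code{p_raw}, \code{q}.
#' @export
simple_de <- function(normalized, group_a, group_b, contrast_id = "b_vs_a",
                      pseudocount = 1) {
  a <- as.matrix(normalized[, group_a, drop = FALSE])
  b <- as.matrix(normalized[, group_b, drop = FALSE])
  if (ncol(a) < 2 || ncol(b) < 2) stop("need >= 2 samples per group")
  keep <- rowSums(a) + rowSums(b) > 0
  if (any(!keep)) {
    message(sum(!keep), " gene(s) with all-zero counts dropped from contrast ",
            contrast_id)
    a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
  }
  la <- log2(a + pseudocount); lb <- log2(b + pseudocount)
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- apply(la, 1, stats::var); vb <- apply(lb, 1, stats::var)
  se2 <- va / na + vb / nb
  lfc <- mb - ma
  t_stat <- ifelse(se2 > 0, lfc / sqrt(se2), ifelse(lfc == 0, 0, Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)), 1)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(t_stat), df),
              ifelse(lfc == 0, 1, 0))
  data.frame(gene = rownames(a), contrast_id = contrast_id, log2fc = lfc,
             p_raw = p, q = stats::p.adjust(p, "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Ingest an externally produced differential-expression table
#'
#' Validates a TSV with columns \code{gene}, \code{log2fc}, \code{p},
#' \code{q} (e.g. exported from a dedicated DE engine) and returns records in
#' the internal schema.
#'
#' @param file path to the TSV.
#' @param contrast_id label for the contrast.
#' @param genes optional reference gene universe; genes in the file but
#'   absent from it are flagged in the \code{unknown_gene} column.
#' @return data.frame with \code{gene}, \code{contrast_id}, \code{log2fc},
#'   \code{p_raw}, \code{q}, \code{unknown_gene}.
#' @export
ingest_de_table <- function(file, contrast_id, genes = NULL) {
  x <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("gene", "log2fc", "p", "q")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("DE table ", file, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in c("log2fc", "p", "q")) {
    v <- x[[col]]
    if (is.character(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop("non-numeric ", col, " in ", file, " at data line(s) ",
             paste(bad, collapse = ", "))
      }
      x[[col]] <- num
    }
  }
  dup <- unique(x$gene[duplicated(x$gene)])
  if (length(dup)) {
    stop("duplicate gene(s) within contrast ", contrast_id, ": ",
         paste(dup, collapse = ", "))
  }
  out <- data.frame(gene = x$gene, contrast_id = contrast_id,
                    log2fc = x$log2fc, p_raw = x$p, q = x$q,
                    stringsAsFactors = FALSE)
  out$unknown_gene <- if (is.null(genes)) FALSE else !(out$gene %in% genes)
  if (any(out$unknown_gene)) {
    message(sum(out$unknown_gene), " gene(s) in ", file,
            " absent from the reference gene list")
  }
  out
}

#' Per-gene, per-genotype coefficient of variation
#'
#' CV = sample standard deviation / mean of normalized counts across the
#' replicates of each genotype. Genotypes with a single sample are excluded
#' with a warning; genes with zero mean in a genotype get NA.
#'
#' @param normalized genes x samples normalized matrix with rownames.
#' @param genotype genotype label per sample (length = ncol).
#' @return data.frame with \code{gene}, \code{genotype}, \code{cv}.
#' @export
expression_cv <- function(normalized, genotype) {
  normalized <- as.matrix(normalized)
  if (length(genotype) != ncol(normalized)) {
    stop("one genotype label per sample required")
  }
  tab <- table(genotype)
  drop <- names(tab)[tab < 2]
  if (length(drop)) {
    warning("genotype(s) with a single sample excluded: ",
            paste(drop, collapse = ", "))
  }
  keep <- setdiff(names(tab), drop)
  out <- do.call(rbind, lapply(keep, function(g) {
    m <- normalized[, genotype == g, drop = FALSE]
    mu <- rowMeans(m)
    sdev <- apply(m, 1, stats::sd)
    data.frame(gene = rownames(normalized), genotype = g,
               cv = ifelse(mu > 0, sdev / mu, NA_real_),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
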