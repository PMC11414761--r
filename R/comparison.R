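#' Read a protein-protein interaction edge list
#'
#' Expects TSV columns \code{gene_a}, \code{gene_b}, \code{confidence}.
#' Confidence on the common 0-1000 integer scale is auto-detected and
#' divided by 1000. Self-edges are removed; duplicate edges are collapsed to
#' their maximum confidence.
#'
#' @param file path to the edge-list TSV.
#' @return data.frame with \code{gene_a}, \code{gene_b}, \code{confidence}
#'   in \eqn{[0, 1]}.
#' @export
read_ppi <- function(file) {
  x <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "confidence")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("PPI edge list is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (is.character(x$confidence)) {
    suppressWarnings(num <- as.numeric(x$confidence))
    bad <- which(is.na(num) & !is.na(x$confidence))
    if (length(bad)) {
      stop("malformed confidence in ", file, " at data line(s) ",
           paste(bad, collapse = ", "))
    }
    x$confidence <- num
  }
  bad <- which(is.na(x$gene_a) | is.na(x$gene_b) | is.na(x$confidence) |
                 !nzchar(x$gene_a) | !nzchar(x$gene_b))
  if (length(bad)) {
    stop("malformed edge row(s) in ", file, " at data line(s) ",
         paste(bad, collapse = ", "))
  }
  if (max(x$confidence) > 1) x$confidence <- x$confidence / 1000
  x <- x[x$gene_a != x$gene_b, ]
  a <- pmin(x$gene_a, x$gene_b)
  b <- pmax(x$gene_a, x$gene_b)
  key <- paste(a, b, sep = "\r")
  conf <- tapply(x$confidence, key, max)
  parts <- strsplit(names(conf), "\r", fixed = TRUE)
  data.frame(gene_a = vapply(parts, `[`, "", 1),
             gene_b = vapply(parts, `[`, "", 2),
             confidence = unname(conf), stringsAsFactors = FALSE)
}

#' Node degrees in a confidence-filtered PPI network
#'
#' Degree = number of distinct interaction partners with confidence at or
#' above the cutoff. Genes in the universe that appear in no retained edge
#' get degree 0 (or are excluded with \code{include_missing = FALSE}).
#'
#' @param edges data.frame from [read_ppi()] (or with the same columns).
#' @param cutoff confidence cutoff in \eqn{[0, 1]} (default 0.9, the
#'   highest-confidence tier).
#' @param universe optional gene universe defining which absent genes count
#'   as degree 0.
#' @param include_missing whether universe genes absent from the retained
#'   edges are reported with degree 0 (default TRUE).
#' @return named integer vector of degrees.
#' @export
ppi_degrees <- function(edges, cutoff = 0.9, universe = NULL,
                        include_missing = TRUE) {
  if (cutoff < 0 || cutoff > 1) stop("cutoff must lie in [0, 1]")
  keep <- edges$confidence >= cutoff
  deg <- table(c(edges$gene_a[keep], edges$gene_b[keep]))
  out <- stats::setNames(as.integer(deg), names(deg))
  if (!is.null(universe)) {
    if (include_missing) {
      full <- stats::setNames(integer(length(universe)), universe)
      full[names(out)[names(out) %in% universe]] <-
        out[names(out) %in% universe]
      out <- full
    } else {
      out <- out[names(out) %in% universe]
    }
  }
  out
}

#' Compare connectivity between epistatic and non-epistatic genes
#'
#' Group means and medians of a connectivity measure (coexpression
#' \code{k_total} or PPI degree) for flagged versus unflagged genes, with a
#' two-sided Wilcoxon rank-sum test.
#'
#' @param values numeric connectivity per gene.
#' @param flags logical; TRUE = epistatic group.
#' @param labels group labels (flagged first).
#' @return list with per-group \code{mean}/\code{median}, \code{n} and
#'   \code{wilcoxon_p}.
#' @export
compare_connectivity <- function(values, flags,
                                 labels = c("epistatic", "non_epistatic")) {
  a <- values[flags]; b <- values[!flags]
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  p <- stats::wilcox.test(a, b)$p.value
  list(group_a_label = labels[1], group_b_label = labels[2],
       mean_a = mean(a), median_a = stats::median(a), n_a = length(a),
       mean_b = mean(b), median_b = stats::median(b), n_b = length(b),
       wilcoxon_p = p)
}

#' Hub enrichment of a gene set
#'
#' Two-sided Fisher exact test of the 2x2 table crossing set membership with
#' hub status over a gene universe.
#'
#' @param gene_set character vector of genes.
#' @param hub_flags named logical vector (names = the gene universe) or an
#'   unnamed vector aligned with \code{universe}.
#' @param universe gene universe (default: names of \code{hub_flags}).
#' @return list with the 2x2 \code{table}, \code{odds_ratio} and
#'   \code{fisher_p}.
#' @export
hub_enrichment <- function(gene_set, hub_flags,
                           universe = names(hub_flags)) {
  if (is.null(universe)) stop("a gene universe is required")
  gene_set <- intersect(gene_set, universe)
  if (!length(gene_set)) stop("gene set has empty intersection with universe")
  inset <- universe %in% gene_set
  hub <- as.logical(hub_flags)
  tab <- table(factor(inset, c(TRUE, FALSE)), factor(hub, c(TRUE, FALSE)),
               dnn = c("in_set", "hub"))
  ft <- stats::fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate), fisher_p = ft$p.value)
}

#' Map gene identifiers through an alias table
#'
#' Maps names through a two-column alias-to-canonical table (e.g. K-12 gene
#' names onto another strain's annotation). Conflicting duplicate aliases
#' are an error; unmapped names are returned separately, never silently
#' dropped.
#'
#' @param names character vector of gene names to map.
#' @param alias_table data.frame with columns \code{alias},
#'   \code{canonical}, or a path to such a TSV.
#' @return list with \code{mapped} (named character vector) and
#'   \code{unmapped} (character vector).
#' @export
map_gene_ids <- function(names, alias_table) {
  if (is.character(alias_table) && length(alias_table) == 1) {
    alias_table <- utils::read.delim(alias_table, stringsAsFactors = FALSE)
  }
  if (!all(c("alias", "canonical") %in% colnames(alias_table))) {
    stop("alias table needs columns alias, canonical")
  }
  tab <- unique(alias_table[c("alias", "canonical")])
  conflict <- unique(tab$alias[duplicated(tab$alias)])
  if (length(conflict)) {
    stop("conflicting alias(es): ", paste(conflict, collapse = ", "))
  }
  idx <- match(names, tab$alias)
  mapped <- stats::setNames(tab$canonical[idx], names)
  unmapped <- names[is.na(idx)]
  if (length(unmapped)) {
    message(length(unmapped), " name(s) could not be mapped")
  }
  list(mapped = mapped[!is.na(idx)], unmapped = unmapped)
}
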