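#' Classify evolutionary change in gene expression
#'
#' Classifies each gene's expression shift in a mutant into one of five
#' directions of evolutionary change relative to the ancestor's stress
#' response, from three DE contrasts: the ancestor's response to stress
#' (Anc42 vs Anc37), the mutant against the stressed ancestor
#' (Mut42 vs Anc42), and the mutant against the unstressed ancestor
#' (Mut42 vs Anc37). With significance meaning q < \code{q_threshold}:
#' \itemize{
#'   \item \strong{restored}: ancestral response significant, mutant
#'     significantly different from the stressed ancestor in the opposite
#'     direction to the ancestral response;
#'   \item \strong{reinforced}: both significant, same direction;
#'   \item \strong{novel}: ancestral response not significant but the mutant
#'     differs significantly from the ancestor at both temperatures;
#'   \item \strong{unrestored}: ancestral response significant, mutant not
#'     significantly different from the stressed ancestor;
#'   \item \strong{unclassified}: any remaining pattern (the four published
#'     definitions are not exhaustive).
#' }
#'
#' @param anc data.frame for the Anc42-vs-Anc37 contrast (columns
#'   \code{gene}, \code{log2fc}, \code{q}).
#' @param mut42 data.frame for Mut42-vs-Anc42.
#' @param mut37 data.frame for Mut42-vs-Anc37.
#' @param mutant_id label for the mutant.
#' @param q_threshold significance gate (default 0.001).
#' @return data.frame with \code{gene}, \code{mutant_id}, \code{category},
#'   \code{anc_direction}, \code{mut_direction}.
#' @export
classify_expression <- function(anc, mut42, mut37, mutant_id = "mutant",
                                q_threshold = 0.001) {
  for (nm in c("anc", "mut42", "mut37")) {
    d <- get(nm)
    if (is.null(d) || !all(c("gene", "log2fc", "q") %in% names(d))) {
      stop("missing or malformed contrast: ", nm)
    }
  }
  genes <- Reduce(intersect, list(anc$gene, mut42$gene, mut37$gene))
  a <- anc[match(genes, anc$gene), ]
  m42 <- mut42[match(genes, mut42$gene), ]
  m37 <- mut37[match(genes, mut37$gene), ]
  sig_a <- !is.na(a$q) & a$q < q_threshold
  sig_m42 <- !is.na(m42$q) & m42$q < q_threshold
  sig_m37 <- !is.na(m37$q) & m37$q < q_threshold
  dir_a <- sign(a$log2fc)
  dir_m <- sign(m42$log2fc)
  zero_dir <- (sig_a & dir_a == 0) | (sig_m42 & dir_m == 0)
  if (any(zero_dir)) {
    warning(sum(zero_dir),
            " gene(s) with exactly zero log2fc despite significance left",
            " unclassified")
  }
  category <- rep("unclassified", length(genes))
  restored <- sig_a & sig_m42 & dir_m == -dir_a & dir_a != 0 & dir_m != 0
  reinforced <- sig_a & sig_m42 & dir_m == dir_a & dir_a != 0 & dir_m != 0
  novel <- !sig_a & sig_m42 & sig_m37
  unrestored <- sig_a & !sig_m42
  category[unrestored] <- "unrestored"
  category[novel] <- "novel"
  category[reinforced] <- "reinforced"
  category[restored] <- "restored"
  category[zero_dir] <- "unclassified"
  data.frame(gene = genes, mutant_id = mutant_id, category = category,
             anc_direction = dir_a, mut_direction = dir_m,
             stringsAsFactors = FALSE)
}

#' Tabulate evolutionary-change calls across mutants
#'
#' Counts calls per mutant and category, and reports gene sets shared across
#' mutants for a chosen category (e.g. genes restored in every double
#' mutant).
#'
#' @param calls data.frame of calls from [classify_expression()], possibly
#'   concatenated over several mutants.
#' @param intersect_category category to intersect across mutants
#'   (default \code{"restored"}).
#' @param mutants mutants to intersect over (default: all present).
#' @return list with \code{counts} (mutant x category table) and
#'   \code{shared} (genes in \code{intersect_category} in every listed
#'   mutant) plus \code{shared_fraction} of the per-mutant mean.
#' @export
classification_table <- function(calls, intersect_category = "restored",
                                 mutants = unique(calls$mutant_id)) {
  lv <- c("restored", "unrestored", "reinforced", "novel", "unclassified")
  counts <- table(factor(calls$mutant_id, levels = mutants),
                  factor(calls$category, levels = lv))
  sets <- lapply(mutants, function(m) {
    calls$gene[calls$mutant_id == m & calls$category == intersect_category]
  })
  shared <- Reduce(intersect, sets)
  mean_size <- mean(lengths(sets))
  list(counts = counts, shared = shared,
       shared_fraction = if (mean_size > 0) length(shared) / mean_size else
         NA_real_)
}
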