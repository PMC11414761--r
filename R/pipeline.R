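#' Published-style epistasis estimates shipped with the package
#'
#' Per-pair epistatic deviations (with their variances and two-tailed
#' p-values) for eight E. coli rho + rpoB double mutants competed against
#' their common ancestor at 20.0, 37.0 and 42.2 degrees C, as printed in the
#' source study's per-pair results table. Useful as a worked example for the
#' pooled and cross-environment analyses, which operate on exactly this kind
#' of table.
#'
#' @return data.frame with \code{double_id}, \code{temperature},
#'   \code{epsilon}, \code{var_epsilon}, \code{p}.
#' @export
example_epistasis_estimates <- function() {
  utils::read.delim(system.file("extdata", "double_mutant_epistasis.tsv",
                                package = "dmepi"),
                    stringsAsFactors = FALSE)
}

#' Module summary counts shipped with the package
#'
#' Per-module gene counts from the source study's coexpression analysis of
#' 29 RNA-seq libraries: genes per module, genes under significant
#' expression epistasis, hub genes, and epistatic hub genes.
#'
#' @return data.frame with \code{module}, \code{n_genes},
#'   \code{n_epistatic}, \code{n_hubs}, \code{n_hub_epistatic}.
#' @export
example_module_counts <- function() {
  utils::read.delim(system.file("extdata", "module_summary.tsv",
                                package = "dmepi"),
                    stringsAsFactors = FALSE)
}

#' Module-level epistasis fractions
#'
#' Percentage arithmetic over per-module counts: the share of each module's
#' genes under significant expression epistasis and the share of its hub
#' genes under significant epistasis.
#'
#' @param counts data.frame as returned by [example_module_counts()].
#' @return the input with added \code{pct_epistatic},
#'   \code{pct_hub_epistatic} and \code{pct_of_network} columns
#'   (percentages).
#' @export
module_epistasis_summary <- function(counts = example_module_counts()) {
  counts$pct_epistatic <- 100 * counts$n_epistatic / counts$n_genes
  counts$pct_hub_epistatic <- 100 * counts$n_hub_epistatic / counts$n_hubs
  counts$pct_of_network <- 100 * counts$n_genes / sum(counts$n_genes)
  counts
}

#' Run the full analysis pipeline on a synthetic or file-based bundle
#'
#' Orchestrates the stages end-to-end: fitness estimation and fitness
#' epistasis from the competition assays; normalization, internal DE,
#' per-gene expression epistasis and evolutionary-change classification from
#' the count matrix; the coexpression-network stage; and the connectivity
#' comparison against the PPI edge list. Stages can be skipped. Every
#' result bundle carries the seed and a hash of the configuration.
#'
#' @param bundle input bundle from [simulate_bundle()], or a directory
#'   containing the equivalent plain-text files
#'   (\code{competition_assays.tsv}, \code{counts.tsv}, \code{samples.tsv},
#'   \code{pairing.tsv}, \code{ppi_edges.tsv}).
#' @param stages character vector of stages to run; any of
#'   \code{"fitness"}, \code{"expression"}, \code{"network"},
#'   \code{"comparison"}.
#' @param q_threshold,lfc_threshold,z_threshold significance gates
#'   (defaults 0.001, 2, 2).
#' @param beta soft-threshold power for the network stage (default 16).
#' @param min_module_size smallest retained module; default 30, reduce for
#'   small simulations.
#' @return list of class \code{"dmepi_result"} with one element per stage
#'   plus \code{seed} and \code{config_hash}.
#' @export
run_pipeline <- function(bundle,
                         stages = c("fitness", "expression", "network",
                                    "comparison"),
                         q_threshold = 0.001, lfc_threshold = 2,
                         z_threshold = 2, beta = 16, min_module_size = 30) {
  if (is.character(bundle) && length(bundle) == 1) {
    bundle <- read_bundle_dir(bundle)
  }
  cfg <- list(stages = stages, q_threshold = q_threshold,
              lfc_threshold = lfc_threshold, z_threshold = z_threshold,
              beta = beta, min_module_size = min_module_size,
              seed = bundle$seed)
  res <- list(seed = bundle$seed, config_hash = config_hash(cfg))
  run_stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if ("fitness" %in% stages) {
    res$fitness <- run_stage("fitness", {
      fit <- summarize_fitness(bundle$assays)
      eps <- epistasis_table(fit, bundle$pairing)
      pooled <- lapply(split(eps, eps$temperature),
                       function(g) pooled_epistasis(g$epsilon))
      anova <- epistasis_anova(eps$epsilon, eps$temperature)
      dr <- lapply(split(eps, eps$temperature), function(g) {
        allele <- bundle$pairing$rpoB_single_id[
          match(g$double_id, bundle$pairing$double_id)]
        diminishing_returns(g$w_x, g$w_xy, allele)
      })
      list(summary = fit, epistasis = eps, pooled = pooled, anova = anova,
           diminishing_returns = dr)
    })
  }
  de_ctx <- NULL
  if (any(c("expression", "network", "comparison") %in% stages)) {
    de_ctx <- run_stage("normalization", {
      sf <- size_factors(bundle$counts)
      norm <- normalize_counts(bundle$counts, sf)
      list(sf = sf, norm = norm)
    })
  }
  if ("expression" %in% stages) {
    res$expression <- run_stage("expression", {
      samp <- bundle$samples
      cols <- function(g, temp) samp$sample[samp$genotype == g &
                                              samp$temperature == temp]
      anc42 <- cols("ancestor", 42.2)
      anc37 <- cols("ancestor", 37.0)
      de_vs_anc42 <- function(g) {
        simple_de(de_ctx$norm, anc42, cols(g, 42.2),
                  paste0(g, "42_vs_anc42"))
      }
      de_anc <- simple_de(de_ctx$norm, anc37, anc42, "anc42_vs_anc37")
      records <- list(); calls <- list(); signs <- list()
      for (i in seq_len(nrow(bundle$pairing))) {
        p <- bundle$pairing[i, ]
        de_x <- de_vs_anc42(p$rho_single_id)
        de_y <- de_vs_anc42(p$rpoB_single_id)
        de_xy <- de_vs_anc42(p$double_id)
        rec <- expression_epistasis(de_x, de_y, de_xy, p$double_id,
                                    q_threshold, lfc_threshold, z_threshold)
        records[[p$double_id]] <- rec
        signs[[p$double_id]] <- sign_balance(rec$epsilon_exp[rec$tier_b])
        de_m37 <- simple_de(de_ctx$norm, anc37, cols(p$double_id, 42.2),
                            paste0(p$double_id, "42_vs_anc37"))
        calls[[p$double_id]] <- classify_expression(
          de_anc, de_xy, de_m37, p$double_id, q_threshold)
      }
      moments <- lapply(records, function(r)
        epistasis_moments(r$epsilon_exp, r$double_id[1]))
      cv <- expression_cv(de_ctx$norm,
                          bundle$samples$genotype[
                            match(colnames(de_ctx$norm),
                                  bundle$samples$sample)])
      list(records = records, sign_balance = signs, moments = moments,
           classification = classification_table(do.call(rbind, calls)),
           calls = do.call(rbind, calls), cv = cv)
    })
  }
  if ("network" %in% stages) {
    res$network <- run_stage("network", {
      expr <- transform_expression(de_ctx$norm)
      coexpression_network(expr, beta = beta,
                           min_module_size = min_module_size)
    })
  }
  if ("comparison" %in% stages) {
    res$comparison <- run_stage("comparison", {
      if (is.null(res$network) || is.null(res$expression)) {
        stop("comparison requires the network and expression stages")
      }
      genes <- res$network$genes
      epi <- Reduce(`|`, lapply(res$expression$records, function(r) {
        r$tier_b[match(genes$gene, r$gene)]
      }))
      epi[is.na(epi)] <- FALSE
      cmp_or_note <- function(values) {
        tryCatch(compare_connectivity(values, epi), error = function(e)
          list(note = paste("not-applicable:", conditionMessage(e))))
      }
      coexp <- cmp_or_note(genes$k_total)
      deg <- ppi_degrees(bundle$ppi, universe = genes$gene)
      ppi_cmp <- cmp_or_note(unname(deg[genes$gene]))
      hubs <- stats::setNames(genes$hub, genes$gene)
      enrich <- lapply(bundle$gene_sets, function(s) {
        tryCatch(hub_enrichment(s, hubs), error = function(e) NULL)
      })
      list(coexpression = coexp, ppi = ppi_cmp, hub_enrichment = enrich)
    })
  }
  class(res) <- "dmepi_result"
  res
}

# stable hash of the configuration list (md5 of its serialized text form)
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(names(unlist(cfg)), unlist(cfg), sep = "="), f)
  unname(tools::md5sum(f))
}

# read a plain-text bundle directory written by write_bundle()
read_bundle_dir <- function(dir) {
  path <- function(f) file.path(dir, f)
  counts <- utils::read.delim(path("counts.tsv"), check.names = FALSE)
  m <- as.matrix(counts[, -1])
  rownames(m) <- counts$gene
  sets <- list()
  for (f in list.files(dir, "^geneset_.*\\.txt$")) {
    sets[[sub("^geneset_(.*)\\.txt$", "\\1", f)]] <- readLines(path(f))
  }
  list(assays = read_competition_assays(path("competition_assays.tsv")),
       counts = m,
       samples = utils::read.delim(path("samples.tsv")),
       pairing = utils::read.delim(path("pairing.tsv")),
       ppi = read_ppi(path("ppi_edges.tsv")),
       gene_sets = sets,
       seed = NA_integer_)
}

#' Machine-readable summary of a pipeline run
#'
#' Collapses a result bundle into a JSON-ready summary: the per-pair
#' epistasis table, pooled statistics, cross-environment ANOVA, per-double
#' sign tests and tier counts, the module table and the connectivity
#' comparison. Writing the same completed bundle twice gives identical
#' output.
#'
#' @param result a \code{dmepi_result} from [run_pipeline()].
#' @param file optional path; when given the JSON is written there.
#' @return the summary list, invisibly when \code{file} is given.
#' @export
pipeline_report <- function(result, file = NULL) {
  out <- list(schema_version = "1.0", seed = result$seed,
              config_hash = result$config_hash)
  if (!is.null(result$fitness)) {
    out$epistasis <- result$fitness$epistasis
    out$pooled <- result$fitness$pooled
    out$anova <- result$fitness$anova
  }
  if (!is.null(result$expression)) {
    out$tier_counts <- lapply(result$expression$records, function(r) {
      list(tier_a = sum(r$tier_a), tier_b = sum(r$tier_b))
    })
    out$sign_tests <- lapply(result$expression$sign_balance, function(s) {
      if (isTRUE(s$degenerate)) "not-applicable" else s
    })
    out$classification_counts <-
      as.data.frame.matrix(result$expression$classification$counts)
  }
  if (!is.null(result$network)) {
    g <- result$network$genes
    out$modules <- do.call(rbind, lapply(
      split(g, g$module), function(m) data.frame(
        module = m$module[1], n_genes = nrow(m),
        n_hubs = sum(m$hub), mean_k_within = mean(m$k_within))))
  }
  if (!is.null(result$comparison)) out$connectivity <- result$comparison
  if (!is.null(file)) {
    jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    return(invisible(out))
  }
  out
}

#' @export
print.dmepi_result <- function(x, ...) {
  cat("dmepi pipeline result (seed", x$seed, ", config",
      substr(x$config_hash, 1, 8), ")\n")
  cat("stages:", paste(setdiff(names(x), c("seed", "config_hash")),
                       collapse = ", "), "\n")
  invisible(x)
}
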