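# Deterministic per-generator substream: each generator draws from a seed
# derived from (seed, stream name), so adding a generator to a pipeline does
# not shift the randomness of the others.
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 2654435761)
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Default study design for the simulators
#'
#' Genotype table mirroring the study layout: an ancestor assayed at 37.0
#' and 42.2 degrees C, four rho and two rpoB single mutants, and the six
#' double mutants combining the three sequenced rho alleles with both rpoB
#' alleles.
#'
#' @return data.frame with \code{genotype}, \code{type}
#'   (\code{ancestor}/\code{single_rho}/\code{single_rpoB}/\code{double}),
#'   \code{rho_parent}, \code{rpoB_parent}.
#' @export
default_design <- function() {
  rho <- c("rhoA43T", "rhoT231A", "rhoI15N", "rhoI15F")
  rpoB <- c("rpoBI572F", "rpoBI572L")
  doubles <- expand.grid(rho = rho[1:3], rpoB = rpoB,
                         stringsAsFactors = FALSE)
  data.frame(
    genotype = c("ancestor", rho, rpoB,
                 paste(doubles$rho, doubles$rpoB, sep = "_")),
    type = c("ancestor", rep("single_rho", 4), rep("single_rpoB", 2),
             rep("double", 6)),
    rho_parent = c(NA, rho, NA, NA, doubles$rho),
    rpoB_parent = c(NA, rep(NA, 4), rpoB, doubles$rpoB),
    stringsAsFactors = FALSE)
}

#' Simulate competition assays with known true fitness
#'
#' Emulates the serial-transfer competition protocol: the two competitors
#' are mixed 1:1 and plated (initial counts), the culture expands
#' \code{dilution}-fold net over one cycle, and is plated again (final
#' counts). Counts are Poisson around their expectations (plating noise);
#' the expected final mutant count follows the deterministic Malthusian
#' growth implied by the true relative fitness:
#' \eqn{E[N^f_{mut}] = E[N^i_{mut}] \cdot D^{w - 1}} with the ancestor's
#' expected counts unchanged across the cycle.
#'
#' @param truth data.frame with columns \code{genotype},
#'   \code{temperature}, \code{w} (true relative fitness > 0).
#' @param replicates assays per genotype x temperature (>= 2).
#' @param plating_mean expected initial colony count per competitor
#'   (default 30).
#' @param dilution net fold expansion per cycle (default 100).
#' @param noise \code{"poisson"} (default) or \code{"none"} (deterministic
#'   expected counts; the estimator then recovers the truth exactly).
#' @param seed integer seed.
#' @return list with \code{assays} (a competition-assay data.frame usable by
#'   [summarize_fitness()]) and \code{truth}.
#' @export
simulate_competition <- function(truth, replicates = 10, plating_mean = 30,
                                 dilution = 100, noise = c("poisson", "none"),
                                 seed = 1) {
  noise <- match.arg(noise)
  if (any(truth$w <= 0)) stop("true fitness must be positive")
  if (replicates < 2) stop("need >= 2 replicates")
  if (plating_mean <= 0) stop("plating mean must be positive")
  with_seed(substream_seed(seed, "competition"), {
    rows <- lapply(seq_len(nrow(truth)), function(i) {
      w <- truth$w[i]
      e_ni <- plating_mean
      e_nf_anc <- plating_mean
      e_nf_mut <- plating_mean * dilution^(w - 1)
      draw <- function(mu) {
        if (noise == "poisson") {
          pmax(stats::rpois(replicates, mu), 1)  # plates with 0 are recounted
        } else rep(mu, replicates)
      }
      data.frame(genotype = truth$genotype[i],
                 temperature = truth$temperature[i],
                 replicate = seq_len(replicates),
                 bio_replicate = rep(seq_len(2), length.out = replicates),
                 ni_mut = draw(e_ni), nf_mut = draw(e_nf_mut),
                 ni_anc = draw(e_ni), nf_anc = draw(e_nf_anc),
                 dilution = dilution, stringsAsFactors = FALSE)
    })
    list(assays = do.call(rbind, rows), truth = truth, seed = seed)
  })
}

#' Simulate an RNA-seq count matrix with planted effects
#'
#' Negative-binomial counts (mean mu, variance mu + dispersion * mu^2)
#' emulating the study's library design: the ancestor at the unstressed and
#' stressed temperatures, single and double mutants at the stressed
#' temperature, ~2 replicates each. Per-gene expectations combine a baseline
#' mean, the ancestral stress response (Anc42 vs Anc37 log2 fold change),
#' per-genotype planted log2 fold changes versus the stressed ancestor, and
#' a per-sample size factor. Double-mutant fold changes are additive in the
#' singles' plus a planted epistatic deviation:
#' \code{lfc_xy = lfc_x + lfc_y + eps}.
#'
#' @param n_genes number of genes (default 2000).
#' @param replicates replicates per genotype (default 2).
#' @param anc42_replicates replicates of the stressed ancestor (default 3,
#'   giving the study-scale 29 libraries at the defaults).
#' @param design genotype table from [default_design()].
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   baseline means (defaults log(500), 1, a typical bulk sequencing depth).
#' @param dispersion NB dispersion alpha (variance mu + alpha mu^2);
#'   0 gives Poisson counts. Default 0.02 (clonal replicate scale).
#' @param frac_heat fraction of genes with an ancestral stress response
#'   (default 0.2); their Anc42-vs-Anc37 lfc is drawn +/- \code{heat_lfc}.
#' @param heat_lfc magnitude of the ancestral stress response (default 3).
#' @param frac_de fraction of genes differentially expressed in each single
#'   mutant (default 0.1); their lfc is drawn +/- \code{de_lfc}.
#' @param de_lfc magnitude of single-mutant fold changes (default 3).
#' @param n_epistatic number of genes with planted expression epistasis per
#'   double mutant (default 100).
#' @param eps_magnitude planted |epsilon| (default 2; signs alternate).
#' @param size_factor_sdlog spread of the per-sample size factors
#'   (default 0.15).
#' @param n_modules number of block-correlated coexpression modules to
#'   plant (default 0 = independent genes given the genotype effects).
#' @param module_sdlog per-sample module-factor SD on the log2 scale
#'   (default 0.5; only used when \code{n_modules > 0}).
#' @param module_hubs designated hub genes per module (highest loading).
#' @param seed integer seed.
#' @return list with \code{counts} (genes x samples integer matrix),
#'   \code{samples} (sample sheet: sample, genotype, temperature,
#'   replicate), and \code{truth} (true_lfc gene x genotype matrix vs the
#'   stressed ancestor, true_heat_lfc, true_eps gene x double matrix,
#'   size_factors, and module/hub assignments when modules are planted).
#' @export
simulate_counts <- function(n_genes = 2000, replicates = 2,
                            anc42_replicates = 3, design = default_design(),
                            baseline_meanlog = log(500), baseline_sdlog = 1,
                            dispersion = 0.02, frac_heat = 0.2, heat_lfc = 3,
                            frac_de = 0.1, de_lfc = 3, n_epistatic = 100,
                            eps_magnitude = 2, size_factor_sdlog = 0.15,
                            n_modules = 0, module_sdlog = 0.5,
                            module_hubs = 3, seed = 1) {
  if (!"ancestor" %in% design$genotype) stop("design must include an ancestor")
  with_seed(substream_seed(seed, "counts"), {
    genes <- sprintf("g%04d", seq_len(n_genes))
    baseline <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
    # ancestral stress response (Anc42 relative to Anc37)
    heat <- numeric(n_genes)
    heat_idx <- sample.int(n_genes, round(frac_heat * n_genes))
    heat[heat_idx] <- sample(c(-1, 1), length(heat_idx), TRUE) * heat_lfc
    # per-genotype lfc vs the stressed ancestor
    singles <- design$genotype[design$type %in%
                                 c("single_rho", "single_rpoB")]
    doubles <- design$genotype[design$type == "double"]
    lfc <- matrix(0, n_genes, nrow(design),
                  dimnames = list(genes, design$genotype))
    for (g in singles) {
      idx <- sample.int(n_genes, round(frac_de * n_genes))
      # mutants predominantly push stress-responsive genes back, but any
      # gene can respond
      lfc[idx, g] <- sample(c(-1, 1), length(idx), TRUE) * de_lfc
      resp <- intersect(idx, heat_idx)
      lfc[resp, g] <- -sign(heat[resp]) * de_lfc
    }
    # choose the epistatic gene sets first: planted epistatic genes are
    # strong responders in their rho single (like the real flagellar and
    # heat-shock responders), so the stringent significance tier can see
    # them; all singles' fold changes are final before doubles are derived
    eps <- matrix(0, n_genes, length(doubles),
                  dimnames = list(genes, doubles))
    n_epistatic <- min(n_epistatic, n_genes)
    if (n_epistatic > 0) {
      for (d in doubles) {
        drow <- design[design$genotype == d, ]
        idx <- sample.int(n_genes, n_epistatic)
        eps[idx, d] <- rep_len(c(eps_magnitude, -eps_magnitude), n_epistatic)
        zero <- idx[lfc[idx, drow$rho_parent] == 0]
        lfc[zero, drow$rho_parent] <- de_lfc
      }
    }
    for (d in doubles) {
      drow <- design[design$genotype == d, ]
      lfc[, d] <- lfc[, drow$rho_parent] + lfc[, drow$rpoB_parent] + eps[, d]
    }
    # sample sheet
    samp <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
      g <- design$genotype[i]
      if (g == "ancestor") {
        rbind(
          data.frame(genotype = g, temperature = 37.0,
                     replicate = seq_len(replicates)),
          data.frame(genotype = g, temperature = 42.2,
                     replicate = seq_len(anc42_replicates)))
      } else {
        data.frame(genotype = g, temperature = 42.2,
                   replicate = seq_len(replicates))
      }
    }))
    samp$sample <- paste0(samp$genotype, "_", samp$temperature, "_r",
                          samp$replicate)
    samp <- samp[c("sample", "genotype", "temperature", "replicate")]
    sf <- stats::rlnorm(nrow(samp), 0, size_factor_sdlog)
    names(sf) <- samp$sample
    # optional block-correlated module structure: a per-sample latent
    # factor per module scales member genes on the log2 scale, with
    # designated hub genes getting the highest loadings
    module <- rep(NA_character_, n_genes)
    hub <- rep(FALSE, n_genes)
    loading <- numeric(n_genes)
    factors <- NULL
    if (n_modules > 0) {
      module <- paste0("block", rep_len(seq_len(n_modules), n_genes))
      for (m in unique(module)) {
        idx <- which(module == m)
        nh <- min(module_hubs, length(idx))
        loading[idx] <- stats::runif(length(idx), 0.5, 0.85)
        loading[idx[seq_len(nh)]] <- 0.95
        hub[idx[seq_len(nh)]] <- TRUE
      }
      factors <- matrix(stats::rnorm(n_modules * nrow(samp), 0,
                                     module_sdlog),
                        n_modules, nrow(samp),
                        dimnames = list(unique(module), samp$sample))
    }
    counts <- matrix(0L, n_genes, nrow(samp),
                     dimnames = list(genes, samp$sample))
    for (j in seq_len(nrow(samp))) {
      g <- samp$genotype[j]
      mu <- baseline * 2^(lfc[, g]) * sf[j]
      if (samp$temperature[j] < 42) mu <- baseline * 2^(-heat) * sf[j]
      if (n_modules > 0) mu <- mu * 2^(loading * factors[module, j])
      counts[, j] <- if (dispersion > 0) {
        stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
      } else stats::rpois(n_genes, mu)
    }
    list(counts = counts, samples = samp,
         truth = list(true_lfc = lfc, true_heat_lfc = heat, true_eps = eps,
                      size_factors = sf, baseline = baseline,
                      module = module, hub = hub, seed = seed))
  })
}

#' Simulate block-structured expression for network analysis
#'
#' Latent-factor model: each block (planted module) has an independent
#' standard-normal factor per sample; member genes are
#' \code{loading * factor + sqrt(1 - loading^2) * noise}. Designated hub
#' genes receive the highest loadings.
#'
#' @param block_sizes genes per block (each >= 2).
#' @param n_samples number of samples (default 30).
#' @param loading base loading in (0, 1] (default 0.9).
#' @param hub_loading loading of hub genes (default 0.98).
#' @param hubs_per_block designated hub genes per block (default 3).
#' @param n_noise_genes unstructured background genes (default 0).
#' @param seed integer seed.
#' @return list with \code{expr} (genes x samples), \code{truth}
#'   (block label and hub flag per gene).
#' @export
simulate_coexpression <- function(block_sizes = rep(50, 5), n_samples = 30,
                                  loading = 0.9, hub_loading = 0.98,
                                  hubs_per_block = 3, n_noise_genes = 0,
                                  seed = 1) {
  if (any(block_sizes < 2)) stop("block sizes must be >= 2")
  if (loading <= 0 || loading > 1 || hub_loading <= 0 || hub_loading > 1) {
    stop("loadings must lie in (0, 1]")
  }
  with_seed(substream_seed(seed, "coexpression"), {
    rows <- list(); labels <- character(0); hubs <- logical(0)
    for (b in seq_along(block_sizes)) {
      nb <- block_sizes[b]
      factor_b <- stats::rnorm(n_samples)
      nh <- min(hubs_per_block, nb)
      load <- c(rep(hub_loading, nh), rep(loading, nb - nh))
      block <- vapply(load, function(l) {
        l * factor_b + sqrt(1 - l^2) * stats::rnorm(n_samples)
      }, numeric(n_samples))
      rows[[b]] <- t(block)
      labels <- c(labels, rep(paste0("block", b), nb))
      hubs <- c(hubs, rep(c(TRUE, FALSE), c(nh, nb - nh)))
    }
    if (n_noise_genes > 0) {
      rows[[length(rows) + 1]] <-
        matrix(stats::rnorm(n_noise_genes * n_samples), n_noise_genes)
      labels <- c(labels, rep("noise", n_noise_genes))
      hubs <- c(hubs, rep(FALSE, n_noise_genes))
    }
    expr <- do.call(rbind, rows)
    rownames(expr) <- sprintf("g%04d", seq_len(nrow(expr)))
    colnames(expr) <- sprintf("s%02d", seq_len(n_samples))
    list(expr = expr,
         truth = data.frame(gene = rownames(expr), block = labels,
                            hub = hubs, stringsAsFactors = FALSE),
         seed = seed)
  })
}

#' Simulate a protein-protein interaction edge list
#'
#' Configuration-model graph over a requested degree sequence: stubs are
#' paired uniformly at random, self-loops and duplicate edges dropped.
#' Retained edges get confidences above the cutoff; optional decoy edges
#' below the cutoff are added. The truth records the degrees realized at the
#' cutoff.
#'
#' @param degrees named integer vector: intended degree per gene.
#' @param cutoff confidence cutoff used downstream (default 0.9).
#' @param n_decoy number of below-cutoff decoy edges (default 0).
#' @param seed integer seed.
#' @return list with \code{edges} (gene_a, gene_b, confidence) and
#'   \code{truth} (realized degree per gene at the cutoff).
#' @export
simulate_ppi <- function(degrees, cutoff = 0.9, n_decoy = 0, seed = 1) {
  if (is.null(names(degrees))) {
    names(degrees) <- sprintf("g%04d", seq_along(degrees))
  }
  with_seed(substream_seed(seed, "ppi"), {
    stubs <- rep(names(degrees), degrees)
    if (length(stubs) %% 2 == 1) {
      warning("odd degree sum; dropping one stub")
      stubs <- stubs[-length(stubs)]
    }
    # pair stubs, then repair self-loops and duplicate edges by random
    # double-edge swaps; offenders that resist repair are dropped
    s <- sample(stubs)
    a <- s[seq(1, length(s), 2)]
    b <- s[seq(2, length(s), 2)]
    offending <- function(a, b) {
      key <- paste(pmin(a, b), pmax(a, b))
      which(a == b | duplicated(key))
    }
    if (length(a) > 1) {
      for (iter in 1:5000) {
        bad <- offending(a, b)
        if (!length(bad)) break
        i <- bad[1]
        j <- sample(seq_along(a)[-i], 1)
        tmp <- b[i]; b[i] <- b[j]; b[j] <- tmp
      }
    }
    keep <- setdiff(seq_along(a), offending(a, b))
    lo <- pmin(a, b)[keep]; hi <- pmax(a, b)[keep]
    edges <- data.frame(gene_a = lo, gene_b = hi,
                        confidence = stats::runif(length(lo), cutoff, 1),
                        stringsAsFactors = FALSE)
    if (n_decoy > 0) {
      da <- sample(names(degrees), n_decoy, TRUE)
      db <- sample(names(degrees), n_decoy, TRUE)
      ok <- da != db
      edges <- rbind(edges, data.frame(
        gene_a = pmin(da[ok], db[ok]), gene_b = pmax(da[ok], db[ok]),
        confidence = stats::runif(sum(ok), 0, cutoff - 1e-9),
        stringsAsFactors = FALSE))
    }
    realized <- ppi_degrees(edges, cutoff, universe = names(degrees))
    list(edges = edges, truth = realized, seed = seed)
  })
}

#' Simulate gene-set files with configurable enrichment
#'
#' Draws a gene set of the requested size by weighted sampling without
#' replacement, with flagged genes (e.g. planted-epistatic or hub genes)
#' weighted by the enrichment odds.
#'
#' @param universe character vector of genes.
#' @param size set size.
#' @param flags logical vector over the universe (the trait to enrich for).
#' @param odds enrichment odds (1 = no enrichment).
#' @param seed integer seed.
#' @return list with \code{genes} (the set) and \code{truth} (odds used).
#' @export
simulate_gene_set <- function(universe, size, flags = NULL, odds = 1,
                              seed = 1) {
  if (size > length(universe)) stop("set size exceeds universe")
  if (odds <= 0) stop("enrichment odds must be positive")
  with_seed(substream_seed(seed, "genesets"), {
    w <- if (is.null(flags)) rep(1, length(universe)) else
      ifelse(flags, odds, 1)
    genes <- sample(universe, size, prob = w)
    list(genes = genes, truth = list(odds = odds), seed = seed)
  })
}

#' Simulate a complete synthetic input bundle
#'
#' Generates every input the pipeline consumes with one seed: competition
#' assays (with true fitness and hence true fitness epistasis), a count
#' matrix with planted expression effects, a PPI edge list and gene sets.
#' The default parameter values emulate the study scale: ~29 libraries, six
#' double mutants, three assay temperatures, ten fitness assays per
#' genotype and temperature.
#'
#' @param n_genes genes in the count matrix (default 2000).
#' @param replicates RNA-seq replicates per genotype (default 2, the study
#'   scale; use 4 for well-powered internal DE).
#' @param n_epistatic planted expression-epistatic genes per double mutant.
#' @param seed integer seed.
#' @param out_dir optional directory; when given, all inputs are written as
#'   plain-text files (TSV + truth JSON).
#' @return list with \code{assays}, \code{fitness_truth}, \code{counts},
#'   \code{samples}, \code{counts_truth}, \code{pairing}, \code{ppi},
#'   \code{gene_sets}, \code{seed}.
#' @export
simulate_bundle <- function(n_genes = 2000, replicates = 2,
                            n_epistatic = 100, seed = 1, out_dir = NULL) {
  design <- default_design()
  with_seed(substream_seed(seed, "fitness-truth"), {
    w_single <- stats::setNames(
      stats::runif(6, 1.05, 1.35),
      design$genotype[design$type %in% c("single_rho", "single_rpoB")])
    rows <- list()
    for (temp in c(20.0, 37.0, 42.2)) {
      shift <- c(`20` = -0.25, `37` = -0.15, `42.2` = 0)[as.character(temp)]
      for (g in design$genotype[design$type != "ancestor"]) {
        if (design$type[design$genotype == g] == "double") {
          drow <- design[design$genotype == g, ]
          wx <- w_single[drow$rho_parent] + shift
          wy <- w_single[drow$rpoB_parent] + shift
          eps_true <- if (temp > 42) -0.15 else -0.02
          w <- wx * wy + eps_true
        } else {
          w <- w_single[g] + shift
          eps_true <- NA_real_
        }
        rows[[length(rows) + 1]] <- data.frame(
          genotype = g, temperature = temp, w = unname(w),
          true_eps = eps_true, stringsAsFactors = FALSE)
      }
    }
    fitness_truth <- do.call(rbind, rows)
  })
  comp <- simulate_competition(fitness_truth[c("genotype", "temperature",
                                               "w")], seed = seed)
  cnt <- simulate_counts(n_genes = n_genes, replicates = replicates,
                         n_epistatic = n_epistatic, design = design,
                         n_modules = 5, seed = seed)
  doubles <- design[design$type == "double", ]
  pairing <- data.frame(double_id = doubles$genotype,
                        rho_single_id = doubles$rho_parent,
                        rpoB_single_id = doubles$rpoB_parent,
                        stringsAsFactors = FALSE)
  deg <- with_seed(substream_seed(seed, "ppi-degrees"), {
    d <- pmax(stats::rpois(n_genes, 4), 0)
    if (sum(d) %% 2 == 1) d[1] <- d[1] + 1  # even stub count
    stats::setNames(d, rownames(cnt$counts))
  })
  ppi <- simulate_ppi(deg, seed = seed)
  epi_flags <- rowSums(cnt$truth$true_eps != 0) > 0
  set_size <- min(150, floor(n_genes / 4))
  sets <- list(
    heat_shock = simulate_gene_set(rownames(cnt$counts), set_size,
                                   cnt$truth$true_heat_lfc != 0, odds = 5,
                                   seed = seed)$genes,
    rho_terminated = simulate_gene_set(rownames(cnt$counts),
                                       floor(0.2 * n_genes), epi_flags,
                                       odds = 1, seed = seed + 1)$genes)
  bundle <- list(assays = comp$assays, fitness_truth = fitness_truth,
                 counts = cnt$counts, samples = cnt$samples,
                 counts_truth = cnt$truth, pairing = pairing,
                 ppi = ppi$edges, ppi_truth = ppi$truth,
                 gene_sets = sets, seed = seed)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

# plain-text export of a synthetic bundle
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(bundle$assays, "competition_assays.tsv")
  counts <- data.frame(gene = rownames(bundle$counts), bundle$counts,
                       check.names = FALSE)
  wt(counts, "counts.tsv")
  wt(bundle$samples, "samples.tsv")
  wt(bundle$pairing, "pairing.tsv")
  wt(bundle$ppi, "ppi_edges.tsv")
  for (nm in names(bundle$gene_sets)) {
    writeLines(bundle$gene_sets[[nm]],
               file.path(out_dir, paste0("geneset_", nm, ".txt")))
  }
  truth <- list(seed = bundle$seed,
                fitness = bundle$fitness_truth,
                eps_genes = colnames(bundle$counts_truth$true_eps),
                ppi_degrees = as.list(bundle$ppi_truth))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
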