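test_that("generators are pure functions of config and seed", {
  truth <- data.frame(genotype = "m", temperature = 42.2, w = 1.2)
  a <- simulate_competition(truth, seed = 5)
  b <- simulate_competition(truth, seed = 5)
  expect_identical(a$assays, b$assays)
  c1 <- simulate_counts(n_genes = 100, seed = 5)
  c2 <- simulate_counts(n_genes = 100, seed = 5)
  expect_identical(c1$counts, c2$counts)
  e1 <- simulate_coexpression(block_sizes = c(10, 10), seed = 5)
  e2 <- simulate_coexpression(block_sizes = c(10, 10), seed = 5)
  expect_identical(e1$expr, e2$expr)
  p1 <- simulate_ppi(stats::setNames(rep(2, 6), paste0("g", 1:6)), seed = 5)
  p2 <- simulate_ppi(stats::setNames(rep(2, 6), paste0("g", 1:6)), seed = 5)
  expect_identical(p1$edges, p2$edges)
  s1 <- simulate_gene_set(paste0("g", 1:50), 10, seed = 5)
  s2 <- simulate_gene_set(paste0("g", 1:50), 10, seed = 5)
  expect_identical(s1$genes, s2$genes)
})

test_that("noise-free competition assays round-trip the true fitness", {
  truth <- data.frame(genotype = "m", temperature = 42.2, w = 1.2)
  sim <- simulate_competition(truth, noise = "none", seed = 1)
  w <- relative_fitness(sim$assays$ni_mut, sim$assays$nf_mut,
                        sim$assays$ni_anc, sim$assays$nf_anc,
                        sim$assays$dilution)
  expect_equal(w, rep(1.2, nrow(sim$assays)), tolerance = 1e-12)
})

test_that("neutral truth is estimated without bias", {
  sim <- simulate_competition(
    data.frame(genotype = "m", temperature = 37, w = 1.0),
    replicates = 100, seed = 2)
  s <- summarize_fitness(sim$assays)
  expect_lt(abs(s$w_bar - 1.0), 2 * sqrt(s$variance))
})

test_that("fitness estimates tighten with more replicates", {
  spread <- vapply(c(5, 20, 80), function(n) {
    ests <- vapply(1:30, function(seed) {
      sim <- simulate_competition(
        data.frame(genotype = "m", temperature = 42.2, w = 1.15),
        replicates = n, seed = seed)
      summarize_fitness(sim$assays)$w_bar
    }, numeric(1))
    stats::sd(ests)
  }, numeric(1))
  expect_true(all(diff(spread) < 0))
})

test_that("planted count effects obey the declared truth model", {
  cnt <- simulate_counts(n_genes = 300, replicates = 3, seed = 6)
  tr <- cnt$truth
  des <- default_design()
  for (d in des$genotype[des$type == "double"]) {
    row <- des[des$genotype == d, ]
    expect_equal(tr$true_lfc[, d],
                 tr$true_lfc[, row$rho_parent] +
                   tr$true_lfc[, row$rpoB_parent] + tr$true_eps[, d])
  }
  # the default design yields the study-scale 29 libraries
  cnt29 <- simulate_counts(n_genes = 50, seed = 6)
  expect_equal(nrow(cnt29$samples), 29)
})

test_that("Poisson-mode counts realize planted fold changes", {
  des <- default_design()
  cnt <- simulate_counts(n_genes = 2000, replicates = 3, dispersion = 0,
                         baseline_meanlog = log(1000), baseline_sdlog = 0,
                         frac_heat = 0, frac_de = 0.5, de_lfc = 1,
                         n_epistatic = 0, size_factor_sdlog = 0, seed = 7)
  g <- "rhoA43T"
  up <- cnt$truth$true_lfc[, g] == 1
  anc <- cnt$samples$sample[cnt$samples$genotype == "ancestor" &
                              cnt$samples$temperature == 42.2]
  mut <- cnt$samples$sample[cnt$samples$genotype == g]
  ratio <- mean(cnt$counts[up, mut]) / mean(cnt$counts[up, anc])
  expect_equal(ratio, 2, tolerance = 0.05)
})

test_that("planted count modules induce block correlation", {
  cnt <- simulate_counts(n_genes = 300, replicates = 2, n_modules = 5,
                         n_epistatic = 0, frac_de = 0, frac_heat = 0,
                         seed = 1)
  x <- transform_expression(normalize_counts(cnt$counts))
  cm <- stats::cor(t(x))
  mod <- cnt$truth$module[match(rownames(x), rownames(cnt$counts))]
  same <- outer(mod, mod, "==")
  within <- mean(cm[same & upper.tri(cm)])
  between <- mean(cm[!same & upper.tri(cm)])
  expect_gt(within, between + 0.3)
  expect_equal(sum(cnt$truth$hub), 15)
})

test_that("coexpression blocks have the prescribed correlation structure", {
  one <- simulate_coexpression(block_sizes = 5, loading = 1,
                               hub_loading = 1, n_samples = 12, seed = 8)
  expect_equal(min(stats::cor(t(one$expr))), 1, tolerance = 1e-12)
  expect_error(simulate_coexpression(block_sizes = c(5, 1)), ">= 2")
  expect_error(simulate_coexpression(block_sizes = 5, loading = 1.2),
               "loadings")
})

test_that("the configuration model realizes requested degree structure", {
  star <- simulate_ppi(stats::setNames(c(10, rep(1, 10)),
                                       c("hub", paste0("leaf", 1:10))),
                       seed = 9)
  deg <- ppi_degrees(star$edges, 0.9)
  expect_equal(unname(deg["hub"]), 10L)
  # realized degrees recorded as truth match an independent recount
  expect_equal(star$truth,
               ppi_degrees(star$edges, 0.9, universe = names(star$truth)))
  expect_warning(simulate_ppi(stats::setNames(c(2, 1), c("a", "b")),
                              seed = 9), "odd degree sum")
})

test_that("gene-set enrichment odds shift the sampled composition", {
  universe <- paste0("g", 1:2000)
  flags <- rep(c(TRUE, FALSE), c(200, 1800))
  enriched <- simulate_gene_set(universe, 200, flags, odds = 5, seed = 10)
  neutral <- simulate_gene_set(universe, 200, flags, odds = 1, seed = 10)
  frac_e <- mean(enriched$genes %in% universe[flags])
  frac_n <- mean(neutral$genes %in% universe[flags])
  expect_gt(frac_e, frac_n)
  expect_error(simulate_gene_set(universe, 3000), "exceeds")
})

test_that("bundles are written as a complete plain-text directory", {
  dir <- file.path(tempdir(), "bundle-test")
  b <- simulate_bundle(n_genes = 60, seed = 3, out_dir = dir)
  files <- list.files(dir)
  expect_true(all(c("competition_assays.tsv", "counts.tsv", "samples.tsv",
                    "pairing.tsv", "ppi_edges.tsv", "truth.json") %in% files))
  back <- utils::read.delim(file.path(dir, "counts.tsv"), check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), b$counts, ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})
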