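test_that("expression transform keeps only variable genes", {
  m <- rbind(g1 = c(1, 2, 3, 4), g2 = rep(5, 4), g3 = c(10, 0, 7, 3))
  colnames(m) <- paste0("s", 1:4)
  expect_message(x <- transform_expression(m), "zero-variance")
  expect_equal(rownames(x), c("g1", "g3"))
  expect_equal(x[1, ], log2(m[1, ] + 1))
  expect_error(transform_expression(matrix(5, 3, 4)), "no variable genes")
  expect_error(transform_expression(m[, 1:2]), ">= 3 samples")
})

test_that("signed adjacency maps correlation through the soft power", {
  s <- 1:10
  expr <- rbind(a = s, b = 2 * s + 3, c = -s,
                d = c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
  adj <- signed_adjacency(expr, beta = 16)
  expect_equal(adj["a", "b"], 1)           # cor = +1
  expect_equal(adj["a", "c"], 0)           # cor = -1
  expect_equal(diag(adj), rep(0, 4), ignore_attr = TRUE)
  # closed form at zero correlation: (1/2)^beta
  orth <- rbind(x = c(1, -1, 1, -1, 1, -1), y = c(1, 1, -1, -1, 1, 1))
  expect_equal(signed_adjacency(orth, 16)["x", "y"], 2^-16,
               tolerance = 1e-18)
  # monotone in correlation
  set.seed(51)
  base <- stats::rnorm(30)
  expr2 <- rbind(g1 = base,
                 g2 = base + stats::rnorm(30, 0, 0.1),
                 g3 = base + stats::rnorm(30, 0, 1),
                 g4 = stats::rnorm(30))
  a2 <- signed_adjacency(expr2, 6)
  expect_true(a2["g1", "g2"] > a2["g1", "g3"])
  expect_true(a2["g1", "g3"] > a2["g1", "g4"])
})

test_that("topological overlap matches hand and brute-force oracles", {
  a3 <- matrix(0.5, 3, 3); diag(a3) <- 0
  tom3 <- topological_overlap(a3)
  expect_equal(tom3[1, 2], (0.25 + 0.5) / (1 + 1 - 0.5))
  expect_equal(diag(tom3), rep(1, 3))
  zero <- matrix(0, 4, 4)
  expect_equal(topological_overlap(zero) - diag(4), matrix(0, 4, 4))
  set.seed(52)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    a <- matrix(stats::runif(n * n), n)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    expect_equal(topological_overlap(a), tom_brute(a), tolerance = 1e-12)
  }
  bad <- matrix(stats::runif(16), 4)
  expect_error(topological_overlap(bad), "symmetric")
})

test_that("TOM stays within [0, 1] on random adjacencies", {
  set.seed(53)
  for (i in 1:10) {
    a <- matrix(stats::runif(64), 8)
    a <- (a + t(a)) / 2; diag(a) <- 0
    tom <- topological_overlap(a)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
})

test_that("soft-threshold selection prefers the smallest passing power", {
  sim <- simulate_coexpression(block_sizes = c(60, 50, 40), loading = 0.9,
                               n_samples = 40, seed = 7)
  pick <- pick_soft_threshold(sim$expr, powers = c(2, 4, 6, 8, 10))
  tab <- pick$fit_table
  passing <- tab$power[!is.na(tab$rsq_signed) & tab$rsq_signed >= 0.8]
  if (length(passing)) expect_equal(pick$beta, min(passing))
  expect_true(pick$beta %in% tab$power)
  # white noise cannot produce a scale-free fit; fall back with a warning
  set.seed(54)
  noise <- matrix(stats::rnorm(20 * 10), 20)
  res <- tryCatch(pick_soft_threshold(noise, powers = c(2, 4)),
                  warning = function(w) list(warned = TRUE))
  expect_true(isTRUE(res$warned) || res$beta %in% c(2, 4))
})

test_that("planted blocks are recovered as modules", {
  sim <- simulate_coexpression(block_sizes = c(50, 50), loading = 0.97,
                               n_samples = 40, seed = 8)
  adj <- signed_adjacency(sim$expr, 6)
  tom <- topological_overlap(adj)
  labels <- detect_modules(tom, sim$expr, min_module_size = 30)
  expect_equal(sum(labels == "grey"), 0)
  expect_equal(length(unique(labels)), 2)
  expect_equal(unname(sort(table(labels), decreasing = TRUE))[1], 50)
  # planted 5-block structure: near-perfect agreement with the truth
  for (seed in 1:2) {
    sim5 <- simulate_coexpression(block_sizes = rep(40, 5), loading = 0.9,
                                  n_samples = 30, seed = seed)
    adj5 <- signed_adjacency(sim5$expr, 16)
    labels5 <- detect_modules(topological_overlap(adj5), sim5$expr,
                              min_module_size = 20)
    expect_gte(ari(labels5, sim5$truth$block), 0.9)
  }
})

test_that("a homogeneous block forms a single module", {
  sim <- simulate_coexpression(block_sizes = 60, loading = 0.95,
                               n_samples = 30, seed = 9)
  adj <- signed_adjacency(sim$expr, 6)
  labels <- detect_modules(topological_overlap(adj), sim$expr,
                           min_module_size = 30)
  expect_equal(unique(labels), "turquoise")
})

test_that("eigengenes summarize and orient module expression", {
  s <- seq_len(12)
  prof <- sin(s)
  expr <- rbind(g1 = prof, g2 = prof, g3 = prof)
  me <- module_eigengene(expr, rep("m", 3))
  expect_equal(abs(stats::cor(me["m", ], prof)), 1, tolerance = 1e-12)
  expect_gt(stats::cor(me["m", ], prof), 0)  # orientation
  expect_equal(stats::sd(me["m", ]), 1, tolerance = 1e-12)
  # flipping every member flips nothing observable after orientation
  me_flip <- module_eigengene(-expr, rep("m", 3))
  expect_equal(abs(stats::cor(me["m", ], me_flip["m", ])), 1,
               tolerance = 1e-12)
  two <- rbind(a = prof, b = 3 * prof + 2)
  me2 <- module_eigengene(two, c("m", "m"))
  expect_equal(stats::cor(me2["m", ], two["a", ]), 1, tolerance = 1e-12)
})

test_that("eigengene captures the leading variance direction", {
  set.seed(55)
  sim <- simulate_coexpression(block_sizes = 12, n_samples = 25, seed = 10)
  expr <- sim$expr
  me <- module_eigengene(expr, rep("m", nrow(expr)))["m", ]
  zs <- t(scale(t(expr)))
  sv <- svd(zs)
  # the top singular vector explains the most variance among unit vectors;
  # the eigengene must match it up to sign
  expect_equal(abs(stats::cor(me, sv$v[, 1])), 1, tolerance = 1e-10)
})

test_that("module membership follows the correlation t-test", {
  set.seed(56)
  expr <- matrix(stats::rnorm(5 * 29), 5, 29,
                 dimnames = list(paste0("g", 1:5), NULL))
  me <- rbind(m = expr[1, ])
  mm <- module_membership(expr, me)
  expect_equal(mm$kme["g1", "m"], 1)
  expect_lt(mm$p["g1", "m"], 1e-20)
  # closed form at n = 29, r = 0.9: t = 0.9 sqrt(27) / sqrt(0.19)
  t_expected <- 0.9 * sqrt(27) / sqrt(1 - 0.81)
  p_expected <- 2 * stats::pt(-t_expected, 27)
  r <- 0.9
  t_back <- r * sqrt(27) / sqrt(1 - r^2)
  expect_equal(t_back, 10.73, tolerance = 0.01)
  expect_lt(p_expected, 0.01)
})

test_that("connectivity splits into within- and total-module sums", {
  set.seed(57)
  a <- matrix(stats::runif(36), 6); a <- (a + t(a)) / 2; diag(a) <- 0
  rownames(a) <- colnames(a) <- paste0("g", 1:6)
  labels <- c("m1", "m1", "m1", "m2", "m2", "grey")
  conn <- intramodular_connectivity(a, labels)
  expect_equal(conn$k_total, unname(rowSums(a)))
  expect_equal(conn$k_within[1], sum(a[1, 2:3]))
  expect_equal(conn$k_within[6], 0)  # singleton grey
  expect_true(all(conn$k_within <= conn$k_total + 1e-12))
  expect_equal(intramodular_connectivity(matrix(0, 3, 3),
                                         rep("m", 3))$k_total, rep(0, 3))
})

test_that("hub rules enforce the strict membership boundary", {
  conn <- data.frame(gene = paste0("g", 1:20), module = "m1",
                     k_within = 20:1, k_total = 20:1)
  kme <- c(0.9, rep(0.95, 19))     # top gene sits exactly on the boundary
  p <- rep(1e-4, 20)
  hubs <- identify_hubs(conn, kme, p)
  expect_false(hubs[1])            # kME = 0.9 exactly is not a hub
  expect_true(hubs[2])             # next best k passes
  expect_equal(sum(hubs), 1)       # only the top decile qualifies
  # no gene above the membership bar: zero hubs
  expect_equal(sum(identify_hubs(conn, rep(0.85, 20), p)), 0)
  # grey genes are never hubs
  conn$module <- "grey"
  expect_equal(sum(identify_hubs(conn, rep(0.99, 20), p)), 0)
})

test_that("hub flags are invariant to gene order", {
  set.seed(58)
  conn <- data.frame(gene = paste0("g", 1:30),
                     module = rep(c("m1", "m2"), 15),
                     k_within = stats::runif(30, 0, 10),
                     k_total = stats::runif(30, 10, 20))
  kme <- stats::runif(30, 0.85, 1)
  p <- stats::runif(30, 0, 0.02)
  hubs <- identify_hubs(conn, kme, p)
  perm <- sample(30)
  hubs_perm <- identify_hubs(conn[perm, ], kme[perm], p[perm])
  expect_equal(hubs_perm, hubs[perm])
})

test_that("planted hub genes are preferentially flagged", {
  sim <- simulate_coexpression(block_sizes = rep(40, 3), loading = 0.85,
                               hub_loading = 0.99, hubs_per_block = 3,
                               n_samples = 30, seed = 11)
  net <- coexpression_network(sim$expr, beta = 6, min_module_size = 20)
  found <- net$genes$gene[net$genes$hub]
  planted <- sim$truth$gene[sim$truth$hub]
  expect_gte(mean(planted %in% found), 0.8)
})

test_that("module-trait association recovers exact relationships", {
  sim <- simulate_coexpression(block_sizes = c(40, 40), n_samples = 25,
                               seed = 12)
  net <- coexpression_network(sim$expr, beta = 6, min_module_size = 20)
  me <- net$eigengenes
  assoc <- module_trait_association(me, me[1, ])
  expect_equal(assoc$cor[assoc$module == rownames(me)[1]], 1,
               tolerance = 1e-10)
  assoc_neg <- module_trait_association(me, -me[1, ])
  expect_equal(assoc_neg$cor[assoc_neg$module == rownames(me)[1]], -1,
               tolerance = 1e-10)
  expect_warning(res <- module_trait_association(me, rep(2, 25)),
                 "constant trait")
  expect_true(all(is.na(res$cor)))
})

test_that("eigengene merging collapses highly correlated modules", {
  # two blocks driven by nearly the same factor should merge into one
  set.seed(59)
  f <- stats::rnorm(30)
  mk_block <- function(n) t(vapply(seq_len(n), function(i)
    0.95 * f + sqrt(1 - 0.95^2) * stats::rnorm(30), numeric(30)))
  expr <- rbind(mk_block(40), mk_block(40))
  rownames(expr) <- paste0("g", 1:80)
  adj <- signed_adjacency(expr, 6)
  labels <- detect_modules(topological_overlap(adj), expr,
                           min_module_size = 20, merge_threshold = 0.75)
  expect_equal(length(setdiff(unique(labels), "grey")), 1)
})
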