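test_that("pairwise correlation matches the nested-loop oracle and flags constants", {
  x <- rand_expression(20, 10, seed = 31)
  cm <- pairwise_correlation(x)
  expect_lt(max(abs(cm - oracle_correlation(x))), 1e-12)
  expect_identical(unname(diag(cm)), rep(1, 20))
  expect_lt(max(abs(cm - t(cm))), 1e-12)

  x2 <- rbind(x, dup = x[1, ], neg = -x[2, ])
  cm2 <- pairwise_correlation(x2)
  expect_equal(cm2["dup", "g1"], 1, tolerance = 1e-12)
  expect_equal(cm2["neg", "g2"], -1, tolerance = 1e-12)

  x3 <- x; x3[5, ] <- 2
  expect_error(pairwise_correlation(x3), "g5")
})

test_that("invariant-gene filter removes pooled and per-condition constants", {
  x <- rand_expression(6, 12, seed = 7)
  x[2, ] <- 3
  ph <- two_group_phenotype(6, 6)
  x[4, 1:6] <- 1  # constant in normal only
  expect_message(res <- filter_invariant_genes(x, ph), "removed 2")
  expect_setequal(res$removed, c("g2", "g4"))
  expect_identical(nrow(res$expression), 4L)

  clean <- rand_expression(5, 8, seed = 8)
  expect_identical(filter_invariant_genes(clean)$expression, clean)

  allbad <- matrix(1, 2, 4, dimnames = list(c("a", "b"), paste0("s", 1:4)))
  expect_error(filter_invariant_genes(allbad), "all genes")
})

test_that("adjacency implements |r|^beta with zero diagonal", {
  x <- rand_expression(8, 15, seed = 12)
  cm <- pairwise_correlation(x)
  a1 <- adjacency(x, 1)
  expect_equal(a1[2, 5], abs(cm[2, 5]), tolerance = 1e-12)
  expect_identical(unname(diag(a1)), rep(0, 8))
  a6 <- adjacency(x, 6)
  expect_equal(a6[3, 7], abs(cm[3, 7])^6, tolerance = 1e-12)
  # 0.5^6 spot value
  cm_fixed <- diag(2); cm_fixed[1, 2] <- cm_fixed[2, 1] <- 0.5
  a_fixed <- abs(cm_fixed)^6; diag(a_fixed) <- 0
  expect_equal(a_fixed[1, 2], 0.015625)
  expect_error(adjacency(x, 0.5), "power")
})

test_that("TOM matches the triple-loop oracle on random instances", {
  for (seed in 1:5) {
    set.seed(seed)
    a <- matrix(runif(64, 0, 0.9), 8, 8)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    dimnames(a) <- list(paste0("g", 1:8), paste0("g", 1:8))
    tom <- topological_overlap(a)
    orc <- oracle_tom(a)
    expect_lt(max(abs(tom[upper.tri(tom)] - orc[upper.tri(orc)])), 1e-12)
    expect_true(all(tom >= 0 & tom <= 1))
  }
})

test_that("TOM limits: complete graph gives 1, empty graph gives 0", {
  n <- 6
  ones <- matrix(1, n, n); diag(ones) <- 0
  dimnames(ones) <- list(paste0("g", 1:n), paste0("g", 1:n))
  tom1 <- topological_overlap(ones)
  expect_equal(unname(tom1[1, 2]), 1, tolerance = 1e-12)
  zeros <- matrix(0, n, n, dimnames = dimnames(ones))
  tom0 <- topological_overlap(zeros)  # denominator min(k)+1-a = 1: defined, 0
  expect_identical(unname(tom0[1, 2]), 0)
  expect_identical(unname(diag(tom0)), rep(1, n))
})

test_that("scale-free fit index is high for planted power-law data and the selector picks the generating power", {
  sf <- simulate_scale_free(n_genes = 600, power = 6)
  st <- pick_soft_threshold(sf$expression, powers = 1:8)
  expect_gte(tidy(st)$r_squared[tidy(st)$power == 6], 0.95)
  expect_identical(chosen_power(st), 6L)
  # powers below the generating one must fail the criterion
  expect_true(all(tidy(st)$r_squared[tidy(st)$power < 6] < 0.8))
})

test_that("independent noise takes the warning path and duplicates are deduplicated", {
  x <- rand_expression(300, 40, seed = 17)
  expect_warning(st <- pick_soft_threshold(x, powers = c(2, 2, 4, 6)), "no candidate")
  expect_identical(nrow(st), 3L)
  expect_true(all(tidy(st)$r_squared < 0.8))
  expect_true(chosen_power(st) %in% c(2L, 4L, 6L))
})

test_that("module detection recovers perfectly separated planted blocks", {
  cfg <- sim_config(n_genes = 100, n_samples_a = 150, n_samples_b = 150,
                    module_sizes = c(40, 35), module_loading = 0.95, seed = 3)
  sim <- simulate_expression(cfg)
  tom <- topological_overlap(adjacency(sim$expression, 6))
  mods <- detect_modules(tom, min_module_size = 30)
  tab <- table(mods$modules$module)
  non_grey <- tab[names(tab) != "grey"]
  expect_identical(sort(as.integer(non_grey), decreasing = TRUE), c(40L, 35L))
  # largest module takes the first palette color
  expect_identical(names(which.max(non_grey)), "turquoise")
  # truth alignment: detected turquoise is exactly planted module M01
  truth_m1 <- names(sim$truth$module_of_gene)[
    !is.na(sim$truth$module_of_gene) & sim$truth$module_of_gene == "M01"]
  expect_setequal(mods$modules$gene[mods$modules$module == "turquoise"], truth_m1)
})

test_that("clusters below min_module_size fall into grey", {
  cfg <- sim_config(n_genes = 60, n_samples_a = 150, n_samples_b = 150,
                    module_sizes = c(10), module_loading = 0.95, seed = 8)
  sim <- simulate_expression(cfg)
  tom <- topological_overlap(adjacency(sim$expression, 6))
  expect_warning(mods <- detect_modules(tom, min_module_size = 30), "grey")
  expect_true(all(mods$modules$module == "grey"))
})

test_that("eigengenes are unit-variance first PCs matching a power-iteration oracle", {
  x <- rand_expression(20, 40, seed = 55)
  x[1:12, ] <- x[1:12, ] + 2 * rep(rnorm(40), each = 12)  # correlated module
  modules <- tibble::tibble(gene = rownames(x),
                            module = rep(c("turquoise", "grey"), c(12, 8)))
  eig <- module_eigengenes(x, modules)
  e <- eig$eigengenes[, "turquoise"]
  expect_equal(sd(e), 1, tolerance = 1e-8)
  xs <- t(scale(t(x[1:12, ])))
  oracle <- oracle_first_pc(xs)
  if (cor(oracle, colMeans(xs)) < 0) oracle <- -oracle
  expect_lt(max(abs(e - oracle)), 1e-8)
  # sign convention: aligned with the module mean profile
  expect_gte(cor(e, colMeans(xs)), 0)

  # identical rows: eigengene equals the shared standardized profile, ve = 1
  xid <- matrix(rep(rnorm(30), each = 4), 4, 30,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:30)))
  eid <- module_eigengenes(xid, tibble::tibble(gene = rownames(xid), module = "blue"))
  expect_equal(eid$variance_explained[["blue"]], 1, tolerance = 1e-12)
  prof <- drop(scale(xid[1, ]))
  expect_lt(min(max(abs(eid$eigengenes[, 1] - prof)),
                max(abs(eid$eigengenes[, 1] + prof))), 1e-8)

  # two perfectly anti-correlated genes still explain all variance
  z <- rnorm(25)
  x2 <- rbind(a = z, b = -z + 0)
  colnames(x2) <- paste0("s", 1:25)
  e2 <- module_eigengenes(x2, tibble::tibble(gene = c("a", "b"), module = "red"))
  expect_equal(e2$variance_explained[["red"]], 1, tolerance = 1e-12)
})

test_that("no random projection beats the eigengene's explained variance", {
  x <- rand_expression(15, 50, seed = 77)
  x[, ] <- x + 1.5 * rep(rnorm(50), each = 15)
  modules <- tibble::tibble(gene = rownames(x), module = "turquoise")
  eig <- module_eigengenes(x, modules)
  xs <- t(scale(t(x)))
  var_of <- function(w) {
    score <- drop(t(xs) %*% w)
    var(score)
  }
  best <- var_of(svd(xs, nu = 1, nv = 0)$u[, 1])
  set.seed(1)
  others <- replicate(1000, {
    w <- rnorm(15); var_of(w / sqrt(sum(w^2)))
  })
  expect_true(all(others <= best + 1e-8))
  expect_equal(eig$variance_explained[["turquoise"]],
               best / sum(apply(xs, 1, var)), tolerance = 1e-8)
})

test_that("module-trait correlation, p-values, GS and MM behave as documented", {
  # closed-form check: r = 0.5, n = 26 -> t = 2.828..., p from the t CDF
  r <- 0.5; n <- 26
  t_exp <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(t_exp, 2.82842712474619, tolerance = 1e-10)

  cfg <- sim_config(n_genes = 50, n_samples_a = 60, n_samples_b = 60,
                    module_sizes = c(20), n_de_genes = 20, de_shift = 2,
                    de_gene_indices = 1:20, seed = 42)
  sim <- simulate_expression(cfg)
  modules <- tibble::tibble(
    gene = rownames(sim$expression),
    module = rep(c("turquoise", "grey"), c(20, 30))
  )
  eig <- module_eigengenes(sim$expression, modules)
  mt <- module_trait(eig, sim$phenotype, sim$expression, modules)
  row <- mt$modules[mt$modules$module == "turquoise", ]
  expect_gt(abs(row$r), 0.5)  # shifted module tracks the trait
  expect_lt(row$p, 1e-6)
  expect_true(all(mt$genes$gs >= 0 & mt$genes$gs <= 1))
  mm <- mt$genes$mm[mt$genes$module == "turquoise"]
  expect_true(all(mm >= 0 & mm <= 1))

  # trait-constant error
  ph_const <- sim$phenotype
  ph_const$condition[] <- "tumor"
  expect_error(module_trait(eig, ph_const), "constant")

  # eigengene equal to the trait gives r = 1
  e_fake <- eig
  tr <- as.numeric(sim$phenotype$condition == "tumor")
  e_fake$eigengenes[, 1] <- (tr - mean(tr)) / sd(tr)
  mt2 <- module_trait(e_fake, sim$phenotype)
  expect_equal(mt2$modules$r[1], 1, tolerance = 1e-10)
})

test_that("independent eigengene rarely correlates with the trait", {
  hits <- 0
  for (s in 1:50) {
    set.seed(s)
    e <- rnorm(100)
    tr <- rep(0:1, each = 50)
    if (abs(cor(e, tr)) >= 0.3) hits <- hits + 1
  }
  expect_lte(hits, 1)
})
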