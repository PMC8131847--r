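test_that("scaling transforms match their closed forms and guard preconditions", {
  x <- abs(rand_expression(6, 20, seed = 2)) + 0.5
  auto <- scale_expression(x, "auto")
  expect_lt(max(abs(rowMeans(auto))), 1e-12)
  expect_equal(unname(apply(auto, 1, sd)), rep(1, 6), tolerance = 1e-12)

  # pareto with SD 4 divides centered values by 2
  g <- x[1, ]
  g <- (g - mean(g)) / sd(g) * 4 + 10
  xp <- rbind(gene1 = g)
  colnames(xp) <- colnames(x)
  pareto <- scale_expression(xp, "pareto")
  expect_equal(unname(pareto[1, ]), unname((g - mean(g)) / 2), tolerance = 1e-10)

  rng <- scale_expression(x, "range")
  expect_equal(unname(rng[2, ]),
               unname((x[2, ] - mean(x[2, ])) / diff(range(x[2, ]))),
               tolerance = 1e-12)
  vast <- scale_expression(x, "vast")
  expect_equal(unname(vast[3, ]),
               unname((x[3, ] - mean(x[3, ])) / sd(x[3, ]) * mean(x[3, ]) / sd(x[3, ])),
               tolerance = 1e-12)
  pw <- scale_expression(x, "power")
  expect_equal(unname(pw[4, ]), unname(sqrt(x[4, ]) - mean(sqrt(x[4, ]))),
               tolerance = 1e-12)

  x0 <- x; x0[1, ] <- rep(c(-1, 1), 10)  # exactly mean 0
  err <- expect_error(scale_expression(x0, "level"))
  expect_match(conditionMessage(err), "level")
  expect_match(conditionMessage(err), "g1")
  xneg <- x; xneg[2, 1] <- -1
  expect_error(scale_expression(xneg, "power"), "negative")
})

test_that("fisher z is the half-log transform, odd, monotone, and invertible", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.53), 0.5 * log(1.53 / 0.47), tolerance = 1e-12)
  expect_equal(fisher_z(0.53), 0.59014, tolerance = 1e-4)
  grid <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-grid), -fisher_z(grid), tolerance = 1e-12)
  expect_true(all(diff(fisher_z(grid)) > 0))
  expect_equal(tanh(fisher_z(grid)), grid, tolerance = 1e-12)
  expect_error(fisher_z(1), "undefined")
})

test_that("z-difference matches step-by-step arithmetic and is antisymmetric", {
  expect_identical(z_difference(0.4, 0.4, 50, 60)$z_diff, 0)
  expect_identical(z_difference(0.4, 0.4, 50, 60)$p_diff, 1)

  # the tumor/normal design: n_A = 58, n_B = 468
  z <- z_difference(-0.58, 0.53, 58, 468)
  za <- 0.5 * log((1 - 0.58) / (1 + 0.58))
  zb <- 0.5 * log((1 + 0.53) / (1 - 0.53))
  manual <- (za - zb) / sqrt(1 / (58 - 3) + 1 / (468 - 3))
  expect_equal(z$z_diff, manual, tolerance = 1e-12)
  expect_gt(abs(z$z_diff), 8)

  zr <- z_difference(0.53, -0.58, 468, 58)
  expect_equal(zr$z_diff, -z$z_diff, tolerance = 1e-12)
  expect_error(z_difference(0.5, 0.5, 3, 100), "exceed 3")
})

test_that("pair records carry correct correlations, counts and p-values", {
  x <- rand_expression(10, 16, seed = 61)
  ph <- two_group_phenotype(8, 8)
  rec <- diffcorr_pairs(x, ph)
  expect_identical(nrow(rec), 45L)
  # oracle correlations per condition
  ca <- oracle_correlation(x[, 1:8])
  cb <- oracle_correlation(x[, 9:16])
  for (i in c(1, 15, 40)) {
    expect_equal(rec$r_a[i], ca[rec$gene_a[i], rec$gene_b[i]], tolerance = 1e-12)
    expect_equal(rec$r_b[i], cb[rec$gene_a[i], rec$gene_b[i]], tolerance = 1e-12)
  }
  # invariant: z_diff recomputes from the stored pieces
  se <- sqrt(1 / (rec$n_a - 3) + 1 / (rec$n_b - 3))
  expect_lt(max(abs(rec$z_diff - (rec$z_a - rec$z_b) / se)), 1e-12)

  # duplicated gene gives r ~ 1 and p ~ 0 in both conditions
  xd <- rbind(x, g1dup = x[1, ] + 1e-9 * rnorm(16))
  rec2 <- diffcorr_pairs(xd, ph, genes = c("g1", "g1dup"))
  expect_gt(rec2$r_a, 0.999)
  expect_lt(rec2$p_a, 1e-10)

  expect_error(diffcorr_pairs(x, two_group_phenotype(3, 13)), ">= 4")
  expect_error(diffcorr_pairs(x, ph, genes = c("g1", "nope")), "nope")
})

test_that("five genes yield C(5,2) = 10 records", {
  x <- rand_expression(5, 20, seed = 1)
  rec <- diffcorr_pairs(x, two_group_phenotype(10, 10))
  expect_identical(nrow(rec), 10L)
})

test_that("condition exchange negates every z_diff and preserves lfdr", {
  x <- rand_expression(25, 30, seed = 10)
  ph <- two_group_phenotype(14, 16)
  ph_swapped <- ph
  ph_swapped$condition <- factor(
    ifelse(ph$condition == "normal", "tumor", "normal"),
    levels = c("normal", "tumor"))
  r1 <- diffcorr_pairs(x, ph)
  r2 <- diffcorr_pairs(x, ph_swapped)
  expect_equal(r2$z_diff, -r1$z_diff, tolerance = 1e-12)
  l1 <- local_fdr(r1$z_diff)
  l2 <- local_fdr(r2$z_diff)
  expect_equal(as.numeric(l1), as.numeric(l2), tolerance = 1e-9)
})

test_that("lfdr is calibrated on a pure null and powerful on a planted mixture", {
  np <- null_pair_sample(58, 468, rho = 0.3, n_pairs = 10000, seed = 6)
  z <- z_difference(np$r_a, np$r_b, 58, 468)$z_diff
  lf <- local_fdr(z)
  expect_gte(attr(lf, "eta0"), 0.9)
  expect_lte(attr(lf, "eta0"), 1.0)
  expect_lte(mean(lf < 0.05), 0.01)
  expect_true(all(lf >= 0 & lf <= 1))

  # 90% null + 10% shifted |Z| ~ N(6,1)
  set.seed(8)
  z_mix <- c(rnorm(9000), sample(c(-1, 1), 1000, TRUE) * rnorm(1000, 6, 1))
  lf_mix <- local_fdr(z_mix)
  expect_gte(attr(lf_mix, "eta0"), 0.85)
  expect_lte(attr(lf_mix, "eta0"), 0.97)
  expect_gte(mean(lf_mix[9001:10000] < 0.05), 0.8)
})

test_that("lfdr falls back to BH below the stability threshold and rejects degenerate input", {
  z <- rnorm(50)
  expect_message(lf <- local_fdr(z), "Benjamini")
  expect_identical(attr(lf, "method"), "BH")
  expect_equal(as.numeric(lf),
               p.adjust(2 * pnorm(-abs(z)), "BH"), tolerance = 1e-12)
  expect_error(local_fdr(rep(1.3, 500)), "degenerate")
})

test_that("switching detection applies sign, lfdr, magnitude and DE rules", {
  rec <- tibble::tibble(
    gene_a = c("a", "a", "b", "c"), gene_b = c("b", "c", "c", "d"),
    r_a = c(0.5, -0.58, 0.45, -0.30), r_b = c(0.6, 0.53, -0.50, 0.35),
    z_diff = c(0.5, -8.8, 7.0, -4.0), lfdr = c(0, 0, 0.001, 0.2)
  )
  de <- tibble::tibble(gene = c("a", "b", "c", "d"),
                       adjusted_p = c(0.01, 0.01, 0.01, 0.5))
  sw <- detect_switching(rec, de)
  # same-sign pair excluded despite lfdr 0; high-lfdr pair excluded;
  # d not DE excludes (c,d) under the both rule
  expect_identical(paste(sw$gene_a, sw$gene_b),
                   c("a c", "b c"))
  expect_true(all(sw$switching))
  # ordering: lfdr ascending
  expect_true(!is.unsorted(sw$lfdr))

  # "either" rule admits a pair with one DE gene
  rec2 <- rec; rec2$lfdr[4] <- 0.01
  sw2 <- detect_switching(rec2, de, de_rule = "either")
  expect_true("c d" %in% paste(sw2$gene_a, sw2$gene_b))
  sw3 <- detect_switching(rec2, de, de_rule = "both")
  expect_false("c d" %in% paste(sw3$gene_a, sw3$gene_b))

  # magnitude filter
  sw4 <- detect_switching(rec, de, min_abs_r = 0.46)
  expect_identical(paste(sw4$gene_a, sw4$gene_b), "a c")

  expect_error(detect_switching(rec, de[-4, ]), "missing from the DE table")
})

test_that("molecule clustering groups by the signed 1 - r distance at the cutoff", {
  set.seed(3)
  n <- 60
  f1 <- rnorm(2 * n); f2 <- rnorm(2 * n)
  mk <- function(f, noise) f + noise * rnorm(2 * n)
  x <- rbind(a1 = mk(f1, 0.3), a2 = mk(f1, 0.3), b1 = mk(f2, 0.3), b2 = mk(f2, 0.3))
  colnames(x) <- paste0("s", seq_len(2 * n))
  ph <- two_group_phenotype(n, n)
  cl <- cluster_molecules(x, ph, r_cutoff = 0.6)
  cc <- cl$clusters
  expect_identical(cc$cluster_normal[cc$gene == "a1"], cc$cluster_normal[cc$gene == "a2"])
  expect_identical(cc$cluster_normal[cc$gene == "b1"], cc$cluster_normal[cc$gene == "b2"])
  expect_false(cc$cluster_normal[cc$gene == "a1"] == cc$cluster_normal[cc$gene == "b1"])

  # two genes with r ~ 0.9 cluster together; r ~ 0.1 do not; anti-correlated
  # genes are far (signed distance ~ 2)
  y <- rbind(p = f1, q = 0.9 * f1 + sqrt(1 - 0.81) * rnorm(2 * n),
             r = rnorm(2 * n), s = -f1)
  colnames(y) <- paste0("s", seq_len(2 * n))
  cl2 <- cluster_molecules(y, ph, r_cutoff = 0.6)$clusters
  expect_identical(cl2$cluster_normal[cl2$gene == "p"], cl2$cluster_normal[cl2$gene == "q"])
  expect_false(cl2$cluster_normal[cl2$gene == "p"] == cl2$cluster_normal[cl2$gene == "r"])
  expect_false(cl2$cluster_normal[cl2$gene == "p"] == cl2$cluster_normal[cl2$gene == "s"])
})

test_that("eigen-module differential correlation flags the planted switching cluster pair", {
  # two clusters whose factors correlate +0.7 in normal and -0.7 in tumor,
  # plus one unrelated cluster
  set.seed(5)
  n_a <- 100; n_b <- 100
  rho <- 0.7
  s1 <- rnorm(n_a + n_b)
  helper <- rnorm(n_a + n_b)
  sign_flip <- rep(c(1, -1), c(n_a, n_b))
  s2 <- sign_flip * (rho * s1 + sqrt(1 - rho^2) * helper)
  s3 <- rnorm(n_a + n_b)
  mk_block <- function(f, m, pre) {
    out <- t(sapply(seq_len(m), function(i) 0.9 * f + sqrt(1 - 0.81) * rnorm(length(f))))
    rownames(out) <- paste0(pre, seq_len(m))
    out
  }
  x <- rbind(mk_block(s1, 5, "u"), mk_block(s2, 5, "v"), mk_block(s3, 5, "w"))
  colnames(x) <- paste0("s", seq_len(n_a + n_b))
  ph <- two_group_phenotype(n_a, n_b)
  cl <- cluster_molecules(x, ph, r_cutoff = 0.6)
  em <- eigen_module_diffcorr(cl, x, ph)
  top <- em[which.max(abs(em$z_diff)), ]
  # the switching eigen-pair has opposite-signed correlations and tops |Z|
  expect_true(sign(top$r_a) * sign(top$r_b) < 0)
  expect_gt(abs(top$z_diff), 5)

  # identical structure in both conditions: all Z ~ 0
  x_same <- rbind(mk_block(s1, 4, "u"), mk_block(s3, 4, "w"))
  colnames(x_same) <- paste0("s", seq_len(n_a + n_b))
  cl_same <- cluster_molecules(x_same, ph, r_cutoff = 0.6)
  em_same <- eigen_module_diffcorr(cl_same, x_same, ph)
  expect_true(all(abs(em_same$z_diff) < 3))

  # graph export round-trip preserves the edge count
  edges <- eigen_module_edges(em, clustering = "tumor")
  path <- withr::local_tempfile()
  write_network(edges, path, "tsv")
  expect_identical(nrow(read_network(path)), nrow(edges))
})
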