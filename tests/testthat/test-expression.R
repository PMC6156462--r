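make_em <- function(values, cultivars, dpas) {
  samples <- data.frame(sample = colnames(values), cultivar = cultivars,
                        dpa = dpas, stringsAsFactors = FALSE)
  expression_matrix(values, samples)
}

test_that("RPKM follows its definition", {
  counts <- matrix(c(100L, 0L), 2L, 1L,
                   dimnames = list(c("g1", "g2"), "s1"))
  samples <- data.frame(sample = "s1", cultivar = "HY405", dpa = 0)
  em <- rpkm(counts, gene_lengths_bp = c(1000L, 500L),
             library_sizes = 1e7, samples = samples)
  expect_equal(em$values["g1", "s1"], 10.0)
  expect_equal(em$values["g2", "s1"], 0.0)

  em2 <- rpkm(counts, c(1000L, 500L), 2e7, samples)
  expect_equal(em2$values, em$values / 2)
})

test_that("expression_matrix validates values and metadata", {
  v <- matrix(1, 1L, 2L, dimnames = list("g", c("s1", "s2")))
  s <- data.frame(sample = c("s1", "s2"), cultivar = "c", dpa = c(0, 5))
  expect_s3_class(expression_matrix(v, s), "expression_matrix")
  expect_error(expression_matrix(-v, s), "negative")
  expect_error(expression_matrix(v, s[1L, ]), "cover")
})

test_that("log transform applies the pseudocount and stays monotone", {
  m <- matrix(c(0, 1, 3, 7), 2L, 2L,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  lt <- log_transform(m)
  expect_equal(lt, matrix(c(0, 1, 2, 3), 2L, 2L,
                          dimnames = dimnames(m)))
  expect_equal(log_transform(m, pseudocount = 0.5)[1L, 1L], -1)
})

test_that("trend clustering recovers planted archetypes", {
  withr::with_seed(1L, {
    ok <- vapply(1:10, function(rep_) {
      down <- c(1.6, 1.2, 0.8, 0.4, 0.2)
      peak <- c(0.2, 1.0, 1.6, 0.8, 0.3)
      n <- 40L
      prof <- rbind(
        t(replicate(n, down + rnorm(5L, 0, 0.1))),
        t(replicate(n, peak + rnorm(5L, 0, 0.1))))
      rownames(prof) <- sprintf("g%02d", seq_len(2L * n))
      colnames(prof) <- c(0, 5, 10, 15, 20)
      prof[prof < 0] <- 0
      cl <- trend_cluster(prof, k = 2L, seed = rep_)
      planted <- rep(c("down", "peak"), each = n)
      mean(vapply(split(cl, planted), function(x)
        mean(x == names(which.max(table(x)))), 1))
    }, 1)
    expect_true(all(ok >= 0.95))
  })
})

test_that("constant profiles land in the flat cluster", {
  prof <- rbind(g1 = c(5, 5, 5, 5), g2 = c(0, 0, 0, 0),
                g3 = c(1, 4, 2, 1), g4 = c(4, 1, 0.5, 0.2),
                g5 = c(0.4, 2, 4, 6))
  colnames(prof) <- c(0, 5, 10, 15)
  cl <- trend_cluster(prof, k = 2L, seed = 1L)
  expect_identical(unname(cl[c("g1", "g2")]), c("flat", "flat"))
  expect_false(any(cl[c("g3", "g4", "g5")] == "flat"))
})

test_that("trend clustering ignores gene order and is seed-deterministic", {
  withr::with_seed(2L, {
    prof <- matrix(runif(60L, 0, 10), 12L, 5L,
                   dimnames = list(sprintf("g%02d", 1:12),
                                   c(0, 5, 10, 15, 20)))
    cl <- trend_cluster(prof, k = 3L, seed = 9L)
    perm <- sample(nrow(prof))
    cl_perm <- trend_cluster(prof[perm, ], k = 3L, seed = 9L)
    expect_identical(cl_perm[names(cl)], cl)
    expect_identical(trend_cluster(prof, k = 3L, seed = 9L), cl)
  })
})

test_that("differential expression has the contracted algebra", {
  withr::with_seed(3L, {
    n <- 30L
    base <- matrix(rlnorm(n * 6L, 2, 0.1), n, 6L,
                   dimnames = list(sprintf("g%02d", 1:n),
                                   sprintf("s%d", 1:6)))
    em_null <- make_em(base, rep(c("A", "B"), each = 3L), rep(0, 6L))
    de0 <- differential(em_null, "A", "B")
    # identical groups give exactly zero fold change
    dup <- base[, c(1:3, 1:3)]
    colnames(dup) <- sprintf("s%d", 1:6)
    em_same <- make_em(dup, rep(c("A", "B"), each = 3L), rep(0, 6L))
    de_same <- differential(em_same, "A", "B")
    expect_true(all(de_same$log2fc == 0))
    expect_false(any(de_same$differential))
    # swapping groups negates the fold change
    de_swap <- differential(em_null, "B", "A")
    expect_equal(de_swap$log2fc, -de0$log2fc)
  })
})

test_that("planted 4-fold genes are recovered as differential", {
  withr::with_seed(6L, {
    n <- 40L
    mu <- rep(30, n)
    hit <- 1:8
    make_group <- function(fold) {
      m <- sapply(1:3, function(r) mu * exp(rnorm(n, 0, 0.05)))
      m[hit, ] <- m[hit, ] * fold
      m
    }
    values <- cbind(make_group(4), make_group(1))
    dimnames(values) <- list(sprintf("g%02d", 1:n), sprintf("s%d", 1:6))
    em <- make_em(values, rep(c("A", "B"), each = 3L), rep(5, 6L))
    de <- differential(em, "A", "B")
    expect_true(all(de$differential[hit]))
    expect_false(any(de$differential[-hit]))
    expect_identical(unique(de$mode), "welch-t")
  })
})

test_that("unreplicated designs fall back to fold-change-only calls", {
  values <- matrix(c(40, 10, 10, 10), 2L, 2L,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  em <- make_em(values, c("A", "B"), c(0, 0))
  de <- differential(em, "A", "B")
  expect_identical(unique(de$mode), "fold-change-only")
  expect_true(all(is.na(de$p)))
  expect_identical(de$differential, c(TRUE, FALSE))
})

test_that("ortholog comparison computes log ratios and reports losses", {
  tv <- matrix(c(8, 16, 2), 3L, 1L,
               dimnames = list(c("gA", "gB", "gC"), "t1"))
  pv <- matrix(c(8, 2), 2L, 1L, dimnames = list(c("oA", "oB"), "p1"))
  tet <- make_em(tv, "tetraploid", 10)
  pro <- make_em(pv, "diploid", 10)
  map <- data.frame(gene_id = c("gA", "gB", "gC"),
                    ortholog_id = c("oA", "oB", "oC"))
  res <- ortholog_compare(tet, pro, map, stages = 10, pseudocount = 0)
  expect_equal(res$log2_ratio[res$gene_id == "gA"], 0)
  expect_equal(res$log2_ratio[res$gene_id == "gB"], 3)
  expect_identical(res$status[res$gene_id == "gC"], "lost")
  expect_true(is.na(res$log2_ratio[res$gene_id == "gC"]))
})

test_that("qPCR relative expression follows 2^-dCt", {
  expect_equal(delta_ct(25, 20), 0.03125)
  expect_equal(delta_ct(20, 20), 1.0)
  expect_gt(delta_ct(19, 20), delta_ct(20, 20))
  expect_equal(delta_ct(c(25, 20), 20), c(0.03125, 1.0))
})

test_that("the one-tailed Welch t matches numerical integration", {
  a <- c(5.1, 6.2, 5.8, 6.0)
  b <- c(4.2, 4.9, 4.4)
  res <- welch_t_one_tailed(a, b)
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t_manual <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_manual <- (va + vb)^2 /
    (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  expect_equal(res$t, t_manual, tolerance = 1e-12)
  expect_equal(res$df, df_manual, tolerance = 1e-12)
  p_quad <- stats::integrate(function(x) stats::dt(x, df_manual),
                             res$t, Inf)$value
  expect_equal(res$p, p_quad, tolerance = 1e-6)
})

test_that("one-tailed p-values are complementary and symmetric at the null", {
  x <- c(1, 2, 3, 4)
  expect_equal(welch_t_one_tailed(x, x)$p, 0.5)
  a <- c(2.3, 3.1, 2.8); b <- c(2.9, 3.4, 2.2)
  expect_equal(welch_t_one_tailed(a, b)$p + welch_t_one_tailed(b, a)$p, 1)
})
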