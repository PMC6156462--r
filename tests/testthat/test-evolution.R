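unit_scores <- align_scoring(match = 1, mismatch = -1,
                             gap_opening = 0, gap_extension = 1)

test_that("global alignment statistics behave on simple cases", {
  same <- global_align("ACGTACGT", "ACGTACGT")
  expect_equal(same$identity, 1.0)
  expect_equal(same$coverage_longer, 1.0)

  aln <- global_align("ACGT", "ACG", scoring = unit_scores)
  expect_equal(aln$identity, 0.75)
  expect_equal(aln$coverage_longer, 1.0)
  expect_equal(aln$score, oracle_best_align_score("ACGT", "ACG"))

  expect_error(global_align("ACGT", "MKWR"), "alphabet")
})

test_that("alignment score is optimal and symmetric on random short pairs", {
  withr::with_seed(5L, {
    for (i in 1:25) {
      a <- paste(sample(c("A", "C", "G", "T"), sample(1:6, 1L), TRUE),
                 collapse = "")
      b <- paste(sample(c("A", "C", "G", "T"), sample(1:6, 1L), TRUE),
                 collapse = "")
      s_ab <- global_align(a, b, scoring = unit_scores)$score
      expect_equal(s_ab, oracle_best_align_score(a, b))
      expect_equal(s_ab, global_align(b, a, scoring = unit_scores)$score)
    }
  })
})

test_that("NG86 handles identical and singly-substituted pairs", {
  a <- "ATGGCTAAACCGTTTGGGTATCACTGA"
  k0 <- ng86_kaks(a, a)
  expect_equal(k0$ka, 0)
  expect_equal(k0$ks, 0)
  expect_true(is.na(k0$ratio))

  # one synonymous third-position change (GGG -> GGA)
  b <- sub("GGG", "GGA", a)
  k1 <- ng86_kaks(a, b)
  expect_equal(k1$ka, 0)
  expect_gt(k1$ks, 0)
})

test_that("NG86 matches the independent counting oracle", {
  withr::with_seed(33L, {
    for (i in 1:30) {
      pair <- random_cds_pair(n_codons = 10L, n_mut = sample(1:6, 1L))
      got <- ng86_kaks(pair$a, pair$b)
      want <- oracle_ng86(pair$a, pair$b)
      expect_equal(got$ka, want$ka, tolerance = 1e-6)
      expect_equal(got$ks, want$ks, tolerance = 1e-6)
    }
  })
})

test_that("NG86 is invariant under swapping the sequences", {
  withr::with_seed(44L, {
    for (i in 1:10) {
      pair <- random_cds_pair(n_codons = 15L, n_mut = 5L)
      k1 <- ng86_kaks(pair$a, pair$b)
      k2 <- ng86_kaks(pair$b, pair$a)
      expect_equal(k1$ka, k2$ka, tolerance = 1e-12)
      expect_equal(k1$ks, k2$ks, tolerance = 1e-12)
    }
  })
})

test_that("NG86 rejects malformed input and flags saturated pairs", {
  expect_error(ng86_kaks("ATGAAA", "ATG"), "lengths differ")
  expect_error(ng86_kaks("ATGA", "ATGA"), "divisible")
  expect_error(ng86_kaks("ATGTAAAAA", "ATGTAAAAA"), "internal stop")
  expect_error(ng86_kaks("ATG-AA", "ATGCAA"), "gap")
})

test_that("p-distance uses pairwise deletion", {
  expect_equal(p_distance("AC", "AA"), 0.5)
  expect_equal(p_distance("A-", "AG"), 0.0)
  expect_equal(p_distance("MKWR", "MKWR"), 0.0)
  expect_error(p_distance("AC", "A"), "length")
  expect_true(is.na(p_distance("--", "AA")))
})

test_that("neighbor joining solves the 2- and 3-taxon cases in closed form", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2L, dimnames = list(c("a", "b"),
                                                      c("a", "b")))
  t2 <- neighbor_joining(d2)
  expect_equal(sort(t2$tip.label), c("a", "b"))
  expect_equal(unname(t2$edge.length), c(0.2, 0.2))

  d3 <- matrix(c(0, 0.3, 0.5,
                 0.3, 0, 0.6,
                 0.5, 0.6, 0), 3L, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- neighbor_joining(d3)
  bl <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2L]])
  expect_equal(bl[["a"]], (0.3 + 0.5 - 0.6) / 2)
  expect_equal(bl[["b"]], (0.3 + 0.6 - 0.5) / 2)
  expect_equal(bl[["c"]], (0.5 + 0.6 - 0.3) / 2)

  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2L)), "asymmetric")
})

test_that("neighbor joining recovers additive trees exactly", {
  withr::with_seed(9L, {
    for (i in 1:12) {
      n <- sample(4:12, 1L)
      true <- ape::rtree(n, br = function(k) runif(k, 0.05, 0.5))
      d <- ape::cophenetic.phylo(true)
      d <- d[order(rownames(d)), order(colnames(d))]
      est <- neighbor_joining(d)
      expect_equal(ape::dist.topo(ape::unroot(true), est), 0,
                   ignore_attr = TRUE)
      # leaf-to-leaf path lengths reproduce the input distances
      dd <- ape::cophenetic.phylo(est)[rownames(d), colnames(d)]
      expect_equal(dd, d, tolerance = 1e-6)
      # cross-check against an independent NJ implementation
      expect_equal(ape::dist.topo(ape::nj(d), est), 0, ignore_attr = TRUE)
    }
  })
})

test_that("bootstrap supports are deterministic, bounded, and saturate", {
  aln <- c(a1 = "KKKKKKKKKKAAAAAAAAAA", a2 = "KKKKKKKKKKAAAAAAAAAA",
           b1 = "DDDDDDDDDDWWWWWWWWWW", b2 = "DDDDDDDDDDWWWWWWWWWW")
  tr <- bootstrap_support(aln, n_reps = 50L, seed = 4L)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  # the a|b split survives every resample
  expect_true(100 %in% sup)

  tr2 <- bootstrap_support(aln, n_reps = 50L, seed = 4L)
  expect_identical(tr$node.label, tr2$node.label)
})

test_that("duplication calling separates tandem, segmental, and no event", {
  lay <- gen_genome_layout(simulation_spec(seed = 21L))
  ev <- call_duplications(lay$catalog, lay$cds_by_gene,
                          all_orfs = lay$all_orfs)
  key <- function(df) sort(paste(df$kind, df$members))
  expect_identical(key(ev), key(lay$truth))
  # the tightly linked 3-gene chain is one event with 3 members
  chain <- ev$members[ev$kind == "tandem" &
                        lengths(strsplit(ev$members, ",")) == 3L]
  expect_length(chain, 1L)
})

test_that("duplication thresholds are strict at the 0.8 boundary", {
  catalog <- data.frame(gene_id = c("x", "y"), chromosome = "S01",
                        start = c(1000L, 9000L), end = c(1299L, 9299L),
                        placed = TRUE, stringsAsFactors = FALSE)
  cds <- c(x = strrep("ACGTT", 60L), y = strrep("ACGTT", 60L))
  # identity exactly 0.8 after mutating exactly 60 of 300 sites
  chars <- strsplit(cds[["y"]], "")[[1L]]
  chars[seq(1L, 300L, by = 5L)] <- "G"
  flip <- strsplit(cds[["x"]], "")[[1L]][seq(1L, 300L, by = 5L)] == "G"
  chars[seq(1L, 300L, by = 5L)][flip] <- "C"
  cds[["y"]] <- paste(chars, collapse = "")
  expect_equal(global_align(cds[["x"]], cds[["y"]])$identity, 0.8)
  ev <- call_duplications(catalog, cds)
  expect_identical(nrow(ev), 0L)
})
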