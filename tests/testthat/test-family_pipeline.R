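test_that("type classification follows the gap-signature decision tree", {
  expect_identical(classify_type(gap_signature(9, 18, 13, 1, 24, 9))$type_label,
                   "XI")
  expect_identical(classify_type(gap_signature(14, 14, 12, 1, 24, 10))$type_label,
                   "V")
  # g3 = 12 routes to IV, not XI
  expect_identical(classify_type(gap_signature(9, 16, 12, 1, 24, 9))$type_label,
                   "IV")
  un <- classify_type(gap_signature(11, 11, 11, 1, 11, 11))
  expect_identical(un$type_label, "unknown")
  expect_match(un$rule_fired, "no rule")
})

test_that("classification reproduces every published catalog label", {
  cat_ <- read_catalog()
  labels <- vapply(cat_$ecm_pattern,
                   function(p) classify_type(p)$type_label, "")
  expect_identical(unname(labels), cat_$type_label)
})

test_that("nearest-reference fallback types unknown signatures, off by default", {
  cat_ <- read_catalog()
  # one step off the type-V signature space
  sig <- gap_signature(15, 14, 12, 1, 24, 10)
  expect_identical(classify_type(sig)$type_label, "unknown")
  fb <- classify_type(sig, fallback = TRUE, catalog = cat_)
  expect_identical(fb$type_label, "V")
  expect_match(fb$rule_fired, "nearest-reference")
})

test_that("the filter cascade applies its stages in pinned order", {
  mk <- function(id, protein, sp_len, domain_ok = NA)
    gene_record(id, protein = protein, sp_len = sp_len, domain_ok = domain_ok)
  motif <- paste0("C", strrep("A", 9), "C", strrep("A", 13), "CC",
                  strrep("A", 19), "C", "A", "C", strrep("A", 21), "C",
                  strrep("A", 13), "C")
  valid <- mk("ok", paste0("M", strrep("L", 22), motif), 23L)
  no_sp <- mk("nosp", paste0("L", strrep("A", 22), motif), 0L)  # fails 1 (and 4)
  long <- mk("long", paste0("M", strrep("L", 22), strrep("A", 121)), 23L)
  nocys <- mk("nocys", paste0("M", strrep("L", 22), strrep("A", 90)), 23L)
  nomet <- mk("nomet", paste0("L", strrep("L", 22), motif), 23L)
  nodom <- mk("nodom", paste0("M", strrep("L", 22), motif), 23L, domain_ok = FALSE)

  rep_ <- filter_candidates(list(valid, no_sp, long, nocys, nomet, nodom))
  expect_identical(rep_$removed_no_signal, 1L)      # nosp counted once, stage 1
  expect_identical(rep_$removed_long_mature, 1L)
  expect_identical(rep_$removed_missing_cys, 1L)
  expect_identical(rep_$removed_no_start_met, 1L)
  expect_identical(rep_$removed_no_domain, 0L)      # stage off by default
  expect_identical(rep_$survivors, c("ok", "nodom"))

  rep2 <- filter_candidates(list(valid, nodom), require_domain = TRUE)
  expect_identical(rep2$removed_no_domain, 1L)
  expect_identical(rep2$survivors, "ok")
})

test_that("the mature-length threshold is strict (exactly 120 is retained)", {
  motif <- paste0("C", strrep("A", 9), "C", strrep("A", 13), "CC",
                  strrep("A", 19), "C", "A", "C", strrep("A", 21), "C",
                  strrep("A", 13), "C")                      # 84 residues
  mature120 <- paste0(motif, strrep("A", 36))
  mature121 <- paste0(motif, strrep("A", 37))
  at <- function(m) filter_candidates(list(gene_record(
    "g", protein = paste0("M", strrep("L", 19), m), sp_len = 20L)))
  expect_identical(at(mature120)$survivors, "g")
  expect_identical(at(mature121)$removed_long_mature, 1L)
})

test_that("empty input gives an all-zero report", {
  rep_ <- filter_candidates(list())
  expect_identical(rep_$n_input, 0L)
  expect_identical(length(rep_$survivors), 0L)
  expect_identical(rep_$removed_no_signal + rep_$removed_long_mature +
                     rep_$removed_missing_cys + rep_$removed_no_start_met +
                     rep_$removed_no_domain, 0L)
})

test_that("the filter report conserves candidates across random pools", {
  for (seed in c(11L, 12L, 13L)) {
    spec <- simulation_spec(
      seed = seed,
      n_valid_per_type = c(I = 4L, XI = 6L, V = 2L),
      decoy_counts = c(no_signal = 3L, long_mature = 5L, missing_cys = 2L,
                       no_start_met = 2L))
    pool <- gen_candidate_pool(spec)
    rep_ <- filter_candidates(pool$records)
    expect_identical(
      rep_$n_input,
      rep_$removed_no_signal + rep_$removed_long_mature +
        rep_$removed_missing_cys + rep_$removed_no_start_met +
        rep_$removed_no_domain + length(rep_$survivors))
  }
})

test_that("chromosome distribution matches the published map", {
  d <- chromosome_distribution(read_catalog())
  expect_identical(d$counts[["D11"]], 13L)
  expect_identical(names(which.max(d$counts)), "D11")
  expect_identical(unname(d$by_type["D11", "XI"]), 9L)
  expect_false("A06" %in% names(d$counts))
  expect_false("D06" %in% names(d$counts))
  expect_identical(length(d$unplaced), 3L)
})

test_that("intron counts equal exons minus one", {
  expect_identical(count_introns(cbind(start = c(1L, 201L),
                                       end = c(100L, 300L))), 1L)
  expect_identical(count_introns(cbind(start = 1L, end = 500L)), 0L)
  expect_identical(count_introns(cbind(start = c(1L, 201L, 401L),
                                       end = c(100L, 300L, 500L))), 2L)
})
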