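# Seeded generators for every input class the pipeline consumes, each a
# pure function of (spec, seed), with planted ground truth returned
# alongside the data.

AA20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
AA_NO_CYS <- setdiff(AA20, "C")

# amino acid -> codons (sense codons only)
REV_CODE <- split(names(Biostrings::GENETIC_CODE), Biostrings::GENETIC_CODE)
STOP_CODONS <- REV_CODE[["*"]]

rand_residues <- function(n, alphabet = AA_NO_CYS) {
  if (n == 0L) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Uniform-synonymous-codon back-translation; appends a stop codon.
back_translate <- function(protein) {
  res <- strsplit(protein, "")[[1L]]
  codons <- vapply(res, function(a) sample(REV_CODE[[a]], 1L), "")
  paste(c(codons, sample(STOP_CODONS, 1L)), collapse = "")
}

#' Simulation specification for the synthetic pipeline inputs
#'
#' Defaults emulate the published cotton survey's input structure: the
#' per-type valid-gene counts of the 138-gene catalog and the four
#' decoy classes of the identification cascade sized to its printed
#' tallies (18 lacking a signal peptide, 46 with mature proteins over
#' 120 residues, 16 without the eight cysteines, 1 without a start
#' methionine; 219 candidates in total), fiber stages at 0/5/10/15/20
#' days post anthesis, and a duplication plan straddling the 30 kb /
#' 15 ORF / 80% identity boundaries.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   (spec, seed).
#' @param n_valid_per_type Named counts of valid genes per nsLTP type.
#' @param decoy_counts Named counts per decoy class (`no_signal`,
#'   `long_mature`, `missing_cys`, `no_start_met`).
#' @param duplication_plan List of planted layout events; each a list
#'   with `kind` (`"tandem"`, `"segmental"`, `"segmental_cis"`,
#'   `"none"`), `n_members`, `identity`, `gap_bp`, `intervening`.
#' @param expression_plan List: archetype profiles over `stages`,
#'   genes per archetype, lognormal `noise_sd`, replicate count,
#'   planted fold change and number of changed genes, cultivar names.
#' @param stages Developmental stages (DPA).
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(
    seed = 1L,
    n_valid_per_type = c(I = 28L, II = 15L, III = 5L, IV = 14L, V = 16L,
                         VI = 4L, VIII = 11L, IX = 3L, XI = 34L, nsLTPy = 8L),
    decoy_counts = c(no_signal = 18L, long_mature = 46L,
                     missing_cys = 16L, no_start_met = 1L),
    duplication_plan = list(
      list(kind = "tandem", n_members = 2L, identity = 0.95,
           gap_bp = 10000L, intervening = 2L),
      list(kind = "tandem", n_members = 3L, identity = 0.92,
           gap_bp = 20000L, intervening = 0L),
      list(kind = "segmental", n_members = 2L, identity = 0.90),
      list(kind = "segmental_cis", n_members = 2L, identity = 0.90,
           gap_bp = 31000L, intervening = 16L),
      list(kind = "none", n_members = 2L, identity = 0.79,
           gap_bp = 10000L, intervening = 0L)),
    expression_plan = list(
      archetypes = list(
        initiation_peak = c(100, 40, 15, 8, 5),
        elongation_peak = c(20, 80, 100, 40, 10),
        monotone_down = c(80, 60, 40, 20, 10),
        flat = c(0, 0, 0, 0, 0)),
      n_per_archetype = c(initiation_peak = 40L, elongation_peak = 30L,
                          monotone_down = 48L, flat = 20L),
      noise_sd = 0.1, n_reps = 3L, fold_change = 4, n_de = 12L,
      cultivars = c("HY405", "CCRI8")),
    stages = c(0, 5, 10, 15, 20)) {
  stopifnot(all(n_valid_per_type >= 0L), all(decoy_counts >= 0L))
  structure(list(seed = as.integer(seed),
                 n_valid_per_type = n_valid_per_type,
                 decoy_counts = decoy_counts,
                 duplication_plan = duplication_plan,
                 expression_plan = expression_plan,
                 stages = stages),
            class = "simulation_spec")
}

# Internal builder drawing from the current RNG stream.
gen_nsltp_gene_impl <- function(type_label, id, catalog) {
  sigs <- catalog$ecm_pattern[catalog$type_label == type_label]
  if (!length(sigs)) stop("no catalog signature for type ", type_label)
  sig <- parse_pattern(sample(sigs, 1L))
  span <- motif_span(sig)
  budget <- 120L - span
  stopifnot(budget >= 0L)
  pre <- sample.int(min(15L, budget) + 1L, 1L) - 1L
  post <- sample.int(min(8L, budget - pre) + 1L, 1L) - 1L
  mature <- paste0(
    rand_residues(pre),
    "C", rand_residues(sig$g1), "C", rand_residues(sig$g2), "CC",
    rand_residues(sig$g3), "C", rand_residues(sig$inner), "C",
    rand_residues(sig$g4), "C", rand_residues(sig$g5), "C",
    rand_residues(post))
  sp_len <- sample(20:30, 1L)
  sp <- paste0("M", rand_residues(sp_len - 1L))
  protein <- paste0(sp, mature)
  rec <- gene_record(id, protein = protein, sp_len = sp_len,
                     cds = back_translate(protein))
  attr(rec, "planted_signature") <- sig
  attr(rec, "type_label") <- type_label
  rec
}

#' Generate one nsLTP-like gene with a planted ECM signature
#'
#' Draws a gap signature from the packaged catalog rows of the given
#' type, fills the inter-cysteine gaps with random non-cysteine
#' residues (so the planted backbone is the only eight-cysteine
#' arrangement), prepends a 20-30 residue signal peptide starting with
#' methionine, and back-translates with uniform synonymous codon
#' choice.  The mature protein never exceeds 120 residues.
#'
#' @param type_label nsLTP type to emulate (must have catalog members).
#' @param seed Integer seed; fixed seed gives an identical record.
#' @param id Gene identifier.
#' @param catalog Catalog supplying signatures (defaults to fixture).
#' @return A [gene_record()] with attributes `planted_signature` and
#'   `type_label`.
#' @export
gen_nsltp_gene <- function(type_label, seed = 1L, id = "synth1",
                           catalog = read_catalog()) {
  withr::with_seed(seed, gen_nsltp_gene_impl(type_label, id, catalog))
}

#' Generate a candidate pool with planted filter-cascade decoys
#'
#' Produces `sum(n_valid_per_type)` valid nsLTP genes plus the four
#' decoy classes of the identification cascade.  Each decoy passes
#' every stage before its designated one and fails exactly there:
#' `no_signal` records carry `sp_len = 0`; `long_mature` records have a
#' signal peptide but a mature protein over 120 residues;
#' `missing_cys` records have at most seven cysteines in a short mature
#' protein; the `no_start_met` record is a valid gene whose precursor
#' starts with a non-methionine residue.  Order is shuffled by seed.
#'
#' @param spec A [simulation_spec()].
#' @param catalog Catalog supplying ECM signatures.
#' @return List: `records` (list of [gene_record()]), `truth` (data
#'   frame `gene_id`, `class`, `type_label`).
#' @export
gen_candidate_pool <- function(spec = simulation_spec(),
                               catalog = read_catalog()) {
  withr::with_seed(spec$seed, {
    records <- list()
    truth <- list()
    add <- function(rec, class, type = NA_character_) {
      records[[length(records) + 1L]] <<- rec
      truth[[length(truth) + 1L]] <<- data.frame(
        gene_id = rec$gene_id, class = class, type_label = type,
        stringsAsFactors = FALSE)
    }
    i <- 0L
    for (ty in names(spec$n_valid_per_type)) {
      for (k in seq_len(spec$n_valid_per_type[[ty]])) {
        i <- i + 1L
        add(gen_nsltp_gene_impl(ty, sprintf("synth%04d", i), catalog),
            "valid", ty)
      }
    }
    dc <- spec$decoy_counts
    for (k in seq_len(dc[["no_signal"]])) {
      i <- i + 1L
      rec <- gen_nsltp_gene_impl(sample(names(spec$n_valid_per_type), 1L),
                                 sprintf("synth%04d", i), catalog)
      rec$sp_len <- 0L
      add(rec, "no_signal")
    }
    for (k in seq_len(dc[["long_mature"]])) {
      i <- i + 1L
      sp_len <- sample(20:30, 1L)
      mature_len <- sample(121:160, 1L)
      protein <- paste0("M", rand_residues(sp_len - 1L),
                        rand_residues(mature_len))
      add(gene_record(sprintf("synth%04d", i), protein = protein,
                      sp_len = sp_len, cds = back_translate(protein)),
          "long_mature")
    }
    for (k in seq_len(dc[["missing_cys"]])) {
      i <- i + 1L
      sp_len <- sample(20:30, 1L)
      mature_len <- sample(60:120, 1L)
      n_cys <- sample(0:7, 1L)
      mature <- strsplit(rand_residues(mature_len), "")[[1L]]
      if (n_cys > 0L) mature[sample.int(mature_len, n_cys)] <- "C"
      protein <- paste0("M", rand_residues(sp_len - 1L),
                        paste(mature, collapse = ""))
      add(gene_record(sprintf("synth%04d", i), protein = protein,
                      sp_len = sp_len, cds = back_translate(protein)),
          "missing_cys")
    }
    for (k in seq_len(dc[["no_start_met"]])) {
      i <- i + 1L
      rec <- gen_nsltp_gene_impl(sample(names(spec$n_valid_per_type), 1L),
                                 sprintf("synth%04d", i), catalog)
      protein <- rec$protein
      substr(protein, 1L, 1L) <- "L"
      rec <- gene_record(rec$gene_id, protein = protein,
                         sp_len = rec$sp_len, cds = back_translate(protein))
      add(rec, "no_start_met")
    }
    truth <- do.call(rbind, truth)
    ord <- sample.int(length(records))
    list(records = records[ord], truth = truth[ord, , drop = FALSE])
  })
}

random_cds_impl <- function(n_codons) {
  aa <- c("M", sample(AA20, n_codons - 1L, replace = TRUE))
  back_translate(paste(aa, collapse = ""))
}

# Mutate exactly n_mut distinct positions (never touching the terminal
# stop codon), resampling any substitution that creates a stop codon.
mutate_cds_impl <- function(cds, n_mut) {
  chars <- strsplit(cds, "")[[1L]]
  L <- length(chars)
  pos_pool <- seq_len(L - 3L)
  pos <- sample(pos_pool, n_mut)
  for (p in pos) {
    codon_i <- (p - 1L) %/% 3L
    repeat {
      alt <- sample(setdiff(NUCS, chars[[p]]), 1L)
      trial <- chars
      trial[[p]] <- alt
      codon <- paste(trial[(codon_i * 3L + 1L):(codon_i * 3L + 3L)],
                     collapse = "")
      if (codon_aa(codon) != "*") { chars <- trial; break }
    }
  }
  paste(chars, collapse = "")
}

#' Generate a chromosome layout with planted duplication events
#'
#' Lays planted duplication events onto synthetic chromosomes together
#' with filler ORFs, including near-boundary negative controls: a
#' same-chromosome pair separated by 31 kb *and* 16 intervening ORFs
#' (a segmental, not tandem, event) and a pair at identity 0.79 (no
#' event at all).  Pair identities are exact by construction: copies
#' differ at exactly `round((1 - identity) * length)` sites and align
#' without gaps.
#'
#' @param spec A [simulation_spec()].
#' @return List: `catalog` (family genes: `gene_id`, `chromosome`,
#'   `start`, `end`, `placed`), `cds_by_gene`, `all_orfs` (full ordered
#'   gene complement incl. fillers), `truth` (data frame `kind`,
#'   `members` with comma-joined ids ordered by position).
#' @export
gen_genome_layout <- function(spec = simulation_spec()) {
  withr::with_seed(spec$seed + 1L, {
    catalog <- list(); orfs <- list(); cds <- character(0); truth <- list()
    gi <- 0L; fi <- 0L
    place <- function(chrom, start, len, family, id = NULL) {
      if (is.null(id)) {
        if (family) { gi <<- gi + 1L; id <- sprintf("dup%03d", gi) }
        else { fi <<- fi + 1L; id <- sprintf("orf%03d", fi) }
      }
      row <- data.frame(gene_id = id, chromosome = chrom,
                        start = start, end = start + len - 1L,
                        placed = TRUE, stringsAsFactors = FALSE)
      orfs[[length(orfs) + 1L]] <<- row
      if (family) catalog[[length(catalog) + 1L]] <<- row
      id
    }
    chrom_i <- 0L
    for (ev in spec$duplication_plan) {
      chrom_i <- chrom_i + 1L
      chrom <- sprintf("S%02d", chrom_i)
      n_codons <- sample(100:130, 1L)
      L <- 3L * (n_codons + 1L)
      base <- random_cds_impl(n_codons)
      n_mut <- max(1L, round((1 - ev$identity) * L))
      if (ev$identity < 0.8) n_mut <- max(n_mut, ceiling(0.201 * L))
      members <- character(ev$n_members)
      seqs <- character(ev$n_members)
      seqs[[1L]] <- base
      for (m in 2:ev$n_members) seqs[[m]] <- mutate_cds_impl(seqs[[m - 1L]], n_mut)
      if (ev$kind == "segmental") {
        # members on different chromosomes
        for (m in seq_len(ev$n_members)) {
          mchrom <- sprintf("S%02d", chrom_i)
          if (m > 1L) { chrom_i <- chrom_i + 1L; mchrom <- sprintf("S%02d", chrom_i) }
          members[[m]] <- place(mchrom, 50000L, L, family = TRUE)
          cds[[members[[m]]]] <- seqs[[m]]
        }
      } else {
        cursor <- 50000L
        for (m in seq_len(ev$n_members)) {
          members[[m]] <- place(chrom, cursor, L, family = TRUE)
          cds[[members[[m]]]] <- seqs[[m]]
          if (m < ev$n_members) {
            gap_end <- cursor + L - 1L + ev$gap_bp
            if (ev$intervening > 0L) {
              slot <- ev$gap_bp %/% (ev$intervening + 1L)
              for (f in seq_len(ev$intervening)) {
                flen <- min(300L, max(60L, slot - 20L))
                place(chrom, cursor + L - 1L + f * slot - flen, flen,
                      family = FALSE)
              }
            }
            cursor <- gap_end + 1L
          }
        }
      }
      kind_truth <- switch(ev$kind,
                           tandem = "tandem",
                           segmental = "segmental",
                           segmental_cis = "segmental",
                           none = NA_character_)
      if (!is.na(kind_truth)) {
        if (kind_truth == "tandem") {
          truth[[length(truth) + 1L]] <- data.frame(
            kind = "tandem", members = paste(members, collapse = ","),
            stringsAsFactors = FALSE)
        } else {
          # segmental events stay pairwise
          for (m in 2:ev$n_members)
            truth[[length(truth) + 1L]] <- data.frame(
              kind = "segmental",
              members = paste(members[c(m - 1L, m)], collapse = ","),
              stringsAsFactors = FALSE)
        }
      }
    }
    # unrelated singleton family genes and background ORFs
    for (k in 1:3) {
      chrom_i <- chrom_i + 1L
      n_codons <- sample(100:130, 1L)
      id <- place(sprintf("S%02d", chrom_i), 50000L, 3L * (n_codons + 1L),
                  family = TRUE)
      cds[[id]] <- random_cds_impl(n_codons)
    }
    catalog <- do.call(rbind, catalog)
    all_orfs <- do.call(rbind, orfs)
    all_orfs <- all_orfs[order(all_orfs$chromosome, all_orfs$start), ,
                         drop = FALSE]
    list(catalog = catalog, cds_by_gene = cds, all_orfs = all_orfs,
         truth = do.call(rbind, truth))
  })
}

#' Generate an expression matrix with planted temporal profiles
#'
#' Genes follow one of the planted archetype profiles (initiation
#' peak, early-elongation peak, monotone decline, flat/silent) across
#' the fiber stages, with multiplicative lognormal noise; two cultivars
#' are produced, with a planted fold change in the first cultivar for a
#' subset of non-flat genes.
#'
#' @param spec A [simulation_spec()].
#' @return List: `em` (an [expression_matrix()], RPKM units), `truth`
#'   (data frame `gene_id`, `archetype`, `de`).
#' @export
gen_expression <- function(spec = simulation_spec()) {
  plan <- spec$expression_plan
  withr::with_seed(spec$seed + 2L, {
    archetype <- rep(names(plan$n_per_archetype), plan$n_per_archetype)
    n_genes <- length(archetype)
    genes <- sprintf("g%03d", seq_len(n_genes))
    de <- rep(FALSE, n_genes)
    de[sample(which(archetype != "flat"), plan$n_de)] <- TRUE
    stages <- spec$stages
    cols <- expand.grid(rep = seq_len(plan$n_reps), dpa = stages,
                        cultivar = plan$cultivars,
                        stringsAsFactors = FALSE)
    cols$sample <- sprintf("%s_%g_r%d", cols$cultivar, cols$dpa, cols$rep)
    values <- matrix(0, n_genes, nrow(cols),
                     dimnames = list(genes, cols$sample))
    for (g in seq_len(n_genes)) {
      base <- plan$archetypes[[archetype[[g]]]]
      for (s in seq_len(nrow(cols))) {
        mu <- base[[match(cols$dpa[[s]], stages)]]
        if (de[[g]] && cols$cultivar[[s]] == plan$cultivars[[1L]])
          mu <- mu * plan$fold_change
        values[g, s] <- mu * exp(rnorm(1L, 0, plan$noise_sd))
      }
    }
    em <- expression_matrix(values,
                            cols[, c("sample", "cultivar", "dpa")],
                            unit = "RPKM")
    list(em = em, truth = data.frame(gene_id = genes, archetype = archetype,
                                     de = de, stringsAsFactors = FALSE))
  })
}
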