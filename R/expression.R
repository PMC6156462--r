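#' Construct an expression matrix with sample metadata
#'
#' A genes x samples abundance table with per-sample metadata
#' (cultivar/species label and developmental stage in days post
#' anthesis, DPA) and a unit tag.
#'
#' @param values Non-negative numeric matrix (genes x samples) with row
#'   and column names.
#' @param samples Data frame with one row per column of `values`:
#'   columns `sample` (matching `colnames(values)`), `cultivar`, `dpa`.
#' @param unit One of `"RPKM"`, `"FPKM"`, `"counts"`.
#' @return Object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, samples,
                              unit = c("RPKM", "FPKM", "counts")) {
  unit <- match.arg(unit)
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(values < 0)) stop("negative abundance values")
  stopifnot(all(c("sample", "cultivar", "dpa") %in% names(samples)))
  if (!setequal(samples$sample, colnames(values)) ||
      nrow(samples) != ncol(values))
    stop("sample metadata does not cover the matrix columns")
  samples <- samples[match(colnames(values), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples, unit = unit),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix>", nrow(x$values), "genes x", ncol(x$values),
      "samples [", x$unit, "]\n")
  cat("  cultivars:", paste(unique(x$samples$cultivar), collapse = ", "), "\n")
  cat("  DPA:", paste(sort(unique(x$samples$dpa)), collapse = ", "), "\n")
  invisible(x)
}

#' RPKM normalization of a count matrix
#'
#' Reads per kilobase of gene model per million mapped reads:
#' `count / (gene length in kb * library size in millions)`.
#'
#' @param counts Non-negative integer matrix (genes x samples).
#' @param gene_lengths_bp Gene model lengths in bp (recycled over rows).
#' @param library_sizes Mapped reads per sample (recycled over columns).
#' @param samples Sample metadata passed to [expression_matrix()].
#' @return `expression_matrix` in RPKM units.
#' @export
rpkm <- function(counts, gene_lengths_bp, library_sizes, samples) {
  stopifnot(all(counts >= 0), all(gene_lengths_bp > 0),
            all(library_sizes > 0))
  v <- sweep(counts, 1L, gene_lengths_bp / 1e3, "/")
  v <- sweep(v, 2L, library_sizes / 1e6, "/")
  expression_matrix(v, samples, unit = "RPKM")
}

#' Log2 transform with pseudocount
#'
#' @param em An `expression_matrix` (or bare matrix).
#' @param pseudocount Added before the log; default 1.
#' @return Same shape, values `log2(x + pseudocount)`.
#' @export
log_transform <- function(em, pseudocount = 1) {
  if (inherits(em, "expression_matrix")) {
    em$values <- log2(em$values + pseudocount)
    em
  } else log2(em + pseudocount)
}

# Stage-profile matrix: genes x stages, averaging samples of equal DPA
# within the given cultivar subset.
stage_profiles <- function(em, cultivar = NULL) {
  s <- em$samples
  keep <- if (is.null(cultivar)) seq_len(nrow(s)) else which(s$cultivar %in% cultivar)
  stages <- sort(unique(s$dpa[keep]))
  prof <- sapply(stages, function(st) {
    cols <- keep[s$dpa[keep] == st]
    rowMeans(em$values[, cols, drop = FALSE])
  })
  colnames(prof) <- stages
  prof
}

#' Cluster genes by expression trend across developmental stages
#'
#' Each gene's stage profile is standardized (z-score across stages);
#' constant profiles (including all-zero genes) go to a dedicated
#' `"flat"` cluster.  Templates are seeded k-means centroids of the
#' standardized profiles; every remaining gene is assigned to the
#' template with the highest Pearson correlation to its profile.
#'
#' @param em `expression_matrix` whose columns are ordered stages, or a
#'   genes x stages matrix.
#' @param k Number of trend templates (>= 2).
#' @param seed Seed for the k-means initialization.
#' @param cultivar Optional cultivar subset when `em` carries metadata.
#' @return Named character vector gene -> cluster label (`"trend1"` ...
#'   `"trendk"` or `"flat"`).
#' @export
trend_cluster <- function(em, k = 4L, seed = 1L, cultivar = NULL) {
  prof <- if (inherits(em, "expression_matrix"))
    stage_profiles(em, cultivar) else em
  if (ncol(prof) < 2L) stop("need at least 2 stages")
  if (k < 2L) stop("k must be >= 2")
  sds <- apply(prof, 1L, sd)
  flat <- sds == 0
  z <- (prof[!flat, , drop = FALSE] -
          rowMeans(prof[!flat, , drop = FALSE])) / sds[!flat]
  out <- setNames(rep("flat", nrow(prof)), rownames(prof))
  if (nrow(z)) {
    k_eff <- min(k, nrow(unique(as.data.frame(z))))
    km <- withr::with_seed(seed, kmeans(z, centers = k_eff, nstart = 10L))
    # canonical template order (lexicographic on centroid values) so that
    # labels do not depend on the input row order
    rank_of <- order(do.call(order, as.data.frame(km$centers)))
    assign_to <- apply(z, 1L, function(g) {
      cors <- apply(km$centers, 1L, function(cen)
        if (sd(cen) == 0 || sd(g) == 0) -Inf else cor(g, cen))
      which.max(cors)
    })
    out[rownames(z)] <- paste0("trend", rank_of[assign_to])
  }
  out
}

#' Differential expression between two cultivar groups, per stage
#'
#' For every developmental stage shared by the two groups, computes the
#' pseudocounted `log2` fold change of group means.  With at least two
#' replicates per group at a stage, a two-sided Welch t-test supplies
#' the significance value, Benjamini-Hochberg adjusted across genes
#' within the stage; unreplicated designs fall back to a
#' `fold-change-only` call (flagged in the output).  A gene is called
#' differential when `|log2FC| >= log2(fc_threshold)` and (when tested)
#' the adjusted significance is below `alpha`.
#'
#' @param em `expression_matrix`.
#' @param group_a,group_b Cultivar labels defining the two groups.
#' @param fc_threshold Fold-change threshold (default 2).
#' @param alpha Adjusted-significance cutoff.
#' @param pseudocount Added to group means before the log ratio.
#' @return Data frame: `gene_id`, `stage`, `log2fc`, `p`, `padj`,
#'   `mode` (`"welch-t"` or `"fold-change-only"`), `direction`,
#'   `differential`.
#' @export
differential <- function(em, group_a, group_b, fc_threshold = 2,
                         alpha = 0.05, pseudocount = 1) {
  s <- em$samples
  stages <- intersect(sort(unique(s$dpa[s$cultivar %in% group_a])),
                      sort(unique(s$dpa[s$cultivar %in% group_b])))
  if (!length(stages)) stop("groups share no stage")
  out <- list()
  for (st in stages) {
    ca <- which(s$cultivar %in% group_a & s$dpa == st)
    cb <- which(s$cultivar %in% group_b & s$dpa == st)
    ma <- rowMeans(em$values[, ca, drop = FALSE])
    mb <- rowMeans(em$values[, cb, drop = FALSE])
    lfc <- log2((ma + pseudocount) / (mb + pseudocount))
    replicated <- length(ca) >= 2L && length(cb) >= 2L
    p <- rep(NA_real_, nrow(em$values))
    if (replicated) {
      for (g in seq_len(nrow(em$values))) {
        xa <- em$values[g, ca]; xb <- em$values[g, cb]
        p[[g]] <- if (sd(xa) == 0 && sd(xb) == 0) {
          if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0
        } else t.test(xa, xb, var.equal = FALSE)$p.value
      }
      padj <- p.adjust(p, method = "BH")
    } else padj <- rep(NA_real_, nrow(em$values))
    fc_hit <- abs(lfc) >= log2(fc_threshold)
    out[[length(out) + 1L]] <- data.frame(
      gene_id = rownames(em$values), stage = st, log2fc = lfc, p = p,
      padj = padj,
      mode = if (replicated) "welch-t" else "fold-change-only",
      direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "none")),
      differential = if (replicated) fc_hit & !is.na(padj) & padj < alpha
        else fc_hit,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Compare tetraploid genes with their diploid-progenitor orthologs
#'
#' Per ortholog pair and stage, the pseudocounted log2 ratio
#' tetraploid/progenitor of stage-mean abundances.  Pairs whose
#' ortholog is absent from the progenitor matrix are reported with
#' status `"lost"` and no ratio.
#'
#' @param tetraploid_em,progenitor_em `expression_matrix` objects.
#' @param ortholog_map Data frame with columns `gene_id` (tetraploid)
#'   and `ortholog_id` (progenitor).
#' @param stages Stages (DPA) to compare; defaults to the shared ones.
#' @param pseudocount Added to both means.
#' @return Data frame: `gene_id`, `ortholog_id`, `stage`, `log2_ratio`,
#'   `status` (`"ok"`/`"lost"`).
#' @export
ortholog_compare <- function(tetraploid_em, progenitor_em, ortholog_map,
                             stages = NULL, pseudocount = 1) {
  if (is.null(stages))
    stages <- intersect(unique(tetraploid_em$samples$dpa),
                        unique(progenitor_em$samples$dpa))
  tp <- stage_profiles(tetraploid_em)
  pp <- stage_profiles(progenitor_em)
  out <- list()
  for (i in seq_len(nrow(ortholog_map))) {
    g <- ortholog_map$gene_id[[i]]; o <- ortholog_map$ortholog_id[[i]]
    lost <- !(o %in% rownames(pp)) || is.na(o)
    for (st in stages) {
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, ortholog_id = o, stage = st,
        log2_ratio = if (lost) NA_real_ else
          log2((tp[g, as.character(st)] + pseudocount) /
                 (pp[o, as.character(st)] + pseudocount)),
        status = if (lost) "lost" else "ok",
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' qPCR relative expression (2^-dCt)
#'
#' `dCt = Ct(target) - Ct(reference)`; relative expression is
#' `2^-dCt`.
#'
#' @param ct_target,ct_reference Cycle-threshold values (vectorized).
#' @return Relative expression (> 0).
#' @export
delta_ct <- function(ct_target, ct_reference) {
  2^-(ct_target - ct_reference)
}

#' One-tailed Welch t-test (mean_a > mean_b)
#'
#' Welch's unequal-variance statistic with Welch-Satterthwaite degrees
#' of freedom and a one-tailed p-value for the alternative
#' `mean(a) > mean(b)` (the spreadsheet convention "tail = 1,
#' type = 3").
#'
#' @param sample_a,sample_b Numeric vectors (each n >= 2).
#' @return List: `t`, `df`, `p`.
#' @export
welch_t_one_tailed <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) >= 2L, length(sample_b) >= 2L)
  ht <- t.test(sample_a, sample_b, alternative = "greater",
               var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
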