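#' Default pairwise-alignment scoring
#'
#' Match/mismatch scores with an affine gap penalty
#' (`gap_opening + gap_extension * gap_length` per gap).
#'
#' @param match,mismatch Substitution scores.
#' @param gap_opening,gap_extension Gap penalties (non-negative costs).
#' @return Scoring list.
#' @export
align_scoring <- function(match = 2, mismatch = -1,
                          gap_opening = 4, gap_extension = 1) {
  list(match = match, mismatch = mismatch,
       gap_opening = gap_opening, gap_extension = gap_extension)
}

guess_alphabet <- function(x) {
  if (grepl("^[ACGTUN]+$", x)) "nucleotide" else "protein"
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch global alignment (via the Biostrings dynamic
#' programming engine) with the given scoring, reporting the two
#' alignment statistics used by the duplication criteria: `identity`,
#' the fraction of matching columns over aligned columns (gap columns
#' count against identity; dual-gap columns are excluded), and
#' `coverage_longer`, the alignment length relative to the longer input
#' (capped at 1).
#'
#' @param a,b Sequences (both nucleotide or both amino acid).
#' @param scoring Scoring list from [align_scoring()].
#' @return Object of class `pairwise_alignment`: `aligned_a`,
#'   `aligned_b`, `score`, `identity`, `coverage_longer`.
#' @export
global_align <- function(a, b, scoring = align_scoring()) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  a <- toupper(a); b <- toupper(b)
  if (guess_alphabet(a) != guess_alphabet(b))
    stop("alphabet mismatch: one sequence looks nucleotide, the other protein")
  letters <- sort(unique(strsplit(paste0(a, b), "")[[1L]]))
  mat <- matrix(scoring$mismatch, length(letters), length(letters),
                dimnames = list(letters, letters))
  diag(mat) <- scoring$match
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b), type = "global",
    substitutionMatrix = mat, gapOpening = scoring$gap_opening,
    gapExtension = scoring$gap_extension)
  pa <- as.character(Biostrings::alignedPattern(aln))
  sa <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(pa, "")[[1L]]; cb <- strsplit(sa, "")[[1L]]
  keep <- !(ca == "-" & cb == "-")
  ncol_aln <- sum(keep)
  identity <- sum(ca[keep] == cb[keep] & ca[keep] != "-") / ncol_aln
  structure(list(
    aligned_a = pa, aligned_b = sa, score = Biostrings::score(aln),
    identity = identity,
    coverage_longer = min(1, ncol_aln / max(nchar(a), nchar(b)))),
    class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> score %.1f identity %.3f coverage %.3f\n",
              x$score, x$identity, x$coverage_longer))
  invisible(x)
}

#' Call tandem and segmental duplication events
#'
#' Candidate pairs are gene pairs whose global CDS alignment exceeds
#' both thresholds (`identity > min_identity` and
#' `coverage_longer > min_coverage`).  A passing pair is **tandem** when
#' both genes sit on the same chromosome and are separated by at most
#' `max_orfs` annotated genes *or* at most `max_span` bp of intergenic
#' distance; otherwise it is **segmental**.  Tightly linked tandem
#' pairs are collapsed into a single event per connected component, so
#' a chain of adjacent duplicates counts once.
#'
#' @param catalog Data frame with `gene_id`, `chromosome`, `start`,
#'   `end`, `placed` (see [read_catalog()]).
#' @param cds_by_gene Named character vector of CDS, keyed by gene id.
#' @param min_identity,min_coverage Alignment thresholds (strict `>`).
#' @param max_orfs,max_span Tandem linkage criteria (inclusive `<=`).
#' @param all_orfs Data frame of the full ordered gene complement
#'   (`gene_id`, `chromosome`, `start`) used to count intervening ORFs;
#'   defaults to the catalog itself.
#' @param scoring Alignment scoring, see [align_scoring()].
#' @return Data frame of events: `members` (comma-joined gene ids,
#'   ordered by position), `kind`, `identity`, `coverage`, `span_bp`,
#'   `intervening_orfs`.  Cluster rows report the minimum
#'   identity/coverage and the maximum spacing over their linked pairs.
#' @export
call_duplications <- function(catalog, cds_by_gene, min_identity = 0.8,
                              min_coverage = 0.8, max_orfs = 15L,
                              max_span = 30000L, all_orfs = NULL,
                              scoring = align_scoring()) {
  if (is.null(all_orfs)) all_orfs <- catalog
  genes <- catalog[catalog$gene_id %in% names(cds_by_gene), , drop = FALSE]
  n <- nrow(genes)
  orf_rank <- function(chrom) {
    orfs <- all_orfs[!is.na(all_orfs$chromosome) &
                       all_orfs$chromosome == chrom, , drop = FALSE]
    setNames(rank(orfs$start, ties.method = "first"), orfs$gene_id)
  }
  pairs <- list()
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in (i + 1L):n) {
      aln <- global_align(cds_by_gene[[genes$gene_id[[i]]]],
                          cds_by_gene[[genes$gene_id[[j]]]], scoring)
      if (!(aln$identity > min_identity && aln$coverage_longer > min_coverage))
        next
      gi <- genes[i, ]; gj <- genes[j, ]
      tandem <- FALSE; span <- NA_integer_; orfs_between <- NA_integer_
      if (is.na(gi$placed) || is.na(gj$placed) || !gi$placed || !gj$placed) {
        warning("pair ", gi$gene_id, "/", gj$gene_id,
                " has unplaced member(s); excluded from tandem evaluation")
      } else if (identical(gi$chromosome, gj$chromosome)) {
        span <- max(0L, max(gi$start, gj$start) - min(gi$end, gj$end))
        rk <- orf_rank(gi$chromosome)
        orfs_between <- abs(rk[[gi$gene_id]] - rk[[gj$gene_id]]) - 1L
        tandem <- orfs_between <= max_orfs || span <= max_span
      }
      pairs[[length(pairs) + 1L]] <- list(
        a = gi$gene_id, b = gj$gene_id, tandem = tandem,
        identity = aln$identity, coverage = aln$coverage_longer,
        span_bp = span, intervening_orfs = orfs_between)
    }
  }
  events <- list()
  # tandem pairs collapse into connected components
  tp <- Filter(function(p) p$tandem, pairs)
  if (length(tp)) {
    comp <- setNames(seq_along(unique(unlist(lapply(tp, function(p) c(p$a, p$b))))),
                     unique(unlist(lapply(tp, function(p) c(p$a, p$b)))))
    for (p in tp) {
      ca <- comp[[p$a]]; cb <- comp[[p$b]]
      if (ca != cb) comp[comp == cb] <- ca
    }
    for (cid in unique(comp)) {
      members <- names(comp)[comp == cid]
      members <- members[order(genes$start[match(members, genes$gene_id)])]
      cp <- Filter(function(p) p$a %in% members && p$b %in% members, tp)
      events[[length(events) + 1L]] <- data.frame(
        members = paste(members, collapse = ","), kind = "tandem",
        identity = min(vapply(cp, `[[`, 1, "identity")),
        coverage = min(vapply(cp, `[[`, 1, "coverage")),
        span_bp = max(vapply(cp, `[[`, 1L, "span_bp")),
        intervening_orfs = max(vapply(cp, `[[`, 1L, "intervening_orfs")),
        stringsAsFactors = FALSE)
    }
  }
  for (p in Filter(function(p) !p$tandem, pairs)) {
    events[[length(events) + 1L]] <- data.frame(
      members = paste(c(p$a, p$b), collapse = ","), kind = "segmental",
      identity = p$identity, coverage = p$coverage, span_bp = p$span_bp,
      intervening_orfs = p$intervening_orfs, stringsAsFactors = FALSE)
  }
  if (!length(events))
    return(data.frame(members = character(0), kind = character(0),
                      identity = numeric(0), coverage = numeric(0),
                      span_bp = integer(0), intervening_orfs = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, events)
}

# --- Nei-Gojobori (1986) -----------------------------------------------

NUCS <- c("A", "C", "G", "T")

codon_aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

# Synonymous site count of one codon: per position, the fraction of the
# three possible changes that preserve the amino acid.  Changes to stop
# codons count as non-synonymous.
ng86_syn_sites <- function(codon) {
  aa <- codon_aa(codon)
  s <- 0
  for (p in 1:3) {
    for (nt in setdiff(NUCS, substr(codon, p, p))) {
      alt <- codon
      substr(alt, p, p) <- nt
      if (identical(codon_aa(alt), aa)) s <- s + 1 / 3
    }
  }
  s
}

# Pathway-averaged (syn, nonsyn) difference counts between two codons.
# Multi-hit codons average over all orders of the single-site steps;
# pathways passing through a stop codon are excluded (unless every
# pathway does).
ng86_codon_diffs <- function(ca, cb) {
  pos <- which(strsplit(ca, "")[[1L]] != strsplit(cb, "")[[1L]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- if (k == 1L) list(pos) else {
    idx <- combinat_perms(k)
    lapply(idx, function(o) pos[o])
  }
  path_counts <- list()
  for (order_ in perms) {
    cur <- ca
    sd <- 0; nd <- 0; ok <- TRUE
    for (p in order_) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (codon_aa(nxt) == "*" && nxt != cb) { ok <- FALSE; break }
      if (identical(codon_aa(cur), codon_aa(nxt))) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) path_counts[[length(path_counts) + 1L]] <- c(sd = sd, nd = nd)
  }
  if (!length(path_counts)) {           # all pathways hit a stop: keep all
    for (order_ in perms) {
      cur <- ca; sd <- 0; nd <- 0
      for (p in order_) {
        nxt <- cur
        substr(nxt, p, p) <- substr(cb, p, p)
        if (identical(codon_aa(cur), codon_aa(nxt))) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      path_counts[[length(path_counts) + 1L]] <- c(sd = sd, nd = nd)
    }
  }
  colMeans(do.call(rbind, path_counts))
}

# All permutations of 1..k (k <= 3 here).
combinat_perms <- function(k) {
  if (k == 1L) return(list(1L))
  if (k == 2L) return(list(c(1L, 2L), c(2L, 1L)))
  out <- list()
  for (i in 1:3) for (j in setdiff(1:3, i)) out[[length(out) + 1L]] <-
      c(i, j, setdiff(1:3, c(i, j)))
  out
}

#' Nei-Gojobori (1986) Ka/Ks for a codon-aligned CDS pair
#'
#' Classic NG86: synonymous/non-synonymous site counts per codon
#' averaged over the two sequences, pathway-averaged difference counts
#' for multi-hit codons (pathways through stop codons excluded), and
#' Jukes-Cantor correction of the proportions.
#'
#' @param cds_a,cds_b Equal-length, gap-free, in-frame coding sequences
#'   without internal stop codons (trailing stop codons, if present on
#'   both, are trimmed).
#' @return Object of class `kaks_result`: `ka`, `ks`, `ratio` (`NA`
#'   when `ks` is 0 or undefined), `pn`, `ps`, `n_sites`, `s_sites`,
#'   `flagged` (`TRUE` when a proportion reaches 3/4 and the correction
#'   is undefined).
#' @export
ng86_kaks <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b)) stop("CDS lengths differ")
  if (nchar(cds_a) %% 3L != 0L) stop("CDS length not divisible by 3")
  if (grepl("-", paste0(cds_a, cds_b), fixed = TRUE)) stop("gap in CDS")
  n <- nchar(cds_a)
  ca <- substring(cds_a, seq(1L, n, 3L), seq(3L, n, 3L))
  cb <- substring(cds_b, seq(1L, n, 3L), seq(3L, n, 3L))
  if (length(ca) > 1L && codon_aa(ca[length(ca)]) == "*" &&
      codon_aa(cb[length(cb)]) == "*") {
    ca <- ca[-length(ca)]; cb <- cb[-length(cb)]
  }
  if (any(codon_aa(ca) == "*") || any(codon_aa(cb) == "*"))
    stop("internal stop codon")
  S <- (sum(vapply(ca, ng86_syn_sites, 1)) +
          sum(vapply(cb, ng86_syn_sites, 1))) / 2
  N <- 3 * length(ca) - S
  diffs <- mapply(function(x, y) ng86_codon_diffs(x, y), ca, cb)
  Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])
  ps <- Sd / S; pn <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -3 / 4 * log(1 - 4 * p / 3) + 0
  ks <- jc(ps); ka <- jc(pn)
  flagged <- is.na(ks) || is.na(ka)
  ratio <- if (flagged || ks == 0) NA_real_ else ka / ks
  structure(list(ka = ka, ks = ks, ratio = ratio, pn = pn, ps = ps,
                 n_sites = N, s_sites = S, flagged = flagged),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("<kaks_result> Ka %.4f Ks %.4f Ka/Ks %s%s\n",
              x$ka, x$ks,
              if (is.na(x$ratio)) "undefined" else sprintf("%.4f", x$ratio),
              if (x$flagged) " [flagged: correction undefined]" else ""))
  invisible(x)
}

#' Amino-acid p-distance between two aligned rows
#'
#' Mismatches over compared sites under pairwise deletion: columns in
#' which either row carries a gap are excluded.
#'
#' @param seq_a,seq_b Equal-length aligned sequences (gaps `-` allowed).
#' @param gap Gap character.
#' @return Fraction of differing compared sites (`NA` if no site is
#'   comparable).
#' @export
p_distance <- function(seq_a, seq_b, gap = "-") {
  if (nchar(seq_a) != nchar(seq_b)) stop("aligned rows differ in length")
  a <- strsplit(toupper(seq_a), "")[[1L]]
  b <- strsplit(toupper(seq_b), "")[[1L]]
  keep <- a != gap & b != gap
  if (!any(keep)) return(NA_real_)
  sum(a[keep] != b[keep]) / sum(keep)
}

#' Pairwise p-distance matrix of a multiple alignment
#'
#' @param alignment Named character vector of equal-length aligned rows.
#' @return Symmetric matrix of pairwise-deletion p-distances.
#' @export
pdist_matrix <- function(alignment) {
  n <- length(alignment)
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- p_distance(alignment[[i]], alignment[[j]])
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with pinned determinism: ties in the
#' Q-criterion are broken by the smallest `(i, j)` index pair of the
#' current matrix, and negative branch lengths are clamped to zero with
#' the deficit moved to the sister edge (preserving the joined pair's
#' distance).
#'
#' @param d Symmetric, zero-diagonal distance matrix (n >= 2) with
#'   unique row names, or a `dist` object.
#' @return An unrooted [ape::read.tree()] `phylo` object (trifurcating
#'   at the root node for n >= 3).
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("asymmetric distance matrix")
  if (any(diag(d) != 0)) stop("non-zero diagonal")
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (anyDuplicated(labels)) stop("duplicate taxa labels")
  node <- labels
  fmt <- function(x) sprintf("%.10g", max(0, x))
  while (n > 3L) {
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    idx <- which(q == min(q), arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    i <- idx[1L, 1L]; j <- idx[1L, 2L]
    li <- d[i, j] / 2 + (r[[i]] - r[[j]]) / (2 * (n - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    merged <- sprintf("(%s:%s,%s:%s)", node[[i]], fmt(li), node[[j]], fmt(lj))
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    node <- c(node[keep], merged)
    n <- n - 1L
  }
  newick <- if (n == 2L) {
    sprintf("(%s:%s,%s:%s);", node[[1L]], fmt(d[1L, 2L] / 2),
            node[[2L]], fmt(d[1L, 2L] / 2))
  } else {
    l1 <- (d[1L, 2L] + d[1L, 3L] - d[2L, 3L]) / 2
    l2 <- (d[1L, 2L] + d[2L, 3L] - d[1L, 3L]) / 2
    l3 <- (d[1L, 3L] + d[2L, 3L] - d[1L, 2L]) / 2
    sprintf("(%s:%s,%s:%s,%s:%s);", node[[1L]], fmt(l1),
            node[[2L]], fmt(l2), node[[3L]], fmt(l3))
  }
  ape::read.tree(text = newick)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the full-data NJ tree from pairwise-deletion p-distances,
#' then resamples alignment columns with replacement `n_reps` times;
#' the support of each internal edge is the percentage of replicate
#' trees containing the same bipartition, written into the tree's
#' `node.label`.
#'
#' @param alignment Named character vector of equal-length aligned
#'   amino-acid rows (>= 4 rows).
#' @param n_reps Number of bootstrap replicates.
#' @param seed Integer seed (column resampling is the only randomness).
#' @return `phylo` object with `node.label` supports in \[0, 100\].
#' @export
bootstrap_support <- function(alignment, n_reps = 1000L, seed = 1L) {
  stopifnot(length(alignment) >= 4L)
  L <- unique(nchar(alignment))
  if (length(L) != 1L) stop("alignment rows differ in length")
  rows <- do.call(rbind, strsplit(alignment, ""))
  rownames(rows) <- names(alignment)
  dist_of <- function(mat) {
    aln <- setNames(apply(mat, 1L, paste, collapse = ""), rownames(mat))
    pdist_matrix(aln)
  }
  full <- neighbor_joining(dist_of(rows))
  reps <- withr::with_seed(seed, {
    lapply(seq_len(n_reps), function(i) {
      neighbor_joining(dist_of(rows[, sample.int(L, L, replace = TRUE),
                                    drop = FALSE]))
    })
  })
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  full$node.label <- round(100 * counts / n_reps, 1L)
  full
}
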