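# Independent oracles used to pin expected values.  These deliberately
# share no code with the package implementations they check.

# --- exhaustive 8-subset ECM oracle ------------------------------------
# Enumerates every choice of 8 cysteines, keeps those satisfying the
# backbone constraints (adjacent CC dyad at slots 3-4, CXC with
# 0 <= inner <= max_inner at slots 5-6), and minimizes
# (stray cysteines inside the span, then the position vector).
oracle_scan_positions <- function(mature, max_inner = 3L) {
  pos <- which(strsplit(toupper(mature), "")[[1L]] == "C")
  if (length(pos) < 8L) return(NULL)
  subsets <- combn(pos, 8L)
  best <- NULL
  best_key <- NULL
  for (s in seq_len(ncol(subsets))) {
    p <- subsets[, s]
    if (p[[4L]] != p[[3L]] + 1L) next
    inner <- p[[6L]] - p[[5L]] - 1L
    if (inner < 0L || inner > max_inner) next
    key <- c(sum(pos > p[[1L]] & pos < p[[8L]]) - 6L, p)
    if (is.null(best_key)) { best_key <- key; best <- p; next }
    diff_at <- which(key != best_key)
    if (length(diff_at) && key[[diff_at[[1L]]]] < best_key[[diff_at[[1L]]]]) {
      best_key <- key; best <- p
    }
  }
  best
}

# --- independent NG86 counting oracle ----------------------------------
GENCODE <- Biostrings::GENETIC_CODE

oracle_syn_sites_codon <- function(codon) {
  nts <- c("A", "C", "G", "T")
  chars <- strsplit(codon, "")[[1L]]
  syn <- 0
  for (p in 1:3) {
    for (alt in nts[nts != chars[[p]]]) {
      mutant <- chars
      mutant[[p]] <- alt
      if (GENCODE[[paste(mutant, collapse = "")]] == GENCODE[[codon]])
        syn <- syn + 1
    }
  }
  syn / 3
}

# DFS over mutation orders; drops paths visiting a stop codon unless all do.
oracle_codon_paths <- function(from, to) {
  diff_pos <- which(strsplit(from, "")[[1L]] != strsplit(to, "")[[1L]])
  walk <- function(cur, remaining, sd, nd, allow_stop) {
    if (!length(remaining)) return(list(c(sd, nd)))
    res <- list()
    for (p in remaining) {
      nxt_chars <- strsplit(cur, "")[[1L]]
      nxt_chars[[p]] <- substr(to, p, p)
      nxt <- paste(nxt_chars, collapse = "")
      if (GENCODE[[nxt]] == "*" && nxt != to && !allow_stop) next
      step_syn <- GENCODE[[cur]] == GENCODE[[nxt]]
      res <- c(res, walk(nxt, setdiff(remaining, p),
                         sd + step_syn, nd + !step_syn, allow_stop))
    }
    res
  }
  paths <- walk(from, diff_pos, 0, 0, allow_stop = FALSE)
  if (!length(paths)) paths <- walk(from, diff_pos, 0, 0, allow_stop = TRUE)
  colMeans(do.call(rbind, paths))
}

oracle_ng86 <- function(cds_a, cds_b) {
  n <- nchar(cds_a)
  ca <- substring(cds_a, seq(1, n, 3), seq(3, n, 3))
  cb <- substring(cds_b, seq(1, n, 3), seq(3, n, 3))
  if (GENCODE[[ca[[length(ca)]]]] == "*") {
    ca <- ca[-length(ca)]; cb <- cb[-length(cb)]
  }
  S <- mean(c(sum(sapply(ca, oracle_syn_sites_codon)),
              sum(sapply(cb, oracle_syn_sites_codon))))
  N <- 3 * length(ca) - S
  d <- rowSums(mapply(oracle_codon_paths, ca, cb))
  ps <- d[[1L]] / S; pn <- d[[2L]] / N
  corr <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - p / 0.75)
  list(ks = corr(ps), ka = corr(pn), ps = ps, pn = pn)
}

# --- brute-force global-alignment score (no DP table) ------------------
# Enumerates every monotone alignment recursively; linear gap penalty.
oracle_best_align_score <- function(a, b, match = 1, mismatch = -1,
                                    gap = -1) {
  rec <- function(i, j) {
    if (i > nchar(a) && j > nchar(b)) return(0)
    best <- -Inf
    if (i <= nchar(a) && j <= nchar(b)) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1))
    }
    if (i <= nchar(a)) best <- max(best, gap + rec(i + 1, j))
    if (j <= nchar(b)) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# --- misc helpers ------------------------------------------------------
random_protein <- function(len, n_cys, alphabet = setdiff(c(
  "A", "R", "N", "D", "E", "Q", "G", "H", "I", "L", "K", "M", "F", "P",
  "S", "T", "W", "Y", "V"), "")) {
  res <- sample(alphabet, len, replace = TRUE)
  if (n_cys > 0L) res[sample.int(len, n_cys)] <- "C"
  paste(res, collapse = "")
}

random_cds_pair <- function(n_codons, n_mut) {
  sense <- names(GENCODE)[GENCODE != "*"]
  repeat {
    a_codons <- sample(sense, n_codons, replace = TRUE)
    a <- paste(a_codons, collapse = "")
    b <- strsplit(a, "")[[1L]]
    for (p in sample(nchar(a), n_mut)) {
      nts <- setdiff(c("A", "C", "G", "T"), b[[p]])
      repeat {
        trial <- b
        trial[[p]] <- sample(nts, 1L)
        ci <- (p - 1L) %/% 3L
        codon <- paste(trial[(ci * 3 + 1):(ci * 3 + 3)], collapse = "")
        if (GENCODE[[codon]] != "*") { b <- trial; break }
      }
    }
    b <- paste(b, collapse = "")
    return(list(a = a, b = b))
  }
}
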