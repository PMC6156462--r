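#' Load the type-classification rule table
#'
#' The nsLTP type system is decided by the ECM gap signature: the first
#' gap `g1` separates most types outright (6 = VIII, 7 = II,
#' 8 = nsLTPy, 10 = VI, 13 = IX, 14 = V) and the `g1 = 9` types are
#' split on `g3` and `g4` (g3 19-20 = I, g3 13 = XI, g3 9 with g4 12 =
#' III, g3 9 or 12 with g4 22-24 = IV).  The ranges are configuration,
#' shipped as a data file; rules are tried in file order and the first
#' match wins.
#'
#' Each rule cell is `*` (any), a comma list (`19,20`), or an inclusive
#' range (`22-24`).
#'
#' @param path Rule file; defaults to the packaged table derived from
#'   the 138-gene cotton catalog.
#' @return Data frame of rules (class `type_rules`).
#' @export
load_type_rules <- function(path = system.file("extdata", "type_rules.tsv",
                                               package = "nsltp")) {
  rules <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  stopifnot(all(c("type", "g1", "g3", "g4") %in% names(rules)))
  structure(rules, class = c("type_rules", "data.frame"))
}

# Does a gap value satisfy a rule cell?
rule_cell_matches <- function(cell, value) {
  if (cell == "*") return(TRUE)
  if (grepl("^\\d+-\\d+$", cell)) {
    b <- as.integer(strsplit(cell, "-", fixed = TRUE)[[1L]])
    return(value >= b[[1L]] && value <= b[[2L]])
  }
  value %in% as.integer(strsplit(cell, ",", fixed = TRUE)[[1L]])
}

#' Classify an nsLTP by its ECM gap signature
#'
#' Applies the rule table (see [load_type_rules()]) to a gap signature.
#' Signatures matched by no rule are labelled `"unknown"` unless
#' `fallback = TRUE`, in which case the nearest catalog signature (by
#' Euclidean distance in gap space) lends its type, recorded as a
#' `nearest-reference` rule.
#'
#' @param signature A [gap_signature()] or ECM pattern string.
#' @param rules A `type_rules` table.
#' @param fallback Use the nearest-reference fallback for unmatched
#'   signatures (off by default).
#' @param catalog Catalog used by the fallback (defaults to the packaged
#'   fixture).
#' @return List (class `type_assignment`): `type_label`, `rule_fired`.
#' @export
classify_type <- function(signature, rules = load_type_rules(),
                          fallback = FALSE, catalog = NULL) {
  if (is.character(signature)) signature <- parse_pattern(signature)
  stopifnot(inherits(signature, "gap_signature"))
  for (i in seq_len(nrow(rules))) {
    if (rule_cell_matches(rules$g1[[i]], signature$g1) &&
        rule_cell_matches(rules$g3[[i]], signature$g3) &&
        rule_cell_matches(rules$g4[[i]], signature$g4)) {
      return(structure(list(
        type_label = rules$type[[i]],
        rule_fired = sprintf("g1=%s g3=%s g4=%s -> %s", rules$g1[[i]],
                             rules$g3[[i]], rules$g4[[i]], rules$type[[i]])),
        class = "type_assignment"))
    }
  }
  if (fallback) {
    if (is.null(catalog)) catalog <- read_catalog()
    ref <- t(vapply(catalog$ecm_pattern,
                    function(p) unlist(parse_pattern(p)), numeric(6L)))
    d <- sqrt(rowSums(sweep(ref, 2L, unlist(signature))^2))
    i <- which.min(d)
    return(structure(list(
      type_label = catalog$type_label[[i]],
      rule_fired = sprintf("nearest-reference %s (gap distance %.2f)",
                           catalog$gene_name[[i]], d[[i]])),
      class = "type_assignment"))
  }
  structure(list(type_label = "unknown", rule_fired = "no rule matched"),
            class = "type_assignment")
}

#' @export
print.type_assignment <- function(x, ...) {
  cat("<type_assignment>", x$type_label, "--", x$rule_fired, "\n")
  invisible(x)
}

#' Run the nsLTP identification filter cascade
#'
#' Applies the published five-stage cascade to candidate gene records,
#' in this fixed order; each record is removed at the first stage it
#' fails:
#'
#' 1. no signal peptide (`sp_len` unknown or 0);
#' 2. mature protein longer than `max_mature_len` residues;
#' 3. no eight-cysteine motif on the mature protein ([scan_ecm()]);
#' 4. precursor not starting with methionine;
#' 5. (optional) external domain-verification flag false.
#'
#' The length threshold is strict (`> max_mature_len` is removed, so a
#' mature protein of exactly 120 residues is retained).
#'
#' @param records List of [gene_record()] objects.
#' @param max_mature_len Mature-length cutoff in residues.
#' @param require_domain Apply stage 5 using each record's `domain_ok`
#'   flag (`NA` flags are treated as verified).
#' @return Object of class `filter_report`: per-stage removal tallies
#'   and `survivors` (gene ids in input order).
#' @export
filter_candidates <- function(records, max_mature_len = 120L,
                              require_domain = FALSE) {
  stages <- c("no_signal", "long_mature", "missing_cys", "no_start_met",
              "no_domain")
  removed <- setNames(vector("list", length(stages)), stages)
  survivors <- character(0)
  for (rec in records) {
    stopifnot(inherits(rec, "gene_record"))
    fail <- NULL
    if (is.na(rec$sp_len) || rec$sp_len == 0L) {
      fail <- "no_signal"
    } else {
      mature <- derive_mature(rec$protein, rec$sp_len)
      if (nchar(mature) > max_mature_len) fail <- "long_mature"
      else if (is.null(scan_ecm(mature))) fail <- "missing_cys"
      else if (substr(rec$protein, 1L, 1L) != "M") fail <- "no_start_met"
      else if (require_domain && isFALSE(rec$domain_ok)) fail <- "no_domain"
    }
    if (is.null(fail)) survivors <- c(survivors, rec$gene_id)
    else removed[[fail]] <- c(removed[[fail]], rec$gene_id)
  }
  structure(list(
    n_input = length(records),
    removed_no_signal = length(removed$no_signal),
    removed_long_mature = length(removed$long_mature),
    removed_missing_cys = length(removed$missing_cys),
    removed_no_start_met = length(removed$no_start_met),
    removed_no_domain = length(removed$no_domain),
    removed_ids = lapply(removed, function(x) as.character(x %||% character(0))),
    survivors = survivors), class = "filter_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>", x$n_input, "candidates\n")
  cat("  - no signal peptide: ", x$removed_no_signal, "\n")
  cat("  - mature protein too long:", x$removed_long_mature, "\n")
  cat("  - eight-cysteine motif absent:", x$removed_missing_cys, "\n")
  cat("  - no start methionine:", x$removed_no_start_met, "\n")
  cat("  - domain verification failed:", x$removed_no_domain, "\n")
  cat("  =>", length(x$survivors), "confirmed nsLTP genes\n")
  invisible(x)
}

#' Chromosome distribution of catalog genes
#'
#' Counts placed genes per chromosome (optionally per type), excluding
#' unplaced genes, which are reported separately.
#'
#' @param catalog Catalog data frame from [read_catalog()].
#' @return List: `counts` (named vector, by chromosome, sorted by name),
#'   `by_type` (chromosome x type table), `unplaced` (gene names).
#' @export
chromosome_distribution <- function(catalog) {
  placed <- catalog[catalog$placed, , drop = FALSE]
  counts <- table(placed$chromosome)
  counts <- setNames(as.integer(counts), names(counts))
  counts <- counts[order(names(counts))]
  by_type <- table(placed$chromosome, placed$type_label)
  list(counts = counts, by_type = by_type,
       unplaced = catalog$gene_name[!catalog$placed])
}

#' Count introns of a gene model
#'
#' @param exons Two-column `start`/`end` exon matrix (one gene), as
#'   returned per gene by [read_gff_exons()].
#' @return Number of introns (`n_exons - 1`).
#' @export
count_introns <- function(exons) {
  stopifnot(is.matrix(exons), nrow(exons) >= 1L)
  nrow(exons) - 1L
}
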