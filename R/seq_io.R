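#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and whitespace/gap characters are stripped;
#' record order is preserved.
#'
#' @param path Path to a FASTA file.  An empty file yields an empty vector.
#' @return Named character vector of sequences (names = record ids, the
#'   first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) return(setNames(character(0), character(0)))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id: ", dup[[1L]])
  seqs <- toupper(as.character(set))
  seqs <- gsub("[-. \t]", "", seqs)
  setNames(unname(seqs), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[[i]]), con)
    s <- seqs[[i]]
    if (nchar(s)) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    }
  }
  invisible(path)
}

#' Parse a catalog location string
#'
#' Location strings come in three dialects:
#' `"A02:3177157,3177498"` (placed on a chromosome),
#' `"scaffold2284A09:62025,62414"` (scaffold attributed to the embedded
#' chromosome, here A09), and `"scaffold5825:3233,3625"` (bare scaffold,
#' unplaced).  Coordinates are 1-based inclusive.
#'
#' @param loc Character vector of location strings.
#' @return Data frame with columns `chromosome` (NA when unplaced),
#'   `start`, `end`, `placed`.
#' @export
parse_location <- function(loc) {
  n <- length(loc)
  out <- data.frame(chromosome = rep(NA_character_, n),
                    start = rep(NA_integer_, n), end = rep(NA_integer_, n),
                    placed = rep(FALSE, n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    parts <- strsplit(loc[[i]], ":", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !grepl("^\\d+,\\d+$", parts[[2L]])) {
      warning("unparseable location, marking unplaced: ", loc[[i]])
      next
    }
    span <- as.integer(strsplit(parts[[2L]], ",", fixed = TRUE)[[1L]])
    out$start[[i]] <- span[[1L]]
    out$end[[i]] <- span[[2L]]
    seqname <- parts[[1L]]
    m <- regmatches(seqname, regexec("^(?:scaffold\\d+)?([AD]\\d{2})$", seqname))[[1L]]
    if (length(m) == 2L) {
      out$chromosome[[i]] <- m[[2L]]
      out$placed[[i]] <- TRUE
    } else if (!grepl("^scaffold\\d+$", seqname)) {
      warning("unparseable location, marking unplaced: ", loc[[i]])
    }
  }
  out
}

#' Read a Table 1-style nsLTP gene catalog
#'
#' Reads a tab-separated catalog with the published table's columns (gene
#' name, gene id, chromosome location, strand, CDS length, precursor
#' length AA, signal peptide SP, mature protein MP, ECM pattern, MW, pI)
#' plus the type label.  Locations are parsed with [parse_location()];
#' en-dash strand marks are normalized to `"-"`.
#'
#' @param path Path to the catalog TSV.  Defaults to the packaged
#'   *G. hirsutum* fixture (138 genes).
#' @return Data frame with one row per gene: `gene_name`, `gene_id`,
#'   `chromosome`, `start`, `end`, `placed`, `strand`, `cds_len`,
#'   `aa_len`, `sp_len`, `mp_len`, `ecm_pattern`, `mw`, `pi`,
#'   `type_label`.
#' @export
read_catalog <- function(path = system.file("extdata", "ghltp_table1.tsv",
                                            package = "nsltp")) {
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  need <- c("Name", "Gene ID", "Chromosome location", "Strand",
            "CDS Length (bp)", "AA", "SP", "MP (AA)", "ECM",
            "MP (MW)", "MP (pI)")
  missing <- setdiff(need, names(raw))
  if (length(missing)) stop("catalog lacks columns: ",
                            paste(missing, collapse = ", "))
  locs <- parse_location(raw[["Chromosome location"]])
  strand <- raw[["Strand"]]
  strand[strand %in% c("–", "−", "—")] <- "-"
  if (!all(strand %in% c("+", "-"))) stop("invalid strand value")
  out <- data.frame(
    gene_name = raw[["Name"]],
    gene_id = raw[["Gene ID"]],
    chromosome = locs$chromosome,
    start = locs$start,
    end = locs$end,
    placed = locs$placed,
    strand = strand,
    cds_len = as.integer(raw[["CDS Length (bp)"]]),
    aa_len = as.integer(raw[["AA"]]),
    sp_len = as.integer(raw[["SP"]]),
    mp_len = as.integer(raw[["MP (AA)"]]),
    ecm_pattern = raw[["ECM"]],
    mw = as.numeric(raw[["MP (MW)"]]),
    pi = as.numeric(raw[["MP (pI)"]]),
    type_label = if ("Type" %in% names(raw)) raw[["Type"]] else NA_character_,
    stringsAsFactors = FALSE
  )
  bad <- which(out$placed & out$start > out$end)
  if (length(bad)) stop("span start > end for ", out$gene_id[bad[[1L]]])
  out
}

#' Read exon structures from a GFF3 file
#'
#' Parses `gene`/`mRNA`/`exon` (and `CDS`) features and returns, per
#' gene, the exon intervals of its primary transcript (the mRNA with the
#' longest total CDS; total exon length is the fallback when no CDS
#' features are present).  Intervals are 1-based inclusive, sorted by
#' start.  Malformed lines and exons whose parent cannot be resolved are
#' skipped with a warning.
#'
#' @param path Path to a GFF3 file.
#' @return Named list (by gene id); each element a two-column integer
#'   matrix with columns `start`, `end`.
#' @export
read_gff_exons <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(structure(list(), names = character(0)))
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))[[1L]]
    if (length(m) == 2L) m[[2L]] else NA_character_
  }
  mrna_gene <- character(0)   # mRNA id -> gene id
  exons <- list()             # mRNA id -> list of c(start, end)
  cds_len <- numeric(0)       # mRNA id -> total CDS bp
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L || is.na(suppressWarnings(as.integer(f[[4L]])))) {
      warning("skipping malformed GFF line: ", substr(ln, 1L, 60L))
      next
    }
    type <- f[[3L]]
    start <- as.integer(f[[4L]]); end <- as.integer(f[[5L]])
    if (type == "mRNA") {
      id <- attr_get(f[[9L]], "ID"); parent <- attr_get(f[[9L]], "Parent")
      if (!is.na(id) && !is.na(parent)) mrna_gene[[id]] <- parent
    } else if (type == "exon" || type == "CDS") {
      parent <- attr_get(f[[9L]], "Parent")
      if (is.na(parent)) {
        warning("skipping ", type, " without Parent at ", f[[1L]], ":", start)
        next
      }
      if (type == "exon") {
        exons[[parent]] <- c(exons[[parent]], list(c(start, end)))
      } else {
        cds_len[[parent]] <- sum(cds_len[parent], end - start + 1L, na.rm = TRUE)
      }
    }
  }
  orphans <- setdiff(names(exons), names(mrna_gene))
  if (length(orphans)) {
    warning("skipping exons with unresolvable parent mRNA: ",
            paste(orphans, collapse = ", "))
    exons <- exons[setdiff(names(exons), orphans)]
  }
  out <- list()
  for (gene in unique(unname(mrna_gene))) {
    mrnas <- names(mrna_gene)[mrna_gene == gene]
    mrnas <- mrnas[mrnas %in% names(exons)]
    if (!length(mrnas)) next
    score <- vapply(mrnas, function(m) {
      if (!is.na(cds_len[m])) cds_len[[m]]
      else sum(vapply(exons[[m]], function(e) e[[2L]] - e[[1L]] + 1L, 1L))
    }, 1)
    best <- mrnas[[which.max(score)]]
    iv <- do.call(rbind, exons[[best]])
    colnames(iv) <- c("start", "end")
    iv <- iv[order(iv[, "start"]), , drop = FALSE]
    out[[gene]] <- iv
  }
  out
}

#' Write gene models (exon structures) to GFF3
#'
#' Inverse of [read_gff_exons()] for round-tripping synthetic gene
#' models: one gene + one mRNA + its exons per entry.
#'
#' @param exons_by_gene Named list of two-column `start`/`end` matrices.
#' @param path Output path.
#' @param seqid Sequence (chromosome) id to write, recycled over genes.
#' @return `path`, invisibly.
#' @export
write_gff_exons <- function(exons_by_gene, path, seqid = "chr1") {
  seqid <- rep_len(seqid, length(exons_by_gene))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_along(exons_by_gene)) {
    gene <- names(exons_by_gene)[[i]]
    iv <- exons_by_gene[[i]]
    span <- c(min(iv[, "start"]), max(iv[, "end"]))
    writeLines(sprintf("%s\tnsltp\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                       seqid[[i]], span[[1L]], span[[2L]], gene), con)
    mrna <- paste0(gene, ".t1")
    writeLines(sprintf("%s\tnsltp\tmRNA\t%d\t%d\t.\t+\t.\tID=%s;Parent=%s",
                       seqid[[i]], span[[1L]], span[[2L]], mrna, gene), con)
    for (j in seq_len(nrow(iv))) {
      writeLines(sprintf("%s\tnsltp\texon\t%d\t%d\t.\t+\t.\tParent=%s",
                         seqid[[i]], iv[j, "start"], iv[j, "end"], mrna), con)
    }
  }
  invisible(path)
}

#' Construct a gene record
#'
#' The unit record consumed by the identification cascade: identity,
#' placement, sequences, and the externally supplied signal-peptide
#' length (signal peptides are annotations, not predictions, throughout
#' the package).
#'
#' @param gene_id Gene identifier.
#' @param protein Precursor amino-acid sequence (may be `NA`).
#' @param sp_len Signal-peptide length in residues; `NA` means unknown
#'   (treated as lacking a signal peptide by the cascade).
#' @param cds Coding sequence (may be `NA`).
#' @param gene_name Display name; defaults to `gene_id`.
#' @param chromosome,start,end,strand Placement (optional).
#' @param domain_ok Optional external domain-verification flag.
#' @return An object of class `gene_record` (a list).
#' @export
gene_record <- function(gene_id, protein = NA_character_, sp_len = NA_integer_,
                        cds = NA_character_, gene_name = gene_id,
                        chromosome = NA_character_, start = NA_integer_,
                        end = NA_integer_, strand = NA_character_,
                        domain_ok = NA) {
  if (!is.na(cds) && nchar(cds) %% 3L != 0L)
    stop("cds length not divisible by 3 for ", gene_id)
  if (!is.na(cds) && !is.na(protein) &&
      nchar(protein) != nchar(cds) / 3L - 1L)
    stop("protein length != cds/3 - 1 for ", gene_id)
  structure(list(gene_id = gene_id, gene_name = gene_name,
                 chromosome = chromosome, start = start, end = end,
                 strand = strand, cds = cds, protein = protein,
                 sp_len = sp_len, domain_ok = domain_ok),
            class = "gene_record")
}

#' @export
print.gene_record <- function(x, ...) {
  cat("<gene_record>", x$gene_id,
      if (!is.na(x$chromosome)) paste0(x$chromosome, ":", x$start, "-", x$end)
      else "(unplaced)",
      if (!is.na(x$protein)) paste0(nchar(x$protein), " aa") else "",
      "\n")
  invisible(x)
}
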