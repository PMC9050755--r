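# Readers and writers for every external representation the package touches.
# Conventions: genome coordinates are 0-based half-open internally; GFF3 I/O
# converts its 1-based inclusive coordinates at this boundary and nowhere
# else. Ambiguity codes (N etc.) are preserved verbatim, never substituted,
# so that octamer windows containing them can be skipped downstream.

#' Read a genome FASTA into a named character vector
#'
#' Sequences are uppercased on read; ambiguity codes are preserved. Record
#' ids are the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) rlang::abort(paste0("empty FASTA: ", path))
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    rlang::abort(paste0("duplicate FASTA ids in ", path, ": ",
                        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  out <- toupper(as.character(ss))
  names(out) <- ids
  out
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

first_parent <- function(parent) {
  vapply(parent, function(p) if (length(p) >= 1L) p[[1L]] else NA_character_,
         character(1))
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/CDS (and optional five_prime_UTR) features into one
#' record per gene. `cds_start` is the 0-based genome index of the first CDS
#' base in gene orientation (the "head of CDS"): the lowest CDS coordinate on
#' `+`, the highest on `-`. Genes without any CDS are skipped with a warning.
#' When `tss_path` is given, experimentally determined peak TSS positions are
#' joined by `gene_id`.
#'
#' @param path Path to a GFF3 file.
#' @param tss_path Optional path to a TSS table TSV (see [read_tss_table()]).
#' @return Tibble with columns `gene_id`, `chrom`, `strand`, `cds_start`,
#'   `tss` (NA when unknown), and list-columns `cds` and `utr5` of 0-based
#'   half-open interval matrices.
#' @export
read_gene_models <- function(path, tss_path = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$ID <- as.character(df$ID)
  df$parent1 <- first_parent(df$Parent)

  genes <- df[df$type == "gene", , drop = FALSE]
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  tx2gene <- stats::setNames(mrna$parent1, mrna$ID)

  owner_gene <- function(parent) {
    ifelse(parent %in% genes$ID, parent, unname(tx2gene[parent]))
  }

  part_intervals <- function(type) {
    p <- df[df$type == type, , drop = FALSE]
    if (nrow(p) == 0L) return(list())
    p$gene <- owner_gene(p$parent1)
    lapply(split(seq_len(nrow(p)), p$gene), function(ix) {
      m <- cbind(p$start[ix] - 1, p$end[ix])
      m[order(m[, 1L]), , drop = FALSE]
    })
  }

  cds_by_gene <- part_intervals("CDS")
  utr_by_gene <- part_intervals("five_prime_UTR")

  n_skipped <- sum(!(genes$ID %in% names(cds_by_gene)))
  if (n_skipped > 0L) {
    rlang::warn(paste0(n_skipped, " gene(s) without CDS skipped"))
  }
  genes <- genes[genes$ID %in% names(cds_by_gene), , drop = FALSE]

  out <- tibble::tibble(
    gene_id = genes$ID,
    chrom = as.character(genes$seqnames),
    strand = as.character(genes$strand),
    cds_start = NA_real_,
    tss = NA_real_,
    cds = unname(cds_by_gene[genes$ID]),
    utr5 = lapply(genes$ID, function(g) {
      m <- utr_by_gene[[g]]
      if (is.null(m)) matrix(numeric(0), ncol = 2L) else m
    })
  )
  out$cds_start <- vapply(seq_len(nrow(out)), function(i) {
    m <- out$cds[[i]]
    if (out$strand[i] == "+") min(m[, 1L]) else max(m[, 2L]) - 1
  }, numeric(1))

  if (!is.null(tss_path)) {
    tss <- read_tss_table(tss_path)
    unknown <- setdiff(tss$gene_id, out$gene_id)
    if (length(unknown) > 0L) {
      rlang::warn(paste0(length(unknown), " TSS id(s) with no gene model"))
    }
    idx <- match(out$gene_id, tss$gene_id)
    out$tss <- tss$pos[idx]
  }
  out
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA, five_prime_UTR and CDS features (1-based inclusive
#' coordinates) from the internal 0-based half-open representation.
#'
#' @param genes Gene-model tibble as produced by [read_gene_models()] or
#'   [make_genome()]; must carry `gene_lo`/`gene_hi` columns or `cds`/`utr5`
#'   list-columns from which the extent is taken.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    cds <- g$cds[[1L]]
    utr <- if (!is.null(g$utr5)) g$utr5[[1L]] else matrix(numeric(0), ncol = 2L)
    lo <- if (!is.null(genes$gene_lo)) g$gene_lo else min(cds[, 1L], utr[, 1L])
    hi <- if (!is.null(genes$gene_hi)) g$gene_hi else max(cds[, 2L], utr[, 2L])
    row <- function(type, s, e, id, parent = NULL) {
      attrs <- paste0("ID=", id, if (!is.null(parent)) paste0(";Parent=", parent))
      paste(g$chrom, "pritss", type, s + 1L, e, ".", g$strand, ".", attrs,
            sep = "\t")
    }
    tid <- paste0(g$gene_id, ".1")
    lines <- c(lines,
               row("gene", lo, hi, g$gene_id),
               row("mRNA", lo, hi, tid, g$gene_id))
    if (nrow(utr) > 0L) {
      for (j in seq_len(nrow(utr))) {
        lines <- c(lines, row("five_prime_UTR", utr[j, 1L], utr[j, 2L],
                              paste0(tid, ".utr5.", j), tid))
      }
    }
    for (j in seq_len(nrow(cds))) {
      lines <- c(lines, row("CDS", cds[j, 1L], cds[j, 2L],
                            paste0(tid, ".cds.", j), tid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a TSS table
#'
#' TSV with '#' comment lines and columns `gene_id`, `chrom`, `pos` (0-based
#' peak TSS), `strand`, and optionally `category` and `tpm`. Extra columns
#' are kept.
#'
#' @param path Path to the TSV.
#' @return Tibble, one row per TSS.
#' @export
read_tss_table <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' Write a TSS table
#'
#' @param tss Tibble of TSS records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tss_table <- function(tss, path) {
  readr::write_tsv(tss, path)
  invisible(path)
}

#' Read a plain-text octamer list
#'
#' One octamer per line; '#' lines and blank lines are ignored.
#'
#' @param path Path to the list file.
#' @return Character vector of octamers.
#' @export
read_octamer_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  bad <- x[!grepl("^[ACGT]{8}$", x)]
  if (length(bad) > 0L) {
    rlang::abort(paste0("invalid octamer(s) in ", path, ": ",
                        paste(utils::head(bad, 3L), collapse = ", ")))
  }
  x
}

#' Write an octamer score table to TSV
#'
#' Header lines starting with '#' record the table kind, source windows,
#' pseudocount and normalization formula so that tables built differently are
#' never silently mixed. Scores are written with 17 significant digits so a
#' write/read round trip reproduces them bit-exactly.
#'
#' @param table An `octamer_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_octamer_table <- function(table, path) {
  stopifnot(inherits(table, "octamer_table"))
  hdr <- c(
    paste0("#kind=", attr(table, "kind")),
    paste0("#windows=", attr(table, "windows")),
    paste0("#pseudocount=", attr(table, "pseudocount")),
    "#formula=log2((c+pc)/(cbar+pc))"
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("octamer\tscore", con)
  writeLines(paste0(table$octamer, "\t", sprintf("%.17g", table$score)), con)
  invisible(path)
}

#' Read an octamer score table from TSV
#'
#' @param path Path written by [write_octamer_table()] (or any TSV with
#'   `octamer` and `score` columns covering all 4^8 octamers).
#' @return An `octamer_table`.
#' @export
read_octamer_table <- function(path) {
  head_lines <- readLines(path, n = 50L)
  meta_lines <- head_lines[startsWith(head_lines, "#")]
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#", "", ln), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) meta[[kv[1L]]] <- kv[2L]
  }
  # scores are parsed with base R's strtod so that the 17-significant-digit
  # representation written by write_octamer_table round-trips bit-exactly
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(
                          octamer = readr::col_character(),
                          score = readr::col_character()))
  if (nrow(df) != 65536L || anyDuplicated(df$octamer)) {
    rlang::abort("octamer table must have exactly 4^8 unique octamers")
  }
  scores <- numeric(65536L)
  scores[oct_index(df$octamer)] <- as.numeric(df$score)
  new_octamer_table(scores,
                    kind = meta$kind %||% "IGI",
                    windows = meta$windows %||% NA_character_,
                    pseudocount = as.numeric(meta$pseudocount %||% NA))
}

#' Write a score track to bedGraph
#'
#' Consecutive runs of equal value are merged into single intervals
#' (0-based half-open, as bedGraph requires).
#'
#' @param track A `score_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "score_track"))
  r <- rle(track$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  lines <- paste(track$chrom, starts, ends, sprintf("%.6g", r$values),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write prediction windows to BED6
#'
#' Intervals are 0-based half-open with the strand in column 6. The BED score
#' column is the peak height scaled into 0..1000 per BED convention; the raw
#' peak height (full precision) is kept in a companion TSV at
#' `paste0(path, ".tsv")`.
#'
#' @param windows Prediction tibble (columns `chrom`, `start`, `end`,
#'   `strand`, `peak_pos`, `peak_height`, optional `gene_id`).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(windows, path) {
  name <- if (!is.null(windows$gene_id) && !all(is.na(windows$gene_id))) {
    ifelse(is.na(windows$gene_id),
           sprintf("pred_%05d", seq_len(nrow(windows))), windows$gene_id)
  } else {
    sprintf("pred_%05d", seq_len(nrow(windows)))
  }
  bed_score <- as.integer(pmax(0, pmin(1000, round(windows$peak_height * 1000))))
  lines <- paste(windows$chrom, windows$start, windows$end, name, bed_score,
                 windows$strand, sep = "\t")
  writeLines(lines, path)
  comp <- tibble::tibble(
    gene_id = name, chrom = windows$chrom, start = windows$start,
    end = windows$end, strand = windows$strand, peak_pos = windows$peak_pos,
    peak_height = sprintf("%.17g", windows$peak_height))
  con <- file(paste0(path, ".tsv"), open = "wt")
  writeLines(paste(colnames(comp), collapse = "\t"), con)
  writeLines(do.call(paste, c(as.list(comp), sep = "\t")), con)
  close(con)
  invisible(path)
}

#' Read prediction windows written by [write_predictions()]
#'
#' Reads the full-precision companion TSV when present, else the BED6 file.
#'
#' @param path BED path given to [write_predictions()].
#' @return Prediction tibble.
#' @export
read_predictions <- function(path) {
  comp <- paste0(path, ".tsv")
  if (file.exists(comp)) {
    df <- readr::read_tsv(comp, show_col_types = FALSE,
                          col_types = readr::cols(
                            gene_id = readr::col_character(),
                            chrom = readr::col_character(),
                            start = readr::col_double(),
                            end = readr::col_double(),
                            strand = readr::col_character(),
                            peak_pos = readr::col_double(),
                            peak_height = readr::col_double()))
    return(tibble::as_tibble(df))
  }
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_names = c("chrom", "start", "end", "gene_id",
                                      "score", "strand"))
  tibble::tibble(gene_id = df$gene_id, chrom = df$chrom, start = df$start,
                 end = df$end, strand = df$strand,
                 peak_pos = NA_real_, peak_height = df$score / 1000)
}

#' Write a positional profile to TSV
#'
#' @param profile A `pri_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  readr::write_tsv(tibble::as_tibble(profile), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
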