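# External formats and coordinate conventions.
#
# All internal intervals are 0-based half-open [start, end); conversion to
# R/Biostrings 1-based coordinates happens only where sequence is extracted.

#' Construct a gene-model table
#'
#' One row per isoform. Coordinates follow the UCSC genePred convention:
#' `tx_start` is 0-based inclusive, `tx_end` exclusive. Exons are stored as
#' list-columns of integer vectors in the same convention.
#'
#' @param gene_id,isoform_id character vectors.
#' @param chrom chromosome names.
#' @param strand `"+"` or `"-"`.
#' @param tx_start,tx_end transcript span, 0-based half-open.
#' @param exon_starts,exon_ends list of integer vectors (one per isoform);
#'   defaults to a single exon spanning the transcript.
#' @return A `data.frame` with class `gene_models`.
#' @export
gene_models <- function(gene_id, isoform_id, chrom, strand, tx_start, tx_end,
                        exon_starts = NULL, exon_ends = NULL) {
  n <- length(gene_id)
  if (is.null(exon_starts)) exon_starts <- as.list(as.integer(tx_start))
  if (is.null(exon_ends)) exon_ends <- as.list(as.integer(tx_end))
  out <- data.frame(
    gene_id = as.character(gene_id),
    isoform_id = as.character(isoform_id),
    chrom = as.character(chrom),
    strand = as.character(strand),
    tx_start = as.integer(tx_start),
    tx_end = as.integer(tx_end),
    stringsAsFactors = FALSE
  )
  out$exon_starts <- lapply(exon_starts, as.integer)
  out$exon_ends <- lapply(exon_ends, as.integer)
  class(out) <- c("gene_models", "data.frame")
  validate_gene_models(out)
  out
}

validate_gene_models <- function(genes) {
  stopifnot(all(c("gene_id", "isoform_id", "chrom", "strand",
                  "tx_start", "tx_end", "exon_starts", "exon_ends") %in%
                  names(genes)))
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  if (any(genes$tx_start >= genes$tx_end)) {
    stop("tx_start must be < tx_end for every model")
  }
  for (i in seq_len(nrow(genes))) {
    s <- genes$exon_starts[[i]]
    e <- genes$exon_ends[[i]]
    if (length(s) != length(e) || any(s >= e)) {
      stop(sprintf("isoform '%s': malformed exon list", genes$isoform_id[i]))
    }
    if (any(s < genes$tx_start[i]) || any(e > genes$tx_end[i])) {
      stop(sprintf("isoform '%s': exon outside transcript span",
                   genes$isoform_id[i]))
    }
    if (length(s) > 1 && any(diff(s) <= 0 | utils::head(e, -1) > s[-1])) {
      stop(sprintf("isoform '%s': exons must be sorted and non-overlapping",
                   genes$isoform_id[i]))
    }
  }
  invisible(genes)
}

#' Gene length, TSS and TTS
#'
#' Gene length is the transcript span from TSS to TTS including introns.
#' The TSS is `tx_start` on the plus strand and `tx_end - 1` on the minus
#' strand (0-based positions); the TTS is the opposite end.
#'
#' @param genes a `gene_models` table.
#' @return Integer vector, one value per row.
#' @export
gene_length <- function(genes) genes$tx_end - genes$tx_start

#' @rdname gene_length
#' @export
tss <- function(genes) {
  ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1L)
}

#' @rdname gene_length
#' @export
tts <- function(genes) {
  ifelse(genes$strand == "+", genes$tx_end - 1L, genes$tx_start)
}

#' Read gene models from refFlat text
#'
#' Parses the 11-column UCSC refFlat format (genePred with a leading gene
#' symbol): geneName, name, chrom, strand, txStart, txEnd, cdsStart, cdsEnd,
#' exonCount, exonStarts, exonEnds. `txStart` is taken as 0-based and `txEnd`
#' as exclusive; trailing commas in the exon lists are tolerated.
#'
#' @param path path to a refFlat file.
#' @return A `gene_models` table, one row per isoform line.
#' @export
read_refflat <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty refFlat file: ", path)
  fields <- strsplit(lines, "[ \t]+")
  bad <- which(vapply(fields, length, 1L) < 11L)
  if (length(bad) > 0) {
    stop(sprintf("malformed refFlat line %d in '%s': expected 11 columns",
                 bad[1], path))
  }
  parse_pos_list <- function(x, line) {
    v <- suppressWarnings(as.integer(strsplit(x, ",")[[1]]))
    if (anyNA(v)) stop(sprintf("malformed exon list at refFlat line %d", line))
    v
  }
  n <- length(fields)
  col <- function(i) vapply(fields, `[[`, "", i)
  strand <- col(4)
  if (!all(strand %in% c("+", "-"))) {
    stop(sprintf("invalid strand at refFlat line %d",
                 which(!strand %in% c("+", "-"))[1]))
  }
  tx_start <- suppressWarnings(as.integer(col(5)))
  tx_end <- suppressWarnings(as.integer(col(6)))
  n_exons <- suppressWarnings(as.integer(col(9)))
  if (anyNA(tx_start) || anyNA(tx_end) || anyNA(n_exons)) {
    stop(sprintf("non-numeric coordinate at refFlat line %d",
                 which(is.na(tx_start) | is.na(tx_end) | is.na(n_exons))[1]))
  }
  exon_starts <- vector("list", n)
  exon_ends <- vector("list", n)
  for (i in seq_len(n)) {
    exon_starts[[i]] <- parse_pos_list(fields[[i]][10], i)
    exon_ends[[i]] <- parse_pos_list(fields[[i]][11], i)
    if (length(exon_starts[[i]]) != n_exons[i]) {
      stop(sprintf("exonCount mismatch at refFlat line %d", i))
    }
  }
  gene_models(col(1), col(2), col(3), strand, tx_start, tx_end,
              exon_starts, exon_ends)
}

#' Write gene models as refFlat text
#'
#' Inverse of [read_refflat()]: the cds span is written equal to the
#' transcript span (these analyses never use it). Round-tripping through
#' [read_refflat()] reproduces identical models.
#'
#' @param genes a `gene_models` table.
#' @param path output path.
#' @export
write_refflat <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    paste(genes$gene_id[i], genes$isoform_id[i], genes$chrom[i],
          genes$strand[i], genes$tx_start[i], genes$tx_end[i],
          genes$tx_start[i], genes$tx_end[i],
          length(genes$exon_starts[[i]]),
          paste0(paste(genes$exon_starts[[i]], collapse = ","), ","),
          paste0(paste(genes$exon_ends[[i]], collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Pick the most abundant isoform of each gene
#'
#' Per-gene statistics are always computed on a single isoform: the one with
#' the highest untreated RNA FPKM, following the convention of assigning reads
#' to the most abundant isoform in the matched control RNA-seq sample. Ties
#' are broken by longest gene length, then lexicographically smallest
#' isoform id. Genes with no expressed isoform are dropped with a warning.
#'
#' @param models a `gene_models` table (one row per isoform).
#' @param expr a data.frame with columns `isoform_id` and `rna_fpkm_unt`.
#' @return A `gene_models` table with one row per gene.
#' @export
select_most_abundant_isoform <- function(models, expr) {
  stopifnot(all(c("isoform_id", "rna_fpkm_unt") %in% names(expr)))
  fpkm <- expr$rna_fpkm_unt[match(models$isoform_id, expr$isoform_id)]
  keep <- !is.na(fpkm)
  dropped <- setdiff(models$gene_id, models$gene_id[keep])
  if (length(dropped) > 0) {
    warning(sprintf("%d gene(s) had no expressed isoform and were excluded",
                    length(dropped)))
  }
  m <- models[keep, , drop = FALSE]
  fpkm <- fpkm[keep]
  len <- gene_length(m)
  ord <- order(m$gene_id, -fpkm, -len, m$isoform_id)
  m <- m[ord, , drop = FALSE]
  out <- m[!duplicated(m$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Construct a fragment set
#'
#' Houses one condition's sequenced ChIP fragments as genomic intervals plus
#' the library size used for per-million normalization. `total_mapped` may
#' exceed the number of stored fragments (fragments mapping outside the
#' regions of interest still count toward library size).
#'
#' @param fragments data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param condition `"UNT"` or `"KD"`.
#' @param total_mapped total mapped fragments in the library; defaults to
#'   the number of fragment records.
#' @return A list with class `fragment_set`.
#' @export
fragment_set <- function(fragments, condition = c("UNT", "KD"),
                         total_mapped = NULL) {
  condition <- match.arg(condition)
  stopifnot(all(c("chrom", "start", "end") %in% names(fragments)))
  bad <- which(fragments$start >= fragments$end)
  if (length(bad) > 0) {
    stop(sprintf("fragment record %d has start >= end (%s:%d-%d)",
                 bad[1], fragments$chrom[bad[1]],
                 fragments$start[bad[1]], fragments$end[bad[1]]))
  }
  if (is.null(total_mapped)) total_mapped <- nrow(fragments)
  if (total_mapped < nrow(fragments)) {
    stop("total_mapped must be >= the number of fragment records")
  }
  structure(
    list(condition = condition,
         fragments = data.frame(chrom = as.character(fragments$chrom),
                                start = as.integer(fragments$start),
                                end = as.integer(fragments$end),
                                stringsAsFactors = FALSE),
         total_mapped = as.double(total_mapped)),
    class = "fragment_set"
  )
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set> condition=%s, %d fragments, %g total mapped\n",
              x$condition, nrow(x$fragments), x$total_mapped))
  invisible(x)
}

#' Read ChIP fragments from a BED file
#'
#' Reads BED3+ text (0-based half-open intervals), one record per sequenced
#' fragment. Extra columns are ignored.
#'
#' @param path path to a BED file.
#' @param condition `"UNT"` or `"KD"`.
#' @param total_mapped optional library size; defaults to the record count.
#' @return A `fragment_set`.
#' @export
read_fragments <- function(path, condition = c("UNT", "KD"),
                           total_mapped = NULL) {
  condition <- match.arg(condition)
  tab <- utils::read.table(path, sep = "", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("BED file must have at least 3 columns: ", path)
  tab <- tab[, 1:3]
  names(tab) <- c("chrom", "start", "end")
  tab$chrom <- as.character(tab$chrom)
  fragment_set(tab, condition = condition, total_mapped = total_mapped)
}

#' Write a fragment set as BED3
#'
#' @param frags a `fragment_set`.
#' @param path output path.
#' @export
write_fragments <- function(frags, path) {
  utils::write.table(frags$fragments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write RNA abundance tables
#'
#' Tab-separated with a header line. Expected columns: `gene_id`,
#' `isoform_id`, `rna_fpkm_unt`, `rna_fpkm_kd`, `count_unt`, `count_kd`
#' (extra columns pass through).
#'
#' @param path path to a TSV file.
#' @return A data.frame.
#' @export
read_expression <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "rna_fpkm_unt", "rna_fpkm_kd")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    stop("expression table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(tab$rna_fpkm_unt)) || any(!is.finite(tab$rna_fpkm_kd))) {
    stop("expression FPKM values must be finite")
  }
  tab
}

#' @rdname read_expression
#' @param expr a data.frame as returned by [read_expression()].
#' @export
write_expression <- function(expr, path) {
  utils::write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that trims FASTA
#' headers to the first word so sequence names match chromosome names used
#' in annotation and fragment files.
#'
#' @param path path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' @rdname read_genome
#' @param genome a named [Biostrings::DNAStringSet].
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}
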