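#' File input/output for the pipeline's interchange formats
#'
#' Coordinate conventions, stated once and enforced here: BED files and all
#' in-memory alignment/segment tables are 0-based half-open; SAM and VCF
#' positions are 1-based. FASTA/FASTQ go through Biostrings; SAM and VCF are
#' written as minimal plain-text records (single-end toy alignments with a
#' fixed-length match CIGAR; sites-only VCF v4.2).
#'
#' @name scellcn-io
NULL

#' Read / write FASTA genomes
#'
#' @param path file path.
#' @return `read_genome_fasta` returns a named [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @rdname read_genome_fasta
#' @param genome named [Biostrings::DNAStringSet].
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with columns `qname`, `seq` (and optionally
#'   `qual`; a constant high quality is written when absent).
#' @param path output path.
#' @export
write_reads_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$seq)
  names(seqs) <- reads$qname
  qual <- if ("qual" %in% names(reads)) reads$qual else
    vapply(nchar(reads$seq), function(n) strrep("I", n), character(1))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' @rdname write_reads_fastq
#' @return `read_reads_fastq` returns a data.frame with `qname`, `seq`.
#' @export
read_reads_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(qname = names(x), seq = as.character(x), stringsAsFactors = FALSE)
}

#' Write / read minimal single-end SAM
#'
#' Emits @SQ headers from `chrom_lengths` and one line per alignment with
#' FLAG 0 (forward) or 16 (reverse), MAPQ 60 and a full-length match CIGAR.
#' POS is 1-based; the in-memory `start` column is 0-based.
#'
#' @param aln data.frame with `qname`, `chrom`, `start` (0-based), `strand`
#'   ("+"/"-"), and optionally `seq`.
#' @param chrom_lengths named integer vector of reference lengths.
#' @param read_length alignment footprint in bp (CIGAR `<read_length>M`).
#' @param path output path.
#' @export
write_alignments_sam <- function(aln, chrom_lengths, read_length, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths), as.integer(chrom_lengths)), con)
  if (nrow(aln) > 0) {
    seq <- if ("seq" %in% names(aln)) aln$seq else "*"
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                       aln$qname, ifelse(aln$strand == "-", 16L, 0L),
                       aln$chrom, as.integer(aln$start) + 1L,
                       as.integer(read_length), seq), con)
  }
  invisible(path)
}

#' @rdname write_alignments_sam
#' @return `read_alignments_sam` returns a data.frame with `qname`, `chrom`,
#'   `start` (0-based), `strand`.
#' @export
read_alignments_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) {
    return(data.frame(qname = character(), chrom = character(),
                      start = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    qname = vapply(f, `[[`, "", 1L),
    chrom = vapply(f, `[[`, "", 3L),
    start = as.integer(vapply(f, `[[`, "", 4L)) - 1L,
    strand = ifelse(bitwAnd(as.integer(vapply(f, `[[`, "", 2L)), 16L) > 0L, "-", "+"),
    stringsAsFactors = FALSE
  )
}

#' Write / read BED (0-based half-open)
#'
#' Any extra columns after `chrom`, `start`, `end` are preserved in order.
#'
#' @param x data.frame whose first three columns are `chrom`, `start`, `end`.
#' @param path file path.
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @param col_names names to give the columns on reading.
#' @export
read_bed <- function(path, col_names = NULL) {
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (!is.null(col_names)) names(x) <- col_names
  else names(x)[1:3] <- c("chrom", "start", "end")
  x
}

#' Write a SNP panel as sites-only VCF v4.2
#'
#' Positions are written 1-based (VCF convention). The parental phase of the
#' alternate allele is carried in INFO as `BALT=1` when the B (second)
#' parental allele holds the ALT base.
#'
#' @param panel data.frame with `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `b_is_alt` (logical).
#' @param chrom_lengths named lengths for contig headers.
#' @param path output path.
#' @export
write_snp_vcf <- function(panel, chrom_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=BALT,Number=1,Type=Integer,Description=\"1 if parental allele B carries ALT\">",
               sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths), as.integer(chrom_lengths)),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(panel) > 0) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tBALT=%d",
                       panel$chrom, as.integer(panel$pos), panel$ref, panel$alt,
                       as.integer(panel$b_is_alt)), con)
  }
  invisible(path)
}

#' @rdname write_snp_vcf
#' @return `read_snp_vcf` returns the panel data.frame.
#' @export
read_snp_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), b_is_alt = logical(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  info <- vapply(f, `[[`, "", 8L)
  data.frame(
    chrom = vapply(f, `[[`, "", 1L),
    pos = as.integer(vapply(f, `[[`, "", 2L)),
    ref = vapply(f, `[[`, "", 4L),
    alt = vapply(f, `[[`, "", 5L),
    b_is_alt = grepl("BALT=1", info, fixed = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Write / read tab-separated tables with a header
#'
#' @param x data.frame.
#' @param path file path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write / read tumor truth events as a BED-style table
#'
#' Columns: chrom, start, end (0-based half-open), clone, fraction, allele,
#' change, kind. Reading back reproduces the event list exactly.
#'
#' @param truth a `TumorTruth` (see [simulate_tumor_truth()]).
#' @param path file path.
#' @export
write_truth_bed <- function(truth, path) {
  rows <- do.call(rbind, lapply(truth$clones, function(cl) {
    if (nrow(cl$events) == 0) return(NULL)
    data.frame(chrom = cl$events$chrom, start = cl$events$start,
               end = cl$events$end, clone = cl$id, fraction = cl$fraction,
               allele = cl$events$allele, change = cl$events$change,
               kind = cl$events$kind, stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(chrom = character(), start = integer(), end = integer(),
                       clone = character(), fraction = numeric(),
                       allele = character(), change = integer(),
                       kind = character(), stringsAsFactors = FALSE)
  }
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_truth_bed
#' @export
read_truth_bed <- function(path) {
  x <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                  colClasses = c(chrom = "character", start = "integer",
                                 end = "integer", clone = "character",
                                 fraction = "numeric", allele = "character",
                                 change = "integer", kind = "character"))
  x
}
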