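#' Read a GTF file into gene annotation and transcript models
#'
#' Parses a GTF (1-based, inclusive coordinates) and returns the annotated
#' genes and the transcript models (exon sets) it contains. Internally both
#' are represented with the standard Bioconductor 1-based closed convention
#' ([GenomicRanges::GRanges]); conversion to other conventions happens only
#' when writing other formats (e.g. BED).
#'
#' @param path path to a GTF file.
#' @return a list with elements `genes` (a `GRanges` with metadata columns
#'   `gene_id` and `biotype`; genes without an annotated biotype are treated
#'   as protein-coding) and `transcripts` (a named `GRangesList` of exons per
#'   transcript, exons sorted in genomic order).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(body) == 0L) {
    warning("empty GTF: ", path)
    return(list(genes = GenomicRanges::GRanges(),
                transcripts = GenomicRanges::GRangesList()))
  }
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    i <- which(nf != 9L)[1L]
    stop(sprintf("malformed GTF line %d: expected 9 tab-separated fields, got %d",
                 body[i], nf[i]))
  }
  st <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4L)))
  en <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L)))
  if (anyNA(st) || anyNA(en)) {
    i <- which(is.na(st) | is.na(en))[1L]
    stop(sprintf("malformed GTF line %d: non-numeric coordinates", body[i]))
  }
  if (any(en < st)) {
    i <- which(en < st)[1L]
    stop(sprintf("invalid GTF line %d: end < start", body[i]))
  }
  gr <- rtracklayer::import(path, format = "gtf")

  genes <- gr[gr$type == "gene"]
  gene_id <- genes$gene_id
  biotype <- genes$gene_biotype %||% genes$biotype %||%
    rep(NA_character_, length(genes))
  biotype[is.na(biotype)] <- "protein_coding"
  if (anyDuplicated(gene_id)) stop("duplicated gene_id in annotation")
  if (length(genes)) {
    S4Vectors::mcols(genes) <- S4Vectors::DataFrame(gene_id = gene_id,
                                                    biotype = biotype)
  }

  exons <- gr[gr$type == "exon"]
  if (length(exons) && anyNA(exons$transcript_id)) {
    warning("rejecting ", sum(is.na(exons$transcript_id)),
            " exon record(s) lacking transcript_id")
    exons <- exons[!is.na(exons$transcript_id)]
  }
  if (length(exons)) {
    tx <- S4Vectors::split(GenomicRanges::granges(exons), exons$transcript_id)
    tx <- GenomicRanges::GRangesList(lapply(tx, GenomicRanges::sort))
  } else {
    tx <- GenomicRanges::GRangesList()
  }
  list(genes = genes, transcripts = tx)
}

#' Write transcript models to GTF
#'
#' Emits one `transcript` and per-exon `exon` records per transcript, with
#' `gene_id` equal to `transcript_id` unless a mapping is supplied.
#'
#' @param transcripts named `GRangesList` of exons per transcript.
#' @param path output path.
#' @param gene_ids optional named character vector transcript -> gene id.
#' @param source source field for the GTF records.
#' @return `path`, invisibly.
#' @export
write_transcripts_gtf <- function(transcripts, path, gene_ids = NULL,
                                  source = "lincscan") {
  ids <- names(transcripts)
  if (is.null(gene_ids)) gene_ids <- stats::setNames(ids, ids)
  rows <- lapply(ids, function(id) {
    ex <- transcripts[[id]]
    span <- range(ex)
    out <- c(span, ex)
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      source = source,
      type = c("transcript", rep("exon", length(ex))),
      gene_id = unname(gene_ids[id]),
      transcript_id = id)
    out
  })
  gr <- if (length(rows)) do.call(c, rows) else GenomicRanges::GRanges()
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Write gene annotation to GTF
#' @param genes `GRanges` with `gene_id` and `biotype` metadata columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genes_gtf <- function(genes, path) {
  gr <- genes
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "lincscan", type = "gene",
    gene_id = genes$gene_id, gene_biotype = genes$biotype)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Write transcript genomic spans to BED (0-based half-open on disk)
#' @param transcripts named `GRangesList` of exons per transcript.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spans_bed <- function(transcripts, path) {
  spans <- unlist(range(transcripts))
  names(spans) <- names(transcripts)
  rtracklayer::export(spans, path, format = "bed")
  invisible(path)
}

#' Extract the spliced, strand-oriented sequence of a transcript
#'
#' Concatenates exon substrings in genomic order and reverse-complements the
#' result for minus-strand transcripts. Unstranded (`.`/`*`) transcripts are
#' treated as plus strand.
#'
#' @param genome a named [Biostrings::DNAStringSet] (or path to a FASTA).
#' @param transcript a `GRanges` of exons for one transcript.
#' @return uppercase character string; its length equals the summed exon
#'   length.
#' @export
extract_sequence <- function(genome, transcript) {
  genome <- as_genome(genome)
  chrom <- as.character(GenomeInfoDb::seqnames(transcript))[1L]
  if (!chrom %in% names(genome)) {
    stop("chromosome not present in genome: ", chrom)
  }
  clen <- length(genome[[chrom]])
  if (any(GenomicRanges::start(transcript) < 1L) ||
      any(GenomicRanges::end(transcript) > clen)) {
    stop("exon interval out of chromosome bounds on ", chrom)
  }
  ex <- GenomicRanges::sort(transcript, ignore.strand = TRUE)
  parts <- vapply(seq_along(ex), function(i) {
    as.character(Biostrings::subseq(genome[[chrom]],
                                    GenomicRanges::start(ex)[i],
                                    GenomicRanges::end(ex)[i]))
  }, character(1))
  s <- toupper(paste(parts, collapse = ""))
  if (as.character(GenomicRanges::strand(transcript))[1L] == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

#' Extract sequences for many transcripts
#' @param genome named `DNAStringSet` or FASTA path.
#' @param transcripts named `GRangesList`.
#' @return named `DNAStringSet` in the input transcript order.
#' @export
extract_sequences <- function(genome, transcripts) {
  genome <- as_genome(genome)
  seqs <- vapply(seq_along(transcripts), function(i) {
    extract_sequence(genome, transcripts[[i]])
  }, character(1))
  Biostrings::DNAStringSet(stats::setNames(seqs, names(transcripts)))
}

as_genome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (!methods::is(genome, "DNAStringSet")) {
    stop("genome must be a DNAStringSet or a FASTA path")
  }
  # FASTA headers may carry descriptions; keep the first token as the name
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Read an FPKM expression table plus sample metadata
#'
#' @param path TSV whose first column holds feature IDs and remaining columns
#'   one sample each (header = sample IDs).
#' @param metadata_path TSV keyed by `sample_id`, with optional columns
#'   `tissue`, `time_days`, `time_rank`, `stage`.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay `fpkm`
#'   and the metadata as `colData`.
#' @export
read_expression_table <- function(path, metadata_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(tab[[1]])
  if (anyDuplicated(rownames(mat))) stop("duplicated feature IDs")
  if (anyNA(mat)) stop("missing values are not allowed in the FPKM table")
  if (any(mat < 0)) stop("negative FPKM values are not allowed")
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta)) stop("metadata lacks a sample_id column")
  missing <- setdiff(colnames(mat), meta$sample_id)
  if (length(missing)) {
    stop("samples absent from metadata: ", paste(missing, collapse = ", "))
  }
  meta <- meta[match(colnames(mat), meta$sample_id), , drop = FALSE]
  rownames(meta) <- meta$sample_id
  validate_time_rank(meta)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = mat),
    colData = S4Vectors::DataFrame(meta))
}

validate_time_rank <- function(meta) {
  if (!"time_rank" %in% names(meta)) return(invisible(TRUE))
  r <- meta$time_rank[!is.na(meta$time_rank)]
  if (length(r) && !setequal(r, seq_along(r))) {
    stop("time_rank must be a permutation of 1..n over the development samples")
  }
  invisible(TRUE)
}

#' Build an expression container from a matrix and metadata data.frame
#' @param mat numeric FPKM matrix (features x samples).
#' @param meta data.frame with one row per sample (`sample_id` column).
#' @param kind optional named character vector feature -> {"lincRNA","mRNA"}.
#' @return a `SummarizedExperiment`.
#' @export
expression_matrix <- function(mat, meta, kind = NULL) {
  if (anyNA(mat) || any(mat < 0)) stop("FPKM matrix must be non-negative, no NA")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  rownames(meta) <- meta$sample_id
  stopifnot(identical(colnames(mat), meta$sample_id))
  validate_time_rank(meta)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = mat), colData = S4Vectors::DataFrame(meta))
  if (!is.null(kind)) {
    SummarizedExperiment::rowData(se)$kind <-
      unname(kind[rownames(mat)])
  }
  se
}

#' Write an expression container back to TSV (values + metadata)
#' @param se `SummarizedExperiment` with assay `fpkm`.
#' @param path values TSV path.
#' @param metadata_path metadata TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(se, path, metadata_path) {
  mat <- SummarizedExperiment::assay(se, "fpkm")
  out <- data.frame(feature_id = rownames(mat), mat,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- as.data.frame(SummarizedExperiment::colData(se))
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read BLAST-style 12-column tabular alignment hits
#'
#' Standard columns: query, subject, percent identity (0-100), alignment
#' length, mismatches, gap opens, q. start, q. end, s. start, s. end,
#' E-value, bit score. Identity is rescaled to a fraction in \[0, 1\].
#'
#' @param path tabular hits path (no header).
#' @return data.frame of hits, rows in file order, with columns `query_id`,
#'   `subject_id`, `percent_identity`, `align_length`, `q_start`, `q_end`,
#'   `s_start`, `s_end`, `score`, `e_value`.
#' @export
read_blast_tabular <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    i <- which(nf != 12L)[1L]
    stop(sprintf("malformed tabular line %d: expected 12 columns, got %d",
                 i, nf[i]))
  }
  m <- do.call(rbind, fields)
  hits <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    percent_identity = as.numeric(m[, 3]) / 100,
    align_length = as.integer(m[, 4]),
    q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
    s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
    score = as.numeric(m[, 12]), e_value = as.numeric(m[, 11]),
    stringsAsFactors = FALSE)
  if (any(hits$e_value < 0)) stop("negative E-value in tabular hits")
  if (any(hits$percent_identity < 0 | hits$percent_identity > 1)) {
    stop("percent identity outside 0-100 in tabular hits")
  }
  hits
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             percent_identity = numeric(), align_length = integer(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             score = numeric(), e_value = numeric(),
             stringsAsFactors = FALSE)
}

#' Write a weighted edge list TSV (network export)
#' @param edges data.frame with columns `from`, `to`, `weight`, `module`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summed exon length per transcript
#' @param transcripts `GRangesList`.
#' @return named integer vector.
#' @export
transcript_lengths <- function(transcripts) {
  stats::setNames(sum(GenomicRanges::width(transcripts)), names(transcripts))
}

#' Genomic span (first exon start to last exon end) per transcript
#' @param transcripts `GRangesList`.
#' @return `GRanges`, one range per transcript.
#' @export
transcript_spans <- function(transcripts) {
  spans <- unlist(range(transcripts))
  names(spans) <- names(transcripts)
  spans
}
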