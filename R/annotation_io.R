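# Genome/annotation input, strand-aware sequence extraction, dataset
# construction and overlap analysis. External files use 1-based inclusive
# coordinates (GFF convention); interval arithmetic is delegated to
# IRanges/GenomicRanges.

ORF_CATEGORIES <- c("verified", "uncharacterized", "dubious")

#' Read a FASTA file
#'
#' Light structural validation (headers, empty records) with line numbers
#' in error messages, then parsing through Biostrings. Sequences are
#' uppercase-normalized; record order is preserved.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @return Named character vector: names are the first whitespace-delimited
#'   token of each header, values the uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  nonblank <- which(!grepl("^\\s*$", lines))
  if (length(nonblank) == 0L)
    stop("FASTA format error: file is empty", call. = FALSE)
  if (!startsWith(lines[nonblank[1L]], ">"))
    stop(sprintf("FASTA format error at line %d: expected '>' header",
                 nonblank[1L]), call. = FALSE)
  headers <- which(startsWith(lines, ">"))
  for (i in seq_along(headers)) {
    h <- headers[i]
    if (gsub("\\s", "", lines[h]) == ">")
      stop(sprintf("FASTA format error at line %d: empty header", h),
           call. = FALSE)
    nxt <- if (i < length(headers)) headers[i + 1L] else length(lines) + 1L
    body <- lines[seq.int(h + 1L, length.out = max(0L, nxt - h - 1L))]
    if (!any(nzchar(gsub("\\s", "", body))))
      stop(sprintf("FASTA format error at line %d: record '%s' has no sequence",
                   h, sub("^>\\s*", "", lines[h])), call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

.parse_category <- function(raw) {
  cat <- tolower(trimws(raw))
  cat[!cat %in% ORF_CATEGORIES] <- NA_character_
  cat
}

.finish_records <- function(df, source) {
  bad <- is.na(df$category)
  if (any(bad)) {
    warning(sprintf("%s: skipped %d record(s) with unknown category (%s)",
                    source, sum(bad),
                    paste(unique(head(df$orf_id[bad], 5L)), collapse = ", ")),
            call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  if (any(df$start > df$end))
    stop("annotation format error: start > end for ",
         paste(head(df$orf_id[df$start > df$end], 3L), collapse = ", "),
         call. = FALSE)
  if (!all(df$strand %in% c("+", "-")))
    stop("annotation format error: strand must be + or -", call. = FALSE)
  rownames(df) <- NULL
  df
}

#' Read an ORF annotation
#'
#' Two dialects are supported. `"gff3"` reads a GFF3 file (via
#' rtracklayer); ORF rows are those carrying the annotation class in an
#' `orf_classification` (or `category`) attribute, as the SGD GFF dumps
#' do. `"sgd_tab"` reads a tab-delimited feature table with a header row
#' and columns `orf_id`, `gene_name`, `chrom`, `start`, `end`, `strand`,
#' `category`. Coordinates are kept 1-based inclusive. Rows whose category
#' is not one of verified / uncharacterized / dubious are skipped with a
#' warning; `start > end` is a format error.
#'
#' @param path Annotation file path.
#' @param dialect `"gff3"` or `"sgd_tab"`.
#' @return Data frame of ORF records: `orf_id`, `gene_name`, `chrom`,
#'   `start`, `end`, `strand`, `category`.
#' @export
read_annotation <- function(path, dialect = c("gff3", "sgd_tab")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "gff3") {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires the rtracklayer package", call. = FALSE)
    gr <- rtracklayer::import(path, format = "gff3")
    meta <- S4Vectors::mcols(gr)
    raw_cat <- if ("orf_classification" %in% names(meta)) {
      as.character(meta$orf_classification)
    } else if ("category" %in% names(meta)) {
      as.character(meta$category)
    } else {
      rep(NA_character_, length(gr))
    }
    keep <- !is.na(raw_cat)
    gr <- gr[keep]
    meta <- S4Vectors::mcols(gr)
    ids <- if ("ID" %in% names(meta)) as.character(meta$ID)
           else as.character(meta$Name)
    gene <- if ("gene" %in% names(meta)) as.character(meta$gene)
            else rep(NA_character_, length(gr))
    df <- data.frame(
      orf_id = ids, gene_name = gene,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      category = .parse_category(raw_cat[keep]),
      stringsAsFactors = FALSE)
  } else {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("orf_id", "gene_name", "chrom", "start", "end", "strand",
              "category")
    if (!all(need %in% names(tab)))
      stop("sgd_tab format error: expected columns ",
           paste(need, collapse = ", "), call. = FALSE)
    df <- tab[, need]
    df$category <- .parse_category(df$category)
  }
  .finish_records(df, basename(path))
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Extract the coding-strand sequence of one ORF
#'
#' Plus-strand ORFs are the genome substring `[start, end]`; minus-strand
#' ORFs are the reverse complement of that substring, so the returned
#' sequence always reads 5'-3' on the coding strand.
#'
#' @param genome Named character vector of chromosome sequences (from
#'   [read_fasta()]), or a single unnamed sequence.
#' @param orf One ORF record (single-row data frame or list with `chrom`,
#'   `start`, `end`, `strand`).
#' @return The ORF nucleotide sequence (single string).
#' @export
extract_orf_sequence <- function(genome, orf) {
  chrom_seq <- if (length(genome) == 1L && is.null(names(genome))) {
    genome
  } else {
    if (!orf$chrom %in% names(genome))
      stop("chromosome not in genome: ", orf$chrom, call. = FALSE)
    genome[[orf$chrom]]
  }
  if (orf$start < 1L || orf$end > nchar(chrom_seq) || orf$start > orf$end)
    stop(sprintf("coordinates [%d, %d] out of range for a %d-bp sequence",
                 orf$start, orf$end, nchar(chrom_seq)), call. = FALSE)
  s <- substr(chrom_seq, orf$start, orf$end)
  if (orf$strand == "-") s <- .revcomp(s)
  s
}

#' Extract intergenic sequences
#'
#' Removes the union of all annotated record intervals (all categories,
#' both strands collapsed onto one coordinate track) from each chromosome
#' and returns the maximal uncovered runs strictly longer than `min_len`
#' ("longer than 300 bp" read strictly, matching the negative-set rule).
#'
#' @param genome Named character vector of chromosome sequences.
#' @param records ORF record data frame ([read_annotation()]).
#' @param min_len Minimum exclusive length in bp (default 300).
#' @return Data frame of labeled sequences: `seq_id`
#'   (`<chrom>_ig_<start>_<end>`), `sequence`, `label` (-1), `source`
#'   (`"intergenic"`).
#' @export
extract_intergenic <- function(genome, records, min_len = 300L) {
  out <- list()
  for (chrom in names(genome)) {
    len <- nchar(genome[[chrom]])
    r <- records[records$chrom == chrom, , drop = FALSE]
    covered <- IRanges::reduce(IRanges::IRanges(start = r$start, end = r$end))
    gaps <- IRanges::gaps(covered, start = 1L, end = len)
    gaps <- gaps[IRanges::width(gaps) > min_len]
    if (length(gaps) == 0L) next
    out[[chrom]] <- data.frame(
      seq_id = sprintf("%s_ig_%d_%d", chrom, IRanges::start(gaps),
                       IRanges::end(gaps)),
      sequence = substring(genome[[chrom]], IRanges::start(gaps),
                           IRanges::end(gaps)),
      label = -1L, source = "intergenic", stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(seq_id = character(0), sequence = character(0),
                      label = integer(0), source = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Overlap and antisense relations between two ORF sets
#'
#' A candidate overlaps a reference ORF when their 1-based inclusive
#' intervals on the same chromosome share at least one bp (strand
#' ignored for the overlap itself). For each candidate the partner with
#' the largest overlap is reported (ties: first in reference order), with
#' orientation `antisense` iff the strands differ. The summary counts
#' overlapping candidates and the antisense fraction among them.
#'
#' @param candidates,reference ORF record data frames.
#' @return List of class `overlap_report`: `per_candidate` data frame
#'   (`orf_id`, `partner`, `overlap_bp`, `orientation`) and `summary`
#'   (`n_candidates`, `n_overlapping`, `antisense_fraction`).
#' @export
classify_overlaps <- function(candidates, reference) {
  cg <- GenomicRanges::GRanges(candidates$chrom,
                               IRanges::IRanges(candidates$start, candidates$end),
                               strand = candidates$strand)
  rg <- GenomicRanges::GRanges(reference$chrom,
                               IRanges::IRanges(reference$start, reference$end),
                               strand = reference$strand)
  hits <- GenomicRanges::findOverlaps(cg, rg, ignore.strand = TRUE)
  ov_bp <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(cg)[S4Vectors::queryHits(hits)],
    IRanges::ranges(rg)[S4Vectors::subjectHits(hits)]))
  per <- data.frame(orf_id = candidates$orf_id,
                    partner = NA_character_,
                    overlap_bp = NA_integer_,
                    orientation = NA_character_,
                    stringsAsFactors = FALSE)
  if (length(hits)) {
    ord <- order(S4Vectors::queryHits(hits), -ov_bp, S4Vectors::subjectHits(hits))
    q <- S4Vectors::queryHits(hits)[ord]
    first <- !duplicated(q)
    qi <- q[first]
    si <- S4Vectors::subjectHits(hits)[ord][first]
    per$partner[qi] <- reference$orf_id[si]
    per$overlap_bp[qi] <- ov_bp[ord][first]
    per$orientation[qi] <- ifelse(candidates$strand[qi] == reference$strand[si],
                                  "same_strand", "antisense")
  }
  n_ov <- sum(!is.na(per$partner))
  structure(
    list(per_candidate = per,
         summary = list(
           n_candidates = nrow(candidates),
           n_overlapping = n_ov,
           antisense_fraction = if (n_ov > 0)
             sum(per$orientation == "antisense", na.rm = TRUE) / n_ov
           else NA_real_)),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%d / %d candidates overlap a reference ORF; antisense fraction %.3f\n",
              s$n_overlapping, s$n_candidates,
              if (is.na(s$antisense_fraction)) NA else s$antisense_fraction))
  invisible(x)
}

#' Construct training and test datasets from a genome annotation
#'
#' The dataset-construction rule of the workflow: verified ORF sequences
#' are the positive (coding) class; intergenic runs longer than `min_len`
#' bp the negative class; dubious and uncharacterized ORFs form the test
#' set of questionable sequences.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param records ORF record data frame.
#' @param min_len Strict minimum intergenic length in bp.
#' @return List with data frames `positive`, `negative`, `test` (columns
#'   `seq_id`, `sequence`, `label`, `source`) and `manifest` (named counts).
#' @export
build_datasets <- function(genome, records, min_len = 300L) {
  grab <- function(r, label, source) {
    if (nrow(r) == 0L)
      return(data.frame(seq_id = character(0), sequence = character(0),
                        label = integer(0), source = character(0)))
    data.frame(
      seq_id = r$orf_id,
      sequence = vapply(seq_len(nrow(r)), function(i)
        extract_orf_sequence(genome, r[i, ]), character(1)),
      label = label, source = source, stringsAsFactors = FALSE)
  }
  pos <- grab(records[records$category == "verified", , drop = FALSE],
              1L, "verified_orf")
  test <- rbind(
    grab(records[records$category == "uncharacterized", , drop = FALSE],
         0L, "uncharacterized"),
    grab(records[records$category == "dubious", , drop = FALSE],
         0L, "dubious"))
  neg <- extract_intergenic(genome, records, min_len = min_len)
  list(positive = pos, negative = neg, test = test,
       manifest = c(n_positive = nrow(pos), n_negative = nrow(neg),
                    n_test = nrow(test),
                    n_verified = sum(records$category == "verified"),
                    n_uncharacterized = sum(records$category == "uncharacterized"),
                    n_dubious = sum(records$category == "dubious")))
}

#' Guanine/thymine usage at the first codon position
#'
#' The two-dimensional composition diagnostic separating coding from
#' non-coding ORFs: genes favor G at codon position 1, non-coding
#' sequences favor T.
#'
#' @param seqs Named character vector of sequences.
#' @return Data frame: `seq_id`, `G1`, `T1` (frequencies at codon
#'   position 1).
#' @export
#' @examples
#' gt_first_position(c(a = "ATGTAA"))  # G1 = 0, T1 = 0.5
gt_first_position <- function(seqs) {
  x <- encode_features(seqs, 1L)
  data.frame(seq_id = rownames(x) %||% as.character(seq_len(nrow(x))),
             G1 = unname(x[, "nt_pos1_G"]), T1 = unname(x[, "nt_pos1_T"]),
             stringsAsFactors = FALSE)
}
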