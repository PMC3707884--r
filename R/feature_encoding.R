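# Six frame-aware sequence-statistic encoders and their assembly into a
# feature vector. Ordering is frozen for model portability: blocks by
# measurement id 1..6; nucleotide k-mers lexicographic over A<C<G<T; amino
# acids alphabetical by one-letter code with the stop symbol last.

NUCLEOTIDES <- c("A", "C", "G", "T")

# 64 codons, first base slowest => lexicographic
CODONS <- as.vector(t(outer(
  as.vector(t(outer(NUCLEOTIDES, NUCLEOTIDES, paste0))),
  NUCLEOTIDES, paste0
)))

DINUCLEOTIDES <- as.vector(t(outer(NUCLEOTIDES, NUCLEOTIDES, paste0)))

STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(CODONS, STOP_CODONS)

# 20 amino acids alphabetical by one-letter code, stop (*) last
AA_ALPHABET <- c(sort(setdiff(unique(unname(Biostrings::GENETIC_CODE)), "*")), "*")

# codon index (1..64, CODONS order) -> amino-acid index (1..21, AA_ALPHABET order)
.CODON_TO_AA <- match(unname(Biostrings::GENETIC_CODE[CODONS]), AA_ALPHABET)

#' Feature-block widths
#'
#' Width of each of the six measurement blocks: 12 (positional
#' mono-nucleotide), 48 (positional di-nucleotide), 64 (mono-codon),
#' 4096 (di-codon), 21 (mono-amino-acid incl. stop), 441 (di-amino-acid).
#' The full six-block assembly has 4682 dimensions.
#'
#' @return Named integer vector of length 6.
#' @export
#' @examples
#' block_widths()
#' sum(block_widths())  # 4682
block_widths <- function() {
  c(mono_nt = 12L, di_nt = 48L, codon = 64L, dicodon = 4096L,
    aa = 21L, diaa = 441L)
}

.aa_label <- function(i) {
  a <- AA_ALPHABET[i]
  ifelse(a == "*", "stop", a)
}

.block_names <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    n1 <- paste0("nt_pos", rep(1:3, each = 4), "_", rep(NUCLEOTIDES, 3))
    n2 <- paste0("dint_", rep(c("p12", "p23", "p31"), each = 16), "_",
                 rep(DINUCLEOTIDES, 3))
    n3 <- paste0("codon_", CODONS)
    n4 <- paste0("dicodon_", rep(CODONS, each = 64), rep(CODONS, 64))
    n5 <- paste0("aa_", .aa_label(1:21))
    n6 <- paste0("diaa_", rep(.aa_label(1:21), each = 21), "_",
                 rep(.aa_label(1:21), 21))
    cache <<- list(n1, n2, n3, n4, n5, n6)
    cache
  }
})

# Split into in-frame codons from position 1; trailing 1-2 nt dropped.
# Returns codon index vector (NA for codons with non-ACGT characters).
.codon_indices <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq) %/% 3L
  if (n < 1L) stop("sequence shorter than one codon", call. = FALSE)
  starts <- 3L * (seq_len(n) - 1L) + 1L
  match(substring(seq, starts, starts + 2L), CODONS)
}

.freq <- function(idx, nbins) {
  # idx: integer indices with NA for invalid entries; all-zero when empty
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) return(numeric(nbins))
  tabulate(idx, nbins) / length(idx)
}

.new_block <- function(values, measurement_id) {
  names(values) <- .block_names()[[measurement_id]]
  values
}

# Core: compute any subset of the six blocks from one pass over the codons.
.encode_seq <- function(seq, selection) {
  ci <- .codon_indices(seq)
  n <- length(ci)
  valid <- !is.na(ci)
  out <- vector("list", length(selection))
  # pair of adjacent codons, both unambiguous
  if (any(selection %in% c(2L, 4L, 6L)) && n >= 2L) {
    i <- seq_len(n - 1L)
    pair_ok <- valid[i] & valid[i + 1L]
  } else {
    pair_ok <- logical(0)
  }
  for (k in seq_along(selection)) {
    m <- selection[k]
    out[[k]] <- switch(m,
      { # 1: base frequency at each codon position, position-major
        vc <- ci[valid]
        b3 <- (vc - 1L) %% 4L + 1L
        b2 <- (vc - 1L) %/% 4L %% 4L + 1L
        b1 <- (vc - 1L) %/% 16L + 1L
        c(.freq(b1, 4L), .freq(b2, 4L), .freq(b3, 4L))
      },
      { # 2: dinucleotide at positions 1&2, 2&3 within codons, 3&1 across
        b3 <- (ci - 1L) %% 4L
        b2 <- (ci - 1L) %/% 4L %% 4L
        b1 <- (ci - 1L) %/% 16L
        g12 <- .freq((b1[valid]) * 4L + b2[valid] + 1L, 16L)
        g23 <- .freq((b2[valid]) * 4L + b3[valid] + 1L, 16L)
        g31 <- if (n >= 2L) {
          i <- which(pair_ok)
          .freq(b3[i] * 4L + b1[i + 1L] + 1L, 16L)
        } else numeric(16L)
        c(g12, g23, g31)
      },
      .freq(ci, 64L),                                    # 3: mono-codon
      { # 4: adjacent-codon 6-mers, window advancing one codon
        if (n >= 2L) {
          i <- which(pair_ok)
          .freq((ci[i] - 1L) * 64L + ci[i + 1L], 4096L)
        } else numeric(4096L)
      },
      .freq(.CODON_TO_AA[ci], 21L),                      # 5: amino acid + stop
      { # 6: consecutive translated residue pairs
        if (n >= 2L) {
          aa <- .CODON_TO_AA[ci]
          i <- which(pair_ok)
          .freq((aa[i] - 1L) * 21L + aa[i + 1L], 441L)
        } else numeric(441L)
      }
    )
  }
  out
}

.check_seq_arg <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("`seq` must be a single nucleotide string", call. = FALSE)
}

#' Positional mono-nucleotide frequencies (measurement 1)
#'
#' Frequency of each base A, C, G, T at codon positions 1, 2 and 3, read in
#' frame from the first position of the sequence. Each codon position is
#' normalized by the number of unambiguous (ACGT-only) codons; trailing
#' 1-2 nt beyond the last full codon are ignored. 12 values,
#' position-major, bases lexicographic.
#'
#' @param seq A single nucleotide string (case-insensitive).
#' @return Named numeric vector of length 12.
#' @export
#' @examples
#' encode_mono_nt("ATGTAA")
encode_mono_nt <- function(seq) {
  .check_seq_arg(seq)
  .new_block(.encode_seq(seq, 1L)[[1L]], 1L)
}

#' Positional di-nucleotide frequencies (measurement 2)
#'
#' Three groups of 16 dinucleotide frequencies over a 3-bp sliding window:
#' codon positions 1&2 and 2&3 within each codon, and 3&1 bridging each
#' adjacent codon pair. Groups are normalized independently by their own
#' pair counts; the 3&1 group is all-zero for single-codon input (no wrap).
#'
#' @inheritParams encode_mono_nt
#' @return Named numeric vector of length 48.
#' @export
#' @examples
#' encode_di_nt("ATGTAA")
encode_di_nt <- function(seq) {
  .check_seq_arg(seq)
  .new_block(.encode_seq(seq, 2L)[[1L]], 2L)
}

#' Mono-codon usage (measurement 3)
#'
#' Frequency of each of the 64 codons among the non-overlapping in-frame
#' codons, normalized by the unambiguous-codon count.
#'
#' @inheritParams encode_mono_nt
#' @return Named numeric vector of length 64.
#' @export
#' @examples
#' encode_codon("ATGGCTTAA")
encode_codon <- function(seq) {
  .check_seq_arg(seq)
  .new_block(.encode_seq(seq, 3L)[[1L]], 3L)
}

#' Di-codon usage (measurement 4)
#'
#' Frequency of each 6-mer over windows advancing one codon at a time
#' (overlapping adjacent-codon pairs), normalized by the window count;
#' all-zero for single-codon input.
#'
#' @inheritParams encode_mono_nt
#' @return Named numeric vector of length 4096.
#' @export
encode_dicodon <- function(seq) {
  .check_seq_arg(seq)
  .new_block(.encode_seq(seq, 4L)[[1L]], 4L)
}

#' Mono-amino-acid usage with stop as a 21st residue (measurement 5)
#'
#' Each in-frame codon is translated by the standard genetic code; the
#' three stop codons TAA, TAG and TGA collapse onto one stop symbol, so
#' termination signals are counted like residues. 21 frequencies
#' normalized by the unambiguous-codon count.
#'
#' @inheritParams encode_mono_nt
#' @return Named numeric vector of length 21.
#' @export
#' @examples
#' encode_aa("ATGTAA")  # Met 0.5, stop 0.5
encode_aa <- function(seq) {
  .check_seq_arg(seq)
  .new_block(.encode_seq(seq, 5L)[[1L]], 5L)
}

#' Di-amino-acid usage (measurement 6)
#'
#' Frequencies of ordered pairs of consecutive translated residues (21 x 21
#' = 441 values, stop included), window advancing one codon; all-zero for
#' single-codon input.
#'
#' @inheritParams encode_mono_nt
#' @return Named numeric vector of length 441.
#' @export
encode_diaa <- function(seq) {
  .check_seq_arg(seq)
  .new_block(.encode_seq(seq, 6L)[[1L]], 6L)
}

.check_selection <- function(selection) {
  selection <- as.integer(selection)
  if (length(selection) == 0L)
    stop("`selection` must name at least one measurement (1..6)", call. = FALSE)
  if (anyNA(selection) || any(selection < 1L | selection > 6L))
    stop("`selection` entries must be in 1..6", call. = FALSE)
  if (anyDuplicated(selection))
    stop("`selection` entries must be unique", call. = FALSE)
  sort(selection)
}

#' Assemble a feature vector from selected measurement blocks
#'
#' Concatenates the selected blocks in measurement-id order. The full
#' selection `1:6` yields 12 + 48 + 64 + 4096 + 21 + 441 = 4682 dimensions.
#'
#' @inheritParams encode_mono_nt
#' @param selection Subset of `1:6` choosing the measurement blocks.
#' @return Named numeric feature vector with attribute `"selection"`.
#' @export
#' @examples
#' length(assemble("ATGGCTTAA", c(5, 6)))  # 462
assemble <- function(seq, selection = 1:6) {
  .check_seq_arg(seq)
  selection <- .check_selection(selection)
  blocks <- .encode_seq(seq, selection)
  v <- unlist(blocks, use.names = FALSE)
  names(v) <- unlist(.block_names()[selection], use.names = FALSE)
  attr(v, "selection") <- selection
  v
}

#' Encode many sequences into a feature matrix
#'
#' Row-wise [assemble()] over a character vector of sequences.
#'
#' @param seqs Character vector of nucleotide sequences; names become row
#'   names.
#' @inheritParams assemble
#' @return Numeric matrix, one row per sequence, columns named per
#'   dimension (e.g. `codon_ATG`, `dicodon_ATGGCT`, `aa_M`).
#' @export
encode_features <- function(seqs, selection = 1:6) {
  selection <- .check_selection(selection)
  width <- sum(block_widths()[selection])
  x <- vapply(seqs, function(s) unlist(.encode_seq(s, selection), use.names = FALSE),
              numeric(width), USE.NAMES = FALSE)
  x <- t(matrix(x, nrow = width))
  colnames(x) <- unlist(.block_names()[selection], use.names = FALSE)
  rownames(x) <- names(seqs)
  attr(x, "selection") <- selection
  x
}

# column index of each selected block inside the full 4682-wide matrix
block_columns <- function(selection) {
  w <- block_widths()
  ends <- cumsum(w)
  starts <- ends - w + 1L
  unlist(lapply(.check_selection(selection), function(m) starts[m]:ends[m]),
         use.names = FALSE)
}

#' Fit a min-max scaling model
#'
#' Records the per-dimension minimum and maximum over a set of training
#' feature vectors. Training vectors scaled with their own model lie in
#' \[0, 1\]; the stored scale is applied unchanged to test vectors.
#'
#' @param x Numeric matrix of training feature vectors (rows = samples).
#' @return An object of class `minmax_scaler` with fields `min`, `max`,
#'   `dim`.
#' @export
fit_scaler <- function(x) {
  if (!is.matrix(x) || nrow(x) < 1L)
    stop("`x` must be a matrix with at least one row", call. = FALSE)
  structure(
    list(min = apply(x, 2L, min), max = apply(x, 2L, max), dim = ncol(x)),
    class = "minmax_scaler"
  )
}

#' Apply a stored min-max scale
#'
#' Maps each dimension to `(x - min) / (max - min)`. Dimensions constant on
#' the training set map to 0. Test values outside the training range are
#' deliberately not clipped and may fall outside \[0, 1\].
#'
#' @param scaler A `minmax_scaler` from [fit_scaler()].
#' @param x Numeric matrix (or single vector) with matching width.
#' @return Scaled matrix (or vector) of the same shape.
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1L)
  if (ncol(x) != scaler$dim)
    stop(sprintf("width mismatch: scaler has %d dimensions, input has %d",
                 scaler$dim, ncol(x)), call. = FALSE)
  range <- scaler$max - scaler$min
  keep <- range > 0
  out <- x
  out[, keep] <- sweep(sweep(x[, keep, drop = FALSE], 2L, scaler$min[keep]),
                       2L, range[keep], "/")
  out[, !keep] <- 0
  if (vec) out[1L, ] else out
}

#' @export
print.minmax_scaler <- function(x, ...) {
  cat(sprintf("min-max scaler over %d dimensions (%d constant)\n",
              x$dim, sum(x$max == x$min)))
  invisible(x)
}

#' Write / read a feature matrix as a tab-delimited table
#'
#' Dense export with a header row naming each dimension plus a leading
#' `seq_id` column; the companion reader restores the matrix.
#'
#' @param x Feature matrix from [encode_features()].
#' @param path File path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the matrix.
#' @export
write_feature_table <- function(x, path) {
  df <- data.frame(seq_id = rownames(x) %||% seq_len(nrow(x)), x,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  x <- as.matrix(df[, -1L, drop = FALSE])
  rownames(x) <- df[[1L]]
  x
}

#' Write a labeled feature matrix in sparse classifier-exchange format
#'
#' One line per sample: `label index:value ...`, indices 1-based, zero
#' entries omitted — the plain-text format shared by the libsvm/liblinear
#' family of tools.
#'
#' @param x Feature matrix.
#' @param labels Numeric labels (+1 / -1), one per row.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_svmlight <- function(x, labels, path) {
  stopifnot(nrow(x) == length(labels))
  lines <- vapply(seq_len(nrow(x)), function(i) {
    nz <- which(x[i, ] != 0)
    paste(labels[i], paste0(nz, ":", formatC(x[i, nz], format = "g", digits = 15),
                            collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
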