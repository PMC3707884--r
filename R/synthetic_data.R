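# Seeded generators for coding-like and non-coding-like sequences so the
# full pipeline (dataset construction, encoding, CV, retrospective
# protocol) is exercisable without any external download.

# run expr with a private RNG state so generators don't disturb the
# caller's random stream
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# uniform integer on [lo, hi]; safe when lo == hi (sample(lo:hi, 1) is not)
.draw_int <- function(lo, hi) {
  if (lo == hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
}

#' Coding-sequence generative model
#'
#' Sequences are an ATG start, i.i.d. sense codons from a 61-entry codon
#' probability table, and one stop codon; internal stops never occur and
#' the emitted length is always a codon multiple — the structural
#' signature the frame-aware encoders are built to detect.
#'
#' @param codon_probs Named numeric vector of weights over the 61 sense
#'   codons (normalized internally). Any stop codon with nonzero weight is
#'   a configuration error.
#' @param stop_probs Named weights over the stop codons TAA, TAG, TGA.
#' @param len_range Two integers: min/max number of internal codons
#'   (uniform draw).
#' @return An object of class `coding_model`.
#' @export
coding_model <- function(codon_probs = yeast_like_codon_probs(),
                         stop_probs = c(TAA = 0.47, TAG = 0.23, TGA = 0.30),
                         len_range = c(100L, 500L)) {
  if (is.null(names(codon_probs)) ||
      !setequal(names(codon_probs), SENSE_CODONS))
    stop("`codon_probs` must be named by the 61 sense codons", call. = FALSE)
  if (any(names(codon_probs) %in% STOP_CODONS & codon_probs > 0))
    stop("stop codons must have zero internal probability", call. = FALSE)
  if (any(codon_probs < 0) || sum(codon_probs) <= 0)
    stop("`codon_probs` must be non-negative with positive sum", call. = FALSE)
  if (!setequal(names(stop_probs), STOP_CODONS) || any(stop_probs < 0))
    stop("`stop_probs` must be named TAA, TAG, TGA", call. = FALSE)
  stopifnot(length(len_range) == 2L, len_range[1] >= 1L,
            len_range[1] <= len_range[2])
  structure(
    list(codon_probs = codon_probs[SENSE_CODONS] / sum(codon_probs),
         stop_probs = stop_probs[STOP_CODONS] / sum(stop_probs),
         len_range = as.integer(len_range)),
    class = "coding_model"
  )
}

#' Non-coding background model
#'
#' Frame-free i.i.d. bases at a given GC fraction (AT and GC split evenly
#' within their pairs), lengths uniform on `len_range`. The default length
#' floor mirrors the negative-set rule that intergenic training sequences
#' are longer than 300 bp.
#'
#' @param gc GC fraction in \[0, 1\].
#' @param len_range Two integers: min/max length in bp.
#' @return An object of class `noncoding_model`.
#' @export
noncoding_model <- function(gc = 0.36, len_range = c(301L, 1500L)) {
  stopifnot(gc >= 0, gc <= 1, length(len_range) == 2L,
            len_range[1] >= 1L, len_range[1] <= len_range[2])
  structure(
    list(base_probs = c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2,
                        T = (1 - gc) / 2),
         len_range = as.integer(len_range)),
    class = "noncoding_model"
  )
}

#' Illustrative yeast-like codon weights
#'
#' The packaged default codon table for the `yeast_like` benchmark:
#' moderately biased sense-codon weights at roughly 40% GC, shaped like
#' budding-yeast usage. The values are illustrative defaults for the
#' generator, not measurements from any annotation release.
#'
#' @return Named numeric vector over the 61 sense codons (unnormalized
#'   weights).
#' @export
yeast_like_codon_probs <- function() {
  path <- system.file("extdata", "yeast_like_codon_usage.tsv",
                      package = "orfsvm", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(tab$weight, tab$codon)
}

#' Sample coding-like sequences
#'
#' @param model A `coding_model`.
#' @param n Number of sequences (>= 0).
#' @param seed Integer seed; regeneration from the same (model, n, seed)
#'   is bit-identical.
#' @param prefix Identifier prefix.
#' @return Data frame of labeled sequences: `seq_id`, `sequence`,
#'   `label` (+1), `source` (`"synthetic"`).
#' @export
sample_coding <- function(model, n, seed = 1, prefix = "pos") {
  stopifnot(inherits(model, "coding_model"), n >= 0)
  seqs <- .with_seed(seed, {
    vapply(seq_len(n), function(i) {
      L <- .draw_int(model$len_range[1], model$len_range[2])
      body <- sample(SENSE_CODONS, L, replace = TRUE, prob = model$codon_probs)
      stop_c <- sample(STOP_CODONS, 1L, prob = model$stop_probs)
      paste0("ATG", paste(body, collapse = ""), stop_c)
    }, character(1))
  })
  data.frame(seq_id = sprintf("%s_%04d", prefix, seq_len(n))[seq_len(n)],
             sequence = seqs, label = rep(1L, n),
             source = rep("synthetic", n), stringsAsFactors = FALSE)
}

#' Sample non-coding background sequences
#'
#' @param model A `noncoding_model`.
#' @inheritParams sample_coding
#' @return Data frame of labeled sequences: `seq_id`, `sequence`,
#'   `label` (-1), `source` (`"synthetic"`).
#' @export
sample_noncoding <- function(model, n, seed = 1, prefix = "neg") {
  stopifnot(inherits(model, "noncoding_model"), n >= 0)
  seqs <- .with_seed(seed, {
    vapply(seq_len(n), function(i) {
      L <- .draw_int(model$len_range[1], model$len_range[2])
      paste(sample(NUCLEOTIDES, L, replace = TRUE, prob = model$base_probs),
            collapse = "")
    }, character(1))
  })
  data.frame(seq_id = sprintf("%s_%04d", prefix, seq_len(n))[seq_len(n)],
             sequence = seqs, label = rep(-1L, n),
             source = rep("synthetic", n), stringsAsFactors = FALSE)
}

#' Build a labeled benchmark set
#'
#' Three signal levels:
#' * `"strong"`: a heavily concentrated codon table against a uniform
#'   (50% GC) background — near-separable by construction.
#' * `"yeast_like"`: the moderately biased packaged codon table (GC ~ 0.40)
#'   against a 36% GC background, the realistic regime.
#' * `"null"`: both classes drawn from the *same* frame-free background
#'   model (positive lengths rounded down to a codon multiple), so no
#'   encoder can do better than chance and a classifier should sit near
#'   50% accuracy.
#'
#' @param n_pos,n_neg Class sizes (>= 0).
#' @param signal `"strong"`, `"yeast_like"` or `"null"`.
#' @param seed Integer seed; same arguments give bit-identical output.
#' @return Data frame of labeled sequences (`seq_id`, `sequence`, `label`,
#'   `source`) with attributes `signal` and `seed`.
#' @export
make_benchmark <- function(n_pos, n_neg,
                           signal = c("yeast_like", "strong", "null"),
                           seed = 1) {
  signal <- match.arg(signal)
  stopifnot(n_pos >= 0, n_neg >= 0)
  if (signal == "strong") {
    # concentrate mass on a fixed quarter of the sense codons
    w <- stats::setNames(rep(1, 61), SENSE_CODONS)
    w[seq(1L, 61L, by = 4L)] <- 40
    pos <- sample_coding(coding_model(codon_probs = w), n_pos, seed = seed)
    neg <- sample_noncoding(noncoding_model(gc = 0.50), n_neg, seed = seed + 1L)
  } else if (signal == "yeast_like") {
    pos <- sample_coding(coding_model(), n_pos, seed = seed)
    neg <- sample_noncoding(noncoding_model(gc = 0.36), n_neg, seed = seed + 1L)
  } else {
    bg <- noncoding_model(gc = 0.36)
    pos <- sample_noncoding(bg, n_pos, seed = seed, prefix = "pos")
    pos$sequence <- substr(pos$sequence, 1L,
                           (nchar(pos$sequence) %/% 3L) * 3L)
    pos$label <- rep(1L, nrow(pos))
    neg <- sample_noncoding(bg, n_neg, seed = seed + 1L)
  }
  out <- rbind(pos, neg)
  rownames(out) <- NULL
  attr(out, "signal") <- signal
  attr(out, "seed") <- seed
  out
}

#' Write a benchmark set as FASTA plus a label table
#'
#' @param dataset Labeled sequence data frame.
#' @param fasta_path,labels_path Output paths (FASTA; tab-delimited
#'   `seq_id`, `label`, `source`).
#' @return `fasta_path`, invisibly.
#' @export
write_benchmark <- function(dataset, fasta_path, labels_path) {
  write_fasta(stats::setNames(dataset$sequence, dataset$seq_id), fasta_path)
  write.table(dataset[, c("seq_id", "label", "source")], labels_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}

#' Read a label table written by [write_benchmark()]
#'
#' @param fasta_path,labels_path Paths written by [write_benchmark()].
#' @return Labeled sequence data frame.
#' @export
read_benchmark <- function(fasta_path, labels_path) {
  seqs <- read_fasta(fasta_path)
  lab <- read.delim(labels_path, stringsAsFactors = FALSE)
  if (!all(lab$seq_id %in% names(seqs)))
    stop("label table and FASTA disagree on sequence ids", call. = FALSE)
  data.frame(seq_id = lab$seq_id, sequence = unname(seqs[lab$seq_id]),
             label = lab$label, source = lab$source, stringsAsFactors = FALSE)
}
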