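# Independent brute-force oracles for the feature encoders and interval
# arithmetic. Deliberately written as naive character-level dictionary
# counts, sharing no code with the package's encoders.

oracle_nt <- c("A", "C", "G", "T")
oracle_codons <- apply(expand.grid(oracle_nt, oracle_nt, oracle_nt)[, 3:1],
                       1, paste0, collapse = "")
oracle_codons <- sort(oracle_codons)
oracle_dints <- sort(apply(expand.grid(oracle_nt, oracle_nt)[, 2:1], 1,
                           paste0, collapse = ""))
oracle_aa <- c(sort(setdiff(unique(unname(Biostrings::GENETIC_CODE)), "*")), "*")

# count occurrences of each dictionary word among items; frequency or zeros
oracle_freq <- function(items, dictionary) {
  items <- items[items %in% dictionary]
  if (length(items) == 0) return(setNames(numeric(length(dictionary)), dictionary))
  tab <- table(factor(items, levels = dictionary))
  as.numeric(tab) / length(items) -> f
  setNames(f, dictionary)
}

oracle_split_codons <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- floor(length(chars) / 3)
  vapply(seq_len(n), function(i)
    paste0(chars[3 * i - 2], chars[3 * i - 1], chars[3 * i]), character(1))
}

# valid = codon made of ACGT only
oracle_valid <- function(codons) codons %in% oracle_codons

oracle_mono_nt <- function(seq) {
  cod <- oracle_split_codons(seq)
  cod <- cod[oracle_valid(cod)]
  unlist(lapply(1:3, function(p)
    oracle_freq(substr(cod, p, p), oracle_nt)), use.names = FALSE)
}

oracle_di_nt <- function(seq) {
  cod <- oracle_split_codons(seq)
  ok <- oracle_valid(cod)
  g12 <- oracle_freq(paste0(substr(cod[ok], 1, 1), substr(cod[ok], 2, 2)),
                     oracle_dints)
  g23 <- oracle_freq(paste0(substr(cod[ok], 2, 2), substr(cod[ok], 3, 3)),
                     oracle_dints)
  if (length(cod) >= 2) {
    i <- which(ok[-length(cod)] & ok[-1])
    g31 <- oracle_freq(paste0(substr(cod[i], 3, 3), substr(cod[i + 1], 1, 1)),
                       oracle_dints)
  } else {
    g31 <- setNames(numeric(16), oracle_dints)
  }
  c(g12, g23, g31)
}

oracle_codon_usage <- function(seq) {
  cod <- oracle_split_codons(seq)
  unname(oracle_freq(cod[oracle_valid(cod)], oracle_codons))
}

oracle_dicodon <- function(seq) {
  cod <- oracle_split_codons(seq)
  dict <- as.vector(outer(oracle_codons, oracle_codons,
                          function(a, b) paste0(a, b)))
  dict <- sort(dict)
  if (length(cod) < 2) return(setNames(numeric(4096), dict))
  ok <- oracle_valid(cod)
  i <- which(ok[-length(cod)] & ok[-1])
  oracle_freq(paste0(cod[i], cod[i + 1]), dict)
}

oracle_translate <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

oracle_aa_usage <- function(seq) {
  cod <- oracle_split_codons(seq)
  unname(oracle_freq(oracle_translate(cod[oracle_valid(cod)]), oracle_aa))
}

oracle_diaa <- function(seq) {
  cod <- oracle_split_codons(seq)
  dict <- as.vector(t(outer(oracle_aa, oracle_aa, paste0)))
  if (length(cod) < 2) return(setNames(numeric(441), dict))
  ok <- oracle_valid(cod)
  i <- which(ok[-length(cod)] & ok[-1])
  aa <- oracle_translate(cod)
  oracle_freq(paste0(aa[i], aa[i + 1]), dict)
}

# manual reverse complement, character by character
oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(seq), "")[[1]]]), collapse = "")
}

# random test sequence, mostly ACGT with occasional ambiguity characters
random_seq <- function(len, p_ambig = 0.02) {
  alpha <- c("A", "C", "G", "T")
  s <- sample(alpha, len, replace = TRUE)
  n_amb <- rbinom(1, len, p_ambig)
  if (n_amb > 0) s[sample(len, n_amb)] <- "N"
  paste(s, collapse = "")
}

# per-base occupancy mask oracle for intergenic extraction
oracle_intergenic_runs <- function(genome_len, starts, ends, min_len) {
  mask <- rep(FALSE, genome_len)
  for (i in seq_along(starts)) mask[starts[i]:ends[i]] <- TRUE
  runs <- rle(!mask)
  pos <- cumsum(c(1, runs$lengths))
  keep <- which(runs$values & runs$lengths > min_len)
  data.frame(start = pos[keep], end = pos[keep] + runs$lengths[keep] - 1)
}
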