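# Programmatic fixtures: a planted synthetic genome with annotated genes,
# hidden coding ORFs and hidden junk ORFs, plus annotation-file writers.

# Genome = spacer, orf, spacer, orf, ... Genes come from the coding model,
# junk ORFs from the background (trimmed to codon length). Status of each
# planted ORF is returned so tests can derive snapshots and hand-computed
# expectations.
make_genome_fixture <- function(seed = 42, n_verified = 40,
                                n_hidden_coding = 6, n_hidden_junk = 6) {
  cm <- coding_model(len_range = c(60L, 200L))
  bg <- noncoding_model(gc = 0.36, len_range = c(400L, 800L))
  n_genes <- n_verified + n_hidden_coding + n_hidden_junk
  genes <- sample_coding(cm, n_verified + n_hidden_coding, seed = seed)$sequence
  junk <- sample_noncoding(noncoding_model(gc = 0.36, len_range = c(180L, 600L)),
                           n_hidden_junk, seed = seed + 1)$sequence
  junk <- substr(junk, 1, nchar(junk) %/% 3 * 3)
  spacers <- sample_noncoding(bg, n_genes + 1, seed = seed + 2)$sequence
  bodies <- c(genes, junk)
  status <- c(rep("verified", n_verified),
              rep("hidden_coding", n_hidden_coding),
              rep("hidden_junk", n_hidden_junk))
  set.seed(seed + 3)
  ord <- sample(n_genes)
  bodies <- bodies[ord]
  status <- status[ord]
  seq <- spacers[1]
  rows <- vector("list", n_genes)
  set.seed(seed + 4)
  for (i in seq_len(n_genes)) {
    strand <- sample(c("+", "-"), 1)
    s <- if (strand == "+") bodies[i] else oracle_revcomp(bodies[i])
    start <- nchar(seq) + 1
    seq <- paste0(seq, s, spacers[i + 1])
    rows[[i]] <- data.frame(
      orf_id = sprintf("YSYN%03d", i), gene_name = NA_character_,
      chrom = "chrS", start = start, end = start + nchar(s) - 1,
      strand = strand, category = status[i], stringsAsFactors = FALSE)
  }
  list(genome = c(chrS = seq), records = do.call(rbind, rows))
}

# older/newer snapshot pair: hidden ORFs start unresolved; `upgrade` ids
# become verified in the newer snapshot
fixture_snapshots <- function(fx, upgrade) {
  older <- fx$records
  older$category[older$category == "hidden_coding"] <- "uncharacterized"
  older$category[older$category == "hidden_junk"] <- "dubious"
  newer <- older
  newer$category[newer$orf_id %in% upgrade] <- "verified"
  list(older = snapshot("older", older), newer = snapshot("newer", newer))
}

write_sgd_tab <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  path
}

write_gff3 <- function(records, path, category_attr = "orf_classification") {
  # SGD-style: category carried in an attribute, names capitalized
  cap <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
  lines <- c("##gff-version 3",
             sprintf("%s\tSGD\tgene\t%d\t%d\t.\t%s\t.\tID=%s;%s=%s",
                     records$chrom, records$start, records$end,
                     records$strand, records$orf_id, category_attr,
                     cap(records$category)))
  writeLines(lines, path)
  path
}

# small labeled dataset for classifier tests
tiny_benchmark <- function(n = 60, seed = 9, signal = "yeast_like") {
  make_benchmark(n, n, signal = signal, seed = seed)
}
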