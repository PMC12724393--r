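# Shared fixtures built in code.

# small deterministic genome for repeat/overlap tests
toy_genome <- function(sequence, name = "toy") {
  structure(list(name = name, sequence = toupper(sequence),
                 length = nchar(sequence), circular = TRUE),
            class = "mito_genome")
}

random_genome <- function(n, seed) {
  set.seed(seed)
  toy_genome(paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                   collapse = ""))
}

# brute-force oracle for the in-register junction repeat: enumerate every
# candidate run start/length explicitly and test substring equality
brute_max_repeat <- function(genome, bp5, bp3, window = 15L) {
  s <- genome$sequence
  a5 <- bp5; a3 <- bp3 - 1L
  best <- 0L
  for (i0 in -window:window) {
    for (i1 in i0:window) {
      len <- i1 - i0 + 1L
      if (len <= best) next
      x <- substr(s, a5 + i0, a5 + i1)
      y <- substr(s, a3 + i0, a3 + i1)
      if (!grepl("N", x, fixed = TRUE) && toupper(x) == toupper(y)) {
        best <- len
      }
    }
  }
  best
}

# per-base membership oracle for impact annotation
brute_span_features <- function(catalog, span_start, span_end) {
  gl <- attr(catalog, "genome_length")
  span_pos <- if (span_start <= span_end) span_start:span_end
  else c(span_start:gl, 1:span_end)
  hits <- character(0); impact <- character(0)
  for (i in seq_len(nrow(catalog))) {
    fpos <- if (catalog$start[i] <= catalog$end[i])
      catalog$start[i]:catalog$end[i]
    else c(catalog$start[i]:gl, 1:catalog$end[i])
    ov <- sum(fpos %in% span_pos)
    if (ov > 0L) {
      hits <- c(hits, catalog$name[i])
      impact <- c(impact, if (ov == length(fpos)) "removed" else "truncated")
    }
  }
  data.frame(name = hits, impact = impact, stringsAsFactors = FALSE)
}

# deletion call rows for tests
del_row <- function(sample_id, bp5, bp3, reads = 10, read_pct = 0.05,
                    benchmark = 10000) {
  data.frame(sample_id = sample_id, bp5 = bp5, bp3 = bp3,
             supporting_reads = reads, read_pct = read_pct,
             benchmark_coverage = benchmark, wraps = bp3 <= bp5,
             stringsAsFactors = FALSE)
}
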