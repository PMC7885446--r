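# Fixture builders and brute-force oracles shared by the test files.
# All fixtures are generated in code; nothing is read from disk except
# files the tests themselves write to tempdir().

# Build an alignment from short sequence strings.
fix_aln <- function(..., groups = NULL) {
  seqs <- c(...)
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  hap_alignment(seqs, groups = groups)
}

# Brute-force pairwise-deletion difference count between two sequence
# strings; independent of the package's vectorised counters.
brute_diff <- function(a, b) {
  a <- strsplit(toupper(a), "")[[1]]
  b <- strsplit(toupper(b), "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  sum(a[ok] != b[ok])
}

# All pairwise differences of an alignment by exhaustive enumeration.
brute_all_pairs <- function(seqs) {
  n <- length(seqs)
  out <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) out <- c(out, brute_diff(seqs[i], seqs[j]))
  }
  out
}

# Write a small FASTA (wrapped at `wrap` columns) for I/O tests.
write_tiny_fasta <- function(seqs, path, wrap = 0) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    cat(">", nm, "\n", sep = "", file = con)
    s <- seqs[[nm]]
    if (wrap > 0) {
      starts <- seq(1, nchar(s), by = wrap)
      for (st in starts) cat(substr(s, st, min(st + wrap - 1, nchar(s))), "\n", sep = "", file = con)
    } else {
      cat(s, "\n", sep = "", file = con)
    }
  }
  path
}

# Hub-and-spokes haplotype sample: one frequent central sequence plus m
# singletons, each one substitution away at a distinct site.
hub_spokes_aln <- function(m = 8, hub_freq = 5, k = 40) {
  base <- strsplit(paste(rep("ACGT", k / 4), collapse = ""), "")[[1]]
  seqs <- character(0)
  for (i in seq_len(hub_freq)) seqs <- c(seqs, paste(base, collapse = ""))
  for (i in seq_len(m)) {
    s <- base
    s[i] <- setdiff(c("A", "C", "G", "T"), base[i])[1]
    seqs <- c(seqs, paste(s, collapse = ""))
  }
  names(seqs) <- paste0("s", seq_along(seqs))
  hap_alignment(seqs)
}
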