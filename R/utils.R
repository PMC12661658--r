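# Internal helpers shared across modules.

# Split sequence strings into character matrices / vectors ---------------------

seq_to_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# All sequences same length -> matrix (n x L) of single characters.
seqs_to_matrix <- function(seqs) {
  L <- unique(nchar(seqs))
  if (length(L) != 1L) {
    abort("All sequences must have the same length.")
  }
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
    nrow = length(seqs), ncol = L, byrow = TRUE
  )
}

chars_to_seq <- function(ch) paste(ch, collapse = "")

check_aa <- function(s, arg = "sequence") {
  bad <- setdiff(unique(seq_to_chars(s)), AA_ALPHABET)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Invalid residue symbol(s) in %s: %s", arg,
      paste(bad, collapse = ", ")
    ))
  }
  invisible(s)
}

# Encode an amino acid string as integer indices into AA_ALPHABET.
aa_index <- function(s) {
  idx <- match(seq_to_chars(s), AA_ALPHABET)
  if (anyNA(idx)) check_aa(s)
  idx
}

aa_index_matrix <- function(seqs) {
  m <- seqs_to_matrix(seqs)
  idx <- match(m, AA_ALPHABET)
  if (anyNA(idx)) {
    bad <- setdiff(unique(as.vector(m)), AA_ALPHABET)
    abort(sprintf(
      "Invalid residue symbol(s): %s", paste(bad, collapse = ", ")
    ))
  }
  matrix(idx, nrow = nrow(m), ncol = ncol(m))
}

# Genetic code ------------------------------------------------------------------

genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

# aa -> codons lookup (stops excluded)
codons_for_aa <- function() {
  gc <- genetic_code()
  gc <- gc[gc != "*"]
  split(names(gc), gc)
}

translate_cds <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) abort("CDS length must be divisible by 3.")
  codons <- substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  aa <- genetic_code()[codons]
  if (anyNA(aa)) abort("CDS contains invalid codons.")
  paste(aa, collapse = "")
}

# Reverse-translate an aa string, choosing synonymous codons at random
# (uses the current RNG stream; callers seed).
reverse_translate <- function(aa) {
  tab <- codons_for_aa()
  ch <- seq_to_chars(aa)
  codons <- vapply(ch, function(a) {
    opts <- tab[[a]]
    if (is.null(opts)) abort(sprintf("No codon for residue '%s'.", a))
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste(codons, collapse = "")
}

# DNA k-mers -------------------------------------------------------------------

revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA", paste(rev(seq_to_chars(s)), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Set of canonical k-mers (lexicographic min of k-mer and its reverse
# complement), strand-aware comparison of promoters.
canonical_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) abort(sprintf("Sequence shorter than k = %d.", k))
  kmers <- substring(s, 1:(n - k + 1L), k:n)
  rc <- revcomp(kmers)
  unique(pmin(kmers, rc))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

random_aa <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

# Misc -------------------------------------------------------------------------

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_rate <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single value in [0, 1].", name))
  }
  as.numeric(x)
}

# log-sum-exp over matrix rows
row_logsumexp <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  mx + log(rowSums(exp(m - mx)))
}

# row-wise softmax
row_softmax <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  e <- exp(m - mx)
  e / rowSums(e)
}

# Sample one category per row from a row-stochastic matrix.
sample_categorical_rows <- function(p) {
  cum <- p %*% upper.tri(diag(ncol(p)), diag = TRUE)
  u <- runif(nrow(p))
  1L + rowSums(cum < u)
}
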