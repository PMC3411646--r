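# Brute-force reference implementations, deliberately written as explicit
# per-column loops so they share no code path with the package.

# pairwise indel events on a projected view (char vectors a, b): maximal runs
# of gap in exactly one taxon; runs touching either alignment end excluded.
bf_pairwise_indels <- function(a, b) {
  n <- length(a)
  state <- character(n)
  for (i in seq_len(n)) {
    state[i] <- if (a[i] == "-" && b[i] != "-") "a"
    else if (b[i] == "-" && a[i] != "-") "b"
    else "."
  }
  out <- data.frame(start = integer(), end = integer(),
                    gapped_taxon = character(), stringsAsFactors = FALSE)
  i <- 1L
  while (i <= n) {
    if (state[i] != ".") {
      j <- i
      while (j < n && state[j + 1L] == state[i]) j <- j + 1L
      if (i > 1L && j < n) {
        out <- rbind(out, data.frame(start = i, end = j,
                                     gapped_taxon = state[i],
                                     stringsAsFactors = FALSE))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# multi-taxon gap loci on a character matrix (rows = taxa): maximal spans
# with a constant non-empty gapped set.
bf_loci <- function(m) {
  nc <- ncol(m)
  keys <- character(nc)
  for (j in seq_len(nc)) {
    g <- which(m[, j] == "-")
    keys[j] <- paste(g, collapse = ",")
  }
  out <- data.frame(start = integer(), end = integer(),
                    gapped = character(), stringsAsFactors = FALSE)
  j <- 1L
  while (j <= nc) {
    if (keys[j] != "") {
      k <- j
      while (k < nc && keys[k + 1L] == keys[j]) k <- k + 1L
      out <- rbind(out, data.frame(start = j, end = k, gapped = keys[j],
                                   stringsAsFactors = FALSE))
      j <- k + 1L
    } else {
      j <- j + 1L
    }
  }
  out
}

# random alignment over an alphabet; guarantees no taxon is all-gap
random_alignment <- function(n_taxa, n_cols, alphabet = c("A", "C", "-")) {
  repeat {
    m <- matrix(sample(alphabet, n_taxa * n_cols, replace = TRUE),
                nrow = n_taxa)
    if (all(apply(m, 1L, function(r) any(r != "-")))) break
  }
  seqs <- apply(m, 1L, paste, collapse = "")
  names(seqs) <- paste0("t", seq_len(n_taxa))
  plastome_alignment(seqs)
}

collapse <- function(chars) paste(chars, collapse = "")
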