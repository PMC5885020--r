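DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#' @param x character scalar over ACGTN
#' @return character scalar
#' @keywords internal
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# integer encoding 1..4 = ACGT, 5 = other; used by the simulator and distances
encode_dna <- function(x) {
  v <- match(strsplit(toupper(x), "")[[1]], DNA_BASES)
  v[is.na(v)] <- 5L
  v
}

decode_dna <- function(v) {
  paste(c(DNA_BASES, "N")[v], collapse = "")
}

# split a concatenated character vector of single bases into a string
collapse_bases <- function(v) paste(v, collapse = "")

#' Evaluate an expression with a fixed RNG seed, restoring RNG state after
#' @keywords internal
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# derive a stage seed from a root seed; keeps results < 2^31
derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, ani = 211L, pangenome = 307L, phylo = 401L,
               recomb = 503L, congruence = 601L, pipeline = 701L)
  off <- offsets[[stage]]
  as.integer((as.double(seed) * 48271 + off) %% 2147483647)
}

# union-find connected components; edges: 2-column integer matrix over 1..n
graph_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges) > 0 && nrow(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      a <- find(edges[e, 1]); b <- find(edges[e, 2])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_phagani <- function(...) stop(..., call. = FALSE)
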