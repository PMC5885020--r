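#' Extract gene nucleotide and protein sequences
#'
#' Cuts genes out of the genomes using the 0-based half-open gene table,
#' reverse-complements minus-strand genes so sequences are in CDS orientation,
#' and translates them with the standard code (terminal stop trimmed; internal
#' stops arising from simulated substitutions are kept as `*`).
#'
#' @param genomes named character vector
#' @param gene_table data.frame with genome_id, gene_id, start, end, strand
#' @return data.frame with genome_id, gene_id, start, end, strand, nt, aa
#' @export
extract_genes <- function(genomes, gene_table) {
  gt <- gene_table
  missing <- setdiff(unique(gt$genome_id), names(genomes))
  if (length(missing) > 0)
    stop_phagani("gene table references unknown genomes: ",
                 paste(missing, collapse = ", "))
  nt <- substring(genomes[gt$genome_id], gt$start + 1, gt$end)
  minus <- gt$strand == "-"
  nt[minus] <- vapply(nt[minus], revcomp_chr, character(1), USE.NAMES = FALSE)
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(nt),
                                           if.fuzzy.codon = "solve"))
  aa <- sub("\\*$", "", aa)
  data.frame(gt[c("genome_id", "gene_id", "start", "end", "strand")],
             nt = nt, aa = aa, row.names = NULL)
}

#' Local protein alignment statistics (AAI and coverage)
#'
#' Best local alignment under BLOSUM62 with affine gaps (a gap of length L
#' costs 10 + L). AAI is identities over alignment columns; coverage of each
#' protein is its aligned length over its full length.
#'
#' @param a,b protein sequences (character scalars)
#' @return list with aai, coverage_a, coverage_b, score
#' @export
protein_match <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                      Biostrings::AAString(b),
                                      type = "local",
                                      substitutionMatrix = "BLOSUM62",
                                      gapOpening = 10, gapExtension = 1)
  ap <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  cols <- nchar(ap)
  ids <- sum(strsplit(ap, "")[[1]] == strsplit(as_, "")[[1]])
  list(aai = 100 * ids / cols,
       coverage_a = nchar(gsub("-", "", ap)) / nchar(a),
       coverage_b = nchar(gsub("-", "", as_)) / nchar(b),
       score = Biostrings::score(pa))
}

# candidate gene pairs sharing at least one amino-acid k-mer
kmer_candidate_pairs <- function(aa, k = 5L, max_occ = 200L) {
  n <- length(aa)
  kmers <- lapply(aa, function(s) {
    if (nchar(s) < k) return(character(0))
    unique(substring(s, seq_len(nchar(s) - k + 1), k:nchar(s)))
  })
  idx <- rep(seq_len(n), lengths(kmers))
  tab <- split(idx, unlist(kmers))
  pairs <- list()
  for (members in tab) {
    if (length(members) < 2 || length(members) > max_occ) next
    pairs[[length(pairs) + 1]] <- t(combn(members, 2))
  }
  if (length(pairs) == 0) return(matrix(integer(0), ncol = 2))
  unique(do.call(rbind, pairs))
}

#' Cluster genes into ortholog families
#'
#' All-versus-all local protein comparison (k-mer prefiltered), with an edge
#' between two genes when AAI >= `aai_min` percent and alignment coverage
#' reaches `cov_min` on both proteins (or the shorter/longer one, per
#' `coverage_rule`); families are connected components, ordered
#' deterministically by the (genome_id, gene_id) of their first member.
#'
#' @param genes data.frame from [extract_genes()]
#' @param aai_min minimum amino-acid identity (percent)
#' @param cov_min minimum coverage fraction
#' @param coverage_rule which protein(s) must reach `cov_min`: "both" (default),
#'   "shorter" or "longer"
#' @return object of class `gene_family_set`: `families` (list of data.frames
#'   of member genes), `counts` (family x genome matrix), `genomes`
#' @export
cluster_families <- function(genes, aai_min = 50, cov_min = 0.5,
                             coverage_rule = c("both", "shorter", "longer")) {
  coverage_rule <- match.arg(coverage_rule)
  if (nrow(genes) == 0) stop_phagani("no genes")
  ord <- order(genes$genome_id, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  n <- nrow(genes)
  genomes <- sort(unique(genes$genome_id))
  cand <- kmer_candidate_pairs(genes$aa)
  edges <- matrix(integer(0), ncol = 2)
  if (nrow(cand) > 0) {
    aa <- Biostrings::AAStringSet(genes$aa)
    lens <- nchar(genes$aa)
    pa <- Biostrings::pairwiseAlignment(aa[cand[, 1]], aa[cand[, 2]],
                                        type = "local",
                                        substitutionMatrix = "BLOSUM62",
                                        gapOpening = 10, gapExtension = 1)
    aai <- Biostrings::pid(pa, type = "PID1")
    cov_a <- Biostrings::width(Biostrings::pattern(pa)) / lens[cand[, 1]]
    cov_b <- Biostrings::width(Biostrings::subject(pa)) / lens[cand[, 2]]
    la <- lens[cand[, 1]]; lb <- lens[cand[, 2]]
    covs <- switch(coverage_rule,
                   both = pmin(cov_a, cov_b),
                   shorter = ifelse(la <= lb, cov_a, cov_b),
                   longer = ifelse(la >= lb, cov_a, cov_b))
    keep <- aai >= aai_min & covs >= cov_min
    edges <- cand[keep, , drop = FALSE]
  }
  comp <- graph_components(n, edges)
  fam_ids <- unique(comp)  # first-occurrence order = (genome_id, gene_id) order
  families <- lapply(fam_ids, function(f)
    genes[comp == f, c("genome_id", "gene_id"), drop = FALSE])
  names(families) <- sprintf("F%04d", seq_along(families))
  counts <- matrix(0L, length(families), length(genomes),
                   dimnames = list(names(families), genomes))
  for (f in seq_along(families)) {
    tb <- table(families[[f]]$genome_id)
    counts[f, names(tb)] <- as.integer(tb)
  }
  structure(list(families = families, counts = counts, genomes = genomes),
            class = "gene_family_set")
}

#' Core and single-copy-core families
#'
#' Core families are present in every genome; single-copy-core families are
#' present exactly once in every genome (the substrate for core-gene
#' alignments).
#'
#' @param fams a `gene_family_set`
#' @return list with `core` and `single_copy_core` family name vectors
#' @export
core_genome <- function(fams) {
  if (length(fams$genomes) == 0) stop_phagani("empty genome set")
  core <- rownames(fams$counts)[rowSums(fams$counts >= 1) == ncol(fams$counts)]
  scc <- rownames(fams$counts)[rowSums(fams$counts == 1) == ncol(fams$counts)]
  list(core = core, single_copy_core = scc)
}

#' Neighbour-joining dendrogram of gene presence-absence
#'
#' Pairwise distance is the proportion of families whose presence differs
#' (simple matching on the binary presence matrix).
#'
#' @param fams a `gene_family_set`
#' @return a `phylo` tree
#' @export
presence_absence_dendrogram <- function(fams) {
  if (length(fams$genomes) < 3) stop_phagani("need >= 3 genomes")
  pa <- t(fams$counts >= 1)  # genomes x families
  n <- nrow(pa)
  d <- matrix(0, n, n, dimnames = list(rownames(pa), rownames(pa)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- mean(pa[i, ] != pa[j, ])
  nj_tree(d)
}

#' Families core to one group and absent from another
#'
#' Families with at least one copy in every member of `group_a` and none in
#' any member of `group_b`: the gene-content difference between two
#' delineated groups.
#'
#' @param fams a `gene_family_set`
#' @param group_a,group_b disjoint character vectors of genome ids
#' @return character vector of family names
#' @export
group_content_diff <- function(fams, group_a, group_b) {
  if (length(intersect(group_a, group_b)) > 0)
    stop_phagani("groups must be disjoint")
  missing <- setdiff(c(group_a, group_b), fams$genomes)
  if (length(missing) > 0)
    stop_phagani("unknown genomes: ", paste(missing, collapse = ", "))
  cc <- fams$counts
  in_a <- rowSums(cc[, group_a, drop = FALSE] >= 1) == length(group_a)
  in_b <- rowSums(cc[, group_b, drop = FALSE]) > 0
  rownames(cc)[in_a & !in_b]
}

#' Per-family gene alignments for single-copy families
#'
#' For each requested single-copy family, stacks the member genes' CDS
#' sequences (equal length under indel-free evolution) into an alignment
#' keyed by genome.
#'
#' @param genes data.frame from [extract_genes()]
#' @param fams a `gene_family_set`
#' @param families family names (default: single-copy core)
#' @return named list of alignments (named character vectors); families whose
#'   members differ in length are dropped with a warning
#' @export
family_alignments <- function(genes, fams, families = NULL) {
  families <- families %||% core_genome(fams)$single_copy_core
  key <- paste(genes$genome_id, genes$gene_id)
  out <- list()
  for (f in families) {
    mem <- fams$families[[f]]
    idx <- match(paste(mem$genome_id, mem$gene_id), key)
    seqs <- setNames(genes$nt[idx], genes$genome_id[idx])
    if (length(unique(nchar(seqs))) != 1) {
      warning("family ", f, " has unequal gene lengths; dropped")
      next
    }
    out[[f]] <- seqs
  }
  out
}
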