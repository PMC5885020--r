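#' Default ANIb parameters
#'
#' Fragment length follows the 500 bp convention of fragment-based ANI; hit
#' qualification (identity >= 30 % over >= 70 % of the fragment) follows the
#' published ANIb definition. The trailing fragment is kept iff at least half
#' the fragment length. Scoring is blastn-like: match +1, mismatch -2, a gap
#' of length L costs 5 + 2L.
#'
#' @param fragment_length fragment size in bp
#' @param min_identity minimum percent identity for a qualifying hit
#' @param min_fraction minimum aligned fraction of the fragment
#' @param min_group_coverage coverage both directions must reach for a group
#'   edge in [delineate_groups()]
#' @param match,mismatch,gap_open,gap_ext alignment scoring
#' @param k seed k-mer size of the heuristic route
#' @param exact_max maximum target length (bp) for the exact Smith-Waterman
#'   route; longer targets use the seeded route
#' @return list of parameters
#' @export
anib_params <- function(fragment_length = 500L, min_identity = 30,
                        min_fraction = 0.7, min_group_coverage = 0.5,
                        match = 1, mismatch = -2, gap_open = 5, gap_ext = 2,
                        k = 11L, exact_max = 10000L) {
  list(fragment_length = as.integer(fragment_length),
       min_identity = min_identity, min_fraction = min_fraction,
       min_group_coverage = min_group_coverage,
       match = match, mismatch = mismatch,
       gap_open = gap_open, gap_ext = gap_ext,
       k = as.integer(k), exact_max = as.integer(exact_max))
}

#' Split a genome into consecutive non-overlapping fragments
#'
#' The trailing fragment is kept iff its length is at least half the fragment
#' length.
#'
#' @param sequence character scalar over ACGTN
#' @param fragment_length fragment size (bp)
#' @return data.frame with index, start, end (0-based half-open) and sequence
#' @export
fragment_genome <- function(sequence, fragment_length = 500L) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0)
    stop_phagani("sequence must be a non-empty character scalar")
  L <- nchar(sequence)
  starts <- seq(0L, L - 1L, by = fragment_length)
  ends <- pmin(starts + fragment_length, L)
  keep <- (ends - starts) >= fragment_length / 2
  starts <- starts[keep]; ends <- ends[keep]
  data.frame(index = seq_along(starts), start = starts, end = ends,
             sequence = substring(sequence, starts + 1, ends))
}

#' Best local alignment of a fragment against a target genome
#'
#' Both strands are searched. Targets up to `exact_max` use exact affine-gap
#' Smith-Waterman; longer targets use the k-mer seeded gapless route. Identity
#' is matched columns over alignment columns; aligned fraction is aligned
#' fragment bases over fragment length.
#'
#' @param fragment character scalar
#' @param target character scalar
#' @param params [anib_params()]
#' @return list with score, identity, aligned_fraction, strand, valid
#' @export
best_local_match <- function(fragment, target, params = anib_params()) {
  res <- align_fragments_cpp(fragment, target, params$k, params$match,
                             params$mismatch, params$gap_open, params$gap_ext,
                             exact = nchar(target) <= params$exact_max)
  list(score = res$score[1],
       identity = if (res$valid[1]) 100 * res$matches[1] / res$columns[1] else NA_real_,
       aligned_fraction = res$q_aligned[1] / nchar(fragment),
       strand = res$strand[1], valid = res$valid[1])
}

#' Directional fragment-based ANI of a query genome against a target
#'
#' The query is tiled into fragments, each locally aligned against the target;
#' ANI is the unweighted mean identity of qualifying hits and coverage the
#' fraction of the query contained in qualifying fragments. With no qualifying
#' fragment, ANI is undefined (NA) and coverage 0.
#'
#' @param query,target character scalars
#' @param params [anib_params()]
#' @return object of class `ani_result`
#' @export
compute_anib <- function(query, target, params = anib_params()) {
  if (nchar(query) == 0 || nchar(target) == 0)
    stop_phagani("genomes must be non-empty")
  fr <- fragment_genome(query, params$fragment_length)
  # genome-scale comparisons go through the seeded route: a fragment hit
  # with no exact k-mer seed cannot reach the qualification thresholds.
  # The exact-DP route is kept for targets too short to index usefully.
  res <- align_fragments_cpp(fr$sequence, target, params$k, params$match,
                             params$mismatch, params$gap_open, params$gap_ext,
                             exact = nchar(target) < 2L * params$fragment_length)
  flen <- fr$end - fr$start
  identity <- ifelse(res$valid, 100 * res$matches / pmax(res$columns, 1), NA_real_)
  aligned_fraction <- res$q_aligned / flen
  qual <- res$valid & !is.na(identity) &
    identity >= params$min_identity & aligned_fraction >= params$min_fraction
  structure(list(ani = if (any(qual)) mean(identity[qual]) else NA_real_,
                 coverage = sum(flen[qual]) / nchar(query),
                 n_fragments = nrow(fr), n_qualifying = sum(qual),
                 hits = data.frame(fr[c("index", "start", "end")],
                                   identity = identity,
                                   aligned_fraction = aligned_fraction,
                                   qualifying = qual)),
            class = "ani_result")
}

#' All-versus-all directional ANI and coverage
#'
#' @param genomes named character vector of genome sequences (unique names)
#' @param params [anib_params()]
#' @return object of class `ani_matrix` with directional `ani` and `coverage`
#'   matrices, the symmetrized ANI (arithmetic mean of defined directions) and
#'   the pair count
#' @export
compute_all_anib <- function(genomes, params = anib_params()) {
  ids <- names(genomes)
  if (length(genomes) < 2) stop_phagani("need >= 2 genomes")
  if (is.null(ids) || anyDuplicated(ids)) stop_phagani("genome ids must be unique")
  n <- length(ids)
  ani <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  cov <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(ani) <- 100; diag(cov) <- 1
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    r <- compute_anib(genomes[[i]], genomes[[j]], params)
    ani[i, j] <- r$ani
    cov[i, j] <- r$coverage
  }
  sym <- (ani + t(ani)) / 2
  one_sided <- is.na(ani) & !is.na(t(ani))
  sym[one_sided] <- t(ani)[one_sided]
  diag(sym) <- 100
  structure(list(ids = ids, ani = ani, coverage = cov, sym_ani = sym,
                 params = params), class = "ani_matrix")
}

#' Delineate groups from an ANI matrix by threshold clustering
#'
#' Builds a graph with an edge between two genomes when their symmetrized ANI
#' reaches the cutoff and coverage in both directions reaches
#' `min_group_coverage` (so that a short near-identical transfer cannot fuse
#' groups); groups are connected components of size >= 2, the rest are
#' singletons.
#'
#' @param am [compute_all_anib()] result
#' @param cutoff ANI group cutoff (percent)
#' @param min_group_coverage minimum directional coverage for a group edge
#' @return object of class `ani_partition` with `groups` (named list),
#'   `singletons`, `cutoff`
#' @export
delineate_groups <- function(am, cutoff = 92.0,
                             min_group_coverage = am$params$min_group_coverage %||% 0.5) {
  n <- length(am$ids)
  adj <- !is.na(am$sym_ani) & am$sym_ani >= cutoff &
    !is.na(am$coverage) & am$coverage >= min_group_coverage &
    !is.na(t(am$coverage)) & t(am$coverage) >= min_group_coverage
  diag(adj) <- FALSE
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  comp <- graph_components(n, edges)
  sizes <- table(comp)
  groups <- list()
  for (cid in names(sizes)[sizes >= 2])
    groups[[length(groups) + 1]] <- am$ids[comp == as.integer(cid)]
  ord <- order(vapply(groups, `[`, character(1), 1))
  groups <- groups[ord]
  names(groups) <- sprintf("G%02d", seq_along(groups))
  singletons <- setdiff(am$ids, unlist(groups))
  structure(list(groups = groups, singletons = singletons, cutoff = cutoff,
                 min_group_coverage = min_group_coverage),
            class = "ani_partition")
}

#' Cluster labels of a partition
#'
#' @param partition an `ani_partition`
#' @return named character vector: group name per genome, singletons get their
#'   own label
#' @export
partition_labels <- function(partition) {
  lab <- character(0)
  for (g in names(partition$groups))
    lab <- c(lab, setNames(rep(g, length(partition$groups[[g]])),
                           partition$groups[[g]]))
  c(lab, setNames(paste0("singleton_", partition$singletons), partition$singletons))
}

#' Find satellite genomes of delineated groups
#'
#' A genome is a satellite of a group when it is not a member and its best
#' symmetrized ANI to the group lies in `[lo, cutoff)`. The relation is per
#' group: one genome can be a satellite of several groups.
#'
#' @param am `ani_matrix`
#' @param partition `ani_partition`
#' @param lo lower bound of the satellite band (percent)
#' @return data.frame with genome, group, max_ani
#' @export
find_satellites <- function(am, partition, lo = 85.0) {
  out <- list()
  for (g in names(partition$groups)) {
    members <- partition$groups[[g]]
    others <- setdiff(am$ids, members)
    for (s in others) {
      a <- suppressWarnings(max(am$sym_ani[s, members], na.rm = TRUE))
      if (is.finite(a) && a >= lo && a < partition$cutoff)
        out[[length(out) + 1]] <- data.frame(genome = s, group = g, max_ani = a)
    }
  }
  if (length(out) == 0)
    return(data.frame(genome = character(0), group = character(0),
                      max_ani = numeric(0)))
  do.call(rbind, out)
}

#' Flag candidate horizontal-transfer pairs (high ANI, low coverage)
#'
#' Ordered genome pairs whose directional ANI is at least `ani_min` while
#' coverage stays at or below `cov_max`: near-identical DNA confined to a
#' small portion of the query genome.
#'
#' @param am `ani_matrix`
#' @param ani_min minimum ANI (percent)
#' @param cov_max maximum coverage fraction
#' @return data.frame with query, target, ani, coverage
#' @export
flag_transfer_candidates <- function(am, ani_min = 92.0, cov_max = 0.2) {
  idx <- which(!is.na(am$ani) & am$ani >= ani_min & am$coverage <= cov_max,
               arr.ind = TRUE)
  idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
  data.frame(query = am$ids[idx[, 1]], target = am$ids[idx[, 2]],
             ani = am$ani[idx], coverage = am$coverage[idx])
}

#' Pairwise ANI tables for reporting
#'
#' @param am `ani_matrix`
#' @param breaks histogram bin edges over the ANI axis
#' @return list with `pairs` (long table of unordered pairs: symmetrized ANI,
#'   mean coverage), `histogram` (bin edges and counts)
#' @export
ani_report <- function(am, breaks = seq(60, 100, by = 1)) {
  n <- length(am$ids)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- data.frame(a = am$ids[ut[, 1]], b = am$ids[ut[, 2]],
                      ani = am$sym_ani[ut],
                      coverage = (am$coverage[ut] + t(am$coverage)[ut]) / 2)
  defined <- pairs[!is.na(pairs$ani), ]
  vals <- pmin(pmax(defined$ani, min(breaks)), max(breaks))
  counts <- if (nrow(defined) > 0)
    graphics::hist(vals, breaks = breaks, plot = FALSE)$counts
  else rep(0L, length(breaks) - 1)
  list(pairs = pairs,
       histogram = data.frame(lo = breaks[-length(breaks)], hi = breaks[-1],
                              count = counts))
}
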