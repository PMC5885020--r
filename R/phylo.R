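#' @title Alignment helpers
#' @description An alignment is a named character vector of equal-length
#'   sequences over ACGTN-; gaps and N are treated as missing.
#' @param seqs named character vector
#' @return integer matrix taxa x sites, 1..4 = ACGT, 0 = missing
#' @keywords internal
aln_int <- function(seqs) {
  if (is.null(names(seqs))) stop_phagani("alignment sequences must be named")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) stop_phagani("alignment rows must have equal length")
  m <- matrix(0L, length(seqs), lens[1],
              dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) {
    v <- match(strsplit(toupper(seqs[[i]]), "")[[1]], DNA_BASES)
    v[is.na(v)] <- 0L
    m[i, ] <- v
  }
  m
}

#' Tamura-Nei (1993) pairwise distances
#'
#' Distinguishes purine transitions, pyrimidine transitions and transversions
#' with unequal base frequencies. Base frequencies per pair are the mean of
#' the two sequences' frequencies over their comparable sites; gaps and N are
#' handled by pairwise deletion (or complete deletion on request). Saturated
#' pairs (non-positive log argument) are flagged infinite.
#'
#' @param seqs named character vector of aligned sequences
#' @param min_sites minimum comparable sites per pair
#' @param deletion "pairwise" (default) or "complete"
#' @return symmetric distance matrix with zero diagonal; attribute
#'   `model = "TN93"`
#' @export
tn93_distance <- function(seqs, min_sites = 50L, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  m <- aln_int(seqs)
  n <- nrow(m)
  if (n < 2) stop_phagani("need >= 2 taxa")
  if (deletion == "complete") {
    keep <- colSums(m == 0) == 0
    m <- m[, keep, drop = FALSE]
  }
  ids <- rownames(m)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] > 0 & m[j, ] > 0
    nc <- sum(ok)
    if (nc < min_sites)
      stop_phagani("too few comparable columns for pair ", ids[i], " / ", ids[j])
    a <- m[i, ok]; b <- m[j, ok]
    freq <- (tabulate(a, 4) + tabulate(b, 4)) / (2 * nc)  # A C G T
    gA <- freq[1]; gC <- freq[2]; gG <- freq[3]; gT <- freq[4]
    gR <- gA + gG; gY <- gC + gT
    diff <- a != b
    ts1 <- mean((a == 1 & b == 3) | (a == 3 & b == 1))  # A<->G
    ts2 <- mean((a == 2 & b == 4) | (a == 4 & b == 2))  # C<->T
    tv <- mean(diff) - ts1 - ts2
    if (gR <= 0 || gY <= 0) {
      d[i, j] <- d[j, i] <- Inf
      next
    }
    k1 <- 2 * gA * gG / gR
    k2 <- 2 * gT * gC / gY
    k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
    w1 <- if (k1 > 0) 1 - ts1 / k1 - tv / (2 * gR) else 1
    w2 <- if (k2 > 0) 1 - ts2 / k2 - tv / (2 * gY) else 1
    w3 <- 1 - tv / (2 * gR * gY)
    d[i, j] <- d[j, i] <- if (w1 <= 0 || w2 <= 0 || w3 <= 0) Inf else
      -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
  }
  attr(d, "model") <- "TN93"
  d
}

#' Neighbour-joining tree
#'
#' Saitou-Nei neighbour joining (via ape) on a finite distance matrix. Taxa
#' are sorted lexicographically beforehand so the result is independent of
#' input order; negative branch lengths are clamped to zero with the
#' remainder transferred to the adjacent branch.
#'
#' @param dm symmetric distance matrix with taxon dimnames
#' @return an unrooted `phylo` tree
#' @export
nj_tree <- function(dm) {
  if (nrow(dm) < 3) stop_phagani("need >= 3 taxa")
  if (any(!is.finite(dm))) {
    bad <- which(!is.finite(dm) & upper.tri(dm), arr.ind = TRUE)
    stop_phagani("saturated (infinite) distances for pairs: ",
                 paste(rownames(dm)[bad[, 1]], colnames(dm)[bad[, 2]],
                       sep = "/", collapse = ", "))
  }
  ord <- order(rownames(dm))
  dm <- dm[ord, ord]
  tr <- ape::nj(stats::as.dist(dm))
  # clamp negative branch lengths, moving the deficit to an adjacent branch
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    adj <- setdiff(which(tr$edge[, 1] == parent | tr$edge[, 2] == parent), e)
    if (length(adj) > 0)
      tr$edge.length[adj[1]] <- tr$edge.length[adj[1]] + tr$edge.length[e]
    tr$edge.length[e] <- 0
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Fitch parsimony branch assignment of substitutions
#'
#' Runs Fitch bottom-up/top-down over the variant columns on the unrooted
#' tree (traversed from its stored basal multifurcation, so every branch of
#' the unrooted tree is a single edge), and assigns each change to the branch
#' where the state switches; ambiguity is resolved by retaining the parent
#' state wherever possible, which pushes changes rootward. Gaps/N are missing
#' and never force a change.
#'
#' @param tree `phylo` tree whose tip labels match the alignment
#' @param seqs named character vector of aligned sequences
#' @return list with `changes` (data.frame: edge, column, node_child),
#'   `tree` (the rooted working copy), `branch_label` (per edge: tip label for
#'   terminal edges, sorted descendant clade for internal), `score`
#' @export
fitch_assign <- function(tree, seqs) {
  if (!setequal(tree$tip.label, names(seqs)))
    stop_phagani("tree leaves and alignment taxa differ")
  tr <- tree
  if (ape::is.rooted(tr)) tr <- ape::unroot(tr)
  tr <- stats::reorder(tr, "postorder")
  m <- aln_int(seqs)[tr$tip.label, , drop = FALSE]
  nt <- length(tr$tip.label)
  L <- ncol(m)
  # variant columns only (two observed states or more)
  obs <- m > 0
  nstates <- apply(m, 2, function(col) length(unique(col[col > 0])))
  var_cols <- which(nstates >= 2)
  bit <- matrix(0L, nt + tr$Nnode, length(var_cols))
  bitcode <- c(1L, 2L, 4L, 8L)
  for (i in seq_len(nt)) {
    v <- m[i, var_cols]
    bit[i, ] <- ifelse(v > 0, bitcode[pmax(v, 1)], 15L)
  }
  edge <- tr$edge
  # bottom-up
  children <- split(seq_len(nrow(edge)), edge[, 1])
  for (node in unique(edge[, 1])) { # postorder: children before parents
    kids <- edge[children[[as.character(node)]], 2]
    s <- bit[kids[1], ]
    for (k in kids[-1]) {
      inter <- bitwAnd(s, bit[k, ])
      un <- bitwOr(s, bit[k, ])
      s <- ifelse(inter > 0L, inter, un)
    }
    bit[node, ] <- s
  }
  lowest_bit <- function(x) bitwAnd(x, -x)
  root <- edge[nrow(edge), 1]
  state <- matrix(0L, nt + tr$Nnode, length(var_cols))
  # root state: the state contained in the most child Fitch sets (Hartigan
  # rule); exact for a multifurcating basal node over binary subtrees,
  # where the plain folded set can overcount. Ties go to the lowest base.
  root_kids <- edge[children[[as.character(root)]], 2]
  best_cnt <- rep(-1L, length(var_cols))
  root_state <- rep(0L, length(var_cols))
  for (b in c(1L, 2L, 4L, 8L)) {
    cnt <- rep(0L, length(var_cols))
    for (k in root_kids) cnt <- cnt + (bitwAnd(bit[k, ], b) > 0L)
    better <- cnt > best_cnt
    root_state[better] <- b
    best_cnt[better] <- cnt[better]
  }
  state[root, ] <- root_state
  changes <- list()
  for (e in rev(seq_len(nrow(edge)))) { # preorder
    par <- edge[e, 1]; ch <- edge[e, 2]
    keep <- bitwAnd(state[par, ], bit[ch, ])
    state[ch, ] <- ifelse(keep > 0L, keep, lowest_bit(bit[ch, ]))
    chg <- which(state[ch, ] != state[par, ] & bit[ch, ] != 15L)
    if (length(chg) > 0)
      changes[[length(changes) + 1]] <-
        data.frame(edge = e, column = var_cols[chg], node_child = ch)
  }
  changes <- if (length(changes) > 0) do.call(rbind, changes) else
    data.frame(edge = integer(0), column = integer(0), node_child = integer(0))
  # branch labels: tip name for terminal edges, sorted clade for internal
  desc <- vector("list", nt + tr$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- tr$tip.label[i]
  for (node in unique(edge[, 1])) {
    kids <- edge[children[[as.character(node)]], 2]
    desc[[node]] <- sort(unlist(desc[kids]))
  }
  branch_label <- vapply(seq_len(nrow(edge)), function(e)
    paste(desc[[edge[e, 2]]], collapse = ","), character(1))
  list(changes = changes, tree = tr, branch_label = branch_label,
       score = nrow(changes), n_columns = L)
}

#' Nontrivial splits of a tree
#'
#' One bipartition per internal edge, canonicalized to the side containing
#' the lexicographically first taxon.
#'
#' @param tree a `phylo` tree (rooted trees are unrooted first)
#' @return data.frame with `split` (taxa of the canonical side, |-joined) and
#'   `size` of that side
#' @export
tree_splits <- function(tree) {
  tr <- tree
  if (ape::is.rooted(tr)) tr <- ape::unroot(tr)
  tr <- stats::reorder(tr, "postorder")
  nt <- length(tr$tip.label)
  edge <- tr$edge
  children <- split(seq_len(nrow(edge)), edge[, 1])
  desc <- vector("list", nt + tr$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- tr$tip.label[i]
  for (node in unique(edge[, 1]))
    desc[[node]] <- unlist(desc[edge[children[[as.character(node)]], 2]])
  first <- min(tr$tip.label)
  out <- character(0)
  root <- edge[nrow(edge), 1]
  for (e in seq_len(nrow(edge))) {
    ch <- edge[e, 2]
    if (ch <= nt) next                 # trivial
    side <- desc[[ch]]
    if (length(side) < 2 || length(side) > nt - 2) next
    if (!(first %in% side)) side <- setdiff(tr$tip.label, side)
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  out <- unique(out)
  data.frame(split = out,
             size = vapply(strsplit(out, "\\|"), length, integer(1)))
}
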