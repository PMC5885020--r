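#' Simulation configuration for synthetic phage genome samples
#'
#' Defines the ancestral genome layout and the group structure of a synthetic
#' sample of lytic phage genomes. Evolution is indel-free by default so that
#' positional homology is exact and no multiple-alignment step is needed
#' downstream; group-specific whole-gene deletions are the only source of
#' length variation.
#'
#' @param genome_length ancestral genome length in bp
#' @param n_genes number of protein-coding genes to place on the ancestor
#' @param gene_length_range length range (bp) genes are drawn from; lengths are
#'   rounded to multiples of 3 and include the start and stop codons
#' @param gc_content stationary GC fraction of the substitution model and of
#'   the ancestral sequence
#' @param groups list of [group_design()] objects
#' @param kappa HKY transition/transversion rate ratio used when evolving
#'   lineages
#' @param seed integer seed; a fixed seed gives byte-identical output
#' @return an object of class `sim_config`
#' @export
sim_config <- function(genome_length = 50000L, n_genes = 60L,
                       gene_length_range = c(300L, 3000L), gc_content = 0.5,
                       groups = list(), kappa = 2, seed = 1L) {
  cfg <- structure(list(genome_length = as.integer(genome_length),
                        n_genes = as.integer(n_genes),
                        gene_length_range = as.integer(gene_length_range),
                        gc_content = gc_content, groups = groups,
                        kappa = kappa, seed = as.integer(seed)),
                   class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Design of one phage group in a synthetic sample
#'
#' Divergence parameters are expected substitutions per site on an HKY clock
#' (realized Hamming divergence is slightly lower through multiple hits).
#' Members radiate from a group ancestor on a star topology whose branch
#' lengths get multiplicative jitter in \[0.75, 1.25\], so gene trees differ
#' only through recombination. Satellites are additional lineages at
#' intermediate divergence from the same group ancestor.
#'
#' @param name group label used in the truth log
#' @param n_members number of core group members
#' @param within_divergence expected pairwise substitutions/site among members
#' @param stem_divergence expected substitutions/site from the sample ancestor
#'   to the group ancestor
#' @param satellite_members number of satellite lineages
#' @param satellite_div_range range of expected substitutions/site between a
#'   satellite and the group members
#' @param recomb_rate expected intragroup gene-conversion events per lineage
#' @param tract_mean_len mean of the geometric tract length (bp)
#' @param intergroup_transfer_rate expected intergroup transfer events per
#'   lineage
#' @param intergroup_donor name of the donor group for intergroup transfers
#'   (default: any other group, uniformly)
#' @param intergroup_tract_mean mean tract length (bp) for intergroup events
#' @param n_gene_loss number of ancestral genes deleted in this group's
#'   ancestor (group-specific gene content)
#' @return an object of class `group_design`
#' @export
group_design <- function(name, n_members, within_divergence, stem_divergence,
                         satellite_members = 0L,
                         satellite_div_range = c(0.10, 0.14),
                         recomb_rate = 0, tract_mean_len = 2000L,
                         intergroup_transfer_rate = 0,
                         intergroup_donor = NULL,
                         intergroup_tract_mean = 10000L,
                         n_gene_loss = 0L) {
  stopifnot(n_members >= 1, within_divergence >= 0, stem_divergence >= 0,
            recomb_rate >= 0, intergroup_transfer_rate >= 0,
            tract_mean_len >= 1, satellite_members >= 0)
  structure(list(name = name, n_members = as.integer(n_members),
                 within_divergence = within_divergence,
                 stem_divergence = stem_divergence,
                 satellite_members = as.integer(satellite_members),
                 satellite_div_range = satellite_div_range,
                 recomb_rate = recomb_rate,
                 tract_mean_len = as.integer(tract_mean_len),
                 intergroup_transfer_rate = intergroup_transfer_rate,
                 intergroup_donor = intergroup_donor,
                 intergroup_tract_mean = as.integer(intergroup_tract_mean),
                 n_gene_loss = as.integer(n_gene_loss)),
            class = "group_design")
}

validate_sim_config <- function(cfg) {
  if (cfg$genome_length < 1) stop_phagani("genome_length must be positive")
  if (cfg$gc_content <= 0 || cfg$gc_content >= 1)
    stop_phagani("gc_content must be in (0, 1)")
  if (cfg$n_genes > 0) {
    min_genic <- cfg$n_genes * max(9L, 3L * floor(cfg$gene_length_range[1] / 3))
    if (min_genic > cfg$genome_length)
      stop_phagani("infeasible packing: genes cannot fit in genome_length")
  }
  for (g in cfg$groups) {
    if (!inherits(g, "group_design")) stop_phagani("groups must be group_design objects")
    if (g$satellite_members > 0 &&
        g$within_divergence >= g$satellite_div_range[1])
      stop_phagani("within_divergence must be below the satellite range (group ",
                   g$name, ")")
  }
  if (length(cfg$groups) >= 2) {
    stems <- vapply(cfg$groups, `[[`, numeric(1), "stem_divergence")
    sat_hi <- vapply(cfg$groups, function(g)
      if (g$satellite_members > 0) g$satellite_div_range[2] else 0, numeric(1))
    wd <- vapply(cfg$groups, `[[`, numeric(1), "within_divergence")
    min_between <- min(outer(stems, stems, "+")[upper.tri(diag(length(stems)))])
    if (max(c(sat_hi, wd)) >= min_between)
      stop_phagani("between-group divergence must exceed satellite and within-group divergence")
  }
  invisible(cfg)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_bases <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(DNA_BASES, n, replace = TRUE, prob = p)
}

random_codons <- function(n, gc) {
  # non-stop codons drawn base-wise at the target GC, resampling stops
  out <- character(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    cand <- apply(matrix(random_bases(3 * length(need), gc), nrow = 3), 2, paste, collapse = "")
    ok <- !(cand %in% STOP_CODONS)
    out[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  out
}

#' Generate the ancestral genome and its gene table
#'
#' Places non-overlapping genes on both strands with start/stop codons and
#' lengths divisible by 3; intergenic spacers are random sequence at the
#' configured GC. Coordinates are 0-based half-open.
#'
#' @param config a [sim_config()]
#' @return list with `sequence` (character scalar) and `genes` (data.frame
#'   with gene_id, start, end, strand, length)
#' @export
generate_ancestor <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    L <- config$genome_length
    ng <- config$n_genes
    if (ng == 0) {
      seq <- collapse_bases(random_bases(L, config$gc_content))
      return(list(sequence = seq,
                  genes = data.frame(gene_id = character(0), start = integer(0),
                                     end = integer(0), strand = character(0),
                                     length = integer(0))))
    }
    lo <- max(9L, 3L * floor(config$gene_length_range[1] / 3))
    hi <- 3L * floor(config$gene_length_range[2] / 3)
    choices <- seq(lo / 3, hi / 3)
    lens <- 3L * choices[sample.int(length(choices), ng, replace = TRUE)]
    # shrink uniformly if the draw does not fit
    while (sum(lens) > L) {
      if (all(lens <= lo)) stop_phagani("infeasible packing: genes cannot fit")
      lens <- pmax(lo, 3L * floor(lens * 0.9 / 3))
    }
    spacer_total <- L - sum(lens)
    # random composition of the intergenic length over ng + 1 spacers
    cuts <- sort(sample(0:spacer_total, ng, replace = TRUE))
    spacers <- diff(c(0L, cuts, spacer_total))
    strands <- sample(c("+", "-"), ng, replace = TRUE)
    pieces <- character(2 * ng + 1)
    genes <- data.frame(gene_id = sprintf("g%03d", seq_len(ng)),
                        start = integer(ng), end = integer(ng),
                        strand = strands, length = lens)
    pos <- 0L
    for (i in seq_len(ng)) {
      pieces[2 * i - 1] <- collapse_bases(random_bases(spacers[i], config$gc_content))
      pos <- pos + spacers[i]
      cds <- paste0("ATG",
                    paste(random_codons(lens[i] / 3 - 2, config$gc_content), collapse = ""),
                    sample(STOP_CODONS, 1))
      genes$start[i] <- pos
      genes$end[i] <- pos + lens[i]
      pieces[2 * i] <- if (strands[i] == "+") cds else revcomp_chr(cds)
      pos <- pos + lens[i]
    }
    pieces[2 * ng + 1] <- collapse_bases(random_bases(spacers[ng + 1], config$gc_content))
    list(sequence = paste(pieces, collapse = ""), genes = genes)
  })
}

#' HKY transition probability matrix
#'
#' Rate matrix with transition/transversion ratio `kappa` and stationary
#' frequencies `freqs` (A, C, G, T), scaled to one expected substitution per
#' site per unit time; returns `expm(Q t)` via eigendecomposition.
#'
#' @param t branch length in expected substitutions/site
#' @param kappa transition/transversion rate ratio
#' @param freqs stationary base frequencies (A, C, G, T)
#' @return 4x4 transition probability matrix
#' @export
hky_pmatrix <- function(t, kappa = 2, freqs = rep(0.25, 4)) {
  stopifnot(length(freqs) == 4, abs(sum(freqs) - 1) < 1e-8, t >= 0)
  Q <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  transitions <- rbind(c(1, 3), c(3, 1), c(2, 4), c(4, 2))  # A<->G, C<->T
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    ti <- any(transitions[, 1] == i & transitions[, 2] == j)
    Q[i, j] <- ifelse(ti, kappa, 1) * freqs[j]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q <- Q / mu
  eg <- eigen(Q)
  P <- Re(eg$vectors %*% diag(exp(eg$values * t)) %*% solve(eg$vectors))
  P[P < 0] <- 0
  P / rowSums(P)
}

# evolve an integer-encoded sequence for branch length t under HKY
mutate_hky <- function(v, t, kappa, freqs) {
  if (t <= 0) return(v)
  P <- hky_pmatrix(t, kappa, freqs)
  out <- v
  for (b in 1:4) {
    idx <- which(v == b)
    if (length(idx) > 0)
      out[idx] <- sample.int(4, length(idx), replace = TRUE, prob = P[b, ])
  }
  out
}

#' Substitute an exact fraction of sites
#'
#' Picks `round(d * length)` distinct positions and changes each to a
#' different base chosen uniformly, giving a pair at exactly the stated
#' Hamming divergence (no multiple hits).
#'
#' @param sequence character scalar over ACGT
#' @param d fraction of sites to substitute
#' @return character scalar
#' @export
mutate_fraction <- function(sequence, d) {
  v <- encode_dna(sequence)
  n <- round(d * length(v))
  if (n == 0) return(sequence)
  idx <- sample(length(v), n)
  shift <- sample.int(3, n, replace = TRUE)
  v[idx] <- ((v[idx] - 1 + shift) %% 4) + 1
  decode_dna(v)
}

#' Evolve a synthetic sample from an ancestor under the group designs
#'
#' Each group gets a group ancestor at its stem divergence from the sample
#' ancestor (with group-specific whole-gene deletions), members radiate on a
#' jittered star, satellites branch at intermediate divergence, and
#' recombination is applied afterwards as copy-paste of homologous donor
#' tracts in random event order. All events are logged; realized pairwise
#' divergence is recorded by direct site counting over shared homologous
#' positions.
#'
#' @param ancestor result of [generate_ancestor()]
#' @param designs list of [group_design()]s
#' @param seed integer seed
#' @param kappa HKY transition/transversion ratio
#' @param gc_content stationary GC used for the substitution model
#' @return list with `genomes` (named character vector), `genes` (gene table
#'   data.frame over all genomes), and `truth` (class `sim_truth`: group
#'   labels, realized divergence matrix, event log, gene-loss table)
#' @export
evolve_sample <- function(ancestor, designs, seed = 1L, kappa = 2,
                          gc_content = 0.5) {
  for (d in designs) if (!inherits(d, "group_design"))
    stop_phagani("designs must be group_design objects")
  freqs <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
             (1 - gc_content) / 2)
  anc <- encode_dna(ancestor$sequence)
  L <- length(anc)
  with_seed(seed, {
    genomes <- list()      # integer vectors
    anc_map <- list()      # ancestral position of each genome position
    labels <- character(0) # group label per genome (satellites get own label)
    member_group <- character(0)  # group a genome belongs to incl. satellites
    is_satellite <- logical(0)
    gene_loss <- data.frame(group = character(0), gene_id = character(0))
    kept_genes <- list()

    for (d in designs) {
      g_anc <- mutate_hky(anc, d$stem_divergence, kappa, freqs)
      keep <- rep(TRUE, L)
      kept <- ancestor$genes$gene_id
      if (d$n_gene_loss > 0) {
        if (d$n_gene_loss > nrow(ancestor$genes))
          stop_phagani("n_gene_loss exceeds gene count")
        drop_ids <- sample(ancestor$genes$gene_id, d$n_gene_loss)
        for (gid in drop_ids) {
          row <- ancestor$genes[ancestor$genes$gene_id == gid, ]
          keep[(row$start + 1):row$end] <- FALSE
        }
        kept <- setdiff(kept, drop_ids)
        gene_loss <- rbind(gene_loss, data.frame(group = d$name, gene_id = drop_ids))
      }
      map <- which(keep)
      g_anc_kept <- g_anc[keep]
      kept_genes[[d$name]] <- kept
      half <- d$within_divergence / 2
      for (m in seq_len(d$n_members)) {
        bl <- half * runif(1, 0.75, 1.25)
        id <- sprintf("%s_m%02d", d$name, m)
        genomes[[id]] <- mutate_hky(g_anc_kept, bl, kappa, freqs)
        anc_map[[id]] <- map
        labels <- c(labels, setNames(d$name, id))
        member_group <- c(member_group, setNames(d$name, id))
        is_satellite <- c(is_satellite, setNames(FALSE, id))
      }
      for (s in seq_len(d$satellite_members)) {
        dsat <- runif(1, d$satellite_div_range[1], d$satellite_div_range[2])
        bl <- max(0, dsat - half)
        id <- sprintf("%s_s%02d", d$name, s)
        genomes[[id]] <- mutate_hky(g_anc_kept, bl, kappa, freqs)
        anc_map[[id]] <- map
        labels <- c(labels, setNames(paste0(d$name, "_sat", s), id))
        member_group <- c(member_group, setNames(d$name, id))
        is_satellite <- c(is_satellite, setNames(TRUE, id))
      }
    }

    ids <- names(genomes)
    group_of <- member_group[ids]
    design_of <- setNames(lapply(ids, function(id) {
      designs[[which(vapply(designs, `[[`, character(1), "name") == group_of[id])]]
    }), ids)

    # draw events, then apply in random global order (donor state is current)
    events <- list()
    for (id in ids) {
      d <- design_of[[id]]
      if (is_satellite[id]) next
      peers <- ids[group_of == d$name & ids != id & !is_satellite[ids]]
      n_intra <- if (d$recomb_rate > 0 && length(peers) > 0) rpois(1, d$recomb_rate) else 0
      for (k in seq_len(n_intra)) {
        donor <- sample(peers, 1)
        len <- rgeom(1, 1 / d$tract_mean_len) + 1L
        gl <- length(genomes[[id]])
        start <- sample.int(gl, 1) - 1L
        end <- min(gl, start + len)
        events[[length(events) + 1]] <-
          list(recipient = id, donor = donor, start = start, end = end,
               type = "intragroup")
      }
      others <- vapply(designs, `[[`, character(1), "name")
      others <- setdiff(others, d$name)
      n_inter <- if (d$intergroup_transfer_rate > 0 && length(others) > 0)
        rpois(1, d$intergroup_transfer_rate) else 0
      for (k in seq_len(n_inter)) {
        dg <- d$intergroup_donor %||% sample(others, 1)
        donors <- ids[group_of == dg & !is_satellite[ids]]
        donor <- if (length(donors) == 1) donors else sample(donors, 1)
        len <- rgeom(1, 1 / d$intergroup_tract_mean) + 1L
        gl <- length(genomes[[id]])
        # pick a recipient tract whose ancestral image is fully held by donor
        for (try in 1:25) {
          start <- sample.int(max(1L, gl - len), 1) - 1L
          end <- min(gl, start + len)
          anc_pos <- anc_map[[id]][(start + 1):end]
          if (all(anc_pos %in% anc_map[[donor]])) break
        }
        events[[length(events) + 1]] <-
          list(recipient = id, donor = donor, start = start, end = end,
               type = "intergroup")
      }
    }
    if (length(events) > 0) {
      ord <- sample(length(events))
      for (e in events[ord]) {
        rec_pos <- (e$start + 1):e$end
        anc_pos <- anc_map[[e$recipient]][rec_pos]
        don_idx <- match(anc_pos, anc_map[[e$donor]])
        ok <- !is.na(don_idx)
        genomes[[e$recipient]][rec_pos[ok]] <- genomes[[e$donor]][don_idx[ok]]
      }
    }

    # realized divergence over shared homologous sites
    n <- length(ids)
    div <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      mi <- anc_map[[ids[i]]]; mj <- anc_map[[ids[j]]]
      idx <- match(mi, mj)
      ok <- !is.na(idx)
      a <- genomes[[ids[i]]][ok]; b <- genomes[[ids[j]]][idx[ok]]
      div[i, j] <- div[j, i] <- mean(a != b)
    }

    # per-genome gene tables (coordinates shifted by group deletions)
    gene_rows <- list()
    for (id in ids) {
      gids <- kept_genes[[group_of[id]]]
      sub <- ancestor$genes[ancestor$genes$gene_id %in% gids, , drop = FALSE]
      if (nrow(sub) > 0) {
        map <- anc_map[[id]]
        new_start <- match(sub$start + 1, map) - 1L
        gene_rows[[id]] <- data.frame(genome_id = id, gene_id = sub$gene_id,
                                      start = new_start,
                                      end = new_start + sub$length,
                                      strand = sub$strand)
      }
    }
    genes <- if (length(gene_rows) > 0) do.call(rbind, gene_rows) else
      data.frame(genome_id = character(0), gene_id = character(0),
                 start = integer(0), end = integer(0), strand = character(0))
    rownames(genes) <- NULL

    ev_df <- if (length(events) > 0)
      do.call(rbind, lapply(events, as.data.frame)) else
      data.frame(recipient = character(0), donor = character(0),
                 start = integer(0), end = integer(0), type = character(0))

    truth <- structure(list(group_label = labels,
                            member_group = member_group,
                            is_satellite = is_satellite,
                            divergence = div, events = ev_df,
                            gene_loss = gene_loss),
                       class = "sim_truth")
    list(genomes = vapply(genomes, decode_dna, character(1)),
         genes = genes, truth = truth)
  })
}

#' Simulate a complete sample from a configuration
#'
#' Convenience wrapper: [generate_ancestor()] then [evolve_sample()] with a
#' seed derived from the configuration seed.
#'
#' @param config a [sim_config()]
#' @return as [evolve_sample()], plus the `ancestor`
#' @export
simulate_sample <- function(config) {
  anc <- generate_ancestor(config)
  res <- evolve_sample(anc, config$groups, seed = derive_seed(config$seed, "simulate"),
                       kappa = config$kappa, gc_content = config$gc_content)
  res$ancestor <- anc
  res
}

#' Write a simulated sample to disk
#'
#' Writes one FASTA per genome plus a combined multi-FASTA, the gene table as
#' TSV, and the truth log as JSON. Files round-trip losslessly through
#' [read_genomes()] / [read_gene_table()].
#'
#' @param sim result of [evolve_sample()] or [simulate_sample()]
#' @param outdir output directory (created if missing)
#' @return invisibly, the paths written
#' @export
write_sim <- function(sim, outdir) {
  if (length(sim$genomes) == 0) stop_phagani("empty genome list")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set <- Biostrings::DNAStringSet(sim$genomes)
  combined <- file.path(outdir, "genomes.fasta")
  Biostrings::writeXStringSet(set, combined)
  singles <- vapply(names(sim$genomes), function(id) {
    p <- file.path(outdir, paste0(id, ".fasta"))
    Biostrings::writeXStringSet(set[id], p)
    p
  }, character(1))
  genes_path <- file.path(outdir, "genes.tsv")
  write.table(sim$genes, genes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth_path <- file.path(outdir, "truth.json")
  tr <- sim$truth
  jsonlite::write_json(list(group_label = as.list(tr$group_label),
                            member_group = as.list(tr$member_group),
                            is_satellite = as.list(tr$is_satellite),
                            divergence = tr$divergence,
                            taxa = rownames(tr$divergence),
                            events = tr$events, gene_loss = tr$gene_loss),
                       truth_path, digits = NA, auto_unbox = TRUE)
  invisible(c(combined, genes_path, truth_path, singles))
}

#' Read genomes from FASTA
#' @param path multi-FASTA file or directory of FASTA files
#' @return named character vector of sequences
#' @export
read_genomes <- function(path) {
  files <- if (dir.exists(path))
    list.files(path, pattern = "\\.(fa|fasta|fna)$", full.names = TRUE) else path
  if (length(files) == 0) stop_phagani("no FASTA files found at ", path)
  sets <- lapply(files, Biostrings::readDNAStringSet)
  set <- do.call(c, sets)
  out <- setNames(as.character(set), sub("\\s.*$", "", names(set)))
  if (anyDuplicated(names(out))) {
    # directory mode also contains the combined file; drop duplicates
    out <- out[!duplicated(names(out))]
  }
  out
}

#' Read a gene table TSV (genome_id, gene_id, start, end, strand; 0-based
#' half-open coordinates)
#' @param path TSV path
#' @return data.frame
#' @export
read_gene_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
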