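#' Default synthetic study design
#'
#' Three groups (8, 6, 5 members) with within-group divergence 4-5 %
#' (expected substitutions/site), two satellites at 10-14 %, deep stems so
#' between-group divergence exceeds 20 %, intragroup gene conversion in every
#' group, and a rare ~10 kb transfer from the distant group C into group A
#' (an Av-05-like event).
#'
#' @param genome_length,n_genes passed to [sim_config()]
#' @param seed integer seed
#' @return a [sim_config()]
#' @export
default_study_design <- function(genome_length = 50000L, n_genes = 60L,
                                 seed = 1L) {
  sim_config(
    genome_length = genome_length, n_genes = n_genes, seed = seed,
    groups = list(
      group_design("A", 8, within_divergence = 0.05, stem_divergence = 0.15,
                   satellite_members = 1, recomb_rate = 6,
                   tract_mean_len = 3000,
                   intergroup_transfer_rate = 0.15, intergroup_donor = "C",
                   intergroup_tract_mean = 10000),
      group_design("B", 6, within_divergence = 0.04, stem_divergence = 0.15,
                   satellite_members = 1, recomb_rate = 4,
                   tract_mean_len = 3000, n_gene_loss = 3),
      group_design("C", 5, within_divergence = 0.05, stem_divergence = 0.40,
                   recomb_rate = 4, tract_mean_len = 3000)))
}

#' Pipeline configuration
#'
#' @param mode "simulate" (default) or "fasta"
#' @param sim a [sim_config()] for simulate mode
#' @param fasta_path multi-FASTA file or directory (fasta mode)
#' @param gene_table_path gene table TSV (fasta mode)
#' @param outdir output directory
#' @param seed root seed; every stage derives its own seed from it
#' @param anib [anib_params()]
#' @param cutoff ANI group cutoff (percent)
#' @param satellite_lo lower bound of the satellite band (percent)
#' @param transfer_ani_min,transfer_cov_max transfer-candidate thresholds
#' @param min_group_size smallest group analysed for recombination/congruence
#' @param phi_w,phi_n_perm,phi_alpha PHI parameters
#' @param clonal_alpha,clonal_max_iter clonal-frame scan parameters
#' @param cadm_n_perm,mantel_n_perm permutation counts
#' @param min_split_freq consensus split threshold
#' @param progressive run the progressive congruence procedure
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(mode = c("simulate", "fasta"),
                            sim = default_study_design(),
                            fasta_path = NULL, gene_table_path = NULL,
                            outdir = tempfile("phagani_run_"), seed = 1L,
                            anib = anib_params(), cutoff = 92.0,
                            satellite_lo = 85.0,
                            transfer_ani_min = 92.0, transfer_cov_max = 0.2,
                            min_group_size = 4L,
                            phi_w = 100L, phi_n_perm = 499L, phi_alpha = 0.05,
                            clonal_alpha = 0.05, clonal_max_iter = 5L,
                            cadm_n_perm = 499L, mantel_n_perm = 199L,
                            min_split_freq = 0.1, progressive = TRUE) {
  mode <- match.arg(mode)
  if (mode == "fasta" && is.null(fasta_path))
    stop_phagani("fasta mode needs fasta_path")
  structure(as.list(environment()), class = "pipeline_config")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  basename(path)
}

#' Run the full analysis pipeline
#'
#' simulate-or-load, all-versus-all ANI with group/satellite/transfer
#' delineation, per-group pangenome and core genome, PHI per core gene,
#' clonal-frame scan on the concatenated single-copy core, CADM per group,
#' progressive congruence from the largest group outward, consensus splits,
#' and (in simulate mode) truth comparison. All outputs are plain text in
#' `config$outdir`; reruns with the same config and seed are byte-identical.
#'
#' @param config a [pipeline_config()]
#' @return object of class `pipeline_report`
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  note_file <- function(f) manifest <<- c(manifest, f)
  stage <- "input"
  report <- list(config = cfg)
  tryCatch({
    if (cfg$mode == "simulate") {
      sim <- cfg$sim
      sim$seed <- derive_seed(cfg$seed, "simulate")
      sample <- simulate_sample(sim)
      truth <- sample$truth
    } else {
      genomes <- read_genomes(cfg$fasta_path)
      if (length(genomes) < 2) stop_phagani("need >= 2 genomes")
      gt <- if (!is.null(cfg$gene_table_path))
        read_gene_table(cfg$gene_table_path) else NULL
      sample <- list(genomes = genomes, genes = gt, truth = NULL)
      truth <- NULL
    }
    report$genomes <- names(sample$genomes)

    cfg_json <- file.path(cfg$outdir, "config.json")
    jsonlite::write_json(resolve_config(cfg), cfg_json, auto_unbox = TRUE,
                         digits = NA, force = TRUE)
    note_file("config.json")

    stage <- "ani"
    am <- compute_all_anib(sample$genomes, cfg$anib)
    part <- delineate_groups(am, cfg$cutoff, cfg$anib$min_group_coverage)
    sats <- find_satellites(am, part, cfg$satellite_lo)
    transfers <- flag_transfer_candidates(am, cfg$transfer_ani_min,
                                          cfg$transfer_cov_max)
    rep_tabs <- ani_report(am)
    report$ani <- am; report$partition <- part
    report$satellites <- sats; report$transfers <- transfers
    report$ani_tables <- rep_tabs
    note_file(write_tsv(rep_tabs$pairs, file.path(cfg$outdir, "ani_pairs.tsv")))
    sym <- data.frame(genome = rownames(am$sym_ani), am$sym_ani,
                      check.names = FALSE)
    note_file(write_tsv(sym, file.path(cfg$outdir, "ani_matrix.tsv")))
    note_file(write_tsv(rep_tabs$histogram,
                        file.path(cfg$outdir, "ani_histogram.tsv")))
    jsonlite::write_json(list(groups = part$groups,
                              singletons = part$singletons,
                              cutoff = part$cutoff),
                         file.path(cfg$outdir, "partition.json"),
                         auto_unbox = TRUE, digits = NA)
    note_file("partition.json")
    note_file(write_tsv(sats, file.path(cfg$outdir, "satellites.tsv")))
    note_file(write_tsv(transfers,
                        file.path(cfg$outdir, "transfer_candidates.tsv")))

    stage <- "pangenome/recombination"
    group_rows <- list(); phi_all <- list(); cf_all <- list()
    group_detail <- list()
    if (!is.null(sample$genes) && nrow(sample$genes) > 0) {
      for (g in names(part$groups)) {
        members <- part$groups[[g]]
        sub <- sample$genes[sample$genes$genome_id %in% members, , drop = FALSE]
        genes <- extract_genes(sample$genomes, sub)
        fams <- cluster_families(genes)
        core <- core_genome(fams)
        row <- data.frame(group = g, n_phages = length(members),
                          all_genes = length(fams$families),
                          core_genes = length(core$core),
                          n_recomb_genes = NA_integer_,
                          clonal_frame_lo = NA_real_,
                          clonal_frame_hi = NA_real_,
                          cadm_w = NA_real_, cadm_p = NA_real_)
        detail <- list(members = members, fams = fams, core = core,
                       genes_df = genes)
        if (length(members) >= cfg$min_group_size &&
            length(core$single_copy_core) >= 2) {
          alns <- family_alignments(genes, fams, core$single_copy_core)
          phi <- phi_scan(alns, w = cfg$phi_w, n_perm = cfg$phi_n_perm,
                          seed = derive_seed(cfg$seed, "recomb"))
          phi$group <- g
          phi_all[[g]] <- phi
          row$n_recomb_genes <- sum(phi$p_value < cfg$phi_alpha, na.rm = TRUE)
          concat <- concat_alignment(alns)
          scan <- detect_recombinant_tracts(concat$aln,
                                            max_iter = cfg$clonal_max_iter,
                                            alpha = cfg$clonal_alpha)
          cf <- clonal_frame(scan)
          cf_all[[g]] <- data.frame(group = g, cf$branches)
          row$clonal_frame_lo <- cf$range[1]
          row$clonal_frame_hi <- cf$range[2]
          dms <- gene_distance_set(alns, taxa = members)
          cr <- cadm(dms, n_perm = cfg$cadm_n_perm, n_perm_mantel = 0,
                     seed = derive_seed(cfg$seed, "congruence"))
          row$cadm_w <- cr$W; row$cadm_p <- cr$p_value
          detail$scan <- scan; detail$concat <- concat; detail$alns <- alns
        }
        group_rows[[g]] <- row
        group_detail[[g]] <- detail
      }
    }
    report$group_report <- if (length(group_rows) > 0)
      do.call(rbind, group_rows) else NULL
    report$phi <- if (length(phi_all) > 0) do.call(rbind, phi_all) else NULL
    report$clonal <- if (length(cf_all) > 0) do.call(rbind, cf_all) else NULL
    report$group_detail <- group_detail
    if (!is.null(report$group_report))
      note_file(write_tsv(report$group_report,
                          file.path(cfg$outdir, "group_report.tsv")))
    if (!is.null(report$phi))
      note_file(write_tsv(report$phi, file.path(cfg$outdir, "phi.tsv")))
    if (!is.null(report$clonal))
      note_file(write_tsv(report$clonal,
                          file.path(cfg$outdir, "clonal_frame.tsv")))

    stage <- "congruence"
    if (cfg$progressive && length(part$groups) >= 2 &&
        !is.null(sample$genes) && nrow(sample$genes) > 0) {
      sizes <- vapply(part$groups, length, integer(1))
      base_g <- names(part$groups)[which.max(sizes)]
      base <- part$groups[[base_g]]
      additions <- list()
      base_sats <- sats$genome[sats$group == base_g]
      if (length(base_sats) > 0) additions <- c(additions, list(base_sats))
      other <- setdiff(names(part$groups), base_g)
      next_ani <- vapply(other, function(og)
        suppressWarnings(max(am$sym_ani[part$groups[[og]], base], na.rm = TRUE)),
        numeric(1))
      next_g <- other[which.max(next_ani)]
      additions <- c(additions, list(part$groups[[next_g]]))
      prog <- progressive_cadm(sample$genomes, sample$genes, base, additions,
                               n_perm = cfg$cadm_n_perm,
                               n_perm_mantel = cfg$mantel_n_perm,
                               seed = derive_seed(cfg$seed, "congruence"))
      report$progressive <- prog
      note_file(write_tsv(prog$steps,
                          file.path(cfg$outdir, "progressive_cadm.tsv")))
      # consensus splits over the final progressive sample
      ids <- sort(c(base, unlist(additions)))
      sub <- sample$genes[sample$genes$genome_id %in% ids, , drop = FALSE]
      genes <- extract_genes(sample$genomes, sub)
      fams <- cluster_families(genes)
      scc <- core_genome(fams)$single_copy_core
      if (length(scc) >= 2) {
        alns <- family_alignments(genes, fams, scc)
        dms <- gene_distance_set(alns, taxa = ids)
        trees <- lapply(dms$matrices, nj_tree)
        ss <- consensus_splits(trees, cfg$min_split_freq)
        report$splits <- ss
        write_splits_nexus(ss, file.path(cfg$outdir, "consensus_splits.nex"))
        note_file("consensus_splits.nex")
      }
    }

    stage <- "truth comparison"
    if (!is.null(truth)) {
      report$truth <- truth
      metrics <- compare_to_truth(report, truth)
      report$truth_metrics <- metrics
      note_file(write_tsv(metrics$summary,
                          file.path(cfg$outdir, "truth_metrics.tsv")))
      note_file(write_tsv(metrics$ani_error,
                          file.path(cfg$outdir, "ani_error.tsv")))
    }
    writeLines(c("status: complete", sort(manifest)),
               file.path(cfg$outdir, "MANIFEST"))
    structure(report, class = "pipeline_report")
  }, error = function(e) {
    writeLines(c(paste0("status: incomplete (failed at stage: ", stage, ")"),
                 sort(manifest)), file.path(cfg$outdir, "MANIFEST"))
    stop_phagani("pipeline failed at stage '", stage, "': ",
                 conditionMessage(e))
  })
}

resolve_config <- function(cfg) {
  out <- cfg
  out$sim <- if (cfg$mode == "simulate") unclass(cfg$sim) else NULL
  if (!is.null(out$sim))
    out$sim$groups <- lapply(out$sim$groups, unclass)
  class(out) <- NULL
  out
}

#' Concatenate gene alignments with a boundary map
#'
#' @param alns named list of equal-taxa alignments
#' @return list with `aln` (named character vector) and `boundaries`
#'   (data.frame gene, start, end; 0-based half-open concat columns)
#' @export
concat_alignment <- function(alns) {
  taxa <- names(alns[[1]])
  for (a in alns) if (!setequal(names(a), taxa))
    stop_phagani("alignments must share taxa")
  pieces <- vapply(alns, function(a) a[taxa], character(length(taxa)))
  aln <- setNames(apply(pieces, 1, paste, collapse = ""), taxa)
  lens <- vapply(alns, function(a) nchar(a[[1]]), integer(1))
  ends <- cumsum(lens)
  list(aln = aln,
       boundaries = data.frame(gene = names(alns),
                               start = c(0L, head(ends, -1)), end = ends))
}

#' Compare a pipeline report against the simulation truth
#'
#' Computes the adjusted Rand index between the inferred partition and the
#' true labels (satellites count as their own singleton labels), a per-pair
#' ANI error table (observed symmetrized ANI versus 100 (1 - realized
#' divergence)), and recombinant-tract recovery precision/recall over the
#' analysed groups' core alignments (NA when nothing was predicted or no
#' event was simulated).
#'
#' @param report a `pipeline_report`
#' @param truth a `sim_truth`
#' @return list with `summary` (metric, value) and `ani_error` data.frame
#' @export
compare_to_truth <- function(report, truth) {
  labs <- partition_labels(report$partition)
  ids <- names(truth$group_label)
  ari <- mclust::adjustedRandIndex(truth$group_label[ids], labs[ids])
  n <- length(ids)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  div <- truth$divergence[ids, ids]
  obs <- report$ani$sym_ani[ids, ids]
  ani_error <- data.frame(a = ids[ut[, 1]], b = ids[ut[, 2]],
                          divergence = div[ut],
                          expected_ani = 100 * (1 - div[ut]),
                          observed_ani = obs[ut])
  ani_error$error <- ani_error$observed_ani - ani_error$expected_ani
  tp <- tract_recovery(report, truth)
  summary <- data.frame(
    metric = c("ari", "n_groups", "n_singletons",
               "tract_precision", "tract_recall",
               "mean_abs_ani_error_defined"),
    value = c(ari, length(report$partition$groups),
              length(report$partition$singletons),
              tp$precision, tp$recall,
              mean(abs(ani_error$error[ani_error$divergence < 1/3]),
                   na.rm = TRUE)))
  list(summary = summary, ani_error = ani_error)
}

# map true recombination events into the analysed groups' concatenated core
# alignments and score detected tracts on terminal branches against them
tract_recovery <- function(report, truth) {
  det_cols <- list(); true_cols <- list()
  for (g in names(report$group_detail)) {
    detail <- report$group_detail[[g]]
    if (is.null(detail$scan)) next
    for (rec in detail$members) {
      ev <- truth$events[truth$events$recipient == rec &
                           truth$events$type == "intragroup", , drop = FALSE]
      tr <- detail$scan$tracts
      tr <- tr[tr$branch == rec, , drop = FALSE]
      dk <- integer(0)
      if (nrow(tr) > 0)
        dk <- unique(unlist(mapply(function(s, e) seq(s + 1, e),
                                   tr$start, tr$end, SIMPLIFY = FALSE)))
      tk <- integer(0)
      if (nrow(ev) > 0) {
        gmap <- gene_concat_map(detail, rec)
        for (r in seq_len(nrow(ev)))
          tk <- c(tk, map_interval_to_concat(gmap, ev$start[r], ev$end[r]))
        tk <- unique(tk)
      }
      det_cols[[paste(g, rec)]] <- dk
      true_cols[[paste(g, rec)]] <- tk
    }
  }
  dn <- length(unlist(det_cols)); tn <- length(unlist(true_cols))
  if (dn == 0 && tn == 0) return(list(precision = NA_real_, recall = NA_real_))
  inter <- sum(vapply(names(det_cols), function(k)
    length(intersect(det_cols[[k]], true_cols[[k]])), integer(1)))
  list(precision = if (dn > 0) inter / dn else NA_real_,
       recall = if (tn > 0) inter / tn else NA_real_)
}

# per-recipient map: concat blocks -> this recipient's member gene of each
# single-copy-core family (gene coordinates come from the group gene table)
gene_concat_map <- function(detail, rec) {
  bounds <- detail$concat$boundaries
  fams <- detail$fams
  out <- list()
  for (i in seq_len(nrow(bounds))) {
    fam <- fams$families[[bounds$gene[i]]]
    row <- fam[fam$genome_id == rec, , drop = FALSE]
    if (nrow(row) != 1) next
    out[[length(out) + 1]] <- list(concat_start = bounds$start[i],
                                   concat_end = bounds$end[i],
                                   gene_id = row$gene_id)
  }
  list(segments = out, rec = rec, genes = detail$genes_df)
}

map_interval_to_concat <- function(gmap, ev_start, ev_end) {
  cols <- integer(0)
  genes <- gmap$genes
  for (seg in gmap$segments) {
    gr <- genes[genes$genome_id == gmap$rec & genes$gene_id == seg$gene_id, ,
                drop = FALSE]
    if (nrow(gr) != 1) next
    lo <- max(ev_start, gr$start); hi <- min(ev_end, gr$end)
    if (hi <= lo) next
    if (gr$strand == "+") {
      off <- lo - gr$start
      cols <- c(cols, seg$concat_start + off + seq_len(hi - lo))
    } else {
      off <- gr$end - hi
      cols <- c(cols, seg$concat_start + off + seq_len(hi - lo))
    }
  }
  cols
}
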