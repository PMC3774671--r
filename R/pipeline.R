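## Config-driven end-to-end orchestration: simulate (or read) -> QC ->
## LD prune -> admixture -> assignment -> F_ST / inbreeding -> segments ->
## PCA / tree -> concordance -> LD decay, with a manifest and fixed seeds.

#' Build a pipeline run configuration
#'
#' All thresholds default to the study parameterisation (QC 0.97/0.98/
#' MAF 0.05/HWE 1e-3; pruning 50/5/0.1; ROH 500 kb/25 SNP/1 het/5 missing/
#' 100 kb; 553 jackknife blocks; Mantel 9999 permutations; decay 5 samples
#' x 50 reps, 1 kb bins). The simulation block defaults to the
#' demonstration cohort of \code{\link{simulate_cohort}}.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed; every stage derives its own seed from it.
#' @param stages Character vector of stages to run, any of "simulate",
#'   "qc", "prune", "admix", "fst", "inbreeding", "roh", "ibd", "pca",
#'   "tree", "mantel", "decay".
#' @param sim Named list overriding \code{simulate_cohort} arguments.
#' @param ped_path,map_path Input PLINK text files (used when "simulate" is
#'   not among the stages).
#' @param K Cluster count for admixture (default 3).
#' @param n_runs Replicate EM runs (default 4).
#' @param prune Named list(window, step, r2_max).
#' @param n_blocks Jackknife blocks for F_ST standard errors.
#' @param tree_reps,tree_n_per_pop Consensus-tree resampling settings.
#' @param mantel_n_perm Mantel permutations.
#' @param decay Named list(max_bp, bin_bp, n_draw, reps).
#' @return A \code{run_config} list.
#' @export
run_config <- function(out_dir = tempfile("popstructr_run_"),
                       seed = 1,
                       stages = c("simulate", "qc", "prune", "admix", "fst",
                                  "inbreeding", "roh", "ibd", "pca", "tree",
                                  "mantel", "decay"),
                       sim = list(),
                       ped_path = NULL, map_path = NULL,
                       K = 3, n_runs = 4,
                       prune = list(window = 50, step = 5, r2_max = 0.1),
                       n_blocks = 553,
                       tree_reps = 200, tree_n_per_pop = 5,
                       mantel_n_perm = 9999,
                       decay = list(max_bp = 1e6, bin_bp = 1000, n_draw = 5,
                                    reps = 50)) {
  structure(list(out_dir = out_dir, seed = seed, stages = stages, sim = sim,
                 ped_path = ped_path, map_path = map_path, K = K,
                 n_runs = n_runs, prune = prune, n_blocks = n_blocks,
                 tree_reps = tree_reps, tree_n_per_pop = tree_n_per_pop,
                 mantel_n_perm = mantel_n_perm, decay = decay),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order, writes every stage's outputs as
#' TSV/Newick text files under \code{config$out_dir}, and records a
#' manifest (stage timings, row/marker counts, output files with MD5
#' hashes, seeds). Re-running with the same config reproduces identical
#' outputs.
#'
#' @param config A \code{\link{run_config}}.
#' @return Invisibly, list(results, manifest).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  res <- list()
  manifest <- list(seed = config$seed, stages = stages, files = character(0),
                   counts = list(), timings = numeric(0))
  tick <- function(stage, t0) {
    manifest$timings[stage] <<- round(as.numeric(Sys.time()) - t0, 2)
    message(sprintf("[%s] done in %.1fs", stage, manifest$timings[stage]))
  }
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write_tsv(df, path)
    manifest$files <<- c(manifest$files, path)
    path
  }

  g <- NULL; map <- NULL; truth <- NULL; cohort <- NULL
  if ("simulate" %in% stages) {
    t0 <- as.numeric(Sys.time())
    sim_args <- utils::modifyList(list(seed = derive_seed(config$seed, 10)),
                                  config$sim)
    cohort <- do.call(simulate_cohort, sim_args)
    g <- cohort$genotypes; map <- cohort$map; truth <- cohort$truth
    write_plink_text(g, map, file.path(config$out_dir, "cohort.ped"),
                     file.path(config$out_dir, "cohort.map"))
    write_truth(cohort, file.path(config$out_dir, "truth.tsv"),
                file.path(config$out_dir, "planted_segments.tsv"))
    manifest$files <- c(manifest$files,
                        file.path(config$out_dir,
                                  c("cohort.ped", "cohort.map", "truth.tsv",
                                    "planted_segments.tsv")))
    manifest$counts$simulated <- dim(g)
    tick("simulate", t0)
  } else if (!is.null(config$ped_path)) {
    inp <- read_plink_text(config$ped_path, config$map_path)
    g <- inp$genotypes; map <- inp$map
    manifest$counts$input <- dim(g)
  } else if (length(stages)) {
    stop("no input: enable the simulate stage or give ped/map paths")
  }

  if ("qc" %in% stages) {
    t0 <- as.numeric(Sys.time())
    qc <- qc_filter(g, map, autosomes = unique(map$chrom))
    g <- qc$genotypes; map <- qc$map
    emit(qc$report, "qc_report.tsv")
    manifest$counts$post_qc <- dim(g)
    res$qc <- qc$report
    tick("qc", t0)
  }

  if ("prune" %in% stages) {
    t0 <- as.numeric(Sys.time())
    kept <- ld_prune(g, map, window = config$prune$window,
                     step = config$prune$step, r2_max = config$prune$r2_max)
    pruned <- g[, kept, drop = FALSE]
    map_pruned <- map[map$marker %in% kept, , drop = FALSE]
    writeLines(kept, file.path(config$out_dir, "pruned_markers.txt"))
    manifest$files <- c(manifest$files,
                        file.path(config$out_dir, "pruned_markers.txt"))
    manifest$counts$pruned <- length(kept)
    res$pruned_ids <- kept
    tick("prune", t0)
  } else {
    pruned <- g; map_pruned <- map
  }

  groups <- NULL
  if ("admix" %in% stages) {
    t0 <- as.numeric(Sys.time())
    fits <- lapply(seq_len(config$n_runs), function(r)
      admix_fit(pruned, config$K, seed = derive_seed(config$seed, 20 + r)))
    al <- align_runs(fits)
    cons <- if (config$n_runs >= 2)
      run_consistency(al$fits, n_perm = 999,
                      seed = derive_seed(config$seed, 30)) else NULL
    Qbar <- Reduce(`+`, lapply(al$fits, `[[`, "Q")) / length(al$fits)
    assign <- assign_majority(Qbar)
    groups <- stats::setNames(assign$group, assign$sample_id)
    emit(cbind(data.frame(sample_id = rownames(Qbar)), as.data.frame(Qbar),
               data.frame(assigned_group = assign$group, tie = assign$tie)),
         "admixture_q.tsv")
    if (!is.null(cons)) emit(cons, "run_consistency.tsv")
    res$admix <- list(fits = al$fits, Q = Qbar, assignment = assign,
                      consistency = cons)
    manifest$counts$groups <- table(assign$group)
    tick("admix", t0)
  } else if (!is.null(truth)) {
    groups <- stats::setNames(truth$group, rownames(g))
  }

  by_group <- NULL
  if (!is.null(groups)) {
    gl <- split(names(groups), groups)
    by_group <- lapply(gl, function(ids) g[ids, , drop = FALSE])
  }

  if ("fst" %in% stages && length(by_group) >= 2) {
    t0 <- as.numeric(Sys.time())
    nms <- names(by_group)
    rows <- list(); k <- 1
    for (i in seq_len(length(nms) - 1)) {
      for (j in seq(i + 1, length(nms))) {
        fr <- fst_pair(by_group[[i]], by_group[[j]], inbreed_adjust = TRUE,
                       n_blocks = config$n_blocks)
        rows[[k]] <- data.frame(group1 = nms[i], group2 = nms[j],
                                fst = fr$estimate, se = fr$se)
        k <- k + 1
      }
    }
    res$fst <- do.call(rbind, rows)
    emit(res$fst, "fst_pairwise.tsv")
    tick("fst", t0)
  }

  if ("inbreeding" %in% stages) {
    t0 <- as.numeric(Sys.time())
    f <- inbreeding_f(g)
    res$inbreeding <- f
    emit(data.frame(sample_id = names(f), F = f), "inbreeding.tsv")
    if (!is.null(groups)) {
      fb <- split(f[names(groups)], groups)
      tab <- bin_f_table(fb)
      emit(as.data.frame(cbind(bin = rownames(tab$counts), tab$counts)),
           "inbreeding_bins.tsv")
      res$f_table <- tab
    }
    tick("inbreeding", t0)
  }

  if ("roh" %in% stages) {
    t0 <- as.numeric(Sys.time())
    rs <- roh_scan(g, map)
    res$roh <- rs
    emit(rs, "roh_segments.tsv")
    manifest$counts$roh <- nrow(rs)
    tick("roh", t0)
  }

  if ("ibd" %in% stages && !is.null(truth)) {
    t0 <- as.numeric(Sys.time())
    ## QC may have dropped markers; restrict the phased truth to the map
    ib <- ibd_scan_all(truth$hap1[, map$marker, drop = FALSE],
                       truth$hap2[, map$marker, drop = FALSE], map)
    res$ibd <- ib
    emit(ib, "ibd_segments.tsv")
    genome_cm <- sum(tapply(map$cM, map$chrom, function(x) max(x) - min(x)))
    res$ibd_summary <- summarize_segments(ib, genome_cm,
                                          cohort_ids = rownames(g))
    if (nrow(ib) >= 10 && mean(ib$cm_length) > 1)
      res$generations <- fit_generations(ib$cm_length, min_cm = 1)
    manifest$counts$ibd <- nrow(ib)
    tick("ibd", t0)
  }

  if ("pca" %in% stages) {
    t0 <- as.numeric(Sys.time())
    pc <- pca_genotypes(pruned)
    res$pca <- pc
    emit(cbind(data.frame(sample_id = rownames(pc$coords)),
               as.data.frame(pc$coords)), "pca_coords.tsv")
    tick("pca", t0)
  }

  if ("tree" %in% stages && length(by_group) >= 3 &&
      all(vapply(by_group, nrow, 0) >= config$tree_n_per_pop)) {
    t0 <- as.numeric(Sys.time())
    ct <- fst_bootstrap_consensus(by_group, n_per_pop = config$tree_n_per_pop,
                                  reps = config$tree_reps,
                                  seed = derive_seed(config$seed, 40))
    res$tree <- ct
    writeLines(ct$newick, file.path(config$out_dir, "consensus_tree.nwk"))
    manifest$files <- c(manifest$files,
                        file.path(config$out_dir, "consensus_tree.nwk"))
    tick("tree", t0)
  }

  if ("mantel" %in% stages && !is.null(groups) && !is.null(truth) &&
      !is.null(truth$surname_origin)) {
    t0 <- as.numeric(Sys.time())
    keep <- !is.na(truth$surname_origin)
    d1 <- labels_to_distance(unname(groups[rownames(g)[keep]]))
    d2 <- labels_to_distance(truth$surname_origin[keep])
    mt <- mantel_test(d1, d2, n_perm = config$mantel_n_perm,
                      seed = derive_seed(config$seed, 50))
    ct <- contingency(unname(groups[rownames(g)[keep]]),
                      truth$surname_origin[keep])
    res$mantel <- mt
    res$contingency <- ct
    emit(data.frame(r = mt$r, p = mt$p, n_perm = mt$n_perm), "mantel.tsv")
    emit(as.data.frame(cbind(group = rownames(ct$counts), ct$counts)),
         "contingency.tsv")
    tick("mantel", t0)
  }

  if ("decay" %in% stages) {
    t0 <- as.numeric(Sys.time())
    dc <- ld_decay(g, map, max_bp = config$decay$max_bp,
                   bin_bp = config$decay$bin_bp,
                   n_draw = config$decay$n_draw, reps = config$decay$reps,
                   seed = derive_seed(config$seed, 60))
    res$decay <- dc
    emit(dc, "ld_decay.tsv")
    tick("decay", t0)
  }

  manifest$hashes <- tryCatch(tools::md5sum(manifest$files),
                              error = function(e) NULL)
  mf <- file.path(config$out_dir, "manifest.txt")
  writeLines(c(paste("seed:", config$seed),
               paste("stages:", paste(stages, collapse = ",")),
               paste("counts:", paste(names(manifest$counts), collapse = ",")),
               if (!is.null(manifest$hashes))
                 paste(basename(names(manifest$hashes)), manifest$hashes)),
             mf)
  invisible(list(results = res, manifest = manifest))
}
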