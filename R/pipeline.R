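#' Derive a per-stage seed from the global seed
#'
#' Stable hash of the stage name mixed with the global seed, so toggling one
#' stage does not shift another stage's random stream.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

default_thresholds <- function() {
  list(cutoff = 0.25, m = NULL, purity = 0.8, min_sites = 5, min_run = 5,
       tau = 0.2, window = 10000, mu = 2.0e-9, assign_threshold = 2 / 3,
       assign_eps = 0.01, min_coverage_fraction = 0.92)
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates simulate (or load) -> allele frequencies and coverage filter
#' -> association scan -> supergene genotyping -> diversity/divergence
#' statistics -> population assignment, writing per-stage TSV/newick/BED
#' artifacts plus a JSON manifest (seed, thresholds, region arithmetic,
#' per-stage row counts) to the output directory. An existing non-empty
#' output directory is moved aside (`<dir>.bak.N`), never overwritten.
#' Rerunning with an identical config and seed reproduces identical tabular
#' outputs.
#'
#' @param config a list, or path to a YAML file, with elements:
#'   `out_dir`; `seed`; exactly one of `simulation` (arguments for
#'   [sim_config()]) or `input` (`vcf`, `popmap`); optional `stages` (named
#'   logical toggles: `simulate`, `freqs`, `scan`, `supergene`, `divstats`,
#'   `assign`); optional `groups` (`group_a`, `group_b` population vectors for
#'   the scan contrast); optional `regions` (named `"chrom:start-end"`
#'   strings); optional `supergene` (`region`, `pure_n`, `pure_s`); optional
#'   `thresholds` overriding the defaults.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config needs out_dir")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  has_sim <- !is.null(config$simulation)
  has_input <- !is.null(config$input)
  if (has_sim == has_input)
    stop("config must contain exactly one of 'simulation' or 'input'")
  stages <- utils::modifyList(
    list(simulate = has_sim, freqs = TRUE, scan = TRUE, supergene = TRUE,
         divstats = TRUE, assign = TRUE),
    if (is.null(config$stages)) list() else config$stages)
  th <- utils::modifyList(default_thresholds(),
                          if (is.null(config$thresholds)) list()
                          else config$thresholds)
  out_dir <- config$out_dir
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0) {
    i <- 1
    while (dir.exists(paste0(out_dir, ".bak.", i))) i <- i + 1
    file.rename(out_dir, paste0(out_dir, ".bak.", i))
    message("existing output moved to ", paste0(out_dir, ".bak.", i))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  opath <- function(...) file.path(out_dir, ...)

  regions <- lapply(if (is.null(config$regions)) list() else config$regions,
                    parse_region)
  manifest <- list(
    seed = seed, stages = stages, thresholds = th,
    package_version = as.character(utils::packageVersion("ecoscan")),
    regions = lapply(names(regions), function(nm) {
      r <- regions[[nm]]
      list(name = nm, chrom = r$chrom, start_bp = r$start_bp,
           end_bp = r$end_bp, span_mb = region_span_mb(r),
           length_bp = r$end_bp - r$start_bp + 1)
    }),
    rows = list())
  names(manifest$regions) <- names(regions)
  fail <- function(stage, e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)

  gm <- NULL; truth <- NULL
  if (stages$simulate) {
    tryCatch({
      sim_args <- config$simulation
      sim_args$seed <- stage_seed(seed, "simulate")
      if (!is.null(sim_args$inversions))
        sim_args$inversions <- lapply(sim_args$inversions, as.list)
      cfg <- do.call(sim_config, sim_args)
      sim <- simulate_dataset(cfg)
      gm <- sim$geno; truth <- sim$truth
      write_vcf(gm, opath("genotypes.vcf"))
      write_popmap(gm$samples, opath("popmap.tsv"))
      write_truth(truth, opath("truth"))
      manifest$rows$simulate <- list(individuals = nrow(gm$genotypes),
                                      sites = ncol(gm$genotypes))
    }, error = function(e) fail("simulate", e))
  } else if (has_input) {
    tryCatch({
      gm <- read_vcf(config$input$vcf, config$input$popmap)
      manifest$rows$load <- list(individuals = nrow(gm$genotypes),
                                  sites = ncol(gm$genotypes))
    }, error = function(e) fail("load", e))
  }

  pf <- NULL
  if (stages$freqs) {
    tryCatch({
      pf <- pop_allele_freqs(gm)
      df <- data.frame(population = rep(rownames(pf$freq),
                                        each = ncol(pf$freq)),
                       chrom = rep(pf$sites$chrom, nrow(pf$freq)),
                       pos = rep(pf$sites$pos, nrow(pf$freq)),
                       freq = as.vector(t(pf$freq)),
                       observed_chroms = as.vector(t(pf$chroms)))
      utils::write.table(df, opath("allele_freqs.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      manifest$rows$freqs <- list(rows = nrow(df))
    }, error = function(e) fail("freqs", e))
  }

  ga <- config$groups$group_a; gb <- config$groups$group_b
  if (is.null(ga) || is.null(gb)) {
    pops <- unique(gm$samples$population)
    ga <- pops[1]; gb <- pops[length(pops)]
  }

  if (stages$scan) {
    tryCatch({
      scan <- association_scan(gm, ga, gb, m = th$m)
      # coverage filter applied per contrast, denominator from group sizes
      n_tot <- 2 * sum(gm$samples$population %in% c(ga, gb))
      obs <- colSums(pf$chroms[c(ga, gb), , drop = FALSE])
      keep <- site_coverage_filter(obs, n_tot,
                                   min_fraction = th$min_coverage_fraction)
      pa <- pool_groups(pf, ga); pb <- pool_groups(pf, gb)
      daf <- data.frame(chrom = pf$sites$chrom, pos = pf$sites$pos,
                        dAF = delta_af(pa$freq, pb$freq))[keep, ]
      daf <- daf[!is.na(daf$dAF), ]
      utils::write.table(scan, opath("scan.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      utils::write.table(daf, opath("delta_af.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      for (nm in names(regions)) {
        hm <- suppressWarnings(
          heatmap_matrix(pf, regions[[nm]], baseline = gb, cutoff = th$cutoff))
        write_matrix_tsv(hm, opath(paste0("heatmap_", nm, ".tsv")))
      }
      manifest$rows$scan <- list(sites_tested = sum(!scan$monomorphic),
                                  sites_retained = sum(keep),
                                  coverage_threshold =
                                    attr(keep, "min_observed"),
                                  coverage_total = attr(keep, "total"),
                                  coverage_fraction_pct =
                                    attr(keep, "fraction_pct"))
    }, error = function(e) fail("scan", e))
  }

  if (stages$supergene && !is.null(config$supergene)) {
    tryCatch({
      sg <- config$supergene
      r <- parse_region(sg$region)
      ref <- build_consensus(pf, sg$pure_n, sg$pure_s, r, purity = th$purity)
      utils::write.table(as.data.frame(ref), opath("haplotype_panel.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      calls <- call_inversion(score_genotypes(gm, ref),
                              min_sites = th$min_sites)
      utils::write.table(calls, opath("inversion_calls.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      segs_all <- list()
      for (popn in rownames(pf$freq)) {
        cls <- classify_population_sites(pf$freq[popn, ], ref, tau = th$tau)
        bg <- if (cls$s_frequency >= 0.5) "S" else "N"
        segs <- detect_recombinant_segments(cls$sites, bg,
                                            min_run = th$min_run)
        if (nrow(segs) > 0) segs_all[[popn]] <- cbind(population = popn, segs)
      }
      segs_df <- if (length(segs_all)) do.call(rbind, segs_all) else
        data.frame()
      if (nrow(segs_df) > 0)
        write_segments_bed(segs_df, r$chrom, opath("recombinant_segments.bed"))
      if (nrow(pf$freq) >= 3) {
        tr <- nj_tree_region(pf, r)
        ape::write.tree(tr, opath("nj_tree_region.nwk"))
      }
      manifest$rows$supergene <- list(
        diagnostic_sites = sum(ref$diagnostic),
        calls = nrow(calls), segments = nrow(segs_df))
    }, error = function(e) fail("supergene", e))
  }

  if (stages$divstats) {
    tryCatch({
      pops <- rownames(pf$freq)
      div <- do.call(rbind, lapply(pops, function(pn)
        cbind(population = pn,
              windowed_diversity(pf, pn, window = th$window))))
      utils::write.table(div, opath("diversity_windows.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      pairs <- utils::combn(pops, 2, simplify = FALSE)
      fst_rows <- lapply(pairs, function(pr) {
        wf <- windowed_fst(pf, pr[1], pr[2], window = th$window)
        list(pair = data.frame(pop1 = pr[1], pop2 = pr[2],
                               fst = wf$genome$fst,
                               n_loci = wf$genome$n_loci),
             windows = cbind(pop1 = pr[1], pop2 = pr[2], wf$windows))
      })
      genome_fst <- do.call(rbind, lapply(fst_rows, `[[`, "pair"))
      win_fst <- do.call(rbind, lapply(fst_rows, `[[`, "windows"))
      utils::write.table(genome_fst, opath("fst_genome.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(win_fst, opath("fst_windows.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      theta_tab <- do.call(rbind, lapply(pops, function(pn) {
        dv <- div[div$population == pn, ]
        S <- sum(dv$S)
        n_med <- stats::median(dv$n_med, na.rm = TRUE)
        L <- th$window * nrow(dv)
        tw <- if (S > 0 && is.finite(n_med)) watterson_theta(S, n_med, L) else 0
        data.frame(population = pn, S = S, theta_w = tw,
                   pi = sum(dv$pi * th$window) / L,
                   N_e = effective_population_size(tw, th$mu))
      }))
      utils::write.table(theta_tab, opath("diversity_genome.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      if (length(pops) >= 2) {
        dmat <- matrix(0, length(pops), length(pops),
                       dimnames = list(pops, pops))
        for (i in seq_len(nrow(genome_fst))) {
          dmat[genome_fst$pop1[i], genome_fst$pop2[i]] <- genome_fst$fst[i]
          dmat[genome_fst$pop2[i], genome_fst$pop1[i]] <- genome_fst$fst[i]
        }
        dmat[dmat < 0] <- 0
        ape::write.tree(upgma_tree(dmat), opath("upgma_tree.nwk"))
      }
      manifest$rows$divstats <- list(windows = nrow(div),
                                      pairs = nrow(genome_fst))
    }, error = function(e) fail("divstats", e))
  }

  if (stages$assign) {
    tryCatch({
      clusters <- stats::setNames(rownames(pf$freq), rownames(pf$freq))
      ll <- genotype_loglik(gm$genotypes, pf$freq, eps = th$assign_eps)
      res <- assign_individuals(ll, clusters,
                                threshold = th$assign_threshold)
      utils::write.table(res, opath("assignments.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      manifest$rows$assign <- list(
        assigned = sum(res$status == "assigned"), total = nrow(res))
    }, error = function(e) fail("assign", e))
  }

  jsonlite::write_json(manifest, opath("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
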