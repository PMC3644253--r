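#' Pipeline run configuration
#'
#' Bundles the simulation config with the analysis thresholds for
#' [run_pipeline()].  Every threshold is validated here; the whole object
#' is echoed verbatim into the run manifest.
#'
#' @param sim A [sim_config()].
#' @param traits Trait names to simulate and analyse (direct phenotype
#'   route), or the traits to extract from activity streams.
#' @param phenotype_source `"direct"` draws per-fly trait values from the
#'   observational model; `"activity"` simulates minute streams and derives
#'   all seven sleep traits through the sleep-metrics stage (slower).
#' @param fdr FDR threshold for significant SNPs.
#' @param alpha Significance level for component tests, infection and
#'   inversion models.
#' @param min_bout Minimum sleep-bout length (minutes).
#' @param dead_window Terminal-inactivity window for the dead-fly rule.
#' @param lights_on Lights-on clock time (metadata for DAM output).
#' @param r2_threshold,max_gap LD-block chaining parameters.
#' @param stop_rule Forward-selection stopping rule.
#' @param quantgen_tests Compute LRT p-values for variance components.
#' @param stages Stages to run, in order.
#' @return Object of class `sleepqg_run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       traits = "night_sleep",
                       phenotype_source = c("direct", "activity"),
                       fdr = 0.01, alpha = 0.05,
                       min_bout = 5L, dead_window = 1440L,
                       lights_on = "08:00",
                       r2_threshold = 0.8, max_gap = 1e5,
                       stop_rule = c("adjusted_r2", "partial_f"),
                       quantgen_tests = FALSE,
                       stages = c("simulate", "phenotype", "quantgen",
                                  "gwas", "ld", "multisnp")) {
  phenotype_source <- match.arg(phenotype_source)
  stop_rule <- match.arg(stop_rule)
  stopifnot(fdr > 0, fdr < 1, alpha > 0, alpha < 1, min_bout >= 1,
            r2_threshold >= 0, r2_threshold <= 1, max_gap > 0)
  validate_sim_config(sim)
  structure(list(sim = sim, traits = traits,
                 phenotype_source = phenotype_source, fdr = fdr,
                 alpha = alpha, min_bout = as.integer(min_bout),
                 dead_window = as.integer(dead_window),
                 lights_on = lights_on, r2_threshold = r2_threshold,
                 max_gap = max_gap, stop_rule = stop_rule,
                 quantgen_tests = quantgen_tests, stages = stages),
            class = "sleepqg_run_config")
}

#' Run the full analysis pipeline into a directory
#'
#' Orchestrates simulate -> phenotype -> quantgen -> gwas -> ld -> multisnp.
#' Stages communicate exclusively through TSV files in `out_dir`, so any
#' stage can be replaced by user-supplied files of the same layout (e.g.
#' disable `"simulate"`/`"phenotype"` and provide `phenotypes.tsv` and
#' `genotypes.tsv`).  A `manifest.json` records the config, seed, package
#' version and MD5 of every file written; identical config + seed give
#' byte-identical stage outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created; existing files overwritten).
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "sleepqg_run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config$sim
  written <- character(0)
  log_msg <- function(...) message("[sleepqg] ", ...)
  need <- function(f) {
    p <- file.path(out_dir, f)
    if (!file.exists(p))
      stop("missing upstream output for this stage: ", f, call. = FALSE)
    p
  }
  put <- function(obj, f) {
    p <- file.path(out_dir, f)
    data.table::fwrite(obj, p, sep = "\t", na = "NA", quote = FALSE)
    written <<- c(written, p)
    p
  }

  if ("simulate" %in% config$stages) {
    log_msg("simulate: ", cfg$n_lines, " lines x ", cfg$n_snps, " sites")
    geno <- simulate_genotypes(cfg)
    write_genotypes_tsv(geno, file.path(out_dir, "genotypes.tsv"))
    written <- c(written, file.path(out_dir, "genotypes.tsv"))
    if (!is.null(geno$inversions)) {
      write_inversions_bed(geno, file.path(out_dir, "inversions.bed"))
      written <- c(written, file.path(out_dir, "inversions.bed"),
                   file.path(out_dir, "inversions.bed.carriers.tsv"))
    }
    put(simulate_wolbachia(cfg), "wolbachia.tsv")
    put(simulate_control(cfg), "control.tsv")
    if (config$phenotype_source == "direct") {
      sims <- lapply(seq_along(config$traits), function(i) {
        cfg_t <- cfg
        cfg_t$seed <- cfg$seed + 1000L * i
        simulate_phenotypes(geno, cfg_t, trait = config$traits[i])
      })
      put(do.call(rbind, lapply(sims, `[[`, "phenos")), "phenotypes.tsv")
      truth_caus <- do.call(rbind, lapply(sims, function(s)
        if (!is.null(s$truth$causal_mean))
          cbind(trait = s$truth$trait, s$truth$causal_mean)))
      if (!is.null(truth_caus)) put(truth_caus, "truth_causal.tsv")
    } else {
      act <- simulate_activity(cfg)
      write_dam_dir(act, file.path(out_dir, "dam"))
    }
  }

  if ("phenotype" %in% config$stages &&
      config$phenotype_source == "activity") {
    log_msg("phenotype: sleep metrics from activity streams")
    act <- read_dam_dir(need("dam/channel_map.tsv") |> dirname())
    summ <- summarize_activity(act, config$min_bout, config$dead_window)
    put(summ, "sleep_summaries.tsv")
    put(phenotype_table(summ), "phenotypes.tsv")
  }
  if (any(c("quantgen", "gwas", "ld", "multisnp") %in% config$stages)) {
    phenos <- read_phenotypes_tsv(need("phenotypes.tsv"))
    cve <- cve_table(phenos)
    put(cve, "cve.tsv")
    traits <- unique(phenos$trait)
    scales <- list(mean = phenos, cve = cve)
  }

  if ("quantgen" %in% config$stages) {
    log_msg("quantgen: variance components for ", length(traits),
            " trait(s) x 2 scales")
    wolb <- as.data.frame(data.table::fread(need("wolbachia.tsv")))
    qg <- NULL
    for (tr in traits) for (sc in names(scales)) {
      d <- scales[[sc]][scales[[sc]]$trait == tr, , drop = FALSE]
      vcp <- fit_variance_model(d, "pooled", tests = config$quantgen_tests)
      vcm <- fit_variance_model(d, "male")
      vcf <- fit_variance_model(d, "female")
      row <- data.frame(trait = tr, scale = sc,
                        H2_pooled = heritability(vcp),
                        H2_male = heritability(vcm),
                        H2_female = heritability(vcf),
                        r_MF = as.numeric(cross_sex_rg(vcp, vcm, vcf)))
      all_terms <- c("block", "line", "sex:line", "rep:block",
                     "sex:rep:block", "rep:line", "sex:rep:line", "residual")
      for (nm in all_terms)
        row[[paste0("var_", gsub(":", "_", nm))]] <-
          if (nm %in% names(vcp$components)) vcp$components[[nm]] else
            NA_real_
      qg <- rbind(qg, row)
    }
    put(qg, "quantgen.tsv")
    ## mean vs CV_E genetic correlation per trait, plus control-line check
    rg <- do.call(rbind, lapply(traits, function(tr) {
      data.frame(trait = tr, r_G_mean_cve = trait_rg(
        line_means(phenos[phenos$trait == tr, ]),
        line_means(cve[cve$trait == tr, ])))
    }))
    put(rg, "rg_mean_cve.tsv")
    ctrl <- as.data.frame(data.table::fread(need("control.tsv")))
    put(control_block_check(ctrl), "control_block_check.tsv")
    ## infection test/adjustment on line x sex means, per trait (mean scale)
    for (tr in traits) {
      lsm <- line_sex_means(phenos[phenos$trait == tr, ])
      wa <- wolbachia_adjust(lsm, wolb, config$alpha)
      put(cbind(trait = tr, wa$adjusted),
          paste0("line_sex_means_", tr, ".tsv"))
      put(cbind(trait = tr, wa$report),
          paste0("wolbachia_report_", tr, ".tsv"))
    }
  }

  if (any(c("gwas", "ld", "multisnp") %in% config$stages))
    geno_f <- filter_snps(read_genotypes_tsv(need("genotypes.tsv")))

  if ("gwas" %in% config$stages) {
    log_msg("gwas: ", ncol(geno_f$geno), " filtered sites")
    for (tr in traits) for (sc in names(scales)) {
      lsm_file <- file.path(out_dir, paste0("line_sex_means_", tr, ".tsv"))
      d <- if (sc == "mean" && file.exists(lsm_file))
        as.data.frame(data.table::fread(lsm_file))
      else scales[[sc]][scales[[sc]]$trait == tr, , drop = FALSE]
      assoc <- gwa_trait(geno_f, d, config$fdr)
      put(assoc, paste0("assoc_", tr, "_", sc, ".tsv"))
      put(qq_table(assoc$p_pooled), paste0("qq_", tr, "_", sc, ".tsv"))
    }
  }

  if ("ld" %in% config$stages) {
    log_msg("ld: blocks, inversions, proxy collapsing")
    counts <- NULL
    for (tr in traits) for (sc in names(scales)) {
      assoc <- as.data.frame(data.table::fread(
        need(paste0("assoc_", tr, "_", sc, ".tsv"))))
      sig <- assoc[assoc$sig, , drop = FALSE]
      blocks <- if (nrow(sig) >= 2L) {
        r2 <- pairwise_r2(geno_f$geno[, sig$site_id, drop = FALSE])
        find_ld_blocks(r2, sig, config$r2_threshold, config$max_gap)
      } else data.frame(block_id = character(0), site_id = character(0),
                        arm = character(0), pos = numeric(0))
      if (nrow(blocks)) put(blocks, paste0("ld_blocks_", tr, "_", sc,
                                           ".tsv"))
      assoc_inv <- NULL
      if (!is.null(geno_f$karyotypes) ||
          file.exists(file.path(out_dir, "inversions.bed"))) {
        kv <- read_inversions_bed(need("inversions.bed"))
        d <- scales[[sc]][scales[[sc]]$trait == tr, , drop = FALSE]
        lsm <- line_sex_means(d)
        inv_res <- do.call(rbind, lapply(kv$inversions$name, function(nm) {
          tv <- test_inversion(kv$karyotypes[, nm], lsm)
          data.frame(trait = tr, scale = sc, inversion = nm,
                     p_inv = tv$p_inv, p_int = tv$p_int)
        }))
        put(inv_res, paste0("inversion_assoc_", tr, "_", sc, ".tsv"))
        assoc_inv <- inv_res$inversion[!is.na(inv_res$p_inv) &
                                         inv_res$p_inv <= config$alpha]
      }
      cp <- collapse_proxies(assoc, blocks, assoc_inv)
      counts <- rbind(counts, data.frame(trait = tr, scale = sc,
                                         n_raw = cp$n_raw,
                                         n_collapsed = cp$n_collapsed))
      if (nrow(cp$proxies)) put(cp$proxies,
                                paste0("proxies_", tr, "_", sc, ".tsv"))
    }
    put(counts, "snp_counts.tsv")
  }

  if ("multisnp" %in% config$stages) {
    log_msg("multisnp: forward selection per trait x sex")
    qg_file <- file.path(out_dir, "quantgen.tsv")
    qg <- if (file.exists(qg_file))
      as.data.frame(data.table::fread(qg_file)) else NULL
    ms_out <- NULL
    for (tr in traits) for (sx in c("M", "F")) {
      d <- phenos[phenos$trait == tr & phenos$sex == sx, , drop = FALSE]
      means <- line_means(d)
      model <- forward_select(means, geno_f, stop_rule = config$stop_rule)
      h2 <- if (!is.null(qg))
        qg[qg$trait == tr & qg$scale == "mean",
           ifelse(sx == "M", "H2_male", "H2_female")] else NA_real_
      frac <- if (length(h2) == 1 && !is.na(h2) && h2 > 0)
        genetic_variance_explained(model$adj_r2, h2) else NA_real_
      if (nrow(model$steps))
        ms_out <- rbind(ms_out, cbind(trait = tr, sex = sx, model$steps,
                                      frac_vg = frac))
    }
    if (!is.null(ms_out)) put(ms_out, "multisnp.tsv")
  }

  manifest <- list(
    package = "sleepqg",
    version = as.character(packageVersion("sleepqg")),
    seed = cfg$seed,
    config = unclass(config$sim)[!vapply(unclass(config$sim), is.data.frame,
                                         TRUE)],
    thresholds = config[c("fdr", "alpha", "min_bout", "r2_threshold",
                          "max_gap", "stop_rule", "phenotype_source")],
    stages = config$stages,
    files = as.list(tools::md5sum(sort(unique(written)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
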