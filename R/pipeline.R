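#' Default pipeline configuration
#'
#' Nested per-stage settings for [run_pipeline()]. Any entry can be
#' overridden via the `...` arguments (named after the blocks) or by a YAML
#' file via [read_pipeline_config()]. The master `seed` overrides the cohort
#' seed so one integer reproduces the whole run.
#'
#' @param seed master seed
#' @param cohort a [cohort_config()]
#' @param prs,methqc,ewas,pmps,enrich per-stage setting lists; see defaults
#'   in the function body
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(seed = 1,
                            cohort = cohort_config(n_samples = 150,
                                                   n_snps = 600, n_blocks = 60,
                                                   n_probes = 4000,
                                                   n_coupled_probes = 40,
                                                   seed = seed),
                            prs = list(optimize = TRUE, p_T = NULL,
                                       clump_kb = 250, clump_r2 = 0.1,
                                       maf_min = 0.05, info_min = 0.8),
                            methqc = list(range_min = 0.05, r_min = 0.3,
                                          use_brain_filter = TRUE),
                            ewas = list(n_sv = "auto", moderate_var = TRUE,
                                        bacon_iterations = 5000,
                                        bacon_burnin = 2000, alpha = 0.05),
                            pmps = list(thresholds = c(0.002, 0.01, 0.05),
                                        scale = "beta", aggregate = "sum",
                                        weight_field = "coef",
                                        p_field = "p_corr"),
                            enrich = list(dmp_p = 0.05, basal_up = 5000,
                                          basal_down = 1000, distal = 5000,
                                          n_toy_sets = 10, fdr = 0.05)) {
  cohort$seed <- seed
  structure(list(seed = seed, cohort = cohort, prs = prs, methqc = methqc,
                 ewas = ewas, pmps = pmps, enrich = enrich),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values in the file override the defaults of [pipeline_config()]; unnamed
#' blocks keep their defaults.
#'
#' @param path YAML file with optional blocks seed, cohort, prs, methqc,
#'   ewas, pmps, enrich
#' @return list of class `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- y$seed %||% 1
  cohort_args <- y$cohort %||% list()
  base <- pipeline_config(seed = seed)
  cohort <- do.call(cohort_config, utils::modifyList(
    list(n_samples = 150, n_snps = 600, n_blocks = 60, n_probes = 4000,
         n_coupled_probes = 40, seed = seed), cohort_args))
  cfg <- pipeline_config(seed = seed, cohort = cohort)
  for (blk in c("prs", "methqc", "ewas", "pmps", "enrich"))
    if (!is.null(y[[blk]])) cfg[[blk]] <- utils::modifyList(cfg[[blk]], y[[blk]])
  cfg
}

stage_provenance <- function(dir, stage, params, seed, files) {
  prov <- list(stage = stage, params = params, seed = seed,
               files = lapply(files, function(f)
                 list(path = basename(f), md5 = unname(tools::md5sum(f)))),
               package_version = as.character(utils::packageVersion("stratmeth")),
               r_version = R.version.string)
  jsonlite::write_json(prov, file.path(dir, paste0(stage, ".provenance.json")),
                       auto_unbox = TRUE, digits = NA)
}

#' Run the full PRS-stratified EWAS pipeline
#'
#' Executes the stages in dependency order on a synthetic cohort: simulate ->
#' polygenic scoring (harmonise, clump, optimise p-threshold) -> quintile
#' stratification -> methylation QC (probe filters, cell deconvolution,
#' smoking inference) -> discovery EWAS in the high-risk stratum contrast ->
#' poly-methylomic profile scores in the held-out control set -> validation
#' GLMs (main, interaction, family-environment) -> gene mapping and
#' enrichment against generated toy gene sets. Every stage writes TSV outputs
#' plus a JSON provenance block (input hashes, settings, seed, versions); a
#' re-run with the same config reproduces identical TSV hashes. A stage
#' failure halts with the stage name; earlier outputs persist.
#'
#' @param config a [pipeline_config()] (or path handled by
#'   [read_pipeline_config()])
#' @param out_dir output directory
#' @return invisibly, a list of in-memory stage results
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  stage <- function(name, expr) {
    message("[stratmeth] stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  res$cohort <- stage("simulate", {
    co <- simulate_cohort(config$cohort)
    write_cohort(co, file.path(out_dir, "cohort"))
    stage_provenance(out_dir, "simulate", config$cohort[names(config$cohort)],
                     config$seed,
                     list.files(file.path(out_dir, "cohort"), full.names = TRUE))
    co
  })
  co <- res$cohort

  res$prs <- stage("prs", {
    pcfg <- config$prs
    harm <- filter_variants(co$panel, co$gwas, maf_min = pcfg$maf_min,
                            info_min = pcfg$info_min)
    kept <- ld_clump(harm$panel, harm$summary, window_kb = pcfg$clump_kb,
                     r2_max = pcfg$clump_r2)
    sub <- snp_panel(harm$panel$dosage[, kept, drop = FALSE],
                     harm$panel$map[match(kept, harm$panel$map$id), ])
    # case/control labels for threshold optimisation; high-risk samples are
    # coded missing so they do not enter the logistic fit
    y <- ifelse(co$samples$group == "CASE", 1L,
                ifelse(co$samples$group == "CON", 0L, NA_integer_))
    p_T <- pcfg$p_T
    opt <- NULL
    if (is.null(p_T)) {
      opt <- optimize_threshold(sub, harm$summary, y)
      p_T <- opt$best_p_T
    }
    prs <- score_prs(sub, harm$summary, p_T)
    mds <- mds_ancestry(co$panel, k = 4)
    out <- cbind(prs$scores, mds[match(prs$scores$sample_id,
                                       rownames(mds)), 1:2])
    f1 <- file.path(out_dir, "prs.tsv"); write_tsv(out, f1)
    f2 <- file.path(out_dir, "prs_profile.tsv")
    if (!is.null(opt)) write_tsv(opt$profile, f2)
    stage_provenance(out_dir, "prs", c(pcfg, list(p_T_used = p_T)),
                     config$seed, c(f1, if (!is.null(opt)) f2))
    list(prs = prs, mds = mds, p_T = p_T, profile = opt$profile,
         harmonised = harm, clumped_ids = kept)
  })

  samples <- co$samples
  idx <- match(samples$sample_id, res$prs$prs$scores$sample_id)
  samples$prs <- res$prs$prs$scores$standardized[idx]
  samples$C1 <- res$prs$mds[idx, 1]
  samples$C2 <- res$prs$mds[idx, 2]
  samples$batchf <- factor(samples$batch)

  res$strata <- stage("strata", {
    hr <- samples$sample_id[samples$group == "HR"]
    con <- samples$sample_id[samples$group == "CON"]
    sa_hr <- quintile_strata(setNames(samples$prs[match(hr, samples$sample_id)], hr))
    sa_con <- quintile_strata(setNames(samples$prs[match(con, samples$sample_id)], con))
    strat <- rbind(cbind(sa_hr$assignment, set = "discovery"),
                   cbind(sa_con$assignment, set = "validation1"))
    f <- file.path(out_dir, "strata.tsv"); write_tsv(strat, f)
    stage_provenance(out_dir, "strata", list(fraction = 0.4), config$seed, f)
    list(discovery = sa_hr, validation1 = sa_con)
  })

  res$methqc <- stage("methqc", {
    mcfg <- config$methqc
    filt <- filter_probes(co$meth$beta, co$meth$manifest,
                          co$meth$blood_variable_ids, co$meth$blood_brain_r,
                          range_min = mcfg$range_min, r_min = mcfg$r_min,
                          use_brain_filter = mcfg$use_brain_filter)
    cells <- estimate_cell_counts(co$meth$beta, co$meth$cell_ref)
    smoke <- infer_smoking(co$meth$beta)
    f1 <- file.path(out_dir, "probe_filter.tsv"); write_tsv(filt$flags, f1)
    f2 <- file.path(out_dir, "cell_counts.tsv")
    write_tsv(data.frame(sample_id = rownames(cells), cells,
                         check.names = FALSE), f2)
    f3 <- file.path(out_dir, "smoking.tsv"); write_tsv(smoke, f3)
    message("[stratmeth] probe filter counts: ",
            paste(names(filt$counts), filt$counts, sep = "=", collapse = ", "))
    stage_provenance(out_dir, "methqc", mcfg, config$seed, c(f1, f2, f3))
    list(filter = filt, cells = cells, smoking = smoke)
  })

  cellcols <- colnames(res$methqc$cells)
  drop_cell <- cellcols[which.max(colMeans(res$methqc$cells))]
  use_cells <- setdiff(cellcols, drop_cell)  # avoid sum-to-one collinearity
  samples <- cbind(samples, res$methqc$cells[match(samples$sample_id,
                                                   rownames(res$methqc$cells)), ])

  res$ewas <- stage("ewas", {
    ecfg <- config$ewas
    disc <- res$strata$discovery$assignment
    disc <- disc[disc$stratum != "Mid", ]
    sdisc <- samples[match(disc$sample_id, samples$sample_id), ]
    sdisc$stratum <- disc$stratum
    M <- beta_to_m(co$meth$beta[res$methqc$filter$retained,
                                sdisc$sample_id, drop = FALSE])
    ew <- run_ewas(M, sdisc, stratum_col = "stratum",
                   covariate_cols = c("sex", "age", "C1", "C2", "tissue",
                                      "batchf", use_cells),
                   n_sv = ecfg$n_sv, moderate_var = ecfg$moderate_var,
                   bacon_iterations = ecfg$bacon_iterations,
                   bacon_burnin = ecfg$bacon_burnin, alpha = ecfg$alpha,
                   seed = config$seed)
    mi <- match(ew$table$probe, co$meth$manifest$probe_id)
    tab <- cbind(ew$table[, "probe", drop = FALSE],
                 chr = co$meth$manifest$chr[mi], pos = co$meth$manifest$pos[mi],
                 ew$table[, -1])
    f <- file.path(out_dir, "ewas.tsv"); write_tsv(tab, f)
    message(sprintf("[stratmeth] EWAS: %d probes, %d SVs, bias %.4g, inflation %.4g, threshold %.3g",
                    nrow(tab), ew$n_sv, ew$empnull$bias, ew$empnull$inflation,
                    ew$threshold$threshold))
    stage_provenance(out_dir, "ewas", ecfg, config$seed, f)
    ew$table <- tab
    ew
  })

  res$pmps <- stage("pmps", {
    pcfg <- config$pmps
    val <- res$strata$validation1$assignment
    beta_val <- co$meth$beta[, val$sample_id, drop = FALSE]
    tabs <- lapply(pcfg$thresholds, function(pt)
      compute_pmps(beta_val, res$ewas$table, pt,
                   weight_field = pcfg$weight_field, p_field = pcfg$p_field,
                   scale = pcfg$scale, aggregate = pcfg$aggregate))
    names(tabs) <- paste0("p_T_", pcfg$thresholds)
    out <- data.frame(sample_id = val$sample_id, stringsAsFactors = FALSE)
    for (nm in names(tabs))
      out[[nm]] <- tabs[[nm]]$scores$pmps[match(out$sample_id,
                                                tabs[[nm]]$scores$sample_id)]
    f <- file.path(out_dir, "pmps.tsv"); write_tsv(out, f)
    stage_provenance(out_dir, "pmps", pcfg, config$seed, f)
    tabs
  })

  res$validate <- stage("validate", {
    pcfg <- config$pmps
    best <- res$pmps[[length(res$pmps)]]  # widest threshold
    val <- res$strata$validation1$assignment
    dat <- samples[match(val$sample_id, samples$sample_id), ]
    dat$stratum <- val$stratum
    dat$pmps <- best$scores$pmps[match(dat$sample_id, best$scores$sample_id)]
    dat <- dat[dat$stratum != "Mid", ]
    main <- validate_glm(dat, "pmps", "stratum",
                         covariates = c("age", "sex", "tissue", use_cells))
    # interaction model across case/control groups, scored on their own PMPS
    cc <- samples[samples$group %in% c("CASE", "CON"), ]
    pm_cc <- compute_pmps(co$meth$beta[, cc$sample_id, drop = FALSE],
                          res$ewas$table, max(pcfg$thresholds),
                          weight_field = pcfg$weight_field,
                          p_field = pcfg$p_field, scale = pcfg$scale,
                          aggregate = pcfg$aggregate)
    cc$pmps <- pm_cc$scores$pmps[match(cc$sample_id, pm_cc$scores$sample_id)]
    inter <- validate_glm(cc, "pmps", "group",
                          covariates = c("age", "sex"), prs = "prs",
                          include_interaction = TRUE)
    fac <- faces_model(cc, "pmps", faces = "faces", prs = "prs",
                       group = "group")
    f <- file.path(out_dir, "validation_glm.tsv")
    write_tsv(rbind(cbind(model = "main", main$terms[, c("term", "df", "F", "p", "partial_eta_sq")]),
                    cbind(model = "interaction", inter$terms[, c("term", "df", "F", "p", "partial_eta_sq")])), f)
    f2 <- file.path(out_dir, "faces_model.tsv"); write_tsv(fac$terms, f2)
    stage_provenance(out_dir, "validate", list(), config$seed, c(f, f2))
    list(main = main, interaction = inter, faces = fac)
  })

  res$enrich <- stage("enrich", {
    ecfg <- config$enrich
    genes <- co$meth$genes
    doms <- build_domains(genes, basal_up = ecfg$basal_up,
                          basal_down = ecfg$basal_down, distal = ecfg$distal)
    probes <- co$meth$manifest[match(res$ewas$table$probe,
                                     co$meth$manifest$probe_id), ]
    all_map <- map_probes(probes, genes, doms)
    dmp <- res$ewas$table[res$ewas$table$p_corr < ecfg$dmp_p, ]
    dmp_probes <- probes[probes$probe_id %in% dmp$probe, ]
    dmp_map <- map_probes(dmp_probes, genes, doms)
    sets <- with_seed(sub_seed(config$seed, 21L), {
      setNames(lapply(seq_len(ecfg$n_toy_sets), function(i)
        sample(all_map$genes, min(25, max(5, length(all_map$genes) %/% 10)))),
        sprintf("TOYSET_%02d", seq_len(ecfg$n_toy_sets)))
    })
    enr <- enrich_gene_sets(dmp_map$genes, sets, all_map$genes)
    f1 <- file.path(out_dir, "probe_gene_map.tsv"); write_tsv(dmp_map$pairs, f1)
    f2 <- file.path(out_dir, "enrichment.tsv"); write_tsv(enr, f2)
    stage_provenance(out_dir, "enrich", ecfg, config$seed, c(f1, f2))
    list(domains = doms, map = dmp_map, enrichment = enr)
  })

  jsonlite::write_json(
    list(seed = config$seed,
         stages = c("simulate", "prs", "strata", "methqc", "ewas", "pmps",
                    "validate", "enrich"),
         completed = TRUE),
    file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE)
  invisible(res)
}
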