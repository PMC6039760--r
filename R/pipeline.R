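#' Subset a genotype matrix by animal or SNP
#'
#' @param g a [genotype_matrix()].
#' @param ids animal ids (`subset_animals`) or SNP ids (`subset_snps`).
#' @return a [genotype_matrix()] (carrying attributes such as
#'   `design_freq`/`sire` along, restricted as appropriate).
#' @export
subset_animals <- function(g, ids) {
  idx <- match(ids, rownames(g$dosage))
  if (anyNA(idx)) stop_("unknown animal id(s)")
  out <- genotype_matrix(g$dosage[idx, , drop = FALSE], g$map)
  attr(out, "design_freq") <- attr(g, "design_freq")
  if (!is.null(attr(g, "sire"))) attr(out, "sire") <- attr(g, "sire")[ids]
  out
}

#' @rdname subset_animals
#' @export
subset_snps <- function(g, ids) {
  idx <- match(ids, g$map$snp_id)
  if (anyNA(idx)) stop_("unknown snp id(s)")
  out <- genotype_matrix(g$dosage[, idx, drop = FALSE],
                         g$map[idx, , drop = FALSE])
  df <- attr(g, "design_freq")
  if (!is.null(df)) attr(out, "design_freq") <- df[ids]
  attr(out, "sire") <- attr(g, "sire")
  out
}

#' Split a simulated cohort into discovery and validation sub-cohorts
#'
#' Both halves share the same loci, allele frequencies and QTL effects
#' (the genetic architecture transfers, as it must for discovery-cohort
#' SNP selection to be testable on the validation cohort).
#'
#' @param sim a [simulate_cohort()] result.
#' @param n_discovery number of animals in the discovery half.
#' @return list with `discovery` and `validation`, each holding
#'   `genotypes`, `phenotypes`, `truth`.
#' @export
split_cohort <- function(sim, n_discovery) {
  ids <- rownames(sim$genotypes$dosage)
  stopifnot(n_discovery >= 1L, n_discovery < length(ids))
  take <- function(sel) {
    tr <- sim$truth
    tr$true_breeding_values <- tr$true_breeding_values[sel]
    list(genotypes = subset_animals(sim$genotypes, sel),
         phenotypes = phenotype_table(
           sim$phenotypes[match(sel, sim$phenotypes$animal_id), ,
                          drop = FALSE]),
         truth = tr)
  }
  list(discovery = take(ids[seq_len(n_discovery)]),
       validation = take(ids[-seq_len(n_discovery)]))
}

#' Default pipeline configuration
#'
#' @param seed global seed; per-stage seeds are derived from it by stage
#'   name hashing so stages can be re-run independently.
#' @param ... overrides for any configuration entry.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    sim = list(n_animals = 400L, m_snps = 1000L, n_qtl = 40L,
               h2_true = 0.3, n_groups = 8L),
    n_discovery = 200L,
    maf_min = 0.01,
    rankers = list(
      rf = list(ntree = 200L, mtry_frac = 0.1),
      gbm = list(ntree = 200L, learning_rate = 0.1)),
    panel_sizes = c(100L, 300L),
    include_positive = TRUE,
    ridge = 0.01,
    cv = list(n_folds = 5L, scheme = "random"))
  cfg <- modifyList(cfg, list(...))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration (JSON)
#' @param path JSON file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

#' @rdname read_pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

config_hash <- function(cfg) {
  fnv1a_hash(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              null = "null"))
}

#' Run the full panel-selection and validation pipeline
#'
#' Simulate (or load) a discovery and a validation cohort, apply QC and
#' phenotype pre-adjustment, rank SNPs on the discovery cohort with the
#' configured tree ensembles, build top-k / positive / evenly spaced /
#' all-SNP panels, then on the validation cohort build each panel's
#' VanRaden GRM, fit REML variance components, and run seeded k-fold
#' cross-validation with shared folds. Writes a report bundle of TSVs to
#' `out_dir`: a top-SNP listing, a variance-component table (with the
#' share of the all-SNP additive variance), a per-panel accuracy table,
#' GRM diagnostic summaries and positive-set overlap counts, plus a
#' `manifest.json` stamped with the config hash and seed. Completed
#' stages are resumable: outputs already on disk are reused when
#' `resume = TRUE`.
#'
#' @param cfg a [pipeline_config()] (or path to its JSON form).
#' @param out_dir output directory (created if needed).
#' @param resume reuse stage outputs found in `out_dir`.
#' @return invisible list with the report tables and file paths.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir, resume = TRUE) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  log_stage <- function(stage, msg = "") {
    message(sprintf("[pipeline %s] %s %s", hash, stage, msg))
  }
  pth <- function(...) file.path(out_dir, paste0(...))

  # -- stage: data ------------------------------------------------------------
  # the written TSVs are the stage interface: even a first run reloads from
  # them, so resumed runs are bit-identical to fresh ones
  load_halves <- function() {
    load_half <- function(tag) list(
      genotypes = read_genotypes(pth(tag, "_genotypes.tsv"), "tsv",
                                 map = pth("snp_map.tsv")),
      phenotypes = read_phenotypes(pth(tag, "_phenotypes.tsv")))
    list(discovery = load_half("discovery"),
         validation = load_half("validation"))
  }
  stage_data <- function() {
    if (resume && file.exists(pth("discovery_genotypes.tsv"))) {
      log_stage("data", "(resumed)")
      return(load_halves())
    }
    log_stage("data")
    if (!is.null(cfg$input)) {
      g <- read_genotypes(cfg$input$genotypes,
                          cfg$input$format %||% "tsv",
                          map = cfg$input$map)
      p <- read_phenotypes(cfg$input$phenotypes)
      half <- list(genotypes = g, phenotypes = p)
      cohorts <- list(discovery = half, validation = half)
    } else {
      simargs <- modifyList(cfg$sim,
                            list(seed = derive_seed(cfg$seed, "data")))
      n_total <- simargs$n_animals
      sim <- simulate_cohort(do.call(sim_config, simargs))
      cohorts <- split_cohort(sim, min(cfg$n_discovery, n_total - 1L))
      jsonlite::write_json(
        list(qtl_ids = sim$truth$qtl_ids,
             h2_realized = sim$truth$h2_realized),
        pth("truth.json"), auto_unbox = TRUE, digits = NA)
    }
    write_snp_map(cohorts$discovery$genotypes$map, pth("snp_map.tsv"))
    for (tag in c("discovery", "validation")) {
      write_genotypes(cohorts[[tag]]$genotypes, pth(tag, "_genotypes.tsv"),
                      "tsv")
      write_phenotypes(cohorts[[tag]]$phenotypes, pth(tag, "_phenotypes.tsv"))
    }
    load_halves()
  }

  withCallingHandlers({
    cohorts <- stage_data()

    # -- stage: qc + adjust ---------------------------------------------------
    log_stage("qc")
    qcd <- lapply(cohorts, function(co) qc_filter(co$genotypes, cfg$maf_min))
    common <- intersect(qcd$discovery$genotypes$map$snp_id,
                        qcd$validation$genotypes$map$snp_id)
    gdis <- subset_snps(qcd$discovery$genotypes, common)
    gval <- subset_snps(qcd$validation$genotypes, common)
    data.table::fwrite(rbind(cbind(cohort = "discovery", qcd$discovery$removed),
                             cbind(cohort = "validation", qcd$validation$removed)),
                       pth("qc_removed.tsv"), sep = "\t", quote = FALSE)
    log_stage("adjust")
    pdis <- adjust_phenotypes(cohorts$discovery$phenotypes)
    pval <- adjust_phenotypes(cohorts$validation$phenotypes)

    # -- stage: rank ----------------------------------------------------------
    vims <- list()
    for (mth in names(cfg$rankers)) {
      f <- pth("vim_", mth, ".tsv")
      if (resume && file.exists(f)) {
        log_stage(paste0("rank:", mth), "(resumed)")
        vt <- data.table::fread(f, data.table = FALSE)
        class(vt) <- c("vim_table", "data.frame")
        attr(vt, "method") <- mth
      } else {
        log_stage(paste0("rank:", mth))
        args <- cfg$rankers[[mth]]
        args$seed <- derive_seed(cfg$seed, paste0("rank_", mth))
        vt <- switch(mth,
          rf = rf_importance(gdis, pdis$y_adjusted, do.call(rf_params, args)),
          gbm = gbm_importance(gdis, pdis$y_adjusted,
                               do.call(boost_params, args)),
          xgb = xgb_importance(gdis, pdis$y_adjusted,
                               do.call(boost_params, args)),
          stop_("unknown ranker: ", mth))
        data.table::fwrite(vt, f, sep = "\t", quote = FALSE)
      }
      vims[[mth]] <- vt
    }
    top_listing <- do.call(rbind, lapply(names(vims), function(mth) {
      v <- vims[[mth]]
      cbind(method = mth, v[order(v$rank)[seq_len(min(20L, nrow(v)))], ])
    }))
    data.table::fwrite(top_listing, pth("top_snps.tsv"), sep = "\t",
                       quote = FALSE)

    # -- stage: panels --------------------------------------------------------
    log_stage("panels")
    panels <- list()
    for (mth in names(vims)) {
      for (k in cfg$panel_sizes)
        panels[[paste0(toupper(mth), k)]] <-
          top_k(vims[[mth]], k, paste0(toupper(mth), k))
      if (isTRUE(cfg$include_positive)) {
        ps <- positive_set(vims[[mth]], paste0(toupper(mth), "pos"))
        if (length(ps$snp_ids) >= 2L) panels[[ps$name]] <- ps
      }
    }
    for (k in cfg$panel_sizes)
      panels[[paste0("Even", k)]] <- evenly_spaced(gval$map, k)
    for (nmp in names(panels))
      writeLines(c(paste0("# panel ", nmp, " provenance=",
                          panels[[nmp]]$provenance, " config=", hash),
                   "snp_id", panels[[nmp]]$snp_ids),
                 pth("panel_", nmp, ".tsv"))
    pos_panels <- panels[grepl("pos$", names(panels))]
    if (length(pos_panels) %in% c(2L, 3L)) {
      ov <- overlap_counts(unname(pos_panels))
      data.table::fwrite(ov, pth("overlap_positive.tsv"), sep = "\t",
                         quote = FALSE)
    }

    # -- stage: grm + reml ----------------------------------------------------
    log_stage("grm/reml")
    X <- build_fixed_design(pval)
    yv <- setNames(pval$y_raw, pval$animal_id)
    eval_panel <- function(panel, nmp) {
      G <- build_vanraden(gval, panel, name = nmp)
      dgn <- grm_diagnostics(G, ridge = cfg$ridge)
      vc <- fit_reml(mixed_model_spec(yv, X, G))
      list(G = G, diag = dgn, vc = vc)
    }
    fits <- lapply(names(panels), function(nmp) eval_panel(panels[[nmp]], nmp))
    names(fits) <- names(panels)
    fits$ALL <- eval_panel(NULL, "ALL")
    vc_all <- fits$ALL$vc
    var_table <- do.call(rbind, lapply(names(fits), function(nmp) {
      vc <- fits[[nmp]]$vc
      data.frame(panel = nmp, m_snps = fits[[nmp]]$G$m_snps,
                 sigma2_a = vc$sigma2_a, se_a = vc$se_sigma2_a,
                 sigma2_e = vc$sigma2_e, se_e = vc$se_sigma2_e,
                 sigma2_p = vc$sigma2_p, h2 = vc$h2, se_h2 = vc$se_h2,
                 pct_sigma2_a_all = variance_share(vc, vc_all))
    }))
    data.table::fwrite(var_table, pth("variance_components.tsv"), sep = "\t",
                       quote = FALSE)
    diag_table <- do.call(rbind, lapply(names(fits), function(nmp) {
      d <- fits[[nmp]]$diag
      data.frame(panel = nmp,
                 diag_mean = d$diag_mean, diag_sd = d$diag_sd,
                 offdiag_mean = d$offdiag_mean, offdiag_sd = d$offdiag_sd,
                 inv_diag_mean = d$inv_diag_mean, inv_diag_sd = d$inv_diag_sd,
                 ridge_used = d$ridge_used,
                 multimodal = d$multimodality_flag)
    }))
    data.table::fwrite(diag_table, pth("grm_diagnostics.tsv"), sep = "\t",
                       quote = FALSE)

    # -- stage: cv ------------------------------------------------------------
    cv_file <- pth("cv_accuracy.tsv")
    if (resume && file.exists(cv_file)) {
      log_stage("cv", "(resumed)")
      acc_table <- data.table::fread(cv_file, data.table = FALSE)
    } else {
      log_stage("cv")
      cvc <- cv_config(n_folds = cfg$cv$n_folds,
                       seed = derive_seed(cfg$seed, "cv"),
                       scheme = cfg$cv$scheme %||% "random")
      fams <- if (!is.null(pval$sire)) setNames(pval$sire, pval$animal_id)
      folds <- make_folds(pval$animal_id, cvc, families = fams)
      run_cv <- function(panel) cv_accuracy(gval, pval, panel, cvc,
                                            folds = folds)
      cvs <- lapply(names(panels), function(nmp) run_cv(panels[[nmp]]))
      names(cvs) <- names(panels)
      cvs$ALL <- run_cv(NULL)
      acc_table <- do.call(rbind, lapply(cvs, function(r)
        data.frame(panel = r$panel_name, mean_accuracy = r$mean_accuracy,
                   sd_accuracy = r$sd_accuracy, h2_used = r$h2_used,
                   t(setNames(r$fold_accuracies,
                              paste0("fold", seq_along(r$fold_accuracies)))))))
      data.table::fwrite(acc_table, cv_file, sep = "\t", quote = FALSE)
    }

    manifest <- list(config = unclass(cfg), config_hash = hash,
                     seed = cfg$seed,
                     stages = c("data", "qc", "adjust",
                                paste0("rank:", names(cfg$rankers)),
                                "panels", "grm/reml", "cv"),
                     panels = names(panels))
    jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)

    invisible(list(variance_table = var_table, accuracy_table = acc_table,
                   diagnostics = diag_table, panels = panels, vims = vims,
                   out_dir = out_dir, config_hash = hash))
  }, error = function(e) {
    message("pipeline halted (completed stage outputs persist in ", out_dir,
            "): ", conditionMessage(e))
  })
}
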