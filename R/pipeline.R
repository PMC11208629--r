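# End-to-end pipeline: QC -> GRM -> heritability -> GWAS -> candidate scan
# -> contingency tests, driven by one config with a single root seed.

default_run_config <- function() {
  list(
    simulate = NULL,          # simulation_config() arguments, or NULL
    genotypes = NULL, map = NULL, phenotypes = NULL, genes = NULL,
    traits = c("AL", "ETvND"),
    qc = list(min_call = 0.9, min_maf = 0.01, autosomes_only = TRUE,
              max_het = 0.5),
    mcmc = list(chain_length = 100000L, burn_in = 25000L, thin = 100L,
                prior_h2 = 0.5, prior_df = 4),
    bayesb = list(pi_null = 0.99, chain_length = 100000L,
                  burn_in = 25000L, thin = 100L),
    gwas_trait = NULL,        # default: first of traits
    window_bp = 1e6,
    fisher_n_sim = 1e5,
    seed = 1L,
    output_dir = "liabgen_run")
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load (or simulate) genotypes and phenotypes; marker
#' and animal QC; mean-dosage fill; GRM and PCA coordinates; class-by-year
#' cohort table with a Fisher test; per-trait threshold-model heritability;
#' BayesB window GWAS on one trait; candidate-gene scan when a gene table
#' is given. All randomness flows from one root seed split per stage, so
#' the same config and seed give byte-identical numeric outputs.
#' Intermediate TSVs and a `report.yaml` are written under
#' `config$output_dir`; a stage failure propagates with the stage name and
#' earlier outputs are retained.
#'
#' @param config Named list overriding the defaults (see the vignette), or
#'   a YAML file path. Supply either `simulate` (arguments to
#'   [simulation_config()]) or paths `genotypes`/`map`/`phenotypes`;
#'   `genes` is an optional gene-interval TSV.
#' @return Invisibly, the output directory; its files are the report.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_run_config(), config)
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  stage_seed <- sample.int(.Machine$integer.max - 1L, 8L)

  if (!is.null(cfg$simulate)) {
    sim <- stage("simulate", {
      sc <- do.call(simulation_config,
                    c(cfg$simulate, list(seed = stage_seed[1L])))
      simulate_cohort(sc)
    })
    geno <- sim$genotypes
    phen <- sim$phenotypes
  } else {
    geno <- stage("load_genotypes", {
      if (is.null(cfg$genotypes) || !file.exists(cfg$genotypes)) {
        stop("genotype path missing: ", cfg$genotypes)
      }
      if (is.null(cfg$map) || !file.exists(cfg$map)) {
        stop("map path missing: ", cfg$map)
      }
      read_genotype_table(cfg$genotypes, "matrix-tsv", cfg$map)
    })
    phen <- stage("load_phenotypes", {
      if (is.null(cfg$phenotypes) || !file.exists(cfg$phenotypes)) {
        stop("phenotype path missing: ", cfg$phenotypes)
      }
      read_phenotypes(cfg$phenotypes)
    })
  }

  qc <- stage("qc", {
    mq <- marker_qc(geno, cfg$qc$min_call, cfg$qc$min_maf,
                    cfg$qc$autosomes_only)
    sq <- sample_qc(mq$genotypes, cfg$qc$min_call, cfg$qc$max_het)
    qc_lines <- c(
      utils::capture.output(print(mq$report)),
      utils::capture.output(print(sq$report)))
    writeLines(qc_lines, file.path(out, "qc_summary.txt"))
    sq$genotypes
  })

  filled <- stage("fill", fill_missing(qc))
  grm <- stage("grm", {
    p <- allele_frequencies(filled)
    g <- build_grm(center_genotypes(filled, p))
    write_grm(g, file.path(out, "grm.tsv"))
    pca <- grm_pca(g, k = min(2L, length(g$animal_ids)))
    data.table::fwrite(
      data.frame(animal_id = g$animal_ids, pca$coordinates,
                 check.names = FALSE),
      file.path(out, "grm_pca.tsv"), sep = "\t")
    g
  })

  stage("cohort_table", {
    phen_g <- phen[phen$animal_id %in% grm$animal_ids, , drop = FALSE]
    tab <- build_contingency(phen_g[, c("birth_year", "class")])
    rep <- class_by_year_report(tab)
    utils::write.table(rep$formatted, file.path(out, "class_by_year.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    # class-by-year tables are far beyond exact enumeration; go straight
    # to the fixed-margins Monte Carlo test
    ft <- fisher_exact(tab, method = "montecarlo", n_sim = cfg$fisher_n_sim,
                       seed = stage_seed[2L])
    writeLines(sprintf("fisher_p\t%g\nmethod\t%s", ft$p_value, ft$method),
               file.path(out, "class_by_year_fisher.tsv"))
  })

  h2_rows <- list()
  fits <- list()
  for (i in seq_along(cfg$traits)) {
    tr <- cfg$traits[[i]]
    fits[[tr]] <- stage(paste0("heritability_", tr), {
      des <- build_design(phen, trait_coding(tr), grm$animal_ids)
      mc <- mcmc_config(cfg$mcmc$chain_length, cfg$mcmc$burn_in,
                        cfg$mcmc$thin, seed = stage_seed[3L] + i,
                        prior_h2 = cfg$mcmc$prior_h2,
                        prior_df = cfg$mcmc$prior_df)
      fit <- fit_threshold_model(des, grm, mc)
      write_posterior_samples(fit,
                              file.path(out, paste0("posterior_", tr, ".tsv")))
      h <- summarize_heritability(fit)
      row <- data.frame(
        trait = tr, n_levels = des$K,
        genetic_variance = sprintf("%.2f +/- %.2f",
                                   h$genetic_variance["mean"],
                                   h$genetic_variance["sd"]),
        total_variance = sprintf("%.2f +/- %.2f",
                                 h$total_variance["mean"],
                                 h$total_variance["sd"]),
        heritability = sprintf("%.2f +/- %.2f (%.2f-%.2f)", h$mean, h$sd,
                               h$credible_set_95[1], h$credible_set_95[2]),
        stringsAsFactors = FALSE)
      list(design = des, fit = fit, h2 = h, row = row)
    })
    h2_rows[[tr]] <- fits[[tr]]$row
  }
  data.table::fwrite(do.call(rbind, h2_rows),
                     file.path(out, "heritability.tsv"), sep = "\t")

  gwas_trait <- if (is.null(cfg$gwas_trait)) cfg$traits[[1L]] else cfg$gwas_trait
  stage(paste0("gwas_", gwas_trait), {
    des <- fits[[gwas_trait]]$design
    vg <- fits[[gwas_trait]]$h2$genetic_variance[["mean"]]
    bc <- bayesb_config(cfg$bayesb$pi_null, cfg$bayesb$chain_length,
                        cfg$bayesb$burn_in, cfg$bayesb$thin,
                        seed = stage_seed[4L], genetic_var_prior = vg)
    bb <- fit_bayesb(des, filled, bc)
    ws <- window_variance(bb, window_bp = cfg$window_bp)
    write_window_summary(ws, file.path(out,
                                       paste0("windows_", gwas_trait, ".tsv")))
    hits <- call_associated(ws)
    write_window_summary(hits, file.path(out,
                                         paste0("associated_", gwas_trait,
                                                ".tsv")))
  })

  if (!is.null(cfg$genes)) {
    stage("candidate_scan", {
      genes <- read_gene_intervals(cfg$genes)
      des <- fits[[cfg$traits[[1L]]]]$design
      mc <- mcmc_config(cfg$mcmc$chain_length, cfg$mcmc$burn_in,
                        cfg$mcmc$thin, seed = stage_seed[5L],
                        prior_h2 = cfg$mcmc$prior_h2,
                        prior_df = cfg$mcmc$prior_df)
      scan <- candidate_scan(des, grm, filled, genes, mc)
      data.table::fwrite(scan, file.path(out, "candidate_scan.tsv"),
                         sep = "\t")
    })
  }

  yaml::write_yaml(list(seed = cfg$seed, stage_seeds = stage_seed,
                        traits = cfg$traits, qc = cfg$qc,
                        mcmc = cfg$mcmc,
                        bayesb = cfg$bayesb[c("pi_null", "chain_length",
                                              "burn_in", "thin")]),
                   file.path(out, "report.yaml"))
  invisible(out)
}
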