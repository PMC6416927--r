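# End-to-end orchestration over synthetic (or precomputed) inputs: simulate
# family trees and states, infer ancestral states by consensus, classify
# duplicate pairs, score asymmetry, fit the kinetic models, and fit the
# retention model. Each stage writes plain TSV/JSON into the run directory,
# and a manifest records the seed and every threshold so a run is auditable
# and exactly repeatable.

#' Build and validate a pipeline run configuration
#'
#' @param out_dir Output directory for stage results.
#' @param seed Integer seed driving every stochastic stage (one RNG stream).
#' @param n_families,tips_per_family,n_items Synthetic-data sizes: gene
#'   families, leaves per family tree, and items (conditions) per gene.
#' @param n_states States for expression items (4 = quartiles).
#' @param sim_rate True symmetric transition rate used when simulating
#'   states on trees.
#' @param consensus_runs,consensus_min,posterior_min Consensus-calling
#'   thresholds: replicate fits per tree, minimum supporting runs (strict),
#'   minimum mean posterior (strict).
#' @param min_partitioned,min_sites Minimum partitioned items / ancestral
#'   sites for a pair to enter the asymmetry analyses.
#' @param permutations,bernoulli_reps Replicates for the re-pairing
#'   expectation and the Bernoulli null.
#' @param ode_variants Constraint variants fit to the pair classes.
#' @param pair_rates True pair-model rates for the fate simulation.
#' @param n_ode_pairs Pairs simulated for the kinetic fit.
#' @param ode_starts Optimizer restarts per kinetic fit.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("dupdyn_run_"), seed = 1,
                       n_families = 50, tips_per_family = 8, n_items = 20,
                       n_states = 4, sim_rate = 0.3,
                       consensus_runs = 100, consensus_min = 50,
                       posterior_min = 0.5,
                       min_partitioned = 5, min_sites = 5,
                       permutations = 1000, bernoulli_reps = 1000,
                       ode_variants = c("one", "two", "four"),
                       pair_rates = c(x = 0.9, y = 0.05, w = 0.12, z = 0.02),
                       n_ode_pairs = 500, ode_starts = 8) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              n_families = n_families, tips_per_family = tips_per_family,
              n_items = n_items, n_states = n_states, sim_rate = sim_rate,
              consensus_runs = consensus_runs, consensus_min = consensus_min,
              posterior_min = posterior_min,
              min_partitioned = min_partitioned, min_sites = min_sites,
              permutations = permutations, bernoulli_reps = bernoulli_reps,
              ode_variants = ode_variants, pair_rates = pair_rates,
              n_ode_pairs = n_ode_pairs, ode_starts = ode_starts)
  thr <- c(cfg$consensus_runs, cfg$consensus_min, cfg$posterior_min,
           cfg$min_partitioned, cfg$min_sites, cfg$permutations,
           cfg$bernoulli_reps)
  if (any(thr <= 0)) stop("all thresholds must be positive")
  if (any(cfg$pair_rates < 0)) stop("pair_rates must be nonnegative")
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML or JSON
#' @param path Config file (`.yaml`/`.yml` needs the yaml package).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs needs the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(vals$pair_rates)) vals$pair_rates <- unlist(vals$pair_rates)
  do.call(run_config, vals)
}

pipeline_stages <- c("simulate", "infer", "classify", "asymmetry", "ode",
                     "retention")

#' Run the analysis pipeline
#'
#' Executes the requested stages in order. With `stages` a subset, earlier
#' stage outputs are read back from `config$out_dir`, so precomputed inputs
#' can be reused. Every stochastic stage draws from the single RNG stream
#' seeded by `config$seed`, so identical config + seed gives identical
#' outputs. Any stage failure aborts the run naming the stage.
#'
#' @param config A [run_config()].
#' @param stages Which stages to run; default all.
#' @return Invisibly, a list of in-memory stage results plus the manifest.
#' @export
run_pipeline <- function(config, stages = pipeline_stages) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  res <- list()
  run_stage <- function(name, fun) {
    if (!name %in% stages) return(NULL)
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out <- function(f) file.path(config$out_dir, f)

  res$simulate <- run_stage("simulate", function() {
    Q <- build_rate_matrix(config$sim_rate, config$n_states, "ER")
    fams <- lapply(seq_len(config$n_families), function(i) {
      tr <- simulate_tree(config$tips_per_family)
      tr$tip.label <- paste0("f", i, "_", tr$tip.label)
      sim <- simulate_states_on_tree(tr, Q, config$n_items)
      list(tree = tr, sim = sim)
    })
    for (i in seq_along(fams)) {
      write_newick_tree(fams[[i]]$tree, out(sprintf("family_%03d.nwk", i)))
    }
    tips_all <- do.call(rbind, lapply(fams, function(f) f$sim$tips))
    write_state_matrix(tips_all, out("tip_states.tsv"))
    fates <- simulate_pair_fates(config$n_ode_pairs, config$pair_rates)
    write_tsv(fates, out("pair_fates.tsv"))
    items <- simulate_pair_items(config$n_ode_pairs, config$n_items,
                                 mode = "pair", rates = config$pair_rates)
    write_tsv(items$retention, out("pair_retention.tsv"))
    write_tsv(items$pairs, out("pair_ds.tsv"))
    feat <- simulate_group_feature_table()
    write_tsv(cbind(group = rownames(feat$features), feat$features),
              out("group_features.tsv"))
    write_tsv(cbind(feat$counts, odds = feat$odds), out("group_counts.tsv"))
    list(families = fams, fates = fates, items = items, feat = feat)
  })

  res$infer <- run_stage("infer", function() {
    fams <- if (!is.null(res$simulate)) res$simulate$families else {
      files <- sort(list.files(config$out_dir, "^family_.*\\.nwk$",
                               full.names = TRUE))
      tips_all <- read_state_matrix(out("tip_states.tsv"))
      lapply(files, function(f) {
        tr <- read_newick_tree(f)
        list(tree = tr,
             sim = list(tips = tips_all[tr$tip.label, , drop = FALSE]))
      })
    }
    calls <- do.call(rbind, lapply(seq_along(fams), function(i) {
      f <- fams[[i]]
      cc <- consensus_ancestral_calls(
        f$tree, f$sim$tips, type = "ER", n_states = config$n_states,
        nodes = length(f$tree$tip.label) + 1L,   # family root ancestor
        runs = config$consensus_runs, min_support = config$consensus_min,
        posterior_min = config$posterior_min)
      cbind(family = i, as.data.frame(cc))
    }))
    write_tsv(calls, out("ancestral_calls.tsv"))
    calls
  })

  res$classify <- run_stage("classify", function() {
    retention <- if (!is.null(res$simulate)) res$simulate$items$retention
      else read_tsv(out("pair_retention.tsv"))
    summ <- pair_expression_summary(retention, n_rep = config$permutations)
    write_tsv(data.frame(class = names(summ$observed),
                         observed = summ$observed, expected = summ$expected,
                         sd = summ$sd, z = summ$z),
              out("pair_state_summary.tsv"))
    cls <- classify_pairs(retention$pair, retention$item,
                          ancestral = 1L,
                          stateA = ifelse(retention$retA, 1L, 0L),
                          stateB = ifelse(retention$retB, 1L, 0L))
    write_tsv(cls, out("pair_item_classes.tsv"))
    list(summary = summ, classes = cls)
  })

  res$asymmetry <- run_stage("asymmetry", function() {
    cls <- if (!is.null(res$classify)) res$classify$classes
      else read_tsv(out("pair_item_classes.tsv"))
    part <- cls[cls$class == "I", ]
    agg <- aggregate(cbind(n = retained_by %in% c("A", "B"),
                           k_A = retained_by == "A") ~ pair,
                     data = part, FUN = sum)
    agg <- agg[agg$n >= config$min_partitioned, ]
    if (!nrow(agg)) stop("no pair passes the min_partitioned filter")
    rec <- asymmetry_records(agg$pair, agg$k_A, agg$n,
                             min_partitioned = config$min_partitioned)
    null <- grouped_bernoulli_null(rec$n, reps = config$bernoulli_reps,
                                   min_partitioned = config$min_partitioned)
    test <- compare_to_null(rec, null)
    write_tsv(rec, out("asymmetry.tsv"))
    jsonlite::write_json(
      list(observed_mean = test$observed_mean, null_mean = test$null_mean,
           p_welch = test$p_welch, ks_statistic = test$ks_statistic,
           p_ks = test$p_ks, n_pairs = test$n_pairs),
      out("asymmetry_null.json"), auto_unbox = TRUE, digits = NA)
    list(records = rec, null = null, test = test)
  })

  res$ode <- run_stage("ode", function() {
    fates <- if (!is.null(res$simulate)) res$simulate$fates
      else read_tsv(out("pair_fates.tsv"))
    fits <- lapply(config$ode_variants, function(v) {
      fit_ode(fates$class, fates$ds, variant = v, model = "pair",
              n_starts = config$ode_starts)
    })
    names(fits) <- config$ode_variants
    lrt <- NULL
    if (all(c("one", "four") %in% names(fits))) {
      lr <- likelihood_ratio_test(fits$one, fits$four)
      lrt <- data.frame(null = "one", alt = "four",
                        statistic = lr$statistic, df = lr$df, p = lr$p.value)
      write_tsv(lrt, out("ode_lrt.tsv"))
    }
    jsonlite::write_json(
      lapply(fits, function(f) list(variant = f$variant,
                                    rates = as.list(f$rates),
                                    loglik = f$loglik, df = f$df)),
      out("ode_fits.json"), auto_unbox = TRUE, digits = NA)
    list(fits = fits, lrt = lrt)
  })

  res$retention <- run_stage("retention", function() {
    if (!is.null(res$simulate)) {
      features <- res$simulate$feat$features
      odds <- res$simulate$feat$odds
    } else {
      features <- read_tsv(out("group_features.tsv"))
      rownames(features) <- features$group
      features$group <- NULL
      counts <- read_tsv(out("group_counts.tsv"))
      odds <- counts$odds
    }
    fit <- fit_retention_model(features, odds)
    loo <- leave_one_out_robustness(features, odds)
    jsonlite::write_json(
      list(selected = fit$selected, coefficients = as.list(fit$coefficients),
           r_squared = fit$r_squared, f_statistic = fit$f_statistic,
           p_value = fit$p_value),
      out("retention_model.json"), auto_unbox = TRUE, digits = NA)
    write_tsv(loo$parameters, out("retention_loo.tsv"))
    list(fit = fit, loo = loo)
  })

  manifest <- list(
    package = "dupdyn",
    version = as.character(utils::packageVersion("dupdyn")),
    seed = config$seed,
    stages = stages,
    thresholds = config[c("consensus_runs", "consensus_min", "posterior_min",
                          "min_partitioned", "min_sites", "permutations",
                          "bernoulli_reps")],
    sizes = config[c("n_families", "tips_per_family", "n_items", "n_states",
                     "n_ode_pairs")]
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
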