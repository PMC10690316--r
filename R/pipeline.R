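pipeline_stage_names <- c("simulate", "embed", "scca", "multicca", "coop",
                          "nestedcv", "cohort_table")

pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "multifuse_run",
    stages = c("simulate", "scca", "coop"),
    views = NULL,
    outcome = NULL,
    catalog = NULL,
    simulate = list(n = 200L, p = c(50L, 50L), K = 1L, sparsity = 5L,
                    snr = 1, outcome_strength = 2,
                    phylogeny = FALSE),
    embed = list(dim = 16L, window = 20L, epochs = 5L, min_count = 1L,
                 iqr_filter = TRUE),
    scca = list(grid = c(0.1, 0.3, 0.5, 0.7), n_permutations = 100L, k = 1L),
    multicca = list(grid = c(1.5, 2, 3), n_permutations = 100L),
    coop = list(rho = 0.1, alpha = 0.2, family = "binomial"),
    nestedcv = list(repeats = 3L, outer_folds = 5L, inner_folds = 5L,
                    alpha_grid = c(0.2, 1.0), rho_grid = c(0, 0.1, 0.5)),
    cohort_table = list(schema = NULL),
    log_level = "info"
  )
}

# scalar grids are a common hand-edit; promote them to vectors quietly
coerce_numeric_vector <- function(x) {
  if (is.null(x)) return(x)
  as.numeric(unlist(x))
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML (or already-parsed list) configuration, fills defaults,
#' coerces scalar grids to vectors, and rejects unknown keys by name.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated `run_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a list", call. = FALSE)
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  for (section in intersect(names(config), names(defaults))) {
    if (is.list(defaults[[section]]) && !is.null(names(defaults[[section]]))) {
      sub_unknown <- setdiff(names(config[[section]]), names(defaults[[section]]))
      if (length(sub_unknown) > 0L)
        stop(sprintf("unknown key(s) in '%s': %s", section,
                     paste(sub_unknown, collapse = ", ")), call. = FALSE)
    }
  }
  cfg <- utils::modifyList(defaults, config)
  cfg$seed <- as.integer(cfg$seed)
  cfg$stages <- as.character(unlist(cfg$stages))
  bad_stage <- setdiff(cfg$stages, pipeline_stage_names)
  if (length(bad_stage) > 0L)
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "), call. = FALSE)
  for (key in c("grid")) {
    cfg$scca[[key]] <- coerce_numeric_vector(cfg$scca[[key]])
    cfg$multicca[[key]] <- coerce_numeric_vector(cfg$multicca[[key]])
  }
  cfg$nestedcv$alpha_grid <- coerce_numeric_vector(cfg$nestedcv$alpha_grid)
  cfg$nestedcv$rho_grid <- coerce_numeric_vector(cfg$nestedcv$rho_grid)
  if (!is.null(cfg$views)) cfg$views <- as.character(unlist(cfg$views))
  structure(cfg, class = "run_config")
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

config_checksum <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

load_pipeline_views <- function(cfg) {
  if (!is.null(cfg$views)) {
    views <- lapply(cfg$views, read_feature_matrix)
    outcome <- if (!is.null(cfg$outcome)) read_outcome(cfg$outcome) else NULL
    align_views(views, outcome = outcome)
  } else {
    sim_files <- file.path(cfg$out_dir, sprintf("view%d.csv",
                                                seq_along(cfg$simulate$p)))
    if (!all(file.exists(sim_files)))
      stop("no input views: provide 'views' paths or run the simulate stage first",
           call. = FALSE)
    views <- lapply(sim_files, read_feature_matrix)
    ofile <- file.path(cfg$out_dir, "outcome.csv")
    outcome <- if (file.exists(ofile)) read_outcome(ofile) else NULL
    align_views(views, outcome = outcome)
  }
}

#' Run the multimodal fusion pipeline
#'
#' Executes the requested stages in canonical order (simulate, embed,
#' scca, multicca, coop, nestedcv, cohort_table), writing every artifact
#' as CSV/JSON under the configured output directory together with a
#' manifest (config checksum, seed, package version). All stage seeds are
#' derived from the single master seed, so a rerun with an identical
#' configuration is bit-identical.
#'
#' @param config Path to a YAML configuration or a list (see
#'   [validate_config()]).
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- pipeline_stage_names[pipeline_stage_names %in% cfg$stages]
  log_msg <- function(...) if (identical(cfg$log_level, "info")) message(sprintf(...))

  if ("simulate" %in% stages) {
    log_msg("stage simulate: n=%d, %d views", cfg$simulate$n, length(cfg$simulate$p))
    sc <- multiview_scenario(n = cfg$simulate$n, p = cfg$simulate$p,
                             K = cfg$simulate$K, sparsity = cfg$simulate$sparsity,
                             snr = cfg$simulate$snr,
                             outcome_strength = cfg$simulate$outcome_strength,
                             seed = derive_seed(cfg$seed, "simulate"))
    gen <- gen_multiview(sc)
    for (m in seq_along(gen$dataset$views))
      write_feature_matrix(gen$dataset$views[[m]],
                           file.path(cfg$out_dir, sprintf("view%d.csv", m)))
    utils::write.csv(data.frame(sample_id = gen$dataset$sample_ids,
                                outcome = gen$dataset$outcome),
                     file.path(cfg$out_dir, "outcome.csv"), row.names = FALSE)
    if (isTRUE(cfg$simulate$phylogeny)) {
      cat_out <- gen_phylogeny(phylogeny_scenario(
        seed = derive_seed(cfg$seed, "phylogeny")))
      write_mutation_catalog(cat_out, file.path(cfg$out_dir, "catalog.tsv"))
    }
  }

  if ("embed" %in% stages) {
    path <- if (!is.null(cfg$catalog)) cfg$catalog
            else file.path(cfg$out_dir, "catalog.tsv")
    if (!file.exists(path))
      stop("embed stage needs a mutation catalog (config key 'catalog')", call. = FALSE)
    cat_in <- read_mutation_catalog(path)
    if (isTRUE(cfg$embed$iqr_filter)) {
      flt <- iqr_filter(cat_in)
      log_msg("stage embed: removed %d outlier strain(s), %d kept",
              length(flt$removed), length(flt$catalog$strains))
      cat_in <- flt$catalog
    }
    emb <- train_skipgram(cat_in, d = cfg$embed$dim, window = cfg$embed$window,
                          epochs = cfg$embed$epochs,
                          min_count = cfg$embed$min_count,
                          seed = derive_seed(cfg$seed, "embed"))
    sv <- emb$strain_vectors
    utils::write.csv(data.frame(strain_id = rownames(sv), sv, check.names = FALSE),
                     file.path(cfg$out_dir, "strain_vectors.csv"), row.names = FALSE)
    proj <- mds_project(cosine_dissimilarity(sv),
                        seed = derive_seed(cfg$seed, "mds"))
    utils::write.csv(data.frame(strain_id = rownames(proj$coordinates),
                                x = proj$coordinates[, 1L],
                                y = proj$coordinates[, 2L]),
                     file.path(cfg$out_dir, "mds_projection.csv"), row.names = FALSE)
    write_json_file(list(stress = proj$stress, vocab = length(emb$vocab),
                         excluded = emb$excluded),
                    file.path(cfg$out_dir, "embed_summary.json"))
  }

  if (any(c("scca", "multicca", "coop", "nestedcv") %in% stages))
    ds <- load_pipeline_views(cfg)

  if ("scca" %in% stages) {
    sds <- standardize(ds)
    log_msg("stage scca: %d samples after alignment", length(sds$sample_ids))
    Xs <- view_matrices(sds)
    tune <- cca_permute(Xs[[1L]], Xs[[2L]], grid = cfg$scca$grid,
                        n_permutations = cfg$scca$n_permutations,
                        seed = derive_seed(cfg$seed, "scca"))
    fit <- sparse_cca(Xs[[1L]], Xs[[2L]], tune$best_l1[1L], tune$best_l1[2L],
                      K = cfg$scca$k)
    utils::write.csv(data.frame(
      l1_x = vapply(tune$grid, `[`, numeric(1L), 1L),
      l1_z = vapply(tune$grid, `[`, numeric(1L), 2L),
      zstat = tune$zstats, correlation = tune$correlations,
      nonzero_x = tune$nonzero[1L, ], nonzero_z = tune$nonzero[2L, ]),
      file.path(cfg$out_dir, "scca_tuning.csv"), row.names = FALSE)
    for (side in c("u", "v")) {
      w <- fit[[side]]
      utils::write.csv(data.frame(feature = rownames(w),
                                  component = rep(seq_len(ncol(w)), each = nrow(w)),
                                  coefficient = as.vector(w)),
                       file.path(cfg$out_dir, sprintf("scca_%s.csv", side)),
                       row.names = FALSE)
    }
    write_json_file(list(best_l1 = tune$best_l1, zstat = tune$zstats[tune$best],
                         pvalue = tune$pvalue,
                         correlation = fit$correlations,
                         nonzero = list(x = unname(fit$nonzero[1L, ]),
                                        z = unname(fit$nonzero[2L, ]))),
                    file.path(cfg$out_dir, "scca_summary.json"))
  }

  if ("multicca" %in% stages) {
    if (length(ds$views) < 3L) stop("multicca stage needs at least 3 views", call. = FALSE)
    sds <- standardize(ds)
    tune <- multi_cca_permute(sds, grid = cfg$multicca$grid,
                              n_permutations = cfg$multicca$n_permutations,
                              seed = derive_seed(cfg$seed, "multicca"))
    fit <- multi_cca(sds, penalties = tune$best_l1, K = 1L)
    write_json_file(list(best_penalties = tune$best_l1,
                         zstat = tune$zstats[tune$best], pvalue = tune$pvalue,
                         correlations = fit$correlations[[1L]][upper.tri(
                           fit$correlations[[1L]])]),
                    file.path(cfg$out_dir, "multicca_summary.json"))
  }

  if ("coop" %in% stages) {
    if (is.null(ds$outcome)) stop("coop stage needs an outcome", call. = FALSE)
    sds <- standardize(ds)
    fit <- fit_coop(sds, sds$outcome, rho = cfg$coop$rho,
                    alpha = cfg$coop$alpha, family = cfg$coop$family)
    cf <- coef(fit)
    utils::write.csv(data.frame(
      view = rep(names(cf), lengths(cf)),
      feature = unlist(lapply(sds$views, function(v) colnames(v$values))),
      coefficient = unlist(cf)),
      file.path(cfg$out_dir, "coop_coefficients.csv"), row.names = FALSE)
    pr <- predict(fit, sds)
    write_json_file(list(rho = cfg$coop$rho, alpha = cfg$coop$alpha,
                         family = cfg$coop$family,
                         lambda_min = min(fit$lambda),
                         train_auc = if (cfg$coop$family == "binomial")
                           auc(pr, sds$outcome) else NULL,
                         nonzero = sum(unlist(cf) != 0)),
                    file.path(cfg$out_dir, "coop_summary.json"))
  }

  if ("nestedcv" %in% stages) {
    if (is.null(ds$outcome)) stop("nestedcv stage needs an outcome", call. = FALSE)
    cvres <- nested_cv(ds, ds$outcome, cv_config(
      outer_folds = cfg$nestedcv$outer_folds,
      inner_folds = cfg$nestedcv$inner_folds,
      repeats = cfg$nestedcv$repeats,
      alpha_grid = cfg$nestedcv$alpha_grid,
      rho_grid = cfg$nestedcv$rho_grid,
      seed = derive_seed(cfg$seed, "nestedcv")))
    utils::write.csv(data.frame(repeat_id = seq_along(cvres$per_repeat_auc),
                                auc = cvres$per_repeat_auc,
                                accuracy = cvres$per_repeat_acc),
                     file.path(cfg$out_dir, "nestedcv_repeats.csv"),
                     row.names = FALSE)
    write_json_file(list(mean_auc = cvres$mean_auc, sd_auc = cvres$sd_auc,
                         mean_acc = cvres$mean_acc, sd_acc = cvres$sd_acc,
                         chosen = as.list(cvres$chosen_hyperparams)),
                    file.path(cfg$out_dir, "nestedcv_summary.json"))
  }

  if ("cohort_table" %in% stages) {
    if (is.null(cfg$cohort_table$schema))
      stop("cohort_table stage needs a schema", call. = FALSE)
    tab_path <- file.path(cfg$out_dir, "cohort.csv")
    if (!file.exists(tab_path))
      stop("cohort_table stage expects ", tab_path, call. = FALSE)
    df <- utils::read.csv(tab_path)
    tab <- build_cohort_table(df, "group", unlist(cfg$cohort_table$schema))
    write_cohort_table(tab, file.path(cfg$out_dir, "cohort_table.csv"))
  }

  write_json_file(list(config_checksum = config_checksum(cfg), seed = cfg$seed,
                       stages = stages,
                       package_version = as.character(utils::packageVersion("multifuse"))),
                  file.path(cfg$out_dir, "manifest.json"))
  invisible(cfg$out_dir)
}
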