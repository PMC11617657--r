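#' Default pipeline run configuration
#'
#' A nested list describing one reproducible run: either a synthetic
#' scenario (the default) or paths to the five input CSVs, stage toggles
#' and stage parameters. Can be serialized to/read from YAML.
#'
#' @param synthetic generate inputs with [simulate_study()] (TRUE) or read
#'   them from `paths`.
#' @param paths named list of input CSV paths (`design`, `traits`,
#'   `peaks`, `fitness`, `dilution`) when `synthetic = FALSE`.
#' @param seed global seed, fanned out deterministically to stages.
#' @param n_perm permutations for the CAP tests.
#' @param stages character vector of stages to run, in dependency order.
#' @param filter a [filter_config()]; `en` an [en_config()].
#' @param n_plants_per_subplot plants per subplot-year for the synthetic
#'   scenario.
#' @return list of class `run_config`.
#' @export
run_config <- function(synthetic = TRUE, paths = NULL, seed = 1L,
                       n_perm = 199L,
                       stages = c("volatiles", "cap", "fitness",
                                  "selection", "concordance"),
                       filter = filter_config(), en = en_config(),
                       n_plants_per_subplot = 5L) {
  if (!synthetic) {
    need <- c("design", "traits", "peaks", "fitness", "dilution")
    miss <- setdiff(need, names(paths))
    if (length(miss)) stop("paths must name: ",
                           paste(miss, collapse = ", "))
    absent <- !vapply(paths[need], file.exists, TRUE)
    if (any(absent)) stop("input file(s) not found: ",
                          paste(unlist(paths[need][absent]),
                                collapse = ", "))
  }
  structure(list(synthetic = synthetic, paths = paths,
                 seed = as.integer(seed), n_perm = as.integer(n_perm),
                 stages = stages, filter = filter, en = en,
                 n_plants_per_subplot = as.integer(n_plants_per_subplot)),
            class = "run_config")
}

#' Validate pipeline input tables
#'
#' Schema and invariant checks with row-level diagnostics: required
#' columns, the flower accounting identity, ambient samples without
#' plant ids, nonnegative peak areas. Returns a report; never errors.
#'
#' @param study list with `peak_table`, `fitness_components`,
#'   `trait_table`, `design` (e.g. a `simulated_study`).
#' @return data.frame `check`, `status`, `detail`.
#' @export
validate_inputs <- function(study) {
  rep_row <- function(check, status, detail = "") {
    data.frame(check = check, status = status, detail = detail,
               stringsAsFactors = FALSE)
  }
  out <- list()
  pk <- study$peak_table
  out[[length(out) + 1]] <- if (any(pk$peak_area < 0, na.rm = TRUE)) {
    rep_row("peak_area_nonnegative", "FAIL",
            paste(sum(pk$peak_area < 0), "negative areas"))
  } else rep_row("peak_area_nonnegative", "OK")
  amb_with_plant <- pk$sample_type == "ambient" & !is.na(pk$plant_id)
  out[[length(out) + 1]] <- if (any(amb_with_plant)) {
    rep_row("ambient_has_no_plant", "FAIL",
            paste("sample(s):",
                  paste(utils::head(unique(pk$sample_id[amb_with_plant]), 5),
                        collapse = ", ")))
  } else rep_row("ambient_has_no_plant", "OK")
  fl_plants <- unique(pk$plant_id[pk$sample_type == "floral"])
  known <- unique(study$trait_table$plant_id)
  orphan <- setdiff(fl_plants, known)
  out[[length(out) + 1]] <- if (length(orphan)) {
    rep_row("floral_sample_maps_to_plant", "FAIL",
            paste("plant(s):", paste(utils::head(orphan, 5),
                                     collapse = ", ")))
  } else rep_row("floral_sample_maps_to_plant", "OK")
  fc <- study$fitness_components
  id_ok <- tryCatch({check_components(fc); TRUE},
                    error = function(e) conditionMessage(e))
  out[[length(out) + 1]] <- if (isTRUE(id_ok)) {
    rep_row("flower_accounting_identity", "OK")
  } else rep_row("flower_accounting_identity", "FAIL", id_ok)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order (volatiles, then ordination
#' and class totals, fitness, selection, concordance), writes result CSVs
#' and a JSON run manifest (config hash, package version, per-stage row
#' counts, warnings, timing) to `outdir`.
#'
#' @param config a [run_config()].
#' @param outdir output directory.
#' @return the manifest, invisibly; results are also returned in
#'   `attr(, "results")`.
#' @export
run_pipeline <- function(config = run_config(), outdir = tempfile("run")) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  t0 <- Sys.time()
  warn <- character()
  wh <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warn <<- c(warn, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  manifest <- list(config_hash = digest::digest(unclass(config)),
                   package_version =
                     as.character(utils::packageVersion("scentselect")),
                   seed = config$seed, stages = list())
  res <- list()

  study <- if (config$synthetic) {
    simulate_study(seed = config$seed,
                   n_plants_per_subplot = config$n_plants_per_subplot)
  } else {
    read_study(config$paths)
  }
  res$validation <- validate_inputs(study)
  utils::write.csv(res$validation, file.path(outdir, "validation.csv"),
                   row.names = FALSE)

  if ("volatiles" %in% config$stages) {
    vp <- wh(volatile_pipeline(study$peak_table, study$dilution_series,
                               config$filter))
    res$volatiles <- vp
    utils::write.csv(vp$audit, file.path(outdir, "filter_audit.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(plant_id = rownames(vp$emissions),
                                vp$emissions, check.names = FALSE),
                     file.path(outdir, "emissions.csv"), row.names = FALSE)
    utils::write.csv(data.frame(plant_id = rownames(vp$class_totals),
                                vp$class_totals, check.names = FALSE),
                     file.path(outdir, "class_totals.csv"),
                     row.names = FALSE)
    manifest$stages$volatiles <- list(
      rows_in = nrow(study$peak_table),
      compounds_retained = length(vp$retained),
      plants = nrow(vp$emissions))
  }

  traits <- study$trait_table
  if ("cap" %in% config$stages && !is.null(res$volatiles)) {
    em <- res$volatiles$emissions
    keep <- rowSums(em) > 0
    em <- em[keep, , drop = FALSE]
    tr <- traits[match(rownames(em), traits$plant_id), ]
    d <- bray_curtis(transform_sqrt(em))
    pc <- pcoa(d)
    mod <- wh(cap_fit(pc, ~ factor(year) * snow_treatment *
                        precip_treatment, tr))
    pt <- sequential_perm_test(mod, n_perm = config$n_perm,
                               seed = child_seed(config$seed, "cap"))
    pt$percent_inertia <- percent_inertia(mod)$percent
    res$cap <- list(model = mod, tests = pt)
    utils::write.csv(pt, file.path(outdir, "cap_tests.csv"),
                     row.names = FALSE)
    if (!is.null(mod$species_scores)) {
      utils::write.csv(data.frame(compound = rownames(mod$species_scores),
                                  mod$species_scores, check.names = FALSE),
                       file.path(outdir, "cap_species_scores.csv"),
                       row.names = FALSE)
    }
    manifest$stages$cap <- list(n = nrow(em),
                                percent_inertia =
                                  percent_inertia(mod)$percent)
  }

  if ("fitness" %in% config$stages) {
    ft <- fitness_table(study$fitness_components)
    res$fitness <- ft
    utils::write.csv(ft, file.path(outdir, "fitness.csv"),
                     row.names = FALSE)
    manifest$stages$fitness <- list(plants = nrow(ft),
                                    missing = sum(is.na(ft$total_seeds)))
  }

  if ("selection" %in% config$stages && !is.null(res$volatiles) &&
        !is.null(res$fitness)) {
    sel <- wh(selection_stage(study, res, config))
    res$selection <- sel
    utils::write.csv(sel$univariate, file.path(outdir,
                                               "selection_univariate.csv"),
                     row.names = FALSE)
    utils::write.csv(sel$elastic_net, file.path(outdir,
                                                "selection_elastic_net.csv"),
                     row.names = FALSE)
    utils::write.csv(sel$env_effects, file.path(outdir,
                                                "env_fitness_effects.csv"),
                     row.names = FALSE)
    manifest$stages$selection <- list(traits = length(unique(
      sel$univariate$trait)))
  }

  if ("concordance" %in% config$stages && !is.null(res$selection)) {
    conc <- wh(concordance_stage(study, res))
    res$concordance <- conc
    utils::write.csv(conc$records, file.path(outdir, "concordance.csv"),
                     row.names = FALSE)
    utils::write.csv(conc$proportions,
                     file.path(outdir, "concordance_proportions.csv"),
                     row.names = FALSE)
    manifest$stages$concordance <- list(records = nrow(conc$records))
  }

  manifest$warnings <- warn
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  out <- manifest
  attr(out, "results") <- res
  invisible(out)
}

# univariate + elastic-net + class-model selection on the pipeline state
selection_stage <- function(study, res, config) {
  em <- res$volatiles$emissions
  traits <- study$trait_table
  tr <- traits[match(rownames(em), traits$plant_id), ]
  ft <- res$fitness[match(rownames(em), res$fitness$plant_id), ]
  sq <- transform_sqrt(em)
  elig <- eligible_volatiles(em, 0.75)
  morph <- intersect(morphology_catalog()$trait, names(tr))
  trait_mat <- cbind(sq[, elig, drop = FALSE],
                     as.matrix(tr[, morph, drop = FALSE]))
  measures <- c("rel_total_seeds", "rel_seeds_per_flower",
                "rel_escape_predation", "rel_eggs_per_flower")
  uni <- do.call(rbind, lapply(measures, function(m) {
    w <- ft[[m]]
    do.call(rbind, lapply(colnames(trait_mat), function(trn) {
      x <- trait_mat[, trn]
      ok <- stats::complete.cases(x, w)
      if (sum(ok) < 10 || stats::sd(x[ok]) == 0) return(NULL)
      z <- (x - mean(x[ok])) / stats::sd(x[ok])
      cbind(fitness_measure = m, trait = trn,
            univariate_env_selection(z[ok], w[ok], tr$snowmelt_date[ok],
                                     tr$summer_precip[ok]))
    }))
  }))
  en <- do.call(rbind, lapply(measures, function(m) {
    w <- ft[[m]]
    ok <- stats::complete.cases(trait_mat, w)
    if (sum(ok) < config$en$n_folds) return(NULL)
    zs <- standardize_traits(trait_mat[ok, , drop = FALSE])$z
    enr <- elastic_net_gradients(zs, w[ok],
                                 env = cbind(S = tr$snowmelt_date[ok],
                                             P = tr$summer_precip[ok]),
                                 config = config$en)
    cbind(fitness_measure = m, enr$coefficients)
  }))
  envf <- do.call(rbind, lapply(measures, function(m) {
    cbind(fitness_measure = m,
          env_fitness_effects(ft[[m]], tr$snowmelt_date,
                              tr$summer_precip))
  }))
  list(univariate = uni, elastic_net = en, env_effects = envf,
       trait_matrix = trait_mat, eligible = elig, aligned_traits = tr,
       aligned_fitness = ft)
}

# per-contrast concordance records over eligible traits (fly eggs
# excluded: a less direct fitness measure)
concordance_stage <- function(study, res) {
  sel <- res$selection
  tr <- sel$aligned_traits
  ft <- sel$aligned_fitness
  measures <- c("total_seeds", "seeds_per_flower", "escape_predation")
  contrasts <- list(
    list(factor = "snow_treatment", new = "early", control = "control",
         other = "precip_treatment"),
    list(factor = "precip_treatment", new = "reduced", control = "control",
         other = "snow_treatment"),
    list(factor = "precip_treatment", new = "addition",
         control = "control", other = "snow_treatment")
  )
  recs <- list()
  for (yr in unique(tr$year)) {
    dyr <- tr$year == yr
    for (ct in contrasts) {
      for (trn in colnames(sel$trait_matrix)) {
        d <- cbind(tr[dyr, ], .trait = sel$trait_matrix[dyr, trn])
        pl <- tryCatch(
          plasticity_fold_change(d, ".trait", ct$factor, ct$new,
                                 ct$control, ct$other),
          error = function(e) NULL)
        if (is.null(pl) || is.na(pl$fold_change)) next
        new_rows <- dyr & tr[[ct$factor]] == ct$new
        for (m in measures) {
          se <- selection_in_new_env(sel$trait_matrix[, trn],
                                     ft[[m]], new_rows)
          if (is.na(se$beta)) next
          cc <- classify_concordance(pl, se)
          recs[[length(recs) + 1]] <- cbind(
            year = yr, contrast = paste0(ct$factor, ":", ct$new),
            fitness_measure = m, cc,
            plast_significant = isTRUE(pl$significant),
            sel_significant = !is.na(se$p) & se$p < 0.05)
        }
      }
    }
  }
  records <- do.call(rbind, recs)
  list(records = records, proportions = proportion_test(records),
       stringent = stringent_summary(records))
}

#' Read a study from the five input CSVs
#'
#' @param paths named list/vector with `design`, `traits`, `peaks`,
#'   `fitness`, `dilution`.
#' @return list shaped like a `simulated_study` (without truth).
#' @export
read_study <- function(paths) {
  rd <- function(p) {
    if (!file.exists(p)) stop("input file not found: ", p)
    utils::read.csv(p, stringsAsFactors = FALSE)
  }
  design <- rd(paths$design)
  design$snow_treatment <- factor(design$snow_treatment,
                                  levels = c("control", "early"))
  pl <- unique(design$precip_treatment)
  design$precip_treatment <- factor(design$precip_treatment,
                                    levels = union("control", pl))
  traits <- rd(paths$traits)
  traits$snow_treatment <- factor(traits$snow_treatment,
                                  levels = levels(design$snow_treatment))
  traits$precip_treatment <- factor(traits$precip_treatment,
                                    levels =
                                      levels(design$precip_treatment))
  need_pk <- c("sample_id", "sample_type", "compound", "retention_time",
               "peak_area")
  pk <- rd(paths$peaks)
  miss <- setdiff(need_pk, names(pk))
  if (length(miss)) stop("peaks CSV lacks column(s): ",
                         paste(miss, collapse = ", "))
  list(design = design, trait_table = traits, peak_table = pk,
       fitness_components = rd(paths$fitness),
       dilution_series = rd(paths$dilution))
}

#' Read a YAML run configuration
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [run_config()]; `filter` and `en` sub-maps are passed to
#'   [filter_config()] / [en_config()].
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  flt <- do.call(filter_config, as.list(y$filter))
  enc <- do.call(en_config, as.list(y$en))
  y$filter <- NULL; y$en <- NULL
  do.call(run_config, c(y, list(filter = flt, en = enc)))
}
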