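# One-command pipeline: validate input, run AMMI + stability + GGE for
# the raw trait (and a derived RUE trait when rainfall metadata is
# supplied) and write all analysis tables as CSV plus a run log. Every
# number in the log also appears in a machine-readable table; CSVs carry
# full precision, rounding happens only in the log.

write_table <- function(x, dir, file) {
  readr::write_csv(tibble::as_tibble(x), file.path(dir, file))
}

run_trait <- function(data, out_root, n_axes, svp, log) {
  dir <- file.path(out_root, data$trait)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  fit <- fit_ammi(data)
  write_table(fit$anova, dir, "anova.csv")

  an <- fit$anova
  sn <- partition_signal_noise(
    ss_gei = an$ss[an$source == "GEI"],
    df_gei = an$df[an$source == "GEI"],
    ms_resid = an$ms[an$source == "Residuals"]
  )
  write_table(sn, dir, "signal_noise.csv")

  scores <- rbind(
    tibble::tibble(type = "genotype", name = rownames(fit$genotype_scores),
                   tibble::as_tibble(fit$genotype_scores)),
    tibble::tibble(type = "environment", name = rownames(fit$environment_scores),
                   tibble::as_tibble(fit$environment_scores))
  )
  write_table(scores, dir, "ipca_scores.csv")
  write_table(ammi1_coords(fit, data), dir, "ammi1_coords.csv")

  stab <- ssi_table(fit, data, n_axes = n_axes)
  write_table(stab, dir, "stability.csv")

  gge <- gge_fit(fit$means, svp = svp)
  gcoords <- rbind(
    tibble::tibble(type = "genotype", name = rownames(gge$genotype_coords),
                   tibble::as_tibble(gge$genotype_coords)),
    tibble::tibble(type = "environment", name = rownames(gge$environment_coords),
                   tibble::as_tibble(gge$environment_coords))
  )
  write_table(gcoords, dir, "gge_coords.csv")

  skipped <- character(0)
  www <- tryCatch(which_won_where(gge), error = function(e) e)
  if (inherits(www, "error")) {
    skipped <- c(skipped, paste("which_won_where:", conditionMessage(www)))
    www <- NULL
  } else {
    write_table(www$winners, dir, "www_winners.csv")
  }
  diag_tab <- tryCatch(discriminativeness_representativeness(gge),
                       error = function(e) e)
  if (inherits(diag_tab, "error")) {
    skipped <- c(skipped, paste("env_diagnostics:", conditionMessage(diag_tab)))
    diag_tab <- NULL
  } else {
    write_table(diag_tab, dir, "env_diagnostics.csv")
  }
  rank_tab <- tryCatch(ideal_genotype_ranking(gge), error = function(e) e)
  if (inherits(rank_tab, "error")) {
    skipped <- c(skipped, paste("genotype_ranking:", conditionMessage(rank_tab)))
    rank_tab <- NULL
  } else {
    write_table(rank_tab, dir, "genotype_ranking.csv")
  }

  log(sprintf("== trait: %s ==", data$trait))
  log(sprintf("design: %d genotypes x %d environments x %d replicates",
              data$g, data$e, data$r))
  log(sprintf("MASI axes N' = %d; theta = (%s)", attr(stab, "n_axes"),
              paste(sprintf("%.4f", attr(stab, "theta")), collapse = ", ")))
  pct <- an$pct_ss[match(c("Environment", "Genotype", "GEI"), an$source)]
  log(sprintf("%%SS: environment %.2f, genotype %.2f, GEI %.2f", pct[1], pct[2], pct[3]))
  log(sprintf("GEI signal %.2f%% / noise %.2f%%", sn$pct_signal, sn$pct_noise))
  log(sprintf("selected (lowest SSI): %s",
              paste(stab$genotype[stab$selected], collapse = ", ")))
  ties <- attr(stab, "ties")
  for (kind in names(ties)) {
    for (grp in ties[[kind]]) {
      log(sprintf("tie notice (%s): %s broken by input order", kind,
                  paste(stab$genotype[grp], collapse = " / ")))
    }
  }
  gge_pct <- gge$pct_explained
  log(sprintf("GGE 2-D view explains %.2f%% of G+GE (svp = %d)", gge_pct, svp))
  for (s in skipped) log(paste("skipped:", s))

  list(fit = fit, signal_noise = sn, stability = stab, gge = gge,
       www = www, env_diagnostics = diag_tab, genotype_ranking = rank_tab,
       skipped = skipped)
}

#' Run the full stability-analysis pipeline
#'
#' Validates a long-format trial file, runs AMMI ANOVA, the signal/noise
#' partition, IPCA scores, AMMI1 coordinates, MASI/SSI stability and all
#' four GGE analyses, and writes one CSV per table under
#' `out_dir/<trait>/` plus a `run_log.txt`. When environment metadata
#' with rainfall is supplied, the whole chain is repeated for the derived
#' rain-water-use-efficiency trait. Degenerate GGE geometry (e.g.
#' collinear genotype points on purely additive data) skips only the
#' affected view, with a notice in the log.
#'
#' @param input Path to the observations CSV, or a [met_dataset].
#' @param out_dir Output directory (created if needed).
#' @param trait Trait name for the raw input values.
#' @param env_meta Optional path to environment metadata CSV, or a data
#'   frame with `environment` and `rainfall_mm`.
#' @param include_rue Analyze derived RUE as a second trait (default:
#'   whenever `env_meta` is given).
#' @param n_axes IPCA axes used for MASI (default all).
#' @param svp Singular-value partition for GGE (default 2).
#' @param rue_scale Scale factor for RUE (default 1).
#' @param verbose Echo the run log to the console.
#' @return Invisibly, a named list of per-trait result bundles.
#' @export
run_pipeline <- function(input, out_dir, trait = "trait", env_meta = NULL,
                         include_rue = !is.null(env_meta), n_axes = NULL,
                         svp = 2, rue_scale = 1, verbose = TRUE) {
  data <- if (inherits(input, "met_dataset")) input else load_met(input, trait = trait)
  if (!is.null(env_meta) && !is.data.frame(env_meta)) {
    env_meta <- load_environment_meta(env_meta)
  } else if (!is.null(env_meta)) {
    env_meta <- validate_environment_meta(env_meta)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  lines <- character(0)
  log <- function(msg) {
    lines <<- c(lines, msg)
    if (verbose) message(msg)
  }
  log(sprintf("metstab %s | R %s", as.character(packageVersion("metstab")),
              paste(R.version$major, R.version$minor, sep = ".")))
  log(sprintf("input: %s", if (is.character(input)) input else "<met_dataset>"))
  log(sprintf("config: n_axes=%s svp=%d rue_scale=%g include_rue=%s",
              if (is.null(n_axes)) "all" else n_axes, svp, rue_scale, include_rue))

  results <- list()
  results[[data$trait]] <- run_trait(data, out_dir, n_axes, svp, log)
  if (include_rue) {
    if (is.null(env_meta)) {
      stop("metadata error: include_rue requires environment metadata", call. = FALSE)
    }
    rue_data <- derive_rue(data, env_meta, scale = rue_scale)
    results[[rue_data$trait]] <- run_trait(rue_data, out_dir, n_axes, svp, log)
  }
  writeLines(lines, file.path(out_dir, "run_log.txt"))
  invisible(results)
}
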