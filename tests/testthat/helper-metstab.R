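# Shared fixtures and independent oracles. The ANOVA oracle computes
# every sum of squares from its definition with nested loops, never
# touching the package's (aov-based) path.

# small balanced dataset from an explicit value array: values indexed
# [genotype, environment, replicate]
toy_met <- function(values, trait = "toy") {
  dims <- dim(values)
  obs <- expand.grid(genotype = sprintf("G%d", seq_len(dims[1])),
                     environment = sprintf("E%d", seq_len(dims[2])),
                     replicate = sprintf("R%d", seq_len(dims[3])),
                     stringsAsFactors = FALSE)
  obs$value <- values[cbind(match(obs$genotype, sprintf("G%d", seq_len(dims[1]))),
                            match(obs$environment, sprintf("E%d", seq_len(dims[2]))),
                            match(obs$replicate, sprintf("R%d", seq_len(dims[3]))))]
  met_dataset(obs, trait = trait)
}

rand_met <- function(g, e, r, seed, noise_sd = 1, k = NULL) {
  if (is.null(k)) k <- min(g - 1, e - 1)
  cfg <- synthetic_config(
    g = g, e = e, r = r, mu = 10, genotype_sd = 2, environment_sd = 3,
    gei_singular_values = if (k > 0) seq(k, 1) * 2 else numeric(0),
    rep_sd = 0.5, noise_sd = noise_sd, seed = seed
  )
  generate_met(cfg)
}

# from-definition ANOVA sums of squares for the RCBD-across-environments
# layout, by nested loops over the raw observations
oracle_anova_ss <- function(data) {
  df <- as.data.frame(data$data)
  gs <- data$genotypes; es <- data$environments; rs <- data$replicates
  y <- array(NA_real_, c(length(gs), length(es), length(rs)))
  for (row in seq_len(nrow(df))) {
    y[match(df$genotype[row], gs), match(df$environment[row], es),
      match(df$replicate[row], rs)] <- df$value[row]
  }
  g <- length(gs); e <- length(es); r <- length(rs)
  grand <- mean(y)
  env_m <- apply(y, 2, mean)            # over genotypes and reps
  gen_m <- apply(y, 1, mean)            # over environments and reps
  cell_m <- apply(y, c(1, 2), mean)     # over reps
  rep_m <- apply(y, c(2, 3), mean)      # env x rep means over genotypes

  ss_e <- 0
  for (j in seq_len(e)) ss_e <- ss_e + g * r * (env_m[j] - grand)^2
  ss_rep <- 0
  for (j in seq_len(e)) for (l in seq_len(r)) {
    ss_rep <- ss_rep + g * (rep_m[j, l] - env_m[j])^2
  }
  ss_g <- 0
  for (i in seq_len(g)) ss_g <- ss_g + e * r * (gen_m[i] - grand)^2
  ss_gei <- 0
  for (i in seq_len(g)) for (j in seq_len(e)) {
    ss_gei <- ss_gei + r * (cell_m[i, j] - gen_m[i] - env_m[j] + grand)^2
  }
  ss_res <- 0
  for (i in seq_len(g)) for (j in seq_len(e)) for (l in seq_len(r)) {
    ss_res <- ss_res + (y[i, j, l] - cell_m[i, j] - rep_m[j, l] + env_m[j])^2
  }
  c(Environment = ss_e, `Rep(Environment)` = ss_rep, Genotype = ss_g,
    GEI = ss_gei, Residuals = ss_res)
}

ref_anova <- function() {
  readr::read_csv(system.file("extdata", "groundnut_anova_reference.csv",
                              package = "metstab"),
                  show_col_types = FALSE)
}

ref_stability <- function() {
  readr::read_csv(system.file("extdata", "groundnut_stability_reference.csv",
                              package = "metstab"),
                  show_col_types = FALSE)
}
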