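# AMMI: ANOVA for the RCBD-across-environments layout, SVD of the
# doubly-centered interaction matrix, Gollob F-tests of the IPCA axes,
# %SS accounting, GEI signal/noise partition, and AMMI1 biplot
# coordinates.
#
# Conventions (fixed here, stated in the vignette):
#  * F for Environment uses the Rep(Environment) mean square as
#    denominator; every other effect (and each IPCA axis) is tested
#    against the pooled residual mean square.
#  * IPCA df follow Gollob: g + e - 1 - 2k.
#  * Reported IPCA scores use the symmetric singular-value partition
#    (singular-vector entry times sqrt(lambda)); raw singular vectors are
#    kept alongside.
#  * Each SVD axis is oriented so the genotype entry of largest
#    magnitude is positive, making output deterministic across
#    linear-algebra backends.

#' Gollob degrees of freedom for an IPCA axis
#'
#' @param g,e Numbers of genotypes and environments.
#' @param k Axis index, `1 <= k <= min(g - 1, e - 1)`.
#' @return The integer `g + e - 1 - 2k`.
#' @export
#' @examples
#' gollob_df(30, 3, 1)  # 30
#' gollob_df(30, 3, 2)  # 28
gollob_df <- function(g, e, k) {
  g <- as.integer(g); e <- as.integer(e); k <- as.integer(k)
  if (any(k < 1L) || any(k > min(g - 1L, e - 1L))) {
    stop("axis error: k must lie in 1..min(g-1, e-1) = 1..",
         min(g - 1L, e - 1L), call. = FALSE)
  }
  g + e - 1L - 2L * k
}

# interaction decomposition shared by fit_ammi() and ammi_anova():
# cell means, centered interaction matrix, sign-fixed SVD
ammi_decomp <- function(data) {
  m <- cell_means(data)
  mu <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  z <- sweep(sweep(m, 1, row_m), 2, col_m) + mu
  K <- min(data$g - 1L, data$e - 1L)
  sv <- svd(unclass(z))
  lambda <- sv$d[seq_len(K)]
  u <- sv$u[, seq_len(K), drop = FALSE]
  v <- sv$v[, seq_len(K), drop = FALSE]
  for (k in seq_len(K)) {
    s <- sign(u[which.max(abs(u[, k])), k])
    if (s < 0) { u[, k] <- -u[, k]; v[, k] <- -v[, k] }
  }
  dimnames(u) <- list(data$genotypes, paste0("PC", seq_len(K)))
  dimnames(v) <- list(data$environments, paste0("PC", seq_len(K)))
  theta <- if (sum(lambda^2) > 0) lambda^2 / sum(lambda^2) else rep(0, K)
  list(means = m, mu = mu,
       genotype_effects = setNames(row_m - mu, data$genotypes),
       environment_effects = setNames(col_m - mu, data$environments),
       z = unclass(z), K = K, lambda = lambda, u = u, v = v, theta = theta)
}

significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' AMMI analysis of variance
#'
#' ANOVA of a balanced RCBD multi-environment trial with the interaction
#' further partitioned into IPCA axes. Strata: Environment (df `e-1`,
#' tested against Rep(Environment)), Rep(Environment) (df `e(r-1)`),
#' Genotype (df `g-1`), GEI (df `(g-1)(e-1)`), one row per IPCA axis with
#' Gollob df `g+e-1-2k`, and Residuals (df `e(g-1)(r-1)`). Main-source
#' `pct_ss` is percent of the total SS; IPCA rows carry percent of the GEI
#' SS instead.
#'
#' @param data A [met_dataset].
#' @return A tibble of class `ammi_anova` with columns `source`, `df`,
#'   `ss`, `ms`, `f`, `p`, `sig` and `pct_ss`.
#' @export
ammi_anova <- function(data) {
  stopifnot(inherits(data, "met_dataset"))
  df <- as.data.frame(data$data)
  df$environment <- factor(df$environment, levels = data$environments)
  df$genotype <- factor(df$genotype, levels = data$genotypes)
  df$replicate <- factor(df$replicate, levels = data$replicates)

  fit <- aov(value ~ environment + environment:replicate + genotype +
               environment:genotype, data = df)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  pick <- function(name) {
    i <- match(name, rn)
    if (is.na(i)) stop("internal error: ANOVA stratum '", name, "' not found")
    c(df = tab[i, "Df"], ss = tab[i, "Sum Sq"])
  }
  strata <- list(
    Environment = pick("environment"),
    `Rep(Environment)` = pick("environment:replicate"),
    Genotype = pick("genotype"),
    GEI = pick("environment:genotype"),
    Residuals = pick("Residuals")
  )
  dec <- ammi_decomp(data)
  ss_pc <- data$r * dec$lambda^2
  df_pc <- gollob_df(data$g, data$e, seq_len(dec$K))

  src <- c("Environment", "Rep(Environment)", "Genotype", "GEI",
           paste0("PC", seq_len(dec$K)), "Residuals")
  dfs <- c(strata$Environment["df"], strata$`Rep(Environment)`["df"],
           strata$Genotype["df"], strata$GEI["df"], df_pc,
           strata$Residuals["df"])
  sss <- c(strata$Environment["ss"], strata$`Rep(Environment)`["ss"],
           strata$Genotype["ss"], strata$GEI["ss"], ss_pc,
           strata$Residuals["ss"])
  out <- tibble::tibble(source = src, df = as.integer(dfs), ss = as.numeric(sss))
  out$ms <- out$ss / out$df

  ms_rep <- out$ms[out$source == "Rep(Environment)"]
  ms_res <- out$ms[out$source == "Residuals"]
  df_res <- out$df[out$source == "Residuals"]
  df_rep <- out$df[out$source == "Rep(Environment)"]
  out$f <- NA_real_
  out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    s <- out$source[i]
    if (s == "Residuals") next
    if (s == "Environment") {
      out$f[i] <- out$ms[i] / ms_rep
      out$p[i] <- pf(out$f[i], out$df[i], df_rep, lower.tail = FALSE)
    } else {
      out$f[i] <- out$ms[i] / ms_res
      out$p[i] <- pf(out$f[i], out$df[i], df_res, lower.tail = FALSE)
    }
  }
  out$sig <- significance_stars(out$p)
  out <- percent_ss(out)
  class(out) <- c("ammi_anova", class(out))
  out
}

#' Fill in the percent-of-sum-of-squares column of an AMMI ANOVA
#'
#' Main sources (Environment, Rep(Environment), Genotype, GEI, Residuals)
#' are expressed as percent of their summed SS; IPCA (`PCk`) rows as
#' percent of the GEI SS. Percentages are computed unrounded; rounding is
#' left to the report layer.
#'
#' @param anova A data frame with at least `source` and `ss` columns.
#' @return The same table with a `pct_ss` column.
#' @export
percent_ss <- function(anova) {
  stopifnot(all(c("source", "ss") %in% names(anova)))
  is_pc <- grepl("^PC[0-9]+$", anova$source)
  total <- sum(anova$ss[!is_pc])
  ss_gei <- anova$ss[anova$source == "GEI"]
  anova$pct_ss <- NA_real_
  anova$pct_ss[!is_pc] <- 100 * anova$ss[!is_pc] / total
  if (any(is_pc)) {
    if (length(ss_gei) != 1) {
      stop("percent_ss: need exactly one GEI row to scale PC rows", call. = FALSE)
    }
    anova$pct_ss[is_pc] <- vapply(anova$ss[is_pc], ipca_pct_of_gei,
                                  numeric(1), ss_gei = ss_gei)
  }
  anova
}

#' Percent of the interaction sum of squares on one IPCA axis
#'
#' @param ss_pc SS attributed to the axis (`0 <= ss_pc <= ss_gei`).
#' @param ss_gei Total interaction SS.
#' @return `100 * ss_pc / ss_gei`, or `NA` with a warning when
#'   `ss_gei` is zero.
#' @export
#' @examples
#' ipca_pct_of_gei(409852, 471146)  # 86.99
ipca_pct_of_gei <- function(ss_pc, ss_gei) {
  if (ss_gei == 0) {
    warning("interaction SS is zero; axis share undefined")
    return(NA_real_)
  }
  if (ss_pc < 0 || ss_pc > ss_gei * (1 + 1e-8)) {
    stop("axis error: ss_pc must lie in [0, ss_gei]", call. = FALSE)
  }
  100 * ss_pc / ss_gei
}

#' Partition the interaction SS into signal and noise
#'
#' The noise part is estimated as `df_gei * ms_resid` (the SS a purely
#' random interaction stratum would accrue); the remainder is signal.
#' If the noise estimate exceeds the interaction SS it is clamped with a
#' warning.
#'
#' @param ss_gei Interaction sum of squares.
#' @param df_gei Interaction degrees of freedom (`(g-1)(e-1)`).
#' @param ms_resid Residual mean square.
#' @return A tibble with `ss_signal`, `ss_noise`, `pct_signal`,
#'   `pct_noise` (percent of the interaction SS).
#' @export
#' @examples
#' partition_signal_noise(471146, 58, 464)
partition_signal_noise <- function(ss_gei, df_gei, ms_resid) {
  stopifnot(ss_gei >= 0, df_gei >= 1, ms_resid >= 0)
  if (ss_gei == 0) {
    stop("partition undefined: interaction SS is zero", call. = FALSE)
  }
  ss_noise <- df_gei * ms_resid
  if (ss_noise > ss_gei) {
    warning("noise estimate exceeds interaction SS; clamping to ss_gei")
    ss_noise <- ss_gei
  }
  ss_signal <- ss_gei - ss_noise
  tibble::tibble(
    ss_signal = ss_signal,
    ss_noise = ss_noise,
    pct_signal = 100 * ss_signal / ss_gei,
    pct_noise = 100 * ss_noise / ss_gei
  )
}

#' Fit the AMMI model
#'
#' Decomposes the cell-mean matrix into grand mean, centered genotype and
#' environment main effects, and an SVD of the doubly-centered interaction
#' matrix `Z_ij = m_ij - rowmean_i - colmean_j + grandmean`. With all
#' `K = min(g-1, e-1)` axes retained the decomposition reconstructs every
#' cell mean exactly; `r * sum(lambda^2)` equals the interaction SS.
#'
#' @param data A [met_dataset].
#' @param anova Logical; also compute the [ammi_anova()] table
#'   (default `TRUE`).
#' @return An object of class `ammi_fit`: grand mean `mu`,
#'   `genotype_effects`, `environment_effects`, `singular_values`,
#'   symmetric-scaled `genotype_scores` / `environment_scores` (entries
#'   times `sqrt(lambda)`), raw `genotype_vectors` / `environment_vectors`,
#'   per-axis interaction shares `theta` (proportions summing to 1),
#'   `residual_matrix` (zero at full rank), `means`, and `anova`.
#' @export
fit_ammi <- function(data, anova = TRUE) {
  stopifnot(inherits(data, "met_dataset"))
  dec <- ammi_decomp(data)
  K <- dec$K
  scl <- diag(sqrt(dec$lambda), K)
  gscores <- dec$u %*% scl
  escores <- dec$v %*% scl
  dimnames(gscores) <- dimnames(dec$u)
  dimnames(escores) <- dimnames(dec$v)
  recon <- dec$u %*% diag(dec$lambda, K) %*% t(dec$v)
  structure(
    list(
      mu = dec$mu,
      genotype_effects = dec$genotype_effects,
      environment_effects = dec$environment_effects,
      singular_values = dec$lambda,
      genotype_scores = gscores,
      environment_scores = escores,
      genotype_vectors = dec$u,
      environment_vectors = dec$v,
      theta = dec$theta,
      residual_matrix = dec$z - recon,
      means = dec$means,
      g = data$g, e = data$e, r = data$r, K = K,
      trait = data$trait,
      anova = if (anova) ammi_anova(data) else NULL
    ),
    class = "ammi_fit"
  )
}

#' @export
print.ammi_fit <- function(x, ...) {
  cat("AMMI fit:", x$g, "genotypes x", x$e, "environments (r =", x$r, ")\n")
  cat("  grand mean:", format(x$mu, digits = 6), "\n")
  cat("  singular values:", paste(format(x$singular_values, digits = 5),
                                  collapse = ", "), "\n")
  cat("  interaction shares (theta):",
      paste(sprintf("%.2f%%", 100 * x$theta), collapse = ", "), "\n")
  if (!is.null(x$anova)) {
    cat("\n")
    print(as.data.frame(x$anova), digits = 4)
  }
  invisible(x)
}

#' AMMI1 biplot coordinates
#'
#' Marginal mean (abscissa) against IPCA1 score (ordinate) for genotypes
#' and environments, with the grand mean carried as the reference line.
#' IPCA1 scores of both kinds sum to zero by construction.
#'
#' @param fit An [fit_ammi()] result.
#' @param data The [met_dataset] the fit was computed on.
#' @return A tibble with columns `type` ("genotype"/"environment"),
#'   `name`, `mean` and `ipca1`; attribute `grand_mean`.
#' @export
ammi1_coords <- function(fit, data) {
  stopifnot(inherits(fit, "ammi_fit"), inherits(data, "met_dataset"))
  if (fit$g != data$g || fit$e != data$e ||
      !identical(names(fit$genotype_effects), data$genotypes)) {
    stop("fit and data do not match", call. = FALSE)
  }
  out <- tibble::tibble(
    type = c(rep("genotype", fit$g), rep("environment", fit$e)),
    name = c(data$genotypes, data$environments),
    mean = unname(c(fit$mu + fit$genotype_effects, fit$mu + fit$environment_effects)),
    ipca1 = unname(c(fit$genotype_scores[, 1], fit$environment_scores[, 1]))
  )
  attr(out, "grand_mean") <- fit$mu
  out
}
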