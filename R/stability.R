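# Stability layer: the modified AMMI stability index (MASI), integer
# ranking with documented tie handling, and the simultaneous selection
# index SSI = rank(MASI) + rank(mean).

#' Modified AMMI stability index
#'
#' `MASI_i = sqrt(sum_n PC_in^2 * theta_n^2)` over the first `N'` IPCA
#' axes, where `theta_n` is the share of the interaction SS explained by
#' axis `n`. Smaller values indicate more stable genotypes. Rescaling all
#' `theta` by a common constant rescales every MASI by that constant and
#' cannot change any rank-based output.
#'
#' @param scores Per-genotype IPCA score matrix (`g x N'`), or a vector
#'   for a single axis.
#' @param theta Per-axis interaction shares, length `N'`.
#' @return Nonnegative numeric vector of length `g`.
#' @export
#' @examples
#' masi(cbind(c(3, 0)), 1)            # single axis
#' masi(matrix(c(3, 4), 1), c(1, 1))  # 5
masi <- function(scores, theta) {
  scores <- as.matrix(scores)
  if (ncol(scores) != length(theta)) {
    stop("shape error: score matrix has ", ncol(scores),
         " axes but theta has length ", length(theta), call. = FALSE)
  }
  if (any(!is.finite(theta)) || any(theta < 0)) {
    stop("theta must be nonnegative and finite", call. = FALSE)
  }
  out <- sqrt(drop(scores^2 %*% theta^2))
  setNames(as.numeric(out), rownames(scores))
}

#' Integer ranks with input-order tie-breaking
#'
#' Rank 1 is the best value: the smallest for `direction = "ascending"`
#' (stability indices) or the largest for `"descending"` (trait means).
#' Tied values receive consecutive integer ranks, broken by input order;
#' tie groups are recorded in the `"ties"` attribute so reports can flag
#' them.
#'
#' @param values Numeric vector, all finite.
#' @param direction `"ascending"` or `"descending"`.
#' @return Integer ranks (a permutation of `1..length(values)`), with
#'   attribute `"ties"` listing index groups of tied input values.
#' @export
#' @examples
#' rank_values(c(5, 5, 1))                       # 2 3 1
#' rank_values(c(10, 30, 20), "descending")      # 3 1 2
rank_values <- function(values, direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  if (any(!is.finite(values))) {
    stop("rank error: all values must be finite", call. = FALSE)
  }
  key <- if (direction == "ascending") values else -values
  rk <- as.integer(rank(key, ties.method = "first"))
  dup <- unique(values[duplicated(values)])
  ties <- lapply(dup, function(v) which(values == v))
  attr(rk, "ties") <- ties[lengths(ties) > 1]
  rk
}

#' Stability ranking table from MASI and mean columns
#'
#' Combines a stability index column and a performance column into the
#' joint ranking: `r_masi` ranks MASI ascending (1 = most stable),
#' `r_mean` ranks the trait mean descending (1 = highest), and
#' `SSI = r_masi + r_mean`. The genotype(s) with the lowest SSI are
#' flagged as selected.
#'
#' @param genotypes Genotype identifiers.
#' @param masi Per-genotype MASI values.
#' @param means Per-genotype trait means across environments.
#' @return A tibble of class `stability_table` with columns `genotype`,
#'   `masi`, `r_masi`, `mean`, `r_mean`, `ssi`, `selected`; tie groups
#'   are carried in the `"ties"` attribute.
#' @export
stability_table <- function(genotypes, masi, means) {
  stopifnot(length(genotypes) == length(masi), length(masi) == length(means))
  r_masi <- rank_values(masi, "ascending")
  r_mean <- rank_values(means, "descending")
  ssi <- as.integer(r_masi + r_mean)
  out <- tibble::tibble(
    genotype = as.character(genotypes),
    masi = as.numeric(masi),
    r_masi = as.vector(r_masi),
    mean = as.numeric(means),
    r_mean = as.vector(r_mean),
    ssi = ssi,
    selected = ssi == min(ssi)
  )
  attr(out, "ties") <- list(masi = attr(r_masi, "ties"),
                            mean = attr(r_mean, "ties"))
  class(out) <- c("stability_table", class(out))
  out
}

#' Simultaneous selection table from an AMMI fit
#'
#' Computes MASI from the first `n_axes` IPCA axes of the fit (default:
#' all `K = min(g-1, e-1)` axes), the genotype marginal means (for a
#' balanced design these equal least-squares adjusted means), and the
#' SSI ranking.
#'
#' @param fit An [fit_ammi()] result.
#' @param data The [met_dataset] the fit was computed on.
#' @param n_axes Number of IPCA axes `N'` used for MASI (default all).
#' @return A [stability_table()] with attributes `trait`, `n_axes` and
#'   `theta` (the axis weights actually used).
#' @export
ssi_table <- function(fit, data, n_axes = NULL) {
  stopifnot(inherits(fit, "ammi_fit"), inherits(data, "met_dataset"))
  K <- fit$K
  if (is.null(n_axes)) n_axes <- K
  n_axes <- as.integer(n_axes)
  if (n_axes < 1L || n_axes > K) {
    stop("axis error: n_axes must lie in 1..", K, call. = FALSE)
  }
  scores <- fit$genotype_scores[, seq_len(n_axes), drop = FALSE]
  theta <- fit$theta[seq_len(n_axes)]
  m <- masi(scores, theta)
  means <- fit$mu + fit$genotype_effects
  out <- stability_table(data$genotypes, m[data$genotypes], means[data$genotypes])
  attr(out, "trait") <- data$trait
  attr(out, "n_axes") <- n_axes
  attr(out, "theta") <- theta
  out
}

#' @export
print.stability_table <- function(x, ...) {
  cat("Stability / simultaneous selection table")
  if (!is.null(attr(x, "trait"))) cat(" (", attr(x, "trait"), ")", sep = "")
  cat("\n")
  df <- as.data.frame(x)
  df$masi <- round(df$masi, 2)
  df$mean <- round(df$mean, 2)
  print(df, row.names = FALSE)
  sel <- x$genotype[x$selected]
  cat("selected (lowest SSI):", paste(sel, collapse = ", "), "\n")
  invisible(x)
}
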