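# GGE biplot computations as plain tables: environment-centered SVD with
# a chosen singular-value partition, which-won-where sectors from the
# genotype convex hull, mean-vs-stability projections on the average
# environment coordinate (AEC), environment discriminativeness /
# representativeness, and ideal-genotype ranking.
#
# Defaults follow the standard biplot conventions: data untransformed and
# unscaled, environment centering (centering = 2), column-metric
# preserving singular-value partition (svp = 2). Tie/boundary rules are
# explicit because biplot packages differ silently: boundary environment
# vectors go to the counter-clockwise sector, ranking ties break by
# input order.

#' Fit a GGE model (environment-centered SVD)
#'
#' Centers each environment column of the cell-mean matrix
#' (`centered_ij = mean_ij - colmean_j`, i.e. genotype main effect plus
#' interaction, G + GE) and takes its SVD. Under the column-metric
#' preserving partition (`svp = 2`) the singular values are assigned to
#' the environment coordinates; under `svp = 1` to the genotypes. The
#' rank-2 coordinate product is the same either way. Axis signs are fixed
#' by orienting each axis so its largest-magnitude genotype entry is
#' positive.
#'
#' @param means A `g x e` [cell_means()] matrix (or plain labelled
#'   matrix), `g >= 3`, `e >= 2`.
#' @param svp Singular-value partition: `2` (column-metric preserving,
#'   default) or `1` (row-metric preserving).
#' @return An object of class `gge_fit` with the centered matrix,
#'   `genotype_coords` (`g x 2`), `environment_coords` (`e x 2`), the full
#'   `singular_values`, `pct_explained` (percent of G+GE captured by the
#'   2-D view) and `svp`.
#' @export
gge_fit <- function(means, svp = 2) {
  m <- unclass(as.matrix(means))
  g <- nrow(m); e <- ncol(m)
  if (g < 3 || e < 2) {
    stop("design error: GGE needs at least 3 genotypes and 2 environments",
         call. = FALSE)
  }
  if (!svp %in% c(1, 2)) stop("svp must be 1 or 2", call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- sprintf("G%02d", seq_len(g))
  if (is.null(colnames(m))) colnames(m) <- sprintf("E%d", seq_len(e))
  centered <- sweep(m, 2, colMeans(m))
  if (max(abs(centered)) < 1e-12 * max(1, max(abs(m)))) {
    stop("degenerate error: environment-centered matrix is zero (no G or GE)",
         call. = FALSE)
  }
  sv <- svd(centered)
  d <- sv$d
  u <- sv$u[, 1:2, drop = FALSE]
  v <- sv$v[, 1:2, drop = FALSE]
  for (k in 1:2) {
    s <- sign(u[which.max(abs(u[, k])), k])
    if (s < 0) { u[, k] <- -u[, k]; v[, k] <- -v[, k] }
  }
  if (svp == 2) {
    gcoord <- u
    ecoord <- v %*% diag(d[1:2], 2)
  } else {
    gcoord <- u %*% diag(d[1:2], 2)
    ecoord <- v
  }
  dimnames(gcoord) <- list(rownames(m), c("axis1", "axis2"))
  dimnames(ecoord) <- list(colnames(m), c("axis1", "axis2"))
  structure(
    list(centered = centered,
         genotype_coords = gcoord,
         environment_coords = ecoord,
         singular_values = d,
         pct_explained = 100 * sum(d[1:2]^2) / sum(d^2),
         svp = svp),
    class = "gge_fit"
  )
}

#' @export
print.gge_fit <- function(x, ...) {
  cat("GGE fit:", nrow(x$genotype_coords), "genotypes x",
      nrow(x$environment_coords), "environments\n")
  cat("  SVP:", if (x$svp == 2) "column-metric preserving (2)" else "row-metric preserving (1)", "\n")
  cat(sprintf("  2-D view explains %.2f%% of G+GE\n", x$pct_explained))
  invisible(x)
}

# polar angle in [0, 2*pi)
.angle <- function(xy) {
  a <- atan2(xy[2], xy[1])
  if (a < 0) a <- a + 2 * pi
  a
}

#' Which-won-where sector analysis
#'
#' Builds the convex hull of the genotype points, draws sector boundary
#' rays from the origin perpendicular to the hull edges, and assigns each
#' environment to the hull vertex (winning genotype) maximizing the dot
#' product with its vector — equivalent to the sector containing the
#' environment. An environment exactly on a boundary is assigned to the
#' counter-clockwise sector.
#'
#' @param fit A [gge_fit()].
#' @param tol Relative tolerance for dot-product ties (boundary cases).
#' @return A list of class `www_result`: `hull_vertices` (genotype names,
#'   counter-clockwise), `winners` (tibble environment/winner), and
#'   `sector_boundaries` (tibble of boundary ray angles in radians).
#' @export
which_won_where <- function(fit, tol = 1e-9) {
  stopifnot(inherits(fit, "gge_fit"))
  gc <- fit$genotype_coords
  d <- fit$singular_values
  if (!is.null(d) && (d[1] == 0 || d[2] / d[1] < 1e-9)) {
    stop("geometry error: centered matrix is numerically rank 1 (singular value ",
         "ratio ", format(d[2] / max(d[1], 1e-300), digits = 3),
         "); the same genotype wins everywhere and sectors are undefined",
         call. = FALSE)
  }
  spread <- svd(sweep(gc, 2, colMeans(gc)))$d
  if (spread[1] == 0 || spread[2] / spread[1] < 1e-9) {
    stop("geometry error: genotype points are collinear or coincident ",
         "(planar spread ratio ", format(spread[2] / max(spread[1], 1e-300), digits = 3),
         "); which-won-where sectors are undefined", call. = FALSE)
  }
  hull_idx <- rev(grDevices::chull(gc))  # chull is clockwise; store CCW
  if (length(hull_idx) < 3) {
    stop("geometry error: genotype points are collinear or coincident (hull has ",
         length(hull_idx), " vertices); which-won-where sectors are undefined",
         call. = FALSE)
  }
  hv <- gc[hull_idx, , drop = FALSE]
  ec <- fit$environment_coords
  scale_ref <- max(abs(hv)) * max(1, max(abs(ec)))
  winners <- character(nrow(ec))
  for (j in seq_len(nrow(ec))) {
    d <- drop(hv %*% ec[j, ])
    mx <- max(d)
    tied <- which(d >= mx - tol * max(scale_ref, abs(mx)))
    if (length(tied) == 1L) {
      winners[j] <- rownames(hv)[tied]
    } else {
      # boundary: take the tied vertex on the counter-clockwise side of
      # the environment vector (smallest positive CCW angular offset)
      ea <- .angle(ec[j, ])
      offs <- vapply(tied, function(i) {
        da <- .angle(hv[i, ]) - ea
        if (da < 0) da <- da + 2 * pi
        da
      }, numeric(1))
      winners[j] <- rownames(hv)[tied[which.min(offs)]]
    }
  }
  n <- nrow(hv)
  edges <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  boundary <- t(apply(edges, 1, function(idx) {
    p1 <- hv[idx[1], ]; p2 <- hv[idx[2], ]
    edge <- p2 - p1
    ray <- c(-edge[2], edge[1])              # perpendicular to the edge
    if (sum(ray * (p1 + p2)) < 0) ray <- -ray  # point toward the edge
    c(angle = .angle(ray))
  }))
  structure(
    list(
      hull_vertices = rownames(hv),
      winners = tibble::tibble(environment = rownames(ec), winner = winners),
      sector_boundaries = tibble::tibble(
        from = rownames(hv)[edges[, 1]],
        to = rownames(hv)[edges[, 2]],
        angle = as.numeric(boundary)
      )
    ),
    class = "www_result"
  )
}

#' @export
print.www_result <- function(x, ...) {
  cat("Which-won-where: hull vertices", paste(x$hull_vertices, collapse = ", "), "\n")
  print(as.data.frame(x$winners), row.names = FALSE)
  invisible(x)
}

# unit AEC axis (direction of the mean environment vector)
aec_axis <- function(fit) {
  aec <- colMeans(fit$environment_coords)
  nrm <- sqrt(sum(aec^2))
  if (nrm < 1e-12 * max(1, max(abs(fit$environment_coords)))) {
    stop("AEC undefined error: average environment vector has zero length",
         call. = FALSE)
  }
  aec / nrm
}

#' Mean versus stability projections
#'
#' Projects every genotype point onto the average environment coordinate
#' (AEC) axis. The projection along the axis is the mean-performance
#' proxy; the absolute perpendicular component is the instability
#' measure. `aec_projection^2 + aec_deviation^2` equals the squared
#' distance of the point from the origin.
#'
#' @param fit A [gge_fit()].
#' @return A tibble with `genotype`, `aec_projection`, `aec_deviation`
#'   and `rank_projection` (1 = largest projection; ties by input order).
#' @export
mean_vs_stability <- function(fit) {
  stopifnot(inherits(fit, "gge_fit"))
  u <- aec_axis(fit)
  gc <- fit$genotype_coords
  proj <- drop(gc %*% u)
  perp <- gc - outer(proj, u)
  dev <- sqrt(rowSums(perp^2))
  tibble::tibble(
    genotype = rownames(gc),
    aec_projection = as.numeric(proj),
    aec_deviation = as.numeric(dev),
    rank_projection = as.vector(rank_values(proj, "descending"))
  )
}

#' Environment discriminativeness and representativeness
#'
#' Discriminativeness is the environment vector length; representativeness
#' is the cosine of its angle to the AEC axis. Environments are classified
#' with the package's operational thresholds (configurable): type-2
#' (long vector, small angle: best for selecting superior genotypes),
#' type-3 (long vector, wide angle: useful for culling unstable
#' genotypes), type-1 otherwise (short vector, average information).
#'
#' @param fit A [gge_fit()].
#' @param length_threshold Minimum vector length for type-2/3; default
#'   the median environment vector length.
#' @param max_angle Maximum angle (degrees) to the AEC for type-2;
#'   default 45.
#' @return A tibble with `environment`, `vector_length`,
#'   `cos_angle_to_aec`, `classification`, plus the thresholds used as
#'   attributes.
#' @export
discriminativeness_representativeness <- function(fit, length_threshold = NULL,
                                                  max_angle = 45) {
  stopifnot(inherits(fit, "gge_fit"))
  u <- aec_axis(fit)
  ec <- fit$environment_coords
  len <- sqrt(rowSums(ec^2))
  cosang <- ifelse(len > 0, drop(ec %*% u) / len, NA_real_)
  if (is.null(length_threshold)) length_threshold <- median(len)
  cos_min <- cos(max_angle * pi / 180)
  cls <- ifelse(len >= length_threshold & cosang >= cos_min, "type-2",
                ifelse(len >= length_threshold, "type-3", "type-1"))
  out <- tibble::tibble(
    environment = rownames(ec),
    vector_length = as.numeric(len),
    cos_angle_to_aec = as.numeric(cosang),
    classification = unname(cls)
  )
  attr(out, "length_threshold") <- length_threshold
  attr(out, "max_angle") <- max_angle
  out
}

#' Ideal-genotype ranking
#'
#' The ideal point lies on the AEC axis at the maximal genotype
#' projection (highest mean proxy, zero instability). Genotypes are
#' ranked by Euclidean distance to it (rank 1 = closest; ties by input
#' order).
#'
#' @param fit A [gge_fit()].
#' @return A tibble with `genotype`, `aec_projection`, `aec_deviation`,
#'   `distance_to_ideal` and `rank`; the ideal point is attached as the
#'   `"ideal_point"` attribute.
#' @export
ideal_genotype_ranking <- function(fit) {
  stopifnot(inherits(fit, "gge_fit"))
  u <- aec_axis(fit)
  ms <- mean_vs_stability(fit)
  ideal <- u * max(ms$aec_projection)
  gc <- fit$genotype_coords
  dist <- sqrt(rowSums(sweep(gc, 2, ideal)^2))
  out <- tibble::tibble(
    genotype = ms$genotype,
    aec_projection = ms$aec_projection,
    aec_deviation = ms$aec_deviation,
    distance_to_ideal = as.numeric(dist),
    rank = as.vector(rank_values(dist, "ascending"))
  )
  attr(out, "ideal_point") <- ideal
  out
}
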