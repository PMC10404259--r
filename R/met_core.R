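# Core trial container, long-format I/O, validation, cell means and
# derived traits. All downstream stages (AMMI, stability, GGE) consume
# the `met_dataset` built here; unbalanced data are rejected outright
# because every downstream degree of freedom presumes a complete layout.

#' Construct a multi-environment trial dataset
#'
#' Builds a validated balanced trial object from long-format observations.
#' The design must be complete: exactly one observation per
#' (genotype, environment, replicate) triple, with at least two genotypes,
#' two environments and two replicates. Genotype and environment order is
#' first-appearance order in `data`, so score tables downstream align with
#' the user's input; unbalanced data are rejected, never imputed.
#'
#' @param data A data frame with columns `genotype`, `environment`,
#'   `replicate` and `value` (one observation per row).
#' @param trait Name of the measured trait (e.g. `"pod_yield"`).
#' @param units Optional units string (e.g. `"g/m2"`).
#'
#' @return An object of class `met_dataset`: a list with the observation
#'   tibble (`$data`), `$trait`, `$units`, the ordered `$genotypes`,
#'   `$environments` and `$replicates`, and the counts `$g`, `$e`, `$r`.
#' @export
#' @examples
#' obs <- expand.grid(replicate = c("R1", "R2"), environment = c("E1", "E2"),
#'                    genotype = c("G1", "G2"))
#' obs$value <- 1:8
#' met_dataset(obs, trait = "toy")
met_dataset <- function(data, trait = "trait", units = NULL) {
  data <- as.data.frame(data)
  required <- c("genotype", "environment", "replicate", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("format error: missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(data$value)) {
    val <- suppressWarnings(as.numeric(as.character(data$value)))
    bad <- which(is.na(val) & !is.na(data$value))
    if (length(bad) > 0) {
      stop("parse error: non-numeric value in row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    data$value <- val
  }
  if (anyNA(data$value) || any(!is.finite(data$value))) {
    bad <- which(!is.finite(data$value))
    stop("parse error: missing or non-finite value in row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  for (key in c("genotype", "environment", "replicate")) {
    data[[key]] <- as.character(data[[key]])
    if (any(is.na(data[[key]]) | data[[key]] == "")) {
      stop("format error: empty ", key, " identifier", call. = FALSE)
    }
  }

  genotypes <- unique(data$genotype)
  environments <- unique(data$environment)
  replicates <- unique(data$replicate)
  g <- length(genotypes); e <- length(environments); r <- length(replicates)

  check_balance(data, genotypes, environments, replicates)
  if (g < 2 || e < 2 || r < 2) {
    stop("design error: need at least 2 genotypes, 2 environments and 2 replicates (got g=",
         g, ", e=", e, ", r=", r, ")", call. = FALSE)
  }

  structure(
    list(
      data = tibble::as_tibble(data[, required]),
      trait = trait,
      units = units,
      genotypes = genotypes,
      environments = environments,
      replicates = replicates,
      g = g, e = e, r = r
    ),
    class = "met_dataset"
  )
}

# one observation per triple, g*e*r rows; reports the offending triples
check_balance <- function(data, genotypes, environments, replicates) {
  key <- paste(data$genotype, data$environment, data$replicate, sep = "\r")
  expected <- expand.grid(genotype = genotypes, environment = environments,
                          replicate = replicates, stringsAsFactors = FALSE)
  exp_key <- paste(expected$genotype, expected$environment, expected$replicate,
                   sep = "\r")
  missing <- setdiff(exp_key, key)
  dup <- unique(key[duplicated(key)])
  fmt <- function(k) paste0("(", gsub("\r", ", ", k), ")")
  if (length(missing) > 0 || length(dup) > 0) {
    msg <- "balance error:"
    if (length(missing) > 0) {
      msg <- paste0(msg, " missing triple(s) ",
                    paste(fmt(utils::head(missing, 10L)), collapse = "; "))
    }
    if (length(dup) > 0) {
      msg <- paste0(msg, " duplicated triple(s) ",
                    paste(fmt(utils::head(dup, 10L)), collapse = "; "))
    }
    stop(msg, call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.met_dataset <- function(x, ...) {
  cat("Multi-environment trial dataset\n")
  cat("  trait: ", x$trait, if (!is.null(x$units)) paste0(" (", x$units, ")"), "\n", sep = "")
  cat("  ", x$g, " genotypes x ", x$e, " environments x ", x$r,
      " replicates = ", nrow(x$data), " observations\n", sep = "")
  cat("  environments: ", paste(x$environments, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read a multi-environment trial from CSV
#'
#' Expects a UTF-8 CSV with header `genotype,environment,replicate,value`,
#' one observation per row. Genotype/environment order is taken from first
#' appearance in the file.
#'
#' @param path Path to the CSV file.
#' @param trait Trait name to attach to the dataset.
#' @param units Optional units string.
#' @return A [met_dataset].
#' @export
load_met <- function(path, trait = "trait", units = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  met_dataset(raw, trait = trait, units = units)
}

#' Write a multi-environment trial to CSV
#'
#' Values are written in shortest round-trip notation, so a write/load
#' cycle reproduces the dataset to full floating-point precision.
#'
#' @param x A [met_dataset].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_met <- function(x, path) {
  stopifnot(inherits(x, "met_dataset"))
  readr::write_csv(x$data, path)
  invisible(path)
}

#' Read per-environment metadata (cumulative rainfall)
#'
#' @param path CSV with header `environment,rainfall_mm`; rainfall is the
#'   cumulative seeding-to-harvest rainfall in mm and must be positive.
#' @return A tibble with columns `environment` and `rainfall_mm`.
#' @export
load_environment_meta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- readr::read_csv(path, col_types = readr::cols(
    environment = readr::col_character(),
    rainfall_mm = readr::col_double()
  ), progress = FALSE)
  validate_environment_meta(meta)
}

#' @rdname load_environment_meta
#' @param meta A data frame with columns `environment` and `rainfall_mm`.
#' @export
validate_environment_meta <- function(meta) {
  meta <- tibble::as_tibble(meta)
  if (!all(c("environment", "rainfall_mm") %in% names(meta))) {
    stop("format error: environment metadata needs columns environment, rainfall_mm",
         call. = FALSE)
  }
  if (any(!is.finite(meta$rainfall_mm)) || any(meta$rainfall_mm <= 0)) {
    stop("metadata error: rainfall_mm must be positive and finite", call. = FALSE)
  }
  if (anyDuplicated(meta$environment)) {
    stop("metadata error: duplicated environment in metadata", call. = FALSE)
  }
  meta
}

#' Genotype-by-environment cell means
#'
#' Averages the `r` replicate observations in each (genotype, environment)
#' cell. The grand mean of the returned matrix equals the grand mean of the
#' observations (balanced design).
#'
#' @param x A [met_dataset].
#' @return A `g x e` matrix of class `cell_means` with genotypes as rows and
#'   environments as columns, carrying attributes `trait` and `r`.
#' @export
cell_means <- function(x) {
  stopifnot(inherits(x, "met_dataset"))
  m <- tapply(x$data$value,
              list(factor(x$data$genotype, levels = x$genotypes),
                   factor(x$data$environment, levels = x$environments)),
              mean)
  m <- matrix(m, nrow = x$g, ncol = x$e,
              dimnames = list(x$genotypes, x$environments))
  structure(m, class = c("cell_means", class(m)), trait = x$trait, r = x$r)
}

#' Write a cell-means matrix to CSV
#'
#' @param m A `cell_means` matrix (genotypes as rows).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_means <- function(m, path) {
  df <- tibble::as_tibble(unclass(m), rownames = "genotype")
  readr::write_csv(df, path)
  invisible(path)
}

#' Rain-water-use efficiency
#'
#' Yield per millimetre of cumulative in-season rainfall, optionally
#' rescaled: `scale * yield / rainfall`. With `scale = 1` this is the
#' definition exactly as usually printed (g/m2 per mm).
#'
#' @param yield_value Trait value(s), e.g. pod yield in g/m2.
#' @param rainfall Cumulative rainfall in mm (positive).
#' @param scale Positive scale factor (default 1).
#' @return Numeric RUE value(s).
#' @export
#' @examples
#' rue(100, 250)          # 0.4
#' rue(114, 228, scale = 100)  # 50
rue <- function(yield_value, rainfall, scale = 1) {
  if (any(!is.finite(rainfall)) || any(rainfall <= 0)) {
    stop("metadata error: rainfall must be positive", call. = FALSE)
  }
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    stop("scale must be a single positive number", call. = FALSE)
  }
  scale * yield_value / rainfall
}

#' Derive a rain-water-use-efficiency dataset
#'
#' Applies [rue()] per observation, dividing each value by its
#' environment's cumulative rainfall, and returns a new balanced dataset
#' with the same keys. Being a positive per-environment rescaling, this
#' preserves genotype rank order within every environment.
#'
#' @param x A [met_dataset] of yield observations.
#' @param env_meta Environment metadata as returned by
#'   [load_environment_meta()] (must cover every environment in `x`).
#' @param scale Positive scale factor passed to [rue()].
#' @return A [met_dataset] with trait `"RUE"`.
#' @export
derive_rue <- function(x, env_meta, scale = 1) {
  stopifnot(inherits(x, "met_dataset"))
  env_meta <- validate_environment_meta(env_meta)
  missing_env <- setdiff(x$environments, env_meta$environment)
  if (length(missing_env) > 0) {
    stop("metadata error: no rainfall for environment(s): ",
         paste(missing_env, collapse = ", "), call. = FALSE)
  }
  rain <- setNames(env_meta$rainfall_mm, env_meta$environment)
  out <- x$data
  out$value <- rue(out$value, rain[out$environment], scale = scale)
  met_dataset(out, trait = "RUE",
              units = if (scale == 1) "g/m2/mm" else paste0("g/m2/mm x ", scale))
}
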