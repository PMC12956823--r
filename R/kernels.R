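#' Kernel configuration for the spatial Gaussian process
#'
#' Distances between societies are great-circle (Haversine) distances,
#' normalized to `[0, 1]` by the maximum pairwise distance in the sample;
#' `rho` is the Matern 3/2 decay length on that normalized scale. The
#' smallest value typically used, 0.02, corresponds to covariance that is
#' strong within roughly an overnight sailing voyage (~160 km) and
#' essentially zero beyond ~1000 km on a Pacific-wide sample.
#'
#' @param rho Positive decay length on the normalized-distance scale.
#' @param sigma_sq Marginal variance; 1 for use as a correlation matrix.
#' @param earth_radius_km Radius of the spherical Earth model.
#' @return A `kernel_config` list.
#' @export
kernel_config <- function(rho = 0.02, sigma_sq = 1, earth_radius_km = 6371) {
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0) {
    ct_config_error("rho must be a single positive number")
  }
  if (!is.numeric(sigma_sq) || length(sigma_sq) != 1L || sigma_sq <= 0) {
    ct_config_error("sigma_sq must be a single positive number")
  }
  structure(list(rho = rho, sigma_sq = sigma_sq,
                 earth_radius_km = earth_radius_km),
            class = "kernel_config")
}

#' Haversine great-circle distance matrix
#'
#' @param table A [society_table] with valid coordinates.
#' @param earth_radius_km Sphere radius.
#' @return Symmetric matrix of distances in km, labelled by society id.
#' @export
haversine_matrix <- function(table, earth_radius_km = 6371) {
  stopifnot(inherits(table, "society_table"))
  miss <- which(is.na(table$latitude) | is.na(table$longitude))
  if (length(miss) > 0L) {
    ct_validation_error(paste0("missing coordinates for society ",
      paste(table$society_id[miss], collapse = ", ")))
  }
  lat <- table$latitude * pi / 180
  lon <- table$longitude * pi / 180
  n <- length(lat)
  dlat <- outer(lat, lat, "-")
  dlon <- outer(lon, lon, "-")
  a <- sin(dlat / 2)^2 + outer(cos(lat), cos(lat)) * sin(dlon / 2)^2
  a <- pmin(pmax(a, 0), 1)
  D <- 2 * earth_radius_km * asin(sqrt(a))
  diag(D) <- 0
  dimnames(D) <- list(table$society_id, table$society_id)
  D
}

#' Normalize a distance matrix to the unit interval
#'
#' Divides by the maximum pairwise distance in the current sample, so the
#' largest entry maps exactly to 1. A monotone transform: the ordering of
#' distances is preserved.
#'
#' @param D Symmetric nonnegative distance matrix.
#' @return The normalized matrix.
#' @export
normalize_distances <- function(D) {
  if (any(D < 0)) ct_validation_error("distance matrix has negative entries")
  m <- max(D)
  if (m <= 0) ct_numeric_error("degenerate distance matrix: all zero")
  D / m
}

#' Matern 3/2 covariance function
#'
#' `k(d) = sigma_sq * (1 + sqrt(3) d / rho) * exp(-sqrt(3) d / rho)`;
#' `k(0) = sigma_sq`, strictly decreasing in `d`.
#'
#' @param d Nonnegative distance(s), typically on the normalized scale.
#' @param cfg A [kernel_config].
#' @return Covariance value(s), same shape as `d`.
#' @export
matern32 <- function(d, cfg = kernel_config()) {
  stopifnot(inherits(cfg, "kernel_config"))
  if (any(d < 0)) ct_validation_error("matern32 requires nonnegative distances")
  s <- sqrt(3) * d / cfg$rho
  cfg$sigma_sq * (1 + s) * exp(-s)
}

#' Spatial covariance specification for a society sample
#'
#' Haversine distances, max-normalized, pushed through the Matern 3/2
#' kernel. A diagonal jitter is added before any factorization downstream.
#'
#' @param table A [society_table].
#' @param cfg A [kernel_config].
#' @return A `covariance_spec` of kind `"spatial"`.
#' @export
spatial_covariance <- function(table, cfg = kernel_config()) {
  D <- haversine_matrix(table, earth_radius_km = cfg$earth_radius_km)
  K <- matern32(normalize_distances(D), cfg)
  covariance_spec(K, kind = "spatial")
}

#' Phylogenetic correlation matrix from a rooted tree
#'
#' Entry (i, j) is the shared root-to-tip path length of tips i and j
#' divided by the geometric mean of their root-to-tip depths, i.e. the
#' standard conversion of the phylogenetic variance-covariance matrix to a
#' correlation matrix. For ultrametric trees this is shared depth over total
#' depth; the geometric-mean scaling keeps the diagonal exactly 1 on
#' non-ultrametric trees (posterior language trees need not be ultrametric).
#'
#' @param tree A rooted `phylo` with nonnegative branch lengths.
#' @return A `covariance_spec` of kind `"phylogenetic"`.
#' @export
phylo_correlation <- function(tree) {
  if (!inherits(tree, "phylo")) ct_validation_error("tree must be a phylo")
  if (!ape::is.rooted(tree)) ct_validation_error("tree must be rooted")
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  if (any(depths <= 0)) {
    ct_numeric_error(paste0("zero root-to-tip depth for tip ",
      paste(tree$tip.label[depths <= 0], collapse = ", ")))
  }
  K <- ape::vcv(tree, corr = TRUE)
  diag(K) <- 1
  covariance_spec(K, kind = "phylogenetic")
}

#' Construct a validated covariance specification
#'
#' @param matrix Symmetric positive-semidefinite matrix with dimnames.
#' @param kind `"spatial"` or `"phylogenetic"`.
#' @param check_psd Verify the smallest eigenvalue is above `-1e-8`.
#' @return A `covariance_spec`: list with `labels`, `matrix`, `kind`.
#' @export
covariance_spec <- function(matrix, kind = c("spatial", "phylogenetic"),
                            check_psd = TRUE) {
  kind <- match.arg(kind)
  if (!isSymmetric(unname(matrix), tol = 1e-8)) {
    ct_validation_error("covariance matrix is not symmetric")
  }
  matrix <- (matrix + t(matrix)) / 2
  if (check_psd) {
    ev <- min(eigen(matrix, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8) {
      ct_numeric_error(paste0("covariance matrix is not PSD (min eigenvalue ",
                              format(ev), ")"))
    }
  }
  labels <- rownames(matrix) %||% as.character(seq_len(nrow(matrix)))
  structure(list(labels = labels, matrix = matrix, kind = kind),
            class = "covariance_spec")
}

#' @export
print.covariance_spec <- function(x, ...) {
  cat("covariance_spec:", x$kind, "-", nrow(x$matrix), "x", ncol(x$matrix), "\n")
  invisible(x)
}

# Lower Cholesky factor with escalating diagonal jitter (starting at 1e-9).
chol_jitter <- function(K, jitter = 1e-9, max_tries = 6L) {
  for (i in seq_len(max_tries)) {
    L <- tryCatch(t(chol(K + diag(jitter, nrow(K)))), error = function(e) NULL)
    if (!is.null(L)) return(L)
    jitter <- jitter * 100
  }
  ct_numeric_error("Cholesky factorization failed even with jitter")
}

# Align a covariance_spec to a vector of society ids (subset + reorder).
align_cov <- function(cov, ids) {
  idx <- match(ids, cov$labels)
  if (anyNA(idx)) {
    ct_alignment_error(paste0("covariance matrix lacks label(s): ",
      paste(ids[is.na(idx)], collapse = ", ")))
  }
  cov$matrix[idx, idx, drop = FALSE]
}

#' Write a labelled covariance matrix as CSV
#'
#' @param cov A `covariance_spec`.
#' @param path Output path.
#' @export
write_covariance <- function(cov, path) {
  stopifnot(inherits(cov, "covariance_spec"))
  df <- data.frame(label = cov$labels, cov$matrix, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
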