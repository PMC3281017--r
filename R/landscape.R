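## Synthetic landscape: grid municipalities, district blocks, Gaussian-field
## covariates, road lengths, district adjacency graph.

#' Generate a synthetic municipality landscape
#'
#' Lays out municipalities on a rectangular grid (one cell = one
#' municipality, centroid = cell center), partitions them into square
#' game-management districts, draws spatially autocorrelated environmental
#' covariates (scaled to [0, 1] by a probability integral transform of
#' Gaussian random fields), assigns lognormal road lengths per category
#' (with structural zeros), flags one contiguous block of districts as
#' red-deer management districts, and returns the rook-adjacency graph of
#' districts.
#'
#' Browsing-intensity covariates are constant within a district: they are
#' the true district-level browsing proportions, from which
#' \code{\link{simulate_browsing_survey}} later draws binomial counts.
#'
#' @param config a \code{\link{landscape_config}} object.
#' @return A list of class \code{"dvc_landscape"} with components
#'   \item{munis}{municipality table: \code{muni_id}, \code{centroid_x},
#'     \code{centroid_y}, \code{district_id}, \code{red_deer}, one
#'     \code{len_<road_type>} column per category (km; 0 = road type
#'     absent) and the 23 covariate columns.}
#'   \item{graph}{district graph of class \code{"district_graph"}:
#'     \code{nodes}, \code{edges} (two-column data frame), district
#'     \code{centroids}, and the true browsing logits per district and
#'     class (attribute \code{browsing_truth}).}
#' @examples
#' land <- generate_landscape(landscape_config(grid_rows = 4, grid_cols = 4,
#'                                             district_block = 2))
#' head(land$munis[, 1:6])
#' land$graph$edges
#' @export
generate_landscape <- function(config) {
  validate_config(config)
  nr <- config$grid_rows; nc <- config$grid_cols; b <- config$district_block
  n <- nr * nc
  row <- rep(seq_len(nr), each = nc)
  col <- rep(seq_len(nc), times = nr)
  munis <- data.frame(
    muni_id = sprintf("m%04d", seq_len(n)),
    centroid_x = col - 0.5,
    centroid_y = row - 0.5)
  drow <- (row - 1L) %/% b + 1L
  dcol <- (col - 1L) %/% b + 1L
  ndc <- nc %/% b
  dix <- (drow - 1L) * ndc + dcol
  munis$district_id <- sprintf("d%03d", dix)

  ## red-deer districts: one contiguous corner block (about 1/9 of the map)
  ndr <- nr %/% b
  red_rows <- seq_len(max(1L, ceiling(ndr / 3)))
  red_cols <- seq_len(max(1L, ceiling(ndc / 3)))
  munis$red_deer <- drow %in% red_rows & dcol %in% red_cols

  with_seed(stream_seed(config$seed, "landscape"), {
    ## road lengths: lognormal per type, structural zeros with p_no_road
    for (rt in road_types()) {
      pars <- config$road_length_params[
        config$road_length_params$road_type == rt, ]
      len <- stats::rlnorm(n, pars$meanlog, pars$sdlog)
      len[stats::runif(n) < config$p_no_road[[rt]]] <- 0
      munis[[paste0("len_", rt)]] <- len
    }
    ## covariates: smooth Gaussian field + nugget, mapped to [0, 1]
    L <- grf_chol(munis$centroid_x, munis$centroid_y,
                  range = config$covariate_spatial_range)
    nug <- config$covariate_nugget
    for (v in c(climate_vars(), landuse_vars())) {
      z <- sqrt(1 - nug) * drop(L %*% stats::rnorm(n)) +
        sqrt(nug) * stats::rnorm(n)
      munis[[v]] <- stats::pnorm(z)
    }
    ## district-level browsing truth (smooth field on district centroids)
    graph <- district_graph(munis)
    D <- length(graph$nodes)
    Ld <- grf_chol(graph$centroids$x / b, graph$centroids$y / b,
                   range = config$browsing_spatial_range)
    bp <- config$browsing_params
    truth_logit <- matrix(NA_real_, D, length(browsing_classes()),
                          dimnames = list(graph$nodes, browsing_classes()))
    for (cl in browsing_classes()) {
      pars <- bp[bp$class == cl, ]
      field <- drop(Ld %*% stats::rnorm(D))
      truth_logit[, cl] <- pars$base_logit + pars$amplitude * field +
        config$browsing_nugget_sd * stats::rnorm(D)
    }
  })
  graph$browsing_truth <- truth_logit
  ## municipality browsing covariates = true district proportions
  di <- match(munis$district_id, graph$nodes)
  for (cl in browsing_classes())
    munis[[cl]] <- stats::plogis(truth_logit[di, cl])

  structure(list(munis = munis, graph = graph, config = config),
            class = "dvc_landscape")
}

## Cholesky factor of a squared-exponential covariance over given points;
## realizations are smooth surfaces (roughness comes only from the
## explicit nugget mixed in by the caller).
grf_chol <- function(x, y, range) {
  d <- as.matrix(stats::dist(cbind(x, y)))
  C <- exp(-(d / range)^2 / 2)
  t(chol(C + diag(1e-6, nrow(C))))
}

#' Rook-adjacency graph of districts
#'
#' @param munis a municipality table with \code{district_id},
#'   \code{centroid_x}, \code{centroid_y}.
#' @return Object of class \code{"district_graph"}: \code{nodes} (district
#'   ids), \code{edges} (data frame \code{from}, \code{to}, each unordered
#'   pair once, no self-loops) and district \code{centroids}.
#' @export
district_graph <- function(munis) {
  cx <- tapply(munis$centroid_x, munis$district_id, mean)
  cy <- tapply(munis$centroid_y, munis$district_id, mean)
  nodes <- sort(unique(munis$district_id))
  cx <- cx[nodes]; cy <- cy[nodes]
  ## block grid positions from ranked centroid coordinates
  px <- match(cx, sort(unique(cx)))
  py <- match(cy, sort(unique(cy)))
  from <- character(0); to <- character(0)
  for (i in seq_along(nodes)) {
    nb <- which((abs(px - px[i]) + abs(py - py[i])) == 1L)
    nb <- nb[nb > i]
    from <- c(from, rep(nodes[i], length(nb)))
    to <- c(to, nodes[nb])
  }
  structure(list(nodes = nodes,
                 edges = data.frame(from = from, to = to,
                                    stringsAsFactors = FALSE),
                 centroids = data.frame(district_id = nodes,
                                        x = as.numeric(cx),
                                        y = as.numeric(cy))),
            class = "district_graph")
}

#' Moran's I spatial autocorrelation
#'
#' Moran's I of a variable observed on areal units with binary neighbour
#' weights. Used to verify that generated covariate surfaces are spatially
#' autocorrelated.
#'
#' @param x numeric vector.
#' @param W binary (or general nonnegative) weight matrix, zero diagonal.
#' @return Moran's I statistic.
#' @export
morans_i <- function(x, W) {
  stopifnot(length(x) == nrow(W), nrow(W) == ncol(W))
  z <- x - mean(x)
  n <- length(x)
  (n / sum(W)) * drop(crossprod(z, W %*% z)) / sum(z^2)
}

#' @rdname morans_i
#' @param munis municipality table on the generator's grid; builds the rook
#'   weight matrix of grid cells.
#' @export
grid_rook_weights <- function(munis) {
  n <- nrow(munis)
  W <- matrix(0, n, n)
  dx <- outer(munis$centroid_x, munis$centroid_x, function(a, b) abs(a - b))
  dy <- outer(munis$centroid_y, munis$centroid_y, function(a, b) abs(a - b))
  W[dx + dy == 1] <- 1
  W
}

#' @export
print.dvc_landscape <- function(x, ...) {
  cat(sprintf("Synthetic landscape: %d municipalities, %d districts (%d red deer)\n",
              nrow(x$munis), length(x$graph$nodes),
              length(unique(x$munis$district_id[x$munis$red_deer]))))
  invisible(x)
}

#' @export
print.district_graph <- function(x, ...) {
  cat(sprintf("District graph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}
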