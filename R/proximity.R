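# Fixed-radius neighborhood statistics. The implementation uses a k-d
# tree (RANN) with adaptive k; neighborhoods are closed balls (distance
# <= r counts as inside) and a cell is never its own neighbor.

as_xy <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 2)
    m <- points
  } else if (is.data.frame(points)) {
    stopifnot(all(c("x", "y") %in% names(points)))
    m <- cbind(points$x, points$y)
  } else {
    stop("points must be a 2-column matrix or a data frame with x and y",
         call. = FALSE)
  }
  storage.mode(m) <- "double"
  if (!all(is.finite(m))) stop("non-finite coordinates", call. = FALSE)
  m
}

#' Nearest-neighbor distances
#'
#' Euclidean distance from each point to its nearest other point, in the
#' units of the coordinates (micrometers for cell tables).
#'
#' @param points A 2-column matrix or a data frame with `x`, `y`.
#' @return Numeric vector, one distance per point.
#' @export
nearest_neighbor_distances <- function(points) {
  xy <- as_xy(points)
  if (nrow(xy) < 2) {
    stop("at least 2 points are required for nearest-neighbor distances",
         call. = FALSE)
  }
  # k = 2: the first neighbor of a query on its own data set is itself
  # (distance 0, possibly another coincident point, which is equivalent).
  RANN::nn2(xy, k = 2)$nn.dists[, 2]
}

#' Minimum distance unit and proximity radius per stratum
#'
#' For each (sample, region) stratum, the minimum distance unit `d` is
#' the median of the per-cell nearest-neighbor distances, and the
#' proximity radius is `r = multiplier * d` (default multiplier 5),
#' restricting the neighborhood to immediate cell contacts. Strata never
#' mix samples or regions.
#'
#' @param cells A cell table.
#' @param multiplier Radius multiplier (default 5).
#' @return Tibble with one row per (sample_id, region): `d`, `r`,
#'   `multiplier`, `n_cells`.
#' @export
compute_distance_units <- function(cells, multiplier = 5) {
  stopifnot(multiplier > 0)
  strata <- dplyr::distinct(cells, .data$sample_id, .data$region)
  purrr::pmap_dfr(strata, function(sample_id, region) {
    sub <- cells[cells$sample_id == sample_id & cells$region == region, ]
    if (nrow(sub) < 2) {
      stop("stratum (sample ", sample_id, ", region ", region,
           ") has fewer than 2 cells; distance unit undefined",
           call. = FALSE)
    }
    d <- stats::median(nearest_neighbor_distances(sub))
    tibble(sample_id = sample_id, region = region,
           d = d, r = multiplier * d, multiplier = multiplier,
           n_cells = nrow(sub))
  })
}

# Radius neighbor counts for one coordinate set. Returns a list with
# n_total (length n) and n_b (n x n_types matrix, columns = type levels).
radius_type_counts <- function(xy, r, types) {
  n <- nrow(xy)
  lev <- sort(unique(types))
  tcode <- match(types, lev)
  k <- min(n, 64L)
  repeat {
    res <- RANN::nn2(xy, k = k, searchtype = "radius", radius = r)
    saturated <- k < n && any(res$nn.idx[, k] > 0)
    if (!saturated) break
    k <- min(n, k * 2L)
  }
  idx <- res$nn.idx
  valid <- idx > 0 & idx != row(idx)   # drop padding and self-matches
  ii <- row(idx)[valid]
  jj <- idx[valid]
  n_total <- tabulate(ii, nbins = n)
  lin <- (tcode[jj] - 1L) * n + ii
  n_b <- matrix(tabulate(lin, nbins = n * length(lev)), n, length(lev),
                dimnames = list(NULL, lev))
  list(n_total = n_total, n_b = n_b, types = lev)
}

#' Fixed-radius neighbor counts within one stratum
#'
#' For every cell of one (sample, region) stratum, counts the other
#' cells within Euclidean distance `r` (closed ball), in total and per
#' surround type. The center cell itself is excluded.
#'
#' @param cells A cell table.
#' @param sample_id,region Stratum selector.
#' @param r Radius in micrometers.
#' @param type_level `"cell_subtype"` (default) or `"cell_type"`.
#' @return Long tibble: one row per (center cell, surround type present
#'   in the stratum) with `n_b` and `n_total`.
#' @export
count_neighbors <- function(cells, sample_id, region, r,
                            type_level = c("cell_subtype", "cell_type")) {
  type_level <- match.arg(type_level)
  stopifnot(r > 0)
  sub <- cells[cells$sample_id == sample_id & cells$region == region, ]
  if (nrow(sub) == 0) {
    stop("no cells in stratum (", sample_id, ", ", region, ")", call. = FALSE)
  }
  types <- sub[[type_level]]
  if (anyNA(types) || any(!nzchar(types))) {
    bad <- sub$cell_id[is.na(types) | !nzchar(types)]
    stop("untyped cell(s) at level ", type_level, ": ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  rc <- radius_type_counts(as_xy(sub), r, types)
  tidyr::expand_grid(center_cell_id = sub$cell_id,
                     surround_type = rc$types) %>%
    dplyr::arrange(match(.data$center_cell_id, sub$cell_id)) %>%
    dplyr::mutate(
      n_b = as.vector(t(rc$n_b)),
      n_total = rep(rc$n_total, each = length(rc$types))
    )
}

#' B-ratio observations from neighbor counts
#'
#' Converts per-cell neighbor counts into B-ratio observations
#' (`b_ratio = n_b / n_total`), one row per (center cell, surround
#' type). Center cells with no neighbor inside the radius yield no
#' observation (0/0 is undefined) and are tallied in the `skipped`
#' attribute.
#'
#' @param neighbor_counts Output of [count_neighbors()], optionally
#'   augmented with metadata columns.
#' @return Tibble of observations with a `skipped` attribute listing the
#'   isolated center cells.
#' @export
compute_b_ratios <- function(neighbor_counts) {
  skipped <- neighbor_counts %>%
    dplyr::filter(.data$n_total == 0) %>%
    dplyr::distinct(.data$center_cell_id)
  obs <- neighbor_counts %>%
    dplyr::filter(.data$n_total > 0) %>%
    dplyr::mutate(b_ratio = .data$n_b / .data$n_total)
  attr(obs, "skipped") <- skipped
  obs
}

#' Proximity observations for a whole cell table
#'
#' Orchestrates the proximity statistic over all (sample, region)
#' strata: derives each stratum's distance unit `d` and radius
#' `r = multiplier * d` (unless a fixed `r` is supplied), counts
#' fixed-radius neighbors per surround type, and computes B-ratios.
#'
#' @inheritParams compute_distance_units
#' @param type_level `"cell_subtype"` (default) or `"cell_type"`.
#' @param r Optional fixed radius in micrometers overriding the
#'   data-derived one (applied to every stratum).
#' @return A `proximity_result`: list with `observations` (center cell,
#'   sample, condition, region, center type, surround type, n_b,
#'   n_total, b_ratio), `distance_units`, `skipped` (isolated center
#'   cells), and `params`.
#' @export
compute_proximity <- function(cells, type_level = c("cell_subtype", "cell_type"),
                              multiplier = 5, r = NULL) {
  type_level <- match.arg(type_level)
  units <- compute_distance_units(cells, multiplier = multiplier)
  if (!is.null(r)) {
    stopifnot(r > 0)
    units$r <- r
  }
  meta_cols <- c("cell_id", "sample_id", "condition", "region", type_level)
  pieces <- purrr::pmap(units, function(sample_id, region, d, r, ...) {
    nc <- count_neighbors(cells, sample_id, region, r, type_level = type_level)
    obs <- compute_b_ratios(nc)
    meta <- cells[cells$sample_id == sample_id & cells$region == region,
                  meta_cols]
    names(meta) <- c("center_cell_id", "sample_id", "condition", "region",
                     "center_type")
    list(obs = dplyr::inner_join(meta, obs, by = "center_cell_id"),
         skipped = dplyr::inner_join(meta, attr(obs, "skipped"),
                                     by = "center_cell_id"))
  })
  observations <- dplyr::bind_rows(purrr::map(pieces, "obs"))
  skipped <- dplyr::bind_rows(purrr::map(pieces, "skipped"))
  structure(list(observations = observations,
                 distance_units = units,
                 skipped = skipped,
                 params = list(type_level = type_level,
                               multiplier = multiplier, fixed_r = r,
                               boundary = "closed ball (distance <= r)")),
            class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, ...) {
  cat("<proximity_result> ", nrow(x$observations), " observations, ",
      nrow(x$distance_units), " strata, ",
      nrow(x$skipped), " isolated center cell(s) skipped\n", sep = "")
  invisible(x)
}
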