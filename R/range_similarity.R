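# Core/full-range volume isopleths and Bhattacharyya comparisons of
# normalized utilization distributions.

#' Volume isopleth: highest-density cells enclosing a mass level
#'
#' Cells are ranked by density descending (ties broken lexicographically
#' by `(ix, iy)` for determinism) and accumulated until the cumulative
#' mass first reaches `level`.  The 50% isopleth is the conventional core
#' range; 95% the full range.  Zero and `NA` cells are never included.
#'
#' @param p A normalized `prob_raster` (see [normalize_raster()]).
#' @param level Fraction in (0, 1), canonically 0.5 or 0.95.
#' @return List of class `isopleth` with `level`, `cells` (data frame of
#'   0-based `ix`, `iy`, `density`), `mass` (fraction actually enclosed,
#'   `>= level`) and `area_m2` (cell count times cell area).
#' @export
volume_isopleth <- function(p, level) {
  stopifnot(level > 0, level < 1)
  .check_prob(p)
  v <- p$values
  v[is.na(v)] <- 0
  idx <- which(v > 0, arr.ind = TRUE)
  dens <- v[idx]
  ix <- idx[, 1] - 1L; iy <- idx[, 2] - 1L
  o <- order(-dens, ix, iy)
  cum <- cumsum(dens[o])
  n_take <- which(cum >= level - 1e-12)[1]
  if (is.na(n_take)) n_take <- length(o)   # mass sums to < level (degenerate)
  take <- o[seq_len(n_take)]
  structure(list(level = level,
                 cells = data.frame(ix = ix[take], iy = iy[take],
                                    density = dens[take]),
                 mass = cum[n_take],
                 area_m2 = n_take * p$grid$cell_size^2),
            class = "isopleth")
}

#' @export
print.isopleth <- function(x, ...) {
  cat(sprintf("isopleth %.0f%%: %d cells, mass %.4f, area %g m^2\n",
              100 * x$level, nrow(x$cells), x$mass, x$area_m2))
  invisible(x)
}

#' Bhattacharyya coefficient between two normalized distributions
#'
#' `BC = sum_i sqrt(P_i Q_i)` over all grid cells: 1 iff the distributions
#' are identical cell-wise, 0 iff their supports are disjoint.  The
#' radical form is the Bhattacharyya coefficient proper; `form =
#' "product"` computes the plain cross-product `sum_i P_i Q_i` for
#' sensitivity checks (note the product form is below 1 even for
#' identical non-degenerate distributions).
#'
#' @param p,q Normalized `prob_raster`s on the same grid.
#' @param form `"radical"` (default) or `"product"`.
#' @return A fraction in `[0, 1]`.
#' @export
bhattacharyya_coefficient <- function(p, q, form = c("radical", "product")) {
  form <- match.arg(form)
  if (!.same_grid(p$grid, q$grid))
    stop("distributions are on different grids", call. = FALSE)
  .check_prob(p); .check_prob(q)
  pv <- p$values; qv <- q$values
  pv[is.na(pv)] <- 0; qv[is.na(qv)] <- 0
  if (form == "radical") sum(sqrt(pv * qv)) else sum(pv * qv)
}

#' Core/full range summary, optionally split by field region
#'
#' Computes the volume isopleth at each level on the full raster, then
#' tallies included cells (and area) per region of `mask`.
#'
#' @param p A normalized `prob_raster`.
#' @param levels Numeric vector of mass levels (default `c(0.5, 0.95)`).
#' @param mask Optional `region_mask` on the same grid; `NULL` gives one
#'   `"all"` region.
#' @return Data frame with columns `level`, `region`, `cells`, `area_m2`,
#'   `mass` (total mass enclosed at that level).
#' @export
range_summary <- function(p, levels = c(0.5, 0.95), mask = NULL) {
  if (!is.null(mask) && !.same_grid(p$grid, mask$grid))
    stop("mask is on a different grid", call. = FALSE)
  regions <- if (is.null(mask)) "all" else
    sort(unique(as.vector(mask$membership)))
  out <- list()
  for (lv in levels) {
    iso <- volume_isopleth(p, lv)
    lab <- if (is.null(mask)) rep("all", nrow(iso$cells)) else
      mask$membership[cbind(iso$cells$ix + 1L, iso$cells$iy + 1L)]
    for (rg in regions) {
      n <- sum(lab == rg)
      out[[length(out) + 1L]] <- data.frame(
        level = lv, region = rg, cells = n,
        area_m2 = n * p$grid$cell_size^2, mass = iso$mass)
    }
  }
  do.call(rbind, out)
}

#' Pairwise Bhattacharyya comparison matrix
#'
#' @param rasters Named list of normalized `prob_raster`s sharing one
#'   grid.
#' @param form Passed to [bhattacharyya_coefficient()].
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
comparison_matrix <- function(rasters, form = "radical") {
  n <- length(rasters)
  nm <- names(rasters) %||% paste0("r", seq_len(n))
  m <- matrix(1, n, n, dimnames = list(nm, nm))
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      bc <- bhattacharyya_coefficient(rasters[[i]], rasters[[j]], form)
      m[i, j] <- bc; m[j, i] <- bc
    }
  }
  m
}
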