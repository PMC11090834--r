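#' Grid specification for utilization distributions
#'
#' @param nx,ny number of cells along x and y.
#' @param origin numeric length-2, coordinates of the lower-left corner.
#' @param cell_size side length of a (square) cell, in map units
#'   (default 1 cell = 10 m in the synthetic world's units of cells).
#' @return list of class \code{ud_grid}.
#' @export
ud_grid <- function(nx, ny = nx, origin = c(0, 0), cell_size = 1) {
  stopifnot(nx >= 1, ny >= 1, cell_size > 0)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 origin = as.numeric(origin), cell_size = cell_size),
            class = "ud_grid")
}

.grid_centers <- function(grid) {
  cx <- grid$origin[1L] + (seq_len(grid$nx) - 0.5) * grid$cell_size
  cy <- grid$origin[2L] + (seq_len(grid$ny) - 0.5) * grid$cell_size
  list(x = cx, y = cy)
}

#' Estimate a gridded utilization distribution from logger detections
#'
#' Detection counts per logger are placed at the logger coordinates and
#' smoothed with an isotropic Gaussian kernel of the given bandwidth, then
#' renormalized over the grid. This is a fixed-bandwidth kernel density
#' substitute for continuous-time movement models, appropriate when
#' locations come from a modest number of fixed loggers.
#'
#' @param filtered output of [filter_detections()] (or any table with
#'   \code{tag_id} and \code{logger_id} columns).
#' @param individual individual id.
#' @param loggers data.frame \code{logger_id, x, y} in map units.
#' @param grid a [ud_grid()].
#' @param bandwidth Gaussian kernel standard deviation in map units;
#'   defaults to one inter-logger spacing heuristic (median nearest
#'   neighbour distance among loggers).
#' @param min_detections individuals with fewer filtered detections are
#'   rejected (mirrors field exclusions of sparsely observed animals).
#' @return object of class \code{util_dist}: list with \code{p}
#'   (\code{ny x nx} matrix summing to 1), \code{grid} and \code{n_det}.
#' @export
estimate_ud <- function(filtered, individual, loggers, grid,
                        bandwidth = NULL, min_detections = 10) {
  d <- filtered[filtered$tag_id == individual, , drop = FALSE]
  n_det <- nrow(d)
  if (n_det < min_detections) {
    stop(sprintf("individual %s excluded: %d detections < min_detections = %d",
                 individual, n_det, min_detections))
  }
  cnt <- table(d$logger_id)
  li <- match(names(cnt), loggers$logger_id)
  if (anyNA(li)) stop("detections at loggers missing from the logger table")
  if (is.null(bandwidth)) {
    dm <- as.matrix(stats::dist(loggers[, c("x", "y")]))
    diag(dm) <- Inf
    bandwidth <- stats::median(apply(dm, 1L, min))
  }
  ctr <- .grid_centers(grid)
  p <- matrix(0, grid$ny, grid$nx)
  for (k in seq_along(li)) {
    lx <- loggers$x[li[k]]; ly <- loggers$y[li[k]]
    if (bandwidth <= 0) {
      ix <- which.min(abs(ctr$x - lx)); iy <- which.min(abs(ctr$y - ly))
      p[iy, ix] <- p[iy, ix] + as.numeric(cnt[k])
    } else {
      kx <- dnorm(ctr$x, lx, bandwidth)
      ky <- dnorm(ctr$y, ly, bandwidth)
      p <- p + as.numeric(cnt[k]) * outer(ky, kx)
    }
  }
  s <- sum(p)
  if (s <= 0) stop("utilization distribution has zero mass on the grid")
  structure(list(p = p / s, grid = grid, individual = individual,
                 n_det = n_det, bandwidth = bandwidth),
            class = "util_dist")
}

#' Utilization distributions for many individuals
#'
#' Individuals failing the minimum-detections rule are excluded (not an
#' error) and reported in \code{attr(, "excluded")}.
#'
#' @inheritParams estimate_ud
#' @param ids individuals to attempt; default all in \code{filtered}.
#' @return named list of [estimate_ud()] results.
#' @export
estimate_uds <- function(filtered, loggers, grid, bandwidth = NULL,
                         min_detections = 10, ids = NULL) {
  if (is.null(ids)) ids <- sort(unique(filtered$tag_id))
  out <- list(); excl <- character()
  for (id in ids) {
    ud <- tryCatch(estimate_ud(filtered, id, loggers, grid, bandwidth,
                               min_detections),
                   error = function(e) NULL)
    if (is.null(ud)) excl <- c(excl, id) else out[[id]] <- ud
  }
  if (length(excl)) {
    message(sprintf("excluded %d of %d individuals (< %d detections)",
                    length(excl), length(ids), min_detections))
  }
  attr(out, "excluded") <- excl
  out
}

#' Bhattacharyya coefficient between two utilization distributions
#'
#' \code{sum(sqrt(p * q))} over grid cells; 1 for identical distributions,
#' 0 for disjoint supports.
#'
#' @param p,q \code{util_dist} objects on the same grid, or bare
#'   probability vectors/matrices of equal dimension.
#' @return numeric in \code{[0, 1]}.
#' @export
bhattacharyya <- function(p, q) {
  if (inherits(p, "util_dist") && inherits(q, "util_dist")) {
    if (!identical(unclass(p$grid), unclass(q$grid))) {
      stop("utilization distributions are on different grids")
    }
    p <- p$p; q <- q$p
  }
  if (length(p) != length(q)) stop("grid mismatch: unequal lengths")
  min(1, sum(sqrt(as.numeric(p) * as.numeric(q))))
}

#' Pairwise Bhattacharyya overlap matrix
#'
#' @param uds named list of \code{util_dist} (see [estimate_uds()]).
#' @return symmetric matrix with unit diagonal.
#' @export
overlap_matrix <- function(uds) {
  ids <- names(uds)
  n <- length(ids)
  m <- diag(1, n); dimnames(m) <- list(ids, ids)
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    m[i, j] <- m[j, i] <- bhattacharyya(uds[[i]], uds[[j]])
  }
  m
}

#' Core home range at a coverage level
#'
#' The smallest set of grid cells whose cumulative utilization probability
#' reaches the coverage level: cells are ranked by descending probability
#' and included until the cumulative sum first reaches \code{level}. Ties
#' are broken by row-major cell index.
#'
#' @param ud a \code{util_dist}.
#' @param level coverage probability, default 0.75 (the 75\% core range).
#' @return list of class \code{core_range}: \code{cells} (two-column matrix
#'   of row/col indices), \code{level}, \code{area} (cells x cell area) and
#'   \code{prob} (attained cumulative probability).
#' @export
core_range <- function(ud, level = 0.75) {
  stopifnot(inherits(ud, "util_dist"), level > 0, level <= 1)
  p <- as.numeric(ud$p)
  ord <- order(-p, seq_along(p)) # descending prob, row-major ties
  cum <- cumsum(p[ord])
  k <- which(cum >= level - 1e-12)[1L]
  if (is.na(k)) k <- length(p)
  sel <- ord[seq_len(k)]
  rc <- cbind(row = ((sel - 1L) %% ud$grid$ny) + 1L,
              col = ((sel - 1L) %/% ud$grid$ny) + 1L)
  structure(list(cells = rc, level = level,
                 area = k * ud$grid$cell_size^2, prob = cum[k],
                 grid = ud$grid),
            class = "core_range")
}

#' Habitat profile of a core range
#'
#' Normalized abundance per ground-cover type: the summed cover area
#' (percent / 100 x cell area) of each type across the core cells, divided
#' by the core range area.
#'
#' @param core a [core_range()].
#' @param survey data.frame \code{cell_x, cell_y, cover_type, percent}
#'   (column indices of the grid; percentages sum to 100 within a cell).
#' @return named numeric vector over cover types (entries in \code{[0,1]}).
#' @export
habitat_profile <- function(core, survey) {
  types <- sort(unique(survey$cover_type))
  prof <- setNames(numeric(length(types)), types)
  cell_area <- core$grid$cell_size^2
  for (r in seq_len(nrow(core$cells))) {
    cx <- core$cells[r, "col"]; cy <- core$cells[r, "row"]
    rows <- survey$cell_x == cx & survey$cell_y == cy
    if (!any(rows)) {
      stop(sprintf("core cell (%d, %d) missing from the habitat survey", cx, cy))
    }
    s <- survey[rows, ]
    prof[as.character(s$cover_type)] <-
      prof[as.character(s$cover_type)] + s$percent / 100 * cell_area
  }
  prof / core$area
}

#' Bray-Curtis similarity
#'
#' \code{1 - sum(|x - y|) / sum(x + y)} for non-negative vectors; defined as
#' 0 when both vectors are all-zero. Used both for habitat similarity
#' between normalized cover profiles and (on relative abundances) as an
#' abundance-weighted microbiota similarity.
#'
#' @param x,y equal-length non-negative numeric vectors.
#' @return numeric in \code{[0, 1]}.
#' @export
bray_curtis_similarity <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop("Bray-Curtis requires non-negative entries")
  tot <- sum(x + y)
  if (tot == 0) return(0)
  1 - sum(abs(x - y)) / tot
}

#' Pairwise habitat similarity matrix
#'
#' @param profiles named list (or row-named matrix) of habitat profiles.
#' @return symmetric Bray-Curtis similarity matrix with unit diagonal.
#' @export
habitat_similarity_matrix <- function(profiles) {
  if (is.list(profiles)) profiles <- do.call(rbind, profiles)
  ids <- rownames(profiles)
  n <- nrow(profiles)
  m <- diag(1, n); dimnames(m) <- list(ids, ids)
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    m[i, j] <- m[j, i] <- bray_curtis_similarity(profiles[i, ], profiles[j, ])
  }
  m
}
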