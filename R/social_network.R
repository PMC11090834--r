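#' Filter a raw detection stream to the nocturnal activity window
#'
#' Keeps detections whose wall-clock time falls in the activity window
#' \code{[16:00, 08:00)}, de-duplicates to one record per (individual,
#' logger, calendar minute), and assigns each record to a logging night.
#' A "night" is labelled by the calendar date of its 16:00 boundary, so a
#' detection at 02:00 on date \code{d} belongs to night \code{d - 1}.
#'
#' @param detections data.frame with columns \code{tag_id}, \code{logger_id}
#'   and \code{timestamp} (POSIXct, or character parseable by
#'   \code{as.POSIXct}; interpreted in \code{tz}).
#' @param tz time zone used to interpret character timestamps.
#' @return \code{data.table} with columns \code{tag_id}, \code{logger_id},
#'   \code{timestamp}, \code{night} (Date of the 16:00 boundary) and
#'   \code{tsec} (seconds since the start of that night).
#' @export
filter_detections <- function(detections, tz = "UTC") {
  stopifnot(all(c("tag_id", "logger_id", "timestamp") %in% names(detections)))
  ts <- detections$timestamp
  if (!inherits(ts, "POSIXct")) {
    chr <- sub("T", " ", as.character(ts), fixed = TRUE)
    t1 <- as.POSIXct(strptime(chr, "%Y-%m-%d %H:%M:%S", tz = tz))
    t2 <- as.POSIXct(strptime(chr, "%Y-%m-%d %H:%M", tz = tz))
    t1[is.na(t1)] <- t2[is.na(t1)]
    ts <- t1
  }
  bad <- which(is.na(ts) | !nzchar(as.character(detections$tag_id)) |
                 !nzchar(as.character(detections$logger_id)))
  if (length(bad)) {
    stop("unparseable or empty detection records at rows: ",
         paste(head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "")
  }
  lt <- as.POSIXlt(ts, tz = tz)
  hr <- lt$hour
  keep <- hr >= 16L | hr < 8L
  dt <- data.table(
    tag_id = as.character(detections$tag_id)[keep],
    logger_id = as.character(detections$logger_id)[keep],
    timestamp = ts[keep]
  )
  if (nrow(dt) == 0L) {
    dt[, `:=`(night = as.Date(character()), tsec = numeric())]
    return(dt[])
  }
  lt <- as.POSIXlt(dt$timestamp, tz = tz)
  date <- as.Date(format(dt$timestamp, "%Y-%m-%d", tz = tz))
  dt[, night := date - (lt$hour < 8L)]
  # unique-minute rule: one record per individual x logger x calendar minute
  dt[, minute_key := floor(as.numeric(timestamp) / 60)]
  dt <- dt[!duplicated(dt, by = c("tag_id", "logger_id", "minute_key"))]
  night_start <- as.POSIXct(paste(dt$night, "16:00:00"), tz = tz)
  dt[, tsec := as.numeric(timestamp) - as.numeric(night_start)]
  dt[, minute_key := NULL]
  setkey(dt, night, logger_id)
  dt[]
}

#' Alive windows inferred from a detection table
#'
#' Default rule: an individual is considered alive from its first to its
#' last filtered detection night. Field studies would augment this with
#' trapping records; supply your own table to override.
#'
#' @param filtered output of [filter_detections()].
#' @return data.frame with columns \code{id}, \code{first}, \code{last}.
#' @export
alive_windows <- function(filtered) {
  aw <- filtered[, .(first = min(night), last = max(night)), by = tag_id]
  setnames(aw, "tag_id", "id")
  as.data.frame(aw)
}

#' Lifespan-adjusted simple ratio index
#'
#' \code{X / (X + y_AB + y_A + y_B)}, where \code{X} is the number of
#' nights a pair was associated, \code{y_AB} nights both were observed but
#' not associated, and \code{y_A}, \code{y_B} nights only one of the pair
#' was observed while both were known alive. Returns 0 when the denominator
#' is 0. Vectorized.
#'
#' @param x,y_ab,y_a,y_b non-negative tally counts.
#' @return numeric in \code{[0, 1]}.
#' @export
adjusted_sri <- function(x, y_ab, y_a, y_b) {
  v <- c(x, y_ab, y_a, y_b)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("tally counts must be finite and non-negative")
  }
  denom <- x + y_ab + y_a + y_b
  ifelse(denom == 0, 0, x / denom)
}

# Per-night association events: pairs seen at the same logger within
# window_h hours, and pairs seen at the same logger that night at all.
# Gap between two individuals' detection-time intervals at one logger is 0
# if the intervals overlap, else the smallest cross distance.
.association_events <- function(filtered, window_h) {
  spans <- filtered[, .(tmin = min(tsec), tmax = max(tsec)),
                    by = .(night, logger_id, tag_id)]
  out_assoc <- vector("list", 0L)
  out_same <- vector("list", 0L)
  grp <- split(spans, by = c("night", "logger_id"), drop = TRUE)
  wsec <- window_h * 3600
  for (g in grp) {
    m <- nrow(g)
    if (m < 2L) next
    cmb <- combn(m, 2L)
    i <- cmb[1L, ]; j <- cmb[2L, ]
    gap <- pmax(0, pmax(g$tmin[i] - g$tmax[j], g$tmin[j] - g$tmax[i]))
    a <- ifelse(g$tag_id[i] < g$tag_id[j], g$tag_id[i], g$tag_id[j])
    b <- ifelse(g$tag_id[i] < g$tag_id[j], g$tag_id[j], g$tag_id[i])
    out_same[[length(out_same) + 1L]] <-
      data.table(night = g$night[1L], id1 = a, id2 = b)
    keep <- gap <= wsec
    if (any(keep)) {
      out_assoc[[length(out_assoc) + 1L]] <-
        data.table(night = g$night[1L], id1 = a[keep], id2 = b[keep])
    }
  }
  list(
    assoc = if (length(out_assoc)) unique(rbindlist(out_assoc)) else
      data.table(night = as.Date(character()), id1 = character(), id2 = character()),
    same = if (length(out_same)) unique(rbindlist(out_same)) else
      data.table(night = as.Date(character()), id1 = character(), id2 = character())
  )
}

#' Tally association nights for one pair
#'
#' Classifies every night on which both individuals were known alive:
#' \code{x} if they were detected at the same logger within \code{window_h}
#' hours of each other; otherwise \code{y_ab} if both were observed that
#' night (at any logger by default; at a shared logger under
#' \code{mode = "same_logger"}); \code{y_a}/\code{y_b} if only one was
#' observed. Nights with neither observed contribute nothing.
#'
#' @param filtered output of [filter_detections()].
#' @param alive data.frame \code{id, first, last} (see [alive_windows()]).
#' @param a,b individual ids.
#' @param window_h association window in hours (default 12).
#' @param mode \code{"any_logger"} (default) counts a night toward
#'   \code{y_ab} whenever both were observed anywhere but never associated;
#'   \code{"same_logger"} is the narrower reading requiring co-occurrence
#'   at a shared logger more than \code{window_h} apart.
#' @return list with integer fields \code{x, y_ab, y_a, y_b}.
#' @export
tally_pair <- function(filtered, alive, a, b, window_h = 12,
                       mode = c("any_logger", "same_logger")) {
  mode <- match.arg(mode)
  net <- build_network(filtered, alive, window_h = window_h, mode = mode,
                       ids = c(a, b), quiet = TRUE)
  tl <- attr(net, "tallies")
  row <- tl[(tl$id_a == a & tl$id_b == b) | (tl$id_a == b & tl$id_b == a), ]
  if (nrow(row) == 0L) return(list(x = 0L, y_ab = 0L, y_a = 0L, y_b = 0L))
  ya <- if (row$id_a[1L] == a) row$y_a[1L] else row$y_b[1L]
  yb <- if (row$id_a[1L] == a) row$y_b[1L] else row$y_a[1L]
  list(x = row$x[1L], y_ab = row$y_ab[1L], y_a = ya, y_b = yb)
}

#' Build the adjusted-SRI association network
#'
#' Computes the lifespan-adjusted simple ratio index for every pair of
#' individuals from a filtered detection table, restricted to nights both
#' pair members were known alive (and, optionally, to a night range such as
#' a season).
#'
#' @inheritParams tally_pair
#' @param night_range optional length-2 Date vector; only nights within the
#'   closed range are tallied (alive windows are clipped to it).
#' @param ids optional character vector restricting the individuals; by
#'   default all individuals in \code{alive} whose (clipped) windows are
#'   non-empty.
#' @param quiet suppress the summary message.
#' @return symmetric numeric matrix of adjusted SRI values (diagonal 0),
#'   with a long-format tally table in \code{attr(, "tallies")}
#'   (\code{id_a, id_b, sri, x, y_ab, y_a, y_b}).
#' @export
build_network <- function(filtered, alive = alive_windows(filtered),
                          night_range = NULL, window_h = 12,
                          mode = c("any_logger", "same_logger"),
                          ids = NULL, quiet = FALSE) {
  mode <- match.arg(mode)
  alive <- as.data.frame(alive)
  stopifnot(all(c("id", "first", "last") %in% names(alive)),
            all(alive$first <= alive$last))
  if (!is.null(night_range)) {
    alive$first <- pmax(alive$first, as.Date(night_range[1L]))
    alive$last <- pmin(alive$last, as.Date(night_range[2L]))
    alive <- alive[alive$first <= alive$last, , drop = FALSE]
    filtered <- filtered[night >= as.Date(night_range[1L]) &
                           night <= as.Date(night_range[2L])]
  }
  if (!is.null(ids)) alive <- alive[alive$id %in% ids, , drop = FALSE]
  all_ids <- sort(unique(alive$id))
  n <- length(all_ids)
  mat <- matrix(0, n, n, dimnames = list(all_ids, all_ids))
  empty_tal <- data.frame(id_a = character(), id_b = character(),
                          sri = numeric(), x = integer(), y_ab = integer(),
                          y_a = integer(), y_b = integer())
  if (n == 0L) {
    warning("no individuals to tally; returning empty matrix")
    attr(mat, "tallies") <- empty_tal
    return(mat)
  }
  filtered <- filtered[tag_id %in% all_ids]
  if (nrow(filtered) == 0L) {
    if (n > 1L) warning("empty detection table; returning zero matrix")
    attr(mat, "tallies") <- empty_tal
    return(mat)
  }
  ev <- .association_events(filtered, window_h)
  # observed nights per individual (integer days, sorted)
  obs <- unique(filtered[, .(tag_id, night)])
  obs_by_id <- lapply(split(as.integer(obs$night), obs$tag_id), sort)
  first <- setNames(as.integer(as.Date(alive$first)), alive$id)
  last <- setNames(as.integer(as.Date(alive$last)), alive$id)

  pair_key <- function(a, b) paste(a, b, sep = "\r")
  assoc_nights <- split(as.integer(ev$assoc$night),
                        pair_key(ev$assoc$id1, ev$assoc$id2))
  same_nights <- split(as.integer(ev$same$night),
                       pair_key(ev$same$id1, ev$same$id2))
  count_in <- function(v, lo, hi) {
    if (is.null(v) || lo > hi) return(0L)
    v <- sort(v)
    sum(v >= lo & v <= hi)
  }
  tal <- vector("list", n * (n - 1L) / 2L)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- all_ids[i]; b <- all_ids[j]
      lo <- max(first[[a]], first[[b]])
      hi <- min(last[[a]], last[[b]])
      key <- pair_key(a, b)
      x <- count_in(assoc_nights[[key]], lo, hi)
      oa <- count_in(obs_by_id[[a]], lo, hi)
      ob <- count_in(obs_by_id[[b]], lo, hi)
      both <- if (lo > hi) 0L else {
        na <- obs_by_id[[a]]; nb <- obs_by_id[[b]]
        length(intersect(na[na >= lo & na <= hi], nb[nb >= lo & nb <= hi]))
      }
      y_ab <- if (mode == "any_logger") both - x else
        count_in(same_nights[[key]], lo, hi) - x
      y_a <- oa - both
      y_b <- ob - both
      sri <- adjusted_sri(x, y_ab, y_a, y_b)
      mat[i, j] <- mat[j, i] <- sri
      k <- k + 1L
      tal[[k]] <- data.frame(id_a = a, id_b = b, sri = sri, x = x,
                             y_ab = y_ab, y_a = y_a, y_b = y_b)
    }
  }
  tallies <- if (k > 0L) do.call(rbind, tal[seq_len(k)]) else empty_tal
  attr(mat, "tallies") <- tallies
  if (!quiet && n > 1L) {
    deg <- rowSums(mat > 0)
    message(sprintf(
      "SRI network: %d individuals, mean degree %.2f, mean non-zero SRI %.3f",
      n, mean(deg), if (any(mat > 0)) mean(mat[upper.tri(mat)][mat[upper.tri(mat)] > 0]) else 0))
  }
  mat
}

#' Split a study period into two equal-duration seasons
#'
#' The study period is cut into two equal halves by night; the first half
#' is labelled \code{spring}, the second \code{autumn}.
#'
#' @param nights Date vector of observed nights (the full range is used).
#' @return named list of two length-2 Date vectors (\code{spring},
#'   \code{autumn}).
#' @export
season_ranges <- function(nights) {
  lo <- min(nights); hi <- max(nights)
  mid <- lo + floor(as.numeric(hi - lo) / 2)
  list(spring = c(lo, mid), autumn = c(mid + 1, hi))
}
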