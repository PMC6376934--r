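# position at arclength t along a polyline (t clamped to [0, L])
point_along_polyline <- function(vx, vy, t) {
  seg_len <- sqrt(diff(vx)^2 + diff(vy)^2)
  cum <- c(0, cumsum(seg_len))
  L <- cum[length(cum)]
  t <- pmin(pmax(t, 0), L)
  i <- findInterval(t, cum, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(seg_len))
  frac <- ifelse(seg_len[i] > 0, (t - cum[i]) / seg_len[i], 0)
  cbind(x = vx[i] + frac * (vx[i + 1] - vx[i]),
        y = vy[i] + frac * (vy[i + 1] - vy[i]))
}

#' Split transects into analysis segments
#'
#' Each transect of length `L` is divided into `m = max(1, round(L /
#' seg_length_m))` contiguous segments of equal length `L / m`, so no
#' effort is discarded and nominal 1.8 km segments absorb non-divisible
#' transect lengths. Along-transect intervals are half-open
#' `[start, end)` except the last, which is closed.
#'
#' @param transects vertex table (`transect_id`, `vertex_index`, `x_m`, `y_m`).
#' @param seg_length_m nominal segment length (m), default 1800.
#' @return data frame of class `mds_segments`: `segment_id`,
#'   `transect_id`, `seg_index`, `length_m`, `start_m`, `end_m` (arclength
#'   interval), `x_m`, `y_m` (midpoint). Counts and covariates are added
#'   by [assign_sightings()] and [extract_covariates()].
#' @export
segment_transects <- function(transects, seg_length_m = 1800) {
  if (seg_length_m <= 0) stop("invalid-config: seg_length must be positive")
  ids <- unique(transects$transect_id)
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    v <- transects[transects$transect_id == ids[k], ]
    v <- v[order(v$vertex_index), ]
    L <- sum(sqrt(diff(v$x_m)^2 + diff(v$y_m)^2))
    if (L <= 0) {
      warning("zero-length transect ", ids[k], " skipped")
      next
    }
    m <- max(1L, round(L / seg_length_m))
    len <- L / m
    start <- (seq_len(m) - 1) * len
    mid <- point_along_polyline(v$x_m, v$y_m, start + len / 2)
    out[[k]] <- data.frame(
      transect_id = ids[k], seg_index = seq_len(m),
      length_m = len, start_m = start, end_m = start + len,
      x_m = mid[, "x"], y_m = mid[, "y"]
    )
  }
  segs <- do.call(rbind, out)
  if (is.null(segs)) stop("empty-data: no usable transects")
  segs <- cbind(segment_id = seq_len(nrow(segs)), segs)
  class(segs) <- c("mds_segments", "data.frame")
  segs
}

#' Assign sightings to segments as individual counts
#'
#' Each sighting with perpendicular distance at most `w` adds its group
#' size to the count `n_j` of the segment, on the same transect, whose
#' along-transect interval contains the projection of the sighting onto
#' the transect line. A sighting exactly on an interior boundary goes to
#' the downstream (later) segment by the half-open interval rule.
#' Segment areas `A_j = 2 w l_j` (both sides of the line, km^2) are also
#' attached.
#'
#' @param sightings sightings table (`transect_id`, `x_m`, `y_m`,
#'   `perp_distance_m`, `group_size`).
#' @param segments output of [segment_transects()].
#' @param transects the vertex table the segments came from.
#' @param w truncation distance (m); sightings beyond it are excluded.
#' @return `segments` with columns `count` (individuals) and `area_km2`.
#' @export
assign_sightings <- function(sightings, segments, transects, w) {
  segments$count <- 0L
  segments$area_km2 <- 2 * (w / 1000) * (segments$length_m / 1000)
  if (any(segments$area_km2 <= 0)) stop("data error: non-positive segment area")
  keep <- sightings$perp_distance_m <= w
  s <- sightings[keep, , drop = FALSE]
  if (nrow(s) == 0) return(segments)
  unknown <- setdiff(unique(s$transect_id), unique(segments$transect_id))
  if (length(unknown))
    stop("data-integrity: sightings reference unknown transect(s): ",
         paste(unknown, collapse = ", "))
  for (id in unique(s$transect_id)) {
    v <- transects[transects$transect_id == id, ]
    v <- v[order(v$vertex_index), ]
    si <- s[s$transect_id == id, ]
    along <- project_onto_polyline(si$x_m, si$y_m, v$x_m, v$y_m)$along
    seg <- segments[segments$transect_id == id, ]
    m <- nrow(seg)
    len <- seg$length_m[1]
    idx <- pmin(floor(along / len) + 1L, m) # boundary -> later segment; end closed
    for (j in seq_along(idx)) {
      row <- which(segments$transect_id == id & segments$seg_index == idx[j])
      segments$count[row] <- segments$count[row] + si$group_size[j]
    }
  }
  segments
}

#' Attach landscape covariates to segments
#'
#' Covariate values are sampled at the segment midpoint cell
#' (nearest-cell sampling). `ranch_dist` is recomputed exactly from the
#' ranch point locations when they are available, rather than read from
#' its raster.
#'
#' @param segments an `mds_segments` table (or prediction-cell table with
#'   `x_m`, `y_m`).
#' @param landscape an `mds_landscape`.
#' @param covariates names to extract; default all landscape covariates.
#' @param nodata "error" (default) to fail on NA cells, or "nearest" to
#'   take the nearest non-NA cell.
#' @return `segments` with one column per covariate.
#' @export
extract_covariates <- function(segments, landscape,
                               covariates = names(landscape$covariates),
                               nodata = c("error", "nearest")) {
  nodata <- match.arg(nodata)
  ex <- landscape$extent
  if (any(segments$x_m < ex["xmin"] | segments$x_m > ex["xmax"] |
          segments$y_m < ex["ymin"] | segments$y_m > ex["ymax"]))
    stop("data error: segment midpoint outside the landscape extent")
  for (nm in covariates) {
    if (nm == "ranch_dist" && !is.null(landscape$ranch_points)) {
      p <- landscape$ranch_points
      d2 <- outer(segments$x_m, p[, 1], `-`)^2 + outer(segments$y_m, p[, 2], `-`)^2
      segments[[nm]] <- sqrt(apply(d2, 1, min))
      next
    }
    r <- landscape$covariates[[nm]]
    if (is.null(r)) stop("invalid-config: unknown covariate ", nm)
    v <- raster_extract(r, segments$x_m, segments$y_m)
    if (anyNA(v)) {
      if (nodata == "error")
        stop("data error: midpoint in a no-data cell for covariate ", nm)
      bad <- which(is.na(v))
      ok <- which(!is.na(r$values))
      ctr <- raster_centers(r)
      okxy <- cbind(ctr$x[(ok - 1L) %/% r$ny + 1L], ctr$y[(ok - 1L) %% r$ny + 1L])
      for (b in bad) {
        d2 <- (okxy[, 1] - segments$x_m[b])^2 + (okxy[, 2] - segments$y_m[b])^2
        v[b] <- r$values[ok[which.min(d2)]]
      }
    }
    segments[[nm]] <- v
  }
  segments
}

#' Screen covariates for collinearity
#'
#' Pairwise Pearson correlations over segments; while any pair has
#' `|r| >= threshold` the lower-priority member of the worst offending
#' pair is dropped. Priority is the order of `priority` (earlier = kept);
#' covariates not listed rank after listed ones, in input order.
#'
#' @param segment_table data frame holding the covariate columns.
#' @param covariates covariate column names to screen.
#' @param threshold absolute correlation threshold (default 0.7).
#' @param priority character vector, highest priority first.
#' @return list: `retained` (names), `cor_matrix` (full, before drops),
#'   `dropped` (data frame: name, against, r).
#' @export
screen_collinearity <- function(segment_table, covariates,
                                threshold = 0.7, priority = covariates) {
  if (nrow(segment_table) < 3) stop("empty-data: need >= 3 segments")
  covariates <- unique(covariates)
  zero_var <- covariates[vapply(covariates, function(nm)
    stats::sd(segment_table[[nm]]) == 0, logical(1))]
  if (length(zero_var)) {
    warning("zero-variance covariate(s) dropped: ", paste(zero_var, collapse = ", "))
    covariates <- setdiff(covariates, zero_var)
  }
  if (length(covariates) < 2) stop("empty-data: need >= 2 covariates")
  rank_of <- function(nm) {
    i <- match(nm, priority)
    ifelse(is.na(i), length(priority) + match(nm, covariates), i)
  }
  cm <- stats::cor(as.matrix(segment_table[covariates]))
  keep <- covariates
  dropped <- data.frame(name = character(0), against = character(0), r = numeric(0))
  repeat {
    sub <- cm[keep, keep, drop = FALSE]
    off <- abs(sub) * (1 - diag(length(keep)))
    if (all(off < threshold)) break
    worst <- which(off == max(off), arr.ind = TRUE)[1, ]
    pair <- keep[worst]
    loser <- pair[which.max(rank_of(pair))]
    other <- setdiff(pair, loser)
    dropped <- rbind(dropped, data.frame(name = loser, against = other,
                                         r = sub[pair[1], pair[2]]))
    keep <- setdiff(keep, loser)
  }
  list(retained = keep, cor_matrix = cm, dropped = dropped)
}
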