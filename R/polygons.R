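#' Polygon sets in slide coordinates
#'
#' A polygon set holds simple polygons (exterior ring plus holes) with
#' vertices in level-0 pixel coordinates, together with the slide
#' identifier and a role tag (`"predicted"` or `"annotated"`). Rings are
#' stored open (first vertex not repeated); exteriors are positively
#' oriented under the image convention (x right, y down), holes
#' negatively. The `grid` attribute records the lattice step of
#' mask-derived polygons (level-0 pixels per mask pixel).
#'
#' @param polygons list of polygons, each a list with `exterior`
#'   (`n x 2` matrix of x, y), `holes` (list of matrices) and `area`.
#' @param slide slide identifier.
#' @param role `"predicted"` or `"annotated"`.
#' @param grid lattice step of the vertices (1 for free geometry).
#' @return An object of class `pcead_polyset`.
#' @export
polygon_set <- function(polygons = list(), slide = "slide",
                        role = "predicted", grid = 1) {
  structure(list(polygons = polygons, slide = as.character(slide),
                 role = role, grid = grid),
            class = "pcead_polyset")
}

#' @export
print.pcead_polyset <- function(x, ...) {
  cat(sprintf("<pcead_polyset '%s' (%s): %d polygon(s), area %.0f px^2>\n",
              x$slide, x$role, length(x$polygons), total_area(x)))
  invisible(x)
}

#' Total area of a polygon set in pixels squared
#'
#' @param polys a `pcead_polyset`.
#' @return Sum of per-polygon areas.
#' @export
total_area <- function(polys) {
  if (length(polys$polygons) == 0L) return(0)
  sum(vapply(polys$polygons, function(p) p$area, 0))
}

# Signed shoelace area of an open ring (positive = exterior under the
# x-right / y-down convention used throughout).
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_area <- function(poly) {
  a <- abs(ring_area(poly$exterior))
  if (length(poly$holes))
    a <- a - sum(vapply(poly$holes, function(h) abs(ring_area(h)), 0))
  a
}

#' Convert an anomaly mask to polygons
#'
#' Optionally applies morphological closing, labels 4-connected components,
#' traces each component's boundary on the pixel lattice (vertices at
#' integer corners, half-open pixel convention) and drops components whose
#' area is below `min_area`. With `closing_radius = 0` every polygon's area
#' equals its member-pixel count exactly, which keeps the downstream
#' confusion matrix an integer computation.
#'
#' @param mask logical matrix; `mask[i, j]` is the pixel with corner
#'   `(x, y) = (j - 1, i - 1) * scale + origin`.
#' @param origin level-0 `(x, y)` offset of the mask (patch origin).
#' @param scale level-0 pixels per mask pixel (patch span / mask side).
#' @param min_area minimum component area in level-0 pixels squared.
#' @param closing_radius radius (mask pixels) of an optional morphological
#'   closing applied before labeling.
#' @param slide,role provenance tags for the returned set.
#' @return A `pcead_polyset` with one polygon per retained component.
#' @export
mask_to_polygons <- function(mask, origin = c(0, 0), scale = 1,
                             min_area = 256, closing_radius = 0,
                             slide = "slide", role = "predicted") {
  stopifnot(min_area >= 0)
  if (!any(mask)) return(polygon_set(slide = slide, role = role,
                                     grid = scale))
  if (closing_radius > 0) {
    kern <- EBImage::makeBrush(2L * as.integer(closing_radius) + 1L, "disc")
    mask <- EBImage::closing(mask * 1, kern) > 0.5
  }
  labels <- EBImage::bwlabel(mask * 1)
  nlab <- max(labels)
  counts <- tabulate(labels[labels > 0], nbins = nlab)
  polys <- list()
  for (lab in seq_len(nlab)) {
    area <- counts[lab] * scale^2
    if (area < min_area && min_area > 0) next
    idx <- which(labels == lab, arr.ind = TRUE)
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    sub <- labels[r0:r1, c0:c1, drop = FALSE] == lab
    rings <- trace_component(sub)
    off <- c(c0 - 1, r0 - 1)           # (x, y) offset of the sub-grid
    rings <- lapply(rings, function(rg)
      sweep(rg, 2L, off, "+") * scale + rep(origin, each = nrow(rg)))
    signs <- vapply(rings, ring_area, 0)
    polys[[length(polys) + 1L]] <- list(
      exterior = rings[[which.max(signs)]],
      holes = rings[signs < 0],
      area = area)
  }
  polygon_set(polys, slide = slide, role = role, grid = scale)
}

# Trace the boundary rings of a single 4-connected component given as a
# logical matrix. Returns open rings on the unit lattice; the exterior ring
# is positively oriented, holes negatively. At pinch vertices (two
# diagonally-touching boundary corners) the sharpest right turn is taken,
# which keeps 4-connected components separate.
trace_component <- function(M) {
  h <- nrow(M); w <- ncol(M)
  pad_top <- rbind(FALSE, M[-h, , drop = FALSE])
  pad_bot <- rbind(M[-1, , drop = FALSE], FALSE)
  pad_lef <- cbind(FALSE, M[, -w, drop = FALSE])
  pad_rig <- cbind(M[, -1, drop = FALSE], FALSE)
  fx <- integer(0); fy <- integer(0); tx <- integer(0); ty <- integer(0)
  emit <- function(sel, fxo, fyo, txo, tyo) {
    if (!any(sel)) return()
    idx <- which(sel, arr.ind = TRUE)
    x <- idx[, 2] - 1L; y <- idx[, 1] - 1L
    fx <<- c(fx, x + fxo); fy <<- c(fy, y + fyo)
    tx <<- c(tx, x + txo); ty <<- c(ty, y + tyo)
  }
  emit(M & !pad_top, 0L, 0L, 1L, 0L)   # top edge, eastward
  emit(M & !pad_rig, 1L, 0L, 1L, 1L)   # right edge, southward
  emit(M & !pad_bot, 1L, 1L, 0L, 1L)   # bottom edge, westward
  emit(M & !pad_lef, 0L, 1L, 0L, 0L)   # left edge, northward
  n <- length(fx)
  key <- fx * (h + 1L) + fy
  out_edges <- split(seq_len(n), key)
  used <- logical(n)
  rings <- list()
  for (start in seq_len(n)) {
    if (used[start]) next
    cur <- start
    v0x <- fx[start]; v0y <- fy[start]
    vx <- integer(0); vy <- integer(0)
    repeat {
      used[cur] <- TRUE
      vx <- c(vx, fx[cur]); vy <- c(vy, fy[cur])
      nxx <- tx[cur]; nxy <- ty[cur]
      if (nxx == v0x && nxy == v0y) break
      cand <- out_edges[[as.character(nxx * (h + 1L) + nxy)]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) stop("boundary tracing failed (open ring)")
      if (length(cand) > 1L) {
        d1x <- tx[cur] - fx[cur]; d1y <- ty[cur] - fy[cur]
        cross <- d1x * (ty[cand] - fy[cand]) - d1y * (tx[cand] - fx[cand])
        cand <- cand[which.max(cross)]
      }
      cur <- cand
    }
    ring <- cbind(vx, vy)
    rings[[length(rings) + 1L]] <- simplify_ring(ring)
  }
  rings
}

# Drop vertices interior to straight (axis-aligned or any collinear) runs.
simplify_ring <- function(ring) {
  n <- nrow(ring)
  if (n <= 4L) return(unname(ring))
  prv <- rbind(ring[n, ], ring[-n, , drop = FALSE])
  nxt <- rbind(ring[-1, , drop = FALSE], ring[1, ])
  cross <- (ring[, 1] - prv[, 1]) * (nxt[, 2] - ring[, 2]) -
    (ring[, 2] - prv[, 2]) * (nxt[, 1] - ring[, 1])
  keep <- cross != 0
  if (!any(keep)) return(unname(ring))
  unname(ring[keep, , drop = FALSE])
}

#' Rasterize a polygon set over a region
#'
#' Even-odd scanline rasterization with pixel-center inclusion: raster
#' pixel `(i, j)` (1-based) has its center at
#' `(x0 + (j - 1/2) d, y0 + (i - 1/2) d)` and is set when the center lies
#' inside a polygon (exterior minus holes, unioned across polygons).
#' Polygons are effectively half-open on their max edges, so abutting
#' polygons never double-count a pixel.
#'
#' @param polys a `pcead_polyset`.
#' @param region `c(x0, y0, x1, y1)` half-open level-0 rectangle.
#' @param downsample raster step `d` in level-0 pixels.
#' @return Logical matrix with `ceiling((y1-y0)/d)` rows.
#' @export
rasterize_polygons <- function(polys, region, downsample = 1) {
  d <- downsample
  nx <- as.integer(ceiling((region[3] - region[1]) / d))
  ny <- as.integer(ceiling((region[4] - region[2]) / d))
  out <- matrix(FALSE, ny, nx)
  if (nx == 0L || ny == 0L) return(out)
  xc <- region[1] + (seq_len(nx) - 0.5) * d
  for (poly in polys$polygons) {
    rings <- c(list(poly$exterior), poly$holes)
    edges <- do.call(rbind, lapply(rings, function(rg) {
      nxt <- rbind(rg[-1, , drop = FALSE], rg[1, , drop = FALSE])
      cbind(rg, nxt)
    }))
    ylo <- min(edges[, 2], edges[, 4]); yhi <- max(edges[, 2], edges[, 4])
    i0 <- max(1L, as.integer(ceiling((ylo - region[2]) / d + 0.5)))
    i1 <- min(ny, as.integer(ceiling((yhi - region[2]) / d - 0.5)))
    if (i1 < i0) next
    for (i in i0:i1) {
      yc <- region[2] + (i - 0.5) * d
      sel <- (edges[, 2] <= yc & edges[, 4] > yc) |
        (edges[, 4] <= yc & edges[, 2] > yc)
      if (!any(sel)) next
      e <- edges[sel, , drop = FALSE]
      xs <- e[, 1] + (yc - e[, 2]) * (e[, 3] - e[, 1]) / (e[, 4] - e[, 2])
      inside <- (findInterval(xc, sort(xs)) %% 2L) == 1L
      out[i, ] <- out[i, ] | inside
    }
  }
  out
}

#' Merge per-patch polygon sets into a slide-level set
#'
#' Computes the geometric union of all parts by re-rasterizing them onto a
#' common lattice (the finest grid step among the parts), OR-ing, and
#' re-tracing. For mask-derived polygons this is exact: touching polygons
#' from adjacent patches fuse, duplicates collapse, and the total area is
#' the area of the union.
#'
#' @param parts list of `pcead_polyset`, all on the same slide.
#' @return A single `pcead_polyset`.
#' @export
merge_patch_polygons <- function(parts) {
  parts <- parts[vapply(parts, function(p) length(p$polygons) > 0, NA)]
  if (length(parts) == 0L) return(polygon_set())
  slides <- unique(vapply(parts, function(p) p$slide, ""))
  if (length(slides) != 1L)
    stop("cannot merge polygon sets from different slides: ",
         paste(slides, collapse = ", "))
  role <- parts[[1]]$role
  g <- min(vapply(parts, function(p) p$grid, 0))
  allv <- do.call(rbind, unlist(lapply(parts, function(p)
    lapply(p$polygons, function(q) q$exterior)), recursive = FALSE))
  x0 <- floor(min(allv[, 1]) / g) * g
  y0 <- floor(min(allv[, 2]) / g) * g
  x1 <- ceiling(max(allv[, 1]) / g) * g
  y1 <- ceiling(max(allv[, 2]) / g) * g
  region <- c(x0, y0, x1, y1)
  acc <- NULL
  for (p in parts) {
    m <- rasterize_polygons(p, region, downsample = g)
    acc <- if (is.null(acc)) m else acc | m
  }
  mask_to_polygons(acc, origin = c(x0, y0), scale = g, min_area = 0,
                   closing_radius = 0, slide = slides, role = role)
}

#' Write / read polygon sets as GeoJSON
#'
#' Writes an RFC 7946-structured FeatureCollection in pixel coordinates
#' (QuPath convention: x right, y down, no CRS), one Feature per polygon
#' with properties `slide`, `role` and `area_px`. Vertices are written at
#' full precision and round-trip exactly. `read_polygons()` also accepts
#' QuPath-exported files (MultiPolygon geometries, extra properties).
#'
#' @param polys a `pcead_polyset`.
#' @param path GeoJSON file path.
#' @return `write_polygons()` returns `path` invisibly; `read_polygons()` a
#'   `pcead_polyset`.
#' @export
write_polygons <- function(polys, path) {
  ring_coords <- function(rg) {
    closed <- rbind(rg, rg[1, , drop = FALSE])
    unname(lapply(seq_len(nrow(closed)), function(i)
      c(closed[i, 1], closed[i, 2])))
  }
  features <- lapply(polys$polygons, function(poly) {
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = c(list(ring_coords(poly$exterior)),
                                         lapply(poly$holes, ring_coords))),
         properties = list(slide = polys$slide, role = polys$role,
                           area_px = poly$area))
  })
  doc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       null = "list")
  invisible(path)
}

#' @rdname write_polygons
#' @export
read_polygons <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection: ", path)
  polys <- list()
  slide <- "slide"; role <- "annotated"
  for (i in seq_along(doc$features)) {
    ft <- doc$features[[i]]
    geom <- ft$geometry
    if (is.null(geom$type))
      stop(sprintf("malformed GeoJSON feature %d in %s", i, path))
    parse_ring <- function(rg) {
      m <- do.call(rbind, lapply(rg, function(pt)
        c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
      if (nrow(m) < 3L)
        stop(sprintf("malformed ring in feature %d of %s", i, path))
      if (all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
      unname(m)
    }
    add_poly <- function(rings) {
      ext <- parse_ring(rings[[1]])
      holes <- lapply(rings[-1], parse_ring)
      p <- list(exterior = ext, holes = holes)
      p$area <- polygon_area(p)
      polys[[length(polys) + 1L]] <<- p
    }
    if (identical(geom$type, "Polygon")) add_poly(geom$coordinates)
    else if (identical(geom$type, "MultiPolygon"))
      for (part in geom$coordinates) add_poly(part)
    else stop(sprintf("unsupported geometry '%s' in feature %d of %s",
                      geom$type, i, path))
    if (!is.null(ft$properties$slide)) slide <- ft$properties$slide
    if (!is.null(ft$properties$role)) role <- ft$properties$role
  }
  polygon_set(polys, slide = slide, role = role, grid = 1)
}
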