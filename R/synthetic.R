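#' Specification of a synthetic pseudo-histology slide
#'
#' Describes a seeded synthetic slide: bright whitespace background, a
#' tissue block rendered as a correlated Gaussian random field around an
#' H&E-like base colour, planted anomalies (colour/texture-shifted discs
#' with known truth polygons) and optional on-slide ink strokes. The same
#' spec and seed always produce the same slide, byte for byte.
#'
#' @param size slide side in pixels.
#' @param background whitespace luminance in `[0, 1]`.
#' @param base_color RGB triple of the normal-tissue base colour.
#' @param corr_length spatial correlation length of the texture, pixels.
#' @param noise_sd marginal SD of the texture field per channel.
#' @param tissue list with `shape` (`"rect"` or `"disc"`) and `margin`
#'   (fraction of the slide side left as background border).
#' @param anomalies list of anomaly specs from [anomaly_disc()].
#' @param inks list of ink specs from [ink_stroke()].
#' @param id slide identifier.
#' @param seed integer seed.
#' @return A `pcead_slide_spec`.
#' @export
synthetic_slide_spec <- function(size = 512L, background = 0.96,
                                 base_color = c(0.80, 0.55, 0.68),
                                 corr_length = 8, noise_sd = 0.05,
                                 tissue = list(shape = "rect",
                                               margin = 0.06),
                                 anomalies = list(), inks = list(),
                                 id = "synthetic", seed = 1L) {
  for (a in anomalies) {
    if (a$cx - a$r < 0 || a$cy - a$r < 0 ||
        a$cx + a$r > size || a$cy + a$r > size)
      stop("anomaly extends outside the slide bounds")
  }
  structure(list(size = as.integer(size), background = background,
                 base_color = base_color, corr_length = corr_length,
                 noise_sd = noise_sd, tissue = tissue,
                 anomalies = anomalies, inks = inks,
                 id = as.character(id), seed = as.integer(seed)),
            class = "pcead_slide_spec")
}

#' @rdname synthetic_slide_spec
#' @param cx,cy disc centre in level-0 pixels.
#' @param r disc radius in pixels.
#' @param shift RGB colour shift applied inside the anomaly; the default
#'   is a darker, more purple tone (hypercellular tumor takes up more
#'   hematoxylin than normal stroma).
#' @param noise_mult multiplier on the texture SD inside the anomaly.
#' @export
anomaly_disc <- function(cx, cy, r, shift = c(-0.18, -0.21, 0.11),
                         noise_mult = 1) {
  list(cx = cx, cy = cy, r = r, shift = shift, noise_mult = noise_mult)
}

#' @rdname synthetic_slide_spec
#' @param x0,y0,x1,y1 stroke end points in level-0 pixels.
#' @param width stroke width in pixels.
#' @param color stroke RGB (default a green marker ink).
#' @export
ink_stroke <- function(x0, y0, x1, y1, width = 6,
                       color = c(0.10, 0.45, 0.20)) {
  list(x0 = x0, y0 = y0, x1 = x1, y1 = y1, width = width, color = color)
}

# Zero-mean, roughly unit-variance Gaussian random field with separable
# exponential correlation (AR(1) filtering along rows then columns).
gauss_field <- function(n, corr_length) {
  r <- exp(-1 / corr_length)
  z <- matrix(stats::rnorm(n * n), n, n)
  z <- apply(z, 2L, function(col)
    as.numeric(stats::filter(col, r, method = "recursive")))
  z <- t(apply(z, 1L, function(row)
    as.numeric(stats::filter(row, r, method = "recursive"))))
  z * (1 - r^2)
}

disc_polygon <- function(cx, cy, r, n = 64L) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(cx + r * cos(th), cy + r * sin(th))
}

#' Generate a synthetic slide and its truth annotation
#'
#' @param spec a `pcead_slide_spec`.
#' @return List with `slide` (a `pcead_slide`) and `truth` (a
#'   `pcead_polyset` of role `"annotated"` holding exactly the anomaly
#'   polygons).
#' @export
generate_slide <- function(spec) {
  local_seed(spec$seed)
  n <- spec$size
  img <- array(spec$background, c(n, n, 3L))
  m <- as.integer(round((spec$tissue$margin %||% 0.06) * n))
  tis <- matrix(FALSE, n, n)
  if (identical(spec$tissue$shape, "disc")) {
    cx <- n / 2; cy <- n / 2; r <- n / 2 - m
    xg <- matrix(rep(seq_len(n) - 0.5, each = n), n, n)  # x by column
    yg <- matrix(rep(seq_len(n) - 0.5, times = n), n, n) # y by row
    tis <- (xg - cx)^2 + (yg - cy)^2 <= r^2
  } else {
    tis[(m + 1L):(n - m), (m + 1L):(n - m)] <- TRUE
  }
  for (c in 1:3) {
    f <- gauss_field(n, spec$corr_length)
    ch <- img[, , c]
    ch[tis] <- spec$base_color[c] + spec$noise_sd * f[tis]
    img[, , c] <- ch
  }
  polys <- list()
  for (a in spec$anomalies) {
    ring <- disc_polygon(a$cx, a$cy, a$r)
    p <- list(exterior = ring, holes = list())
    p$area <- polygon_area(p)
    polys[[length(polys) + 1L]] <- p
    amask <- rasterize_polygons(
      polygon_set(list(p)), region = c(0, 0, n, n), downsample = 1)
    extra <- if (a$noise_mult != 1)
      spec$noise_sd * (a$noise_mult - 1) * gauss_field(n, spec$corr_length)
    else 0
    for (c in 1:3) {
      ch <- img[, , c]
      ch[amask] <- ch[amask] + a$shift[c] +
        (if (is.matrix(extra)) extra[amask] else 0)
      img[, , c] <- ch
    }
  }
  for (k in spec$inks) {
    imask <- rasterize_polygons(
      polygon_set(list(stroke_polygon(k))), region = c(0, 0, n, n),
      downsample = 1)
    for (c in 1:3) {
      ch <- img[, , c]
      ch[imask] <- k$color[c]
      img[, , c] <- ch
    }
  }
  img <- pmin(pmax(img, 0), 1)
  img <- round(img * 255) / 255        # 8-bit grid, as a scanner would emit
  list(slide = slide_source(img, spec$id),
       truth = polygon_set(polys, slide = spec$id, role = "annotated"))
}

stroke_polygon <- function(k) {
  dx <- k$x1 - k$x0; dy <- k$y1 - k$y0
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) len <- 1
  nx <- -dy / len * k$width / 2; ny <- dx / len * k$width / 2
  ring <- rbind(c(k$x0 + nx, k$y0 + ny), c(k$x1 + nx, k$y1 + ny),
                c(k$x1 - nx, k$y1 - ny), c(k$x0 - nx, k$y0 - ny))
  p <- list(exterior = ring, holes = list())
  p$area <- polygon_area(p)
  p
}

#' Oracle reconstructor: a deterministic stand-in for the trained GAN
#'
#' Reconstructs a patch by regressing it toward the normal-tissue base
#' colour: `recon = base + (1 - shrink) * (smooth(patch) - base)`, with an
#' optional Gaussian pre-smoothing. On normal texture the absolute error is
#' small (`shrink * |noise|`); on colour-shifted anomalous texture it is
#' systematically larger — exactly the contrast the frozen GAN provides,
#' through the same `reconstruct()` interface.
#'
#' @param base_color RGB triple the oracle assumes for normal tissue.
#' @param shrink regression weight toward the base colour, `(0, 1]`.
#' @param blur_sigma optional Gaussian smoothing bandwidth (pixels).
#' @return A `pcead_oracle` usable wherever a frozen model is.
#' @export
oracle_reconstructor <- function(base_color = c(0.80, 0.55, 0.68),
                                 shrink = 0.8, blur_sigma = 0) {
  stopifnot(shrink > 0, shrink <= 1)
  structure(list(base_color = base_color, shrink = shrink,
                 blur_sigma = blur_sigma),
            class = "pcead_oracle")
}

#' @export
reconstruct.pcead_oracle <- function(model, patch, ...) {
  img <- patch$image
  if (model$blur_sigma > 0)
    img <- EBImage::gblur(img, sigma = model$blur_sigma)
  out <- img
  for (c in 1:3)
    out[, , c] <- model$base_color[c] +
      (1 - model$shrink) * (img[, , c] - model$base_color[c])
  out <- pmin(pmax(out, 0), 1)
  new_patch(out, patch$slide, patch$x, patch$y, patch$span)
}

#' Generate a reproducible synthetic cohort with phase splits
#'
#' Writes `n_normal + n_tumor` slides (PNG) with per-slide truth GeoJSON
#' and a JSON manifest. Normal slides are assigned to the three training
#' phases by the split proportions (default 100:20:20 over 140, the
#' canonical normal-cohort split); tumor slides all go to the inference
#' split. Each tumor slide carries one anomalous disc whose area is a
#' uniform draw from `tumor_fraction_range` times the tissue area.
#'
#' @param out_dir output directory (created).
#' @param n_normal,n_tumor slide counts.
#' @param tumor_fraction_range range of tumor-to-tissue area fractions.
#' @param size slide side in pixels.
#' @param seed cohort seed; per-slide seeds are derived from it.
#' @param split_props normal-slide proportions for phases 1..3.
#' @param ... further arguments passed to [synthetic_slide_spec()].
#' @return The manifest, invisibly (list with `slides` data frame).
#' @export
make_cohort <- function(out_dir, n_normal = 10L, n_tumor = 5L,
                        tumor_fraction_range = c(0.03, 0.08),
                        size = 512L, seed = 1L,
                        split_props = c(phase1 = 100, phase2 = 20,
                                        phase3 = 20) / 140, ...) {
  stopifnot(n_normal + n_tumor >= 1L)
  dir.create(file.path(out_dir, "slides"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  local_seed(seed)
  n <- n_normal + n_tumor
  slide_seeds <- sample.int(.Machine$integer.max %/% 2L, n)
  phases <- c(split_counts(n_normal, split_props),
              rep("inference", n_tumor))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tumor <- i > n_normal
    id <- if (tumor) sprintf("tumor%03d", i - n_normal)
    else sprintf("normal%03d", i)
    anomalies <- list()
    frac <- 0
    if (tumor) {
      frac <- stats::runif(1, tumor_fraction_range[1],
                           tumor_fraction_range[2])
      margin <- 0.06 * size
      tissue_area <- (size - 2 * margin)^2
      r <- sqrt(frac * tissue_area / pi)
      lo <- margin + r + 2; hi <- size - margin - r - 2
      anomalies <- list(anomaly_disc(stats::runif(1, lo, hi),
                                     stats::runif(1, lo, hi), r))
    }
    sp <- synthetic_slide_spec(size = size, anomalies = anomalies,
                               id = id, seed = slide_seeds[i], ...)
    out <- generate_slide(sp)
    sfile <- file.path(out_dir, "slides", paste0(id, ".png"))
    tfile <- file.path(out_dir, "truth", paste0(id, ".geojson"))
    write_slide(out$slide, sfile)
    write_polygons(out$truth, tfile)
    rows[[i]] <- data.frame(
      id = id, type = if (tumor) "tumor" else "normal",
      phase = phases[i], file = file.path("slides", paste0(id, ".png")),
      truth = file.path("truth", paste0(id, ".geojson")),
      tumor_fraction = frac, slide_seed = slide_seeds[i],
      stringsAsFactors = FALSE)
  }
  manifest <- list(seed = seed, size = size,
                   slides = do.call(rbind, rows))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = I(17), auto_unbox = TRUE, dataframe = "rows")
  invisible(manifest)
}

# Largest-remainder apportionment of n normal slides over the phases.
split_counts <- function(n, props) {
  if (n == 0L) return(character(0))
  props <- props / sum(props)
  raw <- props * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(names(props), times = base)
}

#' Read a cohort manifest
#'
#' @param dir cohort directory written by [make_cohort()].
#' @return List with `seed`, `size` and the `slides` data frame.
#' @export
read_cohort <- function(dir) {
  jsonlite::fromJSON(file.path(dir, "manifest.json"))
}
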