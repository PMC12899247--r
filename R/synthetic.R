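#' Synthetic aerial scene configuration
#'
#' Configures the seeded generator of UAV-like wildlife scenes. The defaults
#' emulate the statistical profile of large drone wildlife surveys: six
#' classes with a strongly imbalanced frequency distribution, and a
#' log-normal box-side distribution whose median lies well below 32 px, so
#' most instances qualify as small objects.
#'
#' @param image_size square image side (default 640).
#' @param n_objects count, or range `c(min, max)` sampled uniformly.
#' @param size_meanlog,size_sdlog log-normal parameters of the box side in
#'   pixels (defaults give median 18 px, ~87% below 32 px).
#' @param n_classes number of classes (default 6).
#' @param class_probs sampling weights per class; the default follows the
#'   frequency ordering of real aerial wildlife surveys (class 0 dominant).
#' @param clutter_level background texture energy in \[0, 1\].
#' @param occlusion_fraction fraction of objects partially covered.
#' @param brightness_jitter per-object brightness jitter in \[0, 1\].
#' @param seed integer seed; same config + seed gives identical scenes.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(image_size = 640L, n_objects = c(3L, 20L),
                         size_meanlog = log(18), size_sdlog = 0.5,
                         n_classes = 6L,
                         class_probs = c(0.56, 0.27, 0.10, 0.029, 0.020, 0.023),
                         clutter_level = 0.5, occlusion_fraction = 0.1,
                         brightness_jitter = 0.2, seed = 0L) {
  stopifnot(image_size >= 32L, clutter_level >= 0, clutter_level <= 1,
            occlusion_fraction >= 0, occlusion_fraction <= 1)
  if (length(class_probs) != n_classes)
    class_probs <- rep(1 / n_classes, n_classes)
  structure(list(image_size = as.integer(image_size),
                 n_objects = as.integer(n_objects),
                 size_meanlog = size_meanlog, size_sdlog = size_sdlog,
                 n_classes = as.integer(n_classes),
                 class_probs = class_probs / sum(class_probs),
                 clutter_level = clutter_level,
                 occlusion_fraction = occlusion_fraction,
                 brightness_jitter = brightness_jitter,
                 seed = as.integer(seed)),
            class = "scene_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# multi-octave value noise in \[0, 1\]
value_noise <- function(n, octaves = c(4L, 8L, 16L), amp = c(1, 0.5, 0.25)) {
  acc <- matrix(0, n, n)
  for (i in seq_along(octaves)) {
    g <- octaves[i]
    grid <- matrix(runif((g + 1L)^2), g + 1L)
    pos <- seq(1, g + 1L - 1e-9, length.out = n)
    i0 <- pmin(floor(pos), g); f <- pos - i0
    a <- grid[i0, i0]; b <- grid[i0 + 1L, i0]
    cc <- grid[i0, i0 + 1L]; dd <- grid[i0 + 1L, i0 + 1L]
    fr <- matrix(f, n, n); fc <- matrix(f, n, n, byrow = TRUE)
    acc <- acc + amp[i] *
      ((a * (1 - fr) + b * fr) * (1 - fc) + (cc * (1 - fr) + dd * fr) * fc)
  }
  acc <- acc / sum(amp)
  (acc - min(acc)) / max(1e-12, diff(range(acc)))
}

# habitat palettes: desert, grassland, beach (dark/light RGB endpoints)
ywl_palettes <- list(
  desert = list(lo = c(0.62, 0.48, 0.30), hi = c(0.85, 0.74, 0.52)),
  grassland = list(lo = c(0.22, 0.38, 0.16), hi = c(0.52, 0.64, 0.32)),
  beach = list(lo = c(0.55, 0.52, 0.42), hi = c(0.88, 0.84, 0.70)))

# class appearance: body hue and aspect ratio (length/width)
ywl_class_looks <- list(
  list(col = c(0.92, 0.90, 0.86), aspect = 1.5),  # sheep: pale blob
  list(col = c(0.35, 0.22, 0.15), aspect = 1.8),  # cattle: dark brown
  list(col = c(0.45, 0.42, 0.40), aspect = 2.2),  # seal: gray, elongated
  list(col = c(0.72, 0.55, 0.35), aspect = 2.0),  # camelus: tan
  list(col = c(0.50, 0.35, 0.25), aspect = 1.9),  # kiang: chestnut
  list(col = c(0.25, 0.25, 0.28), aspect = 1.7))  # zebra: dark (striped)

#' Generate one synthetic aerial scene
#'
#' Procedural habitat background (multi-octave value noise through one of
#' three habitat palettes) with elliptical animal blobs of class-specific
#' color and aspect ratio. Bounding boxes are tight to the blobs and clipped
#' to the image; a configurable fraction of objects is partially occluded by
#' a background-colored strip.
#'
#' @param cfg a [scene_config()].
#' @return list with `image` (H x W x 3 array in \[0, 1\]) and `annotation`:
#'   a data frame with class_id, cx, cy, w, h (normalized) and `occluded`.
#' @export
generate_scene <- function(cfg = scene_config()) {
  with_seed(cfg$seed, {
    n <- cfg$image_size
    pal <- ywl_palettes[[sample.int(length(ywl_palettes), 1L)]]
    noise <- value_noise(n)
    noise <- 0.5 + cfg$clutter_level * (noise - 0.5)
    img <- array(0, dim = c(n, n, 3L))
    for (ch in 1:3)
      img[, , ch] <- pal$lo[ch] + noise * (pal$hi[ch] - pal$lo[ch])

    n_obj <- if (length(cfg$n_objects) == 2L)
      sample(cfg$n_objects[1L]:cfg$n_objects[2L], 1L) else cfg$n_objects[1L]
    ann <- data.frame(class_id = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0), occluded = logical(0))
    for (o in seq_len(n_obj)) {
      cl <- sample.int(cfg$n_classes, 1L, prob = cfg$class_probs) - 1L
      look <- ywl_class_looks[[cl %% length(ywl_class_looks) + 1L]]
      side <- rlnorm(1L, cfg$size_meanlog, cfg$size_sdlog)
      side <- min(max(side, 4), n / 4)
      if (side > n) stop("object larger than image")
      ww <- side * sqrt(look$aspect)
      hh <- side / sqrt(look$aspect)
      if (runif(1L) < 0.5) { t <- ww; ww <- hh; hh <- t }  # heading
      cx <- runif(1L, ww / 2, n - ww / 2)
      cy <- runif(1L, hh / 2, n - hh / 2)
      jit <- 1 + cfg$brightness_jitter * runif(1L, -1, 1)
      col <- pmin(pmax(look$col * jit, 0), 1)
      rows <- max(1L, floor(cy - hh / 2)):min(n, ceiling(cy + hh / 2))
      cols <- max(1L, floor(cx - ww / 2)):min(n, ceiling(cx + ww / 2))
      ry <- (rows - cy) / (hh / 2)
      rx <- (cols - cx) / (ww / 2)
      mask <- outer(ry^2, rx^2, `+`) <= 1
      occ <- runif(1L) < cfg$occlusion_fraction
      if (occ && length(rows) > 2L) {
        cut <- seq_len(max(1L, length(rows) %/% 3L))
        mask[cut, ] <- FALSE
      }
      for (ch in 1:3) {
        plane <- img[rows, cols, ch]
        plane[mask] <- col[ch]
        img[rows, cols, ch] <- plane
      }
      ann <- rbind(ann, data.frame(
        class_id = cl,
        cx = cx / n, cy = cy / n,
        w = min(ww, n) / n, h = min(hh, n) / n,
        occluded = occ))
    }
    list(image = img, annotation = ann)
  })
}

#' Write YOLO-format labels
#'
#' One line per object: `class cx cy w h`, all normalized to \[0, 1\] with
#' 6-decimal fixed precision.
#'
#' @param annotation data frame with class_id, cx, cy, w, h.
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
write_labels <- function(annotation, path) {
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", annotation$class_id,
                   annotation$cx, annotation$cy, annotation$w, annotation$h)
  writeLines(lines, path)
  invisible(path)
}

#' Read YOLO-format labels
#'
#' @param path label text file.
#' @return data frame with class_id, cx, cy, w, h.
#' @export
read_labels <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(class_id = integer(0), cx = numeric(0),
                      cy = numeric(0), w = numeric(0), h = numeric(0)))
  parts <- strsplit(trimws(lines), "\\s+")
  for (i in seq_along(parts)) {
    p <- suppressWarnings(as.numeric(parts[[i]]))
    if (length(p) != 5L || anyNA(p))
      stop("malformed label line ", i, ": ", lines[i])
  }
  m <- do.call(rbind, lapply(parts, as.numeric))
  data.frame(class_id = as.integer(m[, 1L]), cx = m[, 2L], cy = m[, 3L],
             w = m[, 4L], h = m[, 5L])
}

#' Object-size report
#'
#' Histogram of pixel box sides (the larger of width and height) and the
#' fraction of instances smaller than 32 x 32 pixels.
#'
#' @param annotations data frame (or list of data frames) with normalized
#'   w, h.
#' @param image_size pixels per unit of the normalized coordinates.
#' @return list with `sides` (pixel box sides), `histogram` and
#'   `fraction_below_32`.
#' @export
size_report <- function(annotations, image_size = 640L) {
  if (is.data.frame(annotations)) annotations <- list(annotations)
  sides <- unlist(lapply(annotations, function(a)
    pmax(a$w, a$h) * image_size))
  if (length(sides) == 0L) stop("size report requires at least one object")
  list(sides = sides,
       histogram = graphics::hist(sides, breaks = "Sturges", plot = FALSE),
       fraction_below_32 = mean(sides < 32))
}

#' Write a scene image as PNG
#'
#' @param image H x W x 3 array in \[0, 1\].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scene_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Generate a dataset directory
#'
#' Writes `images/` (PNG), `labels/` (YOLO txt) and a `dataset.yaml` manifest
#' listing the pairs with relative paths. Scene i uses seed `cfg$seed + i`.
#'
#' @param cfg a [scene_config()].
#' @param n number of scenes.
#' @param dir output directory.
#' @param force overwrite an existing non-empty directory.
#' @return the dataset manifest (list), invisibly.
#' @export
generate_dataset <- function(cfg, n, dir, force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) > 0L && !force)
    stop("output directory not empty (use force = TRUE): ", dir)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- cfg
    ci$seed <- cfg$seed + i
    sc <- generate_scene(ci)
    img_rel <- file.path("images", sprintf("scene_%04d.png", i))
    lab_rel <- file.path("labels", sprintf("scene_%04d.txt", i))
    write_scene_png(sc$image, file.path(dir, img_rel))
    write_labels(sc$annotation, file.path(dir, lab_rel))
    entries[[i]] <- list(image = img_rel, labels = lab_rel)
  }
  man <- list(image_size = cfg$image_size, n_classes = cfg$n_classes,
              seed = cfg$seed, items = entries)
  yaml::write_yaml(man, file.path(dir, "dataset.yaml"))
  invisible(man)
}
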