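#' Synthetic endoscopic scene specification
#'
#' Parameters of the generator that emulates the challenge structure of
#' endoscopic instrument datasets: thin, bright, elongated metallic
#' instruments entering from the image border over a reddish low-frequency
#' tissue texture, degraded by blur, glare, blood-like occlusion, smoke and
#' low contrast. The generator targets the statistical challenges
#' (class imbalance, degraded visibility, thin structures), not
#' photorealism.
#'
#' With `num_classes >= 3`, large amorphous "anatomy" regions labelled
#' `2 .. num_classes - 1` are added between background and instruments,
#' echoing multi-class laparoscopic datasets.
#'
#' @param height,width canvas in pixels (divisible by 8 for direct use with
#'   the default network; presets of 240 and 512 mirror common training
#'   resolutions).
#' @param num_classes 2 for binary instrument/background, >= 3 for the
#'   multi-class preset.
#' @param instrument_count_range integer `[lo, hi]` instruments per scene.
#' @param instrument_width_range instrument thickness in pixels.
#' @param instrument_length_range instrument length in pixels.
#' @param artifact_probabilities named probabilities in `[0, 1]` for
#'   `blur`, `glare`, `occlusion`, `smoke`, `low_contrast`.
#' @param background_texture_scale correlation length (pixels) of the
#'   background texture.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(height = 256L, width = 256L, num_classes = 2L,
                       instrument_count_range = c(1L, 2L),
                       instrument_width_range = c(8, 22),
                       instrument_length_range = c(0.4, 1.1) * height,
                       artifact_probabilities = c(blur = 0.30, glare = 0.25,
                                                  occlusion = 0.25,
                                                  smoke = 0.20,
                                                  low_contrast = 0.25),
                       background_texture_scale = 32L) {
  ap <- artifact_probabilities
  need <- c("blur", "glare", "occlusion", "smoke", "low_contrast")
  if (!all(need %in% names(ap))) stopf("artifact_probabilities must name: %s",
                                       paste(need, collapse = ", "))
  if (any(ap < 0 | ap > 1)) stopf("artifact probabilities must be in [0, 1]")
  stopifnot(instrument_count_range[2] >= instrument_count_range[1],
            instrument_count_range[1] >= 0,
            instrument_width_range[2] >= instrument_width_range[1],
            instrument_length_range[2] >= instrument_length_range[1])
  structure(list(height = as.integer(height), width = as.integer(width),
                 num_classes = as.integer(num_classes),
                 instrument_count_range = as.integer(instrument_count_range),
                 instrument_width_range = as.numeric(instrument_width_range),
                 instrument_length_range = as.numeric(instrument_length_range),
                 artifact_probabilities = ap[need],
                 background_texture_scale = as.integer(background_texture_scale)),
            class = "scene_spec")
}

# smooth random field in [0, 1]: coarse uniform grid, bilinear upsampling
smooth_noise <- function(H, W, scale) {
  gh <- max(2L, ceiling(H / scale) + 1L)
  gw <- max(2L, ceiling(W / scale) + 1L)
  g <- matrix(runif(gh * gw), gh, gw)
  yi <- seq(1, gh, length.out = H)
  xi <- seq(1, gw, length.out = W)
  y0 <- pmin(floor(yi), gh - 1L); x0 <- pmin(floor(xi), gw - 1L)
  fy <- yi - y0; fx <- xi - x0
  a <- g[cbind(rep(y0, W), rep(x0, each = H))]
  b <- g[cbind(rep(y0 + 1, W), rep(x0, each = H))]
  cc <- g[cbind(rep(y0, W), rep(x0 + 1, each = H))]
  d <- g[cbind(rep(y0 + 1, W), rep(x0 + 1, each = H))]
  fyr <- rep(fy, W); fxr <- rep(fx, each = H)
  v <- (a * (1 - fyr) + b * fyr) * (1 - fxr) + (cc * (1 - fyr) + d * fyr) * fxr
  matrix(v, H, W)
}

# separable Gaussian blur with replicate borders; robust for any image size
gaussian_blur <- function(img, sigma) {
  d <- dim(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  blur_rows <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    for (t in seq_along(k)) {
      idx <- pmin(pmax(seq_len(nrow(m)) + (t - r - 1L), 1L), nrow(m))
      out <- out + k[t] * m[idx, , drop = FALSE]
    }
    out
  }
  for (c in seq_len(d[3])) {
    ch <- blur_rows(img[, , c])
    img[, , c] <- t(blur_rows(t(ch)))
  }
  img
}

# distance of every pixel centre to the segment (p1, p2)
dist_to_segment <- function(H, W, p1, p2) {
  ys <- matrix(seq_len(H), H, W)
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  vx <- p2[2] - p1[2]; vy <- p2[1] - p1[1]
  len2 <- vx^2 + vy^2
  t <- ((xs - p1[2]) * vx + (ys - p1[1]) * vy) / max(len2, 1e-9)
  t <- pmin(pmax(t, 0), 1)
  sqrt((xs - (p1[2] + t * vx))^2 + (ys - (p1[1] + t * vy))^2)
}

#' Generate one synthetic scene
#'
#' Fully determined by `(spec, seed)`: the same call always returns a
#' bit-identical image and mask. The label mask is drawn before any
#' degradation is applied, so artifacts corrupt the image but never the
#' labels - mirroring real annotation, which describes the instrument, not
#' the imaging artifact.
#'
#' @param spec a [scene_spec()].
#' @param seed integer seed.
#' @return object of class `sample_pair`: list with `image`
#'   (`H x W x 3` in `[0, 1]`), `mask` (`H x W` integer labels, 0 =
#'   background, 1 = instrument, `2..` = anatomy), `seed`, and
#'   `applied_artifacts` (character vector).
#' @export
generate_scene <- function(spec, seed = 1L) {
  with_seed(seed, {
    H <- spec$height; W <- spec$width
    if (max(spec$instrument_length_range) > 2 * sqrt(H^2 + W^2)) {
      stopf("instrument length range exceeds the frame")
    }

    ## tissue background: reddish, low-frequency
    base_r <- 0.45 + 0.35 * smooth_noise(H, W, spec$background_texture_scale)
    base_g <- 0.10 + 0.18 * smooth_noise(H, W, spec$background_texture_scale)
    base_b <- 0.08 + 0.15 * smooth_noise(H, W, spec$background_texture_scale)
    img <- array(c(base_r, base_g, base_b), dim = c(H, W, 3))
    mask <- matrix(0L, H, W)

    ## amorphous anatomy regions for the multi-class preset
    if (spec$num_classes >= 3L) {
      tints <- list(c(0.85, 0.75, 0.35), c(0.55, 0.30, 0.20),
                    c(0.80, 0.55, 0.50), c(0.60, 0.50, 0.60))
      for (k in 2L:(spec$num_classes - 1L)) {
        field <- smooth_noise(H, W, max(16L, spec$background_texture_scale * 2L))
        region <- field > stats::quantile(field, 0.72)
        mask[region] <- k
        tint <- tints[[((k - 2L) %% length(tints)) + 1L]]
        alpha <- 0.65
        for (c in 1:3) {
          ch <- img[, , c]
          ch[region] <- (1 - alpha) * ch[region] + alpha * tint[c]
          img[, , c] <- ch
        }
      }
    }

    ## instruments: anti-aliased capsules entering from a border
    n_ins <- if (spec$instrument_count_range[2] == 0L) 0L else
      sample(spec$instrument_count_range[1]:spec$instrument_count_range[2], 1L)
    for (i in seq_len(n_ins)) {
      side <- sample(4L, 1L)
      entry <- switch(side,
                      c(1, runif(1, 1, W)), c(H, runif(1, 1, W)),
                      c(runif(1, 1, H), 1), c(runif(1, 1, H), W))
      centre <- c(runif(1, 0.3 * H, 0.7 * H), runif(1, 0.3 * W, 0.7 * W))
      dir <- centre - entry + rnorm(2, 0, 0.15 * min(H, W))
      dir <- dir / max(sqrt(sum(dir^2)), 1e-9)
      len <- runif(1, spec$instrument_length_range[1], spec$instrument_length_range[2])
      wid <- runif(1, spec$instrument_width_range[1], spec$instrument_width_range[2])
      tip <- entry + dir * len
      d <- dist_to_segment(H, W, entry, tip)
      inside <- d <= wid / 2
      cover <- pmin(pmax(wid / 2 + 0.5 - d, 0), 1) # anti-aliasing ramp
      # metallic shading: bright gray with a specular stripe off-axis
      shade <- 0.55 + 0.25 * smooth_noise(H, W, 64L)
      stripe <- exp(-((d - wid / 6) / (wid / 5))^2)
      tone <- pmin(shade + 0.45 * stripe, 1)
      tint <- c(1, 1, 1.06)
      for (c in 1:3) {
        ch <- img[, , c]
        ch <- (1 - cover) * ch + cover * pmin(tone * 0.95 * tint[c], 1)
        img[, , c] <- ch
      }
      mask[inside] <- 1L
    }

    ## degradations (image only; the mask is final)
    applied <- character(0)
    strengths <- list(blur = c(0.8, 2.2), glare = c(0.25, 0.7),
                      occlusion = c(0.35, 0.8), smoke = c(0.25, 0.6),
                      low_contrast = c(0.3, 0.65))
    for (art in names(spec$artifact_probabilities)) {
      if (runif(1) < spec$artifact_probabilities[[art]]) {
        s <- runif(1, strengths[[art]][1], strengths[[art]][2])
        img <- degrade(img, art, s, seed = sample.int(.Machine$integer.max, 1L))
        applied <- c(applied, art)
      }
    }
    img <- pmin(pmax(img, 0), 1)
    dim(img) <- c(H, W, 3L)

    structure(list(image = img, mask = mask, seed = as.integer(seed),
                   applied_artifacts = applied),
              class = "sample_pair")
  })
}

#' Apply one image degradation
#'
#' Supported artifacts: `blur` (Gaussian, sigma = `2 * strength` pixels),
#' `glare` (additive saturated bright blob), `occlusion` (semi-transparent
#' dark-red blot), `smoke` (low-frequency white haze), `low_contrast`
#' (range compression toward mid-gray). `strength = 0` is the identity;
#' output is clipped to `[0, 1]`.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param artifact artifact name.
#' @param strength nonnegative scalar (roughly `[0, 1]`; blur sigma scales
#'   with it).
#' @param seed integer seed for the artifact's random placement.
#' @return degraded image, same shape.
#' @export
degrade <- function(image, artifact, strength, seed = 1L) {
  if (strength == 0) return(image)
  d <- dim(image)
  H <- d[1]; W <- d[2]
  out <- with_seed(seed, switch(artifact,
    blur = gaussian_blur(image, sigma = 2 * strength),
    glare = {
      cy <- runif(1, 0.2 * H, 0.8 * H); cx <- runif(1, 0.2 * W, 0.8 * W)
      r <- runif(1, 0.08, 0.2) * min(H, W)
      ys <- matrix(seq_len(H), H, W); xs <- matrix(rep(seq_len(W), each = H), H, W)
      blob <- exp(-((ys - cy)^2 + (xs - cx)^2) / (2 * r^2))
      image + strength * 1.5 * array(rep(blob, 3), dim = d)
    },
    occlusion = {
      cy <- runif(1, 0.2 * H, 0.8 * H); cx <- runif(1, 0.2 * W, 0.8 * W)
      r <- runif(1, 0.1, 0.25) * min(H, W)
      ys <- matrix(seq_len(H), H, W); xs <- matrix(rep(seq_len(W), each = H), H, W)
      blob <- pmin(exp(-((ys - cy)^2 + (xs - cx)^2) / (2 * r^2)) * 2, 1)
      alpha <- strength * array(rep(blob, 3), dim = d)
      tint <- array(rep(c(0.30, 0.02, 0.02), each = H * W), dim = d)
      (1 - alpha) * image + alpha * tint
    },
    smoke = {
      haze <- smooth_noise(H, W, max(24L, floor(min(H, W) / 6)))
      a <- strength * array(rep(haze, 3), dim = d)
      (1 - a) * image + a
    },
    low_contrast = 0.5 + (image - 0.5) * (1 - strength),
    stopf("unknown artifact '%s'", artifact)))
  out <- pmin(pmax(out, 0), 1)
  dim(out) <- d
  out
}

#' Merge rare classes by relabeling
#'
#' Pixel-wise relabeling under a total mapping, the standard preprocessing
#' that pools severely underrepresented classes into a single "Misc" class.
#' The mapping must cover every label present in the mask; pixel count is
#' conserved.
#'
#' @param mask integer label mask.
#' @param mapping named integer vector: `names` are old labels, values new
#'   labels, e.g. `c("0" = 0, "1" = 1, "7" = 6, ...)`.
#' @return relabeled mask, same shape.
#' @export
merge_rare_classes <- function(mask, mapping) {
  labs <- sort(unique(as.integer(mask)))
  missing <- setdiff(as.character(labs), names(mapping))
  if (length(missing)) stopf("mask contains unmapped labels: %s",
                             paste(missing, collapse = ", "))
  out <- mask
  for (old in names(mapping)) {
    out[mask == as.integer(old)] <- as.integer(mapping[[old]])
  }
  out
}

#' Write / read an image-mask pair as PNG files
#'
#' The image is stored as 8-bit RGB PNG (round-trip error at most 1/255 per
#' channel); the mask as a single-channel 8-bit PNG whose pixel values are
#' the label indices, which round-trips losslessly for up to 256 classes.
#'
#' @param pair a `sample_pair` (or any list with `image` and `mask`).
#' @param image_path,mask_path file paths.
#' @export
write_pair <- function(pair, image_path, mask_path) {
  png::writePNG(pair$image, image_path)
  png::writePNG(matrix(pair$mask / 255, nrow(pair$mask), ncol(pair$mask)),
                mask_path)
  invisible(c(image_path, mask_path))
}

#' @rdname write_pair
#' @return `read_pair`: a `sample_pair` with the stored image and mask.
#' @export
read_pair <- function(image_path, mask_path) {
  img <- png::readPNG(image_path)
  mraw <- png::readPNG(mask_path)
  if (length(dim(mraw)) == 3L) mraw <- mraw[, , 1]
  mask <- matrix(as.integer(round(mraw * 255)), nrow(mraw), ncol(mraw))
  if (!identical(dim(img)[1:2], dim(mask))) {
    stopf("image (%s) and mask (%s) sizes differ on disk",
          paste(dim(img)[1:2], collapse = "x"), paste(dim(mask), collapse = "x"))
  }
  structure(list(image = img, mask = mask, seed = NA_integer_,
                 applied_artifacts = character(0)),
            class = "sample_pair")
}

#' Generate a dataset on disk with a manifest
#'
#' Writes `n` scenes as PNG pairs plus a `manifest.csv` (paths, applied
#' artifacts, per-class pixel counts) and the generator spec as YAML.
#' Deterministic given `(spec, n, seed)`.
#'
#' @param spec a [scene_spec()].
#' @param n number of scenes.
#' @param dir output directory (created if needed).
#' @param seed master seed; scene `i` uses a child seed derived from it.
#' @return the manifest as a data.frame (invisibly also written to disk).
#' @export
generate_dataset <- function(spec, n, dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pair <- generate_scene(spec, seed = child_seed(seed, i))
    ip <- file.path(dir, sprintf("img_%04d.png", i))
    mp <- file.path(dir, sprintf("mask_%04d.png", i))
    write_pair(pair, ip, mp)
    cnt <- tabulate(as.integer(pair$mask) + 1L, nbins = spec$num_classes)
    row <- data.frame(image = basename(ip), mask = basename(mp),
                      artifacts = paste(pair$applied_artifacts, collapse = ";"))
    for (k in seq_len(spec$num_classes)) row[[paste0("px_class", k - 1L)]] <- cnt[k]
    rows[[i]] <- row
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  yaml::write_yaml(unclass(spec), file.path(dir, "scene_spec.yaml"))
  invisible(manifest)
}

#' Load a generated dataset from its manifest
#'
#' @param dir directory written by [generate_dataset()].
#' @return list of `sample_pair`s.
#' @export
load_dataset <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    read_pair(file.path(dir, manifest$image[i]), file.path(dir, manifest$mask[i]))
  })
}

#' Generate an in-memory list of scenes
#'
#' @inheritParams generate_dataset
#' @return list of `sample_pair`s.
#' @export
generate_pairs <- function(spec, n, seed = 1L) {
  lapply(seq_len(n), function(i) generate_scene(spec, seed = child_seed(seed, i)))
}
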