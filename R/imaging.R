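# Rendering standardized molecules as fixed-size Kekule structure images
# and stochastic training-time augmentation.
#
# Depictions use 2D coordinates from OpenBabel and the ChemmineR
# structure plotter on an off-screen cairo PNG device: dark bonds with
# explicit double/triple bond lines, element-colored heteroatom labels,
# white background. The raster itself is the contract; rendering
# settings are captured in a provenance hash so images from different
# settings are never silently mixed.

# Per-channel input statistics the classic backbones were trained
# against (the conventional ImageNet normalization constants).
IMAGE_CHANNEL_MEAN <- c(0.485, 0.456, 0.406)
IMAGE_CHANNEL_SD <- c(0.229, 0.224, 0.225)

render_settings <- function(size, atomcex, lwd) {
  list(renderer = "ChemmineR::plotStruc", size = as.integer(size),
       atomcex = atomcex, lwd = lwd,
       chemminer = as.character(utils::packageVersion("ChemmineR")))
}

#' Render a molecule as a Kekule structure image
#'
#' Generates 2D depiction coordinates, draws the structure on a white
#' square canvas and returns the raster as an 8-bit RGB array. Identical
#' input and settings give identical pixel content.
#'
#' @param smiles Canonical SMILES of a standardized molecule.
#' @param compound_id Identifier attached to the image.
#' @param size Canvas edge in pixels; backbones expect 224, other sizes
#'   are allowed but flagged with a warning.
#' @param atomcex Character expansion for atom labels.
#' @param lwd Bond stroke width in device pixels. The default is
#'   deliberately heavy: hairline strokes lose most of their energy to
#'   the aggressive striding of the first backbone convolution, so bonds
#'   are drawn thick enough to survive downsampling.
#' @return An object of class `rendered_image`: list with `compound_id`,
#'   `pixels` (`size x size x 3` integer array, 0-255) and `provenance`
#'   (hash of the rendering settings).
#' @export
render_kekule <- function(smiles, compound_id = smiles, size = 224L,
                          atomcex = 1.3, lwd = 3) {
  if (size != 224L) {
    warning("image size ", size, " != 224; pretrained-style backbones ",
            "expect 224 x 224 input", call. = FALSE)
  }
  sdf_text <- suppressWarnings(tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n"),
                              options = data.frame(names = "gen2d", args = "")),
    error = function(e) ""
  ))
  if (!nzchar(sdf_text) || !grepl("V2000", sdf_text, fixed = TRUE)) {
    stop("cannot generate a Kekule depiction for compound '", compound_id,
         "' (structure: ", smiles, ")", call. = FALSE)
  }
  sdfset <- methods::as(ChemmineR::read.SDFstr(strsplit(sdf_text, "\n")[[1]]),
                        "SDFset")
  tmp <- tempfile(fileext = ".png")
  on.exit(unlink(tmp), add = TRUE)
  grDevices::png(tmp, width = size, height = size, type = "cairo",
                 bg = "white")
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i", lwd = lwd)
  ChemmineR::plotStruc(sdfset[[1]], atomcex = atomcex)
  grDevices::dev.off()
  px <- png::readPNG(tmp)
  if (length(dim(px)) == 3 && dim(px)[3] > 3) px <- px[, , 1:3, drop = FALSE]
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  pixels <- array(as.integer(round(px * 255)), dim(px))
  structure(list(compound_id = compound_id, pixels = pixels,
                 provenance = content_hash(render_settings(size, atomcex,
                                                           lwd))),
            class = "rendered_image")
}

#' Content hash of a rendered image
#'
#' @param image A `rendered_image` or a pixel array.
#' @return Character hash of the pixel content.
#' @export
image_hash <- function(image) {
  px <- if (inherits(image, "rendered_image")) image$pixels else image
  content_hash(as.integer(px))
}

#' Render a compound library to PNG files with a manifest
#'
#' Writes one `<compound_id>.png` per compound plus `manifest.csv`
#' mapping compound id to path, provenance hash and content hash.
#' Compounds whose file already exists with the current provenance hash
#' are not re-rendered; a change of settings invalidates the cache.
#'
#' @param smiles Named character vector (names are compound ids).
#' @param dir Output directory (created if missing).
#' @param size,atomcex,lwd Passed to [render_kekule()].
#' @return The manifest data frame, invisibly also written to `dir`.
#' @export
render_library <- function(smiles, dir, size = 224L, atomcex = 1.3,
                           lwd = 3) {
  assert_that(!is.null(names(smiles)) && all(nzchar(names(smiles))),
              "`smiles` must be named by compound id")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(dir, "manifest.csv")
  old <- if (file.exists(manifest_path)) {
    utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  } else NULL
  prov <- content_hash(render_settings(size, atomcex, lwd))
  rows <- lapply(names(smiles), function(id) {
    path <- file.path(dir, paste0(id, ".png"))
    if (!is.null(old) && id %in% old$compound_id &&
        old$provenance[match(id, old$compound_id)] == prov &&
        file.exists(path)) {
      return(old[match(id, old$compound_id), , drop = FALSE])
    }
    img <- render_kekule(smiles[[id]], id, size = size, atomcex = atomcex,
                         lwd = lwd)
    png::writePNG(img$pixels / 255, path)
    data.frame(compound_id = id, path = path, provenance = prov,
               content_hash = image_hash(img), stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  row.names(manifest) <- NULL
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(manifest)
}

#' Load rendered images from a library directory
#'
#' @param manifest Manifest data frame from [render_library()].
#' @return Named list of 8-bit pixel arrays.
#' @export
load_rendered <- function(manifest) {
  imgs <- lapply(seq_len(nrow(manifest)), function(i) {
    px <- png::readPNG(manifest$path[i])
    if (length(dim(px)) == 3 && dim(px)[3] > 3) px <- px[, , 1:3, drop = FALSE]
    array(as.integer(round(px * 255)), dim(px))
  })
  stats::setNames(imgs, manifest$compound_id)
}

# ---- augmentation -----------------------------------------------------------

#' Stochastic augmentation policy
#'
#' Each transform — horizontal flip, vertical flip, and a 90 degree
#' rotation whose direction is drawn uniformly — is applied
#' independently with its own probability, freshly at every epoch.
#'
#' @param horizontal_flip_prob,vertical_flip_prob,rot90_prob Application
#'   probabilities (default 0.5 each).
#' @param enabled Master switch; a disabled policy is the identity.
#' @return An object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(horizontal_flip_prob = 0.5,
                                vertical_flip_prob = 0.5,
                                rot90_prob = 0.5,
                                enabled = TRUE) {
  for (p in c(horizontal_flip_prob, vertical_flip_prob, rot90_prob)) {
    assert_that(p >= 0 && p <= 1, "probabilities must lie in [0, 1]")
  }
  structure(list(horizontal_flip_prob = horizontal_flip_prob,
                 vertical_flip_prob = vertical_flip_prob,
                 rot90_prob = rot90_prob, enabled = enabled),
            class = "augmentation_policy")
}

flip_h <- function(x) x[, dim(x)[2]:1, , drop = FALSE]
flip_v <- function(x) x[dim(x)[1]:1, , , drop = FALSE]
rot_cw <- function(x) aperm(x[dim(x)[1]:1, , , drop = FALSE], c(2, 1, 3))
rot_ccw <- function(x) rot_cw(rot_cw(rot_cw(x)))

# Draw which transforms apply; returns a composed function and the draws.
draw_augmentation <- function(policy) {
  u <- stats::runif(4)
  list(
    hflip = u[1] < policy$horizontal_flip_prob,
    vflip = u[2] < policy$vertical_flip_prob,
    rot = u[3] < policy$rot90_prob,
    clockwise = u[4] < 0.5
  )
}

apply_augmentation <- function(x, draw) {
  if (draw$hflip) x <- flip_h(x)
  if (draw$vflip) x <- flip_v(x)
  if (draw$rot) x <- if (draw$clockwise) rot_cw(x) else rot_ccw(x)
  x
}

#' Apply stochastic augmentation to an image
#'
#' Consumes the current RNG stream; seed the session (or wrap the call)
#' for reproducibility. Spatial dimensions are preserved for square
#' images, and any composition of the three transforms is an element of
#' the 8-element dihedral group.
#'
#' @param x Pixel array `(H, W, 3)`.
#' @param policy An [augmentation_policy()].
#' @return The transformed pixel array.
#' @export
augment_image <- function(x, policy = augmentation_policy()) {
  if (!isTRUE(policy$enabled)) return(x)
  apply_augmentation(x, draw_augmentation(policy))
}

# Key identifying a dihedral element by its action on a 2x2 probe.
dihedral_key <- function(f) {
  probe <- array(1:4, c(2, 2, 1))
  paste(as.integer(f(probe)), collapse = "")
}

# All 8 dihedral transforms of a square image, as named functions.
dihedral_transforms <- function() {
  gens <- list(identity = identity, h = flip_h, v = flip_v, cw = rot_cw,
               ccw = rot_ccw, hv = function(x) flip_v(flip_h(x)),
               hcw = function(x) rot_cw(flip_h(x)),
               vcw = function(x) rot_cw(flip_v(x)))
  keys <- vapply(gens, dihedral_key, character(1))
  gens[!duplicated(keys)]
}

#' Normalize an 8-bit image for a backbone
#'
#' Scales intensities to `[0, 1]` and standardizes each channel with the
#' fixed per-channel mean/SD constants the classic backbones expect,
#' returning a channel-first tensor.
#'
#' @param x Pixel array `(H, W, 3)` with 0-255 intensities.
#' @return Numeric array `(3, H, W)`.
#' @export
normalize_for_backbone <- function(x) {
  d <- dim(x)
  y <- aperm(x / 255, c(3, 1, 2))
  (y - IMAGE_CHANNEL_MEAN) / IMAGE_CHANNEL_SD
}

#' @rdname normalize_for_backbone
#' @param z Normalized channel-first tensor.
#' @return `denormalize_image` returns the 8-bit-scale `(H, W, 3)` array
#'   (numeric, not rounded).
#' @export
denormalize_image <- function(z) {
  y <- z * IMAGE_CHANNEL_SD + IMAGE_CHANNEL_MEAN
  aperm(y, c(2, 3, 1)) * 255
}
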