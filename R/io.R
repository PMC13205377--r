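#' Read and write genotype tables
#'
#' Genotypes travel as CSV/TSV with a header row of marker ids, one row per
#' animal, first column `animal_id`, additive 0/1/2 integer codes. The
#' round trip is lossless.
#'
#' @param geno A `geno_matrix`.
#' @param path File path (`.csv` or `.tsv`).
#' @return `write_genotypes()` returns `path` invisibly; `read_genotypes()`
#'   a `geno_matrix`.
#' @export
write_genotypes <- function(geno, path) {
  df <- as_tibble(geno$codes)
  df <- dplyr::bind_cols(tibble(animal_id = rownames(geno$codes)), df)
  if (grepl("\\.tsv$", path)) readr::write_tsv(df, path)
  else readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  df <- reader(path, show_col_types = FALSE, progress = FALSE)
  codes <- as.matrix(df[-1])
  if (!all(codes %in% 0:2))
    abort("genotype codes must be 0, 1 or 2.")
  storage.mode(codes) <- "integer"
  rownames(codes) <- df[[1]]
  structure(list(codes = codes, allele_freq = colMeans(codes) / 2,
                 drawn_freq = NULL,
                 pedigree = tibble(animal_id = df[[1]],
                                   sire = NA_character_,
                                   dam = NA_character_)),
            class = "geno_matrix")
}

#' Read and write phenotype/covariate tables
#'
#' One row per animal x time point, CSV.
#'
#' @param data Phenotype tibble.
#' @param path File path.
#' @export
write_phenotypes <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a depth video as PNG frames plus CSV distance maps
#'
#' Each frame becomes `<stem>_NNN.png` (pseudo-color rendering) and
#' `<stem>_NNN.csv` (comma-separated distances in metres, one line per pixel
#' row, no header), mirroring a depth-camera export layout.
#'
#' @param video A `depth_video`.
#' @param dir Output directory (created if needed).
#' @param stem Filename stem (default `"frame"`).
#' @return The directory, invisibly.
#' @export
write_depth_video <- function(video, dir, stem = "frame") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(video$frames)) {
    fr <- video$frames[[i]]
    png::writePNG(frame_color(fr),
                  file.path(dir, sprintf("%s_%03d.png", stem, i)))
    dmap <- fr$distance_map
    lines <- apply(dmap, 1, function(r) paste(format(r, digits = 9),
                                              collapse = ","))
    writeLines(lines, file.path(dir, sprintf("%s_%03d.csv", stem, i)))
  }
  invisible(dir)
}

read_distance_csv <- function(path) {
  lines <- readLines(path)
  rows <- strsplit(lines, ",", fixed = TRUE)
  ncols <- length(rows[[1]])
  out <- matrix(NA_real_, length(rows), ncols)
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]]))
    if (length(v) != ncols || anyNA(v)) {
      bad <- which(is.na(v))[1]
      abort(sprintf("parse error in %s at row %d, column %s",
                    basename(path), i,
                    if (length(v) != ncols) "(ragged row)" else bad))
    }
    out[i, ] <- v
  }
  out
}

#' Read a depth video from paired PNG/CSV frames
#'
#' Pairs every `*.png` in `dir` with its same-stem `*.csv` distance map. The
#' PNG and CSV of a frame must have identical dimensions; a mismatch is an
#' error naming the frame. The hue channel is recovered from the PNG; the
#' distance map is taken from the CSV (exact metres).
#'
#' @param dir Directory of frames written by [write_depth_video()].
#' @param camera_height Camera height (m).
#' @param hue_max Floor hue (degrees).
#' @return A `depth_video`.
#' @export
read_depth_video <- function(dir, camera_height = 1.40, hue_max = 240) {
  pngs <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(pngs)) abort(paste0("no PNG frames in ", dir))
  frames <- lapply(seq_along(pngs), function(i) {
    pth <- pngs[i]
    csv <- sub("\\.png$", ".csv", pth)
    if (!file.exists(csv))
      abort(paste0("missing distance map for frame ", basename(pth)))
    dmap <- read_distance_csv(csv)
    img <- png::readPNG(pth)
    if (!identical(dim(img)[1:2], dim(dmap)))
      abort(sprintf("dimension mismatch between %s (%dx%d) and its CSV (%dx%d)",
                    basename(pth), dim(img)[1], dim(img)[2],
                    nrow(dmap), ncol(dmap)))
    fr <- depth_frame(dmap, camera_height, hue_max, frame_index = i)
    # hue from the PNG (quantized); distance map stays exact from the CSV
    r <- img[, , 1]
    g <- img[, , 2]
    b <- img[, , 3]
    mx <- pmax(r, g, b)
    mn <- pmin(r, g, b)
    delta <- mx - mn
    h <- matrix(0, nrow(r), ncol(r))
    idx <- delta > 0 & mx == r
    h[idx] <- ((g - b)[idx] / delta[idx]) %% 6
    idx <- delta > 0 & mx == g & mx != r
    h[idx] <- (b - r)[idx] / delta[idx] + 2
    idx <- delta > 0 & mx == b & mx != r & mx != g
    h[idx] <- (r - g)[idx] / delta[idx] + 4
    fr$hue <- h * 60
    fr
  })
  structure(list(frames = frames, shape = NULL,
                 camera_height = camera_height, hue_max = hue_max),
            class = "depth_video")
}

#' Read or write an experiment configuration as YAML
#'
#' @param config An `experiment_config`.
#' @param path YAML file path.
#' @export
write_experiment_config <- function(config, path) {
  lst <- unclass(config)
  lst$sim <- unclass(lst$sim)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  lst <- yaml::read_yaml(path)
  sim <- do.call(sim_config, lst$sim)
  lst$sim <- NULL
  do.call(experiment_config, c(list(sim = sim), lst))
}
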